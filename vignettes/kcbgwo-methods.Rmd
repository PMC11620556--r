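---
title: "Clustered grey wolf optimization, extreme learning machines, and rule-based lesion screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustered grey wolf optimization, extreme learning machines, and rule-based lesion screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kcbgwo)
```

This vignette is the package's account of its methods: the models, the
choices made where the design was genuinely open, and what the synthetic
test beds do and do not establish.

## The optimizer

### Grey wolf mechanics

Grey wolf optimization mimics a pack hunt. The three fittest wolves
(alpha, beta, delta) define the current estimate of the prey's location;
every wolf takes one stochastic step toward each leader and lands on the
average. For a leader at $X_p$ and a wolf at $X$:

$$K = |C \circ X_p - X|, \qquad \text{cand}_p = X_p - A \circ K,$$

with $A = 2 a r_1 - a$ and $C = 2 r_2$ drawn per dimension
($r_1, r_2 \sim U[0,1]$), and the control parameter decaying linearly,
$a(\tau) = 2 - 2\tau/T$. Early on $|A|$ can exceed 1, producing steps that
overshoot the leaders (exploration); by the end $A \to 0$ and every wolf
collapses onto its leaders (exploitation). The new continuous position is
the mean of the three candidates, clamped to the box. `control_parameter()`,
`sample_coefficients()`, `leader_component()` and `blend_components()`
expose these pieces individually; each is unit-tested against a literal
elementwise transcription.

### The k-means clustering layer

Plain GWO uses one global leader triple, which drains population diversity
quickly. KCBGWO instead partitions the pack with Lloyd's k-means
(Euclidean, centroids initialized from $K$ sampled wolves, empty clusters
re-seeded at a random wolf) and assigns an alpha/beta/delta hierarchy
*inside each cluster*; every wolf follows its own cluster's leaders. The
pack is re-clustered every iteration by default (`recluster_period`
exposes the cost knob). Clusters with fewer than four members fill their
missing leader roles with their best wolf. The globally best wolf is
tracked for reporting and for the optional early-stop threshold, but does
not steer other clusters.

Two consequences we rely on in tests: with $K = 1$ the algorithm is
*step-identical* to standard GWO (verified bit-for-bit under shared random
draws), and the within-cluster sum of squares never increases within one
partitioning call.

The k-means step is implemented in the package rather than delegated to
`stats::kmeans` because the partitioning is part of the method itself and
needs specific degenerate-case behavior (duplicate positions are routine
in binary packs, where `stats::kmeans` refuses duplicate centers; empty
clusters are re-seeded from a random wolf; the per-iteration objective
trace backs a monotonicity test). `stats::kmeans` serves as an independent
cross-check on well-conditioned data in the test suite.

### Binary mode

Binary problems keep the same leader guidance but resample each bit with
probability $\sigma(\bar c)$, where $\bar c$ is the mean of the three
leader-guided components and $\sigma(x) = 1/(1+e^{-x})$; the bit becomes 1
iff a fresh uniform draw is strictly below the probability. One property of
these dynamics is worth knowing: because positions are bits, the candidate
components converge to the leader's bit values, so the bit-set probability
saturates at $\sigma(1) \approx 0.73$ rather than 1. Even a fully converged
pack keeps flipping bits — on a 20-bit OneMax problem a (20 wolves, 100
iterations) budget finds the exact optimum in roughly 70% of seeds and is
within one bit otherwise. The test suite asserts exactly that behavior
rather than pretending the dynamics are deterministic.

### Randomness and reproducibility

Each run consumes one R RNG stream seeded from `config$seed`. The draw
order is documented and fixed: initialization fills the $N \times D$
position matrix column-wise; per iteration, wolves are updated in index
order, leaders in alpha/beta/delta order, $r_1$ before $r_2$, and (binary
mode) the per-dimension acceptance draws after a wolf's coefficient draws.
The re-clustering step runs under its own seed derived from
(run seed, iteration) and restores the main stream afterwards, so
clustering never perturbs the update draws — this is what makes the
$K = 1 \equiv$ GWO equivalence exact rather than merely statistical.

### Hyperparameter encodings

`encode_search_space()` maps finite parameter domains onto a bit string
($\lceil \log_2 |\text{domain}| \rceil$ bits per parameter, most
significant bit first); decoding indexes the domain modulo its size, so
*every* bit string is a valid setting and the binary optimizer needs no
repair step. The wrap intentionally makes some settings slightly more
probable (those aliased by the modulo); with typical domain sizes this bias
is small, and totality is worth more than uniformity here.

## The benchmark suite and trial protocol

Ten classical functions (Sphere; Schwefel 2.22, 1.2, 2.21; Generalized
Rosenbrock; Generalized Schwefel 2.26; Rastrigin; Ackley; Griewank;
Generalized Penalized No. 1) with their standard domains, at $D = 30$ by
default — the conventional setting for this suite. Schwefel 2.26 is
shifted by $418.9829\,D$ so its optimum is approximately zero and reported
values are positive. Every evaluator is verified at its known minimizer
and against an independent loop transcription on random points.

The trial protocol runs an optimizer $R$ times (run $i$ seeded
`base_seed + i`), records each run's best value, and reports mean and
standard deviation — the standard comparison table layout (default
$R = 30$, population 30, 500 iterations). `pso_minimize()` supplies a
textbook global-best PSO baseline ($w = 0.729$, $c_1 = c_2 = 1.49445$,
velocity clamped to half the box width). A genetic-algorithm baseline is
out of scope. Registered optimizer ids: `kcbgwo`, `gwo` (= $K = 1$
continuous), `bgwo` (= $K = 1$ binary, exploring the $\{0,1\}^D$ corners —
the only meaningful reading of a binary optimizer on a continuous box),
`pso`.

The default update uses the plain three-leader mean. A
`leader_blend_weights` hook accepts a length-3 weight vector, but no
weighting is applied by default: there is no defining equation for a
weighted variant we trust, and the unweighted mean is the established
form.

## The extreme learning machine

A single-hidden-layer network with $G$ hidden nodes: input weights
$a \in \mathbb{R}^{G \times n}$ and biases $c \in \mathbb{R}^G$ are drawn
uniformly in $[-1, 1]$ and never trained; the hidden response matrix is
$M_{ji} = f(a_i \cdot x_j + c_i)$, and the output weights solve
$M w = T$ in closed form via the Moore-Penrose pseudoinverse,
$w = M^+ T$. We compute $M^+$ by SVD with singular values below
$10^{-10} \sigma_{\max}$ treated as zero; this tolerates rank-deficient
$M$ (duplicate samples) gracefully. With $G$ equal to the number of
distinct samples, $M$ is square and generically invertible, so the network
interpolates its targets — the test suite holds this to MSE
$\le 10^{-6}$ across 50 seeds.

Multi-class targets are one-hot encoded and predictions taken by row-wise
arg-max (ties to the first class, for determinism). The bias draw range
matches the weight range $[-1,1]$. Default activation is the sigmoid;
`tanh` and `linear` are available.

### KCBGWO-ELM

`tune_elm()` couples the two: a candidate is the flattened
$(a, c)$ vector (dimension $G(n+1)$, bounds $[-1,1]$ — the same range the
random initializer uses), and its fitness is the MSE between one-hot
targets and the outputs of the ELM whose output weights are solved on the
spot. By default fitness is measured on the training split itself (the
literal reading of an MSE training objective); a `holdout` policy is
available for users who prefer tuning against generalization. The tuner
runs in continuous mode — the weights being tuned are real-valued, so
forcing the binary encoding onto them would discard the method's natural
fit.

## Synthetic data: what it emulates and what it does not

`simulate_dr_features()` stands in for fused CNN feature vectors: each
severity grade is an isotropic Gaussian whose mean sits on its own
orthogonal axis, scaled so all pairwise mean distances equal `separation`
(this requires `dim` at least the class count). The default class profile
(134, 20, 84, 74, 49) mirrors the canonical retinopathy grade imbalance.
Real CNN features are anisotropic, correlated and non-Gaussian with
unequal class difficulty; a high accuracy on this generator therefore
validates the pipeline's bookkeeping and the optimizer/classifier
coupling, not clinical performance. `separation = 0` gives
indistinguishable classes and is used to confirm the pipeline does *not*
manufacture accuracy.

`balance_classes()` replaces generative augmentation with feature-space
jitter oversampling: minority classes are topped up to the majority count
by resampling class members plus Gaussian jitter scaled to
`jitter_scale` times the per-feature class standard deviation. Added rows
carry a `"synthetic"` provenance flag so they can be excluded downstream;
original rows are preserved bit-exactly.

`synth_fundus()` emulates fundus rasters as a smooth background
(base 0.55) with a gentle quadratic vignette (amplitude 0.03), Gaussian
pixel noise (SD 0.02), and circular lesions at a contrast of 0.3 — dark
discs for red lesions, bright for exudate-like ones. The vignette and
noise are deliberately mild relative to the lesion contrast so that a
single global threshold is a sound model; real fundus photographs have
vessels, illumination gradients and reflections that this generator does
not attempt.

## Lesion screening: parameters and conventions

The chain is binarize, refine, measure, filter:

- **Binarization** is polarity-aware: red screening thresholds *below*,
  bright screening *above*. Otsu's criterion is the default; a quantile
  threshold (`q` = tail mass on the polarity's side) is available. A
  single Otsu threshold on an image containing *both* strong dark and
  bright lesions can land in the wrong gap of the trimodal histogram —
  for mixed images use the quantile method per kind. A constant image has
  no Otsu split and raises an error.
- **Refinement**: morphological closing (radius 2) then opening (radius 1)
  with disc structuring elements, then a minimum-size filter. Note that
  EBImage's 3-pixel "disc" brush is a full 3×3 box, so opening at radius 1
  removes any component that cannot contain a 3×3 square; `screen_lesions()`
  therefore defers *all* size-based rejection to the geometric filter stage
  (it runs refinement with `min_size = 1`) so that small components appear
  as rejected calls with a stated reason instead of vanishing silently.
- **Geometry**: components are 8-connected (4-connected labeling plus a
  union-find merge across diagonals). Area is the pixel count. Perimeter
  uses weighted border-pixel counting (straight steps 1, diagonal
  $\sqrt 2$, corner configurations $(1+\sqrt 2)/2$) — the standard
  neighborhood-code estimator, which keeps a rasterized disc's border
  complexity $P^2 / (4\pi A)$ near 1. Elongation is the axis ratio of the
  second-moment ellipse, with a $1/12$ per-pixel variance term so a single
  pixel has elongation exactly 1. Coordinates are row-major, origin
  top-left.
- **Filtering** accepts a component iff area $\ge$ 8 px, elongation
  $\le$ 4, and border complexity $\le$ 3 (all configurable; these defaults
  are calibrated to the fixture generator's lesion sizes, as no canonical
  thresholds exist for this rule set). A rejected call reports its first
  failed rule in that order.

RGB input is reduced to the green channel by default (standard fundus
practice; luminance is the alternative).

## Evaluation metrics

Per-class one-vs-rest counts feed the four quotients (accuracy,
sensitivity, specificity, precision, as percentages). A zero denominator
yields `NA` — an explicit "undefined" marker — rather than a silent 0 or
100. Macro averages are unweighted class means; micro metrics come from
pooled counts, with micro accuracy reported as overall percent-correct
(for pooled one-vs-rest counts, pooled sensitivity equals this quantity;
the pooled "accuracy" quotient would double-count negatives and is not
reported). AUC is the rank statistic (ties counted half), invariant under
monotone score transforms. Jaccard overlap returns 1 for two empty masks —
a perfect-agreement convention, documented rather than assumed.

## Problem sizes and numerical choices

The test suite and the acceptance script choose sizes that make each claim
sharp but cheap: oracle equivalences run on small packs (6–8 wolves, 4–6
dimensions) where bit-identity is checked directly; the benchmark
protocol runs at its native scale (30 wolves, 500 iterations, 30 runs) on
the two reference functions; the classifier property uses the default
(361-sample) grade profile at separation 6. Monotone-history,
bounds-respection and bit-purity properties are asserted on every run the
suite performs. Stochastic assertions (binomial frequencies, lesion
recall) use pre-stated tolerances: three binomial standard errors, or the
order-of-magnitude bands appropriate to metaheuristic tail means.

Known limitations: the optimizer treats constraints only by box clamping;
the ELM is single-hidden-layer (no kernel or sequential variants); the
screening rules are intensity-threshold-based and assume lesion contrast
dominates illumination variation; and all synthetic generators are
idealizations — results on them bound plumbing correctness, not clinical
utility.
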