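# kcbgwo

Diabetic retinopathy (DR) screening pipelines need three things that are
awkward to get from one toolbox: a global optimizer that works in both
continuous and binary search spaces, a classifier cheap enough to retrain
inside the optimizer's fitness loop, and simple rule-based screening of
retinal lesions for triage. `kcbgwo` provides all three for R users working
on retinal image analysis and, more generally, on hyperparameter search for
medical-imaging classifiers:

- **KCBGWO** — a grey wolf optimizer (GWO) whose pack is re-partitioned by
  k-means every iteration, each wolf following its *own cluster's*
  alpha/beta/delta leaders. Continuous mode for box-bounded problems; binary
  mode via a sigmoid transfer for bit-vector problems and hyperparameter
  encodings.
- **ELM** — an extreme learning machine (single-hidden-layer network,
  random input weights, output weights solved in closed form by the
  Moore-Penrose pseudoinverse), and the coupled **KCBGWO-ELM** classifier
  in which the optimizer tunes the input weights and biases against an MSE
  fitness.
- **Lesion screening** — polarity-aware binarization, morphological
  refinement and geometric filtering of dark ("red lesion": microaneurysm /
  haemorrhage-like) and bright (exudate-like) regions in fundus-like
  images.

Plus the surrounding apparatus: a ten-function benchmark suite with a
30-run trial protocol, one-vs-rest classification metrics (accuracy,
sensitivity, specificity, precision, AUC), Jaccard overlap, feature-fusion
bookkeeping with the canonical fused widths (FS1 = 6016, FS2 = 3328,
FS3 = 1280), class balancing by jittered oversampling, and synthetic
generators for both labeled feature sets (IDRiD-like grade profile
134/20/84/74/49) and fundus-like rasters with exact ground truth.

## The core update

Wolves move toward prey guided by the three best pack members. For leader
`p` with position `X_p`:

    a(t)   = 2 - 2 t / T                    (linear decay, exploration -> exploitation)
    A = 2 a r1 - a,   C = 2 r2              (r1, r2 ~ U[0,1] per dimension)
    K      = |C * X_p - X|                  (prey distance)
    cand_p = X_p - A * K

The new continuous position is the mean of the alpha/beta/delta candidates
(clamped to the box). In binary mode each bit is resampled as
`1` with probability `sigma((cand_a + cand_b + cand_d) / 3)`,
`sigma(x) = 1/(1+exp(-x))`. What distinguishes KCBGWO from plain GWO is
that leaders are per-cluster: the pack is split by k-means (Lloyd's
algorithm, re-run every iteration) and each wolf follows the hierarchy of
its own cluster, which preserves several independent search basins instead
of collapsing the whole pack onto one leader triple. With `K = 1` the
method reduces exactly to standard GWO.

The ELM solves `M w = T` for the output weights, where
`M[j,i] = f(a_i . x_j + c_i)` is the hidden-layer response matrix, via
`w = pinv(M) T`. `tune_elm()` runs KCBGWO over the flattened
`(input weights, biases)` vector in `[-1, 1]` with the training MSE as
fitness.

## Worked example

```r
library(kcbgwo)

# 1. optimizer on a benchmark
sphere <- benchmark_suite(10)$f1
res <- kcbgwo(sphere, kcbgwo_config(N = 20, T = 100, K = 3, seed = 1))
res$best_fitness
#> [1] 5.965368e-06

# 2. synthetic 5-class DR feature set -> balance -> tune -> evaluate
s  <- simulate_dr_features(dim = 20, separation = 6, noise = 1, seed = 301)
b  <- balance_classes(s, jitter_scale = 0.1, seed = 302)
sp <- split_feature_set(b, 0.7, seed = 303)
tuned <- tune_elm(sp$train, G = 40,
                  config = kcbgwo_config(N = 15, T = 20, K = 3, seed = 304))
rep <- evaluate_split(tuned$model, sp$test)
rep$accuracy
#> [1] 98.51485

# 3. lesion screening on a synthetic fundus raster
lay <- data.frame(row = c(30, 70, 100), col = c(40, 90, 30),
                  radius = c(6, 5, 7), kind = "red", contrast = 0.3)
f  <- synth_fundus(lay, seed = 11)
sc <- screen_lesions(f$image, "red")
sum(sc$calls$accepted)
#> [1] 3
```

The first number is the best Sphere value found in 100 iterations (the
optimum is 0). The second is held-out accuracy on well-separated synthetic
classes — near-perfect because the class means are 6 noise-SDs apart, so
this checks the pipeline plumbing, not real-data performance. The third confirms
all three planted dark lesions are accepted by the geometric filters.

A thin command-line front end with `bench` / `simulate` / `train` /
`screen` subcommands lives at `inst/cli/kcbgwo-cli`
(after installation: `system.file("cli", "kcbgwo-cli", package = "kcbgwo")`).

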