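#' Linearly decaying control parameter
#'
#' The exploration/exploitation control parameter `a` decays linearly from 2
#' at iteration 0 to 0 at the final iteration: `a = 2 - 2 * iteration / T`.
#'
#' @param iteration Current iteration (0..T).
#' @param T Total iteration budget (>= 1).
#' @return The value of `a` in `[0, 2]`.
#' @export
control_parameter <- function(iteration, T) {
  if (T < 1) stop_config("T must be >= 1")
  if (iteration < 0 || iteration > T)
    stop_input("iteration must lie in [0, T]")
  2 - 2 * iteration / T
}

#' Sample the stochastic attraction coefficients
#'
#' Draws fresh `r1`, `r2` uniform in `[0,1]` per dimension (in that order,
#' from the current RNG stream) and forms `A = 2*a*r1 - a` (componentwise in
#' `[-a, a]`) and `C = 2*r2` (in `[0, 2]`).
#'
#' @param a Control parameter in `[0, 2]`.
#' @param D Dimension.
#' @return A `control_coefficients` list with fields `a, r1, r2, A, C`.
#' @export
sample_coefficients <- function(a, D) {
  if (a < 0 || a > 2) stop_config("a must lie in [0, 2]")
  r1 <- stats::runif(D)
  r2 <- stats::runif(D)
  structure(list(a = a, r1 = r1, r2 = r2, A = 2 * a * r1 - a, C = 2 * r2),
            class = "control_coefficients")
}

#' Leader-guided position component
#'
#' For one leader at `X_p`, computes the prey distance
#' `K = |C * X_p - X|` (elementwise) and the candidate component
#' `X_p - A * K`. With `A = 0` the candidate equals the leader position
#' exactly (pure exploitation).
#'
#' @param X Current position.
#' @param X_p Leader position.
#' @param coeffs A `control_coefficients` object (or list with `A`, `C`).
#' @param role Leader role tag, informational (`"alpha"`, `"beta"`, `"delta"`).
#' @return A `leader_step` list with `leader`, `K`, `candidate`, `role`.
#' @export
leader_component <- function(X, X_p, coeffs, role = "alpha") {
  D <- length(X)
  if (length(X_p) != D || length(coeffs$A) != D || length(coeffs$C) != D)
    stop_dim("X, X_p, A and C must share one length")
  K <- abs(coeffs$C * X_p - X)
  structure(list(leader = X_p, K = K,
                 candidate = X_p - coeffs$A * K, role = role),
            class = "leader_step")
}

#' Blend the three leader components
#'
#' The new continuous position is the elementwise arithmetic mean of the
#' alpha-, beta- and delta-guided candidates (optionally a weighted mean via
#' `weights`, a hook that defaults to the plain average).
#'
#' @param c_alpha,c_beta,c_delta Candidate components of equal length.
#' @param weights Optional length-3 non-negative weights, normalized to sum 1.
#' @return Blended position vector.
#' @export
blend_components <- function(c_alpha, c_beta, c_delta, weights = NULL) {
  D <- length(c_alpha)
  if (length(c_beta) != D || length(c_delta) != D)
    stop_dim("the three components must share one length")
  if (is.null(weights)) return((c_alpha + c_beta + c_delta) / 3)
  if (length(weights) != 3 || any(weights < 0) || sum(weights) <= 0)
    stop_config("weights must be 3 non-negative values with positive sum")
  w <- weights / sum(weights)
  w[1] * c_alpha + w[2] * c_beta + w[3] * c_delta
}

#' Sigmoid transfer function
#'
#' `1 / (1 + exp(-v))`, mapping a continuous update component to a bit-set
#' probability; saturates without overflow for large `|v|`.
#'
#' @param v Numeric vector.
#' @return Values in `(0, 1)`.
#' @export
sigmoid_transfer <- function(v) 1 / (1 + exp(-v))

#' Binary position update for one (or each) dimension
#'
#' The bit-set probability is the sigmoid of the mean of the three
#' leader-guided components; the bit becomes 1 iff a fresh uniform draw `u`
#' (from the current RNG stream) satisfies `u < p`.
#'
#' @param c_alpha,c_beta,c_delta Per-dimension leader components (vectors of
#'   equal length are updated elementwise).
#' @return Integer vector of bits.
#' @export
binary_bit_update <- function(c_alpha, c_beta, c_delta) {
  p <- sigmoid_transfer((c_alpha + c_beta + c_delta) / 3)
  u <- stats::runif(length(p))
  as.integer(u < p)
}

#' Global-best particle swarm baseline
#'
#' Standard inertia-weight PSO (w = 0.729, c1 = c2 = 1.49445, velocity
#' clamped to half the box width per dimension), used as an off-the-shelf
#' comparator in the trial protocol. Per particle and iteration the draw
#' order is: cognitive `r1` (D draws) then social `r2` (D draws).
#'
#' @param spec An [objective_spec()].
#' @param N Swarm size. @param T Iteration budget.
#' @param seed Integer seed.
#' @param w,c1,c2 PSO coefficients.
#' @return An `optimization_result` (best position/fitness, best-so-far
#'   history of length T+1, evaluation count, seed).
#' @export
pso_minimize <- function(spec, N, T, seed, w = 0.729, c1 = 1.49445, c2 = 1.49445) {
  if (N < 1 || T < 1) stop_config("N and T must be >= 1")
  D <- spec$D
  lo <- spec$lower; hi <- spec$upper
  vmax <- (hi - lo) / 2
  set.seed(as.integer(seed))
  X <- matrix(stats::runif(N * D), N, D)
  X <- sweep(sweep(X, 2, hi - lo, `*`), 2, lo, `+`)
  V <- matrix(stats::runif(N * D, -1, 1), N, D)
  V <- sweep(V, 2, vmax, `*`)
  fit <- apply(X, 1, spec$fun)
  evals <- N
  P <- X; pfit <- fit
  g <- which.min(pfit)
  gbest <- P[g, ]; gfit <- pfit[g]
  history <- numeric(T + 1)
  history[1] <- gfit
  for (t in seq_len(T)) {
    for (i in seq_len(N)) {
      r1 <- stats::runif(D); r2 <- stats::runif(D)
      V[i, ] <- clamp(w * V[i, ] + c1 * r1 * (P[i, ] - X[i, ]) +
                        c2 * r2 * (gbest - X[i, ]), -vmax, vmax)
      X[i, ] <- clamp(X[i, ] + V[i, ], lo, hi)
    }
    fit <- apply(X, 1, spec$fun)
    evals <- evals + N
    better <- fit < pfit
    P[better, ] <- X[better, , drop = FALSE]
    pfit[better] <- fit[better]
    g <- which.min(pfit)
    if (pfit[g] < gfit) { gfit <- pfit[g]; gbest <- P[g, ] }
    history[t + 1] <- gfit
  }
  structure(list(best_position = gbest, best_fitness = gfit,
                 history = history, evaluations = evals,
                 seed = as.integer(seed),
                 config = list(optimizer = "pso", N = N, T = T,
                               w = w, c1 = c1, c2 = c2)),
            class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf("%s: best fitness %.6e after %d evaluations (seed %d)\n",
              x$config$optimizer %||% "kcbgwo", x$best_fitness,
              x$evaluations, x$seed))
  invisible(x)
}
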