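# Independent oracles used across the suite. Each is a deliberately literal,
# loop-based transcription of the textbook definition, kept separate from the
# package's (vectorized) implementation paths.

# literal scalar-loop transcriptions of the ten benchmark formulas
oracle_benchmarks <- list(
  f1 = function(x) { s <- 0; for (xi in x) s <- s + xi^2; s },
  f2 = function(x) {
    s <- 0; p <- 1
    for (xi in x) { s <- s + abs(xi); p <- p * abs(xi) }
    s + p
  },
  f3 = function(x) {
    s <- 0
    for (i in seq_along(x)) {
      inner <- 0
      for (j in 1:i) inner <- inner + x[j]
      s <- s + inner^2
    }
    s
  },
  f4 = function(x) { m <- 0; for (xi in x) m <- max(m, abs(xi)); m },
  f5 = function(x) {
    s <- 0
    for (i in 1:(length(x) - 1))
      s <- s + 100 * (x[i + 1] - x[i]^2)^2 + (x[i] - 1)^2
    s
  },
  f6 = function(x) {
    s <- 0
    for (xi in x) s <- s + xi * sin(sqrt(abs(xi)))
    418.9829 * length(x) - s
  },
  f7 = function(x) {
    s <- 0
    for (xi in x) s <- s + xi^2 - 10 * cos(2 * pi * xi) + 10
    s
  },
  f8 = function(x) {
    n <- length(x); s1 <- 0; s2 <- 0
    for (xi in x) { s1 <- s1 + xi^2; s2 <- s2 + cos(2 * pi * xi) }
    -20 * exp(-0.2 * sqrt(s1 / n)) - exp(s2 / n) + 20 + exp(1)
  },
  f9 = function(x) {
    s <- 0; p <- 1
    for (i in seq_along(x)) {
      s <- s + x[i]^2 / 4000
      p <- p * cos(x[i] / sqrt(i))
    }
    s - p + 1
  },
  f10 = function(x) {
    n <- length(x)
    y <- numeric(n)
    for (i in 1:n) y[i] <- 1 + (x[i] + 1) / 4
    core <- 10 * sin(pi * y[1])^2
    for (i in 1:(n - 1))
      core <- core + (y[i] - 1)^2 * (1 + 10 * sin(pi * y[i + 1])^2)
    core <- core + (y[n] - 1)^2
    pen <- 0
    for (xi in x) {
      if (xi > 10) pen <- pen + 100 * (xi - 10)^4
      else if (xi < -10) pen <- pen + 100 * (-xi - 10)^4
    }
    pi / n * core + pen
  }
)

# one plain-GWO continuous iteration sweep, literal elementwise transcription
# of the update equations, consuming the current RNG stream in the package's
# documented order (per wolf; per leader alpha, beta, delta; r1 then r2)
oracle_gwo_step <- function(X, fitness, a, lower, upper) {
  N <- nrow(X); D <- ncol(X)
  ord <- order(fitness, seq_len(N))
  Xa <- X[ord[1], ]; Xb <- X[ord[2], ]; Xd <- X[ord[3], ]
  Xnew <- X
  for (i in seq_len(N)) {
    cand <- matrix(0, 3, D)
    leaders <- list(Xa, Xb, Xd)
    for (l in 1:3) {
      r1 <- runif(D); r2 <- runif(D)
      for (d in seq_len(D)) {
        A <- 2 * a * r1[d] - a
        C <- 2 * r2[d]
        K <- abs(C * leaders[[l]][d] - X[i, d])
        cand[l, d] <- leaders[[l]][d] - A * K
      }
    }
    for (d in seq_len(D))
      Xnew[i, d] <- min(max((cand[1, d] + cand[2, d] + cand[3, d]) / 3,
                            lower[d]), upper[d])
  }
  Xnew
}

# quadruple-loop one-vs-rest confusion tally
oracle_confusion <- function(y_true, y_pred, positive) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(y_true)) {
    t_pos <- y_true[i] == positive
    p_pos <- y_pred[i] == positive
    if (t_pos && p_pos) tp <- tp + 1L
    else if (!t_pos && p_pos) fp <- fp + 1L
    else if (t_pos && !p_pos) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(TP = tp, FP = fp, TN = tn, FN = fn)
}

# elementwise-loop mean squared error
oracle_mse <- function(o, p) {
  o <- as.matrix(o); p <- as.matrix(p)
  s <- 0
  for (i in seq_len(nrow(o))) for (j in seq_len(ncol(o)))
    s <- s + (o[i, j] - p[i, j])^2
  s / (nrow(o) * ncol(o))
}

# brute-force minimal within-cluster sum of squares over all assignments
oracle_best_wcss <- function(X, K) {
  N <- nrow(X)
  best <- Inf
  grid <- expand.grid(rep(list(seq_len(K)), N))
  for (r in seq_len(nrow(grid))) {
    assign <- as.integer(grid[r, ])
    w <- 0
    ok <- TRUE
    for (k in seq_len(K)) {
      m <- assign == k
      if (!any(m)) { ok <- FALSE; break }
      cen <- colMeans(X[m, , drop = FALSE])
      w <- w + sum(sweep(X[m, , drop = FALSE], 2, cen)^2)
    }
    if (ok && w < best) best <- w
  }
  best
}

make_disc_mask <- function(h, w, row, col, radius) {
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  (rr - row)^2 + (cc - col)^2 <= radius^2
}
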