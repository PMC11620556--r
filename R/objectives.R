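#' Construct an objective specification
#'
#' An `objective_spec` bundles everything an optimizer needs to know about a
#' minimization problem: the evaluator, its dimension, box bounds, a modality
#' tag, and (when known) the global minimum and one minimizer, used by the
#' test suite to verify the registry.
#'
#' @param id Short identifier (`"f1"`..`"f10"` for the built-in suite, or a
#'   user tag).
#' @param name Display name.
#' @param D Problem dimension (positive integer).
#' @param lower,upper Per-dimension bounds; scalars are recycled to length `D`.
#' @param modality `"unimodal"` or `"multimodal"`.
#' @param fun Evaluator, a function of one numeric vector of length `D`
#'   returning a single finite number. Must be deterministic.
#' @param minimum Known global minimum value, or `NA` if unknown.
#' @param minimizer One known minimizer (length-`D` vector), or `NULL`.
#' @return An object of class `objective_spec`.
#' @export
objective_spec <- function(id, name, D, lower, upper,
                           modality = c("unimodal", "multimodal"),
                           fun, minimum = NA_real_, minimizer = NULL) {
  modality <- match.arg(modality)
  D <- as.integer(D)
  if (D < 1) stop_config("D must be a positive integer")
  lower <- rep_len(as.double(lower), D)
  upper <- rep_len(as.double(upper), D)
  if (any(lower >= upper)) stop_config("lower must be < upper in every dimension")
  if (!is.null(minimizer)) minimizer <- rep_len(as.double(minimizer), D)
  structure(list(id = id, name = name, D = D, lower = lower, upper = upper,
                 modality = modality, fun = fun, minimum = minimum,
                 minimizer = minimizer),
            class = "objective_spec")
}

#' @export
print.objective_spec <- function(x, ...) {
  cat(sprintf("Objective %s (%s), D = %d, bounds [%g, %g], %s\n",
              x$id, x$name, x$D, x$lower[1], x$upper[1], x$modality))
  invisible(x)
}

#' Evaluate an objective at a point
#'
#' Validates the dimension and finiteness of `x`, then applies the stored
#' evaluator. Bounds are deliberately not enforced here: keeping candidates
#' inside the box is the optimizer's job (it clamps), so an out-of-bounds
#' query is treated as a legitimate caller decision.
#'
#' @param spec An [objective_spec()].
#' @param x Numeric vector of length `spec$D`.
#' @return The objective value (single finite number).
#' @export
evaluate_objective <- function(spec, x) {
  if (!inherits(spec, "objective_spec")) stop_input("spec must be an objective_spec")
  if (length(x) != spec$D)
    stop_dim("x has length ", length(x), " but the objective has dimension ", spec$D)
  check_numeric_vector(x, "x")
  spec$fun(x)
}

# penalty term of the generalized penalized function
u_penalty <- function(x, a, k, m) {
  out <- numeric(length(x))
  hi <- x > a
  lo <- x < -a
  out[hi] <- k * (x[hi] - a)^m
  out[lo] <- k * (-x[lo] - a)^m
  out
}

#' The ten-function benchmark suite
#'
#' Returns the classical suite used to compare grey-wolf-family optimizers:
#' five unimodal functions (Sphere; Schwefel 2.22, 1.2 and 2.21; Generalized
#' Rosenbrock) and five multimodal ones (Generalized Schwefel 2.26,
#' Rastrigin, Ackley, Griewank, Generalized Penalized No. 1), each with its
#' standard box domain. All have their global minimum at 0; Schwefel 2.26 is
#' shifted by `418.9829 * D` so its optimum is approximately 0 and values are
#' positive.
#'
#' @param D Dimension (default 30, the conventional setting for this suite).
#' @return Named list of ten [objective_spec()] objects, `f1` through `f10`.
#' @export
#' @examples
#' suite <- benchmark_suite(30)
#' evaluate_objective(suite$f1, rep(0, 30))  # 0
benchmark_suite <- function(D = 30) {
  D <- as.integer(D)
  if (D < 2) stop_config("the suite requires D >= 2")
  list(
    f1 = objective_spec("f1", "Sphere", D, -100, 100, "unimodal",
      function(x) sum(x^2), 0, rep(0, D)),
    f2 = objective_spec("f2", "Schwefel 2.22", D, -10, 10, "unimodal",
      function(x) sum(abs(x)) + prod(abs(x)), 0, rep(0, D)),
    f3 = objective_spec("f3", "Schwefel 1.2", D, -100, 100, "unimodal",
      function(x) sum(cumsum(x)^2), 0, rep(0, D)),
    f4 = objective_spec("f4", "Schwefel 2.21", D, -100, 100, "unimodal",
      function(x) max(abs(x)), 0, rep(0, D)),
    f5 = objective_spec("f5", "Generalized Rosenbrock", D, -30, 30, "unimodal",
      function(x) {
        i <- seq_len(length(x) - 1)
        sum(100 * (x[i + 1] - x[i]^2)^2 + (x[i] - 1)^2)
      }, 0, rep(1, D)),
    f6 = objective_spec("f6", "Generalized Schwefel 2.26", D, -500, 500, "multimodal",
      function(x) 418.9829 * length(x) - sum(x * sin(sqrt(abs(x)))),
      0, rep(420.968746, D)),
    f7 = objective_spec("f7", "Rastrigin", D, -5.12, 5.12, "multimodal",
      function(x) sum(x^2 - 10 * cos(2 * pi * x) + 10), 0, rep(0, D)),
    f8 = objective_spec("f8", "Ackley", D, -32, 32, "multimodal",
      function(x) {
        n <- length(x)
        -20 * exp(-0.2 * sqrt(sum(x^2) / n)) - exp(sum(cos(2 * pi * x)) / n) +
          20 + exp(1)
      }, 0, rep(0, D)),
    f9 = objective_spec("f9", "Griewank", D, -600, 600, "multimodal",
      function(x) {
        sum(x^2) / 4000 - prod(cos(x / sqrt(seq_along(x)))) + 1
      }, 0, rep(0, D)),
    f10 = objective_spec("f10", "Generalized Penalized No. 1", D, -50, 50, "multimodal",
      function(x) {
        n <- length(x)
        y <- 1 + (x + 1) / 4
        core <- 10 * sin(pi * y[1])^2 +
          sum((y[-n] - 1)^2 * (1 + 10 * sin(pi * y[-1])^2)) +
          (y[n] - 1)^2
        pi / n * core + sum(u_penalty(x, 10, 100, 4))
      }, 0, rep(-1, D))
  )
}

#' Run the multi-run trial protocol on one objective
#'
#' Runs a registered optimizer `runs` times on `spec`, run `i` seeded with
#' `base_seed + i`, and summarizes the per-run best objective values by their
#' mean (`av`) and standard deviation (`std`) — the protocol behind
#' comparative benchmark tables (30 runs, population 30, 500 iterations by
#' default).
#'
#' @param optimizer One of `"kcbgwo"`, `"gwo"` (single-cluster continuous
#'   grey wolf), `"bgwo"` (single-cluster binary-transfer variant evaluated
#'   on 0/1 vertices), `"pso"`.
#' @param spec An [objective_spec()].
#' @param runs Number of independent runs (>= 1).
#' @param base_seed Integer base seed; run `i` uses `base_seed + i`.
#' @param N Population size. @param T Iteration budget.
#' @param K Cluster count (kcbgwo only).
#' @param kmeans_max_iter Lloyd iteration cap (kcbgwo only).
#' @param recluster_period Recluster every this many iterations (kcbgwo only).
#' @return A `trial_summary`: per-run bests plus `av`/`std` and the protocol
#'   parameters.
#' @export
run_trials <- function(optimizer = c("kcbgwo", "gwo", "bgwo", "pso"),
                       spec, runs, base_seed,
                       N = 30, T = 500, K = 3,
                       kmeans_max_iter = 100, recluster_period = 1) {
  optimizer <- match.arg(optimizer)
  if (!inherits(spec, "objective_spec")) stop_input("spec must be an objective_spec")
  runs <- as.integer(runs)
  if (runs < 1) stop_config("runs must be >= 1")
  bests <- vapply(seq_len(runs), function(i) {
    seed <- as.integer(base_seed + i)
    res <- switch(optimizer,
      kcbgwo = kcbgwo(spec, kcbgwo_config(
        N = N, T = T, K = K, kmeans_max_iter = kmeans_max_iter,
        mode = "continuous", seed = seed,
        recluster_period = recluster_period)),
      gwo = kcbgwo(spec, kcbgwo_config(
        N = N, T = T, K = 1, mode = "continuous", seed = seed)),
      bgwo = kcbgwo(spec, kcbgwo_config(
        N = N, T = T, K = 1, mode = "binary", seed = seed)),
      pso = pso_minimize(spec, N = N, T = T, seed = seed))
    res$best_fitness
  }, numeric(1))
  structure(list(objective = spec$id, optimizer = optimizer,
                 runs = runs, N = as.integer(N), T = as.integer(T),
                 base_seed = as.integer(base_seed),
                 bests = bests, av = mean(bests), std = stats::sd(bests)),
            class = "trial_summary")
}

#' @export
print.trial_summary <- function(x, ...) {
  cat(sprintf("%s on %s: %d runs (N=%d, T=%d)  Av=%.3e  Std=%.3e\n",
              x$optimizer, x$objective, x$runs, x$N, x$T, x$av,
              if (is.na(x$std)) 0 else x$std))
  invisible(x)
}

#' Tabulate trial summaries into a comparison grid
#'
#' One row per objective, an `Av`/`Std` column pair per optimizer — the
#' layout of a benchmark comparison table. All summaries must share the same
#' protocol (runs, N, T).
#'
#' @param summaries List of `trial_summary` objects.
#' @return A data frame (empty for empty input).
#' @export
comparison_table <- function(summaries) {
  if (length(summaries) == 0) return(data.frame())
  stopifnot(all(vapply(summaries, inherits, logical(1), "trial_summary")))
  proto <- vapply(summaries, function(s) paste(s$runs, s$N, s$T), character(1))
  if (length(unique(proto)) != 1)
    stop_config("protocol mismatch: all summaries must share runs/N/T")
  objs <- unique(vapply(summaries, `[[`, character(1), "objective"))
  opts <- unique(vapply(summaries, `[[`, character(1), "optimizer"))
  out <- data.frame(objective = objs, stringsAsFactors = FALSE)
  for (op in opts) {
    av <- std <- rep(NA_real_, length(objs))
    for (s in summaries) {
      if (s$optimizer == op) {
        i <- match(s$objective, objs)
        av[i] <- s$av
        std[i] <- s$std
      }
    }
    out[[paste0(op, "_av")]] <- av
    out[[paste0(op, "_std")]] <- std
  }
  out
}

#' Write/read trial summaries as CSV
#'
#' Long format, one row per (objective, optimizer) pair with columns
#' `objective, optimizer, av, std, runs, N, T, base_seed`. Values are written
#' with 17 significant digits so a read-back reproduces them exactly.
#'
#' @param summaries List of `trial_summary` objects.
#' @param path Output CSV path.
#' @export
write_trials_csv <- function(summaries, path) {
  rows <- lapply(summaries, function(s) {
    data.frame(objective = s$objective, optimizer = s$optimizer,
               av = format(s$av, digits = 17),
               std = format(if (is.na(s$std)) 0 else s$std, digits = 17),
               runs = s$runs, N = s$N, T = s$T, base_seed = s$base_seed,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$av <- as.numeric(df$av)
  df$std <- as.numeric(df$std)
  df
}
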