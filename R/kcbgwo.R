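#' KCBGWO configuration
#'
#' Collects the optimizer's tunables. Defaults follow the reference setting:
#' population 30, 500 iterations, K = 3 clusters, a 100-iteration Lloyd cap,
#' and reclustering every iteration.
#'
#' @param N Population size (>= 4: a cluster must be able to host the
#'   alpha/beta/delta leaders plus at least one omega across the pack).
#' @param T Iteration budget (>= 1).
#' @param K Number of k-means clusters (1 <= K <= N). `K = 1` reduces the
#'   method to plain grey wolf updates.
#' @param kmeans_max_iter Lloyd iteration cap per reclustering.
#' @param mode `"continuous"` (box-bounded real search) or `"binary"`
#'   (bit vectors via the sigmoid transfer).
#' @param lower,upper Box bounds for continuous mode when the objective is a
#'   bare function; an [objective_spec()] supplies its own.
#' @param threshold Optional early-stop fitness threshold (stop as soon as
#'   the global alpha's fitness is <= threshold); default unset, meaning the
#'   full budget is spent.
#' @param seed Integer seed; if `NULL` one is drawn and recorded.
#' @param recluster_period Recluster every this many iterations.
#' @param leader_blend_weights Optional length-3 weights passed to
#'   [blend_components()]; default `NULL` = the plain three-leader mean.
#' @return A `kcbgwo_config` list.
#' @export
kcbgwo_config <- function(N = 30, T = 500, K = 3, kmeans_max_iter = 100,
                          mode = c("continuous", "binary"),
                          lower = NULL, upper = NULL, threshold = NULL,
                          seed = NULL, recluster_period = 1,
                          leader_blend_weights = NULL) {
  mode <- match.arg(mode)
  N <- as.integer(N); T <- as.integer(T); K <- as.integer(K)
  if (N < 4) stop_config("N must be >= 4")
  if (K < 1 || K > N) stop_config("K must satisfy 1 <= K <= N")
  if (T < 1) stop_config("T must be >= 1")
  if (kmeans_max_iter < 1) stop_config("kmeans_max_iter must be >= 1")
  if (!is.null(threshold) && !is.finite(threshold))
    stop_config("threshold must be finite when set")
  structure(list(N = N, T = T, K = K,
                 kmeans_max_iter = as.integer(kmeans_max_iter),
                 mode = mode, lower = lower, upper = upper,
                 threshold = threshold, seed = seed,
                 recluster_period = as.integer(recluster_period),
                 leader_blend_weights = leader_blend_weights),
            class = "kcbgwo_config")
}

#' Read a KCBGWO configuration from YAML
#'
#' Field names mirror the arguments of [kcbgwo_config()].
#'
#' @param path Path to a YAML file.
#' @return A `kcbgwo_config`.
#' @export
kcbgwo_config_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop_config("the yaml package is required to read YAML configurations")
  do.call(kcbgwo_config, yaml::read_yaml(path))
}

#' Initialize the wolf pack
#'
#' Binary mode: each bit is an independent fair coin. Continuous mode: each
#' coordinate is uniform within its bounds. Uses the current RNG stream;
#' the position matrix is filled column-wise (R's default), `N * D` draws.
#'
#' @param config A [kcbgwo_config()].
#' @param D Dimension.
#' @param lower,upper Bounds (continuous mode); default taken from `config`.
#' @return `N x D` numeric matrix of positions.
#' @export
initialize_population <- function(config, D,
                                  lower = config$lower, upper = config$upper) {
  D <- as.integer(D)
  if (D < 1) stop_config("D must be >= 1")
  N <- config$N
  if (config$mode == "binary") {
    matrix(as.double(stats::runif(N * D) < 0.5), N, D)
  } else {
    if (is.null(lower) || is.null(upper))
      stop_config("continuous mode requires bounds")
    lower <- rep_len(as.double(lower), D)
    upper <- rep_len(as.double(upper), D)
    X <- matrix(stats::runif(N * D), N, D)
    sweep(sweep(X, 2, upper - lower, `*`), 2, lower, `+`)
  }
}

#' Partition the pack with Lloyd's k-means
#'
#' Euclidean k-means on wolf positions: centroids initialized by sampling
#' `K` distinct wolves (current RNG stream), alternating assignment and
#' centroid updates until an assignment fixpoint or `max_iter`. An empty
#' cluster is re-seeded at a randomly chosen wolf. The within-cluster
#' sum-of-squares (WCSS) objective is recorded after every iteration and is
#' non-increasing.
#'
#' @param positions `N x D` matrix.
#' @param K Cluster count (<= N).
#' @param max_iter Lloyd iteration cap.
#' @return A `cluster_model`: `K`, `centroids` (K x D), `assignment`
#'   (length N), `wcss`, `wcss_trace`, `iterations`.
#' @export
kmeans_partition <- function(positions, K, max_iter = 100) {
  N <- nrow(positions); D <- ncol(positions)
  K <- as.integer(K)
  if (K > N) stop_config("K must not exceed the number of wolves")
  if (max_iter < 1) stop_config("max_iter must be >= 1")
  centroids <- positions[sample.int(N, K), , drop = FALSE]
  assignment <- integer(N)
  wcss_trace <- numeric(0)
  iter <- 0
  repeat {
    iter <- iter + 1
    # squared distances N x K
    d2 <- outer(rowSums(positions^2), rep(1, K)) +
      outer(rep(1, N), rowSums(centroids^2)) -
      2 * positions %*% t(centroids)
    new_assign <- max.col(-d2, ties.method = "first")
    for (k in seq_len(K)) {
      members <- new_assign == k
      if (!any(members)) {
        j <- sample.int(N, 1)
        centroids[k, ] <- positions[j, ]
      } else {
        centroids[k, ] <- colMeans(positions[members, , drop = FALSE])
      }
    }
    wcss <- sum(vapply(seq_len(K), function(k) {
      m <- new_assign == k
      if (!any(m)) return(0)
      sum(sweep(positions[m, , drop = FALSE], 2, centroids[k, ])^2)
    }, numeric(1)))
    wcss_trace <- c(wcss_trace, wcss)
    if (identical(new_assign, assignment) || iter >= max_iter) {
      assignment <- new_assign
      break
    }
    assignment <- new_assign
  }
  structure(list(K = K, centroids = centroids, assignment = assignment,
                 wcss = wcss, wcss_trace = wcss_trace, iterations = iter),
            class = "cluster_model")
}

#' Assign pack roles per cluster
#'
#' Within each cluster, wolves are stably sorted by fitness (ascending, ties
#' broken by wolf index); the first three become alpha, beta, delta and the
#' rest omega. Clusters with fewer than four members fill missing leader
#' roles with their best wolf. The globally best wolf (global alpha) is
#' recorded separately for reporting and the early-stop rule.
#'
#' @param fitness Numeric vector of evaluated fitnesses (lower is better).
#' @param assignment Integer cluster assignment per wolf.
#' @return A `role_table`: per-cluster leader indices and omega sets, plus
#'   `global_alpha` index and `global_alpha_fitness`.
#' @export
assign_roles <- function(fitness, assignment) {
  if (anyNA(fitness)) stop_input("all fitnesses must be evaluated before role assignment")
  ks <- sort(unique(assignment))
  clusters <- lapply(ks, function(k) {
    idx <- which(assignment == k)
    ord <- idx[order(fitness[idx], idx)]
    best <- ord[1]
    list(alpha = best,
         beta = if (length(ord) >= 2) ord[2] else best,
         delta = if (length(ord) >= 3) ord[3] else best,
         omega = if (length(ord) >= 4) ord[-(1:3)] else integer(0),
         members = idx)
  })
  names(clusters) <- as.character(ks)
  g <- order(fitness, seq_along(fitness))[1]
  structure(list(clusters = clusters, global_alpha = g,
                 global_alpha_fitness = fitness[g]),
            class = "role_table")
}

#' Minimize an objective with the k-means-clustered grey wolf optimizer
#'
#' The pack is initialized at random, partitioned by k-means, and roles are
#' assigned inside each cluster. Every iteration the control parameter `a`
#' decays linearly; each wolf forms three leader-guided candidates against
#' its own cluster's alpha/beta/delta (drawing `r1` then `r2`, leader order
#' alpha, beta, delta, wolves in index order) and either blends them
#' (continuous mode, then clamps to the bounds) or squashes their mean
#' through the sigmoid transfer to resample bits (binary mode, one uniform
#' draw per dimension after the coefficient draws). Fitnesses are then
#' re-evaluated, the pack is reclustered (on its own derived RNG stream, so
#' clustering never perturbs the update draws), and roles are refreshed. The
#' run stops after `T` iterations, or earlier iff a fitness `threshold` is
#' set and the global alpha reaches it.
#'
#' @param objective An [objective_spec()], or a bare function (then `D` and,
#'   for continuous mode, `config$lower`/`config$upper` must be supplied).
#' @param config A [kcbgwo_config()].
#' @param D Dimension (required when `objective` is a bare function).
#' @return An `optimization_result`: `best_position`, `best_fitness`,
#'   best-so-far `history` (index 1 = iteration 0), `evaluations`, `seed`,
#'   and the config echo.
#' @export
#' @examples
#' sphere <- benchmark_suite(10)$f1
#' res <- kcbgwo(sphere, kcbgwo_config(N = 20, T = 50, K = 3, seed = 1))
#' res$best_fitness
kcbgwo <- function(objective, config = kcbgwo_config(), D = NULL) {
  if (inherits(objective, "objective_spec")) {
    fn <- objective$fun
    D <- objective$D
    lower <- objective$lower
    upper <- objective$upper
  } else {
    if (is.null(D)) stop_config("D is required for a bare objective function")
    fn <- objective
    lower <- config$lower; upper <- config$upper
  }
  D <- as.integer(D)
  binary <- config$mode == "binary"
  if (!binary) {
    if (is.null(lower) || is.null(upper))
      stop_config("continuous mode requires bounds")
    lower <- rep_len(as.double(lower), D)
    upper <- rep_len(as.double(upper), D)
  }
  seed <- config$seed
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  seed <- as.integer(seed)
  set.seed(seed)
  N <- config$N; T <- config$T; K <- config$K

  X <- initialize_population(config, D, lower, upper)
  eval_wolf <- function(x, iter) {
    v <- tryCatch(fn(x), error = function(e)
      stop_input("objective evaluation failed at iteration ", iter, ": ",
                 conditionMessage(e)))
    v
  }
  fitness <- vapply(seq_len(N), function(i) eval_wolf(X[i, ], 0L), numeric(1))
  evals <- N

  recluster <- function(iter) {
    withr::with_seed(derive_seed(seed, iter),
                     kmeans_partition(X, K, config$kmeans_max_iter))
  }
  clusters <- recluster(0L)
  roles <- assign_roles(fitness, clusters$assignment)

  best_idx <- roles$global_alpha
  best_fit <- fitness[best_idx]
  best_pos <- X[best_idx, ]
  history <- numeric(T + 1)
  history[1] <- best_fit
  stopped <- FALSE
  iters_done <- 0L

  for (t in seq_len(T)) {
    if (!is.null(config$threshold) && best_fit <= config$threshold) {
      stopped <- TRUE
      break
    }
    a <- control_parameter(t, T)
    Xnew <- X
    for (i in seq_len(N)) {
      cl <- clusters$assignment[i]
      r <- roles$clusters[[as.character(cl)]]
      leads <- c(r$alpha, r$beta, r$delta)
      cand <- matrix(0, 3, D)
      for (j in 1:3) {
        co <- sample_coefficients(a, D)
        cand[j, ] <- leader_component(X[i, ], X[leads[j], ], co)$candidate
      }
      if (binary) {
        Xnew[i, ] <- as.double(binary_bit_update(cand[1, ], cand[2, ], cand[3, ]))
      } else {
        Xnew[i, ] <- clamp(
          blend_components(cand[1, ], cand[2, ], cand[3, ],
                           config$leader_blend_weights),
          lower, upper)
      }
    }
    X <- Xnew
    fitness <- vapply(seq_len(N), function(i) eval_wolf(X[i, ], t), numeric(1))
    evals <- evals + N
    cur_best <- which.min(fitness)
    if (fitness[cur_best] < best_fit) {
      best_fit <- fitness[cur_best]
      best_pos <- X[cur_best, ]
    }
    history[t + 1] <- best_fit
    iters_done <- t
    if (t %% config$recluster_period == 0) clusters <- recluster(t)
    roles <- assign_roles(fitness, clusters$assignment)
  }
  history <- history[seq_len(iters_done + 1)]
  structure(list(best_position = best_pos, best_fitness = best_fit,
                 history = history, evaluations = evals, seed = seed,
                 early_stopped = stopped,
                 config = c(list(optimizer = "kcbgwo"), unclass(config))),
            class = "optimization_result")
}

#' Serialize an optimization result to JSON
#'
#' @param result An `optimization_result`.
#' @param path Output path.
#' @export
write_result_json <- function(result, path) {
  out <- list(best_position = result$best_position,
              best_fitness = result$best_fitness,
              history = result$history,
              evaluations = result$evaluations,
              seed = result$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Binary encoding of a hyperparameter search space
#'
#' Each parameter domain (a finite categorical or integer set) maps to
#' `ceiling(log2(cardinality))` bits; a candidate bit string decodes by
#' reading each parameter's slice as an unsigned integer (most significant
#' bit first) and indexing the domain modulo its cardinality, so every bit
#' string decodes to a valid setting.
#'
#' @param space Named list of atomic vectors, one per parameter.
#' @return A `search_encoding` descriptor with per-parameter bit widths,
#'   offsets and `total_bits`.
#' @export
#' @examples
#' enc <- encode_search_space(list(nodes = c(4, 8, 16), act = c("sigmoid", "tanh")))
#' enc$total_bits  # 2 + 1
#' decode_candidate(c(1, 0, 1), enc)
encode_search_space <- function(space) {
  if (length(space) == 0 || is.null(names(space)) || any(names(space) == ""))
    stop_config("space must be a non-empty named list of domains")
  card <- vapply(space, length, integer(1))
  if (any(card == 0)) stop_config("empty parameter domain")
  bits <- ifelse(card > 1, ceiling(log2(card)), 0L)
  offsets <- cumsum(c(0L, utils::head(bits, -1)))
  structure(list(params = names(space), domains = space,
                 cardinality = card, bits = as.integer(bits),
                 offsets = as.integer(offsets),
                 total_bits = as.integer(sum(bits))),
            class = "search_encoding")
}

#' @rdname encode_search_space
#' @param bits Bit vector of length `descriptor$total_bits`.
#' @param descriptor A `search_encoding`.
#' @return Named list: the decoded parameter setting.
#' @export
decode_candidate <- function(bits, descriptor) {
  if (length(bits) != descriptor$total_bits)
    stop_dim("expected ", descriptor$total_bits, " bits, got ", length(bits))
  if (!all(bits %in% c(0, 1))) stop_input("bits must be 0/1")
  out <- vector("list", length(descriptor$params))
  names(out) <- descriptor$params
  for (i in seq_along(descriptor$params)) {
    b <- descriptor$bits[i]
    if (b == 0) {
      out[[i]] <- descriptor$domains[[i]][1]
      next
    }
    slice <- bits[descriptor$offsets[i] + seq_len(b)]
    val <- sum(slice * 2^((b - 1):0))
    out[[i]] <- descriptor$domains[[i]][(val %% descriptor$cardinality[i]) + 1]
  }
  out
}
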