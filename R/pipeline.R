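#' DR grade class names
#'
#' The five severity levels: Normal, Mild, Moderate, Severe, PDR
#' (grades 0-4).
#' @export
dr_class_names <- c("Normal", "Mild", "Moderate", "Severe", "PDR")

# named fusion strategies: required block ids in their printed order
fusion_strategies <- list(
  FS1 = c("K1", "K2", "K3", "K4"),
  FS2 = c("L1", "L2", "L3"),
  FS3 = c("M1", "M2", "M3"))

#' Declare a feature block
#'
#' A named slab of features (samples x width) extracted from one source
#' (e.g. one backbone layer), the unit of feature fusion. Canonical block
#' ids and widths: K1 2048, K2 1920, K3 512, K4 1536 (full convolutional
#' bases), L1 1024, L2 1792, L3 512, M1 512, M2 512, M3 256 (intermediate
#' layers).
#'
#' @param id Block id (`K1`..`K4`, `L1`..`L3`, `M1`..`M3`, or a user tag).
#' @param data `samples x width` matrix.
#' @param width Declared width; must equal `ncol(data)`.
#' @param source Free-text provenance annotation.
#' @return A `feature_block`.
#' @export
feature_block <- function(id, data, width = ncol(data), source = "") {
  data <- as.matrix(data)
  if (ncol(data) != width)
    stop_dim("block ", id, " declares width ", width,
             " but has ", ncol(data), " columns")
  structure(list(id = id, width = as.integer(width),
                 source = source, data = data),
            class = "feature_block")
}

#' Fuse feature blocks by column-wise concatenation
#'
#' Blocks are concatenated in the listed order; the fused width is the sum
#' of the block widths. Named strategies pin the required block ids and
#' their order: `FS1 = K1,K2,K3,K4` (2048+1920+512+1536 = 6016),
#' `FS2 = L1,L2,L3` (1024+1792+512 = 3328), `FS3 = M1,M2,M3`
#' (512+512+256 = 1280). No scaling is applied unless `scale = TRUE`
#' (per-block z-scoring, off by default).
#'
#' @param blocks Ordered list of [feature_block()]s sharing one sample count.
#' @param strategy `"custom"` or one of `"FS1"`, `"FS2"`, `"FS3"`.
#' @param scale Z-score each block's columns before concatenation.
#' @return Fused `samples x sum(width)` matrix.
#' @export
fuse_features <- function(blocks, strategy = c("custom", "FS1", "FS2", "FS3"),
                          scale = FALSE) {
  strategy <- match.arg(strategy)
  if (length(blocks) == 0) stop_input("blocks must be non-empty")
  stopifnot(all(vapply(blocks, inherits, logical(1), "feature_block")))
  ids <- vapply(blocks, `[[`, character(1), "id")
  if (strategy != "custom") {
    want <- fusion_strategies[[strategy]]
    if (!identical(ids, want))
      stop_config(strategy, " requires blocks ", paste(want, collapse = ","),
                  " in that order; got ", paste(ids, collapse = ","))
  }
  ns <- vapply(blocks, function(b) nrow(b$data), integer(1))
  if (length(unique(ns)) != 1)
    stop_input("blocks are not sample-aligned: counts ",
               paste(ns, collapse = ","))
  mats <- lapply(blocks, function(b) {
    m <- b$data
    if (scale) {
      mu <- colMeans(m)
      sd <- apply(m, 2, stats::sd)
      sd[sd == 0] <- 1
      m <- sweep(sweep(m, 2, mu), 2, sd, `/`)
    }
    m
  })
  do.call(cbind, mats)
}

#' Simulate class-conditional Gaussian DR feature sets
#'
#' Emulates fused CNN feature vectors for the five DR grades as isotropic
#' Gaussians: class means sit on mutually orthogonal directions scaled so
#' every pair of means is exactly `separation` apart, and each class adds
#' `N(0, noise^2)` noise per coordinate. The default per-class counts follow
#' the canonical IDRiD grade profile (134, 20, 84, 74, 49 for grades 0-4).
#'
#' @param n_per_class Per-class sample counts (length = number of classes).
#' @param dim Feature dimension (must be >= the number of classes).
#' @param separation Pairwise distance between class means (>= 0).
#' @param noise Per-coordinate noise standard deviation.
#' @param seed Integer seed.
#' @param class_names Class labels; default the five DR grades.
#' @return A `labeled_feature_set`: `X` (matrix), `labels` (integer grades
#'   0-based), `classes`, `provenance` (all `"original"`).
#' @export
simulate_dr_features <- function(n_per_class = c(134, 20, 84, 74, 49),
                                 dim = 20, separation = 3, noise = 1,
                                 seed = NULL, class_names = dr_class_names) {
  k <- length(n_per_class)
  if (length(class_names) != k)
    stop_config("class_names must match n_per_class in length")
  if (any(n_per_class < 0)) stop_config("counts must be >= 0")
  if (sum(n_per_class) == 0) stop_input("all class counts are zero")
  if (dim < k) stop_config("dim must be >= the number of classes (", k, ")")
  if (separation < 0) stop_config("separation must be >= 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  # orthogonal unit directions e_c scaled by separation/sqrt(2) give
  # ||mu_i - mu_j|| = separation for every pair
  mu <- matrix(0, k, dim)
  for (c in seq_len(k)) mu[c, c] <- separation / sqrt(2)
  X <- matrix(0, sum(n_per_class), dim)
  labels <- integer(sum(n_per_class))
  at <- 0
  for (c in seq_len(k)) {
    n <- n_per_class[c]
    if (n == 0) next
    rows <- at + seq_len(n)
    X[rows, ] <- matrix(stats::rnorm(n * dim, sd = noise), n, dim,
                        byrow = TRUE) +
      matrix(mu[c, ], n, dim, byrow = TRUE)
    labels[rows] <- c - 1L
    at <- at + n
  }
  structure(list(X = X, labels = labels, classes = class_names,
                 provenance = rep("original", nrow(X))),
            class = "labeled_feature_set")
}

#' @export
print.labeled_feature_set <- function(x, ...) {
  tab <- table(factor(x$labels, levels = seq_along(x$classes) - 1,
                      labels = x$classes))
  cat(sprintf("Labeled feature set: %d samples x %d features (%d synthetic)\n",
              nrow(x$X), ncol(x$X), sum(x$provenance == "synthetic")))
  print(tab)
  invisible(x)
}

#' Balance classes up to the majority count
#'
#' Each minority class is topped up to the majority class count by
#' resampling its existing members (with replacement) and adding Gaussian
#' jitter with per-feature scale `jitter_scale` times the class's
#' per-feature standard deviation. Original rows are preserved bit-exactly;
#' added rows are flagged `"synthetic"`. With `jitter_scale = 0` the added
#' rows are exact copies.
#'
#' @param set A `labeled_feature_set`.
#' @param jitter_scale Jitter magnitude relative to the within-class
#'   per-feature standard deviation.
#' @param seed Optional seed (otherwise the current RNG stream is used).
#' @return A balanced `labeled_feature_set`.
#' @export
balance_classes <- function(set, jitter_scale = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  counts <- table(set$labels)
  present <- as.integer(names(counts))
  if (any(counts == 0) ||
      length(present) < length(set$classes))
    stop_input("every class needs at least one sample to balance from")
  target <- max(counts)
  add_X <- list(); add_lab <- integer(0)
  for (cl in present) {
    idx <- which(set$labels == cl)
    need <- target - length(idx)
    if (need == 0) next
    pick <- idx[sample.int(length(idx), need, replace = TRUE)]
    base <- set$X[pick, , drop = FALSE]
    sds <- apply(set$X[idx, , drop = FALSE], 2, stats::sd)
    sds[!is.finite(sds)] <- 0
    jit <- matrix(stats::rnorm(need * ncol(base)), need) *
      matrix(jitter_scale * sds, need, ncol(base), byrow = TRUE)
    add_X[[length(add_X) + 1]] <- base + jit
    add_lab <- c(add_lab, rep(cl, need))
  }
  if (length(add_X) == 0) return(set)
  structure(list(X = rbind(set$X, do.call(rbind, add_X)),
                 labels = c(set$labels, add_lab),
                 classes = set$classes,
                 provenance = c(set$provenance,
                                rep("synthetic", length(add_lab)))),
            class = "labeled_feature_set")
}

#' Split a labeled feature set
#'
#' Stratified-free random split into train and test subsets.
#'
#' @param set A `labeled_feature_set`.
#' @param fraction Training fraction in (0, 1).
#' @param seed Optional seed.
#' @return List with `train` and `test` feature sets.
#' @export
split_feature_set <- function(set, fraction = 0.7, seed = NULL) {
  if (fraction <= 0 || fraction >= 1) stop_config("fraction must be in (0, 1)")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- nrow(set$X)
  tr <- sample.int(n, floor(fraction * n))
  subset_set <- function(i) structure(
    list(X = set$X[i, , drop = FALSE], labels = set$labels[i],
         classes = set$classes, provenance = set$provenance[i]),
    class = "labeled_feature_set")
  list(train = subset_set(tr), test = subset_set(setdiff(seq_len(n), tr)))
}

#' Tune ELM input weights and biases with KCBGWO
#'
#' Each continuous candidate is the flattened `G x n` input weight matrix
#' followed by the `G` biases (dimension `G * (n + 1)`, bounds `[-1, 1]`,
#' matching the random-initialization range of the network). The fitness of
#' a candidate is the mean squared error between the one-hot targets and the
#' outputs of the ELM whose output weights are solved by pseudoinverse —
#' on the training split itself by default (`fitness_split = "train"`), or
#' on an internal holdout carved from the training data
#' (`fitness_split = "holdout"`). The returned model is trained on the full
#' training set with the best candidate's weights and biases.
#'
#' @param train A `labeled_feature_set` (the training split).
#' @param G Hidden-node count.
#' @param activation Hidden activation.
#' @param config A [kcbgwo_config()] for the tuner; mode and bounds are
#'   forced to continuous `[-1, 1]`.
#' @param fitness_split `"train"` or `"holdout"`.
#' @param holdout_fraction Fraction of the training data reserved for the
#'   holdout fitness policy.
#' @return List with `model` (the tuned `elm`) and `optimization` (the
#'   KCBGWO `optimization_result`).
#' @export
tune_elm <- function(train, G = 40, activation = "sigmoid",
                     config = kcbgwo_config(N = 20, T = 30, K = 3, seed = 1),
                     fitness_split = c("train", "holdout"),
                     holdout_fraction = 0.25) {
  fitness_split <- match.arg(fitness_split)
  n <- ncol(train$X)
  G <- as.integer(G)
  dim_cand <- G * (n + 1)
  if (dim_cand > 1e6)
    stop_config("candidate dimension G*(n+1) = ", dim_cand,
                " exceeds 1e6; reduce G or the feature dimension")
  classes <- seq_along(train$classes) - 1L
  if (fitness_split == "holdout") {
    sp <- split_feature_set(train, 1 - holdout_fraction,
                            seed = derive_seed(config$seed %||% 0L, 77L))
    fit_train <- sp$train; fit_eval <- sp$test
  } else {
    fit_train <- train; fit_eval <- train
  }
  T_eval <- one_hot(fit_eval$labels, classes)
  unpack <- function(v) list(a = matrix(v[seq_len(G * n)], G, n),
                             c = v[G * n + seq_len(G)])
  objective <- function(v) {
    p <- unpack(v)
    m <- elm_train(fit_train$X, fit_train$labels, G, activation,
                   a = p$a, c = p$c, classes = classes)
    elm_mse(T_eval, predict(m, fit_eval$X))
  }
  cfg <- config
  cfg$mode <- "continuous"
  cfg$lower <- -1; cfg$upper <- 1
  opt <- kcbgwo(objective, cfg, D = dim_cand)
  best <- unpack(opt$best_position)
  model <- elm_train(train$X, train$labels, G, activation,
                     a = best$a, c = best$c, classes = classes)
  list(model = model, optimization = opt)
}

#' Evaluate a classifier on a held-out split
#'
#' Predicts by row-wise arg-max and reports the one-vs-rest metric table
#' (accuracy, sensitivity, specificity, precision per class, macro and
#' micro averages, per-class AUC from the raw scores).
#'
#' @param model An `elm` classification model.
#' @param test A `labeled_feature_set`.
#' @return A `metric_report`.
#' @export
evaluate_split <- function(model, test) {
  if (nrow(test$X) == 0) stop_input("empty test set")
  scores <- predict(model, test$X)
  pred <- model$classes[max.col(scores, ties.method = "first")]
  classification_report(test$labels, pred, classes = model$classes,
                        scores = scores)
}

#' Read / write labeled feature tables as CSV
#'
#' Header row, feature columns plus one integer label column (DR grades
#' 0-4).
#'
#' @param path CSV path.
#' @param label_col Name of the label column.
#' @param class_names Ordered class names.
#' @return A `labeled_feature_set`.
#' @export
read_feature_csv <- function(path, label_col = "label",
                             class_names = dr_class_names) {
  df <- utils::read.csv(path)
  if (!label_col %in% names(df))
    stop_input("label column '", label_col, "' not found")
  labels <- as.integer(df[[label_col]])
  if (any(labels < 0 | labels >= length(class_names)))
    stop_input("labels outside 0..", length(class_names) - 1)
  X <- as.matrix(df[setdiff(names(df), label_col)])
  structure(list(X = X, labels = labels, classes = class_names,
                 provenance = rep("original", nrow(X))),
            class = "labeled_feature_set")
}

#' @rdname read_feature_csv
#' @param set A `labeled_feature_set`.
#' @export
write_feature_csv <- function(set, path, label_col = "label") {
  df <- as.data.frame(set$X)
  df[[label_col]] <- set$labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
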