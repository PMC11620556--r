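activation_fun <- function(id) {
  switch(id,
         sigmoid = sigmoid_transfer,
         tanh = tanh,
         linear = identity,
         stop_config("unknown activation: ", id))
}

# Moore-Penrose pseudoinverse via SVD, singular values below
# tol * max(singular value) treated as zero (rank-tolerant).
mp_pinv <- function(M, tol = 1e-10) {
  s <- svd(M)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(M), nrow(M)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Hidden-layer output matrix of a single-hidden-layer network
#'
#' `M[j, i] = f(a_i . x_j + c_i)` for sample `j` and hidden node `i`: the
#' response of each of the `G` random hidden nodes to each of the `H`
#' samples.
#'
#' @param X `H x n` sample matrix.
#' @param a `G x n` input weight matrix (row `i` feeds hidden node `i`).
#' @param c Length-`G` bias vector.
#' @param activation `"sigmoid"`, `"tanh"` or `"linear"`.
#' @return `H x G` matrix.
#' @export
elm_hidden <- function(X, a, c, activation = "sigmoid") {
  X <- as.matrix(X); a <- as.matrix(a)
  if (ncol(X) != ncol(a)) stop_dim("X and a disagree on the feature dimension")
  if (length(c) != nrow(a)) stop_dim("bias length must equal the hidden-node count")
  f <- activation_fun(activation)
  f(X %*% t(a) + matrix(c, nrow(X), nrow(a), byrow = TRUE))
}

#' One-hot target encoding
#'
#' @param labels Vector of class labels.
#' @param classes Ordered class set; defaults to `sort(unique(labels))`.
#' @return `H x m` 0/1 matrix, one 1 per row.
#' @export
one_hot <- function(labels, classes = sort(unique(labels))) {
  m <- matrix(0, length(labels), length(classes),
              dimnames = list(NULL, as.character(classes)))
  idx <- match(labels, classes)
  if (anyNA(idx)) stop_input("labels outside the declared class set")
  m[cbind(seq_along(labels), idx)] <- 1
  m
}

#' Train an extreme learning machine
#'
#' A single-hidden-layer feed-forward network in which the `G` input weights
#' and biases are random (uniform in `[-1, 1]` unless supplied) and only the
#' output weights are learned, in closed form:
#' `w = pinv(M) %*% T` with `M` the hidden-layer output matrix and `pinv`
#' the Moore-Penrose pseudoinverse (SVD, singular-value cutoff
#' `1e-10 * max`). With `G` equal to the number of distinct samples the
#' network interpolates the targets (zero training error up to floating
#' point).
#'
#' @param X `H x n` training matrix.
#' @param y Targets: a factor/character/integer vector (classification;
#'   one-hot encoded internally) or a numeric vector/matrix (regression).
#' @param G Hidden-node count.
#' @param activation Hidden activation (`"sigmoid"`, `"tanh"`, `"linear"`).
#' @param a,c Optional explicit input weights (`G x n`) and biases
#'   (length `G`); drawn uniform `[-1, 1]` from the current RNG stream when
#'   omitted (seed beforehand for reproducibility).
#' @param classes Optional ordered class set for classification.
#' @return An `elm` model: weights, biases, output weights, activation,
#'   dimensions, class labels (classification only), and the training MSE.
#' @export
#' @examples
#' set.seed(1)
#' X <- matrix(runif(20), 10, 2)
#' y <- rowSums(X)
#' m <- elm_train(X, y, G = 10)
#' m$training_mse  # ~0: G = H interpolates
elm_train <- function(X, y, G, activation = "sigmoid",
                      a = NULL, c = NULL, classes = NULL) {
  X <- as.matrix(X)
  if (anyNA(X) || any(!is.finite(X))) stop_input("X contains non-finite values")
  H <- nrow(X); n <- ncol(X)
  G <- as.integer(G)
  if (G < 1 || H < 1) stop_config("G and H must be >= 1")
  classification <- is.factor(y) || is.character(y) ||
    (is.null(dim(y)) && is.integer(y)) || !is.null(classes)
  if (classification) {
    if (is.null(classes)) classes <- sort(unique(y))
    Tm <- one_hot(y, classes)
  } else {
    Tm <- as.matrix(y)
    if (anyNA(Tm) || any(!is.finite(Tm))) stop_input("targets contain non-finite values")
  }
  if (nrow(Tm) != H) stop_dim("targets and X disagree on the sample count")
  if (is.null(a)) a <- matrix(stats::runif(G * n, -1, 1), G, n)
  if (is.null(c)) c <- stats::runif(G, -1, 1)
  a <- as.matrix(a)
  if (!all(dim(a) == c(G, n))) stop_dim("a must be G x n")
  if (length(c) != G) stop_dim("c must have length G")
  M <- elm_hidden(X, a, c, activation)
  w <- mp_pinv(M) %*% Tm
  fitted <- M %*% w
  structure(list(G = G, n = n, m = ncol(Tm), activation = activation,
                 a = a, c = as.double(c), w = w,
                 classes = if (classification) classes else NULL,
                 training_mse = elm_mse(Tm, fitted)),
            class = "elm")
}

#' @export
print.elm <- function(x, ...) {
  cat(sprintf("ELM: %d -> %d (%s) -> %d, training MSE %.3e%s\n",
              x$n, x$G, x$activation, x$m, x$training_mse,
              if (!is.null(x$classes)) paste0(", ", length(x$classes), " classes")
              else ""))
  invisible(x)
}

#' Predict from a trained ELM
#'
#' @param object An `elm` model.
#' @param X New samples (`H x n`).
#' @param type `"raw"` for the network output matrix; `"class"` for row-wise
#'   arg-max labels (classification models only; ties go to the first class).
#' @param ... Unused.
#' @return Output matrix or label vector.
#' @export
predict.elm <- function(object, X, type = c("raw", "class"), ...) {
  type <- match.arg(type)
  X <- as.matrix(X)
  if (ncol(X) != object$n)
    stop_dim("X has ", ncol(X), " features but the model expects ", object$n)
  out <- elm_hidden(X, object$a, object$c, object$activation) %*% object$w
  if (type == "raw") return(out)
  if (is.null(object$classes)) stop_input("model was not trained for classification")
  object$classes[max.col(out, ties.method = "first")]
}

#' Mean squared error
#'
#' Mean over all entries of the squared differences between observed and
#' predicted values; the fitness function of the weight-tuning loop.
#'
#' @param observed,predicted Numeric vectors or matrices of equal shape.
#' @return Single number.
#' @export
elm_mse <- function(observed, predicted) {
  o <- as.matrix(observed); p <- as.matrix(predicted)
  if (!all(dim(o) == dim(p))) stop_dim("observed and predicted shapes differ")
  mean((o - p)^2)
}

#' Serialize / restore an ELM model as JSON
#'
#' Plain nested-array container holding every component needed to reproduce
#' predictions exactly.
#'
#' @param model An `elm`.
#' @param path File path.
#' @export
elm_to_json <- function(model, path) {
  out <- list(G = model$G, n = model$n, m = model$m,
              activation = model$activation,
              a = model$a, c = model$c, w = model$w,
              classes = model$classes, training_mse = model$training_mse)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname elm_to_json
#' @export
elm_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(G = as.integer(raw$G), n = as.integer(raw$n),
                 m = as.integer(raw$m), activation = raw$activation,
                 a = matrix(as.double(raw$a), raw$G, raw$n),
                 c = as.double(raw$c),
                 w = matrix(as.double(raw$w), raw$G, raw$m),
                 classes = raw$classes,
                 training_mse = raw$training_mse),
            class = "elm")
}
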