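# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dim <- function(...) stop(structure(
  class = c("kcbgwo_dimension_error", "error", "condition"),
  list(message = paste0(...), call = sys.call(-1))))

stop_config <- function(...) stop(structure(
  class = c("kcbgwo_config_error", "error", "condition"),
  list(message = paste0(...), call = sys.call(-1))))

stop_input <- function(...) stop(structure(
  class = c("kcbgwo_input_error", "error", "condition"),
  list(message = paste0(...), call = sys.call(-1))))

check_numeric_vector <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x)) stop_input(name, " must be numeric")
  if (anyNA(x) || any(!is.finite(x))) stop_input(name, " contains non-finite values")
  invisible(x)
}

# derive a deterministic 31-bit sub-seed from (seed, salt) without
# consuming the caller's RNG stream
derive_seed <- function(seed, salt) {
  s <- (as.double(seed) %% 2147483647) + 999983 * (as.double(salt) + 1)
  as.integer(s %% 2147483647L)
}

clamp <- function(x, lower, upper) pmin(pmax(x, lower), upper)
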