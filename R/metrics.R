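#' One-vs-rest confusion counts
#'
#' Tallies TP/FP/TN/FN for one class treated as positive against all others.
#'
#' @param y_true,y_pred Label vectors of equal length.
#' @param positive The positive class.
#' @return A `confusion_counts` list with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(y_true, y_pred, positive) {
  if (length(y_true) != length(y_pred))
    stop_input("y_true and y_pred lengths differ")
  tp <- sum(y_true == positive & y_pred == positive)
  fp <- sum(y_true != positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  tn <- sum(y_true != positive & y_pred != positive)
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn),
            class = "confusion_counts")
}

#' Accuracy, sensitivity, specificity and precision from counts
#'
#' The four standard quotients, as percentages:
#' `Ac = (TP+TN)/(TP+TN+FP+FN)`, `Sn = TP/(TP+FN)`, `Sp = TN/(TN+FP)`,
#' `Pr = TP/(TP+FP)`, each times 100. A zero denominator yields `NA`
#' (an explicit undefined marker), never 0 or 100.
#'
#' @param counts A [confusion_counts()] (or list with TP/FP/TN/FN).
#' @return Named numeric vector `c(Ac, Sn, Sp, Pr)` in percent.
#' @export
metrics_from_counts <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  tot <- tp + fp + tn + fn
  if (tot == 0) stop_input("all counts are zero")
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  c(Ac = ratio(tp + tn, tot),
    Sn = ratio(tp, tp + fn),
    Sp = ratio(tn, tn + fp),
    Pr = ratio(tp, tp + fp))
}

#' Multi-class classification report
#'
#' Per-class one-vs-rest counts and metrics, a macro average (unweighted
#' class mean, `NA`s dropped), and a micro average from pooled counts. The
#' micro accuracy is reported as pooled correct/total (which for pooled
#' one-vs-rest counts coincides with micro sensitivity). Optional per-class
#' AUC from a score matrix.
#'
#' @param y_true,y_pred Label vectors.
#' @param classes Ordered class set (default: union of observed labels).
#' @param scores Optional `H x m` score matrix (columns ordered as
#'   `classes`) for per-class one-vs-rest AUC.
#' @return A `metric_report`: `per_class` data frame, `macro`, `micro`,
#'   `accuracy` (overall percent correct), `n`, `classes`.
#' @export
classification_report <- function(y_true, y_pred, classes = NULL, scores = NULL) {
  if (length(y_true) == 0) stop_input("empty evaluation set")
  if (length(y_true) != length(y_pred))
    stop_input("y_true and y_pred lengths differ")
  if (is.null(classes)) classes <- sort(unique(c(y_true, y_pred)))
  per <- lapply(classes, function(cl) {
    cc <- confusion_counts(y_true, y_pred, cl)
    m <- metrics_from_counts(cc)
    auc <- NA_real_
    if (!is.null(scores)) {
      lab <- as.integer(y_true == cl)
      if (length(unique(lab)) == 2)
        auc <- roc_auc(scores[, match(cl, classes)], lab)
    }
    data.frame(class = as.character(cl), TP = cc$TP, FP = cc$FP,
               TN = cc$TN, FN = cc$FN,
               Ac = m["Ac"], Sn = m["Sn"], Sp = m["Sp"], Pr = m["Pr"],
               AUC = auc, stringsAsFactors = FALSE, row.names = NULL)
  })
  per <- do.call(rbind, per)
  macro <- colMeans(per[, c("Ac", "Sn", "Sp", "Pr")], na.rm = TRUE)
  pooled <- list(TP = sum(per$TP), FP = sum(per$FP),
                 TN = sum(per$TN), FN = sum(per$FN))
  micro <- metrics_from_counts(pooled)
  overall <- 100 * mean(y_true == y_pred)
  micro["Ac"] <- overall
  structure(list(per_class = per, macro = macro, micro = micro,
                 accuracy = overall, n = length(y_true),
                 classes = as.character(classes)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("Classification report (n = %d), overall accuracy %.2f%%\n",
              x$n, x$accuracy))
  print(x$per_class, digits = 4)
  cat("macro:", paste(sprintf("%s=%.2f", names(x$macro), x$macro),
                      collapse = "  "), "\n")
  invisible(x)
}

#' Serialize a metric report to JSON / confusion counts to CSV
#'
#' @param report A `metric_report`.
#' @param path Output path.
#' @export
report_to_json <- function(report, path) {
  jsonlite::write_json(
    list(per_class = report$per_class, macro = as.list(report$macro),
         micro = as.list(report$micro), accuracy = report$accuracy,
         n = report$n, classes = report$classes),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname report_to_json
#' @export
confusion_to_csv <- function(report, path) {
  utils::write.csv(report$per_class[, c("class", "TP", "FP", "TN", "FN")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Rank-based ROC AUC
#'
#' The probability that a uniformly chosen positive outscores a uniformly
#' chosen negative, with ties counted half — the normalized Mann-Whitney
#' statistic. Invariant under strictly monotone transformations of the
#' scores.
#'
#' @param scores Numeric score vector.
#' @param labels Binary labels (0/1 or logical); both classes must occur.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels))
    stop_input("scores and labels lengths differ")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop_input("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Jaccard overlap coefficient of two binary masks
#'
#' Intersection over union. Two empty masks agree perfectly and return 1 by
#' convention.
#'
#' @param mask_a,mask_b Binary (logical or 0/1) arrays of equal shape.
#' @return Value in `[0, 1]`.
#' @export
jaccard_index <- function(mask_a, mask_b) {
  a <- as.logical(mask_a); b <- as.logical(mask_b)
  da <- dim(mask_a) %||% length(mask_a)
  db <- dim(mask_b) %||% length(mask_b)
  if (!identical(da, db)) stop_dim("mask shapes differ")
  uni <- sum(a | b)
  if (uni == 0) return(1)
  sum(a & b) / uni
}
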