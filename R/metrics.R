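# ---------------------------------------------------------------------------
# Overlap metrics on pixel confusion counts, and the soft Dice loss:
#   Dice      = 2TP / (2TP + FP + FN)
#   Jaccard   =  TP / (TP + FP + FN)
#   Precision =  TP / (TP + FP)
#   Recall    =  TP / (TP + FN)
#   Accuracy  = (TP + TN) / (TP + TN + FP + FN)
# Zero-denominator convention: if both masks are empty the overlap metrics
# are 1 (perfect agreement); if exactly one is empty the affected metrics
# are 0. Accuracy is always defined.
# ---------------------------------------------------------------------------

check_binary <- function(m, what = "mask") {
  if (!all(m %in% c(0, 1))) stop(what, " must be binary (0/1)")
  invisible(m)
}

#' Pixel confusion counts between two binary masks
#'
#' @param pred,truth binary arrays/matrices of identical shape; foreground
#'   is the positive class.
#' @return a `confusion_counts` list with TP, FP, FN, TN.
#' @export
#' @examples
#' confusion(matrix(c(1, 1, 0, 1), 2), matrix(c(1, 0, 1, 1), 2))
confusion <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth)) {
    stop("pred and truth must have identical shape")
  }
  check_binary(pred, "pred")
  check_binary(truth, "truth")
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  tn <- sum(pred == 0 & truth == 0)
  structure(list(TP = tp, FP = fp, FN = fn, TN = tn),
            class = "confusion_counts")
}

#' Overlap metrics from confusion counts
#'
#' @param c a [confusion()] result or a list with TP, FP, FN, TN.
#' @return a value in \[0, 1\].
#' @name overlap-metrics
NULL

#' @rdname overlap-metrics
#' @export
dice <- function(c) {
  den <- 2 * c$TP + c$FP + c$FN
  if (den == 0) 1 else 2 * c$TP / den
}

#' @rdname overlap-metrics
#' @export
jaccard <- function(c) {
  den <- c$TP + c$FP + c$FN
  if (den == 0) 1 else c$TP / den
}

#' @rdname overlap-metrics
#' @export
precision <- function(c) {
  if (c$TP + c$FP == 0) return(if (c$FN == 0) 1 else 0)
  c$TP / (c$TP + c$FP)
}

#' @rdname overlap-metrics
#' @export
recall <- function(c) {
  if (c$TP + c$FN == 0) return(if (c$FP == 0) 1 else 0)
  c$TP / (c$TP + c$FN)
}

#' @rdname overlap-metrics
#' @export
accuracy <- function(c) {
  (c$TP + c$TN) / (c$TP + c$TN + c$FP + c$FN)
}

all_metrics <- function(cc) {
  c(dice = dice(cc), jaccard = jaccard(cc), precision = precision(cc),
    recall = recall(cc), accuracy = accuracy(cc))
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(p*t) + eps) / (sum(p) + sum(t) + eps)`, the differentiable
#' training objective; equals `1 - Dice` for crisp (0/1) predictions up to
#' the smoothing term.
#'
#' @param prob probability map in \[0, 1\].
#' @param truth binary mask of identical shape.
#' @param eps smoothing constant (default 1e-6).
#' @return scalar loss in \[0, 1\].
#' @export
dice_loss <- function(prob, truth, eps = 1e-6) {
  if (length(prob) != length(truth)) {
    stop("prob and truth must have identical shape")
  }
  if (any(prob < 0 | prob > 1)) stop("prob must lie in [0, 1]")
  check_binary(truth, "truth")
  1 - (2 * sum(prob * truth) + eps) / (sum(prob) + sum(truth) + eps)
}

#' Evaluate a set of predictions
#'
#' Binarizes each probability map at `threshold`, computes the five overlap
#' metrics per image, and reports per-image values plus their arithmetic
#' means ("mean Dice" aggregation). Set `pooled = TRUE` to instead pool the
#' confusion counts over all pixels of the set before computing metrics.
#'
#' @param preds list of probability maps (or an H x W x N array).
#' @param truths list of binary masks (or an H x W x N array).
#' @param threshold binarization threshold in (0, 1); default 0.5.
#' @param ids optional image identifiers.
#' @param pooled pool pixel counts across images instead of averaging
#'   per-image metrics.
#' @return a `metrics_report` with `$per_image` (data.frame), `$means`
#'   (named vector), and `$n_images`.
#' @export
evaluate_set <- function(preds, truths, threshold = 0.5, ids = NULL,
                         pooled = FALSE) {
  preds <- as_map_list(preds)
  truths <- as_map_list(truths)
  if (length(preds) == 0L) stop("empty prediction list")
  if (length(preds) != length(truths)) {
    stop("preds and truths must have equal length")
  }
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (is.null(ids)) ids <- sprintf("img_%04d", seq_along(preds))
  rows <- matrix(0, length(preds), 5,
                 dimnames = list(NULL, c("dice", "jaccard", "precision",
                                         "recall", "accuracy")))
  pool <- list(TP = 0, FP = 0, FN = 0, TN = 0)
  for (i in seq_along(preds)) {
    cc <- confusion((preds[[i]] >= threshold) * 1, truths[[i]])
    rows[i, ] <- all_metrics(cc)
    for (k in names(pool)) pool[[k]] <- pool[[k]] + cc[[k]]
  }
  means <- if (pooled) all_metrics(structure(pool, class = "confusion_counts"))
           else colMeans(rows)
  structure(list(per_image = data.frame(image_id = ids, rows,
                                        stringsAsFactors = FALSE),
                 means = means, n_images = length(preds), pooled = pooled),
            class = "metrics_report")
}

as_map_list <- function(x) {
  if (is.list(x)) return(x)
  d <- dim(x)
  if (is.matrix(x)) return(list(x))
  if (length(d) == 3L) return(lapply(seq_len(d[3]), function(i) x[, , i]))
  stop("expected a list of maps or an H x W x N array")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Metrics over %d image(s)%s:\n", x$n_images,
              if (isTRUE(x$pooled)) " (pooled pixel counts)" else ""))
  print(round(x$means, 4))
  invisible(x)
}

#' Write a metrics report to CSV
#'
#' One row per image (image_id, dice, jaccard, precision, recall, accuracy)
#' plus a final `mean` row.
#'
#' @param report a [evaluate_set()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(report, path) {
  df <- report$per_image
  df <- rbind(df, data.frame(image_id = "mean", t(report$means),
                             stringsAsFactors = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
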