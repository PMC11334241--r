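#' Mean absolute error
#'
#' \code{mean(|y_true - y_pred|)}.
#'
#' @param y_true,y_pred Numeric vectors of equal, non-zero length.
#' @return Non-negative scalar.
#' @examples
#' mae(c(70, 80), c(72, 77))  # 2.5
#' @export
mae <- function(y_true, y_pred) {
  if (!length(y_true)) stopf("inputs must be non-empty")
  if (length(y_true) != length(y_pred))
    stopf("length mismatch: %d vs %d", length(y_true), length(y_pred))
  mean(abs(y_true - y_pred))
}

#' F1 score from confusion counts
#'
#' Precision = TP/(TP+FP), Recall = TP/(TP+FN), F1 = 2PR/(P+R).  Degenerate
#' cases follow the standard zero-rule: if TP = 0 and FP + FN > 0, precision,
#' recall and F1 are 0; with TP = FP = FN = 0 the classifier is vacuously
#' perfect and F1 is 1.
#'
#' @param tp,fp,fn,tn Non-negative integer counts (tn is carried but unused
#'   by F1).
#' @return List with \code{precision}, \code{recall}, \code{f1}.
#' @examples
#' f1_score(tp = 2, fp = 1, fn = 1)$f1  # 2/3
#' @export
f1_score <- function(tp, fp, fn, tn = 0) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("confusion counts must be non-negative integers")
  if (tp == 0 && fp == 0 && fn == 0)
    return(list(precision = 1, recall = 1, f1 = 1))
  if (tp == 0) return(list(precision = 0, recall = 0, f1 = 0))
  precision <- tp / (tp + fp)
  recall <- tp / (tp + fn)
  list(precision = precision, recall = recall,
       f1 = 2 * precision * recall / (precision + recall))
}

confusion_counts <- function(truth, pred, positive = 1) {
  list(tp = sum(truth == positive & pred == positive),
       fp = sum(truth != positive & pred == positive),
       fn = sum(truth == positive & pred != positive),
       tn = sum(truth != positive & pred != positive))
}

#' Artifact-Tolerance curve
#'
#' Evaluates a metric over cumulative test subgroups defined by an upper
#' limit u on per-sample signal quality (artifact fraction): the subgroup at
#' u contains all samples with quality <= u, so the top threshold covers the
#' whole test set and its metric equals the overall metric.  Subgroup sizes
#' are therefore non-decreasing in u.  Empty subgroups get size 0 and an NA
#' metric.
#'
#' @param quality Per-sample artifact fractions in [0, 1].
#' @param y_true,y_pred Aligned targets and predictions (numeric for MAE;
#'   binary 0/1 labels for F1).
#' @param metric_name \code{"mae"} or \code{"f1"}.
#' @param thresholds Ascending quality upper limits in [0, 1]
#'   (default 0, 0.1, ..., 1).
#' @return Data.frame of class \code{at_curve} with columns
#'   \code{threshold}, \code{n}, \code{metric}.
#' @examples
#' at_curve(c(0.1, 0.5, 0.9), c(0, 0, 0), c(1, 2, 3), "mae", c(0.2, 1))
#' @export
at_curve <- function(quality, y_true, y_pred, metric_name = c("mae", "f1"),
                     thresholds = seq(0, 1, by = 0.1)) {
  metric_name <- match.arg(metric_name)
  n <- length(quality)
  if (length(y_true) != n || length(y_pred) != n)
    stopf("`quality`, `y_true` and `y_pred` must be aligned (lengths %d, %d, %d)",
          n, length(y_true), length(y_pred))
  if (is.unsorted(thresholds, strictly = FALSE) ||
      any(thresholds < 0 | thresholds > 1))
    stopf("`thresholds` must be ascending fractions in [0, 1]")
  rows <- lapply(thresholds, function(u) {
    idx <- which(quality <= u)
    m <- if (!length(idx)) NA_real_
    else if (metric_name == "mae") mae(y_true[idx], y_pred[idx])
    else {
      cc <- confusion_counts(y_true[idx], y_pred[idx])
      f1_score(cc$tp, cc$fp, cc$fn, cc$tn)$f1
    }
    data.frame(threshold = u, n = length(idx), metric = m)
  })
  out <- do.call(rbind, rows)
  attr(out, "metric_name") <- metric_name
  class(out) <- c("at_curve", "data.frame")
  out
}

#' @export
print.at_curve <- function(x, ...) {
  cat(sprintf("<at_curve> metric = %s\n", attr(x, "metric_name")))
  print.data.frame(x)
  invisible(x)
}

#' Plot an Artifact-Tolerance curve
#'
#' Bars show cumulative subgroup sizes; the overlaid line traces the metric
#' within each subgroup.
#'
#' @param x An \code{at_curve}.
#' @param ... Passed to \code{barplot}.
#' @export
plot.at_curve <- function(x, ...) {
  mids <- graphics::barplot(x$n, names.arg = x$threshold,
                            xlab = "quality upper limit",
                            ylab = "subgroup size", ...)
  graphics::par(new = TRUE)
  graphics::plot(mids, x$metric, type = "b", axes = FALSE, xlab = "",
                 ylab = "", col = "red3", pch = 16)
  graphics::axis(4, col.axis = "red3")
  graphics::mtext(attr(x, "metric_name"), side = 4, line = 2, col = "red3")
  invisible(x)
}

cosine_similarity_matrix <- function(emb) {
  nrm <- sqrt(rowSums(emb^2))
  nrm[nrm == 0] <- 1
  zn <- emb / nrm
  tcrossprod(zn)
}

#' Latent-space clustering diagnostics
#'
#' Quantifies whether embeddings cluster by physiological state (heart rate)
#' rather than by noise level: reports the mean cosine similarity of
#' same-group pairs (restricted to pairs with different noise levels when
#' noise annotations are given), the mean similarity of different-group
#' pairs, their gap, and a silhouette-style score computed on the
#' 1 - cosine distance with the group as label.
#'
#' @param embeddings Matrix, one row per embedding.
#' @param group Grouping label per row (e.g. heart rate); at least two
#'   distinct groups, each with at least one member.
#' @param noise_level Optional per-row noise annotation; when present,
#'   within-group similarity averages only across-noise pairs.
#' @return List with \code{within}, \code{between}, \code{gap},
#'   \code{silhouette}.
#' @export
latent_diagnostics <- function(embeddings, group, noise_level = NULL) {
  if (is.vector(embeddings)) embeddings <- matrix(embeddings, nrow = 1)
  n <- nrow(embeddings)
  if (length(group) != n) stopf("`group` must have one label per embedding")
  group <- as.character(group)
  if (length(unique(group)) < 2)
    stopf("need at least two distinct groups")
  S <- cosine_similarity_matrix(embeddings)
  same <- outer(group, group, "==")
  diag(same) <- NA
  pairmask_within <- same
  if (!is.null(noise_level)) {
    diffnoise <- outer(noise_level, noise_level, "!=")
    pairmask_within <- same & diffnoise
    if (!any(pairmask_within, na.rm = TRUE))
      pairmask_within <- same  # fall back: no across-noise pairs exist
  }
  within <- mean(S[which(pairmask_within)], na.rm = TRUE)
  between <- mean(S[which(!same)], na.rm = TRUE)

  # silhouette on 1 - cosine distance
  D <- 1 - S
  sil <- vapply(seq_len(n), function(i) {
    a <- mean(D[i, group == group[i] & seq_len(n) != i])
    if (is.nan(a)) return(0)
    b <- min(vapply(setdiff(unique(group), group[i]),
                    function(g) mean(D[i, group == g]), 0))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, 0)
  list(within = within, between = between, gap = within - between,
       silhouette = mean(sil))
}
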