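# ROC machinery: every classifier in the package reduces to a per-sample
# scalar score, evaluated by the area under the empirical ROC curve.

#' Per-sample scores with class labels
#'
#' @param scores numeric vector of per-sample scalar scores.
#' @param labels character/factor vector of `"normal"`/`"tumor"`, same length.
#' @param orientation `"tumor_high"` if larger scores indicate tumor,
#'   `"tumor_low"` otherwise.
#' @return an object of class `score_set`.
#' @export
score_set <- function(scores, labels, orientation = c("tumor_high", "tumor_low")) {
  orientation <- match.arg(orientation)
  labels <- as.character(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels must have the same length", call. = FALSE)
  }
  if (!all(labels %in% c("normal", "tumor"))) {
    stop("labels must be 'normal' or 'tumor'", call. = FALSE)
  }
  if (anyNA(scores) || any(!is.finite(scores))) {
    stop("scores must be finite", call. = FALSE)
  }
  structure(list(scores = as.double(scores), labels = labels,
                 orientation = orientation),
            class = "score_set")
}

#' @export
print.score_set <- function(x, ...) {
  cat(sprintf("<score_set> %d samples (%d normal, %d tumor), %s\n",
              length(x$scores), sum(x$labels == "normal"),
              sum(x$labels == "tumor"), x$orientation))
  invisible(x)
}

# Oriented scores: larger value = more tumor-like, whatever the stored
# orientation.
oriented_scores <- function(ss) {
  if (ss$orientation == "tumor_low") -ss$scores else ss$scores
}

check_two_classes <- function(labels) {
  if (!any(labels == "normal") || !any(labels == "tumor")) {
    stop("ROC computation needs at least one sample in each class",
         call. = FALSE)
  }
}

# Fast rank-based AUC for a numeric score vector under tumor_high
# orientation. Equals the Mann-Whitney statistic: the fraction of
# (normal, tumor) pairs in which the tumor score exceeds the normal score,
# ties counted one half.
auroc_raw <- function(scores, is_tumor) {
  r <- rank(scores)
  nt <- sum(is_tumor)
  nn <- length(scores) - nt
  (sum(r[is_tumor]) - nt * (nt + 1) / 2) / (nt * nn)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic: the probability that a randomly
#' chosen tumor sample scores higher than a randomly chosen normal sample,
#' ties counted 0.5, under the score set's tumor-high orientation.
#'
#' @param ss a [score_set] with both classes present.
#' @return the auROC, in \[0, 1\].
#' @examples
#' auroc(score_set(c(1, 2, 3, 4, 5, 6),
#'                 rep(c("normal", "tumor"), each = 3)))
#' @export
auroc <- function(ss) {
  stopifnot(inherits(ss, "score_set"))
  check_two_classes(ss$labels)
  auroc_raw(oriented_scores(ss), ss$labels == "tumor")
}

#' Empirical ROC curve with a suggested operating threshold
#'
#' Builds the full empirical ROC curve of a [score_set] and suggests an
#' operating threshold at the maximum of Youden's J = sensitivity +
#' specificity - 1 (ties broken toward higher specificity, then toward the
#' higher threshold). The area under the curve is the trapezoidal area,
#' which equals [auroc] exactly.
#'
#' @param ss a [score_set].
#' @return an object of class `roc_result`: `thresholds` (decreasing, on the
#'   oriented score scale; first entry `Inf`), `tpr`, `fpr` (nondecreasing
#'   along the curve), `auroc`, `suggested_threshold`, `sens_at_threshold`,
#'   `spec_at_threshold`. A sample is called tumor when its oriented score
#'   is `>=` the threshold.
#' @export
roc_curve <- function(ss) {
  stopifnot(inherits(ss, "score_set"))
  check_two_classes(ss$labels)
  sc <- oriented_scores(ss)
  is_tumor <- ss$labels == "tumor"
  nt <- sum(is_tumor); nn <- sum(!is_tumor)
  cuts <- sort(unique(sc), decreasing = TRUE)
  thresholds <- c(Inf, cuts)
  tpr <- vapply(thresholds, function(t) sum(sc[is_tumor] >= t) / nt, numeric(1L))
  fpr <- vapply(thresholds, function(t) sum(sc[!is_tumor] >= t) / nn, numeric(1L))
  area <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  youden <- tpr - fpr
  best <- which(youden == max(youden))
  if (length(best) > 1L) best <- best[order(fpr[best], -thresholds[best])][1L]
  # Place the suggested cutoff between the classes rather than exactly on a
  # sample score, when a gap exists above the chosen cut.
  thr <- thresholds[best]
  if (is.finite(thr)) {
    below <- sc[sc < thr]
    if (length(below)) thr <- (thr + max(below)) / 2
  } else {
    thr <- max(sc) + 1
  }
  structure(list(thresholds = thresholds, tpr = tpr, fpr = fpr,
                 auroc = area,
                 suggested_threshold = thr,
                 sens_at_threshold = tpr[best],
                 spec_at_threshold = 1 - fpr[best]),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> auROC = %.3f; suggested threshold %.4g (sens %.2f, spec %.2f)\n",
              x$auroc, x$suggested_threshold, x$sens_at_threshold,
              x$spec_at_threshold))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "s", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "1 - specificity", ylab = "sensitivity", ...)
  graphics::abline(0, 1, lty = 3, col = "grey")
  i <- which.min(abs(x$tpr - x$sens_at_threshold) +
                   abs((1 - x$fpr) - x$spec_at_threshold))
  graphics::points(x$fpr[i], x$tpr[i], col = "red", pch = 19)
  invisible(x)
}
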