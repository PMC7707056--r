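# The user-facing fitted model: PCA + auROC-driven component selection +
# random-search linear discriminant, wrapped as one classed object.

#' Fit a PCA-LDA spectral classifier
#'
#' The central fitting function: computes a mean-centered PCA basis of the
#' preprocessed dataset, selects the most discriminative components by
#' greedy auROC-driven forward selection, trains the random-search linear
#' discriminant on the selected PC scores, and records the training ROC
#' curve with a Youden-suggested operating threshold.
#'
#' @param d a preprocessed [spectral_dataset] with both tissue classes.
#' @param n_components PCA working dimensionality (default 15).
#' @param n_select number of components entering the discriminant (default 4).
#' @param stop_n stop rule of the final random search (default 500).
#' @param stop_n_select stop rule of the per-candidate searches inside the
#'   greedy selection (default 200).
#' @param pc_indices optional integer vector forcing the selected components
#'   (bypasses [select_pcs]); e.g. `c(3, 7, 10, 13)`.
#' @param seed integer seed; the fit is fully reproducible.
#' @return an object of class `spectral_classifier` with components `basis`
#'   ([pca_fit]), `selected` (PC indices), `combo`
#'   ([random_search_lda] result), `scores` (training [score_set]), `roc`
#'   ([roc_curve] result), `modality`, `call`.
#' @seealso [predict.spectral_classifier], [kfold_cv], [fuse_scores]
#' @export
fit_spectral_classifier <- function(d, n_components = 15L, n_select = 4L,
                                    stop_n = 500L, stop_n_select = 200L,
                                    pc_indices = NULL, seed = NULL) {
  stopifnot(inherits(d, "spectral_dataset"))
  check_two_classes(d$meta$label)
  basis <- pca_fit(d, n_components = n_components)
  proj <- project(d, basis)
  selected <- if (is.null(pc_indices)) {
    select_pcs(proj, d$meta$label, n_select = n_select,
               stop_n = stop_n_select, rng_seed = derive_seed(seed, 1))
  } else {
    stopifnot(all(pc_indices >= 1L), all(pc_indices <= basis$n_kept))
    as.integer(pc_indices)
  }
  combo <- random_search_lda(proj[, selected, drop = FALSE], d$meta$label,
                             stop_n = stop_n,
                             rng_seed = derive_seed(seed, 2),
                             pc_indices = as.integer(selected))
  scores <- score_set(combo_score(combo, proj[, selected, drop = FALSE]),
                      d$meta$label)
  structure(list(basis = basis,
                 selected = as.integer(selected),
                 pc_aurocs = attr(selected, "pc_aurocs"),
                 combo = combo,
                 scores = scores,
                 roc = roc_curve(scores),
                 modality = d$modality,
                 labels = d$meta$label,
                 call = match.call()),
            class = "spectral_classifier")
}

#' @export
print.spectral_classifier <- function(x, ...) {
  cat(sprintf("PCA-LDA spectral classifier (%s)\n", x$modality))
  cat(sprintf("  selected components: PC%s\n",
              paste(x$selected, collapse = ", PC")))
  cat(sprintf("  training auROC: %.3f (%d search draws)\n",
              x$combo$train_auroc, x$combo$n_draws))
  cat(sprintf("  suggested threshold: %.4g (sens %.2f, spec %.2f)\n",
              x$roc$suggested_threshold, x$roc$sens_at_threshold,
              x$roc$spec_at_threshold))
  invisible(x)
}

#' @export
summary.spectral_classifier <- function(object, ...) {
  out <- list(modality = object$modality,
              selected = object$selected,
              coefficients = stats::coef(object),
              train_auroc = object$combo$train_auroc,
              sens = object$roc$sens_at_threshold,
              spec = object$roc$spec_at_threshold,
              threshold = object$roc$suggested_threshold,
              explained_variance = object$basis$explained_variance)
  class(out) <- "summary.spectral_classifier"
  out
}

#' @export
print.summary.spectral_classifier <- function(x, ...) {
  cat(sprintf("PCA-LDA spectral classifier (%s)\n", x$modality))
  cat("  signed coefficients on selected PC scores:\n")
  print(round(x$coefficients, 3))
  cat(sprintf("  train auROC %.3f; threshold %.4g -> sens %.2f / spec %.2f\n",
              x$train_auroc, x$threshold, x$sens, x$spec))
  invisible(x)
}

#' @export
coef.spectral_classifier <- function(object, ...) {
  stats::setNames(object$combo$coefficients * object$combo$sign_flips,
                  paste0("PC", object$selected))
}

#' Score new spectra with a fitted classifier
#'
#' Projects new (preprocessed, same grid) spectra onto the stored PCA basis
#' and applies the trained linear combination; larger scores indicate tumor.
#'
#' @param object a [fit_spectral_classifier] result.
#' @param newdata a [spectral_dataset] or intensity matrix on the training
#'   grid; defaults to the training scores.
#' @param type `"score"` for the continuous discriminant value, `"class"`
#'   for the thresholded `"normal"`/`"tumor"` call at the suggested
#'   threshold.
#' @param ... unused.
#' @return numeric scores or a character vector of class calls.
#' @export
predict.spectral_classifier <- function(object, newdata = NULL,
                                        type = c("score", "class"), ...) {
  type <- match.arg(type)
  sc <- if (is.null(newdata)) {
    object$scores$scores
  } else {
    proj <- project(newdata, object$basis)
    combo_score(object$combo, proj[, object$selected, drop = FALSE])
  }
  if (type == "score") return(sc)
  ifelse(sc >= object$roc$suggested_threshold, "tumor", "normal")
}

#' @export
plot.spectral_classifier <- function(x, which = c("roc", "scores"), ...) {
  which <- match.arg(which)
  if (which == "roc") {
    plot(x$roc, main = sprintf("%s classifier, auROC %.2f", x$modality,
                               x$roc$auroc), ...)
  } else {
    is_tumor <- x$labels == "tumor"
    graphics::stripchart(list(normal = x$scores$scores[!is_tumor],
                              tumor = x$scores$scores[is_tumor]),
                         vertical = TRUE, method = "jitter", pch = 19,
                         col = c("black", "red"), ylab = "classifier score", ...)
    graphics::abline(h = x$roc$suggested_threshold, lty = 2)
  }
  invisible(x)
}

#' Cross-validate a fitted classifier's configuration
#'
#' Convenience wrapper re-running the full selection + search pipeline under
#' stratified k-fold CV on the dataset, with the fitted model's settings.
#'
#' @param object a [fit_spectral_classifier] result.
#' @param d the [spectral_dataset] it was fitted to.
#' @param k folds (default 4).
#' @param seed integer seed.
#' @return see [kfold_cv].
#' @export
cv_classifier <- function(object, d, k = 4L, seed = NULL) {
  proj <- project(d, object$basis)
  kfold_cv(proj, d$meta$label, k = k, rng_seed = seed,
           n_select = length(object$selected))
}
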