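# Principal-component analysis of spectral datasets.

#' Fit a PCA basis to a spectral dataset
#'
#' Mean-centered PCA of the sample-by-wavelength intensity matrix, keeping
#' the leading `n_components` components (15 by default, matching the usual
#' working dimensionality before auROC-driven selection). Components carry a
#' deterministic sign convention: the loading element of largest magnitude
#' is positive.
#'
#' @param d a [spectral_dataset] (or a plain numeric matrix) with at least 2
#'   samples.
#' @param n_components number of components to keep; reduced with a warning
#'   when the matrix rank is lower.
#' @return an object of class `pca_basis`: `mean_spectrum`, `components`
#'   (n_kept x n_points, orthonormal rows), `explained_variance`
#'   (nonincreasing), `n_kept`.
#' @export
pca_fit <- function(d, n_components = 15L) {
  m <- if (inherits(d, "spectral_dataset")) d$matrix else as.matrix(d)
  n <- nrow(m)
  if (n < 2L) stop("PCA needs at least 2 samples", call. = FALSE)
  n_components <- min(n_components, n - 1L, ncol(m))
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  var_exp <- pc$sdev^2
  nonzero <- sum(var_exp > max(var_exp) * 1e-12)
  if (nonzero == 0L || max(var_exp) == 0) {
    stop("dataset has zero variance; PCA basis is empty", call. = FALSE)
  }
  n_kept <- min(n_components, nonzero)
  if (n_kept < n_components) {
    warning(sprintf("rank deficiency: keeping %d of %d requested components",
                    n_kept, n_components))
  }
  comp <- t(pc$rotation[, seq_len(n_kept), drop = FALSE])
  for (j in seq_len(n_kept)) {
    i <- which.max(abs(comp[j, ]))
    if (comp[j, i] < 0) comp[j, ] <- -comp[j, ]
  }
  structure(list(mean_spectrum = pc$center,
                 components = comp,
                 explained_variance = var_exp[seq_len(n_kept)],
                 n_kept = n_kept),
            class = "pca_basis")
}

#' @export
print.pca_basis <- function(x, ...) {
  pv <- x$explained_variance / sum(x$explained_variance)
  cat(sprintf("<pca_basis> %d components x %d points; leading shares %s\n",
              x$n_kept, ncol(x$components),
              paste(sprintf("%.1f%%", 100 * pv[seq_len(min(3, x$n_kept))]),
                    collapse = ", ")))
  invisible(x)
}

#' Project spectra onto a PCA basis
#'
#' Centers each spectrum with the basis mean and projects onto the retained
#' components, yielding the per-sample PC scores used as classifier
#' features.
#'
#' @param d a [spectral_dataset] or numeric matrix on the same axis/grid as
#'   the basis.
#' @param b a [pca_fit] result.
#' @return numeric matrix, n_samples x n_kept; column `j` is the score on
#'   component `j`.
#' @export
project <- function(d, b) {
  stopifnot(inherits(b, "pca_basis"))
  m <- if (inherits(d, "spectral_dataset")) d$matrix else if (is.matrix(d)) d
  else matrix(d, nrow = 1L)
  if (ncol(m) != length(b$mean_spectrum)) {
    stop("axis mismatch between dataset and PCA basis", call. = FALSE)
  }
  sweep(m, 2L, b$mean_spectrum) %*% t(b$components)
}

# Reconstruct spectra from PC scores (internal; used for completeness
# checks and classifier visualisation).
pca_reconstruct <- function(scores, b) {
  sweep(scores %*% b$components, 2L, b$mean_spectrum, `+`)
}
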