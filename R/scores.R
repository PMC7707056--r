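# Simple univariate classifiers: band ratios, long-wavelength slope,
# EGFP peak readout.

#' Ratiometric band score
#'
#' Intensity ratio between two axis positions, `value_at(s, x1) /
#' value_at(s, x2)`. Standard pairs: reflectance 570/690 nm (oxygenation
#' contrast), Raman 1450/985 and 1450/2030 cm^-1.
#'
#' @param s a [spectrum].
#' @param x1 numerator axis position.
#' @param x2 denominator axis position; interpolated intensity must be > 0.
#' @param half_window optional band half-window average (default 0 = peak
#'   height).
#' @return the intensity ratio.
#' @export
ratiometric_score <- function(s, x1, x2, half_window = 0) {
  num <- value_at(s, x1, half_window = half_window)
  den <- value_at(s, x2, half_window = half_window)
  if (!is.finite(den) || den <= 0) {
    stop(sprintf("nonpositive denominator intensity at %g", x2), call. = FALSE)
  }
  num / den
}

#' Long-wavelength reflectance slope
#'
#' Ordinary least-squares slope of intensity versus wavelength over a
#' window, by default 625-730 nm where the reduced scattering coefficient
#' (and hence nuclear size) shapes normalized reflectance. The paper-scale
#' contrast is a normal:tumor slope ratio around 2.6.
#'
#' @param s a [spectrum] on an nm axis.
#' @param lo,hi window bounds (nm); at least 3 grid points must fall inside.
#' @return the OLS slope, intensity units per nm.
#' @export
slope_score <- function(s, lo = 625, hi = 730) {
  stopifnot(inherits(s, "spectrum"))
  keep <- s$axis >= lo & s$axis <= hi
  if (sum(keep) < 3L) {
    stop(sprintf("fewer than 3 points in [%g, %g]", lo, hi), call. = FALSE)
  }
  x <- s$axis[keep]; y <- s$intensity[keep]
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' EGFP peak intensity relative to tissue autofluorescence
#'
#' Ratio of the fluorescence intensity at the EGFP emission peak (510 nm) to
#' the tissue autofluorescence at 660 nm; the relative reading cancels
#' excitation and collection efficiency and tracks tumor extent.
#'
#' @param s a fluorescence [spectrum] whose axis covers 510 and 660 nm.
#' @return the 510/660 nm intensity ratio.
#' @export
egfp_peak_intensity <- function(s) {
  stopifnot(inherits(s, "spectrum"))
  ref <- value_at(s, 660)
  if (!is.finite(ref) || ref <= 0) {
    stop("nonpositive autofluorescence reference at 660 nm", call. = FALSE)
  }
  value_at(s, 510) / ref
}

# Apply a univariate scorer over a dataset, returning a score_set.
dataset_scores <- function(d, scorer, ...) {
  sc <- vapply(seq_len(nrow(d$matrix)),
               function(i) scorer(dataset_spectrum(d, i), ...), numeric(1L))
  score_set(sc, d$meta$label)
}
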