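# Preprocessing of fiber-probe spectra: system-response correction,
# iterative polynomial baseline removal for Raman, band/isosbestic
# normalization.

#' Correct a spectrum for the system transmission
#'
#' Divides the recorded intensity pointwise by the fiber-probe system
#' transmission (interpolated onto the spectrum axis), removing
#' instrument-induced spectral artifacts. Applied to every modality before
#' any further processing.
#'
#' @param s a [spectrum].
#' @param r an [instrument_response] whose transmission covers `s$axis`.
#' @return the corrected [spectrum].
#' @export
correct_transmission <- function(s, r) {
  stopifnot(inherits(s, "spectrum"), inherits(r, "instrument_response"))
  tr <- interp_linear(r$axis, r$transmission, s$axis, "transmission axis")
  if (any(tr <= 0)) stop("transmission <= 0 on the spectrum support", call. = FALSE)
  spectrum(s$axis, s$intensity / tr, s$modality, s$axis_unit,
           allow_negative = TRUE)
}

#' Iterative polynomial baseline removal (Vancouver Raman algorithm)
#'
#' Estimates the broad NIR-fluorescence background beneath Raman peaks by
#' iterative modified polynomial fitting: fit a polynomial of the given
#' order by least squares, compute the residual standard deviation `dev` of
#' the working data about the fit, truncate every intensity above
#' `fit + dev` down to that bound, and refit until the fitted curve
#' stabilizes. Peaks (which rise far above `fit + dev`) are progressively
#' excluded while the noise band around the smooth background is kept, so
#' the converged baseline tracks the mean of the background noise rather
#' than its lower envelope.
#'
#' The fit is performed on the axis mapped affinely to [-1, 1], so the
#' result is invariant to affine axis rescaling and the normal equations
#' stay well conditioned at order 6.
#'
#' @param s a [spectrum] (typically transmission-corrected Raman).
#' @param order polynomial order; 6 is the standard choice for tissue Raman
#'   fluorescence backgrounds.
#' @param max_iter iteration cap.
#' @param tol convergence tolerance: stop when the maximum change of the
#'   fitted baseline between iterations is below `tol` times the intensity
#'   scale of the input.
#' @param floor_at_zero clip negative corrected intensities to zero (display
#'   only); when `FALSE` (default) `baseline + corrected` reconstructs the
#'   input exactly.
#' @return an object of class `baseline_result`: list with `baseline`,
#'   `corrected`, `spectrum` (corrected as a [spectrum]), `n_iterations`,
#'   `converged`.
#' @export
remove_baseline_vancouver <- function(s, order = 6L, max_iter = 100L,
                                      tol = 1e-4, floor_at_zero = FALSE) {
  stopifnot(inherits(s, "spectrum"))
  n <- length(s$axis)
  if (n <= order + 1L) {
    stop("need more than order + 1 points for baseline fitting", call. = FALSE)
  }
  rng <- range(s$axis)
  if (rng[1L] == rng[2L]) stop("degenerate axis", call. = FALSE)
  t <- 2 * (s$axis - rng[1L]) / (rng[2L] - rng[1L]) - 1
  X <- outer(t, 0:order, `^`)
  scale_ref <- max(abs(s$intensity), 1e-300)
  y <- s$intensity
  fit_prev <- rep(Inf, n)
  converged <- FALSE
  iter <- 0L
  keep <- rep(TRUE, n)
  while (iter < max_iter) {
    iter <- iter + 1L
    cf <- qr.coef(qr(X[keep, , drop = FALSE]), y[keep])
    fit <- drop(X %*% cf)
    if (max(abs(fit - fit_prev)) < tol * scale_ref) {
      converged <- TRUE
      fit_prev <- fit
      break
    }
    fit_prev <- fit
    dev <- sqrt(mean((y[keep] - fit[keep])^2))
    if (iter == 1L) {
      # exclude the peak regions flagged by the first fit from later fits
      peak <- y > fit + dev
      if (sum(!peak) > order + 1L) keep <- !peak
    }
    y <- pmin(y, fit + dev)
  }
  baseline <- fit_prev
  corrected <- s$intensity - baseline
  if (floor_at_zero) corrected <- pmax(corrected, 0)
  structure(list(
    baseline = baseline,
    corrected = corrected,
    spectrum = spectrum(s$axis, corrected, s$modality, s$axis_unit,
                        allow_negative = TRUE),
    n_iterations = iter,
    converged = converged
  ), class = "baseline_result")
}

#' @export
print.baseline_result <- function(x, ...) {
  cat(sprintf("<baseline_result> %d iterations, %sconverged\n",
              x$n_iterations, if (x$converged) "" else "NOT "))
  invisible(x)
}

#' Normalize a Raman spectrum to a reference band
#'
#' Divides the (baseline-removed) intensity by the interpolated peak height
#' at the reference band, by default the 1445 cm^-1 CH2/CH3 deformation band
#' dominated by lipids, so every spectrum reads as intensity relative to
#' lipid content.
#'
#' @param s a baseline-corrected Raman [spectrum].
#' @param band reference Raman shift (cm^-1); default 1445.
#' @param half_window optional half-window for a band-average reading instead
#'   of peak height (default 0).
#' @return the normalized [spectrum]; `value_at(result, band) == 1`.
#' @export
normalize_raman <- function(s, band = 1445, half_window = 0) {
  stopifnot(inherits(s, "spectrum"))
  ref <- value_at(s, band, half_window = half_window)
  if (!is.finite(ref) || ref <= 0) {
    stop(sprintf("nonpositive intensity (%g) at the %g cm^-1 reference band; ",
                 ref, band),
         "baseline removal may have failed", call. = FALSE)
  }
  spectrum(s$axis, s$intensity / ref, s$modality, s$axis_unit,
           allow_negative = TRUE)
}

#' Lamp correction and isosbestic normalization of a reflectance spectrum
#'
#' Divides the recorded reflectance pointwise by the lamp emission spectrum,
#' then normalizes to the intensity at an oxy/deoxy-hemoglobin isosbestic
#' wavelength (570 nm by default), where the two chromophores absorb
#' equally, making the normalization insensitive to tissue oxygenation.
#'
#' @param s a reflectance [spectrum].
#' @param r an [instrument_response] carrying `lamp_emission` over `s$axis`.
#' @param iso isosbestic wavelength (nm); default 570.
#' @return the normalized [spectrum]; `value_at(result, iso) == 1`.
#' @export
normalize_reflectance <- function(s, r, iso = 570) {
  stopifnot(inherits(s, "spectrum"), inherits(r, "instrument_response"))
  if (is.null(r$lamp_emission)) {
    stop("instrument response has no lamp_emission spectrum", call. = FALSE)
  }
  lamp <- interp_linear(r$axis, r$lamp_emission, s$axis, "lamp axis")
  y <- s$intensity / lamp
  ref <- interp_linear(s$axis, y, iso, "isosbestic wavelength")
  if (!is.finite(ref) || ref <= 0) {
    stop(sprintf("nonpositive intensity at the %g nm isosbestic point", iso),
         call. = FALSE)
  }
  spectrum(s$axis, y / ref, s$modality, s$axis_unit, allow_negative = TRUE)
}

#' Preprocess a whole dataset for analysis
#'
#' Applies the per-modality chain: transmission correction (all
#' modalities), then for Raman iterative polynomial baseline removal and
#' 1445 cm^-1 band normalization; for reflectance lamp correction, 570 nm
#' isosbestic normalization and cropping to the 540-733 nm analysis window;
#' fluorescence receives transmission correction only.
#'
#' @param d a raw [spectral_dataset].
#' @param response an [instrument_response] for the dataset's modality (must
#'   carry `lamp_emission` for reflectance). May be `NULL` to skip
#'   transmission correction.
#' @param raman_band,iso,reflectance_window preprocessing constants; see
#'   [normalize_raman] and [normalize_reflectance].
#' @param baseline_order,baseline_max_iter,baseline_tol passed to
#'   [remove_baseline_vancouver].
#' @return a preprocessed [spectral_dataset]; attribute `"convergence"`
#'   records per-sample baseline iteration counts for Raman.
#' @export
preprocess_dataset <- function(d, response = NULL, raman_band = 1445,
                               iso = 570, reflectance_window = c(540, 733),
                               baseline_order = 6L, baseline_max_iter = 100L,
                               baseline_tol = 1e-4) {
  stopifnot(inherits(d, "spectral_dataset"))
  conv <- NULL
  spectra <- lapply(seq_len(nrow(d$matrix)), function(i) dataset_spectrum(d, i))
  if (!is.null(response)) {
    spectra <- lapply(spectra, correct_transmission, r = response)
  }
  if (d$modality == "raman") {
    res <- lapply(spectra, remove_baseline_vancouver, order = baseline_order,
                  max_iter = baseline_max_iter, tol = baseline_tol)
    conv <- data.frame(sample_id = d$meta$sample_id,
                       n_iterations = vapply(res, `[[`, integer(1L), "n_iterations"),
                       converged = vapply(res, `[[`, logical(1L), "converged"))
    spectra <- lapply(res, function(r) normalize_raman(r$spectrum, band = raman_band))
  } else if (d$modality == "reflectance") {
    if (is.null(response) || is.null(response$lamp_emission)) {
      stop("reflectance preprocessing needs an instrument response with ",
           "lamp_emission", call. = FALSE)
    }
    spectra <- lapply(spectra, normalize_reflectance, r = response, iso = iso)
    spectra <- lapply(spectra, crop, lo = reflectance_window[1L],
                      hi = reflectance_window[2L])
  }
  out <- spectral_dataset(spectra, d$meta, preprocessed = TRUE)
  attr(out, "convergence") <- conv
  out
}
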