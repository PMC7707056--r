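#' Construct a single optical spectrum
#'
#' A `spectrum` holds one measured or simulated spectrum: a strictly
#' increasing axis (wavelength in nm, or Raman shift in cm^-1), the recorded
#' intensity at each axis point, and the acquisition modality. Raman spectra
#' carry a `inverse_cm` axis; reflectance and fluorescence spectra carry `nm`.
#'
#' @param axis numeric vector, strictly increasing, length >= 2. Wavelengths
#'   (nm) or Raman shifts (cm^-1).
#' @param intensity numeric vector, same length as `axis`. Raw spectra are
#'   nonnegative; baseline-corrected spectra may dip below zero (see
#'   `allow_negative`).
#' @param modality one of `"raman"`, `"reflectance"`, `"fluorescence378"`,
#'   `"fluorescence445"`.
#' @param axis_unit `"inverse_cm"` or `"nm"`. Defaults to the unit implied by
#'   the modality and is checked against it.
#' @param allow_negative logical; permit negative intensities. Baseline
#'   removal deliberately keeps negative residuals so that
#'   `baseline + corrected` reconstructs the input exactly.
#' @return an object of class `spectrum`.
#' @examples
#' s <- spectrum(seq(400, 700, by = 10), runif(31), "reflectance")
#' value_at(s, 555)
#' @export
spectrum <- function(axis, intensity,
                     modality = c("raman", "reflectance",
                                  "fluorescence378", "fluorescence445"),
                     axis_unit = NULL, allow_negative = FALSE) {
  modality <- match.arg(modality)
  axis <- as.double(axis)
  intensity <- as.double(intensity)
  expected_unit <- if (modality == "raman") "inverse_cm" else "nm"
  axis_unit <- axis_unit %||% expected_unit
  if (!identical(axis_unit, expected_unit)) {
    stop(sprintf("modality '%s' requires axis_unit '%s', got '%s'",
                 modality, expected_unit, axis_unit), call. = FALSE)
  }
  if (length(axis) < 2L) stop("a spectrum needs at least 2 points", call. = FALSE)
  if (length(axis) != length(intensity)) {
    stop("axis and intensity must have the same length", call. = FALSE)
  }
  if (anyNA(axis) || anyNA(intensity) || any(!is.finite(axis)) ||
      any(!is.finite(intensity))) {
    stop("axis and intensity must be finite", call. = FALSE)
  }
  if (any(diff(axis) <= 0)) {
    stop("axis must be strictly increasing (duplicate or unsorted values)",
         call. = FALSE)
  }
  if (!allow_negative && any(intensity < 0)) {
    stop("negative intensities in a raw spectrum; use allow_negative = TRUE ",
         "only for baseline-corrected data", call. = FALSE)
  }
  structure(list(axis = axis, intensity = intensity, modality = modality,
                 axis_unit = axis_unit),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s, %d points, %g-%g %s\n", x$modality,
              length(x$axis), x$axis[1L], x$axis[length(x$axis)],
              if (x$axis_unit == "nm") "nm" else "cm^-1"))
  invisible(x)
}

#' @export
plot.spectrum <- function(x, ...) {
  xlab <- if (x$axis_unit == "nm") "wavelength (nm)" else
    expression(paste("Raman shift (", cm^-1, ")"))
  graphics::plot(x$axis, x$intensity, type = "l", xlab = xlab,
                 ylab = "intensity", ...)
  invisible(x)
}

#' Interpolated intensity at an axis position
#'
#' Linear interpolation between the two bracketing grid points; exact stored
#' value when `x` coincides with a grid point. This is the band-lookup
#' primitive behind band normalization (e.g. the 1445 cm^-1 CH2/CH3
#' deformation band) and all ratiometric scores.
#'
#' @param s a [spectrum].
#' @param x axis position (same unit as `s$axis`); may be a vector.
#' @param half_window optional half-width; when positive, the mean intensity
#'   over `[x - half_window, x + half_window]` (on the native grid) is
#'   returned instead of the point value. Default 0 (peak height).
#' @return interpolated intensity value(s).
#' @export
value_at <- function(s, x, half_window = 0) {
  stopifnot(inherits(s, "spectrum"))
  if (half_window > 0) {
    return(vapply(x, function(xi) {
      keep <- s$axis >= xi - half_window & s$axis <= xi + half_window
      if (!any(keep)) return(interp_linear(s$axis, s$intensity, xi))
      mean(s$intensity[keep])
    }, numeric(1L)))
  }
  interp_linear(s$axis, s$intensity, x)
}

#' Crop a spectrum to an axis window
#'
#' Keeps the grid points with `lo <= axis <= hi`. Used, for instance, to
#' restrict reflectance analysis to 540-733 nm where EGFP absorption and
#' emission no longer contaminate the signal.
#'
#' @param s a [spectrum].
#' @param lo,hi window bounds, `lo < hi`.
#' @return the cropped [spectrum].
#' @export
crop <- function(s, lo, hi) {
  stopifnot(inherits(s, "spectrum"), is_number(lo), is_number(hi))
  if (lo >= hi) stop("crop window requires lo < hi", call. = FALSE)
  keep <- s$axis >= lo & s$axis <= hi
  if (sum(keep) < 2L) {
    stop(sprintf("crop to [%g, %g] leaves fewer than 2 points", lo, hi),
         call. = FALSE)
  }
  spectrum(s$axis[keep], s$intensity[keep], s$modality, s$axis_unit,
           allow_negative = TRUE)
}

#' Resample a spectrum onto a new axis
#'
#' Linear interpolation onto `new_axis`; extrapolation is refused. Needed to
#' assemble per-sample spectra onto the common grid of a [spectral_dataset].
#'
#' @param s a [spectrum].
#' @param new_axis strictly increasing numeric vector inside the range of
#'   `s$axis`.
#' @return the resampled [spectrum].
#' @export
resample_to <- function(s, new_axis) {
  stopifnot(inherits(s, "spectrum"))
  new_axis <- as.double(new_axis)
  if (any(new_axis < s$axis[1L]) || any(new_axis > s$axis[length(s$axis)])) {
    stop("resample_to would extrapolate outside the spectrum range",
         call. = FALSE)
  }
  spectrum(new_axis, interp_linear(s$axis, s$intensity, new_axis),
           s$modality, s$axis_unit, allow_negative = TRUE)
}

#' Instrument response of the fiber-probe system
#'
#' Captures the wavelength-dependent transmission of the probe/spectrometer
#' chain (used to correct every recorded spectrum) and, for reflectance, the
#' emission spectrum of the white-light lamp.
#'
#' @param axis strictly increasing numeric vector.
#' @param transmission strictly positive system transmission on `axis`.
#' @param lamp_emission optional strictly positive lamp emission on `axis`
#'   (reflectance only).
#' @return an object of class `instrument_response`.
#' @export
instrument_response <- function(axis, transmission, lamp_emission = NULL) {
  axis <- as.double(axis)
  transmission <- as.double(transmission)
  if (length(axis) != length(transmission) || any(diff(axis) <= 0)) {
    stop("axis/transmission mismatch or non-increasing axis", call. = FALSE)
  }
  if (any(!is.finite(transmission)) || any(transmission <= 0)) {
    stop("transmission must be strictly positive on its support", call. = FALSE)
  }
  if (!is.null(lamp_emission)) {
    lamp_emission <- as.double(lamp_emission)
    if (length(lamp_emission) != length(axis) ||
        any(!is.finite(lamp_emission)) || any(lamp_emission <= 0)) {
      stop("lamp_emission must be strictly positive over the axis", call. = FALSE)
    }
  }
  structure(list(axis = axis, transmission = transmission,
                 lamp_emission = lamp_emission),
            class = "instrument_response")
}

#' Assemble spectra into a dataset on a common grid
#'
#' @param spectra list of [spectrum] objects of one modality. Spectra are
#'   resampled onto `common_axis` (default: the axis of the first spectrum).
#' @param meta data.frame with one row per spectrum and columns `sample_id`,
#'   `animal_id`, `session`, `label` (`"normal"`/`"tumor"`), and
#'   `tumor_radial_size_um` (NA or 0 for normal tissue).
#' @param common_axis optional target grid.
#' @param preprocessed logical flag recording whether rows are raw or
#'   preprocessed intensities.
#' @return an object of class `spectral_dataset` with fields `common_axis`,
#'   `matrix` (n_samples x n_points), `meta`, `modality`, `preprocessed`.
#' @export
spectral_dataset <- function(spectra, meta, common_axis = NULL,
                             preprocessed = FALSE) {
  stopifnot(is.list(spectra), length(spectra) >= 1L,
            all(vapply(spectra, inherits, logical(1L), "spectrum")))
  modality <- spectra[[1L]]$modality
  if (!all(vapply(spectra, function(s) identical(s$modality, modality),
                  logical(1L)))) {
    stop("all spectra in a dataset must share one modality", call. = FALSE)
  }
  common_axis <- as.double(common_axis %||% spectra[[1L]]$axis)
  rows <- lapply(spectra, function(s) resample_to(s, common_axis)$intensity)
  m <- do.call(rbind, rows)
  if (!is.data.frame(meta) || nrow(meta) != nrow(m)) {
    stop("meta must be a data.frame with one row per spectrum", call. = FALSE)
  }
  meta <- validate_meta(meta)
  if (any(!is.finite(m))) stop("non-finite intensities in dataset", call. = FALSE)
  structure(list(common_axis = common_axis, matrix = m, meta = meta,
                 modality = modality, preprocessed = isTRUE(preprocessed)),
            class = "spectral_dataset")
}

validate_meta <- function(meta) {
  required <- c("sample_id", "animal_id", "session", "label",
                "tumor_radial_size_um")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  meta$label <- as.character(meta$label)
  if (!all(meta$label %in% c("normal", "tumor"))) {
    stop("label must be 'normal' or 'tumor'", call. = FALSE)
  }
  if (any(meta$session < 0)) stop("session must be >= 0", call. = FALSE)
  sz <- meta$tumor_radial_size_um
  bad <- meta$label == "normal" & !is.na(sz) & sz > 0
  if (any(bad)) {
    stop("normal samples must have missing or zero tumor_radial_size_um",
         call. = FALSE)
  }
  if (any(!is.na(sz) & sz < 0)) stop("tumor size must be nonnegative", call. = FALSE)
  meta
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("<spectral_dataset> %s (%s), %d samples x %d points (%d normal, %d tumor)\n",
              x$modality, if (x$preprocessed) "preprocessed" else "raw",
              nrow(x$matrix), ncol(x$matrix),
              sum(x$meta$label == "normal"), sum(x$meta$label == "tumor")))
  invisible(x)
}

# Extract one row as a spectrum.
dataset_spectrum <- function(d, i) {
  spectrum(d$common_axis, d$matrix[i, ], d$modality, allow_negative = TRUE)
}

#' Per-class mean and standard-error curves
#'
#' Pointwise class mean and standard error (sd/sqrt(n)) over the common axis,
#' the summary displayed as mean +/- SE curves for normal and tumor tissue.
#'
#' @param d a [spectral_dataset] with at least 2 samples in each class.
#' @return a list with `axis`, and per class `mean` and `se` vectors.
#' @export
summarize_spectra <- function(d) {
  stopifnot(inherits(d, "spectral_dataset"))
  out <- list(axis = d$common_axis)
  for (cls in c("normal", "tumor")) {
    rows <- d$matrix[d$meta$label == cls, , drop = FALSE]
    if (nrow(rows) < 2L) {
      stop(sprintf("class '%s' needs >= 2 samples for a standard error", cls),
           call. = FALSE)
    }
    out[[cls]] <- list(mean = colMeans(rows),
                       se = apply(rows, 2L, stats::sd) / sqrt(nrow(rows)))
  }
  out
}
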