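# Plain-text spectral file I/O.
#
# Dialect: UTF-8, '#'-prefixed header lines ('# modality=raman',
# '# axis_unit=inverse_cm'), then two tab-separated numeric columns
# (axis, intensity). Chosen for diffability; one file per measurement.

#' Read a spectrum from a two-column text file
#'
#' @param path path to a file written by [write_spectrum] (or by hand in the
#'   same dialect: `#` header lines carrying `modality=` and `axis_unit=`,
#'   then two delimited numeric columns).
#' @return a validated [spectrum]; rows are sorted by axis before validation.
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty spectrum file: ", path, call. = FALSE)
  header <- grep("^#", lines, value = TRUE)
  body_idx <- grep("^[^#]", lines)
  body_idx <- body_idx[nzchar(trimws(lines[body_idx]))]
  get_field <- function(key) {
    hit <- grep(paste0("^#\\s*", key, "\\s*="), header, value = TRUE)
    if (!length(hit)) {
      stop(sprintf("header '# %s=...' missing in %s", key, path), call. = FALSE)
    }
    trimws(sub(paste0("^#\\s*", key, "\\s*="), "", hit[1L]))
  }
  modality <- get_field("modality")
  axis_unit <- get_field("axis_unit")
  if (!modality %in% c("raman", "reflectance", "fluorescence378",
                       "fluorescence445")) {
    stop("unknown modality '", modality, "' in ", path, call. = FALSE)
  }
  parts <- strsplit(trimws(lines[body_idx]), "[\t, ]+")
  n_fields <- lengths(parts)
  if (any(n_fields != 2L)) {
    bad <- body_idx[which(n_fields != 2L)[1L]]
    stop(sprintf("malformed row at line %d of %s: expected 2 columns", bad, path),
         call. = FALSE)
  }
  vals <- suppressWarnings(vapply(parts, as.double, numeric(2L)))
  if (anyNA(vals)) {
    bad <- body_idx[which(colSums(is.na(vals)) > 0)[1L]]
    stop(sprintf("non-numeric value at line %d of %s", bad, path), call. = FALSE)
  }
  axis <- vals[1L, ]
  intensity <- vals[2L, ]
  o <- order(axis)
  axis <- axis[o]; intensity <- intensity[o]
  if (anyDuplicated(axis)) {
    stop("duplicated axis value in ", path, " (axis value ",
         axis[which(duplicated(axis))[1L]], ")", call. = FALSE)
  }
  spectrum(axis, intensity, modality, axis_unit, allow_negative = TRUE)
}

#' Write a spectrum to a two-column text file
#'
#' Values are written with 15 significant digits so a read/write round trip
#' preserves intensities to better than 1e-12 relative error.
#'
#' @param s a [spectrum].
#' @param path output file path.
#' @return `invisible(path)`.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "spectrum"))
  if (!length(s$intensity)) stop("refusing to write an empty spectrum", call. = FALSE)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("# modality=%s", s$modality),
               sprintf("# axis_unit=%s", s$axis_unit),
               sprintf("%.15g\t%.15g", s$axis, s$intensity)), con)
  invisible(path)
}

#' Write a cohort to a directory
#'
#' One spectral text file per sample and modality, a `metadata.csv` table,
#' and a `manifest.json` naming every file; readable back with [read_cohort].
#'
#' @param cohort a cohort as produced by [gen_cohort] (list of
#'   [spectral_dataset] per modality plus shared `meta`).
#' @param dir output directory (created if needed).
#' @return `invisible(dir)`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  modalities <- names(cohort$datasets)
  manifest <- list(modalities = modalities, files = list())
  utils::write.csv(cohort$meta, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  for (m in modalities) {
    d <- cohort$datasets[[m]]
    files <- sprintf("%s_%s.txt", m, d$meta$sample_id)
    for (i in seq_len(nrow(d$matrix))) {
      write_spectrum(dataset_spectrum(d, i), file.path(dir, files[i]))
    }
    manifest$files[[m]] <- files
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort]
#'
#' @param dir cohort directory containing `manifest.json`, `metadata.csv`
#'   and the per-sample spectral files.
#' @return a list with `datasets` (named list of [spectral_dataset]) and
#'   `meta`.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  meta <- utils::read.csv(file.path(dir, "metadata.csv"),
                          stringsAsFactors = FALSE)
  datasets <- lapply(manifest$modalities, function(m) {
    spectra <- lapply(file.path(dir, manifest$files[[m]]), read_spectrum)
    spectral_dataset(spectra, meta)
  })
  names(datasets) <- manifest$modalities
  list(datasets = datasets, meta = meta)
}
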