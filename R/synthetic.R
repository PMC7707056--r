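# Class-conditional synthetic spectra: Raman band mixtures over the
# fingerprint region, a Beer-Lambert-style reflectance model with exact
# oxy/deoxy-hemoglobin isosbestic points, and EGFP fluorescence linear in
# tumor size. The generator is a statistical stand-in with the structure
# the analysis assumes, not a tissue-optics simulation.

#' Default Raman band table
#'
#' Gaussian band parameters for normal and tumor brain tissue, relative to
#' the 1445 cm^-1 CH2/CH3 (lipid) band which is 1 in both classes. Healthy
#' tissue carries relatively stronger amino-acid (950 cm^-1), amide III and
#' tryptophan (1210 cm^-1) bands; tumor carries a relatively stronger
#' amide I band (1650 cm^-1) and slightly stronger nucleic-acid bands
#' (1060, 1575 cm^-1). A weak band near 2030 cm^-1 supports the
#' 1450/2030 ratiometric score.
#'
#' @return data.frame with columns `center`, `width` (Gaussian sd, cm^-1),
#'   `amplitude_normal`, `amplitude_tumor`.
#' @export
raman_band_table <- function() {
  data.frame(
    center           = c(950, 1000, 1030, 1060, 1210, 1445, 1575, 1600, 1650, 2030),
    width            = c(12,    9,    9,   11,   12,   16,   11,    9,   13,   14),
    amplitude_normal = c(0.55, 0.45, 0.40, 0.50, 0.62, 1.00, 0.45, 0.40, 0.72, 0.20),
    amplitude_tumor  = c(0.40, 0.42, 0.38, 0.56, 0.45, 1.00, 0.52, 0.43, 0.95, 0.26)
  )
}

validate_band_table <- function(bands) {
  need <- c("center", "width", "amplitude_normal", "amplitude_tumor")
  if (!is.data.frame(bands) || !all(need %in% names(bands))) {
    stop("band table needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(bands$amplitude_normal < 0) || any(bands$amplitude_tumor < 0) ||
      any(bands$width <= 0)) {
    stop("band amplitudes must be >= 0 and widths > 0", call. = FALSE)
  }
  i1445 <- which(bands$center == 1445)
  if (!length(i1445) || bands$amplitude_normal[i1445] != 1 ||
      bands$amplitude_tumor[i1445] != 1) {
    stop("the 1445 cm^-1 reference band must have amplitude 1 in both classes",
         call. = FALSE)
  }
  invisible(bands)
}

# Hemoglobin-like pseudo-extinction curves. The oxy-deoxy difference is a
# degree-5 polynomial with roots exactly at the five isosbestic wavelengths,
# damped by a Gaussian window; the shared base carries the 540/575 nm
# oxy-hemoglobin absorption bumps. Sign pattern: deoxy > oxy above 584 nm
# (the 600-730 nm hypoxia contrast), oxy > deoxy around 540 and 575 nm.
pseudo_extinction <- function(lambda) {
  iso <- c(452, 529, 545, 570, 584)
  d <- -5.7e-11 *
    (lambda - iso[1]) * (lambda - iso[2]) * (lambda - iso[3]) *
    (lambda - iso[4]) * (lambda - iso[5]) *
    exp(-((lambda - 545) / 70)^2)
  base <- 0.9 * exp(-((lambda - 555) / 60)^2) +
    0.4 * exp(-((lambda - 430) / 35)^2) +
    0.35 * exp(-((lambda - 540) / 12)^2) +
    0.30 * exp(-((lambda - 575) / 12)^2) +
    0.05
  list(oxy = base + d / 2, deoxy = base - d / 2, isosbestic = iso)
}

# Noise-free normalized reflectance of one class (lamp and normalization
# at 570 nm divided out).
reflectance_clean <- function(lambda, sat, slope, blood_fraction) {
  eps <- pseudo_extinction(lambda)
  mu <- sat * eps$oxy + (1 - sat) * eps$deoxy
  mu570 <- {
    e570 <- pseudo_extinction(570)
    sat * e570$oxy + (1 - sat) * e570$deoxy
  }
  exp(-blood_fraction * (mu - mu570)) * (1 + slope * pmax(lambda - 584, 0))
}

#' Reflectance generative model
#'
#' Beer-Lambert-style model: `lamp * exp(-blood_fraction * mu(lambda)) *
#' (1 + slope * (lambda - 584)+)`, where `mu` mixes hemoglobin-like oxy and
#' deoxy pseudo-extinction curves by the class oxygen saturation. The two
#' pseudo-extinction curves are equal exactly at 452, 529, 545, 570 and
#' 584 nm, so noise-free normalized class means intersect there by
#' construction. The scattering trend is a hinge beyond the last isosbestic
#' point, keeping those equalities exact; the tumor slope is calibrated by
#' root finding so the realized noise-free 625-730 nm normal:tumor slope
#' ratio equals `slope_ratio` (default 2.6).
#'
#' @param oxygen_saturation_normal,oxygen_saturation_tumor class oxygen
#'   saturations in \[0, 1\]; tumor must be lower (hypoxia).
#' @param scatter_slope_normal per-nm linear trend of normal tissue beyond
#'   584 nm.
#' @param slope_ratio target realized normal:tumor slope ratio over
#'   625-730 nm.
#' @param blood_fraction absorption strength multiplier.
#' @return an object of class `reflectance_model` (includes the calibrated
#'   `scatter_slope_tumor`).
#' @export
reflectance_model <- function(oxygen_saturation_normal = 0.85,
                              oxygen_saturation_tumor = 0.45,
                              scatter_slope_normal = 6e-3,
                              slope_ratio = 2.6,
                              blood_fraction = 1.5) {
  stopifnot(oxygen_saturation_tumor < oxygen_saturation_normal,
            oxygen_saturation_normal <= 1, oxygen_saturation_tumor >= 0,
            scatter_slope_normal > 0, slope_ratio > 0, blood_fraction > 0)
  lambda <- seq(400, 733, by = 1)
  slope_of <- function(sat, m) {
    slope_score(spectrum(lambda,
                         reflectance_clean(lambda, sat, m, blood_fraction),
                         "reflectance"))
  }
  s_n <- slope_of(oxygen_saturation_normal, scatter_slope_normal)
  f <- function(m_t) s_n / slope_of(oxygen_saturation_tumor, m_t) - slope_ratio
  m_t <- stats::uniroot(f, c(1e-6, scatter_slope_normal), tol = 1e-12)$root
  structure(list(oxygen_saturation_normal = oxygen_saturation_normal,
                 oxygen_saturation_tumor = oxygen_saturation_tumor,
                 scatter_slope_normal = scatter_slope_normal,
                 scatter_slope_tumor = m_t,
                 slope_ratio = slope_ratio,
                 blood_fraction = blood_fraction),
            class = "reflectance_model")
}

#' Fluorescence generative model
#'
#' Tissue autofluorescence plus an EGFP Gaussian emission peak at 510 nm
#' whose amplitude grows linearly with tumor radial size; readout is the
#' 510/660 nm ratio of [egfp_peak_intensity].
#'
#' @param egfp_center,egfp_width peak position and Gaussian sd (nm).
#' @param egfp_gain EGFP amplitude (relative to the autofluorescence scale)
#'   per micrometer of tumor radial size.
#' @return an object of class `fluorescence_model`.
#' @export
fluorescence_model <- function(egfp_center = 510, egfp_width = 13,
                               egfp_gain = 0.004) {
  stopifnot(egfp_gain > 0, egfp_width > 0)
  structure(list(egfp_center = egfp_center, egfp_width = egfp_width,
                 egfp_gain = egfp_gain),
            class = "fluorescence_model")
}

# Autofluorescence spectral shape (relative units).
autofluorescence_shape <- function(lambda) {
  0.9 * exp(-((lambda - 530) / 70)^2) +
    0.35 * exp(-((lambda - 650) / 80)^2) + 0.03
}

#' Synthetic cohort configuration
#'
#' All generative parameters of the synthetic study: cohort layout (8
#' animals, 13 paired normal/tumor experiments), class-effect scale (0 gives
#' exchangeable classes, 1 the default separable cohort), per-modality noise
#' levels, band table and per-modality models, and the RNG seed.
#'
#' @param n_animals number of animals (default 8).
#' @param n_experiments number of paired experiments (default 13; must be
#'   >= `n_animals`, at most 3 sessions per animal).
#' @param effect_scale class-effect multiplier in \[0, 1\]; 0 makes the
#'   normal and tumor generative distributions identical.
#' @param noise per-modality noise levels; see Details.
#' @param raman_bands a [raman_band_table].
#' @param reflectance a [reflectance_model].
#' @param fluorescence a [fluorescence_model].
#' @param raman_background 7 polynomial coefficients (constant first) of the
#'   NIR-fluorescence background on the axis mapped to \[0, 1\], times
#'   `raman_background_scale` counts.
#' @param raman_background_scale,raman_band_scale intensity scales (counts).
#' @param seed integer RNG seed for [gen_cohort].
#'
#' @details `noise` is a list with elements
#' `raman = list(band_sdlog, shot_scale)` (per-band lognormal biological
#' variation; additive noise sd = `shot_scale * sqrt(intensity)`),
#' `reflectance = list(sat_sd, slope_sdlog, relative_sd)` and
#' `fluorescence = list(gain_sdlog, relative_sd)`. Setting all elements to
#' zero gives noise-free draws.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_animals = 8L, n_experiments = 13L,
                          effect_scale = 1,
                          noise = list(
                            raman = list(band_sdlog = 0.06, shot_scale = 0.3),
                            reflectance = list(sat_sd = 0.03,
                                               slope_sdlog = 0.10,
                                               relative_sd = 0.004),
                            fluorescence = list(gain_sdlog = 0.10,
                                                relative_sd = 0.01)),
                          raman_bands = raman_band_table(),
                          reflectance = reflectance_model(),
                          fluorescence = fluorescence_model(),
                          raman_background = c(1.2, -0.9, 0.45, -0.2, 0, 0, 0),
                          raman_background_scale = 600,
                          raman_band_scale = 200,
                          seed = 1L) {
  stopifnot(n_experiments >= n_animals, n_experiments <= 3L * n_animals,
            effect_scale >= 0, effect_scale <= 1)
  validate_band_table(raman_bands)
  stopifnot(inherits(reflectance, "reflectance_model"),
            inherits(fluorescence, "fluorescence_model"))
  structure(list(n_animals = as.integer(n_animals),
                 n_experiments = as.integer(n_experiments),
                 effect_scale = effect_scale, noise = noise,
                 raman_bands = raman_bands, reflectance = reflectance,
                 fluorescence = fluorescence,
                 raman_background = raman_background,
                 raman_background_scale = raman_background_scale,
                 raman_band_scale = raman_band_scale,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Class-conditional band amplitudes at a given effect scale: shrink toward
# the class midpoint so effect_scale = 0 makes classes identical.
effective_amplitudes <- function(bands, class, effect_scale) {
  mid <- (bands$amplitude_normal + bands$amplitude_tumor) / 2
  a <- if (class == "normal") bands$amplitude_normal else bands$amplitude_tumor
  mid + effect_scale * (a - mid)
}

#' Generate one raw Raman spectrum
#'
#' Sum of Gaussian bands with class-dependent amplitudes, a smooth
#' polynomial NIR-fluorescence background, per-band multiplicative lognormal
#' biological variation, and additive shot-like noise. The output is raw
#' (pre-baseline-removal, pre-normalization) on a 600-2100 cm^-1 axis at
#' 2 cm^-1 steps.
#'
#' @param class `"normal"` or `"tumor"`.
#' @param cfg a [cohort_config].
#' @param rng_seed optional seed; when `NULL`, draws from the current RNG
#'   state (as [gen_cohort] does inside its seeded block).
#' @param amplitude_factor extra multiplicative factor (per-animal random
#'   intercept).
#' @return a raw Raman [spectrum].
#' @export
gen_raman <- function(class = c("normal", "tumor"), cfg = cohort_config(),
                      rng_seed = NULL, amplitude_factor = 1) {
  class <- match.arg(class)
  validate_band_table(cfg$raman_bands)
  with_seed(rng_seed, {
    x <- seq(600, 2100, by = 2)
    bands <- cfg$raman_bands
    amps <- effective_amplitudes(bands, class, cfg$effect_scale)
    sdlog <- cfg$noise$raman$band_sdlog
    jitter <- if (sdlog > 0) exp(stats::rnorm(nrow(bands), 0, sdlog)) else
      rep(1, nrow(bands))
    clean <- rep(0, length(x))
    for (b in seq_len(nrow(bands))) {
      clean <- clean + amps[b] * jitter[b] *
        exp(-((x - bands$center[b]) / bands$width[b])^2 / 2)
    }
    t <- (x - min(x)) / (max(x) - min(x))
    bg <- drop(outer(t, seq_along(cfg$raman_background) - 1, `^`) %*%
                 cfg$raman_background) * cfg$raman_background_scale
    if (any(bg < 0)) stop("background polynomial dips below zero", call. = FALSE)
    y <- amplitude_factor * (cfg$raman_band_scale * clean + bg)
    shot <- cfg$noise$raman$shot_scale
    if (shot > 0) y <- y + stats::rnorm(length(y), 0, shot * sqrt(pmax(y, 0)))
    spectrum(x, pmax(y, 0), "raman")
  })
}

#' Generate one raw reflectance spectrum
#'
#' `lamp(lambda) * exp(-blood_fraction * mu_class(lambda)) * (1 +
#' slope_class * (lambda - 584)+)` with per-draw saturation and slope
#' jitter and multiplicative measurement noise, on a 400-733 nm axis at
#' 1 nm. Tumor draws have lower oxygen saturation (stronger 600-730 nm
#' relative absorption) and a shallower long-wavelength slope.
#'
#' @inheritParams gen_raman
#' @param lamp_scale overall lamp intensity (counts); the lamp shape is the
#'   one reported by [cohort_responses].
#' @return a raw reflectance [spectrum].
#' @export
gen_reflectance <- function(class = c("normal", "tumor"),
                            cfg = cohort_config(), rng_seed = NULL,
                            amplitude_factor = 1, lamp_scale = 1000) {
  class <- match.arg(class)
  rm <- cfg$reflectance
  with_seed(rng_seed, {
    lambda <- seq(400, 733, by = 1)
    mid_sat <- (rm$oxygen_saturation_normal + rm$oxygen_saturation_tumor) / 2
    mid_m <- (rm$scatter_slope_normal + rm$scatter_slope_tumor) / 2
    sat <- if (class == "normal") rm$oxygen_saturation_normal else
      rm$oxygen_saturation_tumor
    m <- if (class == "normal") rm$scatter_slope_normal else
      rm$scatter_slope_tumor
    sat <- mid_sat + cfg$effect_scale * (sat - mid_sat)
    m <- mid_m + cfg$effect_scale * (m - mid_m)
    nz <- cfg$noise$reflectance
    if (nz$sat_sd > 0) {
      sat <- min(max(sat + stats::rnorm(1, 0, nz$sat_sd), 0), 1)
    }
    if (nz$slope_sdlog > 0) m <- m * exp(stats::rnorm(1, 0, nz$slope_sdlog))
    y <- lamp_scale * lamp_shape(lambda) * amplitude_factor *
      reflectance_clean(lambda, sat, m, rm$blood_fraction)
    if (nz$relative_sd > 0) {
      y <- y * (1 + stats::rnorm(length(y), 0, nz$relative_sd))
    }
    if (any(y <= 0)) y <- pmax(y, 1e-6 * max(y))
    spectrum(lambda, y, "reflectance")
  })
}

# Lamp emission shape (relative units) over an nm axis.
lamp_shape <- function(lambda) {
  0.6 + 0.4 * exp(-((lambda - 580) / 180)^2)
}

#' Generate one fluorescence spectrum
#'
#' Autofluorescence baseline plus an EGFP Gaussian peak at 510 nm with
#' amplitude `egfp_gain * tumor_size_um` (scaled by the cohort effect
#' scale); size 0 gives the label-free autofluorescence alone. Axis
#' 460-750 nm at 1 nm.
#'
#' @param tumor_size_um tumor radial size in micrometers (>= 0).
#' @inheritParams gen_raman
#' @param intensity_scale overall scale in counts.
#' @return a fluorescence [spectrum] (`fluorescence445`).
#' @export
gen_fluorescence <- function(tumor_size_um, cfg = cohort_config(),
                             rng_seed = NULL, amplitude_factor = 1,
                             intensity_scale = 500) {
  if (!is_number(tumor_size_um) || tumor_size_um < 0) {
    stop("tumor size must be a nonnegative number", call. = FALSE)
  }
  fm <- cfg$fluorescence
  with_seed(rng_seed, {
    lambda <- seq(460, 750, by = 1)
    nz <- cfg$noise$fluorescence
    gain <- fm$egfp_gain * cfg$effect_scale
    if (nz$gain_sdlog > 0 && tumor_size_um > 0) {
      gain <- gain * exp(stats::rnorm(1, 0, nz$gain_sdlog))
    }
    shape <- autofluorescence_shape(lambda) +
      gain * tumor_size_um * exp(-((lambda - fm$egfp_center) / fm$egfp_width)^2 / 2)
    y <- intensity_scale * amplitude_factor * shape
    if (nz$relative_sd > 0) {
      y <- y * (1 + stats::rnorm(length(y), 0, nz$relative_sd))
    }
    spectrum(lambda, pmax(y, 0), "fluorescence445")
  })
}

#' Instrument responses used by the synthetic cohort
#'
#' Smooth positive transmission curves for the Raman and nm-axis modalities
#' and the lamp emission spectrum assumed by [gen_reflectance]; the cohort's
#' raw spectra are multiplied by the transmission so that preprocessing
#' meaningfully inverts it.
#'
#' @return named list of [instrument_response] objects (`raman`,
#'   `reflectance`, `fluorescence445`).
#' @export
cohort_responses <- function() {
  nm_axis <- seq(380, 760, by = 1)
  raman_axis <- seq(600, 2100, by = 2)
  list(
    raman = instrument_response(
      raman_axis, 0.6 + 0.3 * exp(-((raman_axis - 1300) / 700)^2)),
    reflectance = instrument_response(
      nm_axis, 0.55 + 0.35 * exp(-((nm_axis - 600) / 160)^2),
      lamp_emission = 1000 * lamp_shape(nm_axis)),
    fluorescence445 = instrument_response(
      nm_axis, 0.55 + 0.35 * exp(-((nm_axis - 600) / 160)^2))
  )
}

#' Generate a full synthetic cohort
#'
#' Emulates the in-vivo study layout: `n_experiments` paired normal/tumor
#' measurement sessions distributed over `n_animals` animals (at most 3
#' sessions each), with per-animal random intercepts, tumor sizes growing
#' across sessions, and all three modalities recorded per experiment. Raw
#' spectra include the instrument transmission of [cohort_responses], so the
#' standard preprocessing chain applies. Fully reproducible from
#' `cfg$seed`.
#'
#' @param cfg a [cohort_config].
#' @return a list of class `cohort`: `datasets` (named [spectral_dataset]
#'   list: `raman`, `reflectance`, `fluorescence445`), `meta` (shared
#'   metadata, one normal and one tumor row per experiment), `responses`,
#'   `config`.
#' @export
gen_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  responses <- cohort_responses()
  nE <- cfg$n_experiments; nA <- cfg$n_animals
  # Deterministic layout: deal experiments to animals round-robin.
  animal <- rep_len(seq_len(nA), nE)
  session <- stats::ave(animal, animal, FUN = seq_along)
  with_seed(cfg$seed, {
    animal_size_eff <- stats::rnorm(nA, 0, 60)
    intercepts <- matrix(exp(stats::rnorm(nA * 3, 0, 0.05)), nA, 3,
                         dimnames = list(NULL, c("raman", "reflectance",
                                                 "fluorescence445")))
    sizes <- pmax(60, 150 + 280 * session + animal_size_eff[animal] +
                    stats::rnorm(nE, 0, 40))
    spectra <- list(raman = list(), reflectance = list(),
                    fluorescence445 = list())
    meta <- vector("list", 2L * nE)
    row <- 0L
    for (e in seq_len(nE)) {
      for (lab in c("normal", "tumor")) {
        row <- row + 1L
        a <- animal[e]
        s_ram <- gen_raman(lab, cfg, amplitude_factor = intercepts[a, "raman"])
        s_ref <- gen_reflectance(lab, cfg,
                                 amplitude_factor = intercepts[a, "reflectance"])
        s_flu <- gen_fluorescence(if (lab == "tumor") sizes[e] else 0, cfg,
                                  amplitude_factor = intercepts[a, "fluorescence445"])
        spectra$raman[[row]] <- apply_transmission(s_ram, responses$raman)
        spectra$reflectance[[row]] <- apply_transmission(s_ref,
                                                         responses$reflectance)
        spectra$fluorescence445[[row]] <-
          apply_transmission(s_flu, responses$fluorescence445)
        meta[[row]] <- data.frame(
          sample_id = sprintf("e%02d_%s", e, lab),
          animal_id = sprintf("A%02d", a),
          session = session[e],
          label = lab,
          tumor_radial_size_um = if (lab == "tumor") sizes[e] else NA_real_)
      }
    }
    meta <- do.call(rbind, meta)
    datasets <- lapply(spectra, spectral_dataset, meta = meta)
    structure(list(datasets = datasets, meta = meta, responses = responses,
                   config = cfg),
              class = "cohort")
  })
}

# Forward application of the instrument transmission (generation-side
# counterpart of correct_transmission).
apply_transmission <- function(s, r) {
  tr <- interp_linear(r$axis, r$transmission, s$axis, "transmission axis")
  spectrum(s$axis, s$intensity * tr, s$modality, s$axis_unit)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d experiments on %d animals, effect scale %g; modalities: %s\n",
              x$config$n_experiments, x$config$n_animals,
              x$config$effect_scale,
              paste(names(x$datasets), collapse = ", ")))
  invisible(x)
}
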