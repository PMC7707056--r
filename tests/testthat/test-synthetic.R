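# Generator constraints: band recovery, isosbestic structure, slope ratio,
# EGFP linearity, cohort determinism and exchangeability.

test_that("noise-free Raman draws reproduce the configured band heights", {
  cfg <- noise_free_config()
  cfg$raman_background <- rep(0, 7)    # no background, bands only
  s <- gen_raman("normal", cfg)
  bands <- raman_band_table()
  # compare against the summed band model evaluated on the same grid
  model <- rep(0, length(s$axis))
  for (b in seq_len(nrow(bands))) {
    model <- model + bands$amplitude_normal[b] *
      exp(-((s$axis - bands$center[b]) / bands$width[b])^2 / 2)
  }
  model_spec <- spectrum(s$axis, model, "raman")
  expect_equal(value_at(s, bands$center) / cfg$raman_band_scale,
               value_at(model_spec, bands$center), tolerance = 1e-10)
})

test_that("preprocessing recovers Raman relative band heights within 5%", {
  # batch of draws per class so the Monte-Carlo error of the mean (~1%)
  # does not confound the 5% round-trip bound on preprocessing fidelity
  cfg <- cohort_config(seed = 50)
  resp <- cohort_responses()$raman
  bands <- raman_band_table()
  main <- bands$center %in% c(950, 1060, 1210, 1575, 1650)
  withr::with_seed(50, {
    for (cls in c("normal", "tumor")) {
      heights <- replicate(60, {
        raw <- gliospec:::apply_transmission(gen_raman(cls, cfg), resp)
        cor <- correct_transmission(raw, resp)
        norm <- normalize_raman(remove_baseline_vancouver(cor)$spectrum)
        value_at(norm, bands$center[main])
      })
      expected <- vapply(bands$center[main], function(c0) {
        a <- if (cls == "normal") bands$amplitude_normal else
          bands$amplitude_tumor
        sum(a * exp(-((c0 - bands$center) / bands$width)^2 / 2))
      }, numeric(1))
      expect_equal(rowMeans(heights), expected, tolerance = 0.05)
    }
  })
})

test_that("reflectance class means intersect at the isosbestic points", {
  cfg <- noise_free_config()
  resp <- cohort_responses()$reflectance
  norm <- normalize_reflectance(correct_transmission(
    gliospec:::apply_transmission(gen_reflectance("normal", cfg), resp), resp),
    resp)
  tum <- normalize_reflectance(correct_transmission(
    gliospec:::apply_transmission(gen_reflectance("tumor", cfg), resp), resp),
    resp)
  expect_equal(value_at(norm, 570), 1.0, tolerance = 1e-9)
  expect_equal(value_at(tum, 570), 1.0, tolerance = 1e-9)
  diffc <- norm$intensity - tum$intensity
  lam <- norm$axis
  for (iso in c(452, 529, 545, 584)) {
    win <- which(abs(lam - iso) <= 2)
    expect_true(min(abs(diffc[win])) < 1e-6 ||
                  any(diff(sign(diffc[win])) != 0),
                label = sprintf("crossing within 2 nm of %d nm", iso))
  }
  # tumor shows stronger relative absorption over 600-730 nm
  reg <- lam >= 600 & lam <= 730
  expect_true(all(tum$intensity[reg] < norm$intensity[reg]))
})

test_that("realized noise-free slope ratio matches the configured 2.6", {
  cfg <- noise_free_config()
  # the raw draw carries the lamp shape; measure on the normalized form
  resp <- cohort_responses()$reflectance
  n_n <- normalize_reflectance(gen_reflectance("normal", cfg), resp)
  n_t <- normalize_reflectance(gen_reflectance("tumor", cfg), resp)
  ratio <- slope_score(n_n) / slope_score(n_t)
  expect_equal(ratio, cfg$reflectance$slope_ratio, tolerance = 0.1)
})

test_that("EGFP amplitude is linear in tumor size", {
  cfg <- noise_free_config()
  auto <- gen_fluorescence(0, cfg)
  s1 <- gen_fluorescence(200, cfg)
  s2 <- gen_fluorescence(400, cfg)
  lift1 <- value_at(s1, 510) - value_at(auto, 510)
  lift2 <- value_at(s2, 510) - value_at(auto, 510)
  expect_equal(lift2 / lift1, 2, tolerance = 1e-9)
  expect_equal(egfp_peak_intensity(auto),
               value_at(auto, 510) / value_at(auto, 660), tolerance = 1e-12)
  expect_error(gen_fluorescence(-5, cfg), "nonnegative")
})

test_that("size -> EGFP link is recovered with R^2 > 0.8 at default noise", {
  co <- quiet_cohort(seed = 51)
  flu <- preprocess_dataset(co$datasets$fluorescence445,
                            co$responses$fluorescence445)
  tum <- flu$meta$label == "tumor"
  ratios <- vapply(which(tum), function(i) {
    egfp_peak_intensity(gliospec:::dataset_spectrum(flu, i))
  }, numeric(1))
  fit <- correlate(flu$meta$tumor_radial_size_um[tum], ratios)
  expect_gt(fit$R2, 0.8)
  expect_gt(fit$slope, 0)
})

test_that("cohorts are seed-deterministic with the expected layout", {
  c1 <- quiet_cohort(seed = 52)
  c2 <- quiet_cohort(seed = 52)
  expect_identical(c1$datasets$raman$matrix, c2$datasets$raman$matrix)
  expect_identical(c1$datasets$reflectance$matrix, c2$datasets$reflectance$matrix)
  expect_identical(c1$meta, c2$meta)
  c3 <- quiet_cohort(seed = 53)
  expect_false(identical(c1$datasets$raman$matrix, c3$datasets$raman$matrix))

  expect_equal(sum(c1$meta$label == "normal"), 13)
  expect_equal(sum(c1$meta$label == "tumor"), 13)
  expect_equal(length(unique(c1$meta$animal_id)), 8)
  expect_true(all(table(c1$meta$animal_id[c1$meta$label == "tumor"]) <= 3))
  # tumor sizes grow across sessions within an animal
  tum <- c1$meta[c1$meta$label == "tumor", ]
  for (a in unique(tum$animal_id)) {
    sz <- tum$tumor_radial_size_um[tum$animal_id == a][order(tum$session[tum$animal_id == a])]
    if (length(sz) > 1) expect_true(all(diff(sz) > 0))
  }
})

test_that("generated spectra satisfy the spectrum invariants", {
  co <- quiet_cohort(seed = 54)
  for (m in names(co$datasets)) {
    d <- co$datasets[[m]]
    expect_true(all(is.finite(d$matrix)))
    expect_true(all(diff(d$common_axis) > 0))
  }
  expect_true(all(co$datasets$reflectance$matrix > 0))
})

test_that("effect scale 0 makes the class-conditional distributions identical", {
  cfg0 <- noise_free_config(effect_scale = 0)
  expect_equal(gen_raman("normal", cfg0)$intensity,
               gen_raman("tumor", cfg0)$intensity, tolerance = 1e-12)
  expect_equal(gen_reflectance("normal", cfg0)$intensity,
               gen_reflectance("tumor", cfg0)$intensity, tolerance = 1e-12)
  expect_equal(gen_fluorescence(0, cfg0)$intensity,
               gen_fluorescence(500, cfg0)$intensity, tolerance = 1e-12)
})

test_that("band table validation catches broken inputs", {
  bad <- raman_band_table()
  bad$amplitude_normal[bad$center == 1445] <- 2
  cfg <- cohort_config()
  cfg$raman_bands <- bad
  expect_error(gen_raman("normal", cfg), "1445")
  bad2 <- raman_band_table(); bad2$width[1] <- 0
  cfg$raman_bands <- bad2
  expect_error(gen_raman("normal", cfg), "width")
})
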