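# Spectrum type, file round trips, interpolation and axis operations.

test_that("spectrum constructor enforces its invariants", {
  expect_s3_class(spectrum(c(100, 200, 300), c(1, 2, 3), "raman"), "spectrum")
  expect_error(spectrum(c(100, 100, 300), 1:3, "raman"), "increasing")
  expect_error(spectrum(c(300, 200, 100), 1:3, "raman"), "increasing")
  expect_error(spectrum(100, 1, "raman"), "at least 2")
  expect_error(spectrum(1:3, 1:2, "raman"), "same length")
  expect_error(spectrum(1:3, c(1, -1, 2), "raman"), "negative")
  expect_error(spectrum(1:3, 1:3, "raman", axis_unit = "nm"), "axis_unit")
  expect_error(spectrum(1:3, 1:3, "reflectance", axis_unit = "inverse_cm"),
               "axis_unit")
})

test_that("read_spectrum parses a hand-written file and flags bad input", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# modality=raman", "# axis_unit=inverse_cm",
               "100\t1.0", "200\t2.0", "300\t3.0"), path)
  s <- read_spectrum(path)
  expect_equal(s$axis, c(100, 200, 300))
  expect_equal(s$intensity, c(1, 2, 3))
  expect_identical(s$modality, "raman")

  writeLines(c("# modality=raman", "# axis_unit=inverse_cm",
               "100\t1.0", "100\t2.0"), path)
  expect_error(read_spectrum(path), "duplicated axis")

  writeLines(c("# modality=raman", "# axis_unit=inverse_cm",
               "100\t1.0", "200\tabc"), path)
  expect_error(read_spectrum(path), "line 4")

  writeLines(c("# modality=xray", "# axis_unit=nm", "1 2"), path)
  expect_error(read_spectrum(path), "unknown modality")
})

test_that("write/read round trip is exact to 1e-12 on random spectra", {
  set.seed(11)
  path <- withr::local_tempfile(fileext = ".txt")
  for (i in 1:100) {
    mod <- sample(c("raman", "reflectance", "fluorescence445"), 1)
    s <- random_spectrum(n = sample(5:80, 1), modality = mod)
    write_spectrum(s, path)
    s2 <- read_spectrum(path)
    expect_identical(s2$modality, s$modality)
    expect_equal(s2$axis, s$axis, tolerance = 1e-12)
    expect_equal(s2$intensity, s$intensity, tolerance = 1e-12)
  }
  expect_error(write_spectrum(structure(list(axis = 1, intensity = numeric(0)),
                                        class = "spectrum"), path),
               "empty")
})

test_that("value_at interpolates linearly and refuses extrapolation", {
  s <- spectrum(c(0, 2), c(0, 2), "reflectance")
  expect_equal(value_at(s, 1), 1.0)
  expect_equal(value_at(s, 2), 2.0)
  expect_error(value_at(s, 3), "outside")
  set.seed(2)
  for (i in 1:50) {
    s <- random_spectrum(20, "reflectance")
    x <- runif(1, min(s$axis), max(s$axis))
    j <- findInterval(x, s$axis)
    expected <- s$intensity[j] + (x - s$axis[j]) /
      (s$axis[j + 1] - s$axis[j]) * (s$intensity[j + 1] - s$intensity[j])
    expect_equal(value_at(s, x), expected, tolerance = 1e-12)
  }
})

test_that("crop keeps the window, errors when empty, and composes", {
  s <- spectrum(seq(400, 800, 10), rep(1, 41), "reflectance")
  cr <- crop(s, 540, 733)
  expect_true(all(cr$axis >= 540 & cr$axis <= 733))
  expect_equal(crop(s, 400, 800)$axis, s$axis)
  expect_error(crop(s, 10000, 20000), "fewer than 2")
  expect_error(crop(s, 700, 600), "lo < hi")
  # nested crops equal the inner crop
  expect_equal(crop(crop(s, 450, 780), 540, 700), crop(s, 540, 700))
})

test_that("resample_to matches direct interpolation and is identity on own axis", {
  set.seed(3)
  s <- random_spectrum(40, "reflectance")
  expect_equal(resample_to(s, s$axis)$intensity, s$intensity)
  line <- spectrum(c(400, 700), c(1, 4), "reflectance")
  grid <- seq(450, 650, 25)
  expect_equal(resample_to(line, grid)$intensity, 1 + (grid - 400) / 100,
               tolerance = 1e-12)
  expect_error(resample_to(s, c(min(s$axis) - 5, 500)), "extrapolate")
  # fine -> coarse -> fine error bounded by direct interpolation error
  fine <- seq(400, 733, 1)
  smooth <- spectrum(fine, sin(fine / 40) + 2, "reflectance")
  coarse <- resample_to(smooth, seq(400, 729, 7))
  back <- resample_to(coarse, seq(403, 726, 1))
  direct <- sin(seq(403, 726, 1) / 40) + 2
  expect_lt(max(abs(back$intensity - direct)), 1e-2)
  # agreement at shared grid points is exact
  shared <- seq(400, 729, 7)
  expect_equal(resample_to(smooth, shared)$intensity,
               value_at(smooth, shared), tolerance = 1e-14)
})

test_that("spectral_dataset validates metadata and summarizes classes", {
  set.seed(4)
  axis <- seq(400, 733, 3)
  spectra <- lapply(1:6, function(i) {
    spectrum(axis, runif(length(axis), 1, 2), "reflectance")
  })
  meta <- data.frame(sample_id = paste0("s", 1:6), animal_id = "A1",
                     session = 1, label = rep(c("normal", "tumor"), 3),
                     tumor_radial_size_um = rep(c(NA, 300), 3))
  d <- spectral_dataset(spectra, meta)
  expect_equal(dim(d$matrix), c(6L, length(axis)))

  bad <- meta; bad$tumor_radial_size_um[1] <- 100
  expect_error(spectral_dataset(spectra, bad), "normal samples")
  bad2 <- meta; bad2$label[1] <- "healthy"
  expect_error(spectral_dataset(spectra, bad2), "label")

  sm <- summarize_spectra(d)
  nm <- d$matrix[meta$label == "normal", ]
  expect_equal(sm$normal$mean, colMeans(nm), tolerance = 1e-12)
  expect_equal(sm$normal$se, apply(nm, 2, sd) / sqrt(3), tolerance = 1e-12)
  # two identical spectra in a class -> zero SE
  d2 <- spectral_dataset(c(spectra[c(1, 1)], spectra[c(2, 4)]),
                         meta[c(1, 1, 2, 4), ])
  expect_equal(max(summarize_spectra(d2)$normal$se), 0)
})

test_that("cohort directory round trip preserves spectra and metadata", {
  co <- quiet_cohort(seed = 5)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_setequal(names(back$datasets), names(co$datasets))
  expect_equal(back$datasets$raman$matrix, co$datasets$raman$matrix,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$meta$label, co$meta$label)
})
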