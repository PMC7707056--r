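# Shared fixture builders (all generated in code; no stored data).

random_spectrum <- function(n = 50, modality = "raman") {
  axis <- sort(runif(n, if (modality == "raman") 600 else 400,
                     if (modality == "raman") 2100 else 733))
  while (any(diff(axis) <= 0)) axis <- axis + cumsum(rep(1e-9, n))
  spectrum(axis, runif(n, 0.1, 10), modality)
}

# Exhaustive pair-counting AUC: the independent oracle for auroc().
auroc_bruteforce <- function(scores, labels) {
  tum <- scores[labels == "tumor"]
  nor <- scores[labels == "normal"]
  total <- 0
  for (t in tum) for (n in nor) {
    total <- total + if (t > n) 1 else if (t == n) 0.5 else 0
  }
  total / (length(tum) * length(nor))
}

random_score_set <- function(max_per_class = 10, ties = TRUE) {
  nn <- sample(1:max_per_class, 1)
  nt <- sample(1:max_per_class, 1)
  pool <- if (ties) sample(1:6, nn + nt, replace = TRUE) + 0.5 else
    rnorm(nn + nt)
  score_set(pool, c(rep("normal", nn), rep("tumor", nt)))
}

# Small labelled Gaussian feature matrix with known mean shift.
gaussian_features <- function(n_per_class = 13, delta = c(1.5, 1.5, 1.5, 1.5)) {
  d <- length(delta)
  x <- rbind(matrix(rnorm(n_per_class * d), ncol = d),
             matrix(rnorm(n_per_class * d), ncol = d) +
               matrix(delta, n_per_class, d, byrow = TRUE))
  list(features = x,
       labels = rep(c("normal", "tumor"), each = n_per_class))
}

# Closed-form Fisher discriminant (pooled covariance) train auROC.
fisher_auroc <- function(features, labels) {
  is_t <- labels == "tumor"
  mu_t <- colMeans(features[is_t, , drop = FALSE])
  mu_n <- colMeans(features[!is_t, , drop = FALSE])
  s_pool <- ((sum(is_t) - 1) * cov(features[is_t, , drop = FALSE]) +
               (sum(!is_t) - 1) * cov(features[!is_t, , drop = FALSE])) /
    (length(labels) - 2)
  w <- solve(s_pool, mu_t - mu_n)
  auroc(score_set(drop(features %*% w), labels))
}

quiet_cohort <- function(...) {
  cfg <- cohort_config(...)
  gen_cohort(cfg)
}

noise_free_config <- function(effect_scale = 1, seed = 1) {
  cohort_config(
    effect_scale = effect_scale,
    noise = list(raman = list(band_sdlog = 0, shot_scale = 0),
                 reflectance = list(sat_sd = 0, slope_sdlog = 0,
                                    relative_sd = 0),
                 fluorescence = list(gain_sdlog = 0, relative_sd = 0)),
    seed = seed)
}
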