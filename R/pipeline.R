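# End-to-end study runner: preprocessing, per-modality PCA-LDA training,
# cross-validation, multimodal fusion, and the correlation analyses.

#' Pearson correlation and linear fit
#'
#' Ordinary least-squares fit of `y` on `x` with Pearson's r and R^2. When
#' `fixed_intercept` is given (e.g. the mean EGFP readout of normal tissue),
#' only the slope is fitted through that intercept and R^2 is computed from
#' the residuals about the constrained line (total sum of squares still
#' about the mean of `y`); in the free fit R^2 equals r^2 exactly.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param fixed_intercept optional fixed intercept value.
#' @return an object of class `correlation_result`: `r`, `R2`, `slope`,
#'   `intercept`, `fixed_intercept` (logical), `n`.
#' @export
correlate <- function(x, y, fixed_intercept = NULL) {
  x <- as.double(x); y <- as.double(y)
  if (length(x) != length(y) || length(x) < 3L) {
    stop("correlate needs equal-length vectors with at least 3 points",
         call. = FALSE)
  }
  if (stats::var(x) == 0) stop("zero variance in x", call. = FALSE)
  r <- stats::cor(x, y)
  if (is.null(fixed_intercept)) {
    fit <- stats::lm.fit(cbind(1, x), y)
    slope <- fit$coefficients[2L]
    intercept <- fit$coefficients[1L]
    R2 <- r^2
    fixed <- FALSE
  } else {
    stopifnot(is_number(fixed_intercept))
    intercept <- fixed_intercept
    slope <- sum(x * (y - intercept)) / sum(x^2)
    ss_res <- sum((y - intercept - slope * x)^2)
    ss_tot <- sum((y - mean(y))^2)
    R2 <- 1 - ss_res / ss_tot
    fixed <- TRUE
  }
  structure(list(r = r, R2 = R2, slope = unname(slope),
                 intercept = unname(intercept), fixed_intercept = fixed,
                 n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation> r = %.3f, R2 = %.3f, y = %.4g + %.4g x%s (n = %d)\n",
              x$r, x$R2, x$intercept, x$slope,
              if (x$fixed_intercept) " [fixed intercept]" else "", x$n))
  invisible(x)
}

# Train one modality: PCA, greedy selection, random search, ROC. Returns the
# classifier plus the tumor-high training score set.
train_modality <- function(d, config, seed) {
  fit_spectral_classifier(d, n_components = config$n_components,
                          n_select = config$n_select,
                          stop_n = config$stop_n,
                          stop_n_select = config$stop_n_select,
                          seed = seed)
}

#' Default analysis configuration for [run_study]
#'
#' @param seed master seed for every stochastic stage.
#' @param n_components,n_select,stop_n,stop_n_select classifier settings
#'   (see [fit_spectral_classifier]).
#' @param k cross-validation folds.
#' @return a named list.
#' @export
study_config <- function(seed = 1L, n_components = 15L, n_select = 4L,
                         stop_n = 500L, stop_n_select = 200L, k = 4L) {
  list(seed = as.integer(seed), n_components = n_components,
       n_select = n_select, stop_n = stop_n,
       stop_n_select = stop_n_select, k = k)
}

#' Run the full multimodal classification study
#'
#' Executes the whole analysis on a cohort: preprocessing per modality
#' (transmission correction; Raman baseline removal and 1445 cm^-1
#' normalization; reflectance lamp correction, 570 nm normalization and
#' 540-733 nm crop), per-modality PCA-LDA training with auROC-driven
#' component selection, sensitivity/specificity at the Youden-suggested
#' training threshold, stratified k-fold cross-validation, multimodal score
#' fusion (trained and cross-validated on shared folds), and the
#' size/EGFP/reflectance-score correlations. Every stochastic step is seeded
#' from `config$seed`, so reruns are bit-identical.
#'
#' @param cohort a [gen_cohort] result, or any list with `datasets` (named
#'   [spectral_dataset] list including `raman` and `reflectance`), `meta`,
#'   and `responses`.
#' @param config a [study_config] list.
#' @return an object of class `study_report`: per-modality and multimodal
#'   blocks with `train_auroc`, `cv_auroc`, `sensitivity`, `specificity`,
#'   `selected_pcs`, `combination`; plus `cv_fold_aurocs`, `correlations`,
#'   and the preprocessing convergence log. Missing modalities produce `NULL`
#'   blocks rather than errors.
#' @export
run_study <- function(cohort, config = study_config()) {
  seed <- config$seed
  modalities <- intersect(c("raman", "reflectance"), names(cohort$datasets))
  if (!length(modalities)) stop("cohort has no classifiable modality", call. = FALSE)
  meta <- cohort$meta
  report <- list(modalities = list(), multimodal = NULL,
                 correlations = list(), preprocessing = list(),
                 config = config)

  pre <- list(); proj <- list(); fits <- list()
  for (m in modalities) {
    pre[[m]] <- preprocess_dataset(cohort$datasets[[m]],
                                   response = cohort$responses[[m]])
    report$preprocessing[[m]] <- attr(pre[[m]], "convergence")
    fit <- train_modality(pre[[m]], config,
                          seed = derive_seed(seed, match(m, modalities)))
    fits[[m]] <- fit
    proj[[m]] <- project(pre[[m]], fit$basis)
    cv <- kfold_cv(proj[[m]], meta$label, k = config$k,
                   rng_seed = derive_seed(seed, 10, match(m, modalities)),
                   n_select = config$n_select, stop_n = config$stop_n,
                   stop_n_select = config$stop_n_select)
    report$modalities[[m]] <- list(
      train_auroc = fit$roc$auroc,
      cv_auroc = cv$mean_auroc,
      cv_fold_aurocs = cv$fold_aurocs,
      sensitivity = fit$roc$sens_at_threshold,
      specificity = fit$roc$spec_at_threshold,
      selected_pcs = fit$selected,
      combination = list(coefficients = fit$combo$coefficients,
                         sign_flips = fit$combo$sign_flips,
                         train_auroc = fit$combo$train_auroc))
  }

  if (length(modalities) >= 2L) {
    fusion <- fuse_scores(lapply(fits, `[[`, "scores"),
                          stop_n = config$stop_n,
                          rng_seed = derive_seed(seed, 20))
    roc_f <- roc_curve(fusion$fused)
    cv_f <- multimodal_cv(proj, meta$label, config,
                          rng_seed = derive_seed(seed, 21))
    report$multimodal <- list(
      train_auroc = roc_f$auroc,
      cv_auroc = cv_f$mean_auroc,
      cv_fold_aurocs = cv_f$fold_aurocs,
      sensitivity = roc_f$sens_at_threshold,
      specificity = roc_f$spec_at_threshold,
      combination = list(coefficients = fusion$combo$coefficients,
                         sign_flips = fusion$combo$sign_flips))
  }

  if ("fluorescence445" %in% names(cohort$datasets) &&
      "reflectance" %in% modalities) {
    flu <- preprocess_dataset(cohort$datasets$fluorescence445,
                              response = cohort$responses$fluorescence445)
    egfp <- vapply(seq_len(nrow(flu$matrix)),
                   function(i) egfp_peak_intensity(dataset_spectrum(flu, i)),
                   numeric(1L))
    is_tumor <- meta$label == "tumor"
    sizes <- meta$tumor_radial_size_um
    refl_scores <- fits$reflectance$scores$scores
    # Fig-4-style fits on the tumor points; the size/EGFP fit uses the mean
    # normal EGFP readout as a fixed intercept.
    report$correlations <- list(
      size_vs_egfp = correlate(sizes[is_tumor], egfp[is_tumor],
                               fixed_intercept = mean(egfp[!is_tumor])),
      size_vs_reflectance_score = correlate(sizes[is_tumor],
                                            refl_scores[is_tumor]),
      egfp_vs_reflectance_score = correlate(egfp[is_tumor],
                                            refl_scores[is_tumor]))
    report$egfp_ratios <- egfp
  }
  structure(report, class = "study_report")
}

# Shared-fold multimodal CV: per fold, each modality's selection + search is
# retrained on the training folds, the fold-training scores are fused with
# the same random-search routine, and the fused combination scores the
# held-out samples.
multimodal_cv <- function(proj, labels, config, rng_seed = NULL) {
  folds <- make_folds(labels, config$k, rng_seed = derive_seed(rng_seed, 1))
  k <- config$k
  fold_aurocs <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    train_scores <- list(); test_scores <- list()
    for (m in names(proj)) {
      pm <- proj[[m]]
      sel <- as.integer(select_pcs(pm[tr, , drop = FALSE], labels[tr],
                                   n_select = config$n_select,
                                   stop_n = config$stop_n_select,
                                   rng_seed = derive_seed(rng_seed, 2, f,
                                                          match(m, names(proj)))))
      combo <- random_search_lda(pm[tr, sel, drop = FALSE], labels[tr],
                                 stop_n = config$stop_n,
                                 rng_seed = derive_seed(rng_seed, 3, f,
                                                        match(m, names(proj))))
      train_scores[[m]] <- combo_score(combo, pm[tr, sel, drop = FALSE])
      test_scores[[m]] <- combo_score(combo, pm[!tr, sel, drop = FALSE])
    }
    fuse <- random_search_lda(do.call(cbind, train_scores), labels[tr],
                              stop_n = config$stop_n,
                              rng_seed = derive_seed(rng_seed, 4, f))
    fused_test <- combo_score(fuse, do.call(cbind, test_scores))
    fold_aurocs[f] <- auroc_raw(fused_test, labels[!tr] == "tumor")
  }
  list(fold_aurocs = fold_aurocs, mean_auroc = mean(fold_aurocs))
}

#' @export
print.study_report <- function(x, ...) {
  cat("Multimodal spectral classification study\n")
  cat(sprintf("%-14s %11s %9s %12s %12s\n", "", "train auROC", "CV auROC",
              "sensitivity", "specificity"))
  fmt <- function(name, b) {
    cat(sprintf("%-14s %11.2f %9.2f %12.2f %12.2f\n", name,
                b$train_auroc, b$cv_auroc, b$sensitivity, b$specificity))
  }
  for (m in names(x$modalities)) fmt(m, x$modalities[[m]])
  if (!is.null(x$multimodal)) fmt("multimodal", x$multimodal)
  if (length(x$correlations)) {
    cat("correlations (tumor samples):\n")
    for (nm in names(x$correlations)) {
      co <- x$correlations[[nm]]
      cat(sprintf("  %-26s r = %6.3f, R2 = %6.3f\n", nm, co$r, co$R2))
    }
  }
  invisible(x)
}

#' Serialize a study report to JSON
#'
#' Full numeric precision; [read_report] restores an equivalent report.
#'
#' @param report a [run_study] result.
#' @param path output JSON path.
#' @return `invisible(path)`.
#' @export
write_report <- function(report, path) {
  plain <- unclass(report)
  plain$correlations <- lapply(plain$correlations, unclass)
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in names(rep$correlations)) {
    class(rep$correlations[[nm]]) <- "correlation_result"
  }
  structure(rep, class = "study_report")
}
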