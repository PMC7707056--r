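# auROC-maximizing random-search linear discriminant, greedy PC selection,
# stratified k-fold cross-validation, and multimodal score fusion.

# Per-column tumor-high orientation signs: orient each feature so its
# single-feature auROC is >= 0.5 before the nonnegative-coefficient search.
feature_sign_flips <- function(features, is_tumor) {
  vapply(seq_len(ncol(features)), function(j) {
    if (auroc_raw(features[, j], is_tumor) >= 0.5) 1 else -1
  }, numeric(1L))
}

#' Random-search linear discriminant maximizing the auROC
#'
#' Builds a linear classifier over feature columns (typically 4 selected PC
#' scores, or per-modality classifier scores during fusion) by repeated
#' random draws: each iteration draws one coefficient per feature uniformly
#' in `[coeff_lo, coeff_hi]`, scores every sample with the weighted sum, and
#' records the auROC; the best combination so far is tracked and the search
#' stops after `stop_n` consecutive draws without improvement.
#'
#' Because PC signs are arbitrary, each feature is first oriented so its
#' single-feature auROC is at least 0.5 (`sign_flips`); the nonnegative
#' coefficient range then spans the useful directions. Before the random
#' draws, each single-feature candidate is evaluated as a deterministic warm
#' start, so the result is never worse than the best individual feature.
#'
#' @param features numeric matrix, n_samples x n_features.
#' @param labels `"normal"`/`"tumor"` per row.
#' @param coeff_lo,coeff_hi coefficient range for the uniform draws
#'   (default 0-100).
#' @param stop_n stop after this many consecutive non-improving draws
#'   (default 500).
#' @param rng_seed integer seed; identical seeds give identical results.
#' @param pc_indices optional feature labels (e.g. PC numbers) stored in the
#'   result.
#' @return an object of class `linear_combination`: `pc_indices`,
#'   `coefficients`, `sign_flips`, `train_auroc`, `orientation`
#'   (`"tumor_high"`), `n_draws`, and the nondecreasing best-so-far
#'   `trajectory`.
#' @export
random_search_lda <- function(features, labels, coeff_lo = 0, coeff_hi = 100,
                              stop_n = 500L, rng_seed = NULL,
                              pc_indices = NULL) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels))
  check_two_classes(labels)
  is_tumor <- labels == "tumor"
  d <- ncol(features)
  flips <- feature_sign_flips(features, is_tumor)
  xf <- sweep(features, 2L, flips, `*`)

  # Deterministic warm starts: one feature at a time.
  best_coef <- rep(0, d); best_coef[1L] <- coeff_hi
  best_auc <- -Inf
  for (j in seq_len(d)) {
    cand <- rep(0, d); cand[j] <- coeff_hi
    a <- auroc_raw(drop(xf %*% cand), is_tumor)
    if (a > best_auc) { best_auc <- a; best_coef <- cand }
  }

  trajectory <- numeric(0)
  n_draws <- 0L
  with_seed(rng_seed, {
    miss <- 0L
    batch <- 128L
    repeat {
      draws <- matrix(stats::runif(d * batch, coeff_lo, coeff_hi), nrow = d)
      sc <- xf %*% draws
      aucs <- vapply(seq_len(batch),
                     function(b) auroc_raw(sc[, b], is_tumor), numeric(1L))
      stopped <- FALSE
      for (b in seq_len(batch)) {
        n_draws <- n_draws + 1L
        if (aucs[b] > best_auc) {
          best_auc <- aucs[b]
          best_coef <- draws[, b]
          miss <- 0L
        } else miss <- miss + 1L
        trajectory[n_draws] <- best_auc
        if (miss >= stop_n) { stopped <- TRUE; break }
      }
      if (stopped) break
    }
  })
  structure(list(pc_indices = pc_indices %||% seq_len(d),
                 coefficients = best_coef,
                 sign_flips = flips,
                 train_auroc = best_auc,
                 orientation = "tumor_high",
                 n_draws = n_draws,
                 trajectory = trajectory),
            class = "linear_combination")
}

#' @export
print.linear_combination <- function(x, ...) {
  cat(sprintf("<linear_combination> features {%s}, train auROC %.3f (%d draws)\n",
              paste(x$pc_indices, collapse = ", "), x$train_auroc, x$n_draws))
  cat("  coefficients:", paste(sprintf("%+.2f", x$coefficients * x$sign_flips),
                               collapse = ", "), "\n")
  invisible(x)
}

#' Score samples with a trained linear combination
#'
#' @param combo a [random_search_lda] result.
#' @param features matrix whose columns match `combo$pc_indices` in order.
#' @return numeric score per row, tumor-high oriented.
#' @export
combo_score <- function(combo, features) {
  features <- as.matrix(features)
  if (ncol(features) != length(combo$coefficients)) {
    stop("feature count does not match the trained combination", call. = FALSE)
  }
  drop(features %*% (combo$coefficients * combo$sign_flips))
}

#' Greedy auROC-driven selection of principal components
#'
#' Formalizes "pick the PCs that discriminate and that improve the
#' classifier": components are first ranked by their single-PC auROC (after
#' orientation); the best one seeds the set, and each further component is
#' chosen as the one whose addition maximizes the trained random-search
#' combination's auROC on the same samples. Ties go to the lower PC index.
#'
#' @param proj n_samples x n_kept PC-score matrix from [project].
#' @param labels `"normal"`/`"tumor"` per row.
#' @param n_select number of components to keep (default 4).
#' @param stop_n stop rule for the per-candidate searches; smaller than the
#'   final-model default because each greedy step only ranks candidates.
#' @param rng_seed integer seed.
#' @return integer vector of selected 1-based PC indices (in selection
#'   order), with attributes `pc_aurocs` (oriented single-PC auROCs) and
#'   `path` (auROC after each greedy step).
#' @export
select_pcs <- function(proj, labels, n_select = 4L, stop_n = 200L,
                       rng_seed = NULL) {
  proj <- as.matrix(proj)
  labels <- as.character(labels)
  check_two_classes(labels)
  is_tumor <- labels == "tumor"
  K <- ncol(proj)
  if (n_select > K) stop("n_select exceeds the number of components", call. = FALSE)
  single <- vapply(seq_len(K), function(j) {
    a <- auroc_raw(proj[, j], is_tumor)
    max(a, 1 - a)
  }, numeric(1L))
  selected <- which.max(single)
  path <- single[selected]
  step <- 1L
  while (length(selected) < n_select) {
    step <- step + 1L
    candidates <- setdiff(seq_len(K), selected)
    best_j <- NA_integer_; best_a <- -Inf
    for (j in candidates) {
      combo <- random_search_lda(proj[, c(selected, j), drop = FALSE], labels,
                                 stop_n = stop_n,
                                 rng_seed = derive_seed(rng_seed, step, j))
      if (combo$train_auroc > best_a) { best_a <- combo$train_auroc; best_j <- j }
    }
    selected <- c(selected, best_j)
    path <- c(path, best_a)
  }
  structure(selected, pc_aurocs = single, path = path)
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# into k folds as evenly as possible (sizes 4,3,3,3 for 13 samples).
make_folds <- function(labels, k, rng_seed = NULL) {
  labels <- as.character(labels)
  fold <- integer(length(labels))
  with_seed(rng_seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      if (length(idx) < k) {
        stop(sprintf("class '%s' has fewer than k = %d samples", cls, k),
             call. = FALSE)
      }
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

#' Stratified k-fold cross-validation of the PCA-LDA classifier
#'
#' Splits samples into `k` class-stratified folds; for each fold the
#' component selection ([select_pcs]) and the random-search discriminant
#' ([random_search_lda]) are retrained on the remaining folds only, the
#' held-out samples are scored with the trained combination, and the
#' held-out auROC is recorded. With 13 samples per class and `k = 4` the
#' folds have stratified sizes 4,3,3,3 per class.
#'
#' @param features n_samples x n_features matrix (typically the 15-column PC
#'   projection). When `n_features <= n_select` all columns are used and
#'   selection is skipped.
#' @param labels `"normal"`/`"tumor"` per row.
#' @param k number of folds (default 4); every class needs >= k samples.
#' @param rng_seed integer seed governing fold assignment and the searches.
#' @param n_select,stop_n,stop_n_select see [select_pcs] and
#'   [random_search_lda].
#' @return list with `fold_aurocs`, `mean_auroc`, `folds` (per-sample fold
#'   id), and `fold_details` (selected PCs and train auROC per fold).
#' @export
kfold_cv <- function(features, labels, k = 4L, rng_seed = NULL,
                     n_select = 4L, stop_n = 500L, stop_n_select = 200L) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  check_two_classes(labels)
  folds <- make_folds(labels, k, rng_seed = derive_seed(rng_seed, 101))
  fold_aurocs <- numeric(k)
  details <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f
    sel <- if (ncol(features) > n_select) {
      as.integer(select_pcs(features[tr, , drop = FALSE], labels[tr],
                            n_select = n_select, stop_n = stop_n_select,
                            rng_seed = derive_seed(rng_seed, 200, f)))
    } else seq_len(ncol(features))
    combo <- random_search_lda(features[tr, sel, drop = FALSE], labels[tr],
                               stop_n = stop_n,
                               rng_seed = derive_seed(rng_seed, 300, f),
                               pc_indices = sel)
    test_scores <- combo_score(combo, features[!tr, sel, drop = FALSE])
    fold_aurocs[f] <- auroc_raw(test_scores, labels[!tr] == "tumor")
    details[[f]] <- list(selected = sel, train_auroc = combo$train_auroc)
  }
  list(fold_aurocs = fold_aurocs, mean_auroc = mean(fold_aurocs),
       folds = folds, fold_details = details)
}

#' Fuse per-modality classifier scores
#'
#' Runs the same auROC-maximizing random search with modality scores (one
#' column per modality, e.g. Raman and reflectance PCA-LDA scores) as
#' features, producing one fused score per sample. Because each single
#' modality is a warm-start candidate, the fused training auROC is never
#' below the best single modality.
#'
#' @param score_sets list of >= 2 [score_set] objects over the same samples
#'   in the same order (identical label vectors).
#' @param stop_n,rng_seed see [random_search_lda].
#' @return list with `fused` (a tumor-high [score_set]) and `combo` (the
#'   trained [random_search_lda] combination).
#' @export
fuse_scores <- function(score_sets, stop_n = 500L, rng_seed = NULL) {
  if (!is.list(score_sets) || length(score_sets) < 2L) {
    stop("fusion needs at least 2 score sets", call. = FALSE)
  }
  stopifnot(all(vapply(score_sets, inherits, logical(1L), "score_set")))
  labels <- score_sets[[1L]]$labels
  for (ss in score_sets[-1L]) {
    if (!identical(ss$labels, labels)) {
      stop("score sets are not aligned over the same samples", call. = FALSE)
    }
  }
  features <- do.call(cbind, lapply(score_sets, oriented_scores))
  combo <- random_search_lda(features, labels, stop_n = stop_n,
                             rng_seed = rng_seed)
  fused <- score_set(combo_score(combo, features), labels)
  list(fused = fused, combo = combo)
}
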