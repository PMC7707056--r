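# Random-search discriminant, greedy PC selection, cross-validation, fusion.

test_that("a perfectly separating feature yields train auROC 1", {
  labels <- rep(c("normal", "tumor"), each = 6)
  features <- cbind(c(1:6, 11:16), 0, 0, 0)
  combo <- random_search_lda(features, labels, stop_n = 50, rng_seed = 1)
  expect_equal(combo$train_auroc, 1.0)
})

test_that("coefficient scaling leaves the score ranking and auROC unchanged", {
  set.seed(30)
  g <- gaussian_features()
  combo <- random_search_lda(g$features, g$labels, stop_n = 100, rng_seed = 2)
  sc1 <- combo_score(combo, g$features)
  combo2 <- combo; combo2$coefficients <- combo$coefficients * 7.3
  sc2 <- combo_score(combo2, g$features)
  expect_equal(rank(sc1), rank(sc2))
  expect_equal(auroc(score_set(sc1, g$labels)),
               auroc(score_set(sc2, g$labels)))
})

test_that("search is seed-reproducible with a nondecreasing trajectory", {
  set.seed(31)
  g <- gaussian_features()
  c1 <- random_search_lda(g$features, g$labels, rng_seed = 42)
  c2 <- random_search_lda(g$features, g$labels, rng_seed = 42)
  expect_identical(c1$coefficients, c2$coefficients)
  expect_identical(c1$train_auroc, c2$train_auroc)
  expect_true(all(diff(c1$trajectory) >= 0))
  c3 <- random_search_lda(g$features, g$labels, rng_seed = 43)
  expect_false(identical(c3$n_draws, c1$n_draws) &&
                 identical(c3$coefficients, c1$coefficients))
})

test_that("degenerate all-constant features give chance-level auROC", {
  labels <- rep(c("normal", "tumor"), each = 5)
  combo <- random_search_lda(matrix(1, 10, 4), labels, stop_n = 50,
                             rng_seed = 3)
  expect_equal(combo$train_auroc, 0.5)
})

test_that("sign flips orient anti-correlated features", {
  labels <- rep(c("normal", "tumor"), each = 6)
  features <- cbind(-c(1:6, 11:16), 0)   # tumor LOW on the raw feature
  combo <- random_search_lda(features, labels, stop_n = 50, rng_seed = 4)
  expect_equal(combo$sign_flips[1], -1)
  expect_equal(combo$train_auroc, 1.0)
})

test_that("random search approaches the Fisher discriminant on Gaussian data", {
  set.seed(32)
  ok <- 0
  for (i in 1:25) {
    g <- gaussian_features(13, delta = rep(1.5, 4))
    fisher <- fisher_auroc(g$features, g$labels)
    combo <- random_search_lda(g$features, g$labels, stop_n = 500,
                               rng_seed = 1000 + i)
    if (combo$train_auroc >= fisher - 0.02) ok <- ok + 1
  }
  expect_gte(ok / 25, 0.95)
})

test_that("greedy selection finds a single perfectly separating PC first", {
  set.seed(33)
  labels <- rep(c("normal", "tumor"), each = 8)
  proj <- matrix(rnorm(16 * 10), 16)
  proj[, 6] <- c(rnorm(8, 0), rnorm(8, 10))   # PC6 separates perfectly
  sel <- select_pcs(proj, labels, n_select = 4, rng_seed = 5)
  expect_equal(as.integer(sel)[1], 6L)
  expect_length(as.integer(sel), 4L)
  expect_equal(max(attr(sel, "pc_aurocs")), 1.0)
  expect_error(select_pcs(proj, rep("tumor", 16)), "each class")
})

test_that("stratified folds balance classes and respect k", {
  set.seed(34)
  labels <- rep(c("normal", "tumor"), each = 13)
  folds <- gliospec:::make_folds(labels, 4, rng_seed = 6)
  for (f in 1:4) {
    expect_true(sum(folds == f & labels == "normal") %in% 3:4)
    expect_true(sum(folds == f & labels == "tumor") %in% 3:4)
  }
  expect_error(gliospec:::make_folds(rep(c("normal", "tumor"), c(3, 13)), 4),
               "fewer than k")
})

test_that("cross-validation is perfect on a perfectly separating feature set", {
  labels <- rep(c("normal", "tumor"), each = 12)
  features <- cbind(c(rnorm(12, 0, 0.1), rnorm(12, 5, 0.1)),
                    matrix(rnorm(24 * 3), 24))
  cv <- kfold_cv(features, labels, k = 4, rng_seed = 7)
  expect_equal(cv$fold_aurocs, rep(1, 4))
  expect_equal(cv$mean_auroc, 1)
})

test_that("cross-validated auROC is near chance on null features while training overfits", {
  set.seed(35)
  cv_means <- numeric(20); train_means <- numeric(20)
  for (i in 1:20) {
    labels <- rep(c("normal", "tumor"), each = 13)
    features <- matrix(rnorm(26 * 15), 26)
    cv <- kfold_cv(features, labels, k = 4, rng_seed = i,
                   stop_n = 200, stop_n_select = 100)
    cv_means[i] <- cv$mean_auroc
    train_means[i] <- mean(vapply(cv$fold_details, `[[`, numeric(1),
                                  "train_auroc"))
  }
  expect_gt(mean(cv_means), 0.35)
  expect_lt(mean(cv_means), 0.65)
  # the documented overfitting gap: training auROC far above held-out auROC
  expect_gt(mean(train_means), 0.75)
  expect_gt(mean(train_means) - mean(cv_means), 0.1)
})

test_that("fusing two identical score sets reproduces the single auROC", {
  set.seed(36)
  labels <- rep(c("normal", "tumor"), each = 10)
  ss <- score_set(c(rnorm(10), rnorm(10, 1.5)), labels)
  fused <- fuse_scores(list(ss, ss), stop_n = 100, rng_seed = 8)
  expect_equal(auroc(fused$fused), auroc(ss))
})

test_that("fusion never falls below the informative modality", {
  set.seed(37)
  for (i in 1:20) {
    labels <- rep(c("normal", "tumor"), each = 13)
    informative <- score_set(c(rnorm(13), rnorm(13, 2)), labels)
    noise <- score_set(rnorm(26), labels)
    fused <- fuse_scores(list(informative, noise), stop_n = 200,
                         rng_seed = 100 + i)
    expect_gte(auroc(fused$fused), auroc(informative) - 0.02)
  }
})

test_that("fusion input is validated", {
  labels <- rep(c("normal", "tumor"), each = 5)
  ss <- score_set(rnorm(10), labels)
  expect_error(fuse_scores(list(ss)), "at least 2")
  misaligned <- score_set(rnorm(10), rev(labels))
  expect_error(fuse_scores(list(ss, misaligned)), "not aligned")
})
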