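test_that("label binarization marks other defect labels negative", {
  labels <- c("BRCA2d", "CDK12d", "MMRd", "DDRwt", "ATMd", "BRCA2d")
  y <- binarize_labels(labels, "BRCA2d")
  expect_equal(y, c(1L, 0L, 0L, 0L, 0L, 1L))
  expect_equal(sum(binarize_labels(rep("DDRwt", 10), "BRCA2d")), 0)
  expect_equal(length(y), length(labels))
})

test_that("stratified split preserves class balance, is disjoint and seeded", {
  y <- c(rep(1, 10), rep(0, 90))
  sp <- stratified_split(y, 0.4, seed = 3)
  expect_equal(length(intersect(sp$train, sp$test)), 0)
  expect_setequal(c(sp$train, sp$test), seq_along(y))
  expect_equal(sum(y[sp$test]), 4)  # 40% of 10 positives
  expect_equal(length(sp$test), 40)
  expect_identical(sp, stratified_split(y, 0.4, seed = 3))
  expect_false(identical(sp$test, stratified_split(y, 0.4, seed = 4)$test))
  # random fixtures stay disjoint/exhaustive
  set.seed(66)
  for (i in 1:20) {
    yy <- rbinom(50, 1, 0.3)
    s <- stratified_split(yy, 0.4, seed = i)
    expect_setequal(c(s$train, s$test), 1:50)
    expect_equal(length(intersect(s$train, s$test)), 0)
  }
})

test_that("AUC equals the rank-statistic and external oracles", {
  set.seed(12)
  y <- rbinom(200, 1, 0.4)
  p <- runif(200)
  # Mann-Whitney identity via wilcox.test statistic
  w <- wilcox.test(p[y == 1], p[y == 0], exact = FALSE)$statistic
  expect_equal(roc_auc(y, p), unname(w) / (sum(y == 1) * sum(y == 0)))
  skip_if_not_installed("pROC")
  expect_equal(roc_auc(y, p),
               as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE))))
  # perfect separation and chance behaviour
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  set.seed(13)
  yy <- rep(0:1, each = 2500)
  expect_equal(roc_auc(yy, runif(5000)), 0.5, tolerance = 0.05)
})

test_that("threshold scan returns the minimum grid point with maximal F1", {
  expect_equal(derive_threshold(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 0.201)
  # all positives: threshold 0 already yields F1 = 1
  expect_equal(derive_threshold(c(1, 1, 1), c(0.2, 0.5, 0.9)), 0)
  expect_error(derive_threshold(c(0, 0), c(0.1, 0.2)), "positive labels")
  set.seed(21)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    y <- rbinom(n, 1, 0.5)
    if (sum(y) == 0) y[1] <- 1
    p <- round(runif(n), 3)
    expect_equal(derive_threshold(y, p), oracle_threshold(y, p))
  }
})

test_that("a linearly separable cohort trains to AUC 1 with few resources", {
  toy <- toy_separable_cohort()
  cfg <- train_config(folds = 3, grid = 1.0, nrounds = 50, patience = 10,
                      seed = 5)
  m <- grid_search_train(toy$x, toy$y, cfg, target = "toy")
  p <- predict_proba(m, toy$x)
  expect_equal(roc_auc(toy$y, p), 1)
  expect_equal(nrow(m$cv), 1)  # single grid point
  # constant-feature prediction is sample-order invariant
  perm <- sample(nrow(toy$x))
  expect_equal(predict_proba(m, toy$x[perm, ]), p[perm])
})

test_that("lexicographic selection prefers error then log loss on AUC ties", {
  cv <- tibble::tibble(
    auc = c(0.9, 0.9, 0.95), error = c(0.2, 0.1, 0.3),
    logloss = c(0.5, 0.6, 0.7))
  ord <- order(-cv$auc, cv$error, cv$logloss)
  expect_equal(ord[1], 3)      # best AUC wins outright
  cv$auc[3] <- 0.9
  ord <- order(-cv$auc, cv$error, cv$logloss)
  expect_equal(ord[1], 2)      # tie on AUC: lower error wins
  cv$error[1] <- 0.1
  ord <- order(-cv$auc, cv$error, cv$logloss)
  expect_equal(ord[1], 1)      # tie on AUC+error: lower log loss wins
})

test_that("training guards against too many folds for the positives", {
  toy <- toy_separable_cohort(n = 20)
  toy$y <- c(rep(1, 4), rep(0, 16))
  expect_error(
    grid_search_train(toy$x, toy$y, train_config(folds = 6, grid = 1.0),
                      "t"),
    "reduce the fold count")
})

test_that("prediction refuses shuffled feature columns", {
  toy <- toy_separable_cohort()
  m <- grid_search_train(toy$x, toy$y,
                         train_config(folds = 3, grid = 1.0, nrounds = 20),
                         "toy")
  shuffled <- toy$x[, c(2, 1, 3, 4, 5)]
  expect_error(predict_proba(m, shuffled), "training order")
  expect_error(feature_impact(m, shuffled), "training order")
})

test_that("model artifacts round-trip bit-exactly", {
  toy <- toy_separable_cohort()
  m <- grid_search_train(toy$x, toy$y,
                         train_config(folds = 3, grid = c(0.5, 1.0),
                                      nrounds = 30, seed = 2), "toy")
  m$threshold <- derive_threshold(toy$y, predict_proba(m, toy$x))
  dir <- file.path(withr::local_tempdir(), "model")
  save_model(m, dir)
  m2 <- load_model(dir)
  probe <- toy_separable_cohort(n = 20, seed = 99)$x
  expect_identical(predict_proba(m, probe), predict_proba(m2, probe))
  expect_equal(m2$feature_names, m$feature_names)
  expect_equal(m2$threshold, m$threshold)
  expect_equal(m2$params, m$params)
  expect_error(load_model(file.path(dir, "nope")), "metadata not found")
})

test_that("attributions satisfy local accuracy and rank the true feature", {
  toy <- toy_separable_cohort(n = 40)
  m <- grid_search_train(toy$x, toy$y,
                         train_config(folds = 3, grid = 1.0, nrounds = 60),
                         "toy")
  probe <- toy_separable_cohort(n = 20, seed = 7)$x
  imp <- feature_impact(m, probe)
  expect_lt(imp$local_accuracy_error, 1e-4)
  expect_equal(imp$impact$feature[1], "f1")  # only informative feature
  expect_true(all(imp$impact$impact >= 0))
  # margins reconstructed from attributions match predictions
  margins <- rowSums(imp$attributions)
  expect_equal(1 / (1 + exp(-margins)), predict_proba(m, probe),
               tolerance = 1e-6)
})

test_that("evaluation bundles AUC, threshold and curve consistently", {
  set.seed(31)
  y <- rbinom(100, 1, 0.3)
  p <- plogis(rnorm(100, mean = y * 3 - 1.5))
  ev <- evaluate_classification(y, p)
  expect_equal(ev$auc, roc_auc(y, p))
  expect_equal(ev$threshold, oracle_threshold(y, p))
  expect_equal(nrow(ev$curve), 1001)
  g <- glance(ev)
  expect_equal(g$n, 100)
  expect_equal(g$auc, ev$auc)
})
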