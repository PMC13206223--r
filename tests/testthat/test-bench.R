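test_that("binary metrics reproduce closed-form confusion arithmetic", {
  expect_equal(as.numeric(binary_metrics(c(1, 0, 1, 0), c(1, 0, 1, 0))),
               c(100, 100, 100, 100))
  # TP=12 FP=8 FN=14 TN=35 over 69 cases
  predicted <- c(rep(1, 12), rep(1, 8), rep(0, 14), rep(0, 35))
  actual <- c(rep(1, 12), rep(0, 8), rep(1, 14), rep(0, 35))
  m <- binary_metrics(predicted, actual)
  expect_equal(round(as.numeric(m), 2), c(68.12, 46.15, 60.00, 52.17))
  # no positive predictions: flagged zero precision, zero recall
  m0 <- binary_metrics(rep(0, 10), c(rep(1, 3), rep(0, 7)))
  expect_equal(unname(m0[c("recall", "precision", "f1")]), c(0, 0, 0))
  expect_true(attr(m0, "precision_undefined"))
  expect_error(binary_metrics(c(1, 0), c(1)), "length")
})

test_that("trapezoidal AUC equals the concordance count", {
  set.seed(19)
  for (i in 1:25) {
    n <- sample(20:80, 1)
    y <- stats::rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- round(stats::runif(n), sample(c(1, 2, 6), 1))  # force some ties
    auc <- roc_and_auc(s, y)$auc
    pos <- s[y == 1]; neg <- s[y == 0]
    conc <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(auc, mean(conc), tolerance = 1e-12)
  }
  expect_equal(roc_and_auc(rep(0.3, 10), c(rep(1, 4), rep(0, 6)))$auc, 0.5)
  expect_equal(roc_and_auc(1:10, c(rep(0, 5), rep(1, 5)))$auc, 1)
  expect_error(roc_and_auc(1:5, rep(1, 5)), "both classes")
})

test_that("the ROC is a monotone step curve from (0,0) to (1,1)", {
  set.seed(23)
  y <- stats::rbinom(60, 1, 0.3)
  s <- stats::runif(60)
  roc <- roc_and_auc(s, y)$roc
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
})

test_that("AUC matches an independent implementation", {
  set.seed(31)
  y <- stats::rbinom(100, 1, 0.3)
  s <- stats::runif(100)
  ours <- roc_and_auc(s, y)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("Youden threshold matches an exhaustive scan", {
  set.seed(29)
  for (i in 1:20) {
    y <- stats::rbinom(50, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- round(stats::runif(50), 2)
    yt <- youden_threshold(s, y)
    # brute force over a fine grid plus all observed scores
    cand <- sort(unique(c(s, seq(0, 1, by = 0.001))))
    js <- vapply(cand, function(t)
      mean(s[y == 1] >= t) + mean(s[y == 0] < t) - 1, numeric(1))
    expect_equal(yt$j, max(js), tolerance = 1e-12)
  }
  # perfect separation: J = 1 at the lowest achieving midpoint
  yt <- youden_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(yt$j, 1)
  expect_equal(yt$threshold, 0.5)
  expect_equal(yt$sensitivity, 1); expect_equal(yt$specificity, 1)
  # constant scores: no separation achievable
  expect_equal(youden_threshold(rep(0.4, 8), c(1, 1, 0, 0, 1, 0, 0, 1))$j, 0)
})

test_that("calibration bins conserve counts and detect calibrated scores", {
  cb <- calibration_bins(rep(0.5, 100), stats::rbinom(100, 1, 0.5), 10)
  expect_equal(sum(cb$count), 100)
  expect_equal(sum(cb$count > 0), 1)
  set.seed(41)
  s <- stats::runif(10000)
  y <- stats::rbinom(10000, 1, s)
  cb <- calibration_bins(s, y, 10)
  expect_equal(sum(cb$count), 10000)
  dev <- abs(cb$mean_predicted - cb$observed_rate)
  expect_lt(max(dev[cb$count > 0]), 0.05)
})

test_that("stratified splits preserve class balance within one patient", {
  gen <- generate_cohort(generator_config(101, 0.22, n_numeric = 2, seed = 3))
  y <- gen$cohort$outcome
  set.seed(1)
  for (i in 1:10) {
    test_idx <- t2select:::stratified_split(y, 0.3)
    for (cl in 0:1) {
      expect_lt(abs(sum(y[test_idx] == cl) - 0.3 * sum(y == cl)), 1)
    }
  }
})

test_that("a perfectly separable cohort is classified near-perfectly", {
  gen <- generate_cohort(generator_config(
    400, 0.4, n_numeric = 1,
    informative = data.frame(index = 1, effect = 5), seed = 44))
  cfg <- benchmark_config(models = c("logistic_regression", "lda"),
                          n_repeats = 2, seeds = c(11, 12))
  rep <- run_benchmark(gen$cohort,
                       list(feature_set_spec("ALL", schema_names(gen$schema))),
                       cfg, quiet = TRUE)
  expect_true(all(rep$summary$accuracy_mean >= 95))
  expect_true(all(rep$summary$auc > 0.99))
})

test_that("identical seeds and config give identical reports", {
  gen <- small_gen(seed = 50, n = 120)
  sets <- list(feature_set_spec("ALL", schema_names(gen$schema)),
               feature_set_spec("ONE", "num_01"))
  cfg <- benchmark_config(models = c("decision_tree", "gradient_boosting",
                                     "random_forest", "svm"),
                          n_repeats = 2, seeds = c(5, 6))
  r1 <- run_benchmark(gen$cohort, sets, cfg, quiet = TRUE)
  r2 <- run_benchmark(gen$cohort, sets, cfg, quiet = TRUE)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$raw, r2$raw)
  expect_identical(r1$scores, r2$scores)
})

test_that("no statistic of the held-out split enters the fitted pipeline", {
  gen <- small_gen(seed = 51, n = 100)
  tab <- gen$cohort
  train <- cohort_rows(tab, 1:70)
  test <- cohort_rows(tab, 71:100)
  set.seed(2)
  folds <- t2select:::stratified_folds(train$outcome, 3)
  tf1 <- t2select:::tune_and_fit("logistic_regression",
                                 data.frame(lambda = c(0.01, 0.1)),
                                 train, folds, seed = 7)
  # perturb the held-out rows wildly; refit on the same training rows
  test$values <- test$values + 1000
  set.seed(2)
  tf2 <- t2select:::tune_and_fit("logistic_regression",
                                 data.frame(lambda = c(0.01, 0.1)),
                                 train, folds, seed = 7)
  expect_identical(tf1$state, tf2$state)
  expect_equal(unname(tf1$state$center[1]), mean(train$values[, 1]))
  probe <- apply_preprocessor(tf1$state, cohort_rows(tab, 71:100))
  expect_identical(t2select:::predict_prob(tf1$fit, probe$values),
                   t2select:::predict_prob(tf2$fit, probe$values))
})

test_that("summary means and sds are recomputable from the raw table", {
  gen <- small_gen(seed = 52, n = 100)
  cfg <- benchmark_config(models = "decision_tree", n_repeats = 3,
                          seeds = c(1, 2, 3))
  rep <- run_benchmark(gen$cohort,
                       list(feature_set_spec("ALL", schema_names(gen$schema))),
                       cfg, quiet = TRUE)
  raw <- rep$raw
  expect_equal(rep$summary$f1_mean, mean(raw$f1))
  expect_equal(rep$summary$f1_sd, stats::sd(raw$f1))
  expect_equal(rep$summary$accuracy_mean, mean(raw$accuracy))
})

test_that("feature sets are validated against the schema", {
  gen <- small_gen(seed = 53, n = 60)
  expect_error(run_benchmark(gen$cohort,
                             list(feature_set_spec("BAD", "nope")),
                             benchmark_config(models = "lda", n_repeats = 2),
                             quiet = TRUE),
               "unknown feature")
  expect_error(feature_set_spec("EMPTY", character(0)))
})
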