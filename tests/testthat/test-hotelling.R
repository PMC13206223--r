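test_that("univariate T2 equals the squared pooled t statistic", {
  t2 <- hotelling_t2(matrix(c(1, 2, 3)), matrix(c(4, 5, 6)))
  expect_equal(as.numeric(t2), 13.5, tolerance = 1e-12)
  pv <- t2_pvalue(t2, 3, 3, 1)
  expect_equal(pv$f_stat, 13.5, tolerance = 1e-12)
  expect_equal(pv$df1, 1); expect_equal(pv$df2, 4)
  tt <- stats::t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(pv$p_value, tt$p.value, tolerance = 1e-12)
  expect_equal(round(pv$p_value, 4), 0.0213)
})

test_that("d = 1 equivalence with the pooled t-test holds over random draws", {
  set.seed(101)
  for (i in 1:100) {
    n0 <- sample(3:30, 1); n1 <- sample(3:30, 1)
    a <- stats::rnorm(n0, sd = stats::runif(1, 0.5, 2))
    b <- stats::rnorm(n1, mean = stats::runif(1, -1, 1))
    t2 <- as.numeric(hotelling_t2(matrix(a), matrix(b)))
    tt <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(t2, unname(tt$statistic)^2, tolerance = 1e-10)
    pv <- t2_pvalue(t2, n0, n1, 1)
    expect_equal(pv$p_value, tt$p.value, tolerance = 1e-10)
  }
})

test_that("T2 is invariant under invertible linear maps at ridge 0", {
  set.seed(7)
  A <- matrix(stats::rnorm(30), 10, 3)
  B <- matrix(stats::rnorm(36, mean = 0.5), 12, 3)
  base <- as.numeric(hotelling_t2(A, B))
  for (i in 1:20) {
    M <- matrix(stats::rnorm(9), 3, 3)
    while (abs(det(M)) < 1e-2) M <- matrix(stats::rnorm(9), 3, 3)
    mapped <- as.numeric(hotelling_t2(A %*% M, B %*% M))
    expect_equal(mapped, base, tolerance = 1e-8)
  }
})

test_that("T2 decreases monotonically in the ridge", {
  set.seed(8)
  A <- matrix(stats::rnorm(40), 10)
  B <- matrix(stats::rnorm(40, 1), 10)
  t2s <- vapply(c(0, 0.1, 1, 10), function(r)
    as.numeric(hotelling_t2(A, B, ridge = r)), numeric(1))
  expect_true(all(diff(t2s) < 0))
})

test_that("degenerate and singular inputs are handled", {
  A <- matrix(c(1, 2, 3))
  expect_equal(as.numeric(hotelling_t2(A, A)), 0)
  expect_equal(t2_pvalue(0, 5, 5, 2)$p_value, 1)
  expect_error(hotelling_t2(matrix(1), matrix(c(1, 2))), ">= 2 rows")
  expect_error(hotelling_t2(matrix(c(1, NA, 3)), matrix(c(1, 2, 3))),
               "non-finite")
  expect_error(t2_pvalue(5, 3, 3, 6), "permutation")
  # duplicated column makes the pooled covariance singular -> flagged pinv
  set.seed(1)
  x <- stats::rnorm(8)
  t2 <- hotelling_t2(cbind(x, x), cbind(x + 1, x + 1))
  expect_true(attr(t2, "pseudo_inverse"))
  expect_true(is.finite(as.numeric(t2)))
})

test_that("permutation p-value matches exhaustive enumeration on {1,2,3} vs {4,5,6}", {
  # only choose(6,3) = 20 distinct splits; 2 of them reach the observed T2
  p <- permutation_pvalue(matrix(c(1, 2, 3)), matrix(c(4, 5, 6)),
                          n_perm = 999, seed = 11)
  expect_lte(p, 0.11)
  expect_gte(p, 0.06)
  expect_gt(permutation_pvalue(matrix(1:4), matrix(1:4), n_perm = 99,
                               seed = 1), 1 / 100)
})

test_that("permutation and F p-values agree on a well-conditioned instance", {
  set.seed(33)
  A <- matrix(stats::rnorm(200), 100, 2)
  B <- matrix(stats::rnorm(200, 0.25), 100, 2)
  pf_ <- t2_pvalue(as.numeric(hotelling_t2(A, B)), 100, 100, 2)$p_value
  pp <- permutation_pvalue(A, B, n_perm = 999, seed = 2)
  expect_lt(abs(pf_ - pp), 0.05)
})

test_that("feature significance selects by p-value and orders by T2", {
  gen <- small_gen(seed = 4, n = 80, effect = 2.5)
  pre <- preprocessed(gen$cohort)
  sel <- init_selector(pre$schema, small_hp())
  rep0 <- feature_significance(sel, pre, alpha = 0)
  expect_length(rep0$selected, 0)
  rep <- feature_significance(sel, pre, alpha = 0.05)
  res <- rep$results
  expect_identical(res$significant, res$p_value < 0.05)
  expect_identical(rep$selected,
                   res$feature[order(-res$t2, res$feature)][
                     res$significant[order(-res$t2, res$feature)]])
  expect_true(all(res$t2 >= 0))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_identical(res$df1, rep(8L, nrow(res)))   # d_token dimensions
  # adjusted columns are reported and are never smaller than the raw p
  expect_true(all(res$p_bonferroni >= res$p_value - 1e-15))
  expect_true(all(res$p_bh >= res$p_value - 1e-15))
  # single-class outcome is rejected
  pre1 <- pre; pre1$outcome <- rep(0L, pre1$n)
  expect_error(feature_significance(sel, pre1, 0.05), "single class")
})

test_that("p-values are near-uniform on random-selector null representations", {
  # one independent replicate per seed: null cohort, fresh untrained selector,
  # first feature's p-value
  ps <- vapply(1:40, function(s) {
    gen <- generate_cohort(generator_config(
      120, 0.35, n_numeric = 8, seed = 5000 + s))
    pre <- preprocessed(gen$cohort)
    sel <- init_selector(pre$schema, small_hp(seed = s))
    feature_significance(sel, pre)$results$p_value[1]
  }, numeric(1))
  ks <- stats::ks.test(ps, "punif")
  expect_gt(ks$p.value, 0.01)
})
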