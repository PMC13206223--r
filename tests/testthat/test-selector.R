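test_that("hyperparameter invariants are enforced", {
  expect_error(selector_hyperparams(d_token = 30, n_heads = 8))
  expect_error(selector_hyperparams(lambda1 = -1))
  expect_error(selector_hyperparams(epochs = 0))
  hp <- selector_hyperparams()
  expect_equal(hp$d_token, 32L); expect_equal(hp$n_heads, 8L)
  expect_equal(hp$epochs, 3500L); expect_equal(hp$lr, 1e-4)
  expect_equal(hp$lambda1, 1e-5); expect_equal(hp$lambda2, 1e-5)
})

test_that("tokenization is the declared affine/embedding map", {
  gen <- small_gen(seed = 2)
  pre <- preprocessed(gen$cohort)
  sel <- init_selector(pre$schema, small_hp())
  tok <- tokenize(pre, sel)
  d <- sel$hp$d_token
  expect_identical(dim(tok), c(pre$n, ncol(pre$values) + 1L, d))
  # CLS token identical across samples
  expect_equal(max(abs(sweep(tok[, 1, ], 2, tok[1, 1, ]))), 0)
  expect_equal(tok[1, 1, ], sel$params$cls)
  # numeric token: x * w + b; zero input gives exactly b
  pre0 <- pre; pre0$values[1, 1] <- 0
  tok0 <- tokenize(pre0, sel)
  expect_equal(tok0[1, 2, ], sel$params$tok[[1]]$b)
  # linearity: token(x=2) - token(x=1) = w
  pre1 <- pre; pre1$values[1, 1] <- 1
  pre2 <- pre; pre2$values[1, 1] <- 2
  diffv <- tokenize(pre2, sel)[1, 2, ] - tokenize(pre1, sel)[1, 2, ]
  expect_equal(diffv, sel$params$tok[[1]]$w, tolerance = 1e-12)
  # categorical token is the category's embedding column
  j_cat <- which(schema_kinds(pre$schema) == "categorical")
  code <- pre$values[1, j_cat]
  expect_equal(tok[1, j_cat + 1, ],
               sel$params$tok[[j_cat]]$emb[, code + 1])
  # identical rows tokenize identically
  pre$values[2, ] <- pre$values[1, ]
  tok2 <- tokenize(pre, sel)
  expect_identical(tok2[1, , ], tok2[2, , ])
})

test_that("the encoder is permutation-equivariant over feature tokens", {
  gen <- small_gen(seed = 3)
  pre <- preprocessed(gen$cohort)
  sel <- init_selector(pre$schema, small_hp())
  tok <- tokenize(pre, sel)
  enc <- encode(tok, sel)
  p <- ncol(pre$values)
  set.seed(5)
  perm <- sample(p)
  tok_p <- tok[, c(1, perm + 1), ]
  enc_p <- encode(tok_p, sel)
  # un-permute the output and compare
  inv <- order(perm)
  expect_equal(enc_p[, c(1, inv + 1), ], enc, tolerance = 1e-5)
  # logits are invariant
  expect_equal(classification_logit(enc_p, sel),
               classification_logit(enc, sel), tolerance = 1e-8)
})

test_that("zeroed attention/feed-forward projections reduce to the identity", {
  gen <- small_gen(seed = 6)
  pre <- preprocessed(gen$cohort)
  sel <- init_selector(pre$schema, small_hp())
  sel <- with_params(sel, function(p) {
    p$layers[[1]]$Wo[] <- 0; p$layers[[1]]$bo[] <- 0
    p$layers[[1]]$W2[] <- 0; p$layers[[1]]$b2[] <- 0
    p
  })
  tok <- tokenize(pre, sel)
  expect_equal(encode(tok, sel), tok, tolerance = 1e-12)
})

test_that("every output token depends on every input token", {
  gen <- small_gen(seed = 12, n = 20)
  pre <- preprocessed(gen$cohort)
  sel <- init_selector(pre$schema, small_hp())
  tok <- tokenize(pre, sel)
  enc <- encode(tok, sel)
  # perturb one coordinate of one feature token of one sample: its CLS output
  # must move (a constant-vector shift would sit in LayerNorm's null space)
  tok2 <- tok
  tok2[3, 4, 2] <- tok2[3, 4, 2] + 0.1
  enc2 <- encode(tok2, sel)
  expect_gt(max(abs(enc2[3, 1, ] - enc[3, 1, ])), 1e-8)
  # other samples are untouched (attention is within-sample)
  expect_equal(enc2[1, , ], enc[1, , ], tolerance = 1e-12)
})

test_that("classification head is the declared affine map of CLS", {
  gen <- small_gen(seed = 7)
  pre <- preprocessed(gen$cohort)
  sel <- init_selector(pre$schema, small_hp())
  enc <- encode(tokenize(pre, sel), sel)
  enc0 <- enc; enc0[, 1, ] <- 0
  sel0 <- with_params(sel, function(p) { p$head$b <- 0; p })
  expect_equal(classification_logit(enc0, sel0), rep(0, pre$n))
  expect_equal(stats::plogis(0), 0.5)
  lg <- classification_logit(enc, sel)
  expect_equal(lg, as.vector(enc[, 1, ] %*% sel$params$head$w) +
                 sel$params$head$b)
})

test_that("statistical loss behaves as a separability objective", {
  gen <- small_gen(seed = 8, n = 40)
  pre <- preprocessed(gen$cohort)
  sel <- init_selector(pre$schema, small_hp())
  enc <- encode(tokenize(pre, sel), sel)
  y <- pre$outcome
  # identical representations for all samples: zero separation
  enc_same <- enc
  for (j in seq_len(dim(enc)[2])) enc_same[, j, ] <-
    matrix(enc[1, j, ], dim(enc)[1], dim(enc)[3], byrow = TRUE)
  expect_equal(statistical_loss(enc_same, y, ridge = 1e-2), 0,
               tolerance = 1e-12)
  # adding a constant vector to group-1 tokens of one feature increases
  # separation, so the loss strictly decreases
  base <- statistical_loss(enc, y, ridge = 1e-2)
  enc_shift <- enc
  enc_shift[y == 1, 2, ] <- enc_shift[y == 1, 2, ] + 1
  expect_lt(statistical_loss(enc_shift, y, ridge = 1e-2), base)
  # large-ridge closed form: T2 -> (n0 n1 / n) * ||delta||^2 / ridge
  big <- 1e8
  n0 <- sum(y == 0); n1 <- sum(y == 1)
  d2 <- vapply(seq_len(dim(enc)[2] - 1), function(j) {
    delta <- colMeans(enc[y == 1, j + 1, ]) - colMeans(enc[y == 0, j + 1, ])
    sum(delta^2)
  }, numeric(1))
  expected <- -mean((n0 * n1 / (n0 + n1)) * d2 / big)
  expect_equal(statistical_loss(enc, y, ridge = big), expected,
               tolerance = 1e-6)
  # a class with < 2 samples is rejected
  y_bad <- c(1L, rep(0L, length(y) - 1))
  expect_error(statistical_loss(enc, y_bad, 1e-2), ">= 2")
})

test_that("total loss reduces to cross-entropy when both lambdas vanish", {
  gen <- small_gen(seed = 9)
  pre <- preprocessed(gen$cohort)
  hp0 <- small_hp(lambda1 = 0, lambda2 = 0)
  sel <- init_selector(pre$schema, hp0)
  tok <- tokenize(pre, sel)
  enc <- encode(tok, sel)
  lg <- classification_logit(enc, sel)
  y <- pre$outcome
  bce <- -mean(y * log(stats::plogis(lg)) + (1 - y) * log(1 - stats::plogis(lg)))
  expect_equal(total_loss(lg, y, enc, hp0, tok), bce, tolerance = 1e-10)
  # the compiled objective agrees with the R-side composition
  res <- selector_objective(sel, pre, want_encoded = TRUE)
  expect_equal(res$l_cls, bce, tolerance = 1e-10)
  hp <- small_hp()
  sel2 <- init_selector(pre$schema, hp)
  res2 <- selector_objective(sel2, pre, want_encoded = TRUE)
  tok2 <- tokenize(pre, sel2)
  lg2 <- classification_logit(res2$encoded, sel2)
  expect_equal(res2$loss, total_loss(lg2, y, res2$encoded, hp, tok2),
               tolerance = 1e-8)
})

test_that("analytic gradients match central finite differences", {
  gen <- small_gen(seed = 10, n = 30, p_num = 3)
  pre <- preprocessed(gen$cohort)
  sel <- init_selector(pre$schema, small_hp(d_token = 8, n_heads = 2))
  res <- selector_objective(sel, pre, want_grad = TRUE)
  flat <- sel$flat
  set.seed(77)
  idx <- sample(length(flat), 80)
  h <- 1e-5
  for (k in idx) {
    f1 <- flat; f1[k] <- f1[k] + h
    f2 <- flat; f2[k] <- f2[k] - h
    fd <- (selector_objective(sel, pre, flat = f1)$loss -
             selector_objective(sel, pre, flat = f2)$loss) / (2 * h)
    if (abs(fd) > 1e-7)
      expect_lt(abs(res$grad[k] - fd) / abs(fd), 1e-4)
  }
})

test_that("training reduces the classification loss and is reproducible", {
  gen <- generate_cohort(generator_config(
    200, 0.5, n_numeric = 2,
    informative = data.frame(index = 1, effect = 3), seed = 21))
  hp <- small_hp(epochs = 80, lr = 3e-3, seed = 9)
  fit1 <- train_selector(gen$cohort, hp)
  expect_equal(nrow(fit1$log), 80)
  expect_lt(fit1$log$l_cls[80], fit1$log$l_cls[1])
  fit2 <- train_selector(gen$cohort, hp)
  expect_identical(fit1$log, fit2$log)
  expect_identical(fit1$flat, fit2$flat)
  # a trained selector separates the planted feature
  pre <- apply_preprocessor(fit1$preprocessor, gen$cohort)
  rep <- feature_significance(fit1, pre)
  expect_equal(rep$results$feature[which.max(rep$results$t2)], "num_01")
})

test_that("permuting feature tokens permutes T2 values but not their multiset", {
  gen <- small_gen(seed = 13, n = 50)
  pre <- preprocessed(gen$cohort)
  p <- ncol(pre$values)
  ord <- rev(seq_len(p))
  sel <- init_selector(pre$schema, small_hp(seed = 2))
  tok <- tokenize(pre, sel)
  enc <- encode(tok, sel)
  tok_p <- tok[, c(1, ord + 1), ]
  enc_p <- encode(tok_p, sel)
  t2 <- vapply(seq_len(p), function(j)
    as.numeric(hotelling_t2(enc[pre$outcome == 0, j + 1, ],
                            enc[pre$outcome == 1, j + 1, ])), numeric(1))
  t2_p <- vapply(seq_len(p), function(j)
    as.numeric(hotelling_t2(enc_p[pre$outcome == 0, j + 1, ],
                            enc_p[pre$outcome == 1, j + 1, ])), numeric(1))
  expect_equal(sort(t2), sort(t2_p), tolerance = 1e-5)
})

test_that("training on a null cohort does not fabricate separation", {
  # bound frozen from a pre-registered oracle run of the same configuration
  ratios <- vapply(1:5, function(s) {
    gen <- generate_cohort(generator_config(
      100, 0.3, n_numeric = 6, seed = 300 + s))
    pre <- preprocessed(gen$cohort)
    hp <- small_hp(epochs = 60, lr = 1e-3, lambda1 = 1e-5, seed = s)
    sel0 <- init_selector(pre$schema, hp)
    t2_pre <- mean(selector_objective(sel0, pre)$t2)
    fit <- train_selector(pre, hp)
    t2_post <- mean(selector_objective(fit, pre)$t2)
    t2_post / t2_pre
  }, numeric(1))
  expect_lt(mean(ratios), 3)
})

test_that("the sweep utility reports one row per grid setting", {
  gen <- small_gen(seed = 30, n = 40)
  grid <- data.frame(lr = c(1e-3, 1e-2))
  out <- sweep_selector(gen$cohort, grid,
                        base = small_hp(epochs = 5), alpha = 0.05)
  expect_equal(nrow(out), 2)
  expect_true(all(is.finite(out$total)))
  expect_true(all(out$n_selected >= 0))
})
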