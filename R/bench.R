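#' Feature set specification
#'
#' @param name Label of the set (conventionally `"ALL"`, `"DK"`, `"OURS"`, or
#'   a custom name).
#' @param features Non-empty character vector of feature names.
#' @return A `feature_set_spec`.
#' @export
feature_set_spec <- function(name, features) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(features), length(features) >= 1L)
  structure(list(name = name, features = unique(features)),
            class = "feature_set_spec")
}

#' Default tuning grids for the classifier zoo
#'
#' Small fixed grids per model; grids are configuration, not code, and can be
#' replaced wholesale in [benchmark_config()].
#' @return Named list of data frames.
#' @export
default_tuning_grids <- function() {
  list(
    logistic_regression = data.frame(lambda = c(0.001, 0.01, 0.1, 1)),
    decision_tree = data.frame(maxdepth = c(2, 3, 5)),
    random_forest = data.frame(mtry_frac = c(0.3, 0.6, 1.0)),
    svm = data.frame(cost = c(0.01, 0.1, 1, 10)),
    lda = data.frame(.none = NA),
    qda = data.frame(.none = NA),
    gradient_boosting = data.frame(nrounds = c(50, 100, 200)))
}

#' Benchmark configuration
#'
#' Repeated stratified 70/30 holdout (five fixed seeds by default) with
#' hyperparameters tuned by an inner 5-fold cross-validation on the training
#' split; the inner selection metric is the F1-score of the positive class,
#' chosen because accuracy degenerates to majority prediction at ~21%
#' prevalence.
#'
#' @param models Character subset of `logistic_regression, decision_tree,
#'   random_forest, svm, lda, qda, gradient_boosting`.
#' @param n_repeats Number of outer holdout repeats.
#' @param test_fraction Test proportion in (0,1).
#' @param inner_folds Inner CV folds.
#' @param seeds Distinct integer seeds, length `n_repeats`.
#' @param grids Named list of tuning grids (see [default_tuning_grids()]).
#' @return A `benchmark_config`.
#' @export
benchmark_config <- function(models = c("logistic_regression", "decision_tree",
                                        "random_forest", "svm", "lda", "qda",
                                        "gradient_boosting"),
                             n_repeats = 5L, test_fraction = 0.3,
                             inner_folds = 5L, seeds = NULL,
                             grids = default_tuning_grids()) {
  models <- match.arg(models, several.ok = TRUE)
  if (is.null(seeds)) seeds <- seq_len(n_repeats)
  stopifnot(test_fraction > 0, test_fraction < 1,
            length(seeds) == n_repeats, !anyDuplicated(seeds),
            inner_folds >= 2L)
  for (m in models)
    if (is.null(grids[[m]]) || nrow(grids[[m]]) < 1L)
      stop("config error: empty tuning grid for model '", m, "'", call. = FALSE)
  structure(list(models = models, n_repeats = as.integer(n_repeats),
                 test_fraction = test_fraction,
                 inner_folds = as.integer(inner_folds),
                 seeds = as.integer(seeds), grids = grids),
            class = "benchmark_config")
}

#' Binary classification metrics (percent scale)
#'
#' Positive class is outcome 1. When no positive predictions exist, precision
#' is reported as 0 and flagged via the `"precision_undefined"` attribute.
#'
#' @param predicted 0/1 predictions.
#' @param actual 0/1 truths of equal length.
#' @return Named numeric vector `accuracy, recall, precision, f1` on the
#'   0-100 scale.
#' @export
binary_metrics <- function(predicted, actual) {
  if (length(predicted) != length(actual))
    stop("length mismatch", call. = FALSE)
  predicted <- as.integer(predicted); actual <- as.integer(actual)
  tp <- sum(predicted == 1L & actual == 1L)
  fp <- sum(predicted == 1L & actual == 0L)
  fn <- sum(predicted == 0L & actual == 1L)
  tn <- sum(predicted == 0L & actual == 0L)
  acc <- (tp + tn) / length(actual)
  rec <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  prec_undef <- (tp + fp == 0L)
  prec <- if (prec_undef) 0 else tp / (tp + fp)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  structure(100 * c(accuracy = acc, recall = rec, precision = prec, f1 = f1),
            precision_undefined = prec_undef)
}

#' Empirical ROC curve and trapezoidal AUC
#'
#' The AUC of the empirical step ROC equals the normalized Mann-Whitney
#' concordance count (ties counting 0.5).
#'
#' @param scores Numeric scores (higher = more positive).
#' @param actual 0/1 truths; both classes must be present.
#' @return List with `roc` (data frame `threshold, fpr, tpr`) and `auc`.
#' @export
roc_and_auc <- function(scores, actual) {
  actual <- as.integer(actual)
  if (length(unique(actual)) < 2L)
    stop("both classes must be present for a ROC curve", call. = FALSE)
  th <- sort(unique(scores), decreasing = TRUE)
  pos <- scores[actual == 1L]; neg <- scores[actual == 0L]
  tpr <- vapply(th, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(neg >= t), numeric(1))
  roc <- data.frame(threshold = c(Inf, th), fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' Youden-optimal decision threshold
#'
#' Maximizes `J = sensitivity + specificity - 1` over the midpoints of the
#' sorted unique scores (rule: positive iff `score >= threshold`); ties are
#' broken toward the lowest threshold.
#'
#' @inheritParams roc_and_auc
#' @return List with `threshold`, `j`, `sensitivity`, `specificity`,
#'   `accuracy` (the last three on the 0-1 scale).
#' @export
youden_threshold <- function(scores, actual) {
  actual <- as.integer(actual)
  u <- sort(unique(scores))
  cand <- if (length(u) >= 2L) (u[-1] + u[-length(u)]) / 2 else u
  best <- NULL
  for (t in cand) {
    sens <- mean(scores[actual == 1L] >= t)
    spec <- mean(scores[actual == 0L] < t)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12) {
      best <- list(threshold = t, j = j, sensitivity = sens,
                   specificity = spec,
                   accuracy = mean((scores >= t) == (actual == 1L)))
    }
  }
  best
}

#' Calibration bins
#'
#' Equal-width bins on `[0, 1]`; empty bins are reported with count 0.
#'
#' @inheritParams roc_and_auc
#' @param n_bins Number of bins (>= 2).
#' @return Data frame `bin, lower, upper, mean_predicted, observed_rate,
#'   count` (rates `NA` for empty bins).
#' @export
calibration_bins <- function(scores, actual, n_bins = 10L) {
  stopifnot(n_bins >= 2L)
  actual <- as.integer(actual)
  br <- seq(0, 1, length.out = n_bins + 1L)
  idx <- pmin(pmax(findInterval(scores, br, rightmost.closed = TRUE), 1L), n_bins)
  out <- data.frame(bin = seq_len(n_bins), lower = br[-length(br)], upper = br[-1],
                    mean_predicted = NA_real_, observed_rate = NA_real_,
                    count = 0L)
  for (b in seq_len(n_bins)) {
    sel <- idx == b
    out$count[b] <- sum(sel)
    if (any(sel)) {
      out$mean_predicted[b] <- mean(scores[sel])
      out$observed_rate[b] <- mean(actual[sel])
    }
  }
  out
}

# ---- model zoo -------------------------------------------------------------

fallback_model <- function(y, note) {
  structure(list(p = mean(y == 1L), note = note), class = "t2s_fallback")
}

fit_one_model <- function(model, par, X, y, seed) {
  yf <- factor(y, levels = c(0L, 1L))
  tryCatch(switch(model,
    logistic_regression = {
      if (ncol(X) >= 2L) {
        list(kind = "glmnet",
             fit = glmnet::glmnet(X, yf, family = "binomial", alpha = 0,
                                  lambda = par$lambda))
      } else {
        df <- data.frame(y = y, X)
        list(kind = "glm",
             fit = suppressWarnings(stats::glm(y ~ ., data = df,
                                               family = stats::binomial())))
      }
    },
    decision_tree = {
      df <- data.frame(y = yf, X)
      list(kind = "rpart",
           fit = rpart::rpart(y ~ ., data = df, method = "class",
                              control = rpart::rpart.control(
                                maxdepth = par$maxdepth, cp = 0.001)))
    },
    random_forest = {
      df <- data.frame(y = yf, X)
      list(kind = "ranger",
           fit = ranger::ranger(y ~ ., data = df, probability = TRUE,
                                num.trees = 300,
                                mtry = max(1L, floor(par$mtry_frac * ncol(X))),
                                seed = seed, num.threads = 1L))
    },
    svm = {
      list(kind = "svm",
           fit = e1071::svm(X, yf, kernel = "radial", cost = par$cost,
                            scale = FALSE))
    },
    lda = list(kind = "lda", fit = MASS::lda(X, grouping = yf)),
    qda = list(kind = "qda", fit = MASS::qda(X, grouping = yf)),
    gradient_boosting = {
      dtr <- xgboost::xgb.DMatrix(X, label = y)
      list(kind = "xgb",
           fit = xgboost::xgb.train(params = list(objective = "binary:logistic",
                                                  max_depth = 3, eta = 0.1,
                                                  nthread = 1),
                                    data = dtr, nrounds = par$nrounds,
                                    verbose = 0))
    },
    stop("unknown model '", model, "'", call. = FALSE)),
    error = function(e) list(kind = "fallback",
                             fit = fallback_model(y, conditionMessage(e))))
}

predict_prob <- function(obj, X) {
  switch(obj$kind,
    glmnet = as.vector(stats::predict(obj$fit, X, type = "response")),
    glm = as.vector(stats::predict(obj$fit, newdata = data.frame(X),
                                   type = "response")),
    rpart = stats::predict(obj$fit, newdata = data.frame(X), type = "prob")[, "1"],
    ranger = stats::predict(obj$fit, data = data.frame(X),
                            num.threads = 1L)$predictions[, "1"],
    svm = {
      dv <- attr(stats::predict(obj$fit, X, decision.values = TRUE),
                 "decision.values")
      # orient the margin toward class "1", map to (0,1) monotonically
      sgn <- if (grepl("^0/1", colnames(dv)[1])) -1 else 1
      stats::plogis(sgn * as.vector(dv))
    },
    lda = stats::predict(obj$fit, X)$posterior[, "1"],
    qda = stats::predict(obj$fit, X)$posterior[, "1"],
    xgb = stats::predict(obj$fit, xgboost::xgb.DMatrix(X)),
    fallback = rep(obj$fit$p, nrow(X)),
    stop("unknown fitted kind"))
}

stratified_split <- function(y, test_fraction) {
  test <- integer(0)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    n_test <- max(1L, round(length(idx) * test_fraction))
    test <- c(test, sample(idx, n_test))
  }
  sort(test)
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# inner-CV grid search for one model on the (raw) training cohort
tune_and_fit <- function(model, grid, train_tab, folds, seed) {
  best_f1 <- -Inf; best_row <- 1L
  if (nrow(grid) > 1L) {
    for (r in seq_len(nrow(grid))) {
      f1s <- numeric(max(folds))
      for (f in seq_len(max(folds))) {
        tr <- cohort_rows(train_tab, which(folds != f))
        va <- cohort_rows(train_tab, which(folds == f))
        st <- fit_preprocessor(tr)
        trp <- apply_preprocessor(st, tr); vap <- apply_preprocessor(st, va)
        fit <- fit_one_model(model, grid[r, , drop = FALSE], trp$values,
                             trp$outcome, seed + 7L * f + 131L * r)
        pr <- predict_prob(fit, vap$values)
        f1s[f] <- binary_metrics(as.integer(pr >= 0.5), vap$outcome)[["f1"]]
      }
      if (mean(f1s) > best_f1 + 1e-12) { best_f1 <- mean(f1s); best_row <- r }
    }
  }
  st <- fit_preprocessor(train_tab)
  trp <- apply_preprocessor(st, train_tab)
  list(state = st,
       fit = fit_one_model(model, grid[best_row, , drop = FALSE],
                           trp$values, trp$outcome, seed),
       best_row = best_row)
}

#' Run the feature-set x classifier benchmark
#'
#' For each outer seed: stratified 70/30 split of the raw cohort; per feature
#' set and model, preprocessing fitted on the training split only, tuning by
#' inner stratified k-fold CV (selection metric: positive-class F1 at the 0.5
#' threshold), refit on the full training split, evaluation on the held-out
#' test split. Metrics are aggregated as mean and sd over repeats; test
#' scores are pooled across repeats for ROC/AUC, Youden-threshold and
#' calibration analysis.
#'
#' @param cohort A raw (unstandardized) `cohort_table`.
#' @param feature_sets List of [feature_set_spec()] objects.
#' @param config A [benchmark_config()].
#' @param quiet Suppress progress messages.
#' @return A `benchmark_report`: `summary` (per model x set mean/sd metrics,
#'   pooled AUC, Youden threshold row), `raw` (per-seed metrics), `scores`
#'   (pooled test scores), `config`.
#' @export
run_benchmark <- function(cohort, feature_sets, config = benchmark_config(),
                          quiet = FALSE) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (length(unique(cohort$outcome)) < 2L)
    stop("both classes must be present", call. = FALSE)
  all_names <- schema_names(cohort$schema)
  for (fs in feature_sets) {
    bad <- setdiff(fs$features, all_names)
    if (length(bad) > 0L)
      stop("feature set '", fs$name, "' references unknown feature(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  raw <- list()
  scores <- list()
  for (s_i in seq_along(config$seeds)) {
    s <- config$seeds[s_i]
    nb_with_seed(s, {
      test_idx <- stratified_split(cohort$outcome, config$test_fraction)
      train_tab_full <- cohort_rows(cohort, setdiff(seq_len(cohort$n), test_idx))
      test_tab_full <- cohort_rows(cohort, test_idx)
      folds <- stratified_folds(train_tab_full$outcome, config$inner_folds)
      for (fs in feature_sets) {
        train_tab <- cohort_features(train_tab_full, fs$features)
        test_tab <- cohort_features(test_tab_full, fs$features)
        for (model in config$models) {
          tf <- tune_and_fit(model, config$grids[[model]], train_tab, folds,
                             seed = s * 1009L)
          test_p <- apply_preprocessor(tf$state, test_tab)
          pr <- predict_prob(tf$fit, test_p$values)
          met <- binary_metrics(as.integer(pr >= 0.5), test_p$outcome)
          raw[[length(raw) + 1L]] <- data.frame(
            seed = s, model = model, feature_set = fs$name,
            accuracy = met[["accuracy"]], recall = met[["recall"]],
            precision = met[["precision"]], f1 = met[["f1"]],
            fallback = identical(tf$fit$kind, "fallback"))
          key <- paste(model, fs$name, sep = "|")
          scores[[key]] <- rbind(scores[[key]], data.frame(
            seed = s, score = as.numeric(pr), actual = test_p$outcome))
        }
      }
    })
    if (!quiet) message("[benchmark] finished repeat ", s_i, "/",
                        length(config$seeds))
  }
  raw <- do.call(rbind, raw)
  summ <- do.call(rbind, lapply(split(raw, list(raw$model, raw$feature_set),
                                      drop = TRUE), function(d) {
    sc <- scores[[paste(d$model[1], d$feature_set[1], sep = "|")]]
    ra <- roc_and_auc(sc$score, sc$actual)
    yt <- youden_threshold(sc$score, sc$actual)
    data.frame(model = d$model[1], feature_set = d$feature_set[1],
               accuracy_mean = mean(d$accuracy), accuracy_sd = stats::sd(d$accuracy),
               recall_mean = mean(d$recall), recall_sd = stats::sd(d$recall),
               precision_mean = mean(d$precision), precision_sd = stats::sd(d$precision),
               f1_mean = mean(d$f1), f1_sd = stats::sd(d$f1),
               auc = ra$auc, youden_threshold = yt$threshold,
               youden_sensitivity = yt$sensitivity,
               youden_specificity = yt$specificity,
               youden_accuracy = yt$accuracy)
  }))
  rownames(summ) <- NULL
  structure(list(summary = summ, raw = raw, scores = scores, config = config),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("benchmark_report:", length(unique(x$raw$model)), "models x",
      length(unique(x$raw$feature_set)), "feature sets x",
      length(unique(x$raw$seed)), "repeats\n")
  print(x$summary[, c("model", "feature_set", "accuracy_mean", "recall_mean",
                      "precision_mean", "f1_mean", "auc")], digits = 4)
  invisible(x)
}
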