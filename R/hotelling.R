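#' Two-sample Hotelling's T-squared statistic
#'
#' Computes `T2 = (n0*n1/(n0+n1)) * t(delta) %*% solve(Sp + ridge*I) %*% delta`
#' where `delta` is the difference of group mean vectors and `Sp` the pooled
#' sample covariance (denominator `n0 + n1 - 2`). With `ridge = 0` and a
#' singular pooled covariance the Moore-Penrose pseudo-inverse is used
#' (singular values below `1e-10` times the largest are dropped) and the
#' result is flagged via the `"pseudo_inverse"` attribute.
#'
#' @param group_a,group_b Numeric matrices (`n0 x d`, `n1 x d`) of the two
#'   groups' observations; vectors are treated as single-column matrices.
#' @param ridge Non-negative ridge added to the pooled covariance diagonal.
#' @return The T-squared value (scalar, >= 0 up to rounding), with attribute
#'   `pseudo_inverse` (logical).
#' @export
hotelling_t2 <- function(group_a, group_b, ridge = 0) {
  A <- as.matrix(group_a); B <- as.matrix(group_b)
  if (ncol(A) != ncol(B)) stop("groups must share dimension", call. = FALSE)
  n0 <- nrow(A); n1 <- nrow(B); d <- ncol(A)
  if (n0 < 2L || n1 < 2L)
    stop("each group needs >= 2 rows (covariance undefined)", call. = FALSE)
  if (anyNA(A) || anyNA(B) || any(!is.finite(A)) || any(!is.finite(B)))
    stop("non-finite input", call. = FALSE)
  if (ridge < 0) stop("ridge must be >= 0", call. = FALSE)
  delta <- colMeans(B) - colMeans(A)
  Sp <- ((n0 - 1) * stats::cov(A) + (n1 - 1) * stats::cov(B)) / (n0 + n1 - 2)
  M <- Sp + diag(ridge, d)
  used_pinv <- FALSE
  sol <- tryCatch(solve(M, delta), error = function(e) NULL)
  if (is.null(sol) || (ridge == 0 && rcond_sym(M) < 1e-12)) {
    sol <- pinv_solve(M, delta)
    used_pinv <- TRUE
  }
  t2 <- (n0 * n1 / (n0 + n1)) * sum(delta * sol)
  structure(max(t2, 0), pseudo_inverse = used_pinv)
}

rcond_sym <- function(M) {
  ev <- tryCatch(eigen(M, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) c(1, 0))
  if (max(abs(ev)) == 0) return(0)
  min(abs(ev)) / max(abs(ev))
}

pinv_solve <- function(M, b, tol = 1e-10) {
  s <- svd(M)
  keep <- s$d > tol * max(s$d)
  if (!any(keep)) return(rep(0, length(b)))
  s$v[, keep, drop = FALSE] %*%
    ((t(s$u[, keep, drop = FALSE]) %*% b) / s$d[keep])
}

#' F-transform and p-value for a Hotelling T-squared statistic
#'
#' `F = ((n0+n1-d-1) / (d*(n0+n1-2))) * T2` follows an F distribution with
#' `(d, n0+n1-d-1)` degrees of freedom under the two-sample null with
#' multivariate normal data; the p-value is its upper tail. For `d = 1` this
#' reproduces the pooled two-sample t-test exactly.
#'
#' @param t2 The statistic from [hotelling_t2()].
#' @param n0,n1 Group sizes.
#' @param d Dimension the statistic was computed in.
#' @return List with `f_stat`, `df1`, `df2`, `p_value`.
#' @export
t2_pvalue <- function(t2, n0, n1, d) {
  df2 <- n0 + n1 - d - 1
  if (df2 < 1)
    stop("invalid degrees of freedom (n0+n1-d-1 = ", df2,
         " < 1); use permutation_pvalue() instead", call. = FALSE)
  f_stat <- (df2 / (d * (n0 + n1 - 2))) * as.numeric(t2)
  list(f_stat = f_stat, df1 = d, df2 = df2,
       p_value = stats::pf(f_stat, d, df2, lower.tail = FALSE))
}

#' Permutation p-value for the two-sample T-squared
#'
#' Randomly permutes group labels `n_perm` times and reports
#' `p = (1 + #\{T2_perm >= T2_obs\}) / (n_perm + 1)`.
#'
#' @inheritParams hotelling_t2
#' @param n_perm Number of label permutations (>= 99).
#' @param seed Integer seed for the permutation stream.
#' @return Permutation p-value in `(0, 1]`.
#' @export
permutation_pvalue <- function(group_a, group_b, ridge = 0,
                               n_perm = 999L, seed = 1L) {
  if (n_perm < 99L) stop("n_perm must be >= 99", call. = FALSE)
  A <- as.matrix(group_a); B <- as.matrix(group_b)
  obs <- as.numeric(hotelling_t2(A, B, ridge))
  X <- rbind(A, B)
  n0 <- nrow(A); n <- nrow(X)
  nb_with_seed(seed, {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      idx <- sample.int(n, n0)
      t2p <- as.numeric(hotelling_t2(X[idx, , drop = FALSE],
                                     X[-idx, , drop = FALSE], ridge))
      if (t2p >= obs - 1e-12) hits <- hits + 1L
    }
    (1 + hits) / (n_perm + 1)
  })
}

#' Per-feature significance testing on learned representations
#'
#' Encodes the cohort with a trained (or freshly initialized) selector, splits
#' each feature's encoded `d_token`-dimensional token vectors by outcome
#' group, computes the exact Hotelling T-squared with its F-transform p-value
#' per feature, and marks features significant at `alpha` (no multiplicity
#' correction in the headline selection; Bonferroni and Benjamini-Hochberg
#' adjusted p-values are reported alongside). The significant set ordered by
#' descending T-squared (name as tie-break) is the "OURS" feature set.
#'
#' @param selector A `trained_selector` from [train_selector()] (or
#'   [init_selector()] for a random-initialization null analysis).
#' @param cohort A preprocessed `cohort_table` compatible with the selector's
#'   schema.
#' @param alpha Per-feature significance level (default 0.05).
#' @param ridge Ridge for the post-hoc statistic (default 0: exact test with
#'   pseudo-inverse fallback).
#' @return A `selection_report`: data frame `results` (feature, t2, f_stat,
#'   df1, df2, p_value, p_bonferroni, p_bh, significant, pseudo_inverse) plus
#'   `selected` (ordered character vector) and `alpha`.
#' @export
feature_significance <- function(selector, cohort, alpha = 0.05, ridge = 0) {
  stopifnot(inherits(selector, "trained_selector"),
            inherits(cohort, "cohort_table"))
  y <- cohort$outcome
  if (length(unique(y)) < 2L)
    stop("outcome has a single class; the two-sample test is undefined",
         call. = FALSE)
  enc <- encode(tokenize(cohort, selector), selector)
  nms <- schema_names(cohort$schema)
  p <- length(nms)
  res <- data.frame(feature = nms, t2 = NA_real_, f_stat = NA_real_,
                    df1 = NA_integer_, df2 = NA_integer_, p_value = NA_real_,
                    pseudo_inverse = FALSE, stringsAsFactors = FALSE)
  for (j in seq_len(p)) {
    Ej <- enc[, j + 1L, ]                       # token j+1: feature j (1 = CLS)
    t2 <- hotelling_t2(Ej[y == 0L, , drop = FALSE],
                       Ej[y == 1L, , drop = FALSE], ridge = ridge)
    pv <- t2_pvalue(as.numeric(t2), sum(y == 0L), sum(y == 1L), dim(enc)[3])
    res$t2[j] <- as.numeric(t2)
    res$f_stat[j] <- pv$f_stat
    res$df1[j] <- pv$df1; res$df2[j] <- pv$df2
    res$p_value[j] <- pv$p_value
    res$pseudo_inverse[j] <- isTRUE(attr(t2, "pseudo_inverse"))
  }
  res$p_bonferroni <- stats::p.adjust(res$p_value, "bonferroni")
  res$p_bh <- stats::p.adjust(res$p_value, "BH")
  res$significant <- res$p_value < alpha
  ord <- order(-res$t2, res$feature)
  selected <- res$feature[ord][res$significant[ord]]
  structure(list(alpha = alpha, results = res, selected = selected),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("selection_report: ", length(x$selected), "of", nrow(x$results),
      "features significant at alpha =", x$alpha, "\n")
  if (length(x$selected) > 0L)
    cat("  selected:", paste(utils::head(x$selected, 10), collapse = ", "),
        if (length(x$selected) > 10) "..." else "", "\n")
  invisible(x)
}

#' Write a selection report to disk
#'
#' @param report A `selection_report`.
#' @param csv_path Path for the full per-feature CSV.
#' @param list_path Optional path for a plain-text list of the selected
#'   ("OURS") feature names, one per line.
#' @return `csv_path`, invisibly.
#' @export
write_selection_report <- function(report, csv_path, list_path = NULL) {
  utils::write.csv(report$results, csv_path, row.names = FALSE)
  if (!is.null(list_path))
    writeLines(report$selected, list_path)
  invisible(csv_path)
}
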