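#' Compare a selected feature set against an established set
#'
#' Scores a selection against the clinically established (domain-knowledge)
#' feature list as if the latter were ground truth, over a fixed universe of
#' candidate features: `tp` = selected and established, `fp` = selected only,
#' `fn` = established only, `tn` = neither.
#'
#' @param selected Character vector of selected feature names.
#' @param established Character vector of established feature names.
#' @param universe Character vector of all candidate feature names.
#' @return An `agreement_matrix` with fields `tp, fp, fn, tn`.
#' @export
compare_selection <- function(selected, established, universe) {
  universe <- unique(as.character(universe))
  selected <- unique(as.character(selected))
  established <- unique(as.character(established))
  stray <- setdiff(selected, universe)
  if (length(stray) > 0L)
    stop("selected feature(s) outside the universe: ",
         paste(stray, collapse = ", "), call. = FALSE)
  stray <- setdiff(established, universe)
  if (length(stray) > 0L)
    stop("established feature(s) outside the universe: ",
         paste(stray, collapse = ", "), call. = FALSE)
  tp <- length(intersect(selected, established))
  fp <- length(setdiff(selected, established))
  fn <- length(setdiff(established, selected))
  tn <- length(universe) - tp - fp - fn
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn), class = "agreement_matrix")
}

#' @export
print.agreement_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2,
              dimnames = list(established = c("yes", "no"),
                              selected = c("yes", "no")))
  print(m)
  invisible(x)
}

#' Agreement metrics of a selection-vs-established confusion matrix
#'
#' Standard binary metrics over the agreement counts, on the percent scale.
#' When nothing is selected, precision is reported as 0 and flagged.
#'
#' @param m An `agreement_matrix` from [compare_selection()] (or a list with
#'   fields `tp, fp, fn, tn`).
#' @return Named numeric vector `accuracy, precision, recall, f1` in percent.
#' @export
agreement_metrics <- function(m) {
  n <- m$tp + m$fp + m$fn + m$tn
  stopifnot(n > 0)
  acc <- (m$tp + m$tn) / n
  rec <- if (m$tp + m$fn == 0) 0 else m$tp / (m$tp + m$fn)
  prec_undef <- (m$tp + m$fp == 0)
  prec <- if (prec_undef) 0 else m$tp / (m$tp + m$fp)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  structure(100 * c(accuracy = acc, precision = prec, recall = rec, f1 = f1),
            precision_undefined = prec_undef)
}

#' Per-feature logistic-regression selection baseline
#'
#' Fits a single all-features main-effects logistic model by maximum
#' likelihood and returns the features whose Wald p-value falls below
#' `alpha`. With many candidate features relative to the cohort size the fit
#' is frequently unstable or non-convergent; the result is then flagged
#' (attribute `flagged`) with a diagnostic, which is the mechanism by which
#' this traditional baseline tends to select nothing on wide clinical
#' cohorts.
#'
#' @param cohort A `cohort_table` (raw; standardized internally).
#' @param alpha Significance level.
#' @return Character vector of selected feature names, with attributes
#'   `flagged` (logical) and `diagnostic`.
#' @export
baseline_logistic_selection <- function(cohort, alpha = 0.05) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (length(unique(cohort$outcome)) < 2L)
    stop("both classes must be present", call. = FALSE)
  tab <- if (cohort$standardized) cohort
         else apply_preprocessor(fit_preprocessor(cohort), cohort)
  df <- data.frame(y = tab$outcome, tab$values, check.names = FALSE)
  flagged <- FALSE; diag_msg <- ""
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      flagged <<- TRUE
      diag_msg <<- paste(diag_msg, conditionMessage(w), sep = "; ")
      invokeRestart("muffleWarning")
    })
  if (!fit$converged) {
    flagged <- TRUE
    diag_msg <- paste(diag_msg, "IRLS did not converge", sep = "; ")
  }
  co <- summary(fit)$coefficients
  co <- co[rownames(co) != "(Intercept)", , drop = FALSE]
  pv <- co[, "Pr(>|z|)"]
  # aliased (dropped) coefficients never reach the table; they are unselected
  sel <- gsub("^`|`$", "", rownames(co)[is.finite(pv) & pv < alpha])
  if (cohort$n <= ncol(tab$values)) {
    flagged <- TRUE
    diag_msg <- paste(diag_msg, "p >= n: unpenalized fit unreliable", sep = "; ")
  }
  structure(sel, flagged = flagged, diagnostic = sub("^; ", "", diag_msg))
}
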