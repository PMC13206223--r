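#' Construct a cohort table
#'
#' A cohort table is the package's container for a preprocessable patient-by-
#' feature matrix: `n x p` numeric values (categorical features carried as
#' integer codes `0..K-1` in schema category order), a 0/1 outcome vector, and
#' the schema that defines column order and kinds.
#'
#' @param values Numeric matrix, one row per patient, columns in schema order.
#' @param outcome Integer/numeric vector of 0/1 outcomes, length `nrow(values)`.
#' @param schema A [feature_schema()].
#' @param standardized Internal flag: have numeric columns been z-scored?
#' @return A `cohort_table` object.
#' @export
cohort_table <- function(values, outcome, schema, standardized = FALSE) {
  stopifnot(inherits(schema, "feature_schema"))
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  p <- length(schema$specs)
  if (ncol(values) != p)
    stop("values has ", ncol(values), " columns but schema declares ", p,
         " features", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("cohort values contain missing or non-finite entries", call. = FALSE)
  outcome <- as.integer(outcome)
  if (length(outcome) != nrow(values))
    stop("outcome length does not match row count", call. = FALSE)
  if (!all(outcome %in% c(0L, 1L)))
    stop("outcome must contain only 0 and 1", call. = FALSE)
  colnames(values) <- schema_names(schema)
  structure(list(n = nrow(values), values = values, outcome = outcome,
                 schema = schema, standardized = isTRUE(standardized)),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("cohort_table: n =", x$n, ", p =", ncol(x$values),
      ", prevalence =", round(mean(x$outcome), 3),
      if (x$standardized) "(standardized)" else "(raw)", "\n")
  invisible(x)
}

cohort_log <- function(tab, what = "load") {
  kinds <- schema_kinds(tab$schema)
  message(sprintf(
    "[cohort %s] n=%d p=%d prevalence=%.3f (numeric=%d binary=%d categorical=%d)",
    what, tab$n, ncol(tab$values), mean(tab$outcome),
    sum(kinds == "numeric"), sum(kinds == "binary"),
    sum(kinds == "categorical")))
}

#' Load a cohort CSV against a schema
#'
#' Performs schema-driven type conversion: numeric columns are parsed as
#' doubles (an unparseable cell is reported with its row/column coordinates),
#' binary columns must contain only 0/1, and categorical labels are validated
#' against the schema's declared categories and encoded as integers `0..K-1`
#' in category order. Values are NOT standardized here; that is the job of
#' [fit_preprocessor()] / [apply_preprocessor()]. Missing cells are rejected.
#'
#' @param path CSV file with a header row, UTF-8, "." decimal separator.
#' @param schema A [feature_schema()]; header names must match the schema's
#'   feature names plus the outcome column (order-insensitive).
#' @param quiet Suppress the load log line.
#' @return A `cohort_table`.
#' @export
load_cohort <- function(path, schema, quiet = FALSE) {
  stopifnot(inherits(schema, "feature_schema"))
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  nms <- schema_names(schema)
  missing_cols <- setdiff(c(nms, schema$outcome_name), names(raw))
  if (length(missing_cols) > 0L)
    stop("schema mismatch: column(s) missing from file: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  n <- nrow(raw)
  if (n < 1L) stop("cohort file has no data rows", call. = FALSE)
  vals <- matrix(NA_real_, n, length(nms), dimnames = list(NULL, nms))
  for (s in schema$specs) {
    col <- trimws(raw[[s$name]])
    if (any(col == "" | is.na(col)))
      stop("missing value in column '", s$name, "' at row ",
           which(col == "" | is.na(col))[1], " (missing values are rejected)",
           call. = FALSE)
    if (s$kind %in% c("numeric", "binary")) {
      num <- suppressWarnings(as.numeric(col))
      if (anyNA(num))
        stop("conversion error: cell (row ", which(is.na(num))[1],
             ", column '", s$name, "') is not numeric: '",
             col[which(is.na(num))[1]], "'", call. = FALSE)
      if (s$kind == "binary" && !all(num %in% c(0, 1)))
        stop("binary column '", s$name, "' contains values other than 0/1",
             call. = FALSE)
      vals[, s$name] <- num
    } else {
      idx <- match(col, s$categories)
      if (anyNA(idx))
        stop("validation error: column '", s$name, "' has unknown label '",
             col[which(is.na(idx))[1]], "'; admissible labels: ",
             paste(s$categories, collapse = ", "), call. = FALSE)
      vals[, s$name] <- idx - 1
    }
  }
  ocol <- trimws(raw[[schema$outcome_name]])
  onum <- suppressWarnings(as.numeric(ocol))
  if (anyNA(onum) || !all(onum %in% c(0, 1)))
    stop("outcome column '", schema$outcome_name,
         "' must contain only 0 and 1", call. = FALSE)
  tab <- cohort_table(vals, onum, schema)
  if (!quiet) cohort_log(tab, "load")
  tab
}

#' Write a cohort table to CSV
#'
#' Inverse of [load_cohort()]: categorical integer codes are written back as
#' their schema labels, so `write -> load` is an exact round trip on encoded
#' values.
#'
#' @param tab A `cohort_table` (unstandardized values round-trip exactly).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(tab, path) {
  stopifnot(inherits(tab, "cohort_table"))
  df <- as.data.frame(tab$values)
  for (s in tab$schema$specs) {
    if (s$kind == "categorical") {
      df[[s$name]] <- s$categories[df[[s$name]] + 1]
    } else {
      # 17 significant digits make the write -> load round trip exact
      df[[s$name]] <- sprintf("%.17g", df[[s$name]])
    }
  }
  df[[tab$schema$outcome_name]] <- tab$outcome
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fit preprocessing statistics on a training cohort
#'
#' Computes, on the supplied rows only, the per-numeric-feature mean and
#' sample standard deviation (denominator `n - 1`, matching the pooled-
#' covariance convention used by the Hotelling machinery) and the label-to-
#' integer map for each categorical feature (`0..K-1` in schema category
#' order). Binary features are left on the {0,1} scale.
#'
#' @param train A `cohort_table` with at least 2 rows.
#' @return A `preprocessor_state`.
#' @export
fit_preprocessor <- function(train) {
  stopifnot(inherits(train, "cohort_table"))
  if (train$n < 2L) stop("need >= 2 rows to fit a preprocessor", call. = FALSE)
  kinds <- schema_kinds(train$schema)
  nms <- schema_names(train$schema)
  center <- scale_ <- stats::setNames(rep(NA_real_, length(nms)), nms)
  for (j in which(kinds == "numeric")) {
    x <- train$values[, j]
    s <- stats::sd(x)
    if (!is.finite(s) || s <= 0)
      stop("degenerate feature: numeric column '", nms[j],
           "' is constant on the training rows", call. = FALSE)
    center[j] <- mean(x)
    scale_[j] <- s
  }
  label_maps <- list()
  for (j in which(kinds == "categorical")) {
    s <- train$schema$specs[[j]]
    label_maps[[s$name]] <- stats::setNames(seq_along(s$categories) - 1L,
                                            s$categories)
  }
  structure(list(center = center, scale = scale_, label_maps = label_maps,
                 schema = train$schema),
            class = "preprocessor_state")
}

#' Apply fitted preprocessing to a cohort
#'
#' Z-scores numeric columns with the training means/sds held in `state`;
#' categorical columns are already integer-encoded at load time, so the
#' categorical step is the identity (the label map is carried in `state` for
#' provenance). Applying a state to the table it was fitted on yields numeric
#' columns with mean 0 and sd 1.
#'
#' @param state A `preprocessor_state` from [fit_preprocessor()].
#' @param tab A `cohort_table` with a schema identical to the one the state
#'   was fitted on.
#' @return A standardized `cohort_table`.
#' @export
apply_preprocessor <- function(state, tab) {
  stopifnot(inherits(state, "preprocessor_state"),
            inherits(tab, "cohort_table"))
  if (!identical(schema_names(state$schema), schema_names(tab$schema)) ||
      !identical(schema_kinds(state$schema), schema_kinds(tab$schema)))
    stop("schema mismatch between preprocessor state and cohort", call. = FALSE)
  vals <- tab$values
  for (j in which(schema_kinds(tab$schema) == "numeric")) {
    vals[, j] <- (vals[, j] - state$center[j]) / state$scale[j]
  }
  cohort_table(vals, tab$outcome, tab$schema, standardized = TRUE)
}

#' Subset a cohort's rows (splits) or feature columns
#'
#' @param tab A `cohort_table`.
#' @param rows Integer row indices to keep.
#' @return A `cohort_table` restricted to `rows`.
#' @export
cohort_rows <- function(tab, rows) {
  cohort_table(tab$values[rows, , drop = FALSE], tab$outcome[rows],
               tab$schema, standardized = tab$standardized)
}

#' @rdname cohort_rows
#' @param features Character vector of feature names to keep (schema order
#'   preserved).
#' @export
cohort_features <- function(tab, features) {
  nms <- schema_names(tab$schema)
  bad <- setdiff(features, nms)
  if (length(bad) > 0L)
    stop("unknown feature(s): ", paste(bad, collapse = ", "), call. = FALSE)
  keep <- nms %in% features
  sub_schema <- feature_schema(tab$schema$specs[keep],
                               outcome_name = tab$schema$outcome_name)
  cohort_table(tab$values[, keep, drop = FALSE], tab$outcome, sub_schema,
               standardized = tab$standardized)
}
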