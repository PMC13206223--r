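#' Declare a single feature
#'
#' A feature spec describes one column of a cohort table: its name, its kind
#' (`numeric`, `binary` or `categorical`), the admissible category labels for
#' categorical features, the clinical group it belongs to, and whether it is a
#' member of the clinically established ("domain knowledge") feature set.
#'
#' @param name Unique feature name.
#' @param kind One of `"numeric"`, `"binary"`, `"categorical"`.
#' @param categories Ordered character vector of admissible labels; required
#'   for (and only for) categorical features. Their order defines the integer
#'   encoding `0..K-1`.
#' @param group One of `"clinical"`, `"echo"`, `"ecg"`, `"ct"`, `"procedural"`.
#' @param in_domain_knowledge Logical flag marking membership in the
#'   clinically established feature set.
#' @return A `feature_spec` object.
#' @export
feature_spec <- function(name, kind = c("numeric", "binary", "categorical"),
                         categories = NULL,
                         group = c("clinical", "echo", "ecg", "ct", "procedural"),
                         in_domain_knowledge = FALSE) {
  kind <- match.arg(kind)
  group <- match.arg(group)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (kind == "categorical") {
    if (is.null(categories) || length(categories) < 2L)
      stop("categorical feature '", name, "' needs >= 2 declared categories",
           call. = FALSE)
    categories <- as.character(categories)
    if (anyDuplicated(categories))
      stop("duplicate category labels for feature '", name, "'", call. = FALSE)
  } else if (!is.null(categories) && length(categories) > 0L) {
    stop("feature '", name, "' of kind '", kind,
         "' must not declare categories", call. = FALSE)
  } else {
    categories <- NULL
  }
  structure(list(name = name, kind = kind, categories = categories,
                 group = group,
                 in_domain_knowledge = isTRUE(in_domain_knowledge)),
            class = "feature_spec")
}

#' Assemble a feature schema
#'
#' The schema is the ordered list of feature specs plus the name of the binary
#' outcome column. List position defines the canonical feature index used by
#' every downstream module.
#'
#' @param specs List of [feature_spec()] objects.
#' @param outcome_name Name of the 0/1 outcome column; must not collide with a
#'   feature name.
#' @return A `feature_schema` object.
#' @export
feature_schema <- function(specs, outcome_name = "outcome") {
  stopifnot(is.list(specs), length(specs) >= 1L)
  if (!all(vapply(specs, inherits, logical(1), "feature_spec")))
    stop("all elements of 'specs' must be feature_spec objects", call. = FALSE)
  nms <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicate feature names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  if (outcome_name %in% nms)
    stop("outcome_name '", outcome_name, "' collides with a feature name",
         call. = FALSE)
  structure(list(specs = specs, outcome_name = outcome_name),
            class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  kinds <- schema_kinds(x)
  cat("feature_schema:", length(x$specs), "features (",
      sum(kinds == "numeric"), "numeric,", sum(kinds == "binary"), "binary,",
      sum(kinds == "categorical"), "categorical ),",
      sum(schema_dk_flags(x)), "in the domain-knowledge set; outcome:",
      x$outcome_name, "\n")
  invisible(x)
}

#' Feature names of a schema
#' @param schema A `feature_schema`.
#' @return Character vector in canonical order.
#' @export
schema_names <- function(schema) {
  vapply(schema$specs, `[[`, character(1), "name")
}

#' Feature kinds of a schema
#' @inheritParams schema_names
#' @return Character vector of kinds in canonical order.
#' @export
schema_kinds <- function(schema) {
  vapply(schema$specs, `[[`, character(1), "kind")
}

#' @rdname schema_names
#' @export
schema_groups <- function(schema) {
  vapply(schema$specs, `[[`, character(1), "group")
}

schema_dk_flags <- function(schema) {
  vapply(schema$specs, `[[`, logical(1), "in_domain_knowledge")
}

#' Recover the domain-knowledge feature set from a schema
#' @inheritParams schema_names
#' @return Character vector of features flagged `in_domain_knowledge`.
#' @export
domain_knowledge_set <- function(schema) {
  schema_names(schema)[schema_dk_flags(schema)]
}

schema_to_list <- function(schema) {
  list(
    outcome_name = schema$outcome_name,
    features = lapply(schema$specs, function(s) {
      out <- list(name = s$name, kind = s$kind, group = s$group,
                  in_domain_knowledge = s$in_domain_knowledge)
      if (!is.null(s$categories)) out$categories <- as.list(s$categories)
      out
    })
  )
}

schema_from_list <- function(x) {
  stopifnot(is.list(x), !is.null(x$features), !is.null(x$outcome_name))
  specs <- lapply(x$features, function(f) {
    feature_spec(name = f$name, kind = f$kind,
                 categories = if (is.null(f$categories)) NULL
                              else unlist(f$categories, use.names = FALSE),
                 group = f$group,
                 in_domain_knowledge = isTRUE(f$in_domain_knowledge))
  })
  feature_schema(specs, outcome_name = x$outcome_name)
}

#' Read / write a feature schema
#'
#' Schemas are stored as YAML (`.yml`/`.yaml`) or JSON (`.json`) documents with
#' one entry per feature (`name`, `kind`, `categories`, `group`,
#' `in_domain_knowledge`) plus `outcome_name`.
#'
#' @param path File path; the extension selects the format.
#' @return [read_schema()] returns a `feature_schema`; [write_schema()]
#'   returns `path` invisibly.
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) stop("schema file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    "yml" = , "yaml" = yaml::read_yaml(path),
    "json" = jsonlite::read_json(path),
    stop("unsupported schema format '.", ext, "' (use yaml or json)",
         call. = FALSE))
  schema_from_list(x)
}

#' @rdname read_schema
#' @param schema A `feature_schema` to serialize.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "feature_schema"))
  ext <- tolower(tools::file_ext(path))
  x <- schema_to_list(schema)
  switch(ext,
    "yml" = , "yaml" = yaml::write_yaml(x, path),
    "json" = jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE),
    stop("unsupported schema format '.", ext, "'", call. = FALSE))
  invisible(path)
}
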