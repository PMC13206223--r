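stage_seed_offsets <- c(simulate = 1L, train = 2L, select = 3L,
                        benchmark = 4L, compare = 5L)

#' Pipeline run configuration
#'
#' One global seed deterministically derives all stage seeds (global seed +
#' fixed per-stage offset), so an end-to-end run is reproducible from a
#' single integer.
#'
#' @param out_dir Output directory for artifacts.
#' @param stages Ordered subset of
#'   `c("simulate", "train", "select", "benchmark", "compare")`.
#' @param seed Global integer seed.
#' @param cohort_path,schema_path Input cohort/schema paths; defaults point at
#'   the files the `simulate` stage writes into `out_dir`.
#' @param generator A [generator_config()] for the simulate stage (its seed is
#'   overridden by the derived stage seed).
#' @param hyperparams A [selector_hyperparams()] (seed overridden likewise).
#' @param bench A [benchmark_config()] (seeds derived from the stage seed).
#' @param alpha Significance level for selection.
#' @return A `run_config`.
#' @export
run_config <- function(out_dir,
                       stages = c("simulate", "train", "select", "benchmark",
                                  "compare"),
                       seed = 1L,
                       cohort_path = NULL, schema_path = NULL,
                       generator = lbbb_cohort_config(),
                       hyperparams = selector_hyperparams(),
                       bench = benchmark_config(),
                       alpha = 0.05) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(out_dir = out_dir, stages = stages, seed = as.integer(seed),
                 cohort_path = cohort_path, schema_path = schema_path,
                 generator = generator, hyperparams = hyperparams,
                 bench = bench, alpha = alpha),
            class = "run_config")
}

#' Execute the pipeline
#'
#' Runs the requested stages in order (simulate -> train -> select ->
#' benchmark -> compare), writing every artifact plus a JSON manifest that
#' records the config hash, global seed, derived stage seeds, package version
#' and artifact paths. Rerunning with an identical config reproduces
#' identical artifacts.
#'
#' @param config A [run_config()].
#' @param quiet Suppress stage progress messages.
#' @return The manifest, invisibly (list).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[pipeline] ", ...)
  artifacts <- list()
  seeds <- config$seed + stage_seed_offsets

  cohort_path <- config$cohort_path %||% file.path(config$out_dir, "cohort.csv")
  schema_path <- config$schema_path %||%
    file.path(config$out_dir, "cohort_schema.yaml")

  if ("simulate" %in% config$stages) {
    say("simulate")
    gen_cfg <- config$generator
    gen_cfg$seed <- seeds[["simulate"]]
    paths <- write_synthetic_cohort(gen_cfg, config$out_dir, "cohort")
    artifacts[c("cohort", "schema", "truth")] <- paths
    cohort_path <- paths$cohort; schema_path <- paths$schema
  }

  need_cohort <- any(c("train", "select", "benchmark", "compare") %in%
                       config$stages)
  cohort <- schema <- NULL
  if (need_cohort) {
    schema <- read_schema(schema_path)
    cohort <- load_cohort(cohort_path, schema, quiet = quiet)
  }

  selector <- NULL
  if ("train" %in% config$stages) {
    say("train (", config$hyperparams$epochs, " epochs)")
    hp <- config$hyperparams
    hp$seed <- seeds[["train"]]
    selector <- train_selector(cohort, hp)
    log_path <- file.path(config$out_dir, "training_log.csv")
    utils::write.csv(selector$log, log_path, row.names = FALSE)
    sel_path <- file.path(config$out_dir, "selector.rds")
    saveRDS(selector, sel_path)
    artifacts$training_log <- log_path
    artifacts$selector <- sel_path
  }

  report <- NULL
  if ("select" %in% config$stages) {
    say("select (alpha = ", config$alpha, ")")
    if (is.null(selector)) {
      sel_path <- file.path(config$out_dir, "selector.rds")
      if (!file.exists(sel_path))
        stop("select stage needs a trained selector (run the train stage first)",
             call. = FALSE)
      selector <- readRDS(sel_path)
    }
    pre <- apply_preprocessor(selector$preprocessor, cohort)
    report <- feature_significance(selector, pre, alpha = config$alpha)
    csv <- file.path(config$out_dir, "selection_report.csv")
    lst <- file.path(config$out_dir, "ours_features.txt")
    write_selection_report(report, csv, lst)
    artifacts$selection_report <- csv
    artifacts$ours_features <- lst
  }

  if ("benchmark" %in% config$stages) {
    say("benchmark")
    bc <- config$bench
    bc$seeds <- seeds[["benchmark"]] + seq_len(bc$n_repeats) - 1L
    sets <- list(feature_set_spec("ALL", schema_names(schema)))
    dk <- domain_knowledge_set(schema)
    if (length(dk) > 0L)
      sets <- c(sets, list(feature_set_spec("DK", dk)))
    ours <- if (!is.null(report)) report$selected else {
      lst <- file.path(config$out_dir, "ours_features.txt")
      if (file.exists(lst)) readLines(lst) else character(0)
    }
    if (length(ours) > 0L)
      sets <- c(sets, list(feature_set_spec("OURS", ours)))
    bench <- run_benchmark(cohort, sets, bc, quiet = quiet)
    paths <- write_benchmark_report(bench, config$out_dir)
    artifacts[names(paths)] <- paths
  }

  if ("compare" %in% config$stages) {
    say("compare")
    universe <- schema_names(schema)
    established <- domain_knowledge_set(schema)
    ours <- if (!is.null(report)) report$selected else {
      lst <- file.path(config$out_dir, "ours_features.txt")
      if (file.exists(lst)) readLines(lst) else character(0)
    }
    mat <- compare_selection(ours, established, universe)
    met <- agreement_metrics(mat)
    base <- baseline_logistic_selection(cohort, alpha = config$alpha)
    base_mat <- compare_selection(as.character(base), established, universe)
    base_met <- agreement_metrics(base_mat)
    cmp <- list(
      ours = c(unclass(mat), as.list(round(met, 2))),
      logistic_baseline = c(unclass(base_mat), as.list(round(base_met, 2)),
                            list(flagged = attr(base, "flagged"),
                                 diagnostic = attr(base, "diagnostic"))))
    cmp_path <- file.path(config$out_dir, "agreement.json")
    jsonlite::write_json(cmp, cmp_path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    artifacts$agreement <- cmp_path
  }

  cfg_path <- file.path(config$out_dir, "run_config.yaml")
  yaml::write_yaml(serialize_run_config(config), cfg_path)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    stage_seeds = as.list(seeds[intersect(names(seeds), config$stages)]),
    package_version = as.character(utils::packageVersion("t2select")),
    artifacts = artifacts)
  man_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, pretty = TRUE)
  say("done; manifest at ", man_path)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

serialize_run_config <- function(config) {
  list(stages = config$stages, seed = config$seed,
       alpha = config$alpha,
       cohort_path = config$cohort_path, schema_path = config$schema_path,
       generator = lapply(unclass(config$generator), function(x)
         if (is.data.frame(x)) as.list(x) else x),
       hyperparams = unclass(config$hyperparams),
       bench = list(models = config$bench$models,
                    n_repeats = config$bench$n_repeats,
                    test_fraction = config$bench$test_fraction,
                    inner_folds = config$bench$inner_folds,
                    grids = lapply(config$bench$grids, as.list)))
}

#' Write a benchmark report's artifact files
#'
#' Emits the benchmark-table CSV (per model x feature set, metric mean and
#' sd), pooled ROC points, calibration bins, and a JSON summary.
#'
#' @param bench A `benchmark_report`.
#' @param dir Output directory.
#' @return Invisible named list of written paths.
#' @export
write_benchmark_report <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(benchmark_table = file.path(dir, "benchmark_table.csv"),
                benchmark_raw = file.path(dir, "benchmark_raw.csv"),
                roc_points = file.path(dir, "roc_points.csv"),
                calibration = file.path(dir, "calibration.csv"),
                benchmark_json = file.path(dir, "benchmark_summary.json"))
  utils::write.csv(bench$summary, paths$benchmark_table, row.names = FALSE)
  utils::write.csv(bench$raw, paths$benchmark_raw, row.names = FALSE)
  roc_all <- cal_all <- list()
  for (key in names(bench$scores)) {
    sc <- bench$scores[[key]]
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    ra <- roc_and_auc(sc$score, sc$actual)
    roc_all[[key]] <- cbind(model = parts[1], feature_set = parts[2], ra$roc)
    cb <- calibration_bins(sc$score, sc$actual)
    cal_all[[key]] <- cbind(model = parts[1], feature_set = parts[2], cb)
  }
  utils::write.csv(do.call(rbind, roc_all), paths$roc_points, row.names = FALSE)
  utils::write.csv(do.call(rbind, cal_all), paths$calibration, row.names = FALSE)
  jsonlite::write_json(bench$summary, paths$benchmark_json, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}

#' Command-line entry point
#'
#' Thin argument parser behind the `inst/cli/t2select.R` script. Subcommands:
#' `simulate | train | select | benchmark | compare | all`, with options
#' `--out DIR` (required), `--seed N`, `--config FILE` (YAML with
#' `hyperparams:`, `bench:`, `generator:`, `alpha:` overrides), `--cohort`
#' and `--schema` paths, `--alpha`, `--epochs`.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1L) {
    message("usage: t2select.R <simulate|train|select|benchmark|compare|all> ",
            "--out DIR [--seed N] [--config FILE] [--cohort CSV] ",
            "[--schema YAML] [--alpha A] [--epochs E]")
    return(invisible(1L))
  }
  sub <- args[1]
  opt <- list(seed = 1L, alpha = 0.05)
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (i + 1L > length(args)) stop("missing value for --", key, call. = FALSE)
    opt[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  if (is.null(opt$out)) stop("--out is required", call. = FALSE)
  stages <- if (sub == "all")
    c("simulate", "train", "select", "benchmark", "compare") else sub
  hp <- selector_hyperparams()
  gen <- lbbb_cohort_config()
  bc <- benchmark_config()
  alpha <- as.numeric(opt$alpha)
  if (!is.null(opt$config)) {
    cfg <- yaml::read_yaml(opt$config)
    if (!is.null(cfg$hyperparams))
      hp <- do.call(selector_hyperparams,
                    utils::modifyList(unclass(hp), cfg$hyperparams))
    if (!is.null(cfg$generator))
      gen <- do.call(generator_config,
                     utils::modifyList(
                       lapply(unclass(gen), identity), cfg$generator))
    if (!is.null(cfg$bench))
      bc <- do.call(benchmark_config, cfg$bench)
    if (!is.null(cfg$alpha)) alpha <- cfg$alpha
  }
  if (!is.null(opt$epochs))
    hp <- selector_hyperparams(d_token = hp$d_token, n_layers = hp$n_layers,
                               n_heads = hp$n_heads, lr = hp$lr,
                               epochs = as.integer(opt$epochs),
                               lambda1 = hp$lambda1, lambda2 = hp$lambda2,
                               ridge = hp$ridge, seed = hp$seed)
  config <- run_config(out_dir = opt$out, stages = stages,
                       seed = as.integer(opt$seed),
                       cohort_path = opt$cohort, schema_path = opt$schema,
                       generator = gen, hyperparams = hp, bench = bc,
                       alpha = alpha)
  status <- tryCatch({ run_pipeline(config); 0L },
                     error = function(e) {
                       message("[pipeline] stage failure: ", conditionMessage(e))
                       1L
                     })
  invisible(status)
}
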