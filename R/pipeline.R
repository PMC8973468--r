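#' Pipeline configuration
#'
#' Assembles the per-stage configurations and global settings for
#' [run_pipeline()].
#'
#' @param generator a [generator_config()], or `NULL` when `input_csv` is
#'   given.
#' @param input_csv optional path to an existing trace CSV (skips simulation).
#' @param preprocess a [preprocess_config()].
#' @param features a [feature_config()].
#' @param stats list: `random` structure and `influence_threshold`.
#' @param classify list: `k`, `grouping`, `families`.
#' @param seed global seed; stage seeds derive from it.
#' @param out_dir output directory for stage artifacts.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            input_csv = NULL,
                            preprocess = preprocess_config(),
                            features = feature_config(),
                            stats = list(random = "slope",
                                         influence_threshold = 3.0),
                            classify = list(k = 5L, grouping = "none",
                                            families = CLASSIFIER_FAMILIES),
                            seed = 1L,
                            out_dir = "pupilload-run") {
  structure(list(generator = generator, input_csv = input_csv,
                 preprocess = preprocess, features = features,
                 stats = stats, classify = classify,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized sections: `generator`, `preprocess`, `features`, `stats`,
#' `classify`, plus scalars `seed`, `out_dir` and `input_csv`. Keys inside a
#' section must match the corresponding configuration constructor's arguments;
#' unknown sections or keys are rejected.
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("generator", "preprocess", "features", "stats", "classify",
             "seed", "out_dir", "input_csv")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  build <- function(fun, args, section) {
    bad <- setdiff(names(args), names(formals(fun)))
    if (length(bad) > 0L) {
      stop(sprintf("unknown key(s) in section '%s': %s", section,
                   paste(bad, collapse = ", ")))
    }
    listify <- function(x) if (is.list(x)) unlist(x) else x
    do.call(fun, lapply(args, listify))
  }
  args <- list()
  if (!is.null(raw$generator)) {
    args$generator <- build(generator_config, raw$generator, "generator")
  }
  if (!is.null(raw$preprocess)) {
    args$preprocess <- build(preprocess_config, raw$preprocess, "preprocess")
  }
  if (!is.null(raw$features)) {
    args$features <- build(feature_config, raw$features, "features")
  }
  for (key in c("stats", "classify", "seed", "out_dir", "input_csv")) {
    if (!is.null(raw[[key]])) args[[key]] <- raw[[key]]
  }
  defaults <- pipeline_config()
  if (!is.null(args$stats)) args$stats <- utils::modifyList(defaults$stats, args$stats)
  if (!is.null(args$classify)) {
    args$classify <- utils::modifyList(defaults$classify, args$classify)
  }
  do.call(pipeline_config, args)
}

#' Run the full analysis pipeline
#'
#' simulate (or ingest) -> preprocess -> extract -> stats -> classify. Every
#' stage writes its CSV artifact into `config$out_dir`, together with a JSON
#' run manifest (resolved configuration, seed, per-stage row counts) and a
#' plain-text log with stage timings. Identical configuration and seed give
#' byte-identical feature and report CSVs.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with the in-memory stage results: `dataset`,
#'   `clean`, `features`, `analysis`, `search`, and `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "pipeline.log")
  cat(sprintf("pupilload pipeline, seed %d\n", config$seed), file = logf)
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- tic()
    out <- tryCatch(expr, error = function(e) {
      cat(sprintf("%s: FAILED (%s)\n", name, conditionMessage(e)),
          file = logf, append = TRUE)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    cat(sprintf("%s: ok (%.2f s)\n", name, tic() - t0),
        file = logf, append = TRUE)
    out
  }

  dataset <- stage("simulate", {
    if (!is.null(config$input_csv)) {
      read_trials(config$input_csv)
    } else {
      gen <- config$generator
      gen$seed <- config$seed
      simulate_dataset(gen)
    }
  })
  write_trials(dataset, file.path(config$out_dir, "traces.csv"))

  clean <- stage("preprocess", preprocess_dataset(dataset, config$preprocess))
  utils::write.csv(clean$rejections,
                   file.path(config$out_dir, "rejections.csv"),
                   row.names = FALSE)

  empty_features <- data.frame(subject_id = character(0),
                               trial_id = character(0),
                               difficulty = character(0))
  features <- stage("extract", {
    if (length(clean$trials) == 0L) empty_features else
      extract_feature_table(clean$trials, config$features)
  })
  utils::write.csv(features, file.path(config$out_dir, "features.csv"),
                   row.names = FALSE)

  # the analysis stages need all three levels and a handful of rows per
  # class; with heavily artifacted inputs (most trials rejected) they are
  # skipped and empty artifacts written, so the run still completes
  enough <- nrow(features) > 0L &&
    all(table(factor(features$difficulty, levels = DIFFICULTY_LEVELS)) >=
          max(config$classify$k, 2L)) &&
    length(unique(features$subject_id)) >= 2L

  analysis <- NULL
  if (enough) {
    analysis <- stage("stats", run_feature_analysis(
      features, random = config$stats$random,
      influence_threshold = config$stats$influence_threshold))
    utils::write.csv(analysis$lrt, file.path(config$out_dir, "lrt.csv"),
                     row.names = FALSE)
    utils::write.csv(analysis$contrasts,
                     file.path(config$out_dir, "contrasts.csv"),
                     row.names = FALSE)
  } else {
    cat("stats: skipped (insufficient clean trials)\n",
        file = logf, append = TRUE)
    utils::write.csv(data.frame(feature = character(0)),
                     file.path(config$out_dir, "lrt.csv"), row.names = FALSE)
    utils::write.csv(data.frame(feature = character(0)),
                     file.path(config$out_dir, "contrasts.csv"),
                     row.names = FALSE)
  }

  search <- NULL
  if (enough) {
    search <- stage("classify", wrapper_search(
      features, families = config$classify$families, k = config$classify$k,
      seed = config$seed, grouping = config$classify$grouping))
    utils::write.csv(search$reports, file.path(config$out_dir, "report.csv"),
                     row.names = FALSE)
  } else {
    cat("classify: skipped (insufficient clean trials)\n",
        file = logf, append = TRUE)
    utils::write.csv(data.frame(family = character(0)),
                     file.path(config$out_dir, "report.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    seed = config$seed,
    config = unclass_config(config),
    rows = list(traces = nrow(dataset),
                rejected_trials = nrow(clean$rejections),
                clean_trials = length(clean$trials),
                features = nrow(features),
                lrt = if (is.null(analysis)) 0L else nrow(analysis$lrt),
                contrasts = if (is.null(analysis)) 0L else
                  nrow(analysis$contrasts),
                report = if (is.null(search)) 0L else nrow(search$reports)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(dataset = dataset, clean = clean, features = features,
                 analysis = analysis, search = search,
                 out_dir = config$out_dir))
}

# strip S3 classes recursively so the manifest serializes as plain JSON
unclass_config <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_config) else x
}
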