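parse_error <- function(path, line, msg) {
  abort(sprintf("%s: line %d: %s", path, line, msg), class = "wp_parse_error")
}

#' Write and read recording CSV files
#'
#' One CSV per recording with columns `t, ax, ay, az` (seconds, G) plus
#' `gx, gy, gz` (deg/s) for the hand sensor, and a `manifest.csv` listing
#' every file with its provenance (`file, device, participant, task,
#' repetition, nominal_rate`). The round trip preserves values to full
#' precision.
#'
#' @param recordings Recordings tibble.
#' @param dir Output directory (created if needed).
#' @return `write_recordings()` returns the manifest path invisibly;
#'   `read_recordings()` returns a recordings tibble.
#' @export
write_recordings <- function(recordings, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("%s_%s_%s_r%02d.csv", recordings$device,
                   recordings$participant, recordings$task,
                   recordings$repetition)
  for (i in seq_len(nrow(recordings)))
    readr::write_csv(recordings$signal[[i]], file.path(dir, files[i]))
  manifest <- tibble::tibble(
    file = files, device = recordings$device,
    participant = recordings$participant, task = recordings$task,
    repetition = recordings$repetition,
    nominal_rate = recordings$nominal_rate
  )
  mpath <- file.path(dir, "manifest.csv")
  readr::write_csv(manifest, mpath)
  invisible(mpath)
}

#' @rdname write_recordings
#' @export
read_recordings <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) abort(sprintf("no manifest at %s", mpath),
                                 class = "wp_parse_error")
  manifest <- readr::read_csv(mpath, show_col_types = FALSE)
  req <- c("file", "device", "participant", "task", "repetition", "nominal_rate")
  if (!all(req %in% names(manifest)))
    parse_error(mpath, 1L, paste("manifest must have columns",
                                 paste(req, collapse = ", ")))
  sigs <- lapply(seq_len(nrow(manifest)), function(i) {
    path <- file.path(dir, manifest$file[i])
    sig <- readr::read_csv(path, show_col_types = FALSE)
    need <- c("t", "ax", "ay", "az")
    if (manifest$device[i] == "hand_sensor") need <- c(need, "gx", "gy", "gz")
    missing <- setdiff(need, names(sig))
    if (length(missing) > 0)
      parse_error(path, 1L, paste("missing column(s)",
                                  paste(missing, collapse = ", ")))
    sig[need]
  })
  tibble::tibble(
    device = manifest$device, participant = manifest$participant,
    task = manifest$task, repetition = as.integer(manifest$repetition),
    nominal_rate = manifest$nominal_rate, signal = sigs
  )
}

#' Write and read symptom annotation CSV
#'
#' Columns `participant, task, repetition, symptom, score`. On read, rows
#' with an unknown symptom or a score outside 0-4 are rejected with their
#' line number.
#'
#' @param annotations Annotation tibble.
#' @param path CSV file path.
#' @return `write_annotations()` returns `path` invisibly;
#'   `read_annotations()` a validated tibble.
#' @export
write_annotations <- function(annotations, path) {
  readr::write_csv(annotations, path)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  ann <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("participant", "task", "repetition", "symptom", "score")
  if (!all(req %in% names(ann)))
    parse_error(path, 1L, paste("annotation file must have columns",
                                paste(req, collapse = ", ")))
  bad_sym <- which(!ann$symptom %in% c("tremor", "bradykinesia"))
  if (length(bad_sym) > 0)
    parse_error(path, bad_sym[1] + 1L,
                sprintf("unknown symptom '%s' (column symptom)",
                        ann$symptom[bad_sym[1]]))
  bad <- which(!is.finite(ann$score) | ann$score < 0 | ann$score > 4 |
                 ann$score != round(ann$score))
  if (length(bad) > 0)
    parse_error(path, bad[1] + 1L,
                sprintf("score %s outside the integer 0-4 scale (column score)",
                        format(ann$score[bad[1]])))
  ann$repetition <- as.integer(ann$repetition)
  ann$score <- as.integer(ann$score)
  ann
}

#' Write and read a feature matrix CSV
#'
#' One row per valid clip: provenance and score columns followed by the
#' feature columns in canonical order. The column-order contract is stable
#' across runs.
#'
#' @param features Feature tibble from [extract_features()].
#' @param path CSV file path.
#' @return `write_features()` returns `path` invisibly; `read_features()`
#'   the tibble.
#' @export
write_features <- function(features, path) {
  readr::write_csv(features, path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

comparison_to_list <- function(x) {
  means <- colMeans(x$auroc)
  n <- nrow(x$auroc)
  half <- qt(0.975, n - 1) * apply(x$auroc, 2, sd) / sqrt(n)
  list(
    factor = x$factor, conditions = x$conditions,
    anova = x$anova,
    summary = data.frame(condition = x$conditions,
                         mean_auroc = unname(means),
                         ci_lo = unname(means - half),
                         ci_hi = unname(means + half)),
    fold_auroc = cbind(data.frame(left_out = rownames(x$auroc)),
                       as.data.frame(x$auroc)),
    pairwise = as.data.frame(x$pairwise)
  )
}

#' Write comparison results as JSON
#'
#' Serializes one or more `wp_comparison` objects (per-fold AUROC matrix,
#' rmANOVA, pairwise tests, and per-condition means with 95% t-intervals)
#' to a versioned JSON document at full precision, so identical runs give
#' byte-identical files.
#'
#' @param comparisons A `wp_comparison` or a named list of them.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(comparisons, path) {
  if (inherits(comparisons, "wp_comparison"))
    comparisons <- list(result = comparisons)
  payload <- list(schema = "wearpd/comparison/v1",
                  results = lapply(comparisons, comparison_to_list))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_results_json
#' @export
read_results_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

comparison_summary_md <- function(comparisons) {
  lines <- character(0)
  for (nm in names(comparisons)) {
    x <- comparisons[[nm]]
    means <- colMeans(x$auroc)
    n <- nrow(x$auroc)
    half <- qt(0.975, n - 1) * apply(x$auroc, 2, sd) / sqrt(n)
    lines <- c(lines, sprintf("## %s", nm), "",
               sprintf("rmANOVA F(%d, %d) = %.2f, p = %.3g", x$anova$df1,
                       x$anova$df2, x$anova$F, x$anova$p), "",
               "| Condition | AUROC (95% CI) |", "|---|---|",
               sprintf("| %s | %.2f (%.2f-%.2f) |", x$conditions, means,
                       means - half, means + half), "")
  }
  lines
}

#' Run the full analysis pipeline
#'
#' Orchestrates generation -> preprocessing -> feature extraction ->
#' enabled experiments, writing a reproducible report bundle: the resolved
#' configuration (`config.yaml`), a run stamp (`run.json` with the config
#' hash and seed), the annotation and feature tables, and per-experiment
#' directories each holding `comparison.json` and `summary.md` (plus
#' `pareto.csv` for the feature experiment). Rerunning with the same
#' configuration reproduces every output bit-identically except the
#' wall-clock timing column of `pareto.csv`.
#'
#' @param config A [generator_config()].
#' @param output_dir Writable output directory.
#' @param experiments Subset of `c("sensors", "rates", "features")`; empty
#'   means dataset + features only.
#' @param symptoms,modes Model configurations to run per experiment.
#' @param rates Rate ladder for the sampling-rate experiment.
#' @param write_raw Also write every recording CSV (large; default FALSE).
#' @param n_trees Forest size.
#' @param verbose Log stages via `message()`.
#' @return Invisibly, a list with the dataset and any experiment results.
#' @export
run_study <- function(config, output_dir,
                      experiments = c("sensors", "rates", "features"),
                      symptoms = c("tremor", "bradykinesia"),
                      modes = "binary",
                      rates = c(62.5, 50, 40, 30, 20, 10, 7.5, 5),
                      write_raw = FALSE, n_trees = 50, verbose = FALSE) {
  if (length(experiments) > 0)
    experiments <- match.arg(experiments, several.ok = TRUE)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))

  write_config(config, file.path(output_dir, "config.yaml"))
  stamp <- list(config_hash = rlang::hash(unclass(config)), seed = config$seed,
                package = as.character(utils::packageVersion("wearpd")))
  jsonlite::write_json(stamp, file.path(output_dir, "run.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  say("run_study: generating dataset")
  ds <- generate_dataset(config)
  write_annotations(ds$annotations, file.path(output_dir, "annotations.csv"))
  if (write_raw) write_recordings(ds$recordings, file.path(output_dir, "recordings"))

  say("run_study: preprocessing + feature extraction")
  hand_features <- extract_features(preprocess(ds, devices = "hand_sensor"))
  watch_features <- extract_features(preprocess(ds, devices = "watch"),
                                     modalities = "accel")
  write_features(hand_features, file.path(output_dir, "features_hand.csv"))
  write_features(watch_features, file.path(output_dir, "features_watch.csv"))

  results <- list()
  grid <- expand.grid(symptom = symptoms, mode = modes,
                      stringsAsFactors = FALSE)
  bundle <- function(name, comps, pareto = NULL) {
    d <- file.path(output_dir, name)
    dir.create(d, showWarnings = FALSE)
    write_results_json(comps, file.path(d, "comparison.json"))
    writeLines(comparison_summary_md(comps), file.path(d, "summary.md"))
    if (!is.null(pareto)) {
      readr::write_csv(dplyr::bind_rows(pareto, .id = "model"),
                       file.path(d, "pareto.csv"))
    }
  }
  if ("sensors" %in% experiments) {
    say("run_study: sensor-set experiment")
    comps <- list()
    for (i in seq_len(nrow(grid))) {
      key <- paste(grid$symptom[i], grid$mode[i], sep = "_")
      comps[[key]] <- sensor_set_experiment(
        ds, grid$symptom[i], grid$mode[i], n_trees = n_trees,
        seed = config$seed, hand_features = hand_features,
        watch_features = watch_features)
    }
    bundle("sensors", comps)
    results$sensors <- comps
  }
  if ("rates" %in% experiments) {
    say("run_study: sampling-rate experiment")
    comps <- list()
    for (i in seq_len(nrow(grid))) {
      key <- paste(grid$symptom[i], grid$mode[i], sep = "_")
      comps[[key]] <- sampling_rate_experiment(
        ds, grid$symptom[i], grid$mode[i], rates = rates,
        n_trees = n_trees, seed = config$seed)
    }
    bundle("rates", comps)
    results$rates <- comps
  }
  if ("features" %in% experiments) {
    say("run_study: feature-set experiment")
    comps <- list(); paretos <- list()
    for (i in seq_len(nrow(grid))) {
      key <- paste(grid$symptom[i], grid$mode[i], sep = "_")
      fx <- feature_set_experiment(ds, grid$symptom[i], grid$mode[i],
                                   n_trees = n_trees, seed = config$seed)
      comps[[key]] <- fx$comparison
      paretos[[key]] <- tibble::as_tibble(fx$pareto)[
        c("label", "mean_time_ms", "mean_auroc", "retained")]
    }
    bundle("features", comps, pareto = paretos)
    results$features <- comps
  }
  invisible(list(dataset = ds, results = results))
}
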