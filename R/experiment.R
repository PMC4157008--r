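# Experiment runner: fixed-peak-model and feature-selection protocols over
# independent runs, with the 4-measure (average / max / min / stdev) report.

#' Aggregate Gmean values over runs
#'
#' @param values Numeric vector of per-run scores (at least one).
#' @return Named vector: arithmetic `average`, `max`, `min` and the sample
#'   (n-1) standard deviation `stdev` (0 for a single run).
#' @export
aggregate_gmean <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L || anyNA(values)) {
    stop("need at least one run value", call. = FALSE)
  }
  c(average = mean(values), max = max(values), min = min(values),
    stdev = if (length(values) == 1L) 0 else stats::sd(values))
}

#' Run a multi-run training/testing experiment
#'
#' Splits the recording at `boundary`, detects candidates and extracts
#' features once per partition, then performs `n_runs` independent training
#' runs (the optimizer is reseeded with `seed, seed + 1, ...`; feature
#' extraction is deterministic so only the optimizer is reseeded). In
#' fixed-model mode the feature mask is frozen to a named catalogue subset
#' (see [peak_model_catalog()]) and only its thresholds are optimized; in
#' selection mode mask and thresholds are searched jointly. Each trained rule
#' is then scored on the unseen testing partition.
#'
#' @param signal An [eeg_signal()].
#' @param annotations An [annotation_set()].
#' @param algorithm `"pso"` (synchronous) or `"rapso"` (random-asynchronous).
#' @param mode `"select"` for joint feature selection, or a catalogue model
#'   name (`"dumpala"`, `"acir"`, `"liu"`, `"dingle"`) for fixed-model mode.
#' @param n_runs Number of independent runs.
#' @param boundary Split index; default half the recording.
#' @param tolerance Annotation matching tolerance (samples).
#' @param mac_window Moving-average window (samples).
#' @param swarm A [swarm_config()]; its `algorithm` and `seed` fields are
#'   overridden per run.
#' @param seed Master seed; run r uses `seed + r - 1`.
#' @return An object of class `peak_experiment_report`: list with `runs`
#'   (one data.frame row per run: selected features, train/test Gmean and
#'   confusion counts), `summary` (the four aggregate measures for train and
#'   test), `models`, and the configuration.
#' @export
run_experiment <- function(signal, annotations, algorithm = c("pso", "rapso"),
                           mode = "select", n_runs = 10L, boundary = NULL,
                           tolerance = 0L, mac_window = 257L,
                           swarm = swarm_config(), seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (is.null(boundary)) boundary <- signal_length(signal) %/% 2L
  fixed_mask <- if (identical(mode, "select")) NULL else model_subset(mode)

  halves <- split_recording(signal, annotations, boundary)
  prep <- function(part) {
    cand <- detect_candidates(part$signal)
    if (nrow(cand) == 0L) {
      stop("no candidates in a partition; nothing to train on",
           call. = FALSE)
    }
    list(features = peak_features(part$signal, cand, mac_window),
         labels = label_candidates(cand, part$annotations, tolerance))
  }
  tr <- prep(halves$train)
  te <- prep(halves$test)

  swarm$algorithm <- if (algorithm == "pso") "synchronous" else
    "random_asynchronous"

  rows <- vector("list", n_runs)
  models <- vector("list", n_runs)
  histories <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    swarm$seed <- as.integer(seed) + r - 1L
    fit <- run_swarm(tr$features, tr$labels, swarm, fixed_mask = fixed_mask)
    m <- fit$model
    ctr <- confusion(classify(tr$features, m), tr$labels)
    cte <- confusion(classify(te$features, m), te$labels)
    rows[[r]] <- data.frame(
      run = r, algorithm = algorithm, mode = mode,
      features = paste(FEATURE_NAMES[m$mask], collapse = "+"),
      thresholds = paste(sprintf("%.4g", m$thresholds[m$mask]),
                         collapse = "+"),
      train_gmean = gmean(ctr), test_gmean = gmean(cte),
      train_tp = ctr$tp, train_tn = ctr$tn, train_fp = ctr$fp,
      train_fn = ctr$fn,
      test_tp = cte$tp, test_tn = cte$tn, test_fp = cte$fp,
      test_fn = cte$fn,
      stringsAsFactors = FALSE)
    models[[r]] <- m
    histories[[r]] <- fit$gbest_history
  }
  runs <- do.call(rbind, rows)
  summary <- data.frame(
    phase = c("train", "test"),
    rbind(aggregate_gmean(runs$train_gmean),
          aggregate_gmean(runs$test_gmean)))
  structure(list(runs = runs, summary = summary, models = models,
                 histories = histories,
                 algorithm = algorithm, mode = mode, boundary = boundary,
                 tolerance = tolerance, mac_window = mac_window,
                 seed = seed, swarm = swarm),
            class = "peak_experiment_report")
}

#' Check a report's aggregates against its per-run rows
#'
#' Recomputes the summary block from the run rows; an inconsistent report is
#' an error. Called by [print.peak_experiment_report()] and the tests.
#'
#' @param report A `peak_experiment_report`.
#' @return `TRUE`, invisibly.
#' @export
validate_report <- function(report) {
  want <- rbind(aggregate_gmean(report$runs$train_gmean),
                aggregate_gmean(report$runs$test_gmean))
  got <- as.matrix(report$summary[, c("average", "max", "min", "stdev")])
  if (max(abs(want - got)) > 1e-12) {
    stop("report aggregates do not match per-run rows", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.peak_experiment_report <- function(x, ...) {
  validate_report(x)
  cat(sprintf("<peak_experiment_report> %s / mode=%s, %d runs\n",
              toupper(x$algorithm), x$mode, nrow(x$runs)))
  cat("\nPer-run results:\n")
  print(x$runs[, c("run", "features", "train_gmean", "test_gmean")],
        row.names = FALSE, digits = 5)
  cat("\nAggregate Gmean (sample stdev):\n")
  print(x$summary, row.names = FALSE, digits = 5)
  invisible(x)
}

#' Write an experiment report as tab-delimited text
#'
#' Emits the per-run table and, after a blank line, the aggregate block.
#'
#' @param report A `peak_experiment_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  validate_report(report)
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(report$runs, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  writeLines("", con)
  utils::write.table(report$summary, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
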