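#' Pipeline run configuration
#'
#' A fully serializable description of one end-to-end run: simulate a
#' subject's four-step session, select the frequency couple from the
#' calibration step, train and cross-validate the decoder on the
#' offline recordings, replay the online session against the best fold's
#' model, and summarize against chance. Unknown keys are rejected.
#'
#' @param seed Master integer seed; all stage seeds derive from it.
#' @param fs Sampling rate in Hz.
#' @param profile Named list passed to [make_subject_profile()].
#' @param step1_reps Calibration repetitions per class.
#' @param step3_recordings Number of offline recordings (10 for the full
#'   protocol).
#' @param step3_reps,step4_reps Repetitions per class in the offline and
#'   online steps.
#' @param score_resolution PSD grid spacing (Hz) for frequency scoring.
#' @param outdir Optional directory for the JSON report and artefacts.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, fs = 256, profile = list(),
                       step1_reps = 15L, step3_recordings = 10L,
                       step3_reps = 20L, step4_reps = 20L,
                       score_resolution = 0.025, outdir = NULL) {
  cfg <- list(seed = as.integer(seed), fs = fs, profile = profile,
              step1_reps = as.integer(step1_reps),
              step3_recordings = as.integer(step3_recordings),
              step3_reps = as.integer(step3_reps),
              step4_reps = as.integer(step4_reps),
              score_resolution = score_resolution, outdir = outdir)
  structure(cfg, class = "run_config")
}

#' Restore a run configuration from JSON
#'
#' @param path JSON file written by [run_pipeline()] or by hand; keys
#'   must be a subset of [run_config()]'s arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(run_config, raw)
}

# Stable hash of the configuration (md5 of its canonical JSON); the
# output directory does not influence the identity of a run.
.config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$outdir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE,
                                           digits = NA, null = "null")), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline on one synthetic subject
#'
#' Executes, in order: calibration simulation, filtering, epoching,
#' frequency scoring and couple selection; offline simulation of the
#' imagery recordings, feature extraction and 5-fold temporal
#' cross-validation; online simulation and evaluation under the best
#' fold's model; and the chance-level statistics. Deterministic given
#' the configuration: stage seeds are derived from `config$seed`.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return An object of class `vi_report` (list): `config_hash`,
#'   `couple`, `score_totals`, `cv` summary (fold accuracies, mean, sd,
#'   best fold), `online` (accuracy and confusion matrix), and
#'   `chance` (99%/95% bounds for the offline and online designs). When
#'   `config$outdir` is set, the report is also written as
#'   `report.json`.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  profile <- make_subject_profile(config$seed, config$profile)

  say("[1/5] calibration: simulating + scoring (seed %d)", config$seed + 1L)
  p1 <- protocol_spec(1, reps_per_class = config$step1_reps)
  rec1 <- filter_chain(simulate_recording(p1, profile, seed = config$seed + 1L,
                                          fs = config$fs))
  scores <- score_candidates(extract_epochs(rec1, p1),
                             resolution = config$score_resolution)
  couple <- select_couple(scores)
  say("      selected couple: (%g, %g) Hz", couple[1], couple[2])

  say("[2/5] offline: simulating %d recordings", config$step3_recordings)
  p3 <- protocol_spec(3, couple, reps_per_class = config$step3_reps)
  blocks <- lapply(seq_len(config$step3_recordings), function(i) {
    rec <- filter_chain(simulate_recording(p3, profile,
                                           seed = config$seed + 10L + i,
                                           fs = config$fs,
                                           id = sprintf("offline_%02d", i)))
    build_features(extract_epochs(rec, p3))
  })

  say("[3/5] decoder: 5-fold temporal cross-validation")
  cv <- temporal_cv(blocks)
  model <- select_online_model(cv)
  say("      mean accuracy %.2f%% (sd %.2f), best fold %d",
      cv$mean_accuracy, cv$sd_accuracy, cv$best_fold)

  say("[4/5] online: fixed-sequence session under fold-%d model", cv$best_fold)
  p4 <- protocol_spec(4, couple, reps_per_class = config$step4_reps)
  rec4 <- filter_chain(simulate_recording(p4, profile,
                                          seed = config$seed + 50L,
                                          fs = config$fs, id = "online"))
  online <- evaluate(model, build_features(extract_epochs(rec4, p4)))
  say("      online accuracy %.2f%%", online$accuracy)

  say("[5/5] statistics")
  n_off <- config$step3_reps * config$step3_recordings
  chance <- list(
    offline_99 = chance_upper_bound(n_off, 3, 0.01)$bound,
    offline_95 = chance_upper_bound(n_off, 3, 0.05)$bound,
    online_99 = chance_upper_bound(config$step4_reps, 3, 0.01)$bound,
    online_95 = chance_upper_bound(config$step4_reps, 3, 0.05)$bound)

  report <- structure(list(
    config_hash = .config_hash(config),
    seed = config$seed,
    couple = as.numeric(couple),
    score_totals = as.list(scores$total),
    cv = list(fold_accuracy = cv$accuracy, mean = cv$mean_accuracy,
              sd = cv$sd_accuracy, best_fold = cv$best_fold),
    online = list(accuracy = online$accuracy,
                  classes = rownames(online$confusion),
                  confusion = lapply(seq_len(nrow(online$confusion)),
                                     function(i)
                                       as.numeric(online$confusion[i, ]))),
    chance = chance,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "vi_report")
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    out <- unclass(report)
    out$elapsed_s <- NULL   # keep the written report byte-reproducible
    jsonlite::write_json(out, file.path(config$outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.vi_report <- function(x, ...) {
  cat("<vi_report>\n")
  cat(sprintf("  couple: (%g, %g) Hz\n", x$couple[1], x$couple[2]))
  cat(sprintf("  offline CV: mean %.2f%% (sd %.2f), folds %s\n",
              x$cv$mean, x$cv$sd,
              paste(sprintf("%.1f", x$cv$fold_accuracy), collapse = "/")))
  cat(sprintf("  online: %.2f%% (99%% chance bound %.1f%%)\n",
              x$online$accuracy, x$chance$online_99))
  cat(sprintf("  config %s | %.1f s\n", x$config_hash, x$elapsed_s))
  invisible(x)
}
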