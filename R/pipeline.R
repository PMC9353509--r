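#' Pipeline configuration
#'
#' Every analysis parameter with its conventional default: 20 Hz acquisition;
#' Gaussian rate kernel sd 12.5 ms (window two sigma); event threshold
#' \code{s_min} 0.25 (working band 0.2-0.3, per cell, fixed across sessions);
#' k = 4 neighbours for the Kraskov estimator; 2000 circular shuffles;
#' significance at the 95th null percentile (alpha 0.05); strict occupancy
#' gate at 34\%; strong-dominance win-fraction threshold 0.8; minimum
#' circular shift 5 s.
#'
#' @param frame_rate Hz.
#' @param sigma rate-kernel sd, seconds.
#' @param s_min event-detection threshold (see [detectEvents()]).
#' @param threshold_units \code{"dff"} or \code{"noise"}.
#' @param smooth_window moving-average width, frames.
#' @param k neighbour count for [ksgMI()].
#' @param n_shuffles shuffles for [shuffleNull()].
#' @param alpha significance level (threshold percentile is
#'   \code{1 - alpha}).
#' @param occupancy_threshold strict lower bound on occupancy (default 0.34).
#' @param strong_threshold win fraction for the strong label in
#'   [scoreDominance()].
#' @param min_shift minimum circular shift, seconds.
#' @param seed RNG seed used by [runPipeline()].
#' @return A validated list of class \code{"PipelineConfig"}; serializes
#'   losslessly via [writePipelineConfig()] / [readPipelineConfig()].
#' @export
pipelineConfig <- function(frame_rate = 20, sigma = 0.0125, s_min = 0.25,
                           threshold_units = c("dff", "noise"),
                           smooth_window = 5, k = 4, n_shuffles = 2000,
                           alpha = 0.05, occupancy_threshold = 0.34,
                           strong_threshold = 0.8, min_shift = 5, seed = 1L) {
  threshold_units <- match.arg(threshold_units)
  stopifnot(frame_rate > 0, sigma > 0, s_min > 0, smooth_window >= 1,
            k >= 1, n_shuffles >= 1, alpha > 0, alpha < 1,
            occupancy_threshold >= 0, occupancy_threshold < 1,
            strong_threshold > 0, strong_threshold <= 1, min_shift >= 0)
  cfg <- list(frame_rate = as.numeric(frame_rate), sigma = as.numeric(sigma),
              s_min = as.numeric(s_min), threshold_units = threshold_units,
              smooth_window = as.integer(smooth_window), k = as.integer(k),
              n_shuffles = as.integer(n_shuffles), alpha = as.numeric(alpha),
              occupancy_threshold = as.numeric(occupancy_threshold),
              strong_threshold = as.numeric(strong_threshold),
              min_shift = as.numeric(min_shift), seed = as.integer(seed))
  class(cfg) <- "PipelineConfig"
  cfg
}

#' @rdname pipelineConfig
#' @param config a \code{PipelineConfig}.
#' @param file path for the JSON serialization.
#' @export
writePipelineConfig <- function(config, file) {
  jsonlite::write_json(unclass(config), file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname pipelineConfig
#' @export
readPipelineConfig <- function(file) {
  do.call(pipelineConfig, jsonlite::read_json(file, simplifyVector = TRUE))
}

#' Validate an input bundle
#'
#' Collects (rather than fail-fast) schema and consistency problems of an
#' interchange directory: required files, behavior vocabulary, monotone bout
#' times, winner/loser sanity, annotations within the recorded trace length.
#'
#' @param dir directory in the [writeDyadExperiment()] layout.
#' @return \code{data.frame} report with columns \code{file}, \code{check},
#'   \code{ok}, \code{detail}; an empty/all-\code{ok} report means a
#'   consistent bundle.
#' @export
validateInputs <- function(dir) {
  rep <- list()
  add <- function(file, check, ok, detail = "") {
    rep[[length(rep) + 1]] <<- data.frame(file = file, check = check, ok = ok,
                                          detail = detail,
                                          stringsAsFactors = FALSE)
  }
  meta_f <- file.path(dir, "dataset.json")
  if (!file.exists(meta_f)) {
    add("dataset.json", "exists", FALSE, "missing")
    out <- do.call(rbind, rep)
    return(out[!out$ok, , drop = FALSE])
  }
  meta <- jsonlite::read_json(meta_f, simplifyVector = TRUE)
  trials <- NULL
  tf <- file.path(dir, "trials.csv")
  if (!file.exists(tf)) add("trials.csv", "exists", FALSE, "missing")
  else trials <- tryCatch(readTrialRecords(tf), error = function(e) {
    add("trials.csv", "schema", FALSE, conditionMessage(e)); NULL
  })
  bf <- file.path(dir, "bouts.csv")
  if (!file.exists(bf)) {
    add("bouts.csv", "exists", FALSE, "missing")
  } else {
    raw <- read.csv(bf, stringsAsFactors = FALSE)
    lab_ok <- tryCatch({normalizeBehavior(raw$behavior); TRUE},
                       error = function(e) {
      bad_rows <- which(!toupper(trimws(gsub("_", " ", raw$behavior))) %in%
                          ethogramLevels())
      add("bouts.csv", "behavior_vocabulary", FALSE,
          paste("unknown label at row(s):", paste(bad_rows, collapse = ",")))
      FALSE
    })
    mono <- which(!(raw$stop_s > raw$start_s))
    if (length(mono) > 0)
      add("bouts.csv", "monotone_times", FALSE,
          paste("stop <= start at row(s):", paste(mono, collapse = ",")))
    if (lab_ok && length(mono) == 0)
      tryCatch(validateBouts(readBoutTable(bf, trials = trials)),
               error = function(e)
                 add("bouts.csv", "overlap", FALSE, conditionMessage(e)))
  }
  if (!is.null(trials)) {
    for (s in seq_len(meta$n_sessions %||% 0)) {
      trf <- file.path(dir, sprintf("traces_s%d.csv", s))
      if (!file.exists(trf)) {
        add(basename(trf), "exists", FALSE, "missing")
        next
      }
      tm <- readTraceMatrix(trf)
      tr_s <- trials[trials$session == s, ]
      if (nrow(tr_s) > 0) {
        t_end <- max(tr_s$start_s + tr_s$latency_s)
        n_need <- ceiling(t_end * tm$frame_rate)
        if (n_need > ncol(tm$traces))
          add(basename(trf), "annotation_within_trace", FALSE,
              sprintf("annotations run to %.1f s but trace has %d frames",
                      t_end, ncol(tm$traces)))
      }
    }
  }
  if (length(rep) == 0)
    return(data.frame(file = character(0), check = character(0),
                      ok = logical(0), detail = character(0)))
  out <- do.call(rbind, rep)
  out[!out$ok, , drop = FALSE]
}

#' Run the full analysis pipeline
#'
#' End-to-end driver: event detection, behavior statistics, interanimal
#' co-occurrence, dominance scoring, tuning classification, cell metrics,
#' consistency and population activity, written as tidy CSV/JSON outputs with
#' a reproducibility manifest (configuration, package version, output
#' checksums). Deterministic for a fixed configuration seed.
#'
#' @param input a \linkS4class{DyadExperiment} or a directory in the
#'   [writeDyadExperiment()] layout.
#' @param config a [pipelineConfig()].
#' @param out_dir output directory, created if needed; \code{NULL} to skip
#'   writing files.
#' @return Invisibly, a list with all result tables (\code{events},
#'   \code{behavior_stats}, \code{cooccurrence}, \code{dominance},
#'   \code{classification} (the [classifyPopulation()] output),
#'   \code{cell_metrics}, \code{consistency}, \code{population_activity},
#'   \code{manifest}).
#' @export
runPipeline <- function(input, config = pipelineConfig(), out_dir = NULL) {
  dex <- if (is.character(input)) {
    bad <- validateInputs(input)
    if (nrow(bad) > 0)
      stop("input validation failed:\n",
           paste(sprintf("  %s [%s]: %s", bad$file, bad$check, bad$detail),
                 collapse = "\n"))
    readDyadExperiment(input)
  } else input
  stopifnot(is(dex, "DyadExperiment"))
  set.seed(config$seed)
  events <- detectEvents(dex, s_min = config$s_min,
                         threshold_units = config$threshold_units,
                         smooth_window = config$smooth_window)
  stats <- behaviorStats(boutTable(dex))
  coocc <- dyadCooccurrence(boutTable(dex), animals = animalIds(dex),
                            frame_rate = frameRate(dex),
                            trials = trialRecords(dex))
  dom <- scoreDominance(trialRecords(dex),
                        strong_threshold = config$strong_threshold)
  pop <- classifyPopulation(dex, events, config = config)
  met <- cellMetrics(dex, events, pop$classifications)
  cons <- cellConsistency(pop$classifications)
  pact <- populationActivity(dex, dom)
  res <- list(events = events, behavior_stats = stats, cooccurrence = coocc,
              dominance = dom, classification = pop, cell_metrics = met,
              consistency = cons, population_activity = pact)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, name) {
      f <- file.path(out_dir, name)
      write.csv(df, f, row.names = FALSE)
      f
    }
    files <- c(
      wr(events, "events.csv"),
      wr(stats, "behavior_stats.csv"),
      wr(as.data.frame(coocc), "cooccurrence.csv"),
      wr(pop$classifications, "classifications.csv"),
      wr(pop$scores, "mi_scores.csv"),
      wr(met, "cell_metrics.csv"),
      wr(cons$overall, "consistency_overall.csv"),
      wr(cons$per_behavior, "consistency_per_behavior.csv"),
      wr(pact$by_status, "population_by_status.csv"),
      wr(pact$by_outcome, "population_by_outcome.csv"))
    summary_f <- file.path(out_dir, "summary.json")
    jsonlite::write_json(list(
      percentages = pop$percentages,
      unique_by_behavior = pop$unique_by_behavior,
      dominance = list(winner = dom$winner, strength = dom$strength,
                       win_fraction = dom$win_fraction, status = dom$status)),
      summary_f, auto_unbox = TRUE, digits = NA, na = "null")
    files <- c(files, summary_f)
    manifest <- list(package = "dyadtune",
                     version = as.character(packageVersion("dyadtune")),
                     config = unclass(config),
                     outputs = as.list(tools::md5sum(files)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    res$manifest <- manifest
  }
  invisible(res)
}
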