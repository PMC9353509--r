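#' Within-session reliability of a cell for a behavior
#'
#' The percentage of the behavior's within-session bouts in which the cell
#' fired at least one event: \code{100 * occupancy} exactly (shared code
#' path with [occupancy()]).
#'
#' @param event_frames 0-based event frames.
#' @param bout_intervals half-open frame intervals (\code{start}, \code{end}),
#'   one row per bout.
#' @return Reliability in percent, \code{[0, 100]}.
#' @examples
#' iv <- data.frame(start = seq(0, 40, 10), end = seq(5, 45, 10))
#' cellReliability(c(2L, 12L, 41L), iv) # 60
#' @export
cellReliability <- function(event_frames, bout_intervals) {
  100 * occupancy(event_frames, bout_intervals)
}

#' Event rate of a cell during a behavior
#'
#' Number of events falling inside the behavior's bouts divided by the total
#' bout duration in seconds.
#'
#' @param event_frames 0-based event frames.
#' @param bout_intervals half-open frame intervals (\code{start}, \code{end}).
#' @param frame_rate Hz.
#' @return Events per second.
#' @examples
#' iv <- data.frame(start = 0, end = 400) # 20 s at 20 Hz
#' cellEventRate(c(10L, 100L, 250L), iv) # 0.15 events/s
#' @export
cellEventRate <- function(event_frames, bout_intervals, frame_rate = 20) {
  dur <- sum(bout_intervals$end - bout_intervals$start) / frame_rate
  if (dur <= 0) stop("total bout duration must be positive")
  event_frames <- as.integer(event_frames)
  n_in <- sum(vapply(event_frames, function(f)
    any(f >= bout_intervals$start & f < bout_intervals$end), logical(1)))
  n_in / dur
}

#' Cross-session consistency of cell classifications
#'
#' For each cell registered in at least two analyzed sessions: the overall
#' consistency is the percentage of its sessions in which it was classified
#' as encoding (classes \code{unique-own}, \code{unique-other},
#' \code{coincident}, \code{mixed}); the per-behavior consistency is the
#' percentage of its sessions in which that particular target was among the
#' encoded behaviors. A cell can thus be perfectly consistent overall while
#' the specific behavior it encodes changes every session.
#'
#' @param classifications output of [classifyCells()] /
#'   [classifyPopulation()] covering multiple sessions.
#' @param encoding_classes classes counted as "encoding".
#' @return List: \code{overall} (\code{cell_id}, \code{n_sessions},
#'   \code{n_encoding}, \code{consistency_pct}), \code{per_behavior}
#'   (\code{cell_id}, \code{target}, \code{n_sessions}, \code{n_with},
#'   \code{consistency_pct}), \code{excluded} (single-session cell ids).
#' @export
cellConsistency <- function(classifications,
                            encoding_classes = c("unique-own", "unique-other",
                                                 "coincident", "mixed")) {
  ns <- table(classifications$cell_id)
  excluded <- names(ns)[ns < 2]
  if (length(excluded) > 0)
    message(length(excluded), " single-session cell(s) excluded from consistency")
  keep <- classifications[classifications$cell_id %in% names(ns)[ns >= 2], ]
  overall <- list(); per_beh <- list()
  for (id in unique(keep$cell_id)) {
    cc <- keep[keep$cell_id == id, ]
    n_tot <- nrow(cc)
    enc <- cc$class %in% encoding_classes
    overall[[length(overall) + 1]] <- data.frame(
      cell_id = id, n_sessions = n_tot, n_encoding = sum(enc),
      consistency_pct = 100 * mean(enc), stringsAsFactors = FALSE)
    targets <- unique(unlist(strsplit(cc$behaviors[enc], ";", fixed = TRUE)))
    targets <- targets[nzchar(targets)]
    for (tg in targets) {
      with_tg <- vapply(strsplit(cc$behaviors, ";", fixed = TRUE),
                        function(v) tg %in% v, logical(1)) & enc
      per_beh[[length(per_beh) + 1]] <- data.frame(
        cell_id = id, target = tg, n_sessions = n_tot, n_with = sum(with_tg),
        consistency_pct = 100 * sum(with_tg) / n_tot, stringsAsFactors = FALSE)
    }
  }
  list(overall = if (length(overall)) do.call(rbind, overall) else
         data.frame(cell_id = character(0), n_sessions = integer(0),
                    n_encoding = integer(0), consistency_pct = numeric(0)),
       per_behavior = if (length(per_beh)) do.call(rbind, per_beh) else
         data.frame(cell_id = character(0), target = character(0),
                    n_sessions = integer(0), n_with = integer(0),
                    consistency_pct = numeric(0)),
       excluded = excluded)
}

#' Tidy reliability and event-rate table for encoding cells
#'
#' For every encoding classification (unique/mixed cells and their encoded
#' behaviors), computes the within-session reliability and event rate against
#' that behavior's bouts.
#'
#' @param dex a \linkS4class{DyadExperiment}.
#' @param events event table (\code{cell_id}, \code{session}, \code{frame}).
#' @param classifications output of [classifyCells()] covering the sessions
#'   of interest.
#' @return \code{data.frame}: \code{session}, \code{cell_id},
#'   \code{target_animal}, \code{behavior}, \code{n_bouts},
#'   \code{reliability_pct}, \code{event_rate}.
#' @export
cellMetrics <- function(dex, events, classifications) {
  fr <- frameRate(dex)
  out <- list()
  enc <- classifications[classifications$class %in%
                           c("unique-own", "unique-other", "mixed",
                             "mixed-across-animals", "nonspecific"), ]
  for (i in seq_len(nrow(enc))) {
    s <- enc$session[i]; id <- enc$cell_id[i]
    it <- .inTrialData(sessions(dex)[[s]])
    ev0 <- events$frame[events$session == s & events$cell_id == id]
    pos <- .eventsToInTrial(ev0, it$idx)
    for (tg in strsplit(enc$behaviors[i], ";", fixed = TRUE)[[1]]) {
      parts <- strsplit(tg, ":", fixed = TRUE)[[1]]
      labs <- if (parts[1] == "own") it$own else it$other
      runs <- .flagRuns(labs == parts[2], it$trial)
      if (nrow(runs) == 0) next
      out[[length(out) + 1]] <- data.frame(
        session = s, cell_id = id, target_animal = parts[1],
        behavior = parts[2], n_bouts = nrow(runs),
        reliability_pct = cellReliability(pos, runs),
        event_rate = cellEventRate(pos, runs, fr), stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(session = integer(0), cell_id = character(0),
               target_animal = character(0), behavior = character(0),
               n_bouts = integer(0), reliability_pct = numeric(0),
               event_rate = numeric(0))
}

#' Normalized mean population activity by dominance context
#'
#' Per session: each cell's dF/F is min-max normalized over the session's
#' in-trial frames (a zero-range trace is defined as 0, with a warning), then
#' averaged across cells frame by frame. The per-frame series is annotated
#' with the session's dominance context — whether the imaged animal is the
#' overall winner and whether it won each individual trial — and summarized
#' by group.
#'
#' @param dex a \linkS4class{DyadExperiment}.
#' @param dominance optional [scoreDominance()] result (computed from the
#'   trial records when \code{NULL}).
#' @return List: \code{frames} (per in-trial frame: \code{session},
#'   \code{trial}, \code{time_s}, \code{activity} in \code{[0, 1]},
#'   \code{imaged_animal}, \code{imaged_is_winner}, \code{trial_won},
#'   \code{strength}), \code{by_status} (mean activity by strength x
#'   winner/loser), \code{by_outcome} (mean activity on winning vs losing
#'   trials of the imaged animal).
#' @export
populationActivity <- function(dex, dominance = NULL) {
  if (is.null(dominance)) dominance <- scoreDominance(trialRecords(dex))
  trials <- trialRecords(dex)
  out <- list()
  for (s in seq_along(sessions(dex))) {
    se <- sessions(dex)[[s]]
    it <- .inTrialData(se)
    if (length(it$idx) == 0) next
    m <- assay(se, "dff")[, it$idx, drop = FALSE]
    norm <- t(apply(m, 1, function(v) {
      rg <- range(v)
      if (diff(rg) == 0) {
        warning("zero-range trace during normalization; defined as 0",
                call. = FALSE)
        rep(0, length(v))
      } else (v - rg[1]) / diff(rg)
    }))
    act <- colMeans(norm)
    imaged <- imagedAnimal(dex, s)
    tw <- trials$winner_id[match(paste(s, it$trial),
                                 paste(trials$session, trials$trial))]
    out[[length(out) + 1]] <- data.frame(
      session = s, trial = it$trial,
      time_s = colData(se)$time_s[it$idx], activity = act,
      imaged_animal = imaged,
      imaged_is_winner = !is.na(dominance$winner) & imaged == dominance$winner,
      trial_won = tw == imaged, strength = dominance$strength,
      stringsAsFactors = FALSE)
  }
  frames <- do.call(rbind, out)
  rownames(frames) <- NULL
  by_status <- aggregate(activity ~ strength + imaged_is_winner, frames, mean)
  by_outcome <- aggregate(activity ~ trial_won, frames, mean)
  list(frames = frames, by_status = by_status, by_outcome = by_outcome)
}
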