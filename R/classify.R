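## in-trial frame extraction for one session: 1-based frame indices plus the
## own/other labels and trial ids over the concatenated in-trial series
.inTrialData <- function(se) {
  cd <- colData(se)
  idx <- which(!is.na(cd$trial) & !is.na(cd$behavior_own) &
                 !is.na(cd$behavior_other))
  list(idx = idx, own = cd$behavior_own[idx], other = cd$behavior_other[idx],
       trial = cd$trial[idx])
}

## runs of `flag` within trials, as 0-based half-open intervals over the
## concatenated in-trial series; these runs are the behavioral occurrences
.flagRuns <- function(flag, trial) {
  r <- rle(paste(trial, flag))
  stops <- cumsum(r$lengths)
  starts <- c(0L, stops[-length(stops)])
  on <- grepl("TRUE$", r$values)
  data.frame(start = starts[on], end = stops[on])
}

## map 0-based session event frames onto 0-based concatenated in-trial
## positions; events outside trials are dropped
.eventsToInTrial <- function(event_frames0, idx) {
  pos <- match(event_frames0 + 1L, idx)
  sort(pos[!is.na(pos)]) - 1L
}

#' Mutual-information tuning scores for one session
#'
#' Scores every cell of a session against the twelve marginal targets (six
#' behaviors of the imaged animal, six of its partner) and, for cells with no
#' significant marginal target, against the joint own-by-other behavior
#' conjunctions. For each target: the occupancy (fraction of the behavior's
#' bouts containing at least one event), the Kraskov MIS between the cell's
#' Gaussian-convolved event rate and the behavior indicator over in-trial
#' frames, and — for targets passing the strict occupancy gate — the
#' circular-shuffle null threshold. A target is significant when its MIS
#' exceeds the null's \code{1 - alpha} percentile \emph{and} occupancy
#' exceeds \code{occupancy_threshold} (strictly). Marginal targets are each
#' tested at \code{alpha}; the joint pass is Sidak-corrected across the
#' conjunctions a cell is actually tested on, so the chance of a spurious
#' coincident call stays near \code{alpha} despite up to 36 candidate pairs.
#'
#' Only in-trial frames are analyzed; intertrial data are excluded.
#'
#' @param dex a \linkS4class{DyadExperiment}.
#' @param events event table with columns \code{cell_id}, \code{session},
#'   \code{frame} (e.g. from [detectEvents()] or the simulator's ground
#'   truth).
#' @param session 1-based session index.
#' @param config a [pipelineConfig()] supplying \code{sigma}, \code{k},
#'   \code{n_shuffles}, \code{alpha}, \code{occupancy_threshold},
#'   \code{min_shift}.
#' @param joint test joint conjunctions for cells without significant
#'   marginals (default TRUE).
#' @return \code{data.frame}, one row per cell x target: \code{session},
#'   \code{cell_id}, \code{target_animal} (\code{own}/\code{other}/
#'   \code{joint}), \code{behavior1}, \code{behavior2} (partner behavior for
#'   joint targets, else NA), \code{n_bouts}, \code{occupancy}, \code{mis},
#'   \code{null_threshold}, \code{n_shuffles}, \code{significant}.
#' @export
tuningScores <- function(dex, events, session, config = pipelineConfig(),
                         joint = TRUE) {
  se <- sessions(dex)[[session]]
  fr <- frameRate(dex)
  it <- .inTrialData(se)
  n <- length(it$idx)
  if (n == 0) stop("session ", session, " has no in-trial frames")
  lev <- ethogramLevels()
  ids <- rownames(se)
  ev_s <- events[events$session == session, , drop = FALSE]
  rows <- list()
  # MIS and occupancy for one cell x target; the null threshold is filled in
  # afterwards, batched per cell so every eligible target shares the same
  # rotations (and one sort per shuffle)
  scoreTarget <- function(cell_id, pos, rate, flag, animal, b1, b2) {
    runs <- .flagRuns(flag, it$trial)
    if (nrow(runs) == 0) return(NULL)
    occ <- if (length(pos) > 0) occupancy(pos, runs) else 0
    # a cell with no in-trial events carries no information about anything;
    # a behavior filling every in-trial frame carries none either
    mis <- if (length(pos) == 0 || all(flag)) 0
           else ksgMI(rate, flag, k = config$k)
    list(row = data.frame(session = session, cell_id = cell_id,
                          target_animal = animal, behavior1 = b1,
                          behavior2 = b2, n_bouts = nrow(runs),
                          occupancy = occ, mis = mis,
                          null_threshold = NA_real_,
                          n_shuffles = config$n_shuffles,
                          significant = FALSE, stringsAsFactors = FALSE),
         flag = flag,
         testable = length(pos) > 0 && !all(flag) &&
           occ > config$occupancy_threshold)
  }
  # run the nulls for the testable targets and mark significance
  applyNulls <- function(targets, pos, alpha) {
    test <- which(vapply(targets, `[[`, logical(1), "testable"))
    if (length(test) > 0) {
      thr <- .nullThresholdsMulti(pos, lapply(targets[test], `[[`, "flag"),
                                  n, n_shuffles = config$n_shuffles,
                                  sigma = config$sigma, frame_rate = fr,
                                  min_shift = config$min_shift,
                                  k = config$k, alpha = alpha)
      for (i in seq_along(test)) {
        targets[[test[i]]]$row$null_threshold <- thr[i]
        targets[[test[i]]]$row$significant <-
          targets[[test[i]]]$row$mis > thr[i]
      }
    }
    do.call(rbind, lapply(targets, `[[`, "row"))
  }
  for (id in ids) {
    ev0 <- ev_s$frame[ev_s$cell_id == id]
    pos <- .eventsToInTrial(ev0, it$idx)
    rate <- convolveRate(pos, n, sigma = config$sigma, frame_rate = fr)
    marg <- list()
    for (an in c("own", "other")) {
      labs <- if (an == "own") it$own else it$other
      for (b in lev) {
        t <- scoreTarget(id, pos, rate, labs == b, an, b, NA_character_)
        if (!is.null(t)) marg[[length(marg) + 1]] <- t
      }
    }
    marg_df <- applyNulls(marg, pos, config$alpha)
    rows[[length(rows) + 1]] <- marg_df
    if (joint && length(pos) > 0 && !any(marg_df$significant)) {
      # the joint pass is Sidak-corrected across the m conjunctions the cell
      # is actually tested on: testing up to 36 pairs at the marginal alpha
      # would inflate the coincident false-positive rate far above alpha
      cand <- list()
      for (a in lev) {
        fa <- it$own == a
        if (!any(fa)) next
        for (b in lev) {
          fl <- fa & it$other == b
          if (!any(fl)) next
          t <- scoreTarget(id, pos, rate, fl, "joint", a, b)
          if (!is.null(t)) cand[[length(cand) + 1]] <- t
        }
      }
      if (length(cand) > 0) {
        m <- sum(vapply(cand, `[[`, logical(1), "testable"))
        alpha_j <- if (m > 0) 1 - (1 - config$alpha)^(1 / m) else config$alpha
        rows[[length(rows) + 1]] <- applyNulls(cand, pos, alpha_j)
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Classify cells from their tuning scores
#'
#' Applies the taxonomy to a session's [tuningScores()]: with \code{S} the
#' number of significant marginal targets, \code{S = 1} gives
#' \code{unique-own} or \code{unique-other} (per the target's animal);
#' \code{S = 2} within a single animal gives \code{mixed}; \code{S = 2}
#' across the two animals is reported separately as
#' \code{mixed-across-animals}; \code{S >= 3} gives \code{nonspecific};
#' \code{S = 0} with at least one significant joint conjunction gives
#' \code{coincident}; otherwise \code{untuned}. Cells whose encoded behavior
#' includes STILLNESS are flagged uninterpretable but remain counted.
#'
#' @param scores output of [tuningScores()] for one session.
#' @return \code{data.frame}, one row per cell: \code{session},
#'   \code{cell_id}, \code{class}, \code{behaviors}
#'   (\code{;}-separated \code{animal:behavior} targets, or
#'   \code{own_behavior|other_behavior} conjunctions), \code{n_significant},
#'   \code{stillness_flag}.
#' @export
classifyCells <- function(scores) {
  out <- list()
  for (id in unique(scores$cell_id)) {
    sc <- scores[scores$cell_id == id, ]
    marg <- sc[sc$target_animal %in% c("own", "other"), ]
    jnt <- sc[sc$target_animal == "joint", ]
    sig <- marg[marg$significant, ]
    S <- nrow(sig)
    beh <- character(0)
    if (S == 1) {
      cls <- if (sig$target_animal == "own") "unique-own" else "unique-other"
      beh <- paste0(sig$target_animal, ":", sig$behavior1)
    } else if (S == 2) {
      cls <- if (length(unique(sig$target_animal)) == 1) "mixed"
             else "mixed-across-animals"
      beh <- paste0(sig$target_animal, ":", sig$behavior1)
    } else if (S >= 3) {
      cls <- "nonspecific"
      beh <- paste0(sig$target_animal, ":", sig$behavior1)
    } else {
      jsig <- jnt[jnt$significant, ]
      if (nrow(jsig) > 0) {
        cls <- "coincident"
        beh <- paste0(jsig$behavior1, "|", jsig$behavior2)
      } else {
        cls <- "untuned"
      }
    }
    out[[length(out) + 1]] <- data.frame(
      session = sc$session[1], cell_id = id, class = cls,
      behaviors = paste(beh, collapse = ";"), n_significant = S,
      stillness_flag = any(grepl("STILLNESS", beh)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify the whole population across sessions
#'
#' Runs [tuningScores()] and [classifyCells()] for every (or selected)
#' session and summarizes category percentages, the unique-cell breakdown by
#' behavior and own/other, and the dyad's dominance context.
#'
#' @param dex a \linkS4class{DyadExperiment}.
#' @param events event table (\code{cell_id}, \code{session}, \code{frame});
#'   computed by [detectEvents()] when \code{NULL}.
#' @param which_sessions sessions to analyze (default all).
#' @param config a [pipelineConfig()].
#' @return List: \code{classifications} (per session x cell), \code{scores},
#'   \code{percentages} (per class, over all cell x session
#'   classifications), \code{unique_by_behavior}, \code{dominance}.
#' @export
classifyPopulation <- function(dex, events = NULL, which_sessions = NULL,
                               config = pipelineConfig()) {
  if (is.null(events))
    events <- detectEvents(dex, s_min = config$s_min,
                           smooth_window = config$smooth_window)
  if (is.null(which_sessions)) which_sessions <- seq_along(sessions(dex))
  cls <- list(); sco <- list()
  for (s in which_sessions) {
    scores <- tuningScores(dex, events, s, config = config)
    sco[[length(sco) + 1]] <- scores
    cls[[length(cls) + 1]] <- classifyCells(scores)
  }
  classifications <- do.call(rbind, cls)
  scores <- do.call(rbind, sco)
  n_tot <- nrow(classifications)
  tab <- table(classifications$class)
  percentages <- data.frame(class = names(tab), n = as.integer(tab),
                            pct = 100 * as.integer(tab) / n_tot,
                            stringsAsFactors = FALSE)
  uni <- classifications[classifications$class %in%
                           c("unique-own", "unique-other"), ]
  unique_by_behavior <- if (nrow(uni) > 0) {
    parts <- strsplit(uni$behaviors, ":", fixed = TRUE)
    d <- data.frame(target_animal = vapply(parts, `[`, "", 1),
                    behavior = vapply(parts, `[`, "", 2),
                    stringsAsFactors = FALSE)
    agg <- as.data.frame(table(d$target_animal, d$behavior),
                         stringsAsFactors = FALSE)
    names(agg) <- c("target_animal", "behavior", "n")
    agg <- agg[agg$n > 0, ]
    agg$pct <- 100 * agg$n / n_tot
    rownames(agg) <- NULL
    agg
  } else {
    data.frame(target_animal = character(0), behavior = character(0),
               n = integer(0), pct = numeric(0))
  }
  dom <- scoreDominance(trialRecords(dex),
                        strong_threshold = config$strong_threshold)
  list(classifications = classifications, scores = scores,
       percentages = percentages, unique_by_behavior = unique_by_behavior,
       dominance = dom)
}
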