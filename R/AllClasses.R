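#' DyadExperiment: paired-animal tube-test imaging container
#'
#' Holds one tube-test dyad across sessions: per-session
#' \linkS4class{SummarizedExperiment}s with the imaged animal's dF/F traces
#' (assay \code{"dff"}, cells x frames) and frame-level annotations in
#' \code{colData} (\code{frame}, \code{time_s}, \code{trial},
#' \code{behavior_own}, \code{behavior_other}); the dyad's bout table and trial
#' records; and, for synthetic data, the planted ground truth.
#'
#' \code{colData} frames outside any trial carry \code{NA} in \code{trial} and
#' in both behavior columns. Frame indices are 0-based and frames are half-open
#' \code{[frame/frame_rate, (frame+1)/frame_rate)} intervals.
#'
#' @slot sessions a [S4Vectors::SimpleList] of
#'   \linkS4class{SummarizedExperiment}, one per session in order.
#' @slot bouts \code{data.frame} with columns \code{animal_id},
#'   \code{behavior}, \code{start_s}, \code{stop_s} (trial-relative seconds),
#'   \code{trial}, \code{session}.
#' @slot trials \code{data.frame} with columns \code{session}, \code{trial},
#'   \code{start_s} (session-relative trial onset), \code{winner_id},
#'   \code{loser_id}, \code{latency_s}.
#' @slot animals length-2 character vector of animal identifiers.
#' @slot truth list; empty for real data, otherwise the planted ground truth
#'   (see [simulateDyad()]).
#'
#' @aliases DyadExperiment-class
#' @export
setClass("DyadExperiment",
  slots = c(
    sessions = "SimpleList",
    bouts = "data.frame",
    trials = "data.frame",
    animals = "character",
    truth = "list"
  )
)

.requiredColData <- c("frame", "time_s", "trial", "behavior_own", "behavior_other")
.requiredBoutCols <- c("animal_id", "behavior", "start_s", "stop_s", "trial", "session")
.requiredTrialCols <- c("session", "trial", "start_s", "winner_id", "loser_id", "latency_s")

setValidity("DyadExperiment", function(object) {
  msg <- character(0)
  if (length(object@animals) != 2L || anyDuplicated(object@animals))
    msg <- c(msg, "animals must be two distinct identifiers")
  if (!all(.requiredBoutCols %in% names(object@bouts)))
    msg <- c(msg, paste("bouts must have columns:",
                        paste(.requiredBoutCols, collapse = ", ")))
  if (!all(.requiredTrialCols %in% names(object@trials)))
    msg <- c(msg, paste("trials must have columns:",
                        paste(.requiredTrialCols, collapse = ", ")))
  fr <- NA_real_
  for (i in seq_along(object@sessions)) {
    se <- object@sessions[[i]]
    if (!is(se, "SummarizedExperiment")) {
      msg <- c(msg, sprintf("session %d is not a SummarizedExperiment", i))
      next
    }
    if (!"dff" %in% assayNames(se))
      msg <- c(msg, sprintf("session %d lacks a 'dff' assay", i))
    miss <- setdiff(.requiredColData, names(colData(se)))
    if (length(miss) > 0)
      msg <- c(msg, sprintf("session %d colData lacks: %s", i,
                            paste(miss, collapse = ", ")))
    fri <- metadata(se)$frame_rate
    if (is.null(fri) || !is.numeric(fri) || fri <= 0) {
      msg <- c(msg, sprintf("session %d has no positive frame_rate metadata", i))
    } else if (is.na(fr)) {
      fr <- fri
    } else if (fri != fr) {
      msg <- c(msg, "frame_rate differs across sessions")
    }
    ia <- metadata(se)$imaged_animal
    if (is.null(ia) || !(ia %in% object@animals))
      msg <- c(msg, sprintf("session %d imaged_animal not among dyad animals", i))
  }
  if (length(msg) > 0) msg else TRUE
})

#' Construct a DyadExperiment
#'
#' @param sessions list (or [S4Vectors::SimpleList]) of per-session
#'   \linkS4class{SummarizedExperiment}s; see
#'   \linkS4class{DyadExperiment} for the required assay/colData/metadata.
#' @param bouts,trials the dyad's bout table and trial records (see
#'   \linkS4class{DyadExperiment}).
#' @param animals length-2 character vector of animal ids.
#' @param truth optional planted ground truth list (synthetic data only).
#' @return A validated \linkS4class{DyadExperiment}.
#' @export
DyadExperiment <- function(sessions, bouts, trials, animals, truth = list()) {
  if (!is(sessions, "SimpleList")) sessions <- SimpleList(as.list(sessions))
  obj <- new("DyadExperiment", sessions = sessions, bouts = bouts,
             trials = trials, animals = as.character(animals), truth = truth)
  validObject(obj)
  obj
}

setMethod("show", "DyadExperiment", function(object) {
  ns <- length(object@sessions)
  nc <- if (ns > 0) nrow(object@sessions[[1L]]) else 0L
  cat(sprintf("DyadExperiment: %s vs %s\n", object@animals[1L], object@animals[2L]))
  cat(sprintf("  %d session(s), %d trial(s), %d bout row(s)\n",
              ns, nrow(object@trials), nrow(object@bouts)))
  if (ns > 0) {
    fr <- metadata(object@sessions[[1L]])$frame_rate
    cat(sprintf("  frame rate %g Hz; session 1: %d cell(s) x %d frame(s), imaged %s\n",
                fr, nc, ncol(object@sessions[[1L]]),
                metadata(object@sessions[[1L]])$imaged_animal))
  }
  if (length(object@truth) > 0)
    cat("  synthetic: ground truth attached\n")
  invisible(NULL)
})
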