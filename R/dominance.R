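#' Score dominance across tube-test trials
#'
#' Tallies trial wins per animal and per session. The overall winner is the
#' animal with most trial wins; dominance is \code{"strong"} when that animal
#' wins at least \code{strong_threshold} of all trials \emph{and} wins the
#' majority of trials in every session, otherwise \code{"moderate"}. An exact
#' overall tie yields status \code{"tied"} with no strength label.
#'
#' @param trials trial records: \code{data.frame} with columns \code{session},
#'   \code{trial}, \code{winner_id} (and optionally \code{loser_id}).
#' @param strong_threshold minimum overall win fraction for the
#'   \code{"strong"} label (default 0.8).
#' @return A list of class \code{"DominanceSummary"}: \code{per_session}
#'   (wins per animal per session), \code{wins} (total per animal),
#'   \code{winner}, \code{loser}, \code{win_fraction}, \code{strength}
#'   (\code{"strong"}, \code{"moderate"} or \code{NA}), \code{status}
#'   (\code{"decided"} or \code{"tied"}).
#' @examples
#' tr <- data.frame(session = rep(1:2, each = 5), trial = rep(1:5, 2),
#'                  winner_id = c(rep("A", 5), c("A", "A", "B", "A", "A")))
#' scoreDominance(tr)
#' @export
scoreDominance <- function(trials, strong_threshold = 0.8) {
  stopifnot(nrow(trials) >= 1, strong_threshold > 0, strong_threshold <= 1)
  animals <- sort(unique(as.character(trials$winner_id)))
  if ("loser_id" %in% names(trials))
    animals <- sort(unique(c(animals, as.character(trials$loser_id))))
  wins <- table(factor(trials$winner_id, levels = animals))
  per_session <- as.data.frame.matrix(
    table(trials$session, factor(trials$winner_id, levels = animals)))
  total <- nrow(trials)
  mx <- max(wins)
  top <- names(wins)[wins == mx]
  if (length(top) > 1) {
    out <- list(per_session = per_session, wins = wins, winner = NA_character_,
                loser = NA_character_, win_fraction = mx / total,
                strength = NA_character_, status = "tied",
                strong_threshold = strong_threshold)
    class(out) <- "DominanceSummary"
    return(out)
  }
  winner <- top
  loser <- if (length(animals) == 2) setdiff(animals, winner) else NA_character_
  frac <- as.numeric(wins[winner]) / total
  sess_major <- all(per_session[[winner]] > rowSums(per_session) / 2)
  strength <- if (frac >= strong_threshold && sess_major) "strong" else "moderate"
  out <- list(per_session = per_session, wins = wins, winner = winner,
              loser = loser, win_fraction = frac, strength = strength,
              status = "decided", strong_threshold = strong_threshold)
  class(out) <- "DominanceSummary"
  out
}

#' @export
print.DominanceSummary <- function(x, ...) {
  if (x$status == "tied") {
    cat(sprintf("DominanceSummary: tied (win fraction %.2f)\n", x$win_fraction))
  } else {
    cat(sprintf("DominanceSummary: %s dominates %s (%s, win fraction %.2f)\n",
                x$winner, x$loser, x$strength, x$win_fraction))
  }
  invisible(x)
}
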