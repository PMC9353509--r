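#' Per-behavior frequency and normalized duration
#'
#' For each animal and session: the number of bouts of each behavior
#' (frequency per session, the unit shown in ethogram bar summaries) and the
#' total time in that behavior divided by the animal's total in-trial time
#' (normalized duration; sums to 1 across behaviors).
#'
#' @param bouts a bout table (see [readBoutTable()]).
#' @return Tidy \code{data.frame}: \code{session}, \code{animal_id},
#'   \code{behavior}, \code{n_bouts}, \code{total_s}, \code{norm_duration}.
#' @export
behaviorStats <- function(bouts) {
  validateBouts(bouts)
  beh <- factor(bouts$behavior, levels = ethogramLevels())
  key <- interaction(bouts$session, bouts$animal_id, drop = TRUE)
  out <- list()
  for (g in levels(key)) {
    idx <- which(key == g)
    s <- bouts$session[idx[1]]; an <- bouts$animal_id[idx[1]]
    dur <- bouts$stop_s[idx] - bouts$start_s[idx]
    tot <- sum(dur)
    n_b <- table(beh[idx])
    t_b <- tapply(dur, beh[idx], sum, default = 0)
    out[[length(out) + 1]] <- data.frame(
      session = s, animal_id = an, behavior = ethogramLevels(),
      n_bouts = as.integer(n_b), total_s = as.numeric(t_b),
      norm_duration = as.numeric(t_b) / tot, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Interanimal behavior co-occurrence matrix
#'
#' Entry \code{(a, b)} is the Pearson correlation (phi coefficient) between
#' the per-frame indicator of behavior \code{a} in the first animal and
#' behavior \code{b} in the second, over frame-aligned in-trial frames.
#' Combinations in which either behavior never varies (never or always
#' present) are undefined and returned as \code{NA} — these are the
#' combinations rendered white in correlation-matrix figures.
#'
#' @param a,b character vectors of frame-aligned behavior labels for the two
#'   animals (equal length; \code{NA} frames are dropped pairwise).
#' @return A 6 x 6 numeric matrix, rows = behaviors of the first animal,
#'   columns = behaviors of the second, with \code{NA} where undefined.
#' @examples
#' a <- rep(c("PUSH", "STILLNESS"), 50)
#' b <- rep(c("RESIST", "STILLNESS"), 50)
#' m <- cooccurrenceMatrix(a, b)
#' m["PUSH", "RESIST"]    # +1
#' m["PUSH", "STILLNESS"] # -1
#' @export
cooccurrenceMatrix <- function(a, b) {
  stopifnot(length(a) == length(b))
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) stop("no frames with behavior labels for both animals")
  a <- normalizeBehavior(a[keep])
  b <- normalizeBehavior(b[keep])
  lev <- ethogramLevels()
  m <- matrix(NA_real_, 6, 6, dimnames = list(lev, lev))
  for (i in lev) {
    ia <- as.numeric(a == i)
    va <- stats::var(ia)
    for (j in lev) {
      ib <- as.numeric(b == j)
      if (va > 0 && stats::var(ib) > 0) m[i, j] <- cor(ia, ib)
    }
  }
  m
}

#' Co-occurrence matrix for a dyad's bout table
#'
#' Rasterizes both animals' bouts at \code{frame_rate} and applies
#' [cooccurrenceMatrix()] over all in-trial frames pooled across trials and
#' sessions.
#'
#' @param bouts a bout table covering both animals.
#' @param animals optional character(2) selecting/ordering the animals
#'   (rows = first, columns = second); defaults to sorted unique ids.
#' @param frame_rate acquisition rate in Hz.
#' @param trials optional trial records passed to [rasterizeBouts()].
#' @return A 6 x 6 correlation matrix (see [cooccurrenceMatrix()]).
#' @export
dyadCooccurrence <- function(bouts, animals = NULL, frame_rate = 20, trials = NULL) {
  if (is.null(animals)) animals <- sort(unique(bouts$animal_id))
  stopifnot(length(animals) == 2)
  r <- rasterizeBouts(bouts, frame_rate = frame_rate, trials = trials)
  ra <- r[r$animal_id == animals[1], ]
  rb <- r[r$animal_id == animals[2], ]
  key <- function(d) paste(d$session, d$trial, d$frame, sep = "\r")
  mb <- match(key(ra), key(rb))
  ok <- !is.na(mb)
  cooccurrenceMatrix(ra$behavior[ok], rb$behavior[mb[ok]])
}
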