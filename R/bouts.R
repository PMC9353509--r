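#' Read a BORIS-style aggregated-events table of behavior bouts
#'
#' Parses a CSV export with one row per bout and columns \code{subject} (or
#' \code{animal_id}), \code{behavior}, \code{start_s} (or \code{start}),
#' \code{stop_s} (or \code{stop}), \code{trial} and \code{session}. Bout times
#' are seconds relative to trial onset. Labels are case-normalized to the
#' six-category ethogram; unknown labels and overlapping bouts of the same
#' animal are hard errors naming the offending rows. Unannotated in-trial time
#' is filled as \code{STILLNESS} bouts, the residual category.
#'
#' @param file path to the CSV file.
#' @param trials optional trial records (\code{session}, \code{trial},
#'   \code{latency_s}); when given, gaps are filled out to the full trial
#'   duration, otherwise only internal gaps (between the first and last
#'   annotated instant of each animal/trial) are filled.
#' @return A validated bout table \code{data.frame} with columns
#'   \code{animal_id}, \code{behavior}, \code{start_s}, \code{stop_s},
#'   \code{trial}, \code{session}.
#' @seealso [rasterizeBouts()], [behaviorStats()]
#' @export
readBoutTable <- function(file, trials = NULL) {
  if (!file.exists(file)) stop("annotation file not found: ", file)
  df <- read.csv(file, stringsAsFactors = FALSE, comment.char = "#")
  nm <- tolower(names(df))
  pick <- function(...) {
    for (cand in c(...)) {
      i <- match(cand, nm)
      if (!is.na(i)) return(df[[i]])
    }
    stop("annotation file lacks a column named one of: ", paste(c(...), collapse = ", "))
  }
  out <- data.frame(
    animal_id = as.character(pick("subject", "animal_id", "animal")),
    behavior = as.character(pick("behavior")),
    start_s = as.numeric(pick("start_s", "start")),
    stop_s = as.numeric(pick("stop_s", "stop")),
    trial = as.integer(pick("trial")),
    session = as.integer(pick("session")),
    stringsAsFactors = FALSE
  )
  out$behavior <- normalizeBehavior(out$behavior)
  validateBouts(out)
  fillBoutGaps(out, trials = trials)
}

#' Write a bout table as a BORIS-style aggregated-events CSV
#'
#' @param bouts a bout table as returned by [readBoutTable()].
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeBoutTable <- function(bouts, file) {
  df <- data.frame(subject = bouts$animal_id, behavior = bouts$behavior,
                   start_s = bouts$start_s, stop_s = bouts$stop_s,
                   trial = bouts$trial, session = bouts$session)
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Validate a bout table
#'
#' Checks \code{stop_s > start_s} and that bouts of one animal within a trial
#' do not overlap; errors list the offending row indices.
#'
#' @param bouts a bout table \code{data.frame}.
#' @return \code{bouts}, invisibly.
#' @export
validateBouts <- function(bouts) {
  stopifnot(all(.requiredBoutCols %in% names(bouts)))
  bad <- which(!(bouts$stop_s > bouts$start_s))
  if (length(bad) > 0)
    stop("bouts with stop_s <= start_s at rows: ", paste(bad, collapse = ", "))
  key <- interaction(bouts$session, bouts$trial, bouts$animal_id, drop = TRUE)
  for (g in levels(key)) {
    idx <- which(key == g)
    o <- idx[order(bouts$start_s[idx])]
    if (length(o) < 2) next
    ov <- which(bouts$start_s[o][-1] < bouts$stop_s[o][-length(o)] - 1e-9)
    if (length(ov) > 0) {
      rows <- sort(unique(c(o[ov], o[ov + 1])))
      stop("overlapping bouts for one animal within a trial at rows: ",
           paste(rows, collapse = ", "))
    }
  }
  invisible(bouts)
}

## fill unannotated in-trial time with STILLNESS; trial span from `trials`
## (latency_s) when available, else [0, max stop] per animal/trial
fillBoutGaps <- function(bouts, trials = NULL) {
  key <- interaction(bouts$session, bouts$trial, bouts$animal_id, drop = TRUE)
  add <- list()
  for (g in levels(key)) {
    idx <- which(key == g)
    o <- idx[order(bouts$start_s[idx])]
    s <- bouts$session[o[1]]; tr <- bouts$trial[o[1]]; an <- bouts$animal_id[o[1]]
    t_end <- max(bouts$stop_s[o])
    t_start <- 0
    if (!is.null(trials)) {
      m <- which(trials$session == s & trials$trial == tr)
      if (length(m) == 1) t_end <- max(t_end, trials$latency_s[m])
    }
    edges <- c(t_start, as.vector(rbind(bouts$start_s[o], bouts$stop_s[o])), t_end)
    lo <- edges[seq(1, length(edges) - 1, by = 2)]
    hi <- edges[seq(2, length(edges), by = 2)]
    gap <- which(hi - lo > 1e-9)
    for (j in gap) {
      add[[length(add) + 1]] <- data.frame(
        animal_id = an, behavior = "STILLNESS", start_s = lo[j], stop_s = hi[j],
        trial = tr, session = s, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(add) > 0) rbind(bouts, do.call(rbind, add)) else bouts
  out <- out[order(out$session, out$trial, out$animal_id, out$start_s), ]
  rownames(out) <- NULL
  mergeAdjacentBouts(out)
}

## merge back-to-back bouts of the same behavior (same animal/trial/session)
mergeAdjacentBouts <- function(bouts) {
  if (nrow(bouts) < 2) return(bouts)
  keep <- rep(TRUE, nrow(bouts))
  for (i in 2:nrow(bouts)) {
    same <- bouts$session[i] == bouts$session[i - 1] &&
      bouts$trial[i] == bouts$trial[i - 1] &&
      bouts$animal_id[i] == bouts$animal_id[i - 1] &&
      bouts$behavior[i] == bouts$behavior[i - 1] &&
      abs(bouts$start_s[i] - bouts$stop_s[i - 1]) < 1e-9
    if (same) {
      j <- max(which(keep[1:(i - 1)]))
      bouts$stop_s[j] <- bouts$stop_s[i]
      keep[i] <- FALSE
    }
  }
  out <- bouts[keep, ]
  rownames(out) <- NULL
  out
}

#' Rasterize bouts to a per-frame behavior label
#'
#' Frame \code{f} (0-based) carries the bout containing time
#' \code{f / frame_rate}; intervals are half-open, so a bout boundary falling
#' exactly on a frame time assigns that frame to the later bout. One row per
#' animal, trial and frame.
#'
#' @param bouts a bout table (see [readBoutTable()]); bouts of each
#'   animal must tile each trial.
#' @param frame_rate acquisition rate in Hz (default 20).
#' @param trials optional trial records supplying trial durations
#'   (\code{latency_s}); otherwise the span of the annotated bouts is used.
#' @return \code{data.frame} with columns \code{session}, \code{trial},
#'   \code{frame} (0-based within trial), \code{time_s}, \code{animal_id},
#'   \code{behavior}.
#' @examples
#' b <- data.frame(animal_id = "A", behavior = "PUSH", start_s = 0,
#'                 stop_s = 0.5, trial = 1L, session = 1L)
#' r <- rasterizeBouts(b, frame_rate = 20)
#' r$frame # frames 0..9
#' @export
rasterizeBouts <- function(bouts, frame_rate = 20, trials = NULL) {
  stopifnot(frame_rate > 0)
  validateBouts(bouts)
  key <- interaction(bouts$session, bouts$trial, bouts$animal_id, drop = TRUE)
  out <- vector("list", nlevels(key))
  for (gi in seq_len(nlevels(key))) {
    idx <- which(key == levels(key)[gi])
    o <- idx[order(bouts$start_s[idx])]
    s <- bouts$session[o[1]]; tr <- bouts$trial[o[1]]; an <- bouts$animal_id[o[1]]
    dur <- max(bouts$stop_s[o])
    if (!is.null(trials)) {
      m <- which(trials$session == s & trials$trial == tr)
      if (length(m) == 1) dur <- trials$latency_s[m]
    }
    nf <- round(dur * frame_rate)
    if (nf < 1) next
    tt <- (seq_len(nf) - 1) / frame_rate
    # half-open [start, stop): boundary exactly at a frame time -> later bout
    bi <- findInterval(tt, bouts$start_s[o])
    bi[bi < 1] <- 1L
    beh <- bouts$behavior[o][bi]
    # a frame falling in an annotation gap or beyond the last bout gets NA
    beh[tt >= bouts$stop_s[o][bi] - 1e-9] <- NA_character_
    out[[gi]] <- data.frame(session = s, trial = tr, frame = seq_len(nf) - 1L,
                            time_s = tt, animal_id = an, behavior = beh,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Recover bout boundaries from a behavior raster
#'
#' Inverse of [rasterizeBouts()] up to one-frame quantization: runs of
#' identical labels within each animal/trial become bouts with frame-grid
#' boundaries.
#'
#' @param raster output of [rasterizeBouts()].
#' @param frame_rate acquisition rate in Hz.
#' @return A bout table \code{data.frame}.
#' @export
boutsFromRaster <- function(raster, frame_rate = 20) {
  key <- interaction(raster$session, raster$trial, raster$animal_id, drop = TRUE)
  out <- list()
  for (g in levels(key)) {
    idx <- which(key == g)
    o <- idx[order(raster$frame[idx])]
    r <- rle(raster$behavior[o])
    stops <- cumsum(r$lengths)
    starts <- c(0, stops[-length(stops)])
    out[[length(out) + 1]] <- data.frame(
      animal_id = raster$animal_id[o[1]], behavior = r$values,
      start_s = starts / frame_rate, stop_s = stops / frame_rate,
      trial = raster$trial[o[1]], session = raster$session[o[1]],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[!is.na(res$behavior), ]
  rownames(res) <- NULL
  res
}
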