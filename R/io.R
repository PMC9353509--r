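#' Write / read a trace matrix CSV
#'
#' Cells x frames dF/F values with a leading comment header carrying the
#' frame rate (and optionally session index and imaged animal), then one row
#' per cell with a \code{cell_id} column.
#'
#' @param m numeric matrix, cells x frames, rownames = cell ids.
#' @param file path.
#' @param frame_rate Hz.
#' @param session,imaged_animal optional annotations stored in the header.
#' @return \code{writeTraceMatrix}: \code{file}, invisibly.
#'   \code{readTraceMatrix}: list with \code{traces} (matrix),
#'   \code{frame_rate}, \code{session}, \code{imaged_animal}.
#' @export
writeTraceMatrix <- function(m, file, frame_rate, session = NA,
                             imaged_animal = NA) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# frame_rate=%g session=%s imaged_animal=%s",
                     frame_rate, session, imaged_animal), con)
  ids <- rownames(m)
  if (is.null(ids)) ids <- sprintf("cell%03d", seq_len(nrow(m)))
  df <- data.frame(cell_id = ids, m, check.names = FALSE)
  colnames(df) <- c("cell_id", sprintf("f%d", seq_len(ncol(m)) - 1L))
  write.csv(df, con, row.names = FALSE)
  invisible(file)
}

#' @rdname writeTraceMatrix
#' @export
readTraceMatrix <- function(file) {
  if (!file.exists(file)) stop("trace file not found: ", file)
  hdr <- readLines(file, n = 1)
  getfield <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[^ ]+"), hdr))
    if (length(m) == 0) return(NA)
    sub(paste0(key, "="), "", m)
  }
  fr <- as.numeric(getfield("frame_rate"))
  if (!is.finite(fr) || fr <= 0) stop("trace file header lacks frame_rate")
  df <- read.csv(file, comment.char = "#", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$cell_id
  ses <- suppressWarnings(as.integer(getfield("session")))
  list(traces = m, frame_rate = fr, session = ses,
       imaged_animal = as.character(getfield("imaged_animal")))
}

#' Write / read trial records
#'
#' @param trials trial records \code{data.frame} (see
#'   \linkS4class{DyadExperiment}).
#' @param file path.
#' @return \code{writeTrialRecords}: \code{file}, invisibly;
#'   \code{readTrialRecords}: the validated \code{data.frame}.
#' @export
writeTrialRecords <- function(trials, file) {
  write.csv(trials[, .requiredTrialCols], file, row.names = FALSE)
  invisible(file)
}

#' @rdname writeTrialRecords
#' @export
readTrialRecords <- function(file) {
  if (!file.exists(file)) stop("trial file not found: ", file)
  df <- read.csv(file, stringsAsFactors = FALSE)
  miss <- setdiff(.requiredTrialCols, names(df))
  if (length(miss) > 0)
    stop("trial file lacks column(s): ", paste(miss, collapse = ", "))
  if (any(df$winner_id == df$loser_id))
    stop("trial with winner == loser")
  df
}

#' Write a DyadExperiment to a directory of interchange files
#'
#' Writes \code{traces_s<N>.csv} per session, \code{bouts.csv} (BORIS-style
#' aggregated events), \code{trials.csv}, \code{dataset.json} (animals,
#' frame rate, session durations) and, when present, \code{truth.json}
#' (planted ground truth).
#'
#' @param dex a \linkS4class{DyadExperiment}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeDyadExperiment <- function(dex, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ses <- sessions(dex)
  for (s in seq_along(ses)) {
    writeTraceMatrix(assay(ses[[s]], "dff"),
                     file.path(dir, sprintf("traces_s%d.csv", s)),
                     frame_rate = frameRate(dex), session = s,
                     imaged_animal = metadata(ses[[s]])$imaged_animal)
  }
  writeBoutTable(boutTable(dex), file.path(dir, "bouts.csv"))
  writeTrialRecords(trialRecords(dex), file.path(dir, "trials.csv"))
  meta <- list(animals = animalIds(dex), frame_rate = frameRate(dex),
               n_sessions = length(ses),
               session_durations = vapply(ses, function(se)
                 metadata(se)$session_duration %||%
                   (ncol(se) / frameRate(dex)), numeric(1)))
  jsonlite::write_json(meta, file.path(dir, "dataset.json"),
                       auto_unbox = TRUE, digits = NA)
  tr <- groundTruth(dex)
  if (length(tr) > 0) {
    tr_out <- tr
    tr_out$cells$behaviors <- vapply(tr$cells$behaviors, paste, character(1),
                                     collapse = ";")
    jsonlite::write_json(tr_out, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a DyadExperiment from a directory of interchange files
#'
#' Inverse of [writeDyadExperiment()] (the planted ground truth, if any, is
#' reloaded with the \code{behaviors} column as \code{;}-separated strings).
#'
#' @param dir directory written by [writeDyadExperiment()] (or assembled by
#'   hand in the same layout).
#' @return A \linkS4class{DyadExperiment}.
#' @export
readDyadExperiment <- function(dir) {
  meta_f <- file.path(dir, "dataset.json")
  if (!file.exists(meta_f)) stop("dataset.json not found in ", dir)
  meta <- jsonlite::read_json(meta_f, simplifyVector = TRUE)
  trials <- readTrialRecords(file.path(dir, "trials.csv"))
  bouts <- readBoutTable(file.path(dir, "bouts.csv"), trials = trials)
  fr <- meta$frame_rate
  ses <- list()
  for (s in seq_len(meta$n_sessions)) {
    tm <- readTraceMatrix(file.path(dir, sprintf("traces_s%d.csv", s)))
    imaged <- tm$imaged_animal
    partner <- setdiff(meta$animals, imaged)
    bouts_s <- bouts[bouts$session == s, ]
    trials_s <- trials[trials$session == s, ]
    cd <- .sessionColData(bouts_s, trials_s, ncol(tm$traces), fr, imaged,
                          partner)
    se <- SummarizedExperiment(assays = list(dff = tm$traces), colData = cd)
    metadata(se) <- list(session = s, imaged_animal = imaged, frame_rate = fr,
                         session_duration = ncol(tm$traces) / fr)
    ses[[s]] <- se
  }
  truth <- list()
  truth_f <- file.path(dir, "truth.json")
  if (file.exists(truth_f))
    truth <- jsonlite::read_json(truth_f, simplifyVector = TRUE)
  DyadExperiment(sessions = ses, bouts = bouts, trials = trials,
                 animals = meta$animals, truth = truth)
}
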