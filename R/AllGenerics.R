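#' @name DyadExperiment-accessors
#' @title Accessors for DyadExperiment objects
#' @description Accessors for the slots of a \linkS4class{DyadExperiment}:
#'   the per-session [SummarizedExperiment::SummarizedExperiment]s, the bout
#'   table, the trial records, the animal identifiers, the acquisition frame
#'   rate, the imaged animal of a given session, and (for synthetic data) the
#'   planted ground truth.
#' @param x a \linkS4class{DyadExperiment}.
#' @param session 1-based session index.
#' @return \code{sessions}: a [S4Vectors::SimpleList] of
#'   SummarizedExperiments; \code{boutTable}, \code{trialRecords}:
#'   \code{data.frame}s; \code{animalIds}: character(2); \code{frameRate}:
#'   numeric(1) in Hz; \code{imagedAnimal}: character(1); \code{groundTruth}:
#'   a list (empty for real data).
NULL

#' @rdname DyadExperiment-accessors
#' @export
setGeneric("sessions", function(x) standardGeneric("sessions"))
#' @rdname DyadExperiment-accessors
#' @export
setGeneric("boutTable", function(x) standardGeneric("boutTable"))
#' @rdname DyadExperiment-accessors
#' @export
setGeneric("trialRecords", function(x) standardGeneric("trialRecords"))
#' @rdname DyadExperiment-accessors
#' @export
setGeneric("animalIds", function(x) standardGeneric("animalIds"))
#' @rdname DyadExperiment-accessors
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))
#' @rdname DyadExperiment-accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname DyadExperiment-accessors
#' @export
setGeneric("imagedAnimal", function(x, session) standardGeneric("imagedAnimal"))

#' @rdname DyadExperiment-accessors
#' @export
setMethod("sessions", "DyadExperiment", function(x) x@sessions)
#' @rdname DyadExperiment-accessors
#' @export
setMethod("boutTable", "DyadExperiment", function(x) x@bouts)
#' @rdname DyadExperiment-accessors
#' @export
setMethod("trialRecords", "DyadExperiment", function(x) x@trials)
#' @rdname DyadExperiment-accessors
#' @export
setMethod("animalIds", "DyadExperiment", function(x) x@animals)
#' @rdname DyadExperiment-accessors
#' @export
setMethod("groundTruth", "DyadExperiment", function(x) x@truth)
#' @rdname DyadExperiment-accessors
#' @export
setMethod("frameRate", "DyadExperiment", function(x) {
  if (length(x@sessions) == 0L) return(NA_real_)
  metadata(x@sessions[[1L]])$frame_rate
})
#' @rdname DyadExperiment-accessors
#' @export
setMethod("imagedAnimal", "DyadExperiment", function(x, session) {
  metadata(x@sessions[[session]])$imaged_animal
})

#' Detect calcium events
#'
#' Generic for converting dF/F traces into time-stamped event trains; see the
#' matrix and \linkS4class{DyadExperiment} methods in [detectEvents()].
#'
#' @param x a numeric matrix (cells x frames) or a
#'   \linkS4class{DyadExperiment}.
#' @param ... passed to methods.
#' @export
setGeneric("detectEvents", function(x, ...) standardGeneric("detectEvents"))
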