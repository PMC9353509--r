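#' The tube-test ethogram
#'
#' The closed set of six behavior categories scored during a tube-test
#' contest. \code{MOVE FORWARD}: one or both animals advance toward each
#' other. \code{PUSH}: the animal drives the barrier/partner backwards.
#' \code{RESIST}: the animal holds its ground against a push. \code{RETREAT}:
#' enforced backward movement while being pushed. \code{WITHDRAWAL}:
#' unenforced backward movement of the animal's own accord. \code{STILLNESS}:
#' the residual category (neither forward nor backward motion; may include
#' sniffing or grooming).
#'
#' @return Character vector of the six behavior labels, in canonical order.
#' @examples
#' ethogramLevels()
#' @export
ethogramLevels <- function() {
  c("MOVE FORWARD", "PUSH", "RESIST", "RETREAT", "WITHDRAWAL", "STILLNESS")
}

## loser-only terminal behaviors
.terminalBehaviors <- function() c("RETREAT", "WITHDRAWAL")

#' Normalize behavior labels to the canonical ethogram
#'
#' Case-insensitive matching against [ethogramLevels()]; underscores and
#' surrounding whitespace are tolerated. Unknown labels raise an error naming
#' the offending values.
#'
#' @param x character vector of behavior labels.
#' @return Character vector of canonical labels.
#' @export
normalizeBehavior <- function(x) {
  canon <- ethogramLevels()
  xx <- toupper(trimws(gsub("_", " ", as.character(x))))
  bad <- setdiff(unique(xx), canon)
  if (length(bad) > 0) {
    stop("unknown behavior label(s): ", paste(bad, collapse = ", "),
         "; expected one of: ", paste(canon, collapse = ", "))
  }
  xx
}
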