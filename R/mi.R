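## tie-breaking jitter scale for the k-NN estimator (rate series are heavily
## tied); proportional to the signal scale, drawn from the caller's RNG stream
.jitterSd <- function(x) 1e-10 * (sd(x) + abs(mean(x)))

#' Kraskov-type mutual information between a rate series and a discrete label
#'
#' Mixed discrete-continuous k-nearest-neighbour estimator (the Ross variant
#' of the Kraskov-Stogbauer-Grassberger estimator): for sample \code{i} with
#' label \code{y_i}, let \code{d_i} be the distance to its k-th nearest
#' neighbour among same-label samples, \code{m_i} the number of samples within
#' that distance in the full data, and \code{N_y} the same-label count; then
#' \deqn{I = \psi(N) - \langle\psi(N_y)\rangle + \psi(k) -
#'   \langle\psi(m_i)\rangle}
#' converted from nats to bits and clipped at zero. Samples with a
#' singleton label are dropped; within a label of size \code{c < k+1} the
#' neighbour count falls back to \code{c - 1}. Heavy ties in the rate series
#' are broken by a minute seeded jitter, which also makes the estimate
#' invariant under strictly monotone transforms of the rate up to that jitter.
#'
#' @param x numeric vector (e.g. a [convolveRate()] series).
#' @param y discrete label per sample (factor, character, logical or integer);
#'   a single-class label yields 0 with a warning.
#' @param k neighbour count (default 4).
#' @param jitter logical; add tie-breaking jitter (default \code{TRUE}).
#' @return Mutual information score in bits (>= 0).
#' @examples
#' set.seed(1)
#' y <- rep(0:1, each = 500)
#' x <- rnorm(1000, mean = 2 * y)
#' ksgMI(x, y)
#' @export
ksgMI <- function(x, y, k = 4, jitter = TRUE) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have the same length")
  if (any(!is.finite(x))) stop("x must be finite")
  if (n < 10 * k) stop("too few samples: need at least 10 * k = ", 10 * k)
  yf <- as.integer(factor(y)) - 1L
  if (length(unique(yf)) < 2) {
    warning("label has a single class; MI defined as 0")
    return(0)
  }
  if (jitter) x <- x + .jitterSd(x) * rnorm(n)
  ksg_mi_cpp(as.numeric(x), yf, as.integer(k))
}

#' Shuffle-null distribution and significance threshold for one cell/target
#'
#' Builds the chance distribution of the mutual information score by
#' circularly rotating the cell's event train by a uniform offset in
#' \code{[min_shift, T - min_shift]} seconds (preserving the train's
#' autocorrelation), reconvolving with the Gaussian rate kernel and rescoring
#' against the fixed behavior label. The significance threshold is the
#' empirical \code{1 - alpha} percentile (95th by default) of the null. When
#' the series is shorter than \code{2 * min_shift} the null falls back to
#' uniform event-time permutation, with a warning.
#'
#' @param event_frames 0-based event frames (within the analyzed series).
#' @param y discrete behavior label per frame.
#' @param n_frames length of the analyzed series.
#' @param n_shuffles number of shuffles (default 2000).
#' @param sigma,frame_rate rate-convolution parameters (see
#'   [convolveRate()]).
#' @param min_shift minimum rotation, seconds (default 5).
#' @param k neighbour count for [ksgMI()].
#' @param alpha significance level; the threshold is the
#'   \code{100 * (1 - alpha)} percentile (default 0.05).
#' @return List: \code{null} (numeric vector of \code{n_shuffles} null MIS
#'   values, bits), \code{threshold} (bits), \code{n_shuffles},
#'   \code{method} (\code{"rotation"} or \code{"permutation"}).
#' @export
shuffleNull <- function(event_frames, y, n_frames, n_shuffles = 2000,
                        sigma = 0.0125, frame_rate = 20, min_shift = 5,
                        k = 4, alpha = 0.05) {
  stopifnot(length(y) == n_frames, n_shuffles >= 1, alpha > 0, alpha < 1)
  event_frames <- as.integer(event_frames)
  if (length(event_frames) == 0) stop("empty event train")
  yf <- as.integer(factor(y)) - 1L
  min_shift_f <- round(min_shift * frame_rate)
  kern <- gaussianRateKernel(sigma, frame_rate)
  center <- (length(kern) - 1L) %/% 2L
  # jitter scale from the observed (unrotated) rate series
  jsd <- .jitterSd(convolveRate(event_frames, n_frames, sigma, frame_rate))
  if (n_frames >= 2 * min_shift_f + 1) {
    offsets <- sample(seq.int(min_shift_f, n_frames - min_shift_f),
                      n_shuffles, replace = TRUE)
    null <- as.numeric(shuffle_null_multi_cpp(
      event_frames, n_frames, matrix(yf, ncol = 1), kern, center,
      frame_rate, as.integer(offsets), as.integer(k), jsd))
    method <- "rotation"
  } else {
    warning("series shorter than twice min_shift; falling back to ",
            "event-time permutation")
    ne <- length(event_frames)
    null <- vapply(seq_len(n_shuffles), function(i) {
      f <- sample.int(n_frames, ne) - 1L
      r <- convolveRate(f, n_frames, sigma, frame_rate)
      ksg_mi_cpp(r + jsd * rnorm(n_frames), yf, as.integer(k))
    }, numeric(1))
    method <- "permutation"
  }
  list(null = null,
       threshold = quantile(null, 1 - alpha, names = FALSE),
       n_shuffles = n_shuffles, method = method)
}

## batched circular-rotation nulls for one cell scored against several label
## vectors at once (one shared rotation + sort per shuffle); returns the
## per-label null threshold at the given alpha(s)
.nullThresholdsMulti <- function(event_frames, flags, n_frames, n_shuffles,
                                 sigma, frame_rate, min_shift, k, alpha) {
  stopifnot(length(flags) >= 1)
  event_frames <- as.integer(event_frames)
  min_shift_f <- round(min_shift * frame_rate)
  if (n_frames < 2 * min_shift_f + 1) {
    # short series: per-label event-time permutation fallback
    return(vapply(seq_along(flags), function(l) {
      nl <- shuffleNull(event_frames, flags[[l]], n_frames,
                        n_shuffles = n_shuffles, sigma = sigma,
                        frame_rate = frame_rate, min_shift = min_shift,
                        k = k, alpha = if (length(alpha) > 1) alpha[l] else alpha)
      nl$threshold
    }, numeric(1)))
  }
  ym <- vapply(flags, function(f) as.integer(factor(f)) - 1L,
               integer(n_frames))
  kern <- gaussianRateKernel(sigma, frame_rate)
  center <- (length(kern) - 1L) %/% 2L
  jsd <- .jitterSd(convolveRate(event_frames, n_frames, sigma, frame_rate))
  offsets <- sample(seq.int(min_shift_f, n_frames - min_shift_f),
                    n_shuffles, replace = TRUE)
  null <- shuffle_null_multi_cpp(event_frames, n_frames, ym, kern, center,
                                 frame_rate, as.integer(offsets),
                                 as.integer(k), jsd)
  alpha <- rep_len(alpha, length(flags))
  vapply(seq_along(flags), function(l)
    quantile(null[, l], 1 - alpha[l], names = FALSE), numeric(1))
}

#' Occupancy: fraction of behavior bouts containing at least one event
#'
#' A cell is only eligible as encoding a behavior if events are present in
#' strictly more than 34\% of that behavior's bouts; this function computes
#' the fraction itself.
#'
#' @param event_frames 0-based event frames.
#' @param bout_intervals \code{data.frame} with 0-based half-open frame
#'   columns \code{start} and \code{end} (one row per bout).
#' @return Fraction of bouts containing >= 1 event, in \code{[0, 1]};
#'   errors when there are no bouts.
#' @examples
#' iv <- data.frame(start = c(0, 10, 20, 30, 40), end = c(5, 15, 25, 35, 45))
#' occupancy(c(1L, 12L, 41L), iv) # 3 of 5 bouts
#' @export
occupancy <- function(event_frames, bout_intervals) {
  nb <- nrow(bout_intervals)
  if (is.null(nb) || nb == 0) stop("occupancy undefined: zero bouts")
  event_frames <- as.integer(event_frames)
  hit <- vapply(seq_len(nb), function(i)
    any(event_frames >= bout_intervals$start[i] &
          event_frames < bout_intervals$end[i]), logical(1))
  mean(hit)
}
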