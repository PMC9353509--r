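#' Moving-average smoothing of a dF/F trace
#'
#' Centered (linear-phase) moving average; the window shrinks symmetrically at
#' the series edges so the output has the same length with no lag shift.
#' \code{window = 1} is the identity.
#'
#' @param x numeric trace.
#' @param window window width in frames (>= 1, <= length(x)).
#' @return Smoothed numeric vector, same length as \code{x}.
#' @export
smoothTrace <- function(x, window = 5) {
  n <- length(x)
  if (window < 1) stop("window must be >= 1")
  if (window > n) stop("window (", window, ") exceeds series length (", n, ")")
  if (window == 1) return(x)
  cs <- cumsum(c(0, x))
  half_l <- (window - 1) %/% 2
  half_r <- window - 1L - half_l
  i <- seq_len(n)
  lo <- pmax(0L, i - 1L - half_l)
  hi <- pmin(n, i + half_r)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

#' Robust noise-SD estimate of a dF/F trace
#'
#' \code{1.4826 x MAD} of the first differences divided by \code{sqrt(2)}:
#' robust to the sparse large transients riding on the noise.
#'
#' @param x numeric trace.
#' @return Estimated noise standard deviation.
#' @export
estimateNoiseSd <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) stop("trace too short for a noise estimate")
  mad(diff(x)) / sqrt(2)
}

## running lower-percentile baseline: evaluated on a strided grid (0.5 s) with
## centered windows of `window_s` seconds, then linearly interpolated
runningBaseline <- function(x, frame_rate, window_s = 30, p = 0.2) {
  n <- length(x)
  half <- max(1L, round(window_s * frame_rate / 2))
  stride <- max(1L, round(0.5 * frame_rate))
  grid <- unique(c(seq(1L, n, by = stride), n))
  q <- vapply(grid, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    quantile(x[lo:hi], p, names = FALSE)
  }, numeric(1))
  if (length(grid) == 1) return(rep(q, n))
  approx(grid, q, xout = seq_len(n), rule = 2)$y
}

.detectEventsVec <- function(x, frame_rate, s_min, smooth_window,
                             threshold_units, baseline_window_s, baseline_p,
                             refractory, noise_sd = NULL) {
  if (all(is.na(x))) stop("all-NaN trace")
  sm <- smoothTrace(x, smooth_window)
  if (threshold_units == "noise") {
    if (is.null(noise_sd)) noise_sd <- estimateNoiseSd(x)
    if (noise_sd <= 0) stop("zero-variance trace: no noise estimate possible")
    thr_add <- s_min * noise_sd
  } else {
    thr_add <- s_min
  }
  base <- runningBaseline(sm, frame_rate, baseline_window_s, baseline_p)
  d <- sm - base
  n <- length(d)
  # prominence detector: a local maximum fires an event when it rises at
  # least thr_add above the running minimum since the previous event (so
  # stacked transients each count); the event is stamped at the upward
  # threshold crossing preceding the peak, with a refractory gap of one
  # transient rise
  ev <- integer(0)
  ref <- d[1]
  last_ev <- -Inf
  for (t in 2:n) {
    if (d[t] < ref) ref <- d[t]
    is_peak <- if (t < n) d[t] >= d[t - 1] && d[t] > d[t + 1]
               else d[t] >= d[t - 1]
    if (is_peak && d[t] - ref >= thr_add) {
      s <- t
      while (s > 1 && d[s - 1] >= ref + thr_add) s <- s - 1
      if (s - last_ev > refractory) {
        ev <- c(ev, s)
        last_ev <- s
      }
      ref <- d[t]
    }
  }
  as.integer(ev - 1L) # 0-based
}

#' @describeIn detectEvents Detect events in a cells x frames dF/F matrix.
#'   A transient is accepted when the smoothed, baseline-subtracted trace
#'   rises at least \code{s_min} (dF/F units by default, or
#'   \code{s_min * noise_sd} with \code{threshold_units = "noise"}) above the
#'   running minimum since the previous event — so transients stacked on a
#'   decaying shoulder are counted individually — and is stamped at the
#'   preceding upward threshold crossing, with a refractory gap of one
#'   transient rise. The
#'   baseline is a running 20th percentile over 30 s (slow-drift removal).
#'   One threshold per cell, held fixed across all sessions of that cell: when
#'   \code{x} is a \linkS4class{DyadExperiment}, the per-cell noise SD is
#'   pooled across the cell's sessions.
#' @param frame_rate acquisition rate, Hz.
#' @param s_min event threshold; typical working range 0.2-0.3
#'   (per-cell, fixed across sessions).
#' @param threshold_units \code{"dff"} (threshold in dF/F units, default) or
#'   \code{"noise"} (units of the robust noise SD; errors on a zero-variance
#'   trace).
#' @param smooth_window moving-average width in frames (default 5).
#' @param baseline_window_s,baseline_p running-baseline window (s) and
#'   percentile.
#' @param refractory minimum gap between events, frames (one transient rise;
#'   default 2).
#' @return A \code{data.frame} event train: \code{cell_id}, \code{frame}
#'   (0-based), \code{time_s} and, for the \code{DyadExperiment} method,
#'   \code{session}. The per-cell thresholds used are attached as
#'   \code{attr(, "thresholds")}.
#' @export
setMethod("detectEvents", "matrix", function(x, frame_rate = 20, s_min = 0.25,
                                             threshold_units = c("dff", "noise"),
                                             smooth_window = 5,
                                             baseline_window_s = 30,
                                             baseline_p = 0.2, refractory = 2,
                                             ...) {
  threshold_units <- match.arg(threshold_units)
  stopifnot(s_min > 0, frame_rate > 0)
  ids <- rownames(x)
  if (is.null(ids)) ids <- sprintf("cell%03d", seq_len(nrow(x)))
  out <- list()
  for (i in seq_len(nrow(x))) {
    fr0 <- .detectEventsVec(x[i, ], frame_rate, s_min, smooth_window,
                            threshold_units, baseline_window_s, baseline_p,
                            refractory)
    if (length(fr0) > 0)
      out[[length(out) + 1]] <- data.frame(cell_id = ids[i], frame = fr0,
                                           time_s = fr0 / frame_rate,
                                           stringsAsFactors = FALSE)
  }
  res <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(cell_id = character(0), frame = integer(0), time_s = numeric(0))
  attr(res, "thresholds") <- setNames(rep(s_min, length(ids)), ids)
  res
})

#' @describeIn detectEvents Detect events across all sessions of a
#'   \linkS4class{DyadExperiment}; the noise SD (when
#'   \code{threshold_units = "noise"}) is pooled per cell across its sessions
#'   so the threshold is fixed longitudinally.
#' @export
setMethod("detectEvents", "DyadExperiment",
          function(x, s_min = 0.25, threshold_units = c("dff", "noise"),
                   smooth_window = 5, baseline_window_s = 30, baseline_p = 0.2,
                   refractory = 2, ...) {
  threshold_units <- match.arg(threshold_units)
  fr <- frameRate(x)
  ses <- sessions(x)
  # pooled per-cell noise estimate across sessions
  noise <- list()
  if (threshold_units == "noise") {
    allids <- unique(unlist(lapply(ses, rownames)))
    for (id in allids) {
      d <- unlist(lapply(ses, function(se)
        if (id %in% rownames(se)) diff(assay(se, "dff")[id, ]) else NULL))
      noise[[id]] <- mad(d) / sqrt(2)
      if (noise[[id]] <= 0)
        stop("zero-variance trace for cell ", id, ": no noise estimate possible")
    }
  }
  out <- list()
  for (s in seq_along(ses)) {
    m <- assay(ses[[s]], "dff")
    for (i in seq_len(nrow(m))) {
      id <- rownames(m)[i]
      fr0 <- .detectEventsVec(m[i, ], fr, s_min, smooth_window,
                              threshold_units, baseline_window_s, baseline_p,
                              refractory,
                              noise_sd = if (length(noise)) noise[[id]] else NULL)
      if (length(fr0) > 0)
        out[[length(out) + 1]] <- data.frame(cell_id = id, session = s,
                                             frame = fr0,
                                             time_s = fr0 / fr,
                                             stringsAsFactors = FALSE)
    }
  }
  if (length(out) > 0) do.call(rbind, out) else
    data.frame(cell_id = character(0), session = integer(0),
               frame = integer(0), time_s = numeric(0))
})

## discrete Gaussian kernel at frame centers, truncated at +/- 2 sigma,
## renormalized to unit sum
gaussianRateKernel <- function(sigma, frame_rate) {
  stopifnot(sigma > 0, frame_rate > 0)
  dt <- 1 / frame_rate
  half <- floor(2 * sigma / dt)
  tt <- (-half:half) * dt
  k <- dnorm(tt, sd = sigma)
  k / sum(k)
}

#' Convolve an event train into an instantaneous rate series
#'
#' The binary event indicator is convolved with a discrete Gaussian kernel
#' (sd \code{sigma} seconds, truncated at two sigma, renormalized to unit sum)
#' and scaled by \code{frame_rate} so the series is in events/s and its time
#' integral equals the event count. At the conventional
#' \code{sigma = 12.5 ms} and 20 Hz the kernel support is a single 50 ms
#' frame, so the series equals \code{frame_rate} at event frames and 0
#' elsewhere; note 12.5 ms is below one frame period, a configuration kept
#' configurable precisely because it makes the convolution nearly an identity
#' (see the package vignette).
#'
#' @param event_frames integer vector of 0-based event frames.
#' @param n_frames length of the output series.
#' @param sigma Gaussian sd in seconds (default 0.0125).
#' @param frame_rate Hz (default 20).
#' @return Numeric vector of length \code{n_frames}, events/s.
#' @examples
#' r <- convolveRate(c(10L, 30L), 50)
#' sum(r) / 20 # integrates to 2 events
#' @export
convolveRate <- function(event_frames, n_frames, sigma = 0.0125,
                         frame_rate = 20) {
  stopifnot(sigma > 0, n_frames >= 1)
  event_frames <- as.integer(event_frames)
  if (length(event_frames) > 0 &&
      (min(event_frames) < 0 || max(event_frames) >= n_frames))
    stop("event frames outside [0, n_frames)")
  k <- gaussianRateKernel(sigma, frame_rate)
  center <- (length(k) - 1L) %/% 2L
  r <- numeric(n_frames)
  if (length(event_frames) == 0) return(r)
  for (j in seq_along(k)) {
    t0 <- event_frames + (j - 1L) - center
    ok <- t0 >= 0 & t0 < n_frames
    if (any(ok))
      r <- r + k[j] * frame_rate * tabulate(t0[ok] + 1L, nbins = n_frames)
  }
  r
}
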