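#' Default interanimal behavior coupling matrix
#'
#' Conditional probabilities \code{P(partner behavior | driver behavior)} used
#' by the semi-Markov dyad generator: within each bout of the trial's driving
#' animal (the eventual trial winner), the partner's behavior is drawn from
#' the row of this matrix. Defaults encode the qualitative dyadic structure of
#' tube-test contests: pushing by one animal is mostly met by resistance or
#' enforced retreat of the other, resisting by the driver implies the partner
#' is pushing, and stillness is largely shared, while keeping every
#' conditional away from 0/1 so that joint (own x other) behavior conjunctions
#' remain proper subsets of their marginals.
#'
#' @return A 6 x 6 row-stochastic matrix with ethogram dimnames.
#' @export
defaultCoupling <- function() {
  lev <- ethogramLevels()
  m <- rbind(
    `MOVE FORWARD` = c(0.45, 0.05, 0.05, 0.15, 0.05, 0.25),
    PUSH           = c(0.10, 0.00, 0.60, 0.20, 0.05, 0.05),
    RESIST         = c(0.05, 0.75, 0.00, 0.00, 0.00, 0.20),
    RETREAT        = c(0.30, 0.55, 0.00, 0.00, 0.05, 0.10),
    WITHDRAWAL     = c(0.30, 0.15, 0.05, 0.00, 0.10, 0.40),
    STILLNESS      = c(0.12, 0.05, 0.05, 0.05, 0.08, 0.65)
  )
  colnames(m) <- lev
  m[lev, lev]
}

## driver (per-trial winner) semi-Markov transition matrix over the ethogram;
## strong profile zeroes the loser-only behaviors for the driver
.driverTransitions <- function(profile = c("strong", "moderate")) {
  profile <- match.arg(profile)
  lev <- ethogramLevels()
  m <- rbind(
    `MOVE FORWARD` = c(0.10, 0.40, 0.10, 0, 0, 0.40),
    PUSH           = c(0.15, 0.15, 0.15, 0, 0, 0.55),
    RESIST         = c(0.10, 0.35, 0.10, 0, 0, 0.45),
    RETREAT        = c(0.30, 0.25, 0.10, 0, 0, 0.35),
    WITHDRAWAL     = c(0.30, 0.10, 0.10, 0, 0, 0.50),
    STILLNESS      = c(0.30, 0.25, 0.10, 0, 0, 0.35)
  )
  colnames(m) <- lev
  if (profile == "moderate") {
    # allow brief mid-trial retreat/withdrawal by the eventual winner
    m[, "RETREAT"] <- 0.04
    m[, "WITHDRAWAL"] <- 0.03
    m <- m / rowSums(m)
  }
  m[lev, lev]
}

## log-normal bout duration parameters (meanlog, sdlog) per behavior, seconds
.boutDurations <- function() {
  list(`MOVE FORWARD` = c(log(1.5), 0.5), PUSH = c(log(2.5), 0.5),
       RESIST = c(log(2.5), 0.5), RETREAT = c(log(1.2), 0.4),
       WITHDRAWAL = c(log(1.5), 0.4), STILLNESS = c(log(4.0), 0.6))
}

#' Specify planted cells for the synthetic dyad
#'
#' @param cell_id character vector of cell identifiers (stable across
#'   sessions).
#' @param animal animal index (1 or 2) or id each cell belongs to.
#' @param class one of \code{"unique-own"}, \code{"unique-other"},
#'   \code{"coincident"}, \code{"mixed"}, \code{"nonspecific"},
#'   \code{"untuned"}.
#' @param behaviors list of character vectors: the target behavior(s). One
#'   behavior for unique classes; \code{c(own, other)} for coincident; two or
#'   more (own) behaviors for mixed/nonspecific; empty for untuned.
#' @param reliability target fraction of target bouts containing events, in
#'   (0, 1].
#' @param event_rate events per second (within-bout rate for tuned cells,
#'   homogeneous Poisson rate for untuned cells).
#' @return A \code{data.frame} with a \code{behaviors} list-column.
#' @export
plantedCells <- function(cell_id, animal, class, behaviors, reliability = 0.8,
                         event_rate = 0.15) {
  n <- length(cell_id)
  stopifnot(all(reliability > 0), all(reliability <= 1), all(event_rate >= 0))
  cls <- c("unique-own", "unique-other", "coincident", "mixed",
           "nonspecific", "untuned")
  stopifnot(all(class %in% cls))
  if (!is.list(behaviors)) behaviors <- as.list(behaviors)
  df <- data.frame(cell_id = as.character(cell_id),
                   animal = rep_len(animal, n),
                   class = rep_len(class, n),
                   reliability = rep_len(reliability, n),
                   event_rate = rep_len(event_rate, n),
                   stringsAsFactors = FALSE)
  df$behaviors <- lapply(rep_len(behaviors, n), function(b)
    if (length(b) > 0) normalizeBehavior(b) else character(0))
  if (anyDuplicated(df$cell_id)) stop("planted cell_ids must be unique")
  df
}

## default planted population: a mixture of all taxonomy classes per animal;
## tuned cells fire at the conventional within-behavior rate, untuned cells
## at a sparse spontaneous rate
.defaultPlanted <- function(n_cells, reliability = 0.8, event_rate = 0.15,
                            untuned_rate = 0.05) {
  uniq_beh <- c("MOVE FORWARD", "STILLNESS", "PUSH", "RESIST")
  coin_pairs <- list(c("STILLNESS", "MOVE FORWARD"),
                     c("MOVE FORWARD", "STILLNESS"),
                     c("MOVE FORWARD", "RETREAT"))
  mixed_pairs <- list(c("PUSH", "MOVE FORWARD"), c("STILLNESS", "RESIST"))
  out <- list()
  for (a in 1:2) {
    n_uo <- round(0.25 * n_cells); n_ut <- round(0.25 * n_cells)
    n_co <- round(0.10 * n_cells); n_mx <- round(0.05 * n_cells)
    n_un <- n_cells - n_uo - n_ut - n_co - n_mx
    cls <- c(rep("unique-own", n_uo), rep("unique-other", n_ut),
             rep("coincident", n_co), rep("mixed", n_mx),
             rep("untuned", n_un))
    beh <- c(rep_len(as.list(uniq_beh), n_uo), rep_len(as.list(uniq_beh), n_ut),
             rep_len(coin_pairs, n_co), rep_len(mixed_pairs, n_mx),
             rep_len(list(character(0)), n_un))
    out[[a]] <- plantedCells(sprintf("A%d_c%03d", a, seq_len(n_cells)),
                             animal = a, class = cls, behaviors = beh,
                             reliability = reliability,
                             event_rate = ifelse(cls == "untuned",
                                                 untuned_rate, event_rate))
  }
  rbind(out[[1]], out[[2]])
}

#' Configuration for the synthetic dyad generator
#'
#' Bundles the study-design parameters of a simulated tube-test dyad: 10
#' sessions of 5 trials by default, imaged at 20 Hz with the camera alternating
#' between the two animals on odd/even sessions, trial durations uniform
#' within 5-60 s, semi-Markov bout dynamics with interanimal coupling, and
#' GCaMP6f-like transients (fast linear rise, slow exponential decay) on the
#' planted cells.
#'
#' @param n_sessions number of sessions (default 10).
#' @param trials_per_session trials per session (default 5).
#' @param frame_rate imaging rate, Hz (default 20).
#' @param trial_duration_range min/max trial duration, seconds (default
#'   \code{c(5, 60)}).
#' @param behavior_coupling 6 x 6 row-stochastic matrix
#'   \code{P(partner | driver)}; see [defaultCoupling()].
#' @param dominance_profile \code{"strong"} (designated winner wins every
#'   trial and never retreats/withdraws) or \code{"moderate"}.
#' @param win_prob probability the designated winner wins a trial; defaults to
#'   1 for strong, 0.7 for moderate.
#' @param n_cells_per_animal cells per animal when \code{planted_cells} is
#'   \code{NULL} (default 40).
#' @param planted_cells a [plantedCells()] table, or \code{NULL} for the
#'   default mixture of taxonomy classes.
#' @param transient_rise rise time, frames (default 2).
#' @param transient_decay decay time constant, seconds (default 0.5).
#' @param transient_amplitude peak dF/F of a transient (default 1).
#' @param amplitude_jitter multiplicative amplitude jitter sd (default 0.2).
#' @param noise_sd additive Gaussian noise sd, dF/F units (default 0.05).
#' @param iti_range inter-trial interval range, seconds (default
#'   \code{c(10, 20)}); inter-trial frames are recorded but never analyzed.
#' @param lead_s,tail_s recording time before the first / after the last
#'   trial, seconds.
#' @param seed master seed; all randomness derives from it.
#' @return A validated list of class \code{"DyadSimConfig"}.
#' @export
dyadSimConfig <- function(n_sessions = 10, trials_per_session = 5,
                          frame_rate = 20, trial_duration_range = c(5, 60),
                          behavior_coupling = defaultCoupling(),
                          dominance_profile = c("strong", "moderate"),
                          win_prob = NULL, n_cells_per_animal = 40,
                          planted_cells = NULL, transient_rise = 2,
                          transient_decay = 0.5, transient_amplitude = 1,
                          amplitude_jitter = 0.2, noise_sd = 0.05,
                          iti_range = c(10, 20), lead_s = 5, tail_s = 5,
                          seed = 1L) {
  dominance_profile <- match.arg(dominance_profile)
  stopifnot(n_sessions >= 1, trials_per_session >= 1, frame_rate > 0,
            length(trial_duration_range) == 2,
            trial_duration_range[1] > 0,
            trial_duration_range[2] >= trial_duration_range[1],
            transient_rise >= 1, transient_decay > 0, noise_sd >= 0)
  lev <- ethogramLevels()
  bc <- behavior_coupling
  if (!is.matrix(bc) || !all(dim(bc) == c(6, 6)))
    stop("behavior_coupling must be a 6 x 6 matrix")
  if (is.null(rownames(bc))) dimnames(bc) <- list(lev, lev)
  bc <- bc[lev, lev]
  if (any(bc < 0) || any(abs(rowSums(bc) - 1) > 1e-8))
    stop("behavior_coupling rows must be non-negative and sum to 1")
  if (is.null(win_prob))
    win_prob <- if (dominance_profile == "strong") 1.0 else 0.7
  if (dominance_profile == "strong" && win_prob < 1)
    stop("strong profile requires win_prob = 1 (the designated winner must ",
         "never be forced to retreat or withdraw)")
  if (is.null(planted_cells))
    planted_cells <- .defaultPlanted(n_cells_per_animal)
  cfg <- list(n_sessions = as.integer(n_sessions),
              trials_per_session = as.integer(trials_per_session),
              frame_rate = frame_rate,
              trial_duration_range = trial_duration_range,
              behavior_coupling = bc, dominance_profile = dominance_profile,
              win_prob = win_prob,
              n_cells_per_animal = as.integer(n_cells_per_animal),
              planted_cells = planted_cells, transient_rise = transient_rise,
              transient_decay = transient_decay,
              transient_amplitude = transient_amplitude,
              amplitude_jitter = amplitude_jitter, noise_sd = noise_sd,
              iti_range = iti_range, lead_s = lead_s, tail_s = tail_s,
              seed = as.integer(seed))
  class(cfg) <- "DyadSimConfig"
  cfg
}

#' Calcium transient kernel
#'
#' GCaMP6f-like transient shape: linear rise over \code{rise_frames} frames to
#' a peak of 1, then exponential decay with time constant \code{decay_s},
#' truncated at five time constants.
#'
#' @param rise_frames rise duration in frames (default 2).
#' @param decay_s decay time constant in seconds (default 0.5).
#' @param frame_rate Hz (default 20).
#' @return Numeric vector of the kernel sampled at frame resolution, peak 1.
#' @export
transientKernel <- function(rise_frames = 2, decay_s = 0.5, frame_rate = 20) {
  stopifnot(rise_frames >= 1, decay_s > 0, frame_rate > 0)
  rise <- seq_len(rise_frames) / rise_frames
  nd <- max(1L, round(5 * decay_s * frame_rate))
  decay <- exp(-(seq_len(nd) / frame_rate) / decay_s)
  c(rise, decay)
}

## one trial: driver (winner) semi-Markov chain + coupled partner +
## scripted terminal retreat/withdrawal segment for the loser
.simTrial <- function(cfg, winner, loser) {
  lev <- ethogramLevels()
  tm <- .driverTransitions(cfg$dominance_profile)
  dp <- .boutDurations()
  D <- runif(1, cfg$trial_duration_range[1], cfg$trial_duration_range[2])
  term <- min(runif(1, 0.8, 2.5), D / 3)
  body <- D - term
  beh <- "MOVE FORWARD"
  w_beh <- character(0); w_start <- numeric(0); w_stop <- numeric(0)
  t <- 0
  while (t < body - 1e-9) {
    p <- dp[[beh]]
    dur <- min(rlnorm(1, p[1], p[2]), body - t)
    w_beh <- c(w_beh, beh); w_start <- c(w_start, t); w_stop <- c(w_stop, t + dur)
    t <- t + dur
    beh <- sample(lev, 1, prob = tm[beh, ])
  }
  # partner behavior coupled per driver bout
  l_beh <- vapply(w_beh, function(b)
    sample(lev, 1, prob = cfg$behavior_coupling[b, ]), character(1))
  # scripted trial end: the loser's final bout is an enforced RETREAT (winner
  # advancing) or an unenforced WITHDRAWAL (winner still)
  last <- w_beh[length(w_beh)]
  if (last %in% c("PUSH", "MOVE FORWARD", "RESIST")) {
    w_term <- "MOVE FORWARD"; l_term <- "RETREAT"
  } else {
    w_term <- "STILLNESS"; l_term <- "WITHDRAWAL"
  }
  w_beh <- c(w_beh, w_term); l_beh <- c(l_beh, l_term)
  w_start <- c(w_start, body); w_stop <- c(w_stop, D)
  bouts <- rbind(
    data.frame(animal_id = winner, behavior = w_beh, start_s = w_start,
               stop_s = w_stop, stringsAsFactors = FALSE),
    data.frame(animal_id = loser, behavior = l_beh, start_s = w_start,
               stop_s = w_stop, stringsAsFactors = FALSE))
  list(bouts = bouts, duration = D)
}

#' Simulate dyadic tube-test behavior
#'
#' Generates bout sequences for both animals of a dyad and the per-trial
#' outcomes under the semi-Markov coupled-chain model: each trial's duration
#' is drawn uniformly within \code{trial_duration_range}; the trial winner's
#' behavior follows a semi-Markov chain with log-normal bout durations; the
#' partner's behavior is drawn per driver bout from \code{behavior_coupling};
#' and the trial ends with the loser's scripted RETREAT (when the winner is
#' advancing) or WITHDRAWAL (when the winner is still). Under the strong
#' profile the designated winner wins every trial and never retreats or
#' withdraws.
#'
#' @param config a [dyadSimConfig()].
#' @param animals character(2) animal identifiers.
#' @return List with \code{bouts} (bout table, trial-relative seconds),
#'   \code{trials} (trial records with session-relative \code{start_s}) and
#'   \code{session_durations} (seconds, including lead/tail and intertrial
#'   intervals).
#' @export
simulateBehavior <- function(config, animals = c("A1", "A2")) {
  stopifnot(is(config, "DyadSimConfig"), length(animals) == 2)
  set.seed(config$seed)
  .simulateBehaviorNoSeed(config, animals)
}

.simulateBehaviorNoSeed <- function(config, animals = c("A1", "A2")) {
  bouts <- list(); trials <- list(); sdur <- numeric(config$n_sessions)
  for (s in seq_len(config$n_sessions)) {
    cursor <- config$lead_s
    for (tr in seq_len(config$trials_per_session)) {
      desig_wins <- rbinom(1, 1, config$win_prob) == 1
      winner <- if (desig_wins) animals[1] else animals[2]
      loser <- setdiff(animals, winner)
      sim <- .simTrial(config, winner, loser)
      b <- sim$bouts
      b$trial <- tr; b$session <- s
      bouts[[length(bouts) + 1]] <- b
      trials[[length(trials) + 1]] <- data.frame(
        session = s, trial = tr, start_s = cursor, winner_id = winner,
        loser_id = loser, latency_s = sim$duration, stringsAsFactors = FALSE)
      cursor <- cursor + sim$duration + runif(1, config$iti_range[1],
                                              config$iti_range[2])
    }
    # cursor already includes the final intertrial interval
    sdur[s] <- cursor + config$tail_s
  }
  bouts <- mergeAdjacentBouts(do.call(rbind, bouts))
  rownames(bouts) <- NULL
  list(bouts = bouts, trials = do.call(rbind, trials),
       session_durations = sdur)
}

## intersection intervals of behavior a by `own` with behavior b by `partner`
## within each trial; returns absolute-session-time intervals
.jointIntervals <- function(bouts, trials, own, partner, beh_own, beh_other) {
  out <- list()
  for (i in seq_len(nrow(trials))) {
    s <- trials$session[i]; tr <- trials$trial[i]; t0 <- trials$start_s[i]
    ba <- bouts[bouts$session == s & bouts$trial == tr &
                  bouts$animal_id == own & bouts$behavior == beh_own, ]
    bb <- bouts[bouts$session == s & bouts$trial == tr &
                  bouts$animal_id == partner & bouts$behavior == beh_other, ]
    if (nrow(ba) == 0 || nrow(bb) == 0) next
    for (j in seq_len(nrow(ba))) {
      lo <- pmax(ba$start_s[j], bb$start_s)
      hi <- pmin(ba$stop_s[j], bb$stop_s)
      k <- which(hi - lo > 1e-9)
      if (length(k) > 0)
        out[[length(out) + 1]] <- data.frame(start = t0 + lo[k],
                                             stop = t0 + hi[k])
    }
  }
  if (length(out) == 0) return(data.frame(start = numeric(0), stop = numeric(0)))
  do.call(rbind, out)
}

## plant events for one cell in one session; returns event times (s) and
## bout-participation counts
.plantCell <- function(cell, bouts_s, trials_s, session_dur, own, partner) {
  cls <- cell$class
  rel <- cell$reliability
  rate <- cell$event_rate
  beh <- cell$behaviors[[1]]
  poisson_bg <- function() {
    n <- rpois(1, rate * session_dur)
    sort(runif(n, 0, session_dur))
  }
  if (cls == "untuned") {
    return(list(times = poisson_bg(), n_bouts = 0L, n_hit = 0L,
                degenerate = FALSE))
  }
  # target intervals in session time
  if (cls == "coincident") {
    iv <- .jointIntervals(bouts_s, trials_s, own, partner, beh[1], beh[2])
  } else {
    target_animal <- if (cls == "unique-other") partner else own
    sel <- bouts_s$animal_id == target_animal & bouts_s$behavior %in% beh
    bb <- bouts_s[sel, ]
    t0 <- trials_s$start_s[match(paste(bb$session, bb$trial),
                                 paste(trials_s$session, trials_s$trial))]
    iv <- data.frame(start = t0 + bb$start_s, stop = t0 + bb$stop_s)
  }
  if (nrow(iv) == 0) {
    warning(sprintf("planted cell %s: target behavior absent in session; cell degenerates to untuned",
                    cell$cell_id), call. = FALSE)
    return(list(times = poisson_bg(), n_bouts = 0L, n_hit = 0L,
                degenerate = TRUE))
  }
  hit <- runif(nrow(iv)) < rel
  times <- numeric(0)
  for (j in which(hit)) {
    dur <- iv$stop[j] - iv$start[j]
    n_ev <- max(1L, rpois(1, rate * dur))
    times <- c(times, iv$start[j] + runif(n_ev) * dur)
  }
  list(times = sort(times), n_bouts = nrow(iv), n_hit = sum(hit),
       degenerate = FALSE)
}

#' Synthesize dF/F traces for one session
#'
#' Places ground-truth events for each planted cell of the session's imaged
#' animal according to its taxonomy class, convolves them with the transient
#' kernel (amplitude-jittered per event) and adds Gaussian noise.
#'
#' @param bouts,trials session-filtered bout table and trial records.
#' @param config a [dyadSimConfig()].
#' @param imaged id of the imaged animal; \code{partner} the other.
#' @param partner id of the partner animal.
#' @param session_dur recording duration in seconds.
#' @param cells planted-cell table for the imaged animal.
#' @return List: \code{traces} (cells x frames matrix), \code{events}
#'   (planted ground-truth event table with 0-based \code{frame}),
#'   \code{participation} (per-cell target-bout and hit counts),
#'   \code{degenerate} (cell ids that degenerated to untuned).
#' @export
simulateTraces <- function(bouts, trials, config, imaged, partner,
                           session_dur, cells) {
  fr <- config$frame_rate
  n_frames <- round(session_dur * fr)
  kern <- transientKernel(config$transient_rise, config$transient_decay, fr)
  traces <- matrix(0, nrow = nrow(cells), ncol = n_frames,
                   dimnames = list(cells$cell_id, NULL))
  ev <- list(); part <- list(); degen <- character(0)
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    p <- .plantCell(cell, bouts, trials, session_dur, imaged, partner)
    if (p$degenerate) degen <- c(degen, cell$cell_id)
    frames <- pmin(floor(p$times * fr), n_frames - 1L)
    tr <- numeric(n_frames)
    for (f in frames) {
      amp <- config$transient_amplitude *
        max(0.1, 1 + config$amplitude_jitter * rnorm(1))
      idx <- (f + 1L):min(n_frames, f + length(kern))
      tr[idx] <- tr[idx] + amp * kern[seq_along(idx)]
    }
    if (config$noise_sd > 0) tr <- tr + rnorm(n_frames, 0, config$noise_sd)
    traces[ci, ] <- tr
    if (length(frames) > 0)
      ev[[length(ev) + 1]] <- data.frame(cell_id = cell$cell_id,
                                         frame = as.integer(frames),
                                         time_s = p$times,
                                         stringsAsFactors = FALSE)
    part[[length(part) + 1]] <- data.frame(cell_id = cell$cell_id,
                                           n_bouts = p$n_bouts,
                                           n_hit = p$n_hit,
                                           stringsAsFactors = FALSE)
  }
  events <- if (length(ev) > 0) do.call(rbind, ev) else
    data.frame(cell_id = character(0), frame = integer(0), time_s = numeric(0))
  participation <- if (length(part) > 0) do.call(rbind, part) else
    data.frame(cell_id = character(0), n_bouts = integer(0),
               n_hit = integer(0))
  list(traces = traces, events = events,
       participation = participation, degenerate = degen)
}

## frame-level colData for one session
.sessionColData <- function(bouts_s, trials_s, n_frames, fr, imaged, partner) {
  tt <- (seq_len(n_frames) - 1) / fr
  trial <- rep(NA_integer_, n_frames)
  b_own <- rep(NA_character_, n_frames)
  b_oth <- rep(NA_character_, n_frames)
  for (i in seq_len(nrow(trials_s))) {
    t0 <- trials_s$start_s[i]; lat <- trials_s$latency_s[i]
    inb <- which(tt >= t0 - 1e-9 & tt < t0 + lat - 1e-9)
    if (length(inb) == 0) next
    trial[inb] <- trials_s$trial[i]
    rel <- tt[inb] - t0
    for (an in c(imaged, partner)) {
      bb <- bouts_s[bouts_s$trial == trials_s$trial[i] &
                      bouts_s$animal_id == an, ]
      bb <- bb[order(bb$start_s), ]
      if (nrow(bb) == 0) next
      bi <- findInterval(rel + 1e-9, bb$start_s)
      bi[bi < 1] <- 1L
      lab <- bb$behavior[bi]
      lab[rel >= bb$stop_s[bi] - 1e-9] <- NA_character_
      if (an == imaged) b_own[inb] <- lab else b_oth[inb] <- lab
    }
  }
  DataFrame(frame = seq_len(n_frames) - 1L, time_s = tt, trial = trial,
            behavior_own = b_own, behavior_other = b_oth)
}

#' Simulate a complete dyadic imaging dataset
#'
#' Composes [simulateBehavior()] and [simulateTraces()] into a
#' \linkS4class{DyadExperiment}: behavior for both animals in every session,
#' traces for the imaged animal only, with the camera alternating between the
#' two animals (odd-numbered sessions image the first animal, even-numbered
#' the second). Deterministic under a fixed \code{seed}.
#'
#' @param config a [dyadSimConfig()].
#' @param animals character(2) animal identifiers.
#' @return A \linkS4class{DyadExperiment} whose \code{groundTruth()} list
#'   carries \code{cells} (the planted table), \code{events} (planted event
#'   tables per session), \code{participation} (per session/cell target-bout
#'   and hit counts) and \code{degenerate}.
#' @examples
#' cfg <- dyadSimConfig(n_sessions = 2, n_cells_per_animal = 8, seed = 7)
#' dex <- simulateDyad(cfg)
#' dex
#' @export
simulateDyad <- function(config, animals = c("A1", "A2")) {
  stopifnot(is(config, "DyadSimConfig"))
  set.seed(config$seed)
  beh <- .simulateBehaviorNoSeed(config, animals)
  planted <- config$planted_cells
  planted$animal_id <- ifelse(planted$animal %in% animals, planted$animal,
                              animals[as.integer(planted$animal)])
  ses <- vector("list", config$n_sessions)
  truth_events <- vector("list", config$n_sessions)
  truth_part <- list()
  degen <- list()
  for (s in seq_len(config$n_sessions)) {
    imaged <- if (s %% 2 == 1) animals[1] else animals[2]
    partner <- setdiff(animals, imaged)
    bouts_s <- beh$bouts[beh$bouts$session == s, ]
    trials_s <- beh$trials[beh$trials$session == s, ]
    cells <- planted[planted$animal_id == imaged, ]
    sim <- simulateTraces(bouts_s, trials_s, config, imaged, partner,
                          beh$session_durations[s], cells)
    cd <- .sessionColData(bouts_s, trials_s, ncol(sim$traces),
                          config$frame_rate, imaged, partner)
    se <- SummarizedExperiment(
      assays = list(dff = sim$traces),
      rowData = DataFrame(cell_id = cells$cell_id, class = cells$class,
                          behaviors = vapply(cells$behaviors, paste,
                                             character(1), collapse = ";"),
                          reliability = cells$reliability,
                          animal = cells$animal_id),
      colData = cd)
    metadata(se) <- list(session = s, imaged_animal = imaged,
                         frame_rate = config$frame_rate,
                         session_duration = beh$session_durations[s])
    ses[[s]] <- se
    e <- sim$events; if (nrow(e) > 0) e$session <- s
    truth_events[[s]] <- e
    pp <- sim$participation
    if (nrow(pp) > 0) {
      pp$session <- s
      truth_part[[length(truth_part) + 1]] <- pp
    }
    if (length(sim$degenerate) > 0)
      degen[[length(degen) + 1]] <- data.frame(session = s,
                                               cell_id = sim$degenerate)
  }
  truth <- list(cells = planted, events = truth_events,
                participation = do.call(rbind, truth_part),
                degenerate = if (length(degen) > 0) do.call(rbind, degen)
                  else data.frame(session = integer(0), cell_id = character(0)))
  DyadExperiment(sessions = ses, bouts = beh$bouts, trials = beh$trials,
                 animals = animals, truth = truth)
}
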