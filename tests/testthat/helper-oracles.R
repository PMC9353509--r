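# Independent oracles and fixture builders used across the suite.

# Brute-force O(n^2) mixed discrete-continuous k-NN mutual information
# (bits). Independent of the package's C++ path: direct distance
# computations, no sorted-array tricks.
bruteForceMI <- function(x, y, k = 4) {
  cnt <- table(y)
  keep <- cnt[as.character(y)] > 1
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  ks <- cs <- ms <- numeric(n)
  for (i in seq_len(n)) {
    same <- setdiff(which(y == y[i]), i)
    c_i <- length(same) + 1
    kk <- min(k, c_i - 1)
    d <- sort(abs(x[same] - x[i]))[kk]
    m <- sum(abs(x - x[i]) < d) # strict; includes self when d > 0
    ks[i] <- digamma(kk); cs[i] <- digamma(c_i); ms[i] <- digamma(max(m, 1))
  }
  max(0, (digamma(n) + mean(ks) - mean(cs) - mean(ms)) / log(2))
}

# True MI (bits) between a balanced binary class and a unit-variance Gaussian
# shifted by `mu`, by numerical quadrature.
gaussMixMI <- function(mu) {
  f <- function(x) {
    f0 <- dnorm(x); f1 <- dnorm(x, mean = mu); fm <- (f0 + f1) / 2
    out <- 0.5 * f0 * log2(f0 / fm) + 0.5 * f1 * log2(f1 / fm)
    out[!is.finite(out)] <- 0
    out
  }
  integrate(f, -10, mu + 10, rel.tol = 1e-10)$value
}

# Small, fast simulated dyad shared by several tests.
smallDyad <- function(n_sessions = 1, n_cells = 6, seed = 42, ...) {
  simulateDyad(dyadSimConfig(n_sessions = n_sessions,
                             n_cells_per_animal = n_cells, seed = seed, ...))
}

# A noiseless trace with transients planted at given 0-based frames.
plantedTrace <- function(frames, n_frames, amplitude = 1, decay_s = 0.5,
                         rise_frames = 2, frame_rate = 20, noise_sd = 0) {
  k <- transientKernel(rise_frames, decay_s, frame_rate) * amplitude
  x <- numeric(n_frames)
  for (f in frames) {
    idx <- (f + 1):min(n_frames, f + length(k))
    x[idx] <- x[idx] + k[seq_along(idx)]
  }
  if (noise_sd > 0) x <- x + rnorm(n_frames, 0, noise_sd)
  x
}

# Check that each animal's bouts tile each trial with no overlap.
expectTiling <- function(bouts, trials, tol = 1e-6) {
  for (i in seq_len(nrow(trials))) {
    for (an in unique(bouts$animal_id)) {
      b <- bouts[bouts$session == trials$session[i] &
                   bouts$trial == trials$trial[i] & bouts$animal_id == an, ]
      b <- b[order(b$start_s), ]
      expect_gt(nrow(b), 0)
      expect_lt(abs(b$start_s[1]), tol)
      expect_lt(abs(b$stop_s[nrow(b)] - trials$latency_s[i]), tol)
      if (nrow(b) > 1)
        expect_true(all(abs(b$start_s[-1] - b$stop_s[-nrow(b)]) < tol))
    }
  }
}

# A hand-built single-session dyad (zero traces, explicit frame labels) for
# scorer-level checks.
makeTinyDex <- function(own, other, trial = NULL, n_cells = 1,
                        cell_ids = sprintf("c%d", seq_len(n_cells))) {
  n <- length(own)
  if (is.null(trial)) trial <- rep(1L, n)
  cd <- S4Vectors::DataFrame(frame = seq_len(n) - 1L,
                             time_s = (seq_len(n) - 1) / 20,
                             trial = trial, behavior_own = own,
                             behavior_other = other)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dff = matrix(0, n_cells, n, dimnames = list(cell_ids, NULL))),
    colData = cd)
  S4Vectors::metadata(se) <- list(session = 1L, imaged_animal = "A1",
                                  frame_rate = 20, session_duration = n / 20)
  bouts <- data.frame(animal_id = "A1", behavior = "STILLNESS", start_s = 0,
                      stop_s = n / 20, trial = 1L, session = 1L)
  trials <- data.frame(session = 1L, trial = 1L, start_s = 0,
                       winner_id = "A1", loser_id = "A2",
                       latency_s = n / 20)
  DyadExperiment(sessions = list(se), bouts = bouts, trials = trials,
                 animals = c("A1", "A2"))
}

# The planted population used by the class-recovery experiment: unique cells
# mostly on behaviors whose partner conditionals are diffuse (see the methods
# vignette on own/other identifiability), plus coincident and untuned cells.
recoveryPlanted <- function() {
  # unique planting avoids STILLNESS: it is the residual category covering
  # most of the in-trial time, so its indicator carries too little
  # information for MI detection and its encoders are uninterpretable anyway
  own_beh <- rep(c("MOVE FORWARD", "PUSH", "RESIST"), c(18, 6, 6))
  oth_beh <- rep(c("MOVE FORWARD", "RETREAT", "WITHDRAWAL"), c(12, 9, 9))
  coin <- c(rep(list(c("STILLNESS", "MOVE FORWARD")), 4),
            rep(list(c("MOVE FORWARD", "STILLNESS")), 3),
            rep(list(c("MOVE FORWARD", "RETREAT")), 3))
  # within-bout rate 1.0 ev/s for tuned cells and 0.05 ev/s spontaneous for
  # untuned cells: the power regime in which planted tuning is detectable and
  # the 34% occupancy gate binds (see the methods vignette)
  rbind(
    plantedCells(sprintf("uo%02d", 1:30), 1, "unique-own",
                 as.list(own_beh), reliability = 0.9, event_rate = 1.0),
    plantedCells(sprintf("ut%02d", 1:30), 1, "unique-other",
                 as.list(oth_beh), reliability = 0.9, event_rate = 1.0),
    plantedCells(sprintf("co%02d", 1:10), 1, "coincident", coin,
                 reliability = 0.9, event_rate = 1.0),
    plantedCells(sprintf("un%02d", 1:30), 1, "untuned",
                 list(character(0)), event_rate = 0.05))
}
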