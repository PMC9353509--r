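# Bout parsing, rasterization, dominance scoring, behavior statistics and the
# interanimal co-occurrence matrix.

writeBoutsCSV <- function(df) {
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  f
}

test_that("a well-formed annotation file round-trips into a bout table", {
  f <- writeBoutsCSV(data.frame(
    subject = "A", behavior = c("PUSH", "STILLNESS"),
    start_s = c(0, 4), stop_s = c(4, 10), trial = 1L, session = 1L))
  b <- readBoutTable(f)
  expect_equal(nrow(b), 2)
  expect_equal(b$behavior, c("PUSH", "STILLNESS"))
})

test_that("overlapping bouts of one animal and unknown labels are hard errors", {
  f <- writeBoutsCSV(data.frame(
    subject = "A", behavior = c("PUSH", "RESIST"),
    start_s = c(0, 2), stop_s = c(4, 6), trial = 1L, session = 1L))
  expect_error(readBoutTable(f), "overlapping bouts.*rows")
  f2 <- writeBoutsCSV(data.frame(
    subject = "A", behavior = "JUMP", start_s = 0, stop_s = 1,
    trial = 1L, session = 1L))
  expect_error(readBoutTable(f2), "unknown behavior")
  # overlap across animals is fine
  f3 <- writeBoutsCSV(data.frame(
    subject = c("A", "B"), behavior = c("PUSH", "RESIST"),
    start_s = 0, stop_s = 4, trial = 1L, session = 1L))
  expect_silent(b <- readBoutTable(f3))
})

test_that("unannotated in-trial time is gap-filled as STILLNESS", {
  f <- writeBoutsCSV(data.frame(
    subject = "A", behavior = "PUSH", start_s = 0, stop_s = 4,
    trial = 1L, session = 1L))
  trials <- data.frame(session = 1L, trial = 1L, latency_s = 10)
  b <- readBoutTable(f, trials = trials)
  expect_equal(nrow(b), 2)
  fill <- b[b$behavior == "STILLNESS", ]
  expect_equal(c(fill$start_s, fill$stop_s), c(4, 10))
})

test_that("rasterization uses half-open frame intervals", {
  b <- data.frame(animal_id = "A", behavior = "PUSH", start_s = 0,
                  stop_s = 0.5, trial = 1L, session = 1L)
  r <- rasterizeBouts(b, frame_rate = 20)
  expect_equal(r$frame, 0:9)
  expect_true(all(r$behavior == "PUSH"))
  # a boundary exactly at a frame time belongs to the later bout
  b2 <- data.frame(animal_id = "A", behavior = c("PUSH", "RESIST"),
                   start_s = c(0, 0.5), stop_s = c(0.5, 1), trial = 1L,
                   session = 1L)
  r2 <- rasterizeBouts(b2, frame_rate = 20)
  expect_equal(r2$behavior[r2$frame == 10], "RESIST")
  expect_equal(sum(r2$behavior == "PUSH"), 10)
})

test_that("rasterize/de-rasterize recovers bout boundaries to one frame", {
  set.seed(31)
  lev <- ethogramLevels()
  for (rep in 1:5) {
    n <- sample(3:6, 1)
    edges <- sort(c(0, round(runif(n - 1, 0.5, 14.5), 2), 15))
    b <- data.frame(animal_id = "A",
                    behavior = sample(lev, n, replace = TRUE),
                    start_s = edges[-length(edges)], stop_s = edges[-1],
                    trial = 1L, session = 1L)
    b <- dyadtune:::mergeAdjacentBouts(b)
    r <- rasterizeBouts(b, frame_rate = 20)
    b2 <- boutsFromRaster(r, frame_rate = 20)
    expect_equal(nrow(b2), nrow(b))
    expect_equal(b2$behavior, b$behavior)
    expect_true(all(abs(b2$start_s - b$start_s) <= 1 / 20 + 1e-9))
    expect_true(all(abs(b2$stop_s - b$stop_s) <= 1 / 20 + 1e-9))
  }
})

test_that("dominance scoring applies the strong/moderate/tied rules", {
  mk <- function(winners) data.frame(session = rep(seq_len(length(winners) / 5),
                                                   each = 5),
                                     trial = rep(1:5, length(winners) / 5),
                                     winner_id = winners)
  d <- scoreDominance(mk(rep("A", 50)))
  expect_equal(d$strength, "strong")
  expect_equal(d$win_fraction, 1.0)
  # per-session wins 3,2,3,2,3,3,2,3,2,3 of 5: fraction 0.52 -> moderate
  wins_a <- c(3, 2, 3, 2, 3, 3, 2, 3, 2, 3)
  winners <- unlist(lapply(wins_a, function(w) c(rep("A", w), rep("B", 5 - w))))
  d2 <- scoreDominance(mk(winners))
  expect_equal(d2$winner, "A")
  expect_equal(d2$win_fraction, 0.52)
  expect_equal(d2$strength, "moderate")
  d3 <- scoreDominance(mk(c(rep("A", 25), rep("B", 25))))
  expect_equal(d3$status, "tied")
  expect_true(is.na(d3$strength))
})

test_that("behavior statistics: frequencies, durations, invariances", {
  b <- data.frame(animal_id = "A",
                  behavior = c("PUSH", "STILLNESS", "PUSH", "STILLNESS"),
                  start_s = c(0, 2, 5, 6), stop_s = c(2, 5, 6, 10),
                  trial = 1L, session = 1L)
  st <- behaviorStats(b)
  expect_equal(st$n_bouts[st$behavior == "PUSH"], 2L)
  expect_equal(st$norm_duration[st$behavior == "PUSH"], 0.3)
  expect_equal(sum(st$norm_duration), 1, tolerance = 1e-9)
  # single all-STILLNESS trial
  b2 <- data.frame(animal_id = "A", behavior = "STILLNESS", start_s = 0,
                   stop_s = 10, trial = 1L, session = 1L)
  st2 <- behaviorStats(b2)
  expect_equal(st2$norm_duration[st2$behavior == "STILLNESS"], 1)
  expect_true(all(st2$norm_duration[st2$behavior != "STILLNESS"] == 0))
  # invariant to bout-order permutation
  set.seed(4)
  st3 <- behaviorStats(b[sample(nrow(b)), ])
  expect_equal(st3, st)
})

test_that("normalized durations sum to 1 per animal/session on simulated data", {
  beh <- simulateBehavior(dyadSimConfig(n_sessions = 2, seed = 77))
  st <- behaviorStats(beh$bouts)
  sums <- aggregate(norm_duration ~ session + animal_id, st, sum)
  expect_true(all(abs(sums$norm_duration - 1) < 1e-9))
  # strong profile: winner never retreats/withdraws
  win <- unique(beh$trials$winner_id)
  wst <- st[st$animal_id == win & st$behavior %in% c("RETREAT", "WITHDRAWAL"), ]
  expect_true(all(wst$total_s == 0))
})

test_that("co-occurrence phi is +/-1 on the alternating raster and NA when constant", {
  a <- rep(c("PUSH", "STILLNESS"), 50)
  b <- rep(c("RESIST", "STILLNESS"), 50)
  m <- cooccurrenceMatrix(a, b)
  expect_equal(m["PUSH", "RESIST"], 1)
  expect_equal(m["PUSH", "STILLNESS"], -1)
  expect_true(is.na(m["RETREAT", "RESIST"])) # RETREAT never occurs
  # both indicators constant -> flagged absent
  m2 <- cooccurrenceMatrix(rep("PUSH", 40), rep("RESIST", 40))
  expect_true(all(is.na(m2)))
})

test_that("co-occurrence of independent rasters is near zero and swapping transposes", {
  set.seed(9)
  lev <- ethogramLevels()
  a <- sample(lev, 1e4, replace = TRUE)
  b <- sample(lev, 1e4, replace = TRUE)
  m <- cooccurrenceMatrix(a, b)
  expect_true(all(abs(m[!is.na(m)]) < 0.05))
  expect_equal(cooccurrenceMatrix(b, a), t(m))
})

test_that("dyad co-occurrence on simulated data shows the PUSH/RESIST coupling", {
  beh <- simulateBehavior(dyadSimConfig(n_sessions = 3, seed = 21),
                          animals = c("W", "L"))
  m <- dyadCooccurrence(beh$bouts, animals = c("W", "L"), frame_rate = 20,
                        trials = beh$trials)
  # driver PUSH mostly answered by partner RESIST: positive correlation
  expect_gt(m["PUSH", "RESIST"], 0.2)
  expect_equal(dim(m), c(6L, 6L))
})
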