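# Reliability, consistency, event rate and population activity.

test_that("reliability is exactly 100 x occupancy", {
  iv <- data.frame(start = seq(0, 40, 10), end = seq(5, 45, 10))
  expect_equal(cellReliability(c(2L, 12L, 41L), iv), 60)
  expect_equal(cellReliability(as.integer(iv$start), iv), 100)
  expect_identical(cellReliability(c(2L, 12L, 41L), iv),
                   100 * occupancy(c(2L, 12L, 41L), iv))
})

test_that("planted reliability is recovered within binomial uncertainty", {
  pc <- plantedCells("c1", 1, "unique-own", list("STILLNESS"),
                     reliability = 0.6, event_rate = 0.1)
  cfg <- dyadSimConfig(n_sessions = 5, trials_per_session = 8,
                       planted_cells = pc, noise_sd = 0, seed = 71)
  dex <- simulateDyad(cfg)
  rel <- numeric(0)
  for (s in which(seq_len(5) %% 2 == 1)) {
    it <- dyadtune:::.inTrialData(sessions(dex)[[s]])
    ev0 <- groundTruth(dex)$events[[s]]
    pos <- dyadtune:::.eventsToInTrial(ev0$frame[ev0$cell_id == "c1"], it$idx)
    runs <- dyadtune:::.flagRuns(it$own == "STILLNESS", it$trial)
    rel <- c(rel, cellReliability(pos, runs) * nrow(runs))
  }
  part <- groundTruth(dex)$participation
  n <- sum(part$n_bouts)
  expect_lt(abs(sum(rel) / 100 / n - 0.6), 4 * sqrt(0.6 * 0.4 / n))
})

test_that("event rate divides events by behavior time and is scale invariant", {
  iv <- data.frame(start = 0, end = 400) # 20 s at 20 Hz
  expect_equal(cellEventRate(c(10L, 100L, 250L), iv), 0.15)
  expect_equal(cellEventRate(integer(0), iv), 0)
  iv2 <- data.frame(start = c(0, 500), end = c(400, 900)) # doubled duration
  ev2 <- c(10L, 100L, 250L, 510L, 600L, 750L)             # doubled events
  expect_equal(cellEventRate(ev2, iv2), 0.15)
  expect_error(cellEventRate(1L, data.frame(start = 5, end = 5)), "positive")
})

test_that("consistency separates overall encoding from per-behavior encoding", {
  mk <- function(id, classes, behaviors) data.frame(
    session = seq_along(classes), cell_id = id, class = classes,
    behaviors = behaviors, n_significant = as.integer(classes != "untuned"),
    stillness_flag = FALSE, stringsAsFactors = FALSE)
  cl <- rbind(
    # encodes every session but a different behavior each time
    mk("c71", rep("unique-own", 5),
       paste0("own:", c("PUSH", "RESIST", "MOVE FORWARD", "STILLNESS",
                        "RETREAT"))),
    # encodes 2 of 5 sessions
    mk("c87", c("unique-own", "untuned", "untuned", "unique-own", "untuned"),
       c("own:PUSH", "", "", "own:PUSH", "")),
    # never encodes
    mk("c00", rep("untuned", 5), rep("", 5)))
  cons <- cellConsistency(cl)
  ov <- setNames(cons$overall$consistency_pct, cons$overall$cell_id)
  expect_equal(ov[["c71"]], 100)
  expect_equal(ov[["c87"]], 40)
  expect_equal(ov[["c00"]], 0)
  pb71 <- cons$per_behavior[cons$per_behavior$cell_id == "c71", ]
  expect_true(all(pb71$consistency_pct == 20))
  pb87 <- cons$per_behavior[cons$per_behavior$cell_id == "c87", ]
  expect_equal(pb87$consistency_pct[pb87$target == "own:PUSH"], 40)
  # overall consistency bounds the per-behavior consistencies
  for (id in unique(cons$per_behavior$cell_id))
    expect_gte(ov[[id]],
               max(cons$per_behavior$consistency_pct[
                 cons$per_behavior$cell_id == id]))
})

test_that("single-session cells are excluded from consistency", {
  cl <- data.frame(session = c(1L, 2L, 1L), cell_id = c("a", "a", "b"),
                   class = "unique-own", behaviors = "own:PUSH",
                   n_significant = 1L, stillness_flag = FALSE)
  expect_message(cons <- cellConsistency(cl), "excluded")
  expect_identical(cons$excluded, "b")
  expect_identical(cons$overall$cell_id, "a")
})

test_that("population activity is bounded, guards zero range, tracks dominance", {
  # planted asymmetry: high event rate in the designated winner, low in the
  # loser
  pc <- rbind(
    plantedCells(sprintf("w%d", 1:6), 1, "untuned", list(character(0)),
                 event_rate = 0.6),
    plantedCells(sprintf("l%d", 1:6), 2, "untuned", list(character(0)),
                 event_rate = 0.03))
  cfg <- dyadSimConfig(n_sessions = 2, planted_cells = pc, noise_sd = 0.02,
                       seed = 72)
  dex <- simulateDyad(cfg)
  pa <- populationActivity(dex)
  expect_true(all(pa$frames$activity >= 0 & pa$frames$activity <= 1))
  w <- pa$by_status$activity[pa$by_status$imaged_is_winner]
  l <- pa$by_status$activity[!pa$by_status$imaged_is_winner]
  expect_gt(w, l)
  # all-identical constant traces: defined as 0 with a warning
  se <- sessions(dex)[[1]]
  SummarizedExperiment::assay(se, "dff")[1, ] <- 5
  dex2 <- DyadExperiment(sessions = c(list(se), as.list(sessions(dex))[-1]),
                         bouts = boutTable(dex), trials = trialRecords(dex),
                         animals = animalIds(dex))
  expect_warning(pa2 <- populationActivity(dex2), "zero-range")
  expect_true(all(pa2$frames$activity >= 0 & pa2$frames$activity <= 1))
})

test_that("population activity is invariant to per-cell affine rescaling", {
  pc <- plantedCells(sprintf("c%d", 1:4), 1, "untuned", list(character(0)),
                     event_rate = 0.3)
  cfg <- dyadSimConfig(n_sessions = 1, planted_cells = pc, noise_sd = 0.02,
                       seed = 73)
  dex <- simulateDyad(cfg)
  pa1 <- populationActivity(dex)
  se <- sessions(dex)[[1]]
  m <- SummarizedExperiment::assay(se, "dff")
  m2 <- sweep(sweep(m, 1, c(2, 0.5, 10, 1), "*"), 1, c(-1, 3, 0, 7), "+")
  se2 <- se
  SummarizedExperiment::assay(se2, "dff") <- m2
  dex2 <- DyadExperiment(sessions = list(se2), bouts = boutTable(dex),
                         trials = trialRecords(dex), animals = animalIds(dex))
  pa2 <- populationActivity(dex2)
  expect_equal(pa2$frames$activity, pa1$frames$activity, tolerance = 1e-12)
})

test_that("cell metrics table reports reliability and rate per encoded behavior", {
  own <- rep(rep(c("PUSH", "STILLNESS"), times = c(40, 60)), 20)
  other <- rep("STILLNESS", length(own))
  cl <- data.frame(session = 1L, cell_id = "c1", class = "unique-own",
                   behaviors = "own:PUSH", n_significant = 1L,
                   stillness_flag = FALSE)
  cd <- S4Vectors::DataFrame(frame = seq_along(own) - 1L,
                             time_s = (seq_along(own) - 1) / 20,
                             trial = rep(1L, length(own)),
                             behavior_own = own, behavior_other = other)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dff = matrix(0, 1, length(own),
                               dimnames = list("c1", NULL))), colData = cd)
  S4Vectors::metadata(se) <- list(session = 1L, imaged_animal = "A1",
                                  frame_rate = 20,
                                  session_duration = length(own) / 20)
  dex <- DyadExperiment(
    sessions = list(se),
    bouts = data.frame(animal_id = "A1", behavior = "STILLNESS", start_s = 0,
                       stop_s = length(own) / 20, trial = 1L, session = 1L),
    trials = data.frame(session = 1L, trial = 1L, start_s = 0,
                        winner_id = "A1", loser_id = "A2",
                        latency_s = length(own) / 20),
    animals = c("A1", "A2"))
  push_starts <- which(own == "PUSH" & c("", own[-length(own)]) != "PUSH")
  ev <- data.frame(cell_id = "c1", session = 1L,
                   frame = as.integer(push_starts[1:10]) + 1L)
  met <- cellMetrics(dex, ev, cl)
  expect_equal(nrow(met), 1)
  expect_equal(met$reliability_pct, 100 * 10 / 20)
  expect_equal(met$event_rate, 10 / (20 * 40 / 20))
})
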