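# Synthetic dyad generator: behavior structure, ground truth, determinism.

test_that("behavior bouts tile trials disjointly and durations stay in range", {
  cfg <- dyadSimConfig(n_sessions = 3, seed = 101)
  beh <- simulateBehavior(cfg)
  expect_true(all(beh$trials$latency_s >= cfg$trial_duration_range[1]))
  expect_true(all(beh$trials$latency_s <= cfg$trial_duration_range[2]))
  expectTiling(beh$bouts, beh$trials)
})

test_that("each trial has exactly one loser ending in RETREAT or WITHDRAWAL", {
  beh <- simulateBehavior(dyadSimConfig(n_sessions = 2,
                                        dominance_profile = "moderate",
                                        seed = 55))
  for (i in seq_len(nrow(beh$trials))) {
    tr <- beh$trials[i, ]
    b <- beh$bouts[beh$bouts$session == tr$session &
                     beh$bouts$trial == tr$trial, ]
    last <- do.call(rbind, lapply(split(b, b$animal_id), function(d)
      d[which.max(d$stop_s), ]))
    lose_last <- last$behavior[last$animal_id == tr$loser_id]
    win_last <- last$behavior[last$animal_id == tr$winner_id]
    expect_true(lose_last %in% c("RETREAT", "WITHDRAWAL"))
    expect_false(win_last %in% c("RETREAT", "WITHDRAWAL"))
  }
})

test_that("strong profile: designated winner wins all and never retreats/withdraws", {
  cfg <- dyadSimConfig(n_sessions = 10, dominance_profile = "strong",
                       seed = 7)
  beh <- simulateBehavior(cfg, animals = c("W", "L"))
  expect_true(all(beh$trials$winner_id == "W"))
  expect_gte(sum(beh$trials$winner_id == "W"), 45)
  wb <- beh$bouts[beh$bouts$animal_id == "W", ]
  expect_identical(sum(wb$behavior %in% c("RETREAT", "WITHDRAWAL")), 0L)
})

test_that("deterministic coupling forces full PUSH/RESIST overlap", {
  cm <- defaultCoupling()
  cm["PUSH", ] <- 0
  cm["PUSH", "RESIST"] <- 1
  cfg <- dyadSimConfig(n_sessions = 2, behavior_coupling = cm, seed = 3)
  beh <- simulateBehavior(cfg, animals = c("W", "L"))
  # every PUSH bout of the driver (trial winner) is fully covered by RESIST
  # bouts of the partner
  for (i in seq_len(nrow(beh$trials))) {
    tr <- beh$trials[i, ]
    b <- beh$bouts[beh$bouts$session == tr$session &
                     beh$bouts$trial == tr$trial, ]
    push <- b[b$animal_id == tr$winner_id & b$behavior == "PUSH", ]
    res <- b[b$animal_id == tr$loser_id & b$behavior == "RESIST", ]
    if (nrow(push) == 0) next
    for (j in seq_len(nrow(push))) {
      cover <- sum(pmax(0, pmin(push$stop_s[j], res$stop_s) -
                          pmax(push$start_s[j], res$start_s)))
      expect_equal(cover, push$stop_s[j] - push$start_s[j], tolerance = 1e-9)
    }
  }
})

test_that("same seed reproduces the dataset exactly; imaging alternates", {
  cfg <- dyadSimConfig(n_sessions = 4, n_cells_per_animal = 6, seed = 99)
  d1 <- simulateDyad(cfg)
  d2 <- simulateDyad(cfg)
  expect_identical(boutTable(d1), boutTable(d2))
  expect_identical(trialRecords(d1), trialRecords(d2))
  for (s in 1:4) {
    expect_identical(SummarizedExperiment::assay(sessions(d1)[[s]], "dff"),
                     SummarizedExperiment::assay(sessions(d2)[[s]], "dff"))
    expect_identical(imagedAnimal(d1, s),
                     animalIds(d1)[if (s %% 2 == 1) 1 else 2])
  }
  expect_identical(nrow(sessions(d1)[[1]]),
                   sum(groundTruth(d1)$cells$animal_id == animalIds(d1)[1]))
})

test_that("noiseless unique cell fires in every target bout and nowhere else", {
  pc <- plantedCells("c1", animal = 1, class = "unique-own",
                     behaviors = list("PUSH"), reliability = 1,
                     event_rate = 0.15)
  cfg <- dyadSimConfig(n_sessions = 1, planted_cells = pc, noise_sd = 0,
                       seed = 5)
  dex <- simulateDyad(cfg)
  gt <- groundTruth(dex)
  part <- gt$participation
  expect_equal(part$n_hit, part$n_bouts) # reliability 1: every bout hit
  # all planted events lie inside own PUSH bouts
  ev <- gt$events[[1]]
  se <- sessions(dex)[[1]]
  beh <- SummarizedExperiment::colData(se)$behavior_own
  expect_true(all(beh[ev$frame + 1L] == "PUSH"))
})

test_that("planted reliability converges over many bouts (law of large numbers)", {
  pc <- plantedCells("c1", animal = 1, class = "unique-own",
                     behaviors = list("STILLNESS"), reliability = 0.6)
  cfg <- dyadSimConfig(n_sessions = 20, trials_per_session = 8,
                       planted_cells = pc, noise_sd = 0, seed = 12)
  dex <- simulateDyad(cfg)
  part <- groundTruth(dex)$participation
  n_bouts <- sum(part$n_bouts)
  expect_gte(n_bouts, 200)
  p_hat <- sum(part$n_hit) / n_bouts
  se_hat <- sqrt(0.6 * 0.4 / n_bouts)
  expect_lt(abs(p_hat - 0.6), 4 * se_hat)
})

test_that("transient kernel decays with the configured time constant", {
  k <- transientKernel(rise_frames = 2, decay_s = 0.5, frame_rate = 20)
  decay <- k[-(1:2)]
  tt <- seq_along(decay) / 20
  fit <- lm(log(decay) ~ tt)
  tau_hat <- -1 / coef(fit)[["tt"]]
  expect_equal(tau_hat, 0.5, tolerance = 1e-6)
  expect_equal(max(k), 1)
  expect_lte(length(decay), round(5 * 0.5 * 20))
})

test_that("a planted behavior absent from the script degenerates to untuned", {
  # under the strong profile the designated winner never retreats, so a
  # RETREAT-own cell in animal 1 has no target bouts
  pc <- plantedCells("c1", animal = 1, class = "unique-own",
                     behaviors = list("RETREAT"), reliability = 1)
  cfg <- dyadSimConfig(n_sessions = 1, planted_cells = pc,
                       dominance_profile = "strong", seed = 8)
  expect_warning(dex <- simulateDyad(cfg), "degenerates to untuned")
  expect_identical(groundTruth(dex)$degenerate$cell_id, "c1")
})

test_that("invalid configurations are rejected", {
  bad <- defaultCoupling()
  bad[1, 1] <- bad[1, 1] + 0.5
  expect_error(dyadSimConfig(behavior_coupling = bad), "sum to 1")
  expect_error(plantedCells("c", 1, "unique-own", list("PUSH"),
                            reliability = 0), "reliability")
  expect_error(plantedCells("c", 1, "oddclass", list("PUSH")))
})
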