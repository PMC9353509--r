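# Taxonomy rules and the session-level tuning scorer.

mkScore <- function(cell, animal, b1, sig, b2 = NA_character_, occ = 0.5) {
  data.frame(session = 1L, cell_id = cell, target_animal = animal,
             behavior1 = b1, behavior2 = b2, n_bouts = 10L, occupancy = occ,
             mis = if (sig) 0.2 else 0.01, null_threshold = 0.05,
             n_shuffles = 100L, significant = sig, stringsAsFactors = FALSE)
}

test_that("taxonomy rules map significant targets to classes", {
  lev <- ethogramLevels()
  sc <- rbind(
    # only own-PUSH significant -> unique-own
    do.call(rbind, lapply(lev, function(b)
      mkScore("u1", "own", b, b == "PUSH"))),
    # own-PUSH and own-RESIST -> mixed
    do.call(rbind, lapply(lev, function(b)
      mkScore("m1", "own", b, b %in% c("PUSH", "RESIST")))),
    # own-PUSH and other-RESIST -> mixed across animals, reported separately
    rbind(mkScore("x1", "own", "PUSH", TRUE),
          mkScore("x1", "other", "RESIST", TRUE)),
    # three significant behaviors -> nonspecific
    do.call(rbind, lapply(lev, function(b)
      mkScore("n1", "own", b, b %in% c("PUSH", "RESIST", "RETREAT")))),
    # only other-MOVE FORWARD -> unique-other
    mkScore("o1", "other", "MOVE FORWARD", TRUE),
    # no marginal, one significant conjunction -> coincident
    rbind(mkScore("c1", "own", "STILLNESS", FALSE),
          mkScore("c1", "joint", "STILLNESS", TRUE, b2 = "WITHDRAWAL")),
    # nothing significant -> untuned
    mkScore("z1", "own", "PUSH", FALSE))
  cl <- classifyCells(sc)
  got <- setNames(cl$class, cl$cell_id)
  expect_identical(got[["u1"]], "unique-own")
  expect_identical(got[["m1"]], "mixed")
  expect_identical(got[["x1"]], "mixed-across-animals")
  expect_identical(got[["n1"]], "nonspecific")
  expect_identical(got[["o1"]], "unique-other")
  expect_identical(got[["c1"]], "coincident")
  expect_identical(got[["z1"]], "untuned")
  expect_identical(cl$behaviors[cl$cell_id == "u1"], "own:PUSH")
  expect_identical(cl$behaviors[cl$cell_id == "c1"], "STILLNESS|WITHDRAWAL")
  # STILLNESS encoders are flagged uninterpretable but remain classified
  expect_true(cl$stillness_flag[cl$cell_id == "c1"])
  expect_false(cl$stillness_flag[cl$cell_id == "u1"])
})

test_that("classification is invariant to cell order and id relabeling", {
  sc <- rbind(mkScore("a", "own", "PUSH", TRUE),
              mkScore("b", "other", "RESIST", TRUE),
              mkScore("c", "own", "PUSH", FALSE))
  cl1 <- classifyCells(sc)
  cl2 <- classifyCells(sc[rev(seq_len(nrow(sc))), ])
  expect_identical(cl1[order(cl1$cell_id), ], cl2[order(cl2$cell_id), ],
                   ignore_attr = TRUE)
  sc3 <- sc; sc3$cell_id <- paste0("z_", sc3$cell_id)
  cl3 <- classifyCells(sc3)
  expect_identical(cl3$class[order(cl3$cell_id)],
                   cl1$class[order(cl1$cell_id)])
})

test_that("joint conjunctions reduce to the marginal when the partner is constant", {
  set.seed(61)
  n <- 2000
  own <- rep(rep(c("PUSH", "STILLNESS"), times = c(10, 40)), 40)
  other <- rep("STILLNESS", n)
  dex <- makeTinyDex(own, other)
  # sparse events in a few PUSH bouts: below the occupancy gate, so no
  # marginal is significant and the joint pass runs
  push_starts <- which(own == "PUSH" & c("", own[-n]) != "PUSH")
  ev <- data.frame(cell_id = "c1", session = 1L,
                   frame = push_starts[seq(1, 12, by = 2)] + 1L)
  cfg <- pipelineConfig(n_shuffles = 50)
  sc <- tuningScores(dex, ev, 1, config = cfg)
  marg <- sc[sc$target_animal == "own" & sc$behavior1 == "PUSH", ]
  jnt <- sc[sc$target_animal == "joint" & sc$behavior1 == "PUSH" &
              sc$behavior2 == "STILLNESS", ]
  expect_equal(nrow(jnt), 1)
  # identical label vectors up to the estimator's tie-breaking jitter
  expect_lt(abs(jnt$mis - marg$mis), 0.02)
  expect_equal(jnt$occupancy, marg$occupancy)
  expect_equal(jnt$n_bouts, marg$n_bouts)
})

test_that("a strongly behavior-locked cell is classified unique-own", {
  set.seed(62)
  n <- 3000
  own <- rep(rep(c("PUSH", "STILLNESS", "MOVE FORWARD", "STILLNESS"),
                 times = c(40, 60, 40, 60)), 15)
  # partner RESIST placed away from own PUSH so the cell is informative
  # about own PUSH only
  other <- rep(rep(c("STILLNESS", "RESIST", "STILLNESS"),
                   times = c(110, 50, 40)), 15)
  dex <- makeTinyDex(own, other)
  push_bouts <- dyadtune:::.flagRuns(own == "PUSH", rep(1L, n))
  ev <- data.frame(cell_id = "c1", session = 1L,
                   frame = as.integer(push_bouts$start + 3))
  cfg <- pipelineConfig(n_shuffles = 200)
  sc <- tuningScores(dex, ev, 1, config = cfg)
  cl <- classifyCells(sc)
  expect_identical(cl$class, "unique-own")
  expect_identical(cl$behaviors, "own:PUSH")
})

test_that("cells with empty event trains are all untuned", {
  own <- rep(rep(c("PUSH", "STILLNESS"), times = c(20, 30)), 20)
  other <- rep(rep(c("STILLNESS", "RESIST"), times = c(35, 15)), 20)
  dex <- makeTinyDex(own, other, n_cells = 3)
  ev <- data.frame(cell_id = character(0), session = integer(0),
                   frame = integer(0))
  sc <- tuningScores(dex, ev, 1, config = pipelineConfig(n_shuffles = 20))
  cl <- classifyCells(sc)
  expect_equal(nrow(cl), 3)
  expect_true(all(cl$class == "untuned"))
  expect_true(all(sc$mis == 0))
})
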