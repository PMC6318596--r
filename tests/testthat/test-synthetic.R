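test_that("chain generator is deterministic with fixed bond geometry", {
  sys <- buildSystemTopology(pnipamDyadSequences()$atactic)
  co1 <- generateChainCoordinates(sys@chains[[1]], seed = 5)
  co2 <- generateChainCoordinates(sys@chains[[1]], seed = 5)
  expect_identical(co1, co2)
  # consecutive backbone carbons 0.25 nm apart
  bbIdx <- as.vector(rbind(seq(1, 210, by = 7), seq(2, 210, by = 7)))
  bb <- co1[bbIdx, ]
  steps <- sqrt(rowSums(diff(bb)^2))
  expect_true(all(abs(steps - 0.25) < 1e-6))
  # self-avoidance between residues
  res <- rep(1:30, each = 7)
  d <- as.matrix(dist(co1))
  same <- outer(res, res, "==")
  expect_gte(min(d[!same]), 0.15)
})

test_that("separated trajectories contain no inter-chain contacts", {
  sys <- buildSystemTopology(pnipamDyadSequences()$atactic)
  tr <- generateTrajectory(synthConfig(mode = "separated", nFrames = 4,
                                       seed = 42), sys)
  ct <- contactTimeSeries(tr, sys)
  expect_true(all(ct$counts$nPolar == 0))
  expect_true(all(ct$counts$nHydrophobic == 0))
  expect_false(any(ct$residueFlags))
})

test_that("a single planted contact yields a single one-residue junction", {
  sys <- buildSystemTopology(pnipamDyadSequences()$atactic)
  cfg <- synthConfig(mode = "planted", nFrames = 3,
                     plantedContacts = rbind(c(5L, 12L)), seed = 2)
  tr <- generateTrajectory(cfg, sys)
  jt <- junctionTimeSeries(tr, sys)
  a <- jt[jt$chain == "A", ]
  expect_true(all(a$NJ == 1L & a$LJmean == 1 & a$NR == 1L))
})

test_that("planted contact sets round-trip exactly through detection", {
  sys <- buildSystemTopology(pnipamDyadSequences()$isotactic)
  spec <- defaultContactSpec()
  set.seed(77)
  for (rep in 1:12) {
    k <- sample(1:8, 1)
    pc <- unique(cbind(sample(1:30, k, replace = TRUE),
                       sample(1:30, k, replace = TRUE)))
    cfg <- synthConfig(mode = "planted", nFrames = 3,
                       plantedContacts = pc, seed = rep)
    tr <- generateTrajectory(cfg, sys, spec)
    for (f in seq_len(nFrames(tr))) {
      det <- detectContacts(getFrame(tr, f), sys, spec)
      got <- residueContactPairs(det, sys)
      expect_identical(got[order(got[, 1], got[, 2]), , drop = FALSE],
                       pc[order(pc[, 1], pc[, 2]), , drop = FALSE])
    }
  }
})

test_that("infeasible planted patterns are rejected with context", {
  sys <- buildSystemTopology(pnipamDyadSequences()$atactic)
  # a single B residue has only 4 contact-capable partner atoms plus N;
  # 6 pairs on one residue exhaust them
  pc <- cbind(1:6, rep(12L, 6))
  cfg <- synthConfig(mode = "planted", nFrames = 1, plantedContacts = pc,
                     seed = 1)
  expect_error(generateTrajectory(cfg, sys), "infeasible planted pattern")
})

test_that("aggregated mode reaches the 25% residue-contact criterion", {
  sys <- buildSystemTopology(pnipamDyadSequences()$isotactic)
  tr <- generateTrajectory(synthConfig(mode = "aggregated", nFrames = 3,
                                       seed = 7), sys)
  ct <- contactTimeSeries(tr, sys)
  for (f in 1:3) {
    expect_gte(mean(ct$residueFlags[f, 1:30]), 0.25)
    expect_gte(mean(ct$residueFlags[f, 31:60]), 0.25)
  }
})

test_that("touching mode has at least one contact in every frame", {
  sys <- buildSystemTopology(pnipamDyadSequences()$atactic)
  tr <- generateTrajectory(synthConfig(mode = "touching", nFrames = 3,
                                       seed = 9), sys)
  ct <- contactTimeSeries(tr, sys)
  expect_true(all(ct$counts$nPolar + ct$counts$nHydrophobic >= 1))
})

test_that("the two-junction fixture reproduces the worked example", {
  fx <- twoJunctionFixture(seed = 3)
  jt <- junctionTimeSeries(fx$trajectory, fx$system)
  a <- jt[jt$chain == "A", ]
  b <- jt[jt$chain == "B", ]
  expect_equal(c(a$NR, a$NJ, a$LJmean), c(3, 2, 1.5))
  expect_equal(c(b$NR, b$NJ, b$LJmean), c(2, 2, 1))
  det <- detectContacts(getFrame(fx$trajectory, 1), fx$system)
  expect_gt(nrow(det$contacts), 0)
  # the two A-side junctions are separated by >= 2 non-contact residues
  expect_gte(12L - 5L - 1L, 2L)
})

test_that("synthetic config validity is enforced", {
  expect_error(synthConfig(mode = "planted"), "requires plantedContacts")
  expect_error(synthConfig(mode = "separated",
                           plantedContacts = rbind(c(1L, 2L))),
               "only allowed in planted mode")
  expect_error(synthConfig(mode = "planted",
                           plantedContacts = rbind(c(0L, 2L))),
               "1..nRes")
})
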