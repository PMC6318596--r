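test_that("radius of gyration matches analytic and oracle values", {
  sys <- tinySystem(nRes = 3L)
  at <- atomTable(sys)
  co <- spreadCoords(sys, spacing = 2)
  fr <- makeFrame(co, 50)
  # single atom -> 0
  expect_equal(radiusOfGyration(fr, sys, selection = 1L, unwrap = FALSE), 0)
  # two equal masses distance d apart -> d/2 (two carbons)
  cIdx <- which(at$element == "C")[1:2]
  co2 <- co
  co2[cIdx[1], ] <- c(0, 0, 0)
  co2[cIdx[2], ] <- c(1.6, 0, 0)
  expect_equal(radiusOfGyration(makeFrame(co2, 50), sys,
                                selection = cIdx, unwrap = FALSE), 0.8)
  # random cloud vs the pairwise-distance identity:
  # Rg^2 = sum_{i<j} m_i m_j d_ij^2 / M^2
  set.seed(111)
  sel <- sample(nrow(co), 40)
  co3 <- co
  co3[sel, ] <- matrix(rnorm(120), ncol = 3)
  m <- at$mass[sel]
  d2 <- as.matrix(dist(co3[sel, ]))^2
  oracle <- sqrt(sum(outer(m, m) * d2) / (2 * sum(m)^2))
  expect_equal(radiusOfGyration(makeFrame(co3, 50), sys, selection = sel,
                                unwrap = FALSE), oracle, tolerance = 1e-12)
})

test_that("radius of gyration grows when the chains are pulled apart", {
  sys <- buildSystemTopology(pnipamDyadSequences()$atactic)
  tr <- generateTrajectory(synthConfig(mode = "separated", nFrames = 1,
                                       seed = 12), sys)
  fr <- getFrame(tr, 1)
  at <- atomTable(sys)
  idxB <- which(at$chain == "B")
  co <- unwrapChains(fr$coords, sys, fr$box)
  rg1 <- radiusOfGyration(list(coords = co, box = fr$box * 10), sys,
                          unwrap = FALSE)
  comA <- colMeans(co[at$chain == "A", ])
  comB <- colMeans(co[idxB, ])
  co2 <- co
  co2[idxB, ] <- sweep(co[idxB, ], 2, comB - comA, "-")  # to A's com
  co2[idxB, ] <- sweep(co2[idxB, ], 2, 2 * (comB - comA), "+")  # doubled
  rg2 <- radiusOfGyration(list(coords = co2, box = fr$box * 10), sys,
                          unwrap = FALSE)
  expect_gt(rg2, rg1)
})

test_that("end-to-end distance reflects the terminal backbone carbons", {
  sys <- tinySystem(nRes = 4L)
  at <- atomTable(sys)
  co <- spreadCoords(sys, spacing = 2)
  # collinear backbone for chain A: C1/C2 along x, 0.25 nm bonds
  bb <- which(at$chain == "A" & at$name %in% c("C1", "C2"))
  bb <- bb[order(at$residue[bb], at$name[bb])]
  for (k in seq_along(bb)) co[bb[k], ] <- c(0.25 * (k - 1), 0, 0)
  d <- endToEndDistance(makeFrame(co, 100), sys, "A", unwrap = FALSE)
  expect_equal(d, 0.25 * (length(bb) - 1))
  # folded chain with coincident termini
  co[bb[length(bb)], ] <- co[bb[1], ]
  expect_equal(endToEndDistance(makeFrame(co, 100), sys, "A",
                                unwrap = FALSE), 0)
})

test_that("minimum-distance matrix is symmetric with contact-range entries", {
  fx <- twoJunctionFixture(seed = 5)
  dm <- minDistanceMatrix(fx$trajectory, fx$system)
  expect_equal(dim(dm), c(60L, 60L))
  expect_equal(dm, t(dm))
  expect_true(all(diag(dm) == 0))
  # planted residue pairs sit within their class cutoffs
  expect_lte(dm[5, 30 + 12], 0.38)
  expect_lte(dm[12, 30 + 20], 0.38)
  expect_lte(dm[13, 30 + 20], 0.50)
})

test_that("single-frame window equals the per-frame minima exactly", {
  sys <- tinySystem(nRes = 3L)
  set.seed(120)
  co <- matrix(runif(nAtoms(sys) * 3) * 4, ncol = 3)
  tr <- Trajectory(list(co), 0, rep(4, 3))
  dm <- minDistanceMatrix(tr, sys)
  at <- atomTable(sys)
  # oracle: direct loop over residue pairs
  for (gi in c(1, 4)) for (gj in c(2, 5)) {
    ai <- which(at$residueGlobal == gi)
    aj <- which(at$residueGlobal == gj)
    best <- Inf
    for (i in ai) for (j in aj)
      best <- min(best, bruteMinImage(co[i, ], co[j, ], rep(4, 3)))
    expect_equal(dm[gi, gj], best, tolerance = 1e-12)
  }
})

test_that("windowed matrices average over the selected frames only", {
  sys <- tinySystem(nRes = 2L)
  set.seed(121)
  co1 <- matrix(runif(nAtoms(sys) * 3) * 4, ncol = 3)
  co2 <- matrix(runif(nAtoms(sys) * 3) * 4, ncol = 3)
  tr <- Trajectory(list(co1, co2), c(0, 5), rep(4, 3))
  m1 <- minDistanceMatrix(tr, sys, window = c(0, 0))
  m2 <- minDistanceMatrix(tr, sys, window = c(5, 5))
  mAll <- minDistanceMatrix(tr, sys)
  expect_equal(mAll, (m1 + m2) / 2, tolerance = 1e-12)
  expect_error(minDistanceMatrix(tr, sys, window = c(50, 60)), "no frames")
})
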