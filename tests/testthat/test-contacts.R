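test_that("contacts are declared at and below the class cutoff only", {
  sys <- tinySystem(nRes = 2L)
  at <- atomTable(sys)
  box <- 20
  co <- spreadCoords(sys, spacing = 3)  # everything far apart
  nA <- which(at$chain == "A" & at$residue == 1L & at$name == "N")
  oB <- which(at$chain == "B" & at$residue == 1L & at$name == "O")
  co[nA, ] <- c(1, 1, 1)
  co[oB, ] <- c(1 + 0.38, 1, 1)           # exactly at the N-O cutoff
  det <- detectContacts(makeFrame(co, box), sys)
  expect_equal(nrow(det$contacts), 1L)
  expect_equal(det$contacts$class, "N(A)-O(B)")
  expect_equal(det$contacts$distance, 0.38)
  # CI-CI at 0.74 nm: just beyond its 0.73 cutoff
  co2 <- spreadCoords(sys, spacing = 3)
  ciA <- which(at$chain == "A" & at$residue == 1L & at$name == "CI")
  ciB <- which(at$chain == "B" & at$residue == 1L & at$name == "CI")
  co2[ciA, ] <- c(1, 1, 1)
  co2[ciB, ] <- c(1.74, 1, 1)
  det2 <- detectContacts(makeFrame(co2, box), sys)
  expect_equal(nrow(det2$contacts), 0L)
})

test_that("detection matches the brute-force all-pairs oracle", {
  sys <- tinySystem(nRes = 4L)
  box <- 2.5
  set.seed(55)
  for (k in 1:25) {
    co <- matrix(runif(nAtoms(sys) * 3) * box, ncol = 3)
    det <- detectContacts(makeFrame(co, box), sys)
    oracle <- bruteContacts(co, rep(box, 3), sys)
    got <- det$contacts
    gotKey <- sort(paste(got$atomA, got$atomB, sep = "_"))
    # oracle rows are 1-based matrix rows; atom ids are 0-based
    oKey <- sort(paste(oracle$i - 1L, oracle$j - 1L, sep = "_"))
    expect_identical(gotKey, oKey)
  }
})

test_that("contact counts are invariant under translation and wrapping", {
  sys <- tinySystem(nRes = 4L)
  box <- 3
  set.seed(66)
  co <- matrix(runif(nAtoms(sys) * 3) * box, ncol = 3)
  base <- detectContacts(makeFrame(co, box), sys)
  shift <- matrix(rep(c(1.7, -2.4, 0.9), each = nrow(co)), ncol = 3)
  shifted <- co + shift
  wrapped <- shifted - floor(shifted / box) * box
  for (variant in list(shifted, wrapped)) {
    det <- detectContacts(makeFrame(variant, box), sys)
    expect_equal(nrow(det$contacts), nrow(base$contacts))
    expect_equal(sort(det$contacts$distance), sort(base$contacts$distance),
                 tolerance = 1e-9)
  }
})

test_that("polar/hydrophobic totals are symmetric under chain relabeling", {
  sys <- tinySystem(nRes = 4L)
  box <- 2.5
  set.seed(67)
  co <- matrix(runif(nAtoms(sys) * 3) * box, ncol = 3)
  n <- nrow(co) / 2
  swapped <- rbind(co[(n + 1):(2 * n), ], co[1:n, ])
  tr1 <- Trajectory(list(co), 0, rep(box, 3))
  tr2 <- Trajectory(list(swapped), 0, rep(box, 3))
  c1 <- contactTimeSeries(tr1, sys)$counts
  c2 <- contactTimeSeries(tr2, sys)$counts
  expect_equal(c1$nPolar, c2$nPolar)
  expect_equal(c1$nHydrophobic, c2$nHydrophobic)
})

test_that("a planted polar contact is counted as polar only", {
  sys <- buildSystemTopology(pnipamDyadSequences()$atactic)
  cfg <- synthConfig(mode = "planted", nFrames = 2,
                     plantedContacts = rbind(c(3L, 7L)), seed = 4)
  tr <- generateTrajectory(cfg, sys)
  ct <- contactTimeSeries(tr, sys)$counts
  expect_true(all(ct$nPolar == 1L))
  expect_true(all(ct$nHydrophobic == 0L))
})

test_that("unknown atom names in the spec raise a configuration error", {
  sys <- tinySystem(nRes = 2L)
  spec <- defaultContactSpec()
  spec@pairs$namesA[[1]] <- "QZ"
  co <- spreadCoords(sys, spacing = 3)
  expect_error(detectContacts(makeFrame(co, 20), sys, spec), "QZ")
})
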