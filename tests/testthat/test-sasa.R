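test_that("an isolated atom recovers the analytic expanded-sphere area", {
  sys <- tinySystem(nRes = 2L)
  at <- atomTable(sys)
  co <- spreadCoords(sys, spacing = 5)
  cIdx <- which(at$element == "C")[1]
  res <- shrakeRupleySasa(makeFrame(co, 100), sys, probeRadius = 0.14,
                          nPoints = 960, selection = cIdx, unwrap = FALSE)
  analytic <- 4 * pi * (0.170 + 0.14)^2
  expect_lt(abs(res$total - analytic) / analytic, 0.01)
  expect_equal(res$total, sum(res$perAtom))
})

test_that("disjoint spheres are additive and buried atoms contribute zero", {
  sys <- tinySystem(nRes = 2L)
  at <- atomTable(sys)
  co <- spreadCoords(sys, spacing = 5)   # all spheres disjoint
  fr <- makeFrame(co, 100)
  two <- which(at$element == "C")[1:2]
  together <- shrakeRupleySasa(fr, sys, nPoints = 960, selection = two,
                               unwrap = FALSE)$total
  each <- vapply(two, function(i)
    shrakeRupleySasa(fr, sys, nPoints = 960, selection = i,
                     unwrap = FALSE)$total, numeric(1))
  expect_equal(together, sum(each), tolerance = 1e-12)

  # a small sphere fully inside a large one: O shrunk below C via a custom
  # radius table, placed concentric with a carbon
  small <- buildSystemTopology(generateBernoullianSequence(2, 0.5, 1),
                               vdwTable = c(C = 0.30, N = 0.155,
                                            O = 0.02, H = 0.12))
  atS <- atomTable(small)
  coS <- spreadCoords(small, spacing = 5)
  cAtom <- which(atS$element == "C")[1]
  oAtom <- which(atS$element == "O")[1]
  coS[oAtom, ] <- coS[cAtom, ]
  resS <- shrakeRupleySasa(makeFrame(coS, 100), small, nPoints = 960,
                           selection = c(cAtom, oAtom), unwrap = FALSE)
  expect_equal(resS$perAtom[2], 0)
  expect_gt(resS$perAtom[1], 0)
})

test_that("SASA converges with the number of test points", {
  sys <- buildSystemTopology(pnipamDyadSequences()$atactic)
  tr <- generateTrajectory(synthConfig(mode = "aggregated", nFrames = 1,
                                       seed = 14), sys)
  fr <- getFrame(tr, 1)
  a960 <- shrakeRupleySasa(fr, sys, nPoints = 960)$total
  a3840 <- shrakeRupleySasa(fr, sys, nPoints = 3840)$total
  expect_lt(abs(a960 - a3840) / a3840, 0.005)
})

test_that("association buries surface: contact SASA <= separated SASA", {
  sys <- buildSystemTopology(pnipamDyadSequences()$isotactic)
  tr <- generateTrajectory(synthConfig(mode = "separated", nFrames = 1,
                                       seed = 15), sys)
  fr <- getFrame(tr, 1)
  co <- unwrapChains(fr$coords, sys, fr$box)
  sep <- shrakeRupleySasa(list(coords = co, box = fr$box), sys,
                          nPoints = 240, unwrap = FALSE)$total
  at <- atomTable(sys)
  idxB <- which(at$chain == "B")
  shiftVec <- colMeans(co[at$chain == "A", ]) - colMeans(co[idxB, ])
  for (frac in c(0.5, 0.8)) {
    co2 <- co
    co2[idxB, ] <- sweep(co[idxB, ], 2, frac * shiftVec, "+")
    assoc <- shrakeRupleySasa(list(coords = co2, box = fr$box), sys,
                              nPoints = 240, unwrap = FALSE)$total
    expect_lte(assoc, sep + 1e-9)
  }
})

test_that("SASA input contracts are enforced", {
  sys <- tinySystem(nRes = 2L)
  co <- spreadCoords(sys, spacing = 5)
  expect_error(shrakeRupleySasa(makeFrame(co, 100), sys, nPoints = 16),
               "at least 32")
})
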