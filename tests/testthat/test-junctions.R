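test_that("junction decomposition handles the canonical flag patterns", {
  fl <- rep(FALSE, 30); fl[c(5, 12, 13)] <- TRUE
  j <- junctionsPerFrame(fl)
  expect_equal(j$NJ, 2L); expect_equal(j$LJmean, 1.5); expect_equal(j$NR, 3L)
  expect_equal(j$junctions$start, c(5L, 12L))
  expect_equal(j$junctions$length, c(1L, 2L))

  none <- junctionsPerFrame(rep(FALSE, 30))
  expect_equal(none$NJ, 0L); expect_equal(none$NR, 0L)
  expect_true(is.na(none$LJmean))

  all30 <- junctionsPerFrame(rep(TRUE, 30))
  expect_equal(all30$NJ, 1L); expect_equal(all30$LJmean, 30)
  expect_equal(all30$NR, 30L)
})

test_that("decomposition equals the run-length-encoding oracle", {
  set.seed(101)
  for (k in 1:2000) {
    n <- sample(5:40, 1)
    fl <- runif(n) < runif(1)
    j <- junctionsPerFrame(fl)
    o <- rleJunctionOracle(fl)
    expect_identical(j$NJ, o$NJ)
    expect_identical(j$NR, as.integer(o$NR))
    expect_equal(j$LJmean, o$LJmean)
    # the NR = NJ * LJ_mean identity, exactly
    if (j$NJ > 0) expect_equal(j$NJ * j$LJmean, j$NR)
  }
})

test_that("gap tolerance merges runs across single unflagged residues", {
  fl <- rep(FALSE, 10); fl[c(2, 4, 5)] <- TRUE
  strict <- junctionsPerFrame(fl, gap = 0)
  expect_equal(strict$NJ, 2L)
  merged <- junctionsPerFrame(fl, gap = 1)
  expect_equal(merged$NJ, 1L)
  expect_equal(merged$NR, 3L)     # NR still counts flagged residues only
  expect_equal(merged$LJmean, 3)
})

test_that("summary averages only over frames with contacts", {
  # 4-frame toy, hand-computed: chain A has contacts in frames 1 and 3
  flags <- matrix(FALSE, 4, 8)   # nRes = 4, two chains
  flags[1, c(1, 2)] <- TRUE      # NJ 1, LJ 2, NR 2
  flags[3, c(1, 3)] <- TRUE      # NJ 2, LJ 1, NR 2
  st <- junctionStatsFromFlags(flags, 4L, times = c(0, 5, 10, 15))
  s <- summarizeJunctions(st)
  a <- s[s$chain == "A", ]
  expect_equal(a$nFramesWithContact, 2L)
  expect_equal(a$meanNR, 2)
  expect_equal(a$meanNJ, 1.5)
  expect_equal(a$meanLJ, 1.5)
  expect_equal(a$sdNR, 0)                 # population SD over {2, 2}
  expect_equal(a$sdNJ, 0.5)               # over {1, 2}
  b <- s[s$chain == "B", ]
  expect_true(b$empty)
  expect_true(is.na(b$meanNR))
  expect_equal(b$nFramesWithContact, 0L)
})

test_that("constant patterns summarize with zero spread", {
  flags <- matrix(FALSE, 10, 60)
  flags[, c(5, 12, 13, 42, 50)] <- TRUE
  st <- junctionStatsFromFlags(flags, 30L)
  s <- summarizeJunctions(st)
  expect_equal(s$meanNR, c(3, 2))
  expect_equal(s$sdNR, c(0, 0))
  expect_equal(s$sdLJ, c(0, 0))
})

test_that("junction-weighted and frame-weighted LJ means differ as defined", {
  flags <- matrix(FALSE, 2, 20)
  flags[1, 1:4] <- TRUE                  # frame 1: one junction of 4
  flags[2, c(1, 3, 5, 7)] <- TRUE        # frame 2: four junctions of 1
  st <- junctionStatsFromFlags(flags, 10L)
  byFrame <- summarizeJunctions(st, ljWeighting = "frames")
  byJunction <- summarizeJunctions(st, ljWeighting = "junctions")
  a1 <- byFrame[byFrame$chain == "A", ]
  a2 <- byJunction[byJunction$chain == "A", ]
  expect_equal(a1$meanLJ, (4 + 1) / 2)
  expect_equal(a2$meanLJ, (4 + 4) / (1 + 4))
})

test_that("windows outside the trajectory are rejected", {
  flags <- matrix(TRUE, 3, 8)
  st <- junctionStatsFromFlags(flags, 4L, times = c(0, 5, 10))
  expect_error(summarizeJunctions(st, window = c(20, 30)), "outside")
  expect_error(summarizeJunctions(st, window = c(10, 5)), "outside")
})
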