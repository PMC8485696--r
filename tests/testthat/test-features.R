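test_that("MEC is the rectangle rule on the bin grid", {
  expect_equal(computeMEC(matrix(2, 3, 4), binMs = 5),
               matrix(10, 3, 4))
  expect_equal(computeMEC(matrix(0, 2, 2)), matrix(0, 2, 2))
  expect_error(computeMEC(matrix(-1, 1, 1)), "nonnegative")

  # per-bin agreement with trapezoidal integration of the piecewise-
  # constant current (within a bin the signal is flat, so trapezoid and
  # rectangle coincide exactly)
  set.seed(1)
  cur <- matrix(runif(60), 6, 10)
  trap <- (cur + cur) / 2 * 5
  expect_equal(computeMEC(cur, binMs = 5), trap, tolerance = 1e-12)
})

test_that("sMEC is the per-(participant, region) min-max map", {
  # hand-sized cohort where one region block has values {2, 4, 6}
  cfg <- tinyConfig(nParticipants = 1, trialsPerGroup = 2,
                    regions = "R01", epoch = c(0, 15))
  coh <- generateCohort(cfg, seed = 1, groups = "long")
  m <- currents(coh)
  m[, 1] <- c(2, 4, 6)
  m[, 2] <- c(6, 6, 6)
  SummarizedExperiment::assay(coh, "current") <- m
  s <- smec(normalizeSMEC(computeMEC(coh)))
  expect_equal(unname(s[, 1]), c(0, 0.5, 1))
  expect_equal(unname(s[, 2]), c(1, 1, 1))

  # degenerate constant region maps to 0
  m[] <- 3
  SummarizedExperiment::assay(coh, "current") <- m
  s <- smec(normalizeSMEC(computeMEC(coh)))
  expect_true(all(s == 0))
})

test_that("each participant-region block spans [0,1] and gain cancels exactly", {
  coh <- plantedCohort(seed = 2, nParticipants = 4, trialsPerGroup = 6)
  s <- smec(coh)
  expect_true(all(s >= 0 & s <= 1))
  nb <- length(binStarts(coh))
  for (p in participants(coh)) {
    cols <- which(coh$participant_id == p)
    for (r in seq_along(regions(coh))) {
      block <- s[((r - 1) * nb + 1):(r * nb), cols]
      expect_equal(min(block), 0)
      expect_equal(max(block), 1)
    }
  }

  # multiplying one participant's MEC by any positive gain leaves their
  # sMEC unchanged (the normalization's stated purpose)
  coh2 <- coh
  m <- mec(coh2)
  cols <- which(coh2$participant_id == participants(coh2)[1])
  m[, cols] <- m[, cols] * 7.3
  SummarizedExperiment::assay(coh2, "mec") <- m
  s2 <- smec(normalizeSMEC(coh2))
  expect_equal(s2, s, tolerance = 1e-12)
})

test_that("interval features are bin means over half-open grid windows", {
  coh <- plantedCohort(seed = 3, nParticipants = 3, trialsPerGroup = 4)
  s <- smec(coh)

  # constant table gives the constant for any interval
  cohC <- coh
  SummarizedExperiment::assay(cohC, "smec")[] <- 0.5
  expect_true(all(intervalFeature(cohC, c(0, 100)) == 0.5))
  expect_true(all(intervalFeature(cohC, c(25, 30)) == 0.5))

  # single-bin interval is that bin's value
  f1 <- intervalFeature(coh, c(50, 55))
  nb <- length(binStarts(coh))
  expect_equal(unname(f1[, 2]), unname(s[nb + which(binStarts(coh) == 50), ]))

  # brute-force oracle over explicitly enumerated bins
  iv <- c(35, 120)
  f <- intervalFeature(coh, iv)
  bsel <- which(binStarts(coh) >= iv[1] & binStarts(coh) < iv[2])
  for (r in seq_along(regions(coh))) {
    brute <- colMeans(s[(r - 1) * nb + bsel, , drop = FALSE])
    expect_equal(unname(f[, r]), unname(brute), tolerance = 1e-12)
  }

  # splitting an interval and recombining with bin-count weights
  fa <- intervalFeature(coh, c(35, 60))
  fb <- intervalFeature(coh, c(60, 120))
  expect_equal((fa * 5 + fb * 12) / 17, f, tolerance = 1e-12)

  # monotone under pointwise domination
  cohHi <- coh
  SummarizedExperiment::assay(cohHi, "smec") <-
    pmin(s + 0.1, 1)
  expect_true(all(intervalFeature(cohHi, iv) >= f - 1e-12))

  # misaligned intervals name the grid
  expect_error(intervalFeature(coh, c(33, 60)), "grid")
  expect_error(intervalFeature(coh, c(0, 1000)), "epoch")
})

test_that("scan feature cache reproduces intervalFeature", {
  coh <- plantedCohort(seed = 4, nParticipants = 3, trialsPerGroup = 4)
  cums <- credscan:::smecCumsum(coh)
  f <- credscan:::featureFromCumsum(cums, 10, 24)  # bins 11..24 = [50,120)
  expect_equal(f, unname(intervalFeature(coh, c(50, 120))),
               tolerance = 1e-12, ignore_attr = TRUE)
})
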