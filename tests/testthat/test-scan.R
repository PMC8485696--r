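test_that("interval enumeration matches the closed form and brute force", {
  # 25 ms windows on the 5 ms grid within [0, 990): 194 of them
  expect_equal(nrow(enumerateIntervals(scanConfig(lengths = 25))), 194)
  # the full-epoch window is unique
  expect_equal(nrow(enumerateIntervals(scanConfig(lengths = 990))), 1)

  # counts match exhaustive generation for lengths 5..100
  lens <- seq(5, 100, by = 5)
  ivs <- enumerateIntervals(scanConfig(lengths = lens))
  brute <- 0L
  for (len in lens)
    for (a in seq(0, 990 - len, by = 5))
      brute <- brute + 1L
  expect_equal(nrow(ivs), brute)
  expect_equal(nrow(ivs), sum((990 - lens) / 5 + 1))
  # all half-open windows lie on the grid inside the epoch
  expect_true(all(ivs$start_ms %% 5 == 0 & ivs$end_ms <= 990))

  expect_error(scanConfig(lengths = 12), "multiple")
  expect_error(scanConfig(lengths = 1000), "exceed")
})

test_that("region ranking scores and tie rules follow the mean absolute difference", {
  # arithmetic oracle: class means 0.2/0.8 and 0.5/0.5
  feat <- cbind(r_b = c(0.5, 0.5, 0.5, 0.5), r_a = c(0.2, 0.2, 0.8, 0.8))
  pos <- c(FALSE, FALSE, TRUE, TRUE)
  rk <- credscan:::rankRegionsFromFeatures(feat, pos, c(0, 5), Q = 2)
  expect_equal(rk@regions, c("r_a", "r_b"))
  expect_equal(rk@scores, c(0.6, 0), tolerance = 1e-12)

  # identical class distributions: all scores 0, purely lexicographic order
  featT <- cbind(zc = c(1, 1), za = c(1, 1), zb = c(1, 1))
  rkT <- credscan:::rankRegionsFromFeatures(featT, c(TRUE, FALSE), c(0, 5), 3)
  expect_equal(rkT@regions, c("za", "zb", "zc"))
  expect_equal(rkT@scores, c(0, 0, 0))

  # single-class input errors naming the absent class
  expect_error(credscan:::rankRegionsFromFeatures(feat, c(TRUE, TRUE, TRUE, TRUE),
                                                  c(0, 5), 2),
               "not_credible")

  # planted effect occupies the top ranks on a real cohort
  coh <- plantedCohort(seed = 6, nParticipants = 25, trialsPerGroup = 20,
                       effRegions = c("R02", "R05"), amplitude = 2)
  rk2 <- rankRegions(coh, c(100, 200), Q = 5)
  expect_setequal(rk2@regions[1:2], c("R02", "R05"))

  # invariant to trial order
  perm <- sample(ncol(coh))
  rk3 <- rankRegions(coh[, perm], c(100, 200), Q = 5)
  expect_identical(rk2@regions, rk3@regions)
  expect_equal(rk2@scores, rk3@scores, tolerance = 1e-12)
})

test_that("candidate enumeration yields every non-empty subset of the top-Q", {
  rk <- new("RegionRanking", interval = c(0, 25),
            regions = sprintf("R%d", 1:5), scores = rep(0, 5),
            classes = c("credible", "not_credible"))
  cand <- enumerateCandidates(rk)
  expect_length(cand, 31)   # 2^5 - 1, brute-force subset count
  keys <- vapply(cand, function(s) paste(sort(s@regions), collapse = ","),
                 character(1))
  expect_equal(anyDuplicated(keys), 0L)
  expect_true(all(lengths(lapply(cand, slot, "regions")) <= 5))

  rk1 <- new("RegionRanking", interval = c(0, 25), regions = "R1",
             scores = 0, classes = c("credible", "not_credible"))
  expect_length(enumerateCandidates(rk1), 1)
  expect_error(enumerateCandidates(
    new("RegionRanking", interval = c(0, 25), regions = character(),
        scores = numeric(), classes = character())), "empty")
})

test_that("model counting is exact and consistent with enumeration", {
  expect_identical(countModels(88, 5), 39175752)
  expect_identical(countModels(88, 5, I = 2261, limited = TRUE), 70091)
  expect_identical(countModels(88, 5, I = 2261), 88576375272)

  # limited count equals |candidates| x |intervals| on a small config
  cfg <- scanConfig(epoch = c(0, 100), lengths = c(10, 25), maxRegions = 3)
  ivs <- enumerateIntervals(cfg)
  rk <- new("RegionRanking", interval = c(0, 10),
            regions = sprintf("R%d", 1:3), scores = rep(0, 3),
            classes = c("credible", "not_credible"))
  expect_equal(countModels(R = 10, Q = 3, I = nrow(ivs), limited = TRUE),
               nrow(ivs) * length(enumerateCandidates(rk)))

  expect_error(countModels(3, 5), "R >= Q")
})
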