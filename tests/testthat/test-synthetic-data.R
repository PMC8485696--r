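test_that("cohort structure matches the configured trial design", {
  cfg <- tinyConfig(nParticipants = 6, trialsPerGroup = 8,
                    attrition = c(known = 6, short = 5, long = 4))
  coh <- generateCohort(cfg, seed = 3)
  cd <- as.data.frame(SummarizedExperiment::colData(coh))

  # attrition: whole condition groups drop per participant
  expect_equal(length(unique(cd$participant_id[cd$group == "known"])), 6)
  expect_equal(length(unique(cd$participant_id[cd$group == "short"])), 5)
  expect_equal(length(unique(cd$participant_id[cd$group == "long"])), 4)

  # per completing participant: trialsPerGroup per group, known split 50/50
  for (p in unique(cd$participant_id)) {
    sub <- cd[cd$participant_id == p, ]
    for (g in unique(sub$group))
      expect_equal(sum(sub$group == g), 8)
    if ("known" %in% sub$group) {
      expect_equal(sum(sub$case == "TT"), 4)
      expect_equal(sum(sub$case == "FF"), 4)
    }
  }

  # no TF/FT: choice always encodes the case's second letter
  expect_true(all(cd$choice[substr(cd$case, 2, 2) == "T"] == "credible"))
  expect_true(all(cd$choice[substr(cd$case, 2, 2) == "F"] == "not_credible"))
  expect_true(all(cd$case %in% c("TT", "FF", "ST", "SF", "LT", "LF")))
})

test_that("generation is deterministic in (config, seed) with no RNG leakage", {
  cfg <- tinyConfig()
  a <- generateCohort(cfg, seed = 7)
  set.seed(123)  # ensure a global stream exists, then check it is untouched
  before <- .Random.seed
  b <- generateCohort(cfg, seed = 7)
  expect_identical(before, .Random.seed)   # global stream untouched
  expect_identical(currents(a), currents(b))
  expect_identical(as.data.frame(SummarizedExperiment::colData(a)),
                   as.data.frame(SummarizedExperiment::colData(b)))
  d <- generateCohort(cfg, seed = 8)
  expect_false(identical(currents(a), currents(d)))
})

test_that("behavioral choice rates converge to the configured probabilities", {
  # 10,000 long-note trials; observed credible fraction within 3 binomial SD
  cfg <- tinyConfig(nParticipants = 25, trialsPerGroup = 400,
                    regions = "R01", epoch = c(0, 10))
  coh <- generateCohort(cfg, seed = 5, groups = "long")
  expect_equal(ncol(coh), 10000)
  frac <- mean(cases(coh) == "LT")
  expect_lt(abs(frac - 0.536), 3 * sqrt(0.536 * 0.464 / 10000))
})

test_that("trial currents follow the gain x rectified-noise-plus-bump model", {
  regs <- tinyRegions(3)
  eff <- plantedEffect(c("LT", "LF"), "R02", c(40, 80), 1)

  # degenerate noise: every entry is gain x baseline
  cfg0 <- tinyConfig(regions = regs, noiseSd = 0)
  set.seed(1)
  cur <- generateTrialCurrents(1.7, list(), "LT", cfg0)
  expect_true(all(cur == 1.7 * 1))
  expect_identical(dim(cur), c(3L, 20L))

  # doubling the gain doubles every entry
  cfg <- tinyConfig(regions = regs)
  set.seed(2); c1 <- generateTrialCurrents(1, list(eff), "LT", cfg)
  set.seed(2); c2 <- generateTrialCurrents(2, list(eff), "LT", cfg)
  expect_equal(c2, 2 * c1, tolerance = 1e-12)

  # planted effect: elevated-class mean exceeds the other class in the
  # planted (region, window) cells, significantly and scaling with amplitude
  bsel <- which(seq(0, 95, 5) >= 40 & seq(0, 95, 5) < 80)
  mcDiff <- function(amp, n = 500) {
    e <- plantedEffect(c("LT", "LF"), "R02", c(40, 80), amp)
    lt <- replicate(n, mean(generateTrialCurrents(1, list(e), "LT", cfg)["R02", bsel]))
    lf <- replicate(n, mean(generateTrialCurrents(1, list(e), "LF", cfg)["R02", bsel]))
    list(p = t.test(lt, lf)$p.value, d = mean(lt) - mean(lf))
  }
  set.seed(3)
  r1 <- mcDiff(1)
  r3 <- mcDiff(3)
  expect_lt(r1$p, 0.001)
  expect_gt(r1$d, 0)
  expect_gt(r3$d, 2 * r1$d)   # difference scales with amplitude

  # effect window outside the epoch is a configuration error
  bad <- plantedEffect(c("LT", "LF"), "R02", c(50, 150), 1)
  expect_error(generateTrialCurrents(1, list(bad), "LT", cfg),
               "outside the epoch")
})

test_that("invalid configurations name the offending field", {
  expect_error(tinyConfig(pCredibleLong = 1.3), "pCredibleLong")
  expect_error(tinyConfig(trialsPerGroup = 7), "trialsPerGroup")
  expect_error(tinyConfig(regions = c("A", "A")), "unique")
  expect_error(tinyConfig(noiseAr = 1), "noiseAr")
  expect_error(
    tinyConfig(plantedEffects = list(
      plantedEffect(c("LT", "LF"), "R01", c(0, 500), 1))),
    "outside epoch")
})

test_that("cohort files round-trip losslessly, including the empty cohort", {
  cfg <- tinyConfig(nParticipants = 3, trialsPerGroup = 4)
  coh <- generateCohort(cfg, seed = 9)
  path <- tempfile(fileext = ".csv")
  writeCohort(coh, path)
  back <- readCohort(path)
  expect_equal(currents(back), currents(coh), tolerance = 1e-12)
  expect_identical(cases(back), cases(coh))
  expect_identical(participants(back), participants(coh))
  expect_identical(regions(back), regions(coh))

  # schema violations are named
  long <- read.csv(path)
  long$case <- NULL
  broken <- tempfile(fileext = ".csv")
  write.csv(long, broken, row.names = FALSE)
  expect_error(readCohort(broken), "case")

  # empty cohort: header-only file, reads back with zero trials
  emptyPath <- tempfile(fileext = ".csv")
  writeCohort(coh[, 0], emptyPath)
  backEmpty <- readCohort(emptyPath)
  expect_equal(ncol(backEmpty), 0L)
  expect_identical(regions(backEmpty), regions(coh))
})

test_that("parquet variant matches the csv round trip", {
  cfg <- tinyConfig(nParticipants = 2, trialsPerGroup = 4)
  coh <- generateCohort(cfg, seed = 4)
  path <- tempfile(fileext = ".parquet")
  writeCohort(coh, path, format = "parquet")
  back <- readCohort(path, format = "parquet")
  expect_equal(currents(back), currents(coh), tolerance = 1e-12)
  expect_identical(cases(back), cases(coh))
})
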