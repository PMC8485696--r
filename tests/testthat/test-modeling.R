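test_that("participant splits partition the cohort reproducibly", {
  coh <- plantedCohort(seed = 5, nParticipants = 12, trialsPerGroup = 4)
  sp <- splitParticipants(coh, 8, 4, seed = 3)
  expect_length(sp$train, 8)
  expect_length(sp$validation, 4)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_setequal(c(sp$train, sp$validation), participants(coh))
  expect_identical(sp, splitParticipants(coh, 8, 4, seed = 3))
  expect_false(identical(sp, splitParticipants(coh, 8, 4, seed = 4)))
  expect_error(splitParticipants(coh, 10, 4, seed = 1), "partition")
})

test_that("logistic fits agree with the glm IRLS reference to 1e-6", {
  set.seed(10)
  x <- matrix(runif(150), 50, 3, dimnames = list(NULL, c("Ra", "Rb", "Rc")))
  y <- runif(50) < plogis(-1 + 3 * x[, 1] - 2 * x[, 3])
  ours <- fitLogistic(x, y)
  ref <- glm(y ~ x, family = binomial)
  expect_lt(max(abs(coef(ours) - unname(coef(ref)))), 1e-6)
  expect_false(ours@ridged)

  # predictions agree too
  p <- predict(ours, x)
  expect_equal(unname(p), unname(fitted(ref)), tolerance = 1e-6)
})

test_that("degenerate and separable fits behave as documented", {
  # balanced labels with all-zero features: intercept ~ 0, p = 0.5
  x0 <- matrix(0, 40, 1, dimnames = list(NULL, "R"))
  y0 <- rep(c(TRUE, FALSE), 20)
  m0 <- fitLogistic(x0, y0)
  expect_lt(abs(coef(m0)[1]), 1e-8)
  expect_equal(unname(predict(m0, x0)[1]), 0.5)

  # 1-D linearly separable toy set: training accuracy 1, ridge fallback
  xs <- matrix(c(seq(0, 0.4, length.out = 10), seq(0.6, 1, length.out = 10)),
               ncol = 1, dimnames = list(NULL, "R"))
  ys <- rep(c(FALSE, TRUE), each = 10)
  expect_warning(ms <- fitLogistic(xs, ys), "separation")
  expect_true(ms@ridged)
  expect_true(all(is.finite(coef(ms))))
  expect_equal(unname(predict(ms, xs) > 0.5), ys)

  # single-class input is a fitting error
  expect_error(fitLogistic(xs, rep(TRUE, 20)), "class")
})

test_that("bootstrap accuracy calibrates against separable and null data", {
  set.seed(20)
  # perfectly separable data: mean OOB accuracy ~ 1
  xs <- matrix(c(runif(100, 0, 0.3), runif(100, 0.7, 1)), ncol = 1,
               dimnames = list(NULL, "R"))
  ys <- rep(c(FALSE, TRUE), each = 100)
  bs <- bootstrapAccuracy(xs, ys, B = 50, seed = 1)
  expect_gt(bs@meanAccuracy, 0.98)

  # labels independent of features: mean OOB accuracy ~ 0.5 at n = 400
  xn <- matrix(runif(400 * 2), 400, 2, dimnames = list(NULL, c("A", "B")))
  yn <- rep(c(TRUE, FALSE), 200)
  bn <- bootstrapAccuracy(xn, yn, B = 200, seed = 2)
  expect_lt(abs(bn@meanAccuracy - 0.5), 0.05)

  # bit-identical reports from the same seed
  b1 <- bootstrapAccuracy(xn, yn, B = 10, seed = 7)
  b2 <- bootstrapAccuracy(xn, yn, B = 10, seed = 7)
  expect_identical(b1@accuracies, b2@accuracies)
  expect_identical(b1@meanAccuracy, b2@meanAccuracy)
})

test_that("selection returns the single candidate unchanged and breaks ties deterministically", {
  coh <- plantedCohort(seed = 8, nParticipants = 10, trialsPerGroup = 6)
  one <- new("CandidateModelSpec", interval = c(100, 200),
             regions = c("R02", "R05"))
  sel <- selectBest(coh, list(one), B = 20, seed = 1)
  expect_identical(sel$model@spec@regions, one@regions)
  expect_identical(sel$model@spec@interval, one@interval)

  # duplicated candidate: same winner either way (deterministic tie order)
  sel2 <- selectBest(coh, list(one, one), B = 20, seed = 1)
  expect_identical(sel2$model@spec, sel$model@spec)
  expect_equal(sel2$bootstrap@meanAccuracy, sel$bootstrap@meanAccuracy)
})

test_that("the full search agrees with explicit candidate selection", {
  # with Q = |regions| every subset of every window is a candidate, so
  # searchCredModel and selectBest over the explicit list must coincide
  coh <- plantedCohort(seed = 9, nParticipants = 12, trialsPerGroup = 6,
                       regions = tinyRegions(3), epoch = c(0, 100),
                       effRegions = "R02", window = c(25, 75))
  cfg <- scanConfig(epoch = c(0, 100), lengths = 50, maxRegions = 3)
  cand <- list()
  for (i in seq_len(nrow(enumerateIntervals(cfg)))) {
    iv <- as.numeric(enumerateIntervals(cfg)[i, 1:2])
    rk <- rankRegions(coh, iv, Q = 3)
    cand <- c(cand, enumerateCandidates(rk))
  }
  a <- searchCredModel(coh, cfg, B = 30, seed = 5)
  b <- selectBest(coh, cand, B = 30, seed = 5)
  expect_identical(a$model@spec@interval, b$model@spec@interval)
  expect_setequal(a$model@spec@regions, b$model@spec@regions)
  expect_equal(a$bootstrap@meanAccuracy, b$bootstrap@meanAccuracy,
               tolerance = 1e-12)
})

test_that("evaluation metrics satisfy their identities and match pROC", {
  # hand confusion matrix: TP=30 FP=10 FN=20 TN=40
  met <- confusionMetrics(30, 10, 20, 40)
  expect_equal(met$precision, 0.75)
  expect_equal(met$recall, 0.6)
  expect_equal(met$f1, 2 / 3)
  expect_equal(met$accuracy, 0.7)

  coh <- plantedCohort(seed = 11, nParticipants = 8, trialsPerGroup = 6,
                       amplitude = 3)
  # amplitude-3 effect on a tiny cohort may separate; the ridge fallback
  # warning is expected there
  model <- suppressWarnings(
    fitRestricted(coh, c("R02", "R05"), c(100, 200))$model)
  ev <- evaluateModel(model, coh)
  # identities hold exactly on every report
  cm <- ev@confusion
  expect_equal(ev@accuracy, (cm[1, 1] + cm[2, 2]) / sum(cm))
  expect_equal(ev@f1, 2 * ev@precision * ev@recall /
                        (ev@precision + ev@recall))
  # AUC against pROC on the same scores
  p <- predict(model, coh)
  y <- credscan:::pairLabels(coh)
  refAuc <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = p,
                                           quiet = TRUE, direction = "<")))
  expect_equal(ev@auc, refAuc, tolerance = 1e-10)

  # all predictions correct: accuracy, F1 and AUC are 1
  xs <- matrix(c(runif(25, 0, 0.2), runif(25, 0.8, 1)), ncol = 1,
               dimnames = list(NULL, "R"))
  ys <- rep(c(FALSE, TRUE), each = 25)
  ms <- suppressWarnings(fitLogistic(xs, ys))
  evs <- evaluateModel(ms, xs, labels = ys)
  expect_equal(evs@accuracy, 1)
  expect_equal(evs@f1, 1)
  expect_equal(evs@auc, 1)

  # random scorer on balanced data: AUC ~ 0.5 (n = 1000)
  set.seed(30)
  xr <- matrix(runif(1000), ncol = 1, dimnames = list(NULL, "R"))
  yr <- rep(c(TRUE, FALSE), 500)
  mr <- fitLogistic(xr, yr)
  evr <- evaluateModel(mr, xr, labels = yr)
  expect_lt(abs(evr@auc - 0.5), 0.05)

  # single-class validation flags undefined metrics instead of zeros
  ev1 <- evaluateModel(ms, xs[ys, , drop = FALSE], labels = ys[ys])
  expect_true("auc" %in% ev1@undefined)
  expect_true(is.na(ev1@auc))
})

test_that("participant overlap between training and validation is refused", {
  coh <- plantedCohort(seed = 12, nParticipants = 6, trialsPerGroup = 4)
  model <- fitRestricted(coh, "R02", c(100, 200))$model
  expect_error(
    evaluateModel(model, coh, trainParticipants = participants(coh)[1:2]),
    "leakage")
})

test_that("restricted fits separate planted from pure-noise regions", {
  coh <- plantedCohort(seed = 13, nParticipants = 40, trialsPerGroup = 20)
  sp <- splitParticipants(coh, 30, 10, seed = 1)
  train <- coh[, coh$participant_id %in% sp$train]
  val <- coh[, coh$participant_id %in% sp$validation]

  planted <- fitRestricted(train, c("R02", "R05"), c(100, 200), val)
  noise <- fitRestricted(train, c("R01", "R04"), c(100, 200), val)
  expect_gt(planted$evaluation@accuracy, 0.65)
  # a signal-free model can do no better than the long-note base rate
  # (0.536); allow 3 binomial SE around it on the 200 validation trials
  se3 <- 3 * sqrt(0.536 * 0.464 / noise$evaluation@nTrials)
  expect_lt(abs(noise$evaluation@accuracy - 0.536), se3 + 0.02)
  expect_gt(planted$evaluation@accuracy, noise$evaluation@accuracy)

  expect_error(fitRestricted(train, character(), c(100, 200)), "empty")
  expect_error(fitRestricted(train, "R99", c(100, 200)), "R99")
})

test_that("published model fixtures reproduce the printed coefficients", {
  expect_setequal(publishedModelNames(),
                  c("ST_SF", "TT_FF", "LT_LF", "LT_LF_long_preferred"))

  stsf <- publishedModel("ST_SF")
  f0 <- setNames(numeric(5), stsf$spec@regions)
  expect_equal(applyPublishedModel("ST_SF", f0), plogis(-3.23286),
               tolerance = 1e-10)

  # strictly increasing in the R.BA.46 feature (positive coefficient)
  grid <- seq(0, 1, by = 0.1)
  probs <- vapply(grid, function(v) {
    f <- f0; f["R.BA.46"] <- v
    applyPublishedModel("ST_SF", f)
  }, numeric(1))
  expect_true(all(diff(probs) > 0))

  # all-zero coefficients give probability 0.5 for any input
  flat <- new("FittedCredModel",
              spec = new("CandidateModelSpec", interval = c(0, 5),
                         regions = c("A", "B")),
              coefficients = c("(Intercept)" = 0, A = 0, B = 0),
              converged = TRUE, ridged = FALSE, positiveClass = "credible")
  expect_equal(unname(predict(flat, cbind(A = 0.3, B = 0.9))), 0.5)

  expect_error(applyPublishedModel("ST_SF", f0[-1]), "R.BA.46")
  expect_error(applyPublishedModel("LT_LF_long_preferred", f0),
               "without coefficients")
  expect_error(publishedModel("nope"), "unknown")
})

test_that("model comparison reports overlap and interval geometry", {
  stsf <- publishedModel("ST_SF")
  ltlf <- publishedModel("LT_LF")
  lp <- publishedModel("LT_LF_long_preferred")

  self <- compareModels(stsf$model, stsf$model)
  expect_equal(self$jaccard, 1)
  expect_equal(self$intervalOffsetMs, 0)

  cross <- compareModels(stsf$model, ltlf$model)
  expect_equal(cross$jaccard, 0)
  expect_equal(cross$intervalOffsetMs, 830 - 105)
  expect_equal(cross$intervalOverlapMs, 0)

  # entire-population vs long-note-preferred: disjoint region sets
  lpCmp <- compareModels(ltlf$model, lp$spec)
  expect_equal(lpCmp$jaccard, 0)
  expect_setequal(ltlf$spec@regions,
                  c("L.BA.31", "L.BA.44", "R.Hippocampus", "L.BA.09",
                    "R.BA.08"))
  expect_setequal(lp$spec@regions, c("L.BA.40", "R.BA.04", "R.BA.09"))
})
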