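## Logistic classifier fitting, bootstrap model selection, and held-out
## evaluation.
##
## Fitting is plain maximum-likelihood logistic regression (Newton/IRLS in
## compiled code; identical to glm's solution). Under (quasi-)complete
## separation -- which small region subsets on small cohorts do produce --
## a small ridge penalty on the non-intercept coefficients keeps the fit
## finite; the model is flagged `ridged` and a warning is emitted.
##
## Bootstrap validation resamples training trials with replacement (same
## size), refits, and scores the refit on the out-of-bag trials; the mean
## over repetitions is the selection criterion. Resample draws always come
## from R's RNG so runs are reproducible from a single seed.

#' Split participants into training and validation sets
#'
#' Participant-level split: every participant's trials land wholly in one
#' set, so no validation information can reach training. Counts must
#' account for every participant in the cohort.
#'
#' @param cohort a \linkS4class{CredCohort} (typically one condition pair).
#' @param nTrain,nValidation participant counts (e.g. 78/27, 78/26, 74/21
#'   for the known/short/long pairs of a 105-participant cohort).
#' @param seed integer seed for the random assignment.
#' @return list with character vectors `train` and `validation`.
#' @export
splitParticipants <- function(cohort, nTrain, nValidation, seed) {
  ids <- participants(cohort)
  if (nTrain + nValidation != length(ids))
    stop("split ", nTrain, "+", nValidation, " does not partition the ",
         length(ids), " participants present")
  withSeed(seed, {
    tr <- sample(ids, nTrain)
    list(train = sort(tr), validation = sort(setdiff(ids, tr)))
  })
}

labelsOf <- function(y) {
  if (is.logical(y)) return(y)
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    bad <- setdiff(unique(y), CHOICE_LEVELS)
    if (length(bad)) stop("labels must be credible/not_credible")
    return(y == "credible")
  }
  if (is.numeric(y)) return(y > 0.5)
  stop("unsupported label type")
}

RIDGE_FALLBACK <- 1.0

#' Fit a logistic credibility classifier
#'
#' Maximum-likelihood logistic regression of the binary choice on the
#' supplied features (log-odds per unit sMEC). Deterministic given the
#' data. Under perfect separation the fit falls back to a ridge penalty
#' (`lambda = 1`) on the non-intercept coefficients, with a warning.
#'
#' @param features trials x regions numeric matrix with column names.
#' @param labels per-trial choices: logical (TRUE = credible), or
#'   `"credible"`/`"not_credible"`.
#' @param interval optional `[start, end)` ms metadata recording which
#'   window the features came from (NA when fit standalone).
#' @return a \linkS4class{FittedCredModel}.
#' @examples
#' x <- matrix(c(rnorm(20, 0), rnorm(20, 1)), ncol = 1,
#'             dimnames = list(NULL, "R01"))
#' fitLogistic(x, rep(c(FALSE, TRUE), each = 20))
#' @export
fitLogistic <- function(features, labels, interval = c(NA_real_, NA_real_)) {
  features <- as.matrix(features)
  if (is.null(colnames(features)))
    colnames(features) <- sprintf("x%d", seq_len(ncol(features)))
  y <- labelsOf(labels)
  if (length(y) != nrow(features)) stop("labels do not match feature rows")
  if (anyNA(features) || anyNA(y)) stop("missing values in features/labels")
  tab <- table(y)
  if (length(tab) < 2L || any(tab < 2L))
    stop("need at least two trials in each class (got ",
         paste(names(tab), tab, sep = "=", collapse = ", "), ")")
  X <- cbind(1, features)
  fit <- .logisticIRLS(X, as.numeric(y), lambda = 0, tol = 1e-8, maxit = 40)
  ridged <- FALSE
  if (!fit$converged || max(abs(fit$coefficients)) > 30) {
    fit <- .logisticIRLS(X, as.numeric(y), lambda = RIDGE_FALLBACK,
                         tol = 1e-8, maxit = 60)
    ridged <- TRUE
    warning("(quasi-)separation detected; ridge-penalized fallback used")
  }
  beta <- as.numeric(fit$coefficients)
  names(beta) <- c("(Intercept)", colnames(features))
  new("FittedCredModel",
      spec = new("CandidateModelSpec", interval = as.numeric(interval),
                 regions = colnames(features)),
      coefficients = beta, converged = fit$converged, ridged = ridged,
      positiveClass = "credible")
}

#' @describeIn fitLogistic predicted probability of "credible" for new
#'   feature rows (matrix with the model's regions as columns) or for a
#'   \linkS4class{CredCohort} (features recomputed from the model's
#'   interval).
#' @param object a \linkS4class{FittedCredModel}.
#' @param newdata feature matrix or cohort.
#' @export
setMethod("predict", "FittedCredModel", function(object, newdata, ...) {
  feat <- if (is(newdata, "CredCohort")) {
    if (all(is.na(object@spec@interval)))
      stop("model has no interval metadata; supply a feature matrix")
    intervalFeature(newdata, object@spec@interval)
  } else as.matrix(newdata)
  miss <- setdiff(object@spec@regions, colnames(feat))
  if (length(miss))
    stop("missing feature column(s): ", paste(miss, collapse = ", "))
  eta <- drop(cbind(1, feat[, object@spec@regions, drop = FALSE]) %*%
                object@coefficients)
  stats::plogis(eta)
})

## bootstrap resample multiplicities, n x B, drawn from the current RNG
resampleCounts <- function(n, B) {
  vapply(seq_len(B),
         function(b) tabulate(sample.int(n, n, replace = TRUE), n),
         integer(n))
}

#' Bootstrap out-of-bag accuracy of one candidate
#'
#' For each of `B` repetitions: resample the training trials with
#' replacement (same size), fit the logistic model on the resample, and
#' score accuracy on the out-of-bag trials; report the per-repetition
#' accuracies and their mean. Repetitions whose out-of-bag set is empty are
#' skipped, counted, and warned about.
#'
#' @param features trials x regions matrix (the candidate's features).
#' @param labels per-trial choices.
#' @param B repetitions (the reference analysis uses 1000).
#' @param seed integer seed.
#' @return a \linkS4class{BootstrapReport}.
#' @export
bootstrapAccuracy <- function(features, labels, B = 1000L, seed = 1L) {
  features <- as.matrix(features)
  y <- labelsOf(labels)
  n <- nrow(features)
  if (B < 1L) stop("B must be >= 1")
  cnt <- withSeed(seed, resampleCounts(n, B))
  res <- .bootCandidates(features, as.numeric(y),
                         list(seq_len(ncol(features)) - 1L),
                         cnt * 1.0)
  acc <- as.numeric(res$accuracies[1L, ])
  skipped <- as.integer(res$emptyOOB[1L])
  if (skipped > 0L)
    warning(skipped, " repetition(s) had an empty out-of-bag set and were skipped")
  new("BootstrapReport", B = as.integer(B), accuracies = acc,
      meanAccuracy = mean(acc, na.rm = TRUE), seed = as.integer(seed),
      skipped = skipped)
}

## ordering used for ties in model selection: fewer regions, earlier
## interval start, lexicographic region labels. Returns TRUE if a beats b.
beatsTie <- function(accA, specA, accB, specB) {
  if (is.na(accB)) return(TRUE)
  if (is.na(accA)) return(FALSE)
  if (accA != accB) return(accA > accB)
  if (length(specA@regions) != length(specB@regions))
    return(length(specA@regions) < length(specB@regions))
  sa <- specA@interval[1]; sb <- specB@interval[1]
  if (!is.na(sa) && !is.na(sb) && sa != sb) return(sa < sb)
  paste(specA@regions, collapse = ",") < paste(specB@regions, collapse = ",")
}

#' Select the best candidate model by bootstrap accuracy
#'
#' Evaluates every candidate's mean bootstrap out-of-bag accuracy on the
#' training trials and returns the winner, refit on all training trials.
#' One shared set of `B` resamples is used for all candidates (paired
#' comparison). Ties break deterministically: fewer regions, then earlier
#' interval start, then lexicographic region labels.
#'
#' @param train a \linkS4class{CredCohort} of training trials (one
#'   condition pair) with an `"smec"` assay.
#' @param candidates list of \linkS4class{CandidateModelSpec}.
#' @param B bootstrap repetitions.
#' @param seed integer seed for the resamples.
#' @return list: `model` (\linkS4class{FittedCredModel}), `bootstrap`
#'   (\linkS4class{BootstrapReport} of the winner), `scores` (data.frame of
#'   all candidates' mean accuracies).
#' @export
selectBest <- function(train, candidates, B = 1000L, seed = 1L) {
  if (!length(candidates)) stop("empty candidate list")
  y <- as.numeric(pairLabels(train))
  n <- ncol(train)
  cnt <- withSeed(seed, resampleCounts(n, B)) * 1.0
  key <- vapply(candidates, function(s)
    paste(s@interval, collapse = "-"), character(1))
  groups <- split(seq_along(candidates), key)
  bestAcc <- NA_real_
  best <- NULL
  bestAccs <- NULL
  scores <- data.frame(start_ms = numeric(), end_ms = numeric(),
                       regions = character(), meanAccuracy = numeric())
  for (g in groups) {
    interval <- candidates[[g[1L]]]@interval
    feat <- intervalFeature(train, interval)
    subs <- lapply(g, function(i)
      match(candidates[[i]]@regions, colnames(feat)) - 1L)
    if (anyNA(unlist(subs))) stop("candidate regions missing from cohort")
    res <- .bootCandidates(feat, y, subs, cnt)
    for (k in seq_along(g)) {
      spec <- candidates[[g[k]]]
      acc <- res$meanAccuracy[k]
      scores <- rbind(scores, data.frame(
        start_ms = interval[1], end_ms = interval[2],
        regions = paste(spec@regions, collapse = ","),
        meanAccuracy = acc))
      if (is.null(best) || beatsTie(acc, spec, bestAcc, best)) {
        bestAcc <- acc
        best <- spec
        bestAccs <- as.numeric(res$accuracies[k, ])
      }
    }
  }
  finalizeSelection(train, best, bestAcc, bestAccs, B, seed, scores)
}

finalizeSelection <- function(train, best, bestAcc, bestAccs, B, seed,
                              scores) {
  feat <- intervalFeature(train, best@interval)[, best@regions, drop = FALSE]
  model <- fitLogistic(feat, pairLabels(train), interval = best@interval)
  report <- new("BootstrapReport", B = as.integer(B),
                accuracies = bestAccs, meanAccuracy = bestAcc,
                seed = as.integer(seed),
                skipped = as.integer(sum(is.na(bestAccs))))
  list(model = model, bootstrap = report, scores = scores)
}

#' Full interval/region model search
#'
#' The complete search: enumerate every window of the configured lengths on
#' the 5 ms grid, rank regions within each window by mean absolute
#' between-class sMEC difference, form all non-empty subsets of the top-Q
#' regions, estimate each candidate's mean bootstrap out-of-bag accuracy
#' (shared resamples), and return the best model refit on all training
#' trials.
#'
#' @param train training-trial \linkS4class{CredCohort} (one condition
#'   pair) with an `"smec"` assay.
#' @param config a \linkS4class{ScanConfig}.
#' @param B bootstrap repetitions per candidate.
#' @param seed integer seed.
#' @return list: `model`, `bootstrap` (winner's report), `intervalScores`
#'   (data.frame with each interval's best candidate and accuracy).
#' @export
searchCredModel <- function(train, config, B = 100L, seed = 1L) {
  stopifnot(is(config, "ScanConfig"))
  if (!"smec" %in% assayNames(train))
    stop("training cohort lacks an 'smec' assay; run normalizeSMEC()")
  ivs <- enumerateIntervals(config)
  y <- as.numeric(pairLabels(train))
  n <- ncol(train)
  Q <- min(config@maxRegions, length(regions(train)))
  subsTemplate <- subsetIndices(Q)
  cnt <- withSeed(seed, resampleCounts(n, B)) * 1.0
  cums <- smecCumsum(train)
  binMs <- metadata(train)$config@binMs
  epoch0 <- metadata(train)$config@epoch[1]
  bestAcc <- NA_real_
  best <- NULL
  bestAccs <- NULL
  ivBest <- data.frame(start_ms = ivs$start_ms, end_ms = ivs$end_ms,
                       regions = NA_character_,
                       meanAccuracy = NA_real_)
  for (i in seq_len(nrow(ivs))) {
    b1 <- as.integer((ivs$start_ms[i] - epoch0) / binMs)
    b2 <- as.integer((ivs$end_ms[i] - epoch0) / binMs)
    feat <- featureFromCumsum(cums, b1, b2)
    interval <- c(ivs$start_ms[i], ivs$end_ms[i])
    rk <- rankRegionsFromFeatures(feat, y > 0.5, interval, Q)
    topIdx <- match(rk@regions, colnames(feat))
    subs <- lapply(subsTemplate, function(s) topIdx[s + 1L] - 1L)
    res <- .bootCandidates(feat[, , drop = FALSE], y, subs, cnt)
    accs <- res$meanAccuracy
    kBest <- which.max(accs)
    ivBest$regions[i] <- paste(rk@regions[subsTemplate[[kBest]] + 1L],
                               collapse = ",")
    ivBest$meanAccuracy[i] <- accs[kBest]
    for (k in seq_along(subs)) {
      acc <- accs[k]
      if (is.na(acc)) next
      ## only materialize a spec when the candidate can win
      if (!is.null(best) && !is.na(bestAcc) && acc < bestAcc) next
      spec <- new("CandidateModelSpec", interval = interval,
                  regions = rk@regions[subsTemplate[[k]] + 1L])
      if (is.null(best) || beatsTie(acc, spec, bestAcc, best)) {
        bestAcc <- acc
        best <- spec
        bestAccs <- as.numeric(res$accuracies[k, ])
      }
    }
  }
  out <- finalizeSelection(train, best, bestAcc, bestAccs, B, seed,
                           ivBest)
  names(out)[names(out) == "scores"] <- "intervalScores"
  out
}

#' Metrics from confusion-matrix counts
#'
#' @param tp,fp,fn,tn trial counts with "credible" as the positive class.
#' @return named list: accuracy, precision, recall, f1 (NA where the
#'   denominator is zero), plus the 2x2 matrix (rows = predicted,
#'   cols = actual).
#' @examples
#' confusionMetrics(30, 10, 20, 40)$precision  # 0.75
#' @export
confusionMetrics <- function(tp, fp, fn, tn) {
  cm <- matrix(c(tp, fn, fp, tn), 2, 2,
               dimnames = list(predicted = c("credible", "not_credible"),
                               actual = c("credible", "not_credible")))
  total <- sum(cm)
  acc <- if (total > 0) (tp + tn) / total else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
    2 * prec * rec / (prec + rec) else NA_real_
  list(accuracy = acc, precision = prec, recall = rec, f1 = f1,
       confusion = cm)
}

## threshold-swept ROC (TPR vs FPR) and trapezoidal AUC
rocPoints <- function(scores, positive) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- positive[ord]
  nP <- sum(positive)
  nN <- sum(!positive)
  tp <- cumsum(p)
  fp <- cumsum(!p)
  keep <- c(which(diff(s) != 0), length(s))  # one point per threshold
  df <- data.frame(threshold = c(Inf, s[keep]),
                   fpr = c(0, fp[keep] / nN),
                   tpr = c(0, tp[keep] / nP))
  auc <- sum(diff(df$fpr) * (head(df$tpr, -1) + df$tpr[-1]) / 2)
  list(roc = df, auc = auc)
}

#' Evaluate a fitted model on held-out trials
#'
#' Applies the model to validation trials (decision threshold 0.5,
#' positive class "credible"), and reports the confusion matrix, accuracy,
#' precision, recall, F1, a threshold-swept ROC curve and trapezoidal AUC.
#' Metrics whose denominator is empty on the given validation set are NA
#' and named in `undefined` rather than silently zero.
#'
#' @param model a \linkS4class{FittedCredModel}.
#' @param validation a \linkS4class{CredCohort} of held-out trials (must
#'   carry an `"smec"` assay), or a feature matrix.
#' @param labels required when `validation` is a matrix.
#' @param trainParticipants optional: training participant ids, checked for
#'   overlap with the validation participants (data-leakage guard).
#' @return an \linkS4class{EvaluationReport}.
#' @export
evaluateModel <- function(model, validation, labels = NULL,
                          trainParticipants = NULL) {
  if (is(validation, "CredCohort")) {
    if (!is.null(trainParticipants)) {
      overlap <- intersect(trainParticipants, participants(validation))
      if (length(overlap))
        stop("data leakage: participant(s) in both sets: ",
             paste(overlap, collapse = ", "))
    }
    y <- pairLabels(validation)
  } else {
    y <- labelsOf(labels)
  }
  p <- predict(model, validation)
  pred <- p > 0.5
  met <- confusionMetrics(tp = sum(pred & y), fp = sum(pred & !y),
                          fn = sum(!pred & y), tn = sum(!pred & !y))
  undef <- names(which(vapply(met[c("accuracy", "precision", "recall",
                                    "f1")], is.na, logical(1))))
  if (sum(y) == 0 || sum(!y) == 0) {
    roc <- data.frame(threshold = numeric(), fpr = numeric(),
                      tpr = numeric())
    auc <- NA_real_
    undef <- union(undef, "auc")
  } else {
    rr <- rocPoints(p, y)
    roc <- rr$roc
    auc <- rr$auc
  }
  new("EvaluationReport", accuracy = met$accuracy,
      precision = met$precision, recall = met$recall, f1 = met$f1,
      confusion = met$confusion, roc = roc, auc = auc,
      positiveClass = "credible", nTrials = length(y),
      undefined = undef)
}

#' Fit a model with fixed regions and interval (search bypassed)
#'
#' Fits the logistic classifier on prescribed regions and window -- e.g.
#' the frontal regions L.BA.08/L.BA.09 proposed as generic decision-making
#' areas -- so its held-out performance can be compared against the
#' searched model.
#'
#' @param train,validation condition-pair cohorts with `"smec"` assays.
#' @param regionsUsed region labels (non-empty, present in the cohort).
#' @param interval `[start, end)` ms.
#' @return list: `model`, `evaluation` (NULL when `validation` is NULL).
#' @export
fitRestricted <- function(train, regionsUsed, interval, validation = NULL) {
  if (!length(regionsUsed)) stop("region list is empty")
  miss <- setdiff(regionsUsed, regions(train))
  if (length(miss))
    stop("region(s) not in the cohort: ", paste(miss, collapse = ", "))
  feat <- intervalFeature(train, interval)[, regionsUsed, drop = FALSE]
  model <- fitLogistic(feat, pairLabels(train), interval = interval)
  ev <- if (!is.null(validation))
    evaluateModel(model, validation,
                  trainParticipants = participants(train))
  list(model = model, evaluation = ev)
}

specOf <- function(x) {
  if (is(x, "FittedCredModel")) return(x@spec)
  if (is(x, "CandidateModelSpec")) return(x)
  if (is.list(x) && !is.null(x$spec)) return(specOf(x$spec))
  stop("cannot extract a model spec from ", class(x)[1])
}

#' Structural comparison of two models
#'
#' Reports region-set overlap (Jaccard index), interval start offset and
#' overlap in ms, and an aligned coefficient table where both models carry
#' coefficients. Makes no significance claim.
#'
#' @param a,b fitted models, candidate specs, or published-model entries.
#' @return list with `jaccard`, `sharedRegions`, `intervalOffsetMs`,
#'   `intervalOverlapMs`, `coefficients` (data.frame or NULL).
#' @export
compareModels <- function(a, b) {
  sa <- specOf(a)
  sb <- specOf(b)
  shared <- intersect(sa@regions, sb@regions)
  jac <- length(shared) / length(union(sa@regions, sb@regions))
  off <- sb@interval[1] - sa@interval[1]
  ov <- max(0, min(sa@interval[2], sb@interval[2]) -
               max(sa@interval[1], sb@interval[1]))
  coefTab <- NULL
  if (is(a, "FittedCredModel") && is(b, "FittedCredModel")) {
    allReg <- union(names(a@coefficients), names(b@coefficients))
    coefTab <- data.frame(term = allReg,
                          a = a@coefficients[allReg],
                          b = b@coefficients[allReg], row.names = NULL)
  }
  list(jaccard = jac, sharedRegions = shared, intervalOffsetMs = off,
       intervalOverlapMs = ov, coefficients = coefTab)
}

#' @export
setMethod("coef", "FittedCredModel", function(object) object@coefficients)

setMethod("show", "FittedCredModel", function(object) {
  iv <- object@spec@interval
  cat("FittedCredModel: interval [", iv[1], ",", iv[2], ") ms;",
      length(object@spec@regions), "region(s)\n")
  print(round(object@coefficients, 5))
  if (object@ridged) cat("  (ridge fallback: separation detected)\n")
  invisible(NULL)
})

setMethod("show", "BootstrapReport", function(object) {
  cat("BootstrapReport: B =", object@B, " mean OOB accuracy =",
      round(object@meanAccuracy, 4), "\n")
  if (object@skipped > 0L)
    cat("  skipped (empty OOB):", object@skipped, "\n")
  invisible(NULL)
})

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport on", object@nTrials, "trials (positive class:",
      object@positiveClass, ")\n")
  cat(sprintf("  accuracy %.3f  precision %.3f  recall %.3f  f1 %.3f  AUC %.3f\n",
              object@accuracy, object@precision, object@recall, object@f1,
              object@auc))
  print(object@confusion)
  if (length(object@undefined))
    cat("  undefined:", paste(object@undefined, collapse = ", "), "\n")
  invisible(NULL)
})
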