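#' @importFrom methods new validObject is slot slotNames as callNextMethod
#' @importFrom stats rbinom rnorm runif binom.test plogis qlogis setNames coef predict
#' @importFrom utils read.csv write.csv head combn
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @useDynLib credscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## The six observable stimulus-by-choice cases. First letter: stimulus type
## (T/F = true/false translation of a known sign; S/L = short/long note on an
## unknown sign). Second letter: the participant's credibility choice
## (T = credible, F = not credible). TF and FT never occur: participants are
## never wrong about signs they know.
CASE_LEVELS <- c("TT", "FF", "ST", "SF", "LT", "LF")
CHOICE_LEVELS <- c("credible", "not_credible")
GROUP_LEVELS <- c("known", "short", "long")

caseGroup <- function(case) {
  g <- c(TT = "known", FF = "known", ST = "short", SF = "short",
         LT = "long", LF = "long")[case]
  unname(g)
}

caseChoice <- function(case) {
  ifelse(substr(case, 2L, 2L) == "T", "credible", "not_credible")
}

groupPair <- function(group) {
  switch(group,
         known = c("TT", "FF"),
         short = c("ST", "SF"),
         long  = c("LT", "LF"),
         stop("unknown condition group: ", group))
}

#' Planted ground-truth effect for synthetic cohorts
#'
#' Describes a class-dependent elevation of cortical current: within one
#' case pair, trials of the `elevated` case receive an additive
#' Gaussian-in-time bump in the listed regions, confined to `window`.
#' Amplitude is expressed in units of the baseline noise SD so that planted
#' effect sizes are comparable across noise settings.
#'
#' @slot casePair character(2), one of (TT,FF), (ST,SF), (LT,LF).
#' @slot regions character, region labels carrying the effect.
#' @slot window numeric(2), [start, end) in ms, within the epoch.
#' @slot amplitude nonnegative peak height in baseline-SD units.
#' @slot elevated which case of the pair is elevated.
#' @exportClass PlantedEffect
setClass("PlantedEffect",
  representation(casePair = "character", regions = "character",
                 window = "numeric", amplitude = "numeric",
                 elevated = "character"),
  validity = function(object) {
    msg <- character()
    pairs <- list(c("TT", "FF"), c("ST", "SF"), c("LT", "LF"))
    if (!any(vapply(pairs, identical, logical(1), y = object@casePair)))
      msg <- c(msg, "casePair must be one of (TT,FF), (ST,SF), (LT,LF)")
    if (length(object@window) != 2L || diff(object@window) <= 0)
      msg <- c(msg, "window must be [start, end) with end > start")
    if (length(object@amplitude) != 1L || object@amplitude < 0)
      msg <- c(msg, "amplitude must be a single nonnegative number")
    if (!(object@elevated %in% object@casePair))
      msg <- c(msg, "elevated must be a member of casePair")
    if (length(object@regions) < 1L)
      msg <- c(msg, "at least one region required")
    if (length(msg)) msg else TRUE
  })

#' Synthetic cohort configuration
#'
#' Holds the experiment's structure: participant count, three groups of
#' trials (known-sign short notes, unknown-sign short notes, unknown-sign
#' long notes), the epoch and 5 ms bin grid, behavioral credibility rates
#' for the no-knowledge cases, per-condition completion counts, the
#' participant gain range motivating per-participant normalization, the
#' baseline noise process, and any planted effects.
#'
#' @exportClass CohortConfig
setClass("CohortConfig",
  representation(nParticipants = "integer", trialsPerGroup = "integer",
                 regions = "character", epoch = "numeric", binMs = "numeric",
                 pCredibleLong = "numeric", pCredibleShort = "numeric",
                 attrition = "integer", gainRange = "numeric",
                 baselineLevel = "numeric", noiseSd = "numeric",
                 noiseAr = "numeric", nonResponseRate = "numeric",
                 plantedEffects = "list"),
  validity = function(object) {
    msg <- character()
    if (object@nParticipants < 1L)
      msg <- c(msg, "nParticipants must be >= 1")
    if (object@trialsPerGroup < 2L || object@trialsPerGroup %% 2L != 0L)
      msg <- c(msg, "trialsPerGroup must be even (known group splits 50/50 true/false)")
    if (anyDuplicated(object@regions))
      msg <- c(msg, "regions: region labels must be unique")
    if (length(object@epoch) != 2L || diff(object@epoch) <= 0)
      msg <- c(msg, "epoch must be [start_ms, end_ms] with end > start")
    if (object@binMs <= 0 || diff(object@epoch) %% object@binMs != 0)
      msg <- c(msg, "epoch span must be a positive multiple of binMs")
    for (p in c("pCredibleLong", "pCredibleShort", "nonResponseRate")) {
      v <- slot(object, p)
      if (v < 0 || v > 1) msg <- c(msg, paste0(p, " must be in [0,1]"))
    }
    if (length(object@attrition) != 3L ||
        !identical(names(object@attrition), GROUP_LEVELS))
      msg <- c(msg, "attrition must be named counts for known/short/long")
    else if (any(object@attrition < 0L) ||
             any(object@attrition > object@nParticipants))
      msg <- c(msg, "attrition counts must lie in [0, nParticipants]")
    if (length(object@gainRange) != 2L || any(object@gainRange <= 0) ||
        diff(object@gainRange) < 0)
      msg <- c(msg, "gainRange must be a positive interval")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (object@noiseAr < 0 || object@noiseAr >= 1)
      msg <- c(msg, "noiseAr must be in [0, 1)")
    for (e in object@plantedEffects) {
      if (!is(e, "PlantedEffect"))
        msg <- c(msg, "plantedEffects must be PlantedEffect objects")
      else {
        if (e@window[1] < object@epoch[1] || e@window[2] > object@epoch[2])
          msg <- c(msg, "plantedEffects: effect window outside epoch")
        if (!all(e@regions %in% object@regions))
          msg <- c(msg, "plantedEffects: effect regions not in configured regions")
      }
    }
    if (length(msg)) msg else TRUE
  })

#' Cohort of single-trial region-by-time current matrices
#'
#' A \linkS4class{SummarizedExperiment} whose rows are (region, 5 ms bin)
#' pairs and whose columns are trials. The `"current"` assay holds
#' nonnegative source-current values; `computeMEC()` and `normalizeSMEC()`
#' add `"mec"` and `"smec"` assays on the same grid. Column metadata carries
#' participant, case, choice and responded flags; `metadata()` carries the
#' generating \linkS4class{CohortConfig} and seed.
#'
#' @exportClass CredCohort
setClass("CredCohort", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- character()
    cd <- colData(object)
    need <- c("participant_id", "trial_id", "case", "choice", "responded")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
      msg <- c(msg, paste("missing colData columns:",
                          paste(miss, collapse = ", ")))
    rd <- rowData(object)
    if (!all(c("region", "bin_start_ms") %in% colnames(rd)))
      msg <- c(msg, "rowData must have region and bin_start_ms")
    if (!"current" %in% assayNames(object))
      msg <- c(msg, "assay 'current' is required")
    if (!length(msg)) {
      if (!all(cd$case %in% CASE_LEVELS))
        msg <- c(msg, "case labels must be TT/FF/ST/SF/LT/LF")
      else if (!all(cd$choice == caseChoice(cd$case)))
        msg <- c(msg, "choice must encode the case's second letter (no TF/FT)")
      cur <- assay(object, "current")
      if (length(cur) && min(cur) < 0)
        msg <- c(msg, "currents must be nonnegative")
    }
    if (length(msg)) msg else TRUE
  })

#' Toy lead field for the standardized minimum-norm inverse
#'
#' Linear forward operator mapping dipole currents (fixed orientations, one
#' scalar per dipole) to scalp potentials.
#'
#' @slot gain channels x dipoles matrix.
#' @slot channels,dipoles axis labels.
#' @exportClass LeadField
setClass("LeadField",
  representation(gain = "matrix", channels = "character",
                 dipoles = "character"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@gain) < 2L) msg <- c(msg, "need at least 2 channels")
    if (ncol(object@gain) < 1L) msg <- c(msg, "need at least 1 dipole")
    if (length(object@channels) != nrow(object@gain) ||
        length(object@dipoles) != ncol(object@gain))
      msg <- c(msg, "label lengths must match gain dimensions")
    if (any(colSums(object@gain^2) == 0))
      msg <- c(msg, "no all-zero dipole columns allowed")
    if (length(msg)) msg else TRUE
  })

#' Standardized source estimate
#'
#' Per-dipole standardized current magnitude over time, as returned by
#' \code{\link{sloretaInverse}}.
#'
#' @slot activity dipoles x bins matrix of nonnegative magnitudes.
#' @slot alpha the Tikhonov regularization actually used.
#' @exportClass SourceEstimate
setClass("SourceEstimate",
  representation(activity = "matrix", alpha = "numeric"),
  validity = function(object) {
    if (!all(is.finite(object@activity)))
      return("activity must be finite")
    TRUE
  })

#' Interval/region scan configuration
#'
#' @slot epoch numeric(2), ms.
#' @slot binMs grid step, ms.
#' @slot lengths interval lengths to scan, each a positive multiple of binMs.
#' @slot maxRegions maximum regions per candidate model (top-Q ranking cut).
#' @exportClass ScanConfig
setClass("ScanConfig",
  representation(epoch = "numeric", binMs = "numeric", lengths = "numeric",
                 maxRegions = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@epoch) != 2L || diff(object@epoch) <= 0)
      msg <- c(msg, "epoch must be [start, end], end > start")
    if (any(object@lengths %% object@binMs != 0) || any(object@lengths <= 0))
      msg <- c(msg, "lengths must be positive multiples of binMs")
    if (any(object@lengths > diff(object@epoch)))
      msg <- c(msg, "lengths must not exceed the epoch span")
    if (object@maxRegions < 1L)
      msg <- c(msg, "maxRegions must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' Candidate classifier specification: one time window, one region subset
#' @slot interval numeric(2) half-open [start, end) in ms.
#' @slot regions character, the explanatory regions.
#' @exportClass CandidateModelSpec
setClass("CandidateModelSpec",
  representation(interval = "numeric", regions = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@interval) != 2L ||
        (!all(is.na(object@interval)) && diff(object@interval) <= 0))
      msg <- c(msg, "interval must be [start, end) with end > start (or NA for models fit outside the scan)")
    if (length(object@regions) < 1L || anyDuplicated(object@regions))
      msg <- c(msg, "regions must be a non-empty set of unique labels")
    if (length(msg)) msg else TRUE
  })

#' Region ranking for one interval
#'
#' Regions ordered by decreasing mean absolute between-class difference of
#' the interval-averaged sMEC feature, computed on training trials only.
#' Ties are broken lexicographically by region label.
#' @exportClass RegionRanking
setClass("RegionRanking",
  representation(interval = "numeric", regions = "character",
                 scores = "numeric", classes = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@regions) != length(object@scores))
      msg <- c(msg, "regions and scores must align")
    if (is.unsorted(rev(object@scores)))
      msg <- c(msg, "scores must be nonincreasing")
    if (length(msg)) msg else TRUE
  })

#' Fitted logistic credibility classifier
#'
#' @slot spec the \linkS4class{CandidateModelSpec} the model was fit to.
#' @slot coefficients named vector: "(Intercept)" then one log-odds
#'   coefficient per region (per unit sMEC feature).
#' @slot converged,ridged fitting diagnostics; `ridged` marks the ridge
#'   fallback used under (quasi-)separation.
#' @slot positiveClass the choice treated as positive ("credible").
#' @exportClass FittedCredModel
setClass("FittedCredModel",
  representation(spec = "CandidateModelSpec", coefficients = "numeric",
                 converged = "logical", ridged = "logical",
                 positiveClass = "character"),
  validity = function(object) {
    msg <- character()
    want <- c("(Intercept)", object@spec@regions)
    if (!identical(names(object@coefficients), want))
      msg <- c(msg, "coefficients must be (Intercept) plus one per region, in spec order")
    if (!all(is.finite(object@coefficients)))
      msg <- c(msg, "coefficients must be finite")
    if (length(msg)) msg else TRUE
  })

#' Bootstrap validation report
#' @slot B repetitions requested; `accuracies` has one out-of-bag accuracy
#'   per non-degenerate repetition (NA where the out-of-bag set was empty).
#' @exportClass BootstrapReport
setClass("BootstrapReport",
  representation(B = "integer", accuracies = "numeric",
                 meanAccuracy = "numeric", seed = "integer",
                 skipped = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@B < 1L) msg <- c(msg, "B must be >= 1")
    a <- object@accuracies[!is.na(object@accuracies)]
    if (length(a) && (min(a) < 0 || max(a) > 1))
      msg <- c(msg, "accuracies must lie in [0,1]")
    if (length(msg)) msg else TRUE
  })

#' Held-out evaluation report
#'
#' Confusion matrix at threshold 0.5 with "credible" as the positive class,
#' derived metrics, and a threshold-swept ROC curve with trapezoidal AUC.
#' Metrics that are undefined on the given validation set (e.g. precision
#' with no positive predictions) are NA and listed in `undefined`.
#' @exportClass EvaluationReport
setClass("EvaluationReport",
  representation(accuracy = "numeric", precision = "numeric",
                 recall = "numeric", f1 = "numeric", confusion = "matrix",
                 roc = "data.frame", auc = "numeric",
                 positiveClass = "character", nTrials = "integer",
                 undefined = "character"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@confusion), c(2L, 2L)))
      msg <- c(msg, "confusion must be 2x2")
    if (!is.na(object@auc) && (object@auc < 0 || object@auc > 1))
      msg <- c(msg, "AUC must be in [0,1]")
    cm <- object@confusion
    if (!length(msg) && sum(cm) > 0) {
      acc <- (cm[1, 1] + cm[2, 2]) / sum(cm)
      if (abs(acc - object@accuracy) > 1e-12)
        msg <- c(msg, "accuracy inconsistent with confusion matrix")
    }
    if (length(msg)) msg else TRUE
  })

#' Behavioral summary of the no-knowledge credibility choices
#' @exportClass BehavioralSummary
setClass("BehavioralSummary",
  representation(counts = "numeric", proportionLong = "numeric",
                 proportionShort = "numeric", lengthBias = "logical",
                 binomK = "numeric", binomN = "numeric", binomP0 = "numeric",
                 pValue = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!all(c("LT", "LF", "ST", "SF") %in% names(object@counts)))
      msg <- c(msg, "counts must name LT, LF, ST, SF")
    for (p in c("proportionLong", "proportionShort", "pValue")) {
      v <- slot(object, p)
      if (!is.na(v) && (v < 0 || v > 1))
        msg <- c(msg, paste0(p, " must be in [0,1]"))
    }
    if (length(msg)) msg else TRUE
  })
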