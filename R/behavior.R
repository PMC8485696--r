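## Behavioral analysis of the no-knowledge credibility choices: the
## long/short credibility proportions, the exact binomial randomness test,
## and the per-participant long-note-preference (LC/SC) grouping.

#' Proportion of positive credibility evaluations
#'
#' @param nPos,nNeg nonnegative counts (positive and negative evaluations).
#' @return `nPos / (nPos + nNeg)`.
#' @examples
#' proportionPositive(4079, 3526)  # 0.536, long notes
#' proportionPositive(3455, 4977)  # 0.410, short notes
#' @export
proportionPositive <- function(nPos, nNeg) {
  if (nPos < 0 || nNeg < 0) stop("counts must be nonnegative")
  if (nPos + nNeg == 0)
    stop("proportion undefined: both counts are zero")
  nPos / (nPos + nNeg)
}

#' Exact two-sided binomial randomness test
#'
#' Tests whether `k` successes in `n` Bernoulli(p0) draws are compatible
#' with chance, with the standard two-sided p-value that sums the
#' probabilities of all outcomes no more likely than the observed one
#' (stats::binom.test). Used to test whether long/short credibility choices
#' in the no-knowledge cases are binomially random at p0 = 0.5.
#'
#' @param k observed successes (0 <= k <= n).
#' @param n trials.
#' @param p0 null probability, in (0, 1).
#' @return the p-value.
#' @examples
#' binomialRandomnessTest(3455, 7534)  # far below 1e-6
#' binomialRandomnessTest(5, 10)       # 1: the modal outcome
#' @export
binomialRandomnessTest <- function(k, n, p0 = 0.5) {
  if (n < 1 || k < 0 || k > n) stop("need 0 <= k <= n, n >= 1")
  if (p0 <= 0 || p0 >= 1) stop("p0 must be in (0, 1)")
  stats::binom.test(k, n, p0)$p.value
}

#' Behavioral summary of a cohort or of explicit case counts
#'
#' Computes the long- and short-note credibility proportions, the
#' length-bias indicator (long proportion strictly above short), and the
#' binomial randomness test. The test defaults to k = |ST| successes out of
#' n = |ST| + |SF| short-note evaluations at p0 = 0.5; explicit `k`/`n`
#' override, e.g. to reproduce an externally printed pair.
#'
#' @param x a \linkS4class{CredCohort} (responded unknown-sign trials are
#'   counted) or a named vector/list with counts `LT`, `LF`, `ST`, `SF`.
#' @param k,n optional binomial test inputs overriding the defaults.
#' @param p0 null probability for the test.
#' @return a \linkS4class{BehavioralSummary}.
#' @examples
#' behavioralSummary(c(LT = 4079, LF = 3526, ST = 3455, SF = 4977))
#' @export
behavioralSummary <- function(x, k = NULL, n = NULL, p0 = 0.5) {
  counts <- if (is(x, "CredCohort")) {
    cs <- cases(x)[x$responded]
    vapply(c("LT", "LF", "ST", "SF"), function(cl) sum(cs == cl),
           numeric(1))
  } else {
    x <- unlist(x)
    miss <- setdiff(c("LT", "LF", "ST", "SF"), names(x))
    if (length(miss))
      stop("missing count(s): ", paste(miss, collapse = ", "))
    x[c("LT", "LF", "ST", "SF")]
  }
  if (is.null(k)) k <- counts[["ST"]]
  if (is.null(n)) n <- counts[["ST"]] + counts[["SF"]]
  new("BehavioralSummary", counts = counts,
      proportionLong = proportionPositive(counts[["LT"]], counts[["LF"]]),
      proportionShort = proportionPositive(counts[["ST"]], counts[["SF"]]),
      lengthBias = proportionPositive(counts[["LT"]], counts[["LF"]]) >
        proportionPositive(counts[["ST"]], counts[["SF"]]),
      binomK = as.numeric(k), binomN = as.numeric(n), binomP0 = p0,
      pValue = binomialRandomnessTest(k, n, p0))
}

#' Long-note-preference grouping (LC/SC ratio)
#'
#' For each participant, counts how often long notes (LC) and short notes
#' (SC) of unknown signs were judged credible, forms the ratio LC/SC, and
#' flags participants whose ratio lies strictly above the mean ratio of
#' all participants with a defined ratio. Participants with SC = 0 have an
#' undefined ratio: they are flagged and excluded from the mean.
#'
#' @param cohort a \linkS4class{CredCohort} containing unknown-sign trials.
#' @return data.frame: `participant_id`, `LC`, `SC`, `ratio`,
#'   `ratio_defined`, `above_mean`; the mean ratio is in
#'   `attr(, "meanRatio")`.
#' @export
lcscGrouping <- function(cohort) {
  keep <- cohort$responded & cohort$group %in% c("short", "long")
  if (!any(keep))
    stop("cohort has no responded unknown-sign trials")
  cs <- cases(cohort)[keep]
  pid <- cohort$participant_id[keep]
  ids <- unique(pid)
  lc <- vapply(ids, function(p) sum(cs == "LT" & pid == p), numeric(1))
  sc <- vapply(ids, function(p) sum(cs == "ST" & pid == p), numeric(1))
  ratio <- ifelse(sc > 0, lc / sc, NA_real_)
  meanRatio <- mean(ratio, na.rm = TRUE)
  out <- data.frame(participant_id = ids, LC = lc, SC = sc, ratio = ratio,
                    ratio_defined = sc > 0,
                    above_mean = !is.na(ratio) & ratio > meanRatio,
                    row.names = NULL)
  attr(out, "meanRatio") <- meanRatio
  out
}

setMethod("show", "BehavioralSummary", function(object) {
  cat("BehavioralSummary\n")
  cat("  counts:", paste(names(object@counts), object@counts, sep = "=",
                         collapse = " "), "\n")
  cat(sprintf("  p(credible | long)  = %.4f\n", object@proportionLong))
  cat(sprintf("  p(credible | short) = %.4f\n", object@proportionShort))
  cat("  length bias (long > short):", object@lengthBias, "\n")
  cat(sprintf("  binomial test: k=%.0f n=%.0f p0=%.2f -> p = %.3g\n",
              object@binomK, object@binomN, object@binomP0, object@pValue))
  invisible(NULL)
})
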