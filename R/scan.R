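## Exhaustive time-interval / region-subset enumeration.
##
## Candidate windows are half-open [a, a + len) on the 5 ms grid. For each
## window, regions are ranked by the mean absolute between-class difference
## of the interval-averaged sMEC feature (training trials only), the top Q
## regions are kept, and every non-empty subset of them is a candidate
## model -- sum(choose(Q, q), q = 1..Q) candidates per window, times the
## number of windows in total.

#' Construct a scan configuration
#'
#' @param epoch numeric(2) post-stimulus window in ms.
#' @param binMs grid resolution, ms.
#' @param lengths interval lengths (ms) to scan; each must be a positive
#'   multiple of `binMs` and at most the epoch span.
#' @param maxRegions Q, the per-interval region-ranking cut (default 5).
#' @return a \linkS4class{ScanConfig}.
#' @examples
#' scanConfig(lengths = c(25, 50))
#' @export
scanConfig <- function(epoch = c(0, 990), binMs = 5,
                       lengths = c(25, 50, 100), maxRegions = 5L) {
  new("ScanConfig", epoch = as.numeric(epoch), binMs = as.numeric(binMs),
      lengths = as.numeric(lengths), maxRegions = as.integer(maxRegions))
}

#' Enumerate candidate time windows
#'
#' All half-open windows `[a, a + len)` with `a` on the grid and
#' `a + len <= epoch end`, for each configured length:
#' `(span - len) / binMs + 1` windows per length. With the default 0-990 ms
#' epoch and 5 ms grid, length 25 ms yields 194 windows.
#'
#' @param config a \linkS4class{ScanConfig}.
#' @return data.frame with columns `start_ms`, `end_ms`, `length_ms`.
#' @export
enumerateIntervals <- function(config) {
  stopifnot(is(config, "ScanConfig"))
  validObject(config)
  out <- lapply(config@lengths, function(len) {
    a <- seq(config@epoch[1], config@epoch[2] - len, by = config@binMs)
    data.frame(start_ms = a, end_ms = a + len, length_ms = len)
  })
  do.call(rbind, out)
}

## interval features + class labels for one condition pair
pairLabels <- function(cohort) {
  cl <- caseChoice(cases(cohort))
  cl == "credible"
}

#' Rank regions by between-class sMEC separation
#'
#' For one window, computes `d(r) = |mean(feature | credible) -
#' mean(feature | not credible)|` per region on the supplied (training)
#' trials and returns the top `Q` regions in nonincreasing order, ties
#' broken lexicographically by region label.
#'
#' @param cohort a \linkS4class{CredCohort} of one condition pair's
#'   training trials, with an `"smec"` assay.
#' @param interval numeric(2) `[start, end)` in ms.
#' @param Q how many regions to keep.
#' @return a \linkS4class{RegionRanking}.
#' @export
rankRegions <- function(cohort, interval, Q = 5L) {
  feat <- intervalFeature(cohort, interval)
  rankRegionsFromFeatures(feat, pairLabels(cohort), interval, Q)
}

rankRegionsFromFeatures <- function(feat, positive, interval, Q) {
  if (!any(positive) || all(positive))
    stop("both classes must be present (missing: ",
         if (all(positive)) "not_credible" else "credible", ")")
  d <- abs(colMeans(feat[positive, , drop = FALSE]) -
           colMeans(feat[!positive, , drop = FALSE]))
  ord <- order(-d, colnames(feat))
  keep <- head(ord, Q)
  new("RegionRanking", interval = as.numeric(interval),
      regions = colnames(feat)[keep], scores = unname(d[keep]),
      classes = c("credible", "not_credible"))
}

#' Enumerate candidate models from a region ranking
#'
#' All non-empty subsets of the ranked regions:
#' `sum(choose(Q, q), q = 1..Q)` candidates (31 for Q = 5).
#'
#' @param ranking a \linkS4class{RegionRanking}.
#' @return list of \linkS4class{CandidateModelSpec}.
#' @export
enumerateCandidates <- function(ranking) {
  stopifnot(is(ranking, "RegionRanking"))
  regs <- ranking@regions
  if (!length(regs)) stop("empty ranking")
  out <- list()
  for (q in seq_along(regs)) {
    combos <- utils::combn(regs, q, simplify = FALSE)
    out <- c(out, lapply(combos, function(rr)
      new("CandidateModelSpec", interval = ranking@interval, regions = rr)))
  }
  out
}

## 0-based column-index subsets in ranking order, used by the scan engine
subsetIndices <- function(Q) {
  out <- list()
  for (q in seq_len(Q))
    out <- c(out, utils::combn(seq_len(Q) - 1L, q, simplify = FALSE))
  out
}

#' Combinatorial model counts
#'
#' Exact counts of candidate classifiers: per interval there are
#' `choose(R, Q)` unrestricted region subsets of size Q; over `I` intervals
#' the unrestricted total is `I * choose(R, Q)`; restricting each interval
#' to non-empty subsets of its top-Q ranked regions leaves
#' `I * sum(choose(Q, q), q = 1..Q)` models. With R = 88, Q = 5 and
#' I = 2261 these are 39,175,752, 88,576,375,272 and 70,091.
#'
#' @param R number of regions.
#' @param Q maximum regions per model.
#' @param I number of intervals (default 1).
#' @param limited if `TRUE`, count only subsets of the per-interval top-Q
#'   ranking; otherwise all size-Q subsets of all R regions.
#' @return a count (double holding an exact integer).
#' @examples
#' countModels(88, 5)                      # 39175752
#' countModels(88, 5, I = 2261, limited = TRUE)   # 70091
#' countModels(88, 5, I = 2261)            # 88576375272
#' @export
countModels <- function(R, Q, I = 1, limited = FALSE) {
  if (Q < 1 || R < Q || I < 1) stop("need R >= Q >= 1 and I >= 1")
  per <- if (limited) sum(choose(Q, seq_len(Q))) else choose(R, Q)
  total <- I * per
  if (total > 2^53) stop("count exceeds exact double-precision range")
  total
}

setMethod("show", "RegionRanking", function(object) {
  cat("RegionRanking for [", object@interval[1], ",", object@interval[2],
      ") ms:\n")
  print(data.frame(region = object@regions, score = object@scores))
  invisible(NULL)
})

setMethod("show", "CandidateModelSpec", function(object) {
  cat("CandidateModelSpec: [", object@interval[1], ",", object@interval[2],
      ") ms; regions:", paste(object@regions, collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "ScanConfig", function(object) {
  ivs <- enumerateIntervals(object)
  cat("ScanConfig: epoch [", object@epoch[1], ",", object@epoch[2],
      ") ms, step", object@binMs, "ms, lengths",
      paste(object@lengths, collapse = "/"), "ms ->", nrow(ivs),
      "intervals; Q =", object@maxRegions, "\n")
  invisible(NULL)
})
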