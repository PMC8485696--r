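## MEC / sMEC feature computation.
##
## MEC: charge per 5 ms bin = current x bin width (rectangle rule on the
## grid the data are delivered on). sMEC: MEC min-max scaled to [0,1]
## separately for every (participant, region), pooling that participant's
## responded trials and all bins, so that a participant-level gain change
## cancels exactly. Interval features are means of per-bin sMEC over a
## grid-aligned half-open window, one value per (trial, region) -- means,
## not sums, so features from windows of different lengths are comparable
## during the scan.

#' @rdname computeMEC
#' @param binMs bin width in ms.
#' @export
setMethod("computeMEC", "matrix", function(x, binMs = 5) {
  if (length(x) && min(x) < 0)
    stop("currents must be nonnegative (magnitudes expected upstream)")
  x * binMs
})

#' @rdname computeMEC
#' @export
setMethod("computeMEC", "CredCohort", function(x, binMs = NULL) {
  if (is.null(binMs)) binMs <- metadata(x)$config@binMs
  assay(x, "mec") <- computeMEC(assay(x, "current"), binMs = binMs)
  x
})

#' @rdname normalizeSMEC
#' @export
setMethod("normalizeSMEC", "CredCohort", function(x) {
  if (!"mec" %in% assayNames(x)) x <- computeMEC(x)
  m <- assay(x, "mec")
  out <- m
  nb <- length(binStarts(x))
  regs <- regions(x)
  pid <- x$participant_id
  resp <- x$responded
  for (p in unique(pid)) {
    colsAll <- which(pid == p)
    colsPool <- which(pid == p & resp)
    if (!length(colsPool))
      stop("participant ", p, " has no responded trials to normalize over")
    for (r in seq_along(regs)) {
      rows <- ((r - 1L) * nb + 1L):(r * nb)
      blockPool <- m[rows, colsPool, drop = FALSE]
      lo <- min(blockPool)
      hi <- max(blockPool)
      if (hi > lo) {
        out[rows, colsAll] <- (m[rows, colsAll, drop = FALSE] - lo) / (hi - lo)
      } else {
        out[rows, colsAll] <- 0
      }
    }
  }
  ## non-responded trials may fall outside [0,1] of the responded pool;
  ## they are excluded downstream, but keep the assay bounded
  out[out < 0] <- 0
  out[out > 1] <- 1
  assay(x, "smec") <- out
  x
})

#' @rdname normalizeSMEC
#' @export
setMethod("normalizeSMEC", "matrix", function(x) {
  lo <- min(x)
  hi <- max(x)
  if (hi > lo) (x - lo) / (hi - lo) else x * 0
})

checkInterval <- function(interval, epoch, binMs) {
  if (length(interval) != 2L || diff(interval) <= 0)
    stop("interval must be [start, end) in ms with end > start")
  if (any((interval - epoch[1]) %% binMs != 0))
    stop("interval [", interval[1], ", ", interval[2],
         ") is not aligned to the ", binMs, " ms grid starting at ",
         epoch[1], " ms")
  if (interval[1] < epoch[1] || interval[2] > epoch[2])
    stop("interval [", interval[1], ", ", interval[2],
         ") lies outside the epoch [", epoch[1], ", ", epoch[2], ")")
}

#' @rdname intervalFeature
#' @param assayName which assay to average (default `"smec"`).
#' @export
setMethod("intervalFeature", "CredCohort",
          function(x, interval, assayName = "smec") {
  cfg <- metadata(x)$config
  checkInterval(interval, cfg@epoch, cfg@binMs)
  m <- assay(x, assayName)
  nb <- length(binStarts(x))
  bs <- binStarts(x)
  sel <- which(bs >= interval[1] & bs < interval[2])
  regs <- regions(x)
  out <- matrix(0, ncol(x), length(regs),
                dimnames = list(colnames(x), regs))
  for (r in seq_along(regs)) {
    rows <- (r - 1L) * nb + sel
    out[, r] <- colMeans(m[rows, , drop = FALSE])
  }
  out
})

## Precomputed cumulative sums over bins, for fast repeated interval
## averaging during the scan: element [b+1, trial, region-slot] holds the
## sum of the first b bins.
smecCumsum <- function(cohort) {
  m <- smec(cohort)
  nb <- length(binStarts(cohort))
  regs <- regions(cohort)
  lapply(seq_along(regs), function(r) {
    rows <- ((r - 1L) * nb + 1L):(r * nb)
    rbind(0, apply(m[rows, , drop = FALSE], 2, cumsum))
  }) |> stats::setNames(regs)
}

## trials x regions feature matrix for bins (b1+1):b2 (1-based, inclusive)
featureFromCumsum <- function(cums, b1, b2) {
  k <- b2 - b1
  vapply(cums, function(cs) (cs[b2 + 1L, ] - cs[b1 + 1L, ]) / k,
         numeric(ncol(cums[[1L]])))
}
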