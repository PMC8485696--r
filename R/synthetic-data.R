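## Synthetic cohort generation.
##
## The generator reproduces the structure of the credibility experiment:
## each participant sees three groups of trials (known-sign short notes,
## unknown-sign short notes, unknown-sign long notes), choices for known
## signs are always correct (cases TT/FF only), choices for unknown signs
## are Bernoulli draws at the configured long/short credibility rates, and
## per-trial cortical currents are a participant-scaled rectified
## autocorrelated noise process plus planted class-dependent bumps.

#' Default 88-region parcellation labels
#'
#' Left and right Brodmann-area labels (BA 1-41, 44 and 46 per hemisphere)
#' plus left and right hippocampus: 88 regions in total, matching the size
#' of the source-montage parcellation the pipeline assumes.
#'
#' @return character vector of length 88.
#' @export
defaultRegions <- function() {
  ba <- c(1:41, 44, 46)
  c(sprintf("L.BA.%02d", ba), sprintf("R.BA.%02d", ba),
    "L.Hippocampus", "R.Hippocampus")
}

#' Construct a planted effect
#'
#' @param casePair character(2): the condition pair, e.g. `c("LT","LF")`.
#' @param regions region labels carrying the effect.
#' @param window numeric(2) `[start, end)` in ms.
#' @param amplitude peak bump height in baseline-noise-SD units.
#' @param elevated which case of the pair is elevated (default the first).
#' @return a \linkS4class{PlantedEffect}.
#' @examples
#' plantedEffect(c("LT", "LF"), c("L.BA.31", "L.BA.09"), c(830, 855), 1.5)
#' @export
plantedEffect <- function(casePair, regions, window, amplitude,
                          elevated = casePair[1]) {
  new("PlantedEffect", casePair = as.character(casePair),
      regions = as.character(regions), window = as.numeric(window),
      amplitude = as.numeric(amplitude), elevated = as.character(elevated))
}

defaultPlantedEffects <- function(regions) {
  eff <- list(
    plantedEffect(c("ST", "SF"), c("R.BA.46", "R.BA.04"), c(105, 330), 1.5),
    plantedEffect(c("TT", "FF"), c("R.BA.39", "L.BA.37"), c(330, 530), 1.5),
    plantedEffect(c("LT", "LF"), c("L.BA.31", "L.BA.09"), c(830, 855), 1.5))
  Filter(function(e) all(e@regions %in% regions), eff)
}

#' Construct a cohort configuration
#'
#' Defaults encode the experiment's published structure: 105 completing
#' participants, 240 trials each in three groups of 80, an epoch of 0-990 ms
#' at 5 ms bins over 88 regions, no-knowledge credibility rates 0.536 (long
#' notes) and 0.409 (short notes), and per-condition completion counts
#' 105/104/95. Planted effects default to bumps in the windows the search
#' is expected to find (105-330, 330-530, 830-855 ms).
#'
#' The baseline current is a rectified AR(1) Gaussian process
#' `gain * max(0, baselineLevel + noiseSd * z_t + bumps)` with lag-one
#' correlation `noiseAr` and unit-marginal-SD `z_t`; participant gains are
#' uniform on `gainRange`, motivating the per-participant sMEC
#' normalization.
#'
#' @param nParticipants number of participants enrolled.
#' @param trialsPerGroup trials per condition group (even; the known group
#'   splits into half true, half false translations).
#' @param regions region labels (default \code{\link{defaultRegions}}).
#' @param epoch numeric(2) post-stimulus window in ms.
#' @param binMs bin width in ms.
#' @param pCredibleLong,pCredibleShort probability that an unknown-sign
#'   long/short note is judged credible.
#' @param attrition named completion counts for the known/short/long
#'   condition pairs; participants beyond the count lack that group.
#' @param gainRange per-participant multiplicative signal scale range.
#' @param baselineLevel,noiseSd,noiseAr baseline noise process parameters.
#' @param nonResponseRate per-trial probability of no response within the
#'   3.5 s limit (non-responding trials are excluded downstream).
#' @param plantedEffects list of \linkS4class{PlantedEffect}; `NULL` for the
#'   defaults above, `list()` for an effect-free cohort.
#' @return a validated \linkS4class{CohortConfig}.
#' @examples
#' cfg <- cohortConfig(nParticipants = 4, trialsPerGroup = 6,
#'                     regions = sprintf("R%02d", 1:5), plantedEffects = list())
#' @export
cohortConfig <- function(nParticipants = 105L, trialsPerGroup = 80L,
                         regions = defaultRegions(), epoch = c(0, 990),
                         binMs = 5,
                         pCredibleLong = 0.536, pCredibleShort = 0.409,
                         attrition = c(known = nParticipants,
                                       short = nParticipants,
                                       long = nParticipants),
                         gainRange = c(0.5, 2),
                         baselineLevel = 1, noiseSd = 0.3, noiseAr = 0.8,
                         nonResponseRate = 0, plantedEffects = NULL) {
  if (missing(attrition) && nParticipants == 105L)
    attrition <- c(known = 105L, short = 104L, long = 95L)
  if (is.null(names(attrition))) names(attrition) <- GROUP_LEVELS
  if (is.null(plantedEffects))
    plantedEffects <- defaultPlantedEffects(regions)
  new("CohortConfig",
      nParticipants = as.integer(nParticipants),
      trialsPerGroup = as.integer(trialsPerGroup),
      regions = as.character(regions), epoch = as.numeric(epoch),
      binMs = as.numeric(binMs),
      pCredibleLong = pCredibleLong, pCredibleShort = pCredibleShort,
      attrition = stats::setNames(as.integer(attrition[GROUP_LEVELS]),
                                  GROUP_LEVELS),
      gainRange = as.numeric(gainRange), baselineLevel = baselineLevel,
      noiseSd = noiseSd, noiseAr = noiseAr,
      nonResponseRate = nonResponseRate, plantedEffects = plantedEffects)
}

nBins <- function(config) as.integer(diff(config@epoch) / config@binMs)

binStartsOf <- function(config) {
  seq(config@epoch[1], config@epoch[2] - config@binMs, by = config@binMs)
}

## Gaussian-in-time bump profiles, one row per region, summed over the
## effects applicable to a given case.
effectProfile <- function(effects, case, config) {
  nb <- nBins(config)
  prof <- matrix(0, length(config@regions), nb,
                 dimnames = list(config@regions, NULL))
  tc <- binStartsOf(config) + config@binMs / 2
  for (e in effects) {
    if (!identical(e@elevated, case)) next
    mid <- mean(e@window)
    sdt <- diff(e@window) / 4
    bump <- e@amplitude * config@noiseSd *
      exp(-(tc - mid)^2 / (2 * sdt^2)) *
      (tc >= e@window[1] & tc < e@window[2])
    prof[e@regions, ] <- sweep(prof[e@regions, , drop = FALSE], 2, bump, `+`)
  }
  prof
}

## AR(1) latent noise with unit marginal SD, for `nser` parallel series of
## `nb` bins, drawn from the current RNG stream.
arNoise <- function(nser, nb, phi) {
  z <- matrix(rnorm(nser * nb), nser, nb)
  if (phi > 0 && nb > 1L) {
    s <- sqrt(1 - phi^2)
    for (t in 2:nb) z[, t] <- phi * z[, t - 1L] + s * z[, t]
  }
  z
}

#' Simulate the current matrix for one trial
#'
#' `currents = gain * max(0, baseline + noiseSd * z + bumps)` where `z` is
#' an AR(1) Gaussian process with unit marginal SD and `bumps` sums the
#' planted effects whose elevated case matches the trial's case. Draws from
#' the current RNG stream; seed via `set.seed()` (or use
#' \code{\link{generateCohort}}, which manages seeding).
#'
#' @param participantGain positive multiplicative scale.
#' @param effects list of \linkS4class{PlantedEffect}.
#' @param case the trial's case label (e.g. "LT").
#' @param config a \linkS4class{CohortConfig}.
#' @return regions x bins matrix of nonnegative currents.
#' @export
generateTrialCurrents <- function(participantGain, effects, case, config) {
  if (!is.numeric(participantGain) || participantGain <= 0)
    stop("participantGain must be a positive scalar")
  for (e in effects) {
    if (e@window[1] < config@epoch[1] || e@window[2] > config@epoch[2])
      stop("effect window [", e@window[1], ", ", e@window[2],
           ") lies outside the epoch")
  }
  nr <- length(config@regions)
  nb <- nBins(config)
  z <- arNoise(nr, nb, config@noiseAr)
  cur <- participantGain *
    pmax(config@baselineLevel + config@noiseSd * z +
           effectProfile(effects, case, config), 0)
  dimnames(cur) <- list(config@regions, NULL)
  cur
}

## Evaluate an expression under a given seed without leaking RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic cohort
#'
#' Produces a \linkS4class{CredCohort} with the configured trial structure:
#' per completing participant, `trialsPerGroup` trials in each requested
#' group; the known group splits exactly half/half into true (TT) and false
#' (FF) translations with deterministically correct choices; unknown-sign
#' choices are Bernoulli at the configured rates. Attrition drops whole
#' condition groups for participants beyond the per-condition completion
#' counts. Fully reproducible from `(config, seed)`.
#'
#' @param config a \linkS4class{CohortConfig}.
#' @param seed integer seed; all randomness flows through it.
#' @param groups which condition groups to generate (subset of
#'   `c("known", "short", "long")`); restricting groups saves memory when
#'   only one classification pair is analysed.
#' @return a \linkS4class{CredCohort}.
#' @examples
#' cfg <- cohortConfig(nParticipants = 3, trialsPerGroup = 4,
#'                     regions = sprintf("R%02d", 1:4), epoch = c(0, 100),
#'                     plantedEffects = list())
#' coh <- generateCohort(cfg, seed = 1)
#' table(cases(coh))
#' @export
generateCohort <- function(config, seed, groups = GROUP_LEVELS) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  groups <- match.arg(groups, GROUP_LEVELS, several.ok = TRUE)
  withSeed(seed, {
    tpg <- config@trialsPerGroup
    nr <- length(config@regions)
    nb <- nBins(config)
    gains <- runif(config@nParticipants, config@gainRange[1],
                   config@gainRange[2])
    meta <- list()
    mats <- list()
    for (p in seq_len(config@nParticipants)) {
      pid <- sprintf("P%03d", p)
      for (g in groups) {
        if (p > config@attrition[[g]]) next
        case <- switch(g,
          known = sample(rep(c("TT", "FF"), each = tpg / 2L)),
          short = ifelse(rbinom(tpg, 1L, config@pCredibleShort) == 1L,
                         "ST", "SF"),
          long  = ifelse(rbinom(tpg, 1L, config@pCredibleLong) == 1L,
                         "LT", "LF"))
        responded <- rbinom(tpg, 1L, 1 - config@nonResponseRate) == 1L
        ## batched noise for the participant-group block, then per-trial
        ## effect profiles added case by case
        z <- arNoise(nr * tpg, nb, config@noiseAr)
        block <- matrix(0, nr * nb, tpg)
        prof <- lapply(unique(case), function(cs)
          effectProfile(config@plantedEffects, cs, config))
        names(prof) <- unique(case)
        for (k in seq_len(tpg)) {
          zk <- z[((k - 1L) * nr + 1L):(k * nr), , drop = FALSE]
          cur <- gains[p] * pmax(config@baselineLevel +
                                   config@noiseSd * zk + prof[[case[k]]], 0)
          block[, k] <- as.vector(t(cur))  # region-major rows
        }
        meta[[length(meta) + 1L]] <- data.frame(
          participant_id = pid,
          trial_id = sprintf("%s_%s_%02d", pid, g, seq_len(tpg)),
          group = g, case = case, choice = caseChoice(case),
          responded = responded, stringsAsFactors = FALSE)
        mats[[length(mats) + 1L]] <- block
      }
    }
    cd <- do.call(rbind, meta)
    mat <- do.call(cbind, mats)
    newCredCohort(mat, cd, config, seed)
  })
}

newCredCohort <- function(currentMat, colMeta, config, seed = NA_integer_) {
  nb <- nBins(config)
  rd <- S4Vectors::DataFrame(
    region = rep(config@regions, each = nb),
    bin_start_ms = rep(binStartsOf(config), length(config@regions)))
  rownames(currentMat) <- paste0(rd$region, "@", rd$bin_start_ms)
  colnames(currentMat) <- colMeta$trial_id
  se <- SummarizedExperiment(
    assays = list(current = currentMat),
    rowData = rd, colData = S4Vectors::DataFrame(colMeta, row.names = colMeta$trial_id),
    metadata = list(config = config, seed = seed))
  new("CredCohort", se)
}

#' Subset a cohort to one condition pair's responded trials
#'
#' @param cohort a \linkS4class{CredCohort}.
#' @param group `"known"`, `"short"` or `"long"`.
#' @return the cohort restricted to responded trials of that pair.
#' @export
subsetPair <- function(cohort, group) {
  group <- match.arg(group, GROUP_LEVELS)
  keep <- cohort$group == group & cohort$responded
  cohort[, keep]
}

## ---- accessors and show -------------------------------------------------

#' @rdname cohort-accessors
setMethod("currents", "CredCohort", function(x) assay(x, "current"))

#' @rdname cohort-accessors
setMethod("mec", "CredCohort", function(x) {
  if (!"mec" %in% assayNames(x))
    stop("no 'mec' assay; run computeMEC() first")
  assay(x, "mec")
})

#' @rdname cohort-accessors
setMethod("smec", "CredCohort", function(x) {
  if (!"smec" %in% assayNames(x))
    stop("no 'smec' assay; run normalizeSMEC() first")
  assay(x, "smec")
})

#' @rdname cohort-accessors
setMethod("regions", "CredCohort",
          function(x) unique(rowData(x)$region))

#' @rdname cohort-accessors
setMethod("binStarts", "CredCohort",
          function(x) unique(rowData(x)$bin_start_ms))

#' @rdname cohort-accessors
setMethod("participants", "CredCohort",
          function(x) unique(x$participant_id))

#' @rdname cohort-accessors
setMethod("cases", "CredCohort", function(x) x$case)

#' @rdname cohort-accessors
setMethod("choices", "CredCohort", function(x) x$choice)

setMethod("show", "CredCohort", function(object) {
  cat("CredCohort:", length(participants(object)), "participants,",
      ncol(object), "trials,", length(regions(object)), "regions x",
      length(binStarts(object)), "bins\n")
  cat("assays:", paste(assayNames(object), collapse = ", "), "\n")
  print(table(cases(object)))
  invisible(NULL)
})

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig:", object@nParticipants, "participants, 3 x",
      object@trialsPerGroup, "trials,", length(object@regions),
      "regions, epoch [", object@epoch[1], ",", object@epoch[2],
      ") ms at", object@binMs, "ms bins\n")
  cat("  p(credible | long) =", object@pCredibleLong,
      " p(credible | short) =", object@pCredibleShort, "\n")
  cat("  attrition:", paste(names(object@attrition), object@attrition,
                            sep = "=", collapse = " "), "\n")
  cat(" ", length(object@plantedEffects), "planted effect(s)\n")
  invisible(NULL)
})

## ---- cohort I/O ---------------------------------------------------------

cohortColumns <- c("participant_id", "trial_id", "group", "case", "choice",
                   "responded", "region", "bin_start_ms", "current")

#' Write / read a cohort as a columnar file
#'
#' Long-format table with one row per (trial, region, bin):
#' `participant_id, trial_id, group, case, choice, responded, region,
#' bin_start_ms, current`. A sidecar `<path>.meta.json` records the grid
#' (regions, epoch, bin width) and the generating seed so that the round
#' trip is lossless, including for empty cohorts. `format = "parquet"`
#' writes the same schema through the arrow package when it is installed.
#'
#' @param cohort a \linkS4class{CredCohort}.
#' @param path output file.
#' @param format `"csv"` (default) or `"parquet"`.
#' @return `writeCohort` returns `path` invisibly; `readCohort` returns the
#'   reconstructed \linkS4class{CredCohort}.
#' @export
writeCohort <- function(cohort, path, format = c("csv", "parquet")) {
  format <- match.arg(format)
  stopifnot(is(cohort, "CredCohort"))
  cd <- as.data.frame(colData(cohort))
  rd <- as.data.frame(rowData(cohort))
  nrb <- nrow(cohort)
  long <- data.frame(
    participant_id = rep(cd$participant_id, each = nrb),
    trial_id = rep(cd$trial_id, each = nrb),
    group = rep(cd$group, each = nrb),
    case = rep(cd$case, each = nrb),
    choice = rep(cd$choice, each = nrb),
    responded = rep(cd$responded, each = nrb),
    region = rep(rd$region, times = ncol(cohort)),
    bin_start_ms = rep(rd$bin_start_ms, times = ncol(cohort)),
    current = as.vector(currents(cohort)))
  if (format == "csv") {
    utils::write.csv(long, path, row.names = FALSE)
  } else {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("format = 'parquet' needs the arrow package")
    arrow::write_parquet(long, path)
  }
  cfg <- metadata(cohort)$config
  meta <- list(schema_version = 1L, seed = metadata(cohort)$seed,
               regions = cfg@regions, epoch = cfg@epoch, binMs = cfg@binMs)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path, format = c("csv", "parquet")) {
  format <- match.arg(format)
  long <- if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("format = 'parquet' needs the arrow package")
    as.data.frame(arrow::read_parquet(path))
  }
  miss <- setdiff(cohortColumns, colnames(long))
  if (length(miss))
    stop("cohort file lacks required column(s): ",
         paste(miss, collapse = ", "))
  metaPath <- paste0(path, ".meta.json")
  meta <- if (file.exists(metaPath)) jsonlite::read_json(metaPath) else NULL
  if (!is.null(meta)) {
    regions <- unlist(meta$regions)
    epoch <- unlist(meta$epoch)
    binMs <- meta$binMs
    seed <- if (is.null(meta$seed) || is.na(meta$seed)) NA_integer_
            else as.integer(meta$seed)
  } else {
    regions <- unique(long$region)
    binMs <- if (nrow(long)) min(diff(sort(unique(long$bin_start_ms)))) else 5
    epoch <- if (nrow(long)) c(min(long$bin_start_ms),
                               max(long$bin_start_ms) + binMs) else c(0, 0)
    seed <- NA_integer_
  }
  cfg <- cohortConfig(nParticipants = max(1L, length(unique(long$participant_id))),
                      trialsPerGroup = 2L, regions = regions, epoch = epoch,
                      binMs = binMs, plantedEffects = list())
  nb <- nBins(cfg)
  trialIds <- unique(long$trial_id)
  mat <- matrix(0, length(regions) * nb, length(trialIds))
  if (nrow(long)) {
    ri <- match(long$region, regions)
    bi <- match(long$bin_start_ms, binStartsOf(cfg))
    ci <- match(long$trial_id, trialIds)
    if (anyNA(ri) || anyNA(bi))
      stop("cohort file contains regions or bins not on the declared grid")
    mat[cbind((ri - 1L) * nb + bi, ci)] <- long$current
  }
  first <- long[!duplicated(long$trial_id),
                c("participant_id", "trial_id", "group", "case", "choice",
                  "responded")]
  newCredCohort(mat, first, cfg, seed)
}
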