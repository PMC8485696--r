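#' Mean electric charge per bin
#'
#' Charge per bin is `current * binMs` (rectangle rule on the grid the
#' data are delivered on). For a \linkS4class{CredCohort} the result is
#' stored as the `"mec"` assay; for a plain regions x bins matrix the
#' charge matrix is returned.
#'
#' @param x a \linkS4class{CredCohort} or a nonnegative matrix of currents.
#' @param ... passed to methods (`binMs`: bin width in ms, taken from the
#'   cohort config when `x` is a cohort).
#' @return the augmented cohort, or the charge matrix.
#' @examples
#' computeMEC(matrix(2, 3, 4), binMs = 5)  # all entries 10
#' @export
setGeneric("computeMEC", function(x, ...) standardGeneric("computeMEC"))

#' Normalize MEC to sMEC
#'
#' Within each (participant, region), maps `v -> (v - min) / (max - min)`
#' over all of that participant's responded trials and all bins, so every
#' (participant, region) block spans [0, 1] exactly (degenerate constant
#' blocks map to 0). This removes participant-specific signal scale, the
#' consequence of individual differences in signal-to-noise ratio; a
#' positive gain applied to a participant's MEC leaves their sMEC
#' unchanged.
#'
#' @param x a \linkS4class{CredCohort} with a `"mec"` assay (computed on
#'   the fly if absent), or a plain matrix (normalized over all entries).
#' @param ... unused.
#' @return the cohort with an added `"smec"` assay.
#' @export
setGeneric("normalizeSMEC", function(x, ...) standardGeneric("normalizeSMEC"))

#' Interval-averaged sMEC features
#'
#' Mean of per-bin sMEC over a grid-aligned half-open window
#' `[start, end)`, one value per (trial, region). The mean (not the sum)
#' keeps features comparable across windows of different lengths during
#' the scan.
#'
#' @param x a \linkS4class{CredCohort} with an `"smec"` assay.
#' @param interval numeric(2) `[start_ms, end_ms)`.
#' @param ... passed to methods (`assayName`: which assay to average,
#'   default `"smec"`).
#' @return trials x regions matrix of features.
#' @export
setGeneric("intervalFeature",
           function(x, interval, ...) standardGeneric("intervalFeature"))

#' Accessors for cohort assays and annotation
#'
#' `currents()`, `mec()` and `smec()` return the corresponding assay as a
#' (region x bin) by trial matrix; `regions()` and `binStarts()` return the
#' row grid; `participants()`, `cases()` and `choices()` the per-trial
#' annotation.
#'
#' @param x a \linkS4class{CredCohort}.
#' @return matrices or vectors as described.
#' @name cohort-accessors
#' @aliases currents mec smec regions binStarts participants cases choices
#' @export
setGeneric("currents", function(x) standardGeneric("currents"))

#' @rdname cohort-accessors
#' @export
setGeneric("mec", function(x) standardGeneric("mec"))

#' @rdname cohort-accessors
#' @export
setGeneric("smec", function(x) standardGeneric("smec"))

#' @rdname cohort-accessors
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))

#' @rdname cohort-accessors
#' @export
setGeneric("binStarts", function(x) standardGeneric("binStarts"))

#' @rdname cohort-accessors
#' @export
setGeneric("participants", function(x) standardGeneric("participants"))

#' @rdname cohort-accessors
#' @export
setGeneric("cases", function(x) standardGeneric("cases"))

#' @rdname cohort-accessors
#' @export
setGeneric("choices", function(x) standardGeneric("choices"))
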