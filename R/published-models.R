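## Published best-model fixtures: the reported interval, region set and
## (where printed) logistic coefficients for each classification pair,
## shipped as a JSON fixture. Reference metrics are the scores reported on
## the original (non-public) cohort; they are carried as metadata for
## comparison layouts and are never asserted against synthetic runs.

publishedModelsPath <- function() {
  system.file("extdata", "published_models.json", package = "credscan",
              mustWork = TRUE)
}

loadPublishedModels <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- jsonlite::read_json(publishedModelsPath())
    cache
  }
})

#' Names of the published best models
#' @return character vector: `ST_SF`, `TT_FF`, `LT_LF`,
#'   `LT_LF_long_preferred`.
#' @export
publishedModelNames <- function() names(loadPublishedModels()$models)

#' Retrieve a published best model
#'
#' Returns the reported interval, region set and coefficients for the
#' named classification pair. Coefficients were printed for `ST_SF`,
#' `TT_FF` and `LT_LF`; the long-note-preferred model (`LT_LF_long_preferred`)
#' was reported with regions only, so its `model` element is NULL.
#'
#' @param name one of \code{\link{publishedModelNames}()}.
#' @return list: `name`, `description`, `spec`
#'   (\linkS4class{CandidateModelSpec}), `model`
#'   (\linkS4class{FittedCredModel} or NULL), `reference` (named reported
#'   metrics, metadata only).
#' @examples
#' pm <- publishedModel("ST_SF")
#' pm$spec
#' @export
publishedModel <- function(name) {
  db <- loadPublishedModels()$models
  if (!name %in% names(db))
    stop("unknown published model '", name, "'; available: ",
         paste(names(db), collapse = ", "))
  e <- db[[name]]
  coefs <- unlist(e$coefficients)
  regionsUsed <- if (!is.null(coefs)) setdiff(names(coefs), "(Intercept)")
                 else unlist(e$regions)
  spec <- new("CandidateModelSpec",
              interval = as.numeric(unlist(e$interval_ms)),
              regions = regionsUsed)
  model <- NULL
  if (!is.null(coefs)) {
    model <- new("FittedCredModel", spec = spec,
                 coefficients = coefs[c("(Intercept)", regionsUsed)],
                 converged = TRUE, ridged = FALSE,
                 positiveClass = "credible")
  }
  list(name = name, description = e$description, spec = spec,
       model = model, reference = unlist(e$reference_metrics))
}

#' Apply a published model to a feature vector
#'
#' Pure function: `plogis(intercept + sum(coef * feature))` over the
#' model's regions. Features are interval-averaged sMEC values in [0, 1].
#'
#' @param name a published model name (must have printed coefficients).
#' @param features named numeric vector (or single-row matrix) covering
#'   the model's regions.
#' @return predicted probability that the note is judged credible.
#' @examples
#' f <- setNames(numeric(5),
#'               c("R.BA.46", "R.BA.04", "R.BA.36", "L.BA.33", "L.BA.02"))
#' applyPublishedModel("ST_SF", f)  # plogis(-3.23286)
#' @export
applyPublishedModel <- function(name, features) {
  pm <- publishedModel(name)
  if (is.null(pm$model))
    stop("model '", name, "' was published without coefficients")
  if (is.matrix(features)) features <- drop(features)
  miss <- setdiff(pm$spec@regions, names(features))
  if (length(miss))
    stop("missing feature(s): ", paste(miss, collapse = ", "))
  v <- as.numeric(features[pm$spec@regions])
  if (any(v < 0 | v > 1))
    stop("sMEC features must lie in [0, 1]")
  unname(stats::plogis(pm$model@coefficients[1] +
                         sum(pm$model@coefficients[-1] * v)))
}
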