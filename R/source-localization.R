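## Standardized minimum-norm (sLORETA-style) inverse on toy geometry.
##
## The estimate is the Tikhonov-regularized minimum-norm solution on the
## average-referenced sensor space, standardized per dipole by the diagonal
## of the resolution operator. For a single active dipole and alpha -> 0 on
## a full-rank system the standardized power peaks exactly at the true
## dipole (the classical zero-localization-error property), which the test
## suite verifies by construction.

#' Build a deterministic, well-conditioned toy lead field
#'
#' Columns are random directions made near-orthogonal by QR when
#' `nDipoles <= nChannels` (otherwise unit-norm random columns); rows are
#' average-referenced, as EEG gain matrices are.
#'
#' @param nChannels number of sensors (>= 2).
#' @param nDipoles number of sources (>= 1).
#' @param seed integer seed; the construction is deterministic in it.
#' @return a \linkS4class{LeadField}.
#' @examples
#' lf <- buildToyLeadField(8, 12, seed = 1)
#' @export
buildToyLeadField <- function(nChannels, nDipoles, seed = 1L) {
  if (nChannels < 2L) stop("nChannels must be >= 2")
  if (nDipoles < 1L) stop("nDipoles must be >= 1")
  withSeed(seed, {
    G <- matrix(rnorm(nChannels * nDipoles), nChannels, nDipoles)
    if (nDipoles <= nChannels) {
      G <- qr.Q(qr(G))[, seq_len(nDipoles), drop = FALSE]
    } else {
      G <- sweep(G, 2, sqrt(colSums(G^2)), `/`)
    }
    G <- sweep(G, 2, colMeans(G))        # average reference rows
    zero <- colSums(G^2) < 1e-12
    if (any(zero))
      stop("degenerate construction: all-zero dipole column; change seed")
    new("LeadField", gain = G,
        channels = sprintf("E%03d", seq_len(nChannels)),
        dipoles = sprintf("D%03d", seq_len(nDipoles)))
  })
}

## Moore-Penrose pseudo-inverse via SVD (tolerance relative to the largest
## singular value).
pinvMat <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Standardized minimum-norm inverse solution
#'
#' Computes the minimum-norm estimate with Tikhonov regularization on the
#' average-referenced sensor space,
#' `T = K' (K K' + alpha H)^+` with `H = I - 11'/m` the average-reference
#' projector and `K` the centered gain, then standardizes each dipole's
#' time course by the square root of the corresponding diagonal entry of
#' the resolution operator `T K`. The returned activity is the
#' standardized current magnitude (absolute value) per dipole and bin.
#'
#' @param erp channels x bins matrix of scalp potentials.
#' @param leadfield a \linkS4class{LeadField} with matching channel count.
#' @param alpha nonnegative regularization; `NULL` (default) uses
#'   `1e-6 * mean(eigenvalues of the sensor covariance)`, a scale-free
#'   choice; `alpha = 0` uses the pseudo-inverse and requires an
#'   adequately conditioned system.
#' @return a \linkS4class{SourceEstimate}.
#' @examples
#' lf <- buildToyLeadField(8, 12, seed = 2)
#' y <- lf@gain[, 3] %o% sin(seq(0, pi, length.out = 20))
#' est <- sloretaInverse(y, lf, alpha = 0)
#' which.max(rowSums(est@activity^2))  # localizes dipole 3
#' @export
sloretaInverse <- function(erp, leadfield, alpha = NULL) {
  stopifnot(is(leadfield, "LeadField"))
  erp <- as.matrix(erp)
  if (!all(is.finite(erp))) stop("ERP must be finite")
  m <- nrow(leadfield@gain)
  if (nrow(erp) != m)
    stop("ERP has ", nrow(erp), " channels but the lead field has ", m)
  H <- diag(m) - matrix(1 / m, m, m)
  K <- H %*% leadfield@gain
  Y <- H %*% erp
  C <- K %*% t(K)
  if (is.null(alpha)) {
    alpha <- 1e-6 * mean(diag(C))
  }
  if (alpha < 0) stop("alpha must be >= 0")
  M <- C + alpha * H
  Minv <- pinvMat(M)
  if (alpha == 0) {
    ## advise regularization when the sensor-space system is rank-deficient
    s <- svd(M, nu = 0, nv = 0)$d
    if (sum(s > 1e-10 * max(s)) < min(m - 1L, ncol(K)))
      stop("sensor-space operator is rank-deficient at alpha = 0; ",
           "use alpha > 0")
  }
  Tw <- t(K) %*% Minv                       # minimum-norm inverse operator
  S <- Tw %*% Y                             # signed estimate
  resDiag <- rowSums(Tw * t(K))             # diag(T K)
  scale <- sqrt(pmax(resDiag, 0))
  ok <- scale > 1e-12
  Sstd <- S
  Sstd[ok, ] <- S[ok, , drop = FALSE] / scale[ok]
  Sstd[!ok, ] <- 0
  act <- abs(Sstd)
  rownames(act) <- leadfield@dipoles
  new("SourceEstimate", activity = act, alpha = alpha)
}

#' Aggregate a source estimate to region-by-bin currents
#'
#' Region value per bin is the mean of the standardized magnitudes of the
#' region's dipoles.
#'
#' @param src a \linkS4class{SourceEstimate}.
#' @param parcellation named character vector mapping every dipole label to
#'   a region label.
#' @return regions x bins matrix.
#' @export
parcellate <- function(src, parcellation) {
  stopifnot(is(src, "SourceEstimate"))
  dip <- rownames(src@activity)
  unmapped <- setdiff(dip, names(parcellation))
  if (length(unmapped))
    stop("unmapped dipole(s): ", paste(unmapped, collapse = ", "))
  reg <- parcellation[dip]
  out <- rowsum(src@activity, group = reg) /
    as.vector(table(reg)[sort(unique(reg))])
  out[sort(unique(reg)), , drop = FALSE]
}

setMethod("show", "LeadField", function(object) {
  cat("LeadField:", nrow(object@gain), "channels x", ncol(object@gain),
      "dipoles (average-referenced)\n")
  invisible(NULL)
})

setMethod("show", "SourceEstimate", function(object) {
  cat("SourceEstimate:", nrow(object@activity), "dipoles x",
      ncol(object@activity), "bins, alpha =",
      format(object@alpha, digits = 3), "\n")
  invisible(NULL)
})
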