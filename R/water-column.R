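#' Log-radiance moments for a band pair
#'
#' Sample variances and covariance (n-1 convention) of
#' \eqn{\ln(L_i - L_{si})} and \eqn{\ln(L_j - L_{sj})} over a calibration
#' set of pixels.  The calibration mask must select pixels of a uniform
#' bottom type spanning a range of depths — then the log radiances are
#' linear in depth and the moments identify the attenuation ratio.  Every
#' selected pixel must be valid (positive corrected radiance); selecting an
#' invalid pixel is an error, not a silent drop.
#'
#' @param ci,cj corrected bands as returned by
#'   \code{\link{darkPixelSubtract}} (lists with \code{values}, \code{valid}).
#' @param mask logical calibration mask.
#' @param bandI,bandJ band identifiers recorded in the result.
#' @return a \linkS4class{BandPairStats}.
#' @export
bandPairStats <- function(ci, cj, mask, bandI = "i", bandJ = "j") {
  if (!identical(dim(ci$values), dim(cj$values)) ||
      !identical(dim(mask), dim(ci$values)))
    stop("band and mask dimensions disagree")
  if (any(mask & !(ci$valid & cj$valid)))
    stop("calibration mask selects pixels with no valid bottom signal")
  n <- sum(mask)
  if (n < 10L) stop(sprintf("only %d calibration pixels (need at least 10)", n))
  xi <- log(ci$values[mask])
  xj <- log(cj$values[mask])
  sii <- stats::var(xi); sjj <- stats::var(xj); sij <- stats::cov(xi, xj)
  if (sii == 0 || sjj == 0 || sij == 0)
    stop("zero variance/covariance in calibration pixels: attenuation ratio undefined")
  new("BandPairStats", bandI = bandI, bandJ = bandJ,
      sii = sii, sjj = sjj, sij = sij, n = as.integer(n))
}

#' Attenuation-coefficient ratio from band-pair moments
#'
#' The ratio of attenuation coefficients between two bands follows from
#' the log-radiance moments alone:
#' \deqn{a = \frac{\sigma_{ii} - \sigma_{jj}}{2\sigma_{ij}}, \qquad
#'       k_i/k_j = a + \sqrt{a^2 + 1}.}
#' On noiseless pixels of a single bottom type the moments are
#' \eqn{\sigma_{ii} = (f k_i)^2 Var(z)} and
#' \eqn{\sigma_{ij} = f^2 k_i k_j Var(z)}, so the estimator recovers
#' \eqn{k_i/k_j} exactly; no per-band attenuation estimate is needed.
#'
#' @param stats a \linkS4class{BandPairStats}.
#' @return an \linkS4class{AttenuationEstimate}.
#' @export
attenuationRatio <- function(stats) {
  if (stats@sij == 0) stop("zero covariance: attenuation ratio undefined")
  a <- (stats@sii - stats@sjj) / (2 * stats@sij)
  new("AttenuationEstimate", stats = stats, a = a, ratio = a + sqrt(a^2 + 1))
}

#' Per-pixel depth-invariant index for one band pair
#'
#' \deqn{DII_{ij} = \ln(L_i - L_{si}) - (k_i/k_j)\,\ln(L_j - L_{sj})}
#' Under the exponential water-column model the depth terms cancel, leaving
#' an index that depends on the bottom type but not on depth.  The index is
#' defined only where both corrected bands are valid; elsewhere NA.
#'
#' @param ci,cj corrected bands (\code{\link{darkPixelSubtract}} output).
#' @param ratio attenuation ratio \eqn{k_i/k_j} (numeric or an
#'   \linkS4class{AttenuationEstimate}).
#' @return list with \code{values} (numeric matrix, NA where invalid) and
#'   \code{valid} (logical matrix).
#' @export
depthInvariantIndex <- function(ci, cj, ratio) {
  if (is(ratio, "AttenuationEstimate")) ratio <- ratio@ratio
  valid <- ci$valid & cj$valid
  values <- matrix(NA_real_, nrow(valid), ncol(valid))
  values[valid] <- log(ci$values[valid]) - ratio * log(cj$values[valid])
  list(values = values, valid = valid)
}

#' Build the depth-invariant index stack for a scene
#'
#' Runs dark-pixel subtraction on each visible band, estimates the
#' attenuation ratio of every configured band pair from the calibration
#' pixels (intersected with each pair's validity), and assembles one DII
#' layer per pair.  The stack's validity mask is TRUE where the scene mask
#' holds and every layer is defined, so downstream feature vectors are
#' complete.
#'
#' @param scene a \linkS4class{Scene}.
#' @param mask logical usable-water mask (quality and water mask combined).
#' @param deepWater a \linkS4class{DeepWaterRadiance} for this scene.
#' @param calibrationMask logical mask of uniform-bottom calibration pixels
#'   (e.g. sand across depths).
#' @param pairs list of band-name pairs; default all three visible pairs.
#' @param eps validity floor passed to \code{\link{darkPixelSubtract}}.
#' @return a \linkS4class{DIIStack}.
#' @export
buildDIIStack <- function(scene, mask, deepWater, calibrationMask,
                          pairs = list(c("B", "G"), c("B", "R"), c("G", "R")),
                          eps = 1e-6) {
  bands <- unique(unlist(pairs))
  corrected <- lapply(stats::setNames(bands, bands), function(b) {
    cb <- darkPixelSubtract(sceneBand(scene, b), deepWater@values[[b]], eps)
    cb$valid <- cb$valid & mask
    cb
  })
  pairName <- vapply(pairs, paste, character(1), collapse = ".")
  nr <- nrow(mask); nc <- ncol(mask)
  dii <- array(NA_real_, c(nr, nc, length(pairs)),
               dimnames = list(NULL, NULL, pairName))
  estimates <- vector("list", length(pairs))
  names(estimates) <- pairName
  valid <- mask
  for (p in seq_along(pairs)) {
    bi <- pairs[[p]][1]; bj <- pairs[[p]][2]
    calib <- calibrationMask & corrected[[bi]]$valid & corrected[[bj]]$valid
    est <- attenuationRatio(bandPairStats(corrected[[bi]], corrected[[bj]],
                                          calib, bi, bj))
    layer <- depthInvariantIndex(corrected[[bi]], corrected[[bj]], est)
    dii[, , p] <- layer$values
    estimates[[p]] <- est
    valid <- valid & layer$valid
  }
  new("DIIStack", dii = dii, valid = valid, estimates = estimates)
}

setMethod("show", "AttenuationEstimate", function(object) {
  cat(sprintf("AttenuationEstimate %s/%s: ratio %.6f (a = %.6f, n = %d)\n",
              object@stats@bandI, object@stats@bandJ, object@ratio,
              object@a, object@stats@n))
})

setMethod("show", "DIIStack", function(object) {
  cat(sprintf("DIIStack: %d layer(s) [%s], %d valid pixels\n",
              dim(object@dii)[3],
              paste(dimnames(object@dii)[[3]], collapse = ", "),
              sum(object@valid)))
  for (e in object@estimates) show(e)
})

#' @rdname buildDIIStack
#' @param x a \linkS4class{DIIStack}.
#' @param layer layer name or index.
#' @export
diiLayer <- function(x, layer) x@dii[, , layer]

#' @rdname buildDIIStack
#' @export
validMask <- function(x) x@valid
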