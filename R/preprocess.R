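#' Quality-band mask
#'
#' TRUE where a pixel is unobscured: neither the land/fill bit (bit 0) nor
#' the cloud bit (bit 1) of the quality band is set.
#'
#' @param quality integer matrix of quality bit flags.
#' @param scene optional \linkS4class{Scene} for a dimension check.
#' @return logical matrix.
#' @export
qualityMask <- function(quality, scene = NULL) {
  if (!is.null(scene) && !identical(dim(quality), dim(scene@bands)[1:2]))
    stop("quality band dimensions do not match the scene")
  bitwAnd(quality, 3L) == 0L
}

# Otsu threshold: maximize between-class variance of a 256-bin histogram.
.otsuThreshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) < .Machine$double.eps * max(abs(rng), 1))
    stop("cannot auto-threshold a constant band")
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), nbins)
  mids <- (breaks[-1] + breaks[-(nbins + 1L)]) / 2
  w1 <- cumsum(h); w2 <- sum(h) - w1
  m1 <- cumsum(h * mids) / w1
  m2 <- (sum(h * mids) - cumsum(h * mids)) / w2
  bc <- w1 * w2 * (m1 - m2)^2
  bc[!is.finite(bc)] <- -Inf
  best <- which.max(bc)
  # midpoint of the two class means: robust when one mode is much heavier
  (m1[best] + m2[best]) / 2
}

#' Water mask from the NIR band
#'
#' Water absorbs near-infrared light almost completely, so water pixels sit
#' near the deep-water NIR radiance while land (and cloud) pixels are
#' bright.  The mask is TRUE where NIR < threshold.  When no threshold is
#' supplied, an Otsu-style threshold splits the band's bimodal histogram; a
#' constant band cannot be auto-thresholded and raises an error.
#'
#' @param nir numeric matrix, the NIR radiance band.
#' @param threshold optional explicit radiance threshold.
#' @return logical matrix, TRUE = water.
#' @export
waterMaskFromNIR <- function(nir, threshold = NULL) {
  if (is.null(threshold)) threshold <- .otsuThreshold(nir)
  nir < threshold
}

#' Estimate mean deep-water radiance for one band
#'
#' Dark-pixel estimation of the atmosphere + glint signal: either the mean
#' over a supplied optically deep region (strategy \code{"region"},
#' matching the classical mean-deep-water-radiance definition) or the mean
#' of the darkest \code{p} percent of water pixels (strategy
#' \code{"darkest"}, default p = 1), which needs no polygon.  Note the
#' darkest-tail mean is an order statistic and is biased low under sensor
#' noise; prefer \code{"region"} when a deep polygon is available.
#'
#' @param band numeric matrix of radiances.
#' @param mask logical matrix of usable water pixels.
#' @param strategy "darkest" or "region".
#' @param p percentage of darkest pixels to average (darkest strategy).
#' @param region logical matrix delimiting the deep-water region.
#' @return list with \code{value} (mean radiance) and \code{n} (pixels used).
#' @export
estimateDeepWaterRadiance <- function(band, mask,
                                      strategy = c("darkest", "region"),
                                      p = 1, region = NULL) {
  strategy <- match.arg(strategy)
  sel <- mask
  if (strategy == "region") {
    if (is.null(region)) stop("strategy 'region' needs a deep-water region mask")
    sel <- sel & region
  }
  vals <- band[sel]
  if (length(vals) < 30L)
    stop(sprintf("only %d candidate deep-water pixels (need at least 30)",
                 length(vals)))
  if (strategy == "darkest") {
    k <- max(1L, ceiling(p / 100 * length(vals)))
    vals <- sort(vals)[seq_len(k)]
  }
  list(value = mean(vals), n = length(vals))
}

#' Estimate deep-water radiance for every band of a scene
#'
#' @param scene a \linkS4class{Scene}.
#' @param mask logical water mask.
#' @inheritParams estimateDeepWaterRadiance
#' @return a \linkS4class{DeepWaterRadiance}.
#' @export
estimateDeepWater <- function(scene, mask, strategy = c("darkest", "region"),
                              p = 1, region = NULL) {
  strategy <- match.arg(strategy)
  bands <- dimnames(scene@bands)[[3]]
  ests <- lapply(bands, function(b)
    estimateDeepWaterRadiance(scene@bands[, , b], mask, strategy, p, region))
  new("DeepWaterRadiance",
      values = stats::setNames(vapply(ests, `[[`, numeric(1), "value"), bands),
      n = as.integer(ests[[1]]$n), strategy = strategy)
}

#' Dark-pixel subtraction with validity flagging
#'
#' Subtracts the deep-water radiance from a band.  Pixels whose corrected
#' radiance does not exceed \code{eps} are flagged invalid for downstream
#' log operations rather than clipped: clipping would fabricate extreme
#' index values where there is no usable bottom signal.
#'
#' @param band numeric matrix of radiances.
#' @param Ls deep-water radiance of the same band.
#' @param eps validity floor on the corrected radiance (default 1e-6).
#' @return list with \code{values} (band - Ls, unclipped) and \code{valid}
#'   (logical matrix, TRUE where values > eps).
#' @export
darkPixelSubtract <- function(band, Ls, eps = 1e-6) {
  v <- band - Ls
  list(values = v, valid = v > eps)
}
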