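#' Configure a synthetic reef scene
#'
#' Builds the study conditions for one simulated site: a 30 m-pixel raster
#' with a land strip along the left edge, an optically deep strip along the
#' right edge (needed by dark-pixel subtraction), a smoothly varying shallow
#' depth field, benthic patches from a seeded nearest-centroid tessellation,
#' optional cloud patches, and a programmed conversion of a fraction of the
#' coral pixels to another class in epoch 2.
#'
#' @param nrow,ncol raster dimensions (>= 16).
#' @param pixelSize pixel edge in metres (default 30, Landsat-like).
#' @param depthRange shallow depth range in metres, default c(0.5, 12).
#' @param depthSmoothness Gaussian sigma in pixels of the depth field.
#' @param deepDepth depth of the deep strip in metres; optically deep for
#'   all bands (default 300).
#' @param classProportions named proportions over the benthic classes.
#' @param nPatches tessellation seed count.
#' @param deepFraction,landFraction,cloudFraction area fractions in [0, 1].
#' @param changeFraction fraction of coral pixels converted in epoch 2.
#' @param changeTo replacement class for converted pixels.
#' @param bottomVariability sd (log scale) of the per-pixel bottom
#'   brightness factor (default 0.10); 0 gives a perfectly uniform bottom
#'   per class.
#' @param seed integer seed.
#' @return a \linkS4class{SceneConfig}.
#' @export
sceneConfig <- function(nrow = 128L, ncol = 128L, pixelSize = 30,
                        depthRange = c(0.5, 12), depthSmoothness = 6,
                        deepDepth = 300,
                        classProportions = c(coral = 0.35, sand = 0.25,
                                             algae = 0.15, rubble = 0.15,
                                             seagrass = 0.10),
                        nPatches = 40L, deepFraction = 0.15,
                        landFraction = 0.10, cloudFraction = 0,
                        changeFraction = 0, changeTo = "algae",
                        bottomVariability = 0.10, seed = 1L) {
  if (changeFraction > 1) stop("changeFraction must not exceed 1")
  new("SceneConfig", nrow = as.integer(nrow), ncol = as.integer(ncol),
      pixelSize = pixelSize, depthRange = depthRange,
      depthSmoothness = depthSmoothness, deepDepth = deepDepth,
      classProportions = classProportions, nPatches = as.integer(nPatches),
      deepFraction = deepFraction, landFraction = landFraction,
      cloudFraction = cloudFraction, changeFraction = changeFraction,
      changeTo = changeTo, bottomVariability = bottomVariability,
      seed = as.integer(seed))
}

# Smoothed standard-normal field rescaled to [lo, hi].  The blur kernel is
# capped so its support fits inside small rasters.
.smoothField <- function(nr, nc, sigma, lo, hi) {
  x <- matrix(stats::rnorm(nr * nc), nr, nc)
  sigma <- min(sigma, floor((min(nr, nc) - 1) / 2) / 3)
  if (sigma > 0) x <- as.matrix(EBImage::imageData(EBImage::gblur(x, sigma = sigma)))
  rng <- range(x)
  lo + (x - rng[1]) / (rng[2] - rng[1]) * (hi - lo)
}

# Reflectance of exposed land per band (dry carbonate/soil, bright in NIR).
.LAND_REFL <- c(B = 0.18, G = 0.20, R = 0.22, NIR = 0.45)

.renderBands <- function(truth, depth, landMask, cloudMask, params, bottoms,
                         brightness) {
  bands <- names(params@Ls)
  nr <- nrow(depth); nc <- ncol(depth)
  out <- array(NA_real_, c(nr, nc, length(bands)),
               dimnames = list(NULL, NULL, bands))
  refl <- bottoms@reflectance
  water <- !landMask
  for (b in bands) {
    r <- matrix(0, nr, nc)                        # NA truth (deep) => no bottom term
    known <- water & !is.na(truth)
    r[known] <- pmin(refl[truth[known], b] * brightness[known], 1)
    L <- radianceForward(r, depth, params@Ls[[b]], params@a[[b]],
                         params@k[[b]], params@f)
    L[landMask] <- params@Ls[[b]] + params@a[[b]] * .LAND_REFL[[b]]
    L[cloudMask] <- params@Ls[[b]] + 0.85 * params@a[[b]]   # bright cloud top
    if (params@noiseSD[[b]] > 0)
      L <- L + matrix(stats::rnorm(nr * nc, 0, params@noiseSD[[b]]), nr, nc)
    out[, , b] <- L
  }
  out
}

#' Simulate a seeded two-epoch scene pair
#'
#' Generates two radiance scenes of the same site via the radiative forward
#' model.  The epoch-2 bottom map differs from epoch 1 only at the
#' programmed converted coral pixels — exactly
#' \code{round(changeFraction * initial coral count)} of them — while the
#' per-band sensor noise is drawn independently per epoch.  NIR over water
#' sits near its deep-water value (water absorbs NIR), land is bright in
#' NIR, and cloud pixels are flagged in the quality band (bit 1) with their
#' radiances overwritten by bright values.  Deep-strip and land pixels
#' carry truth class NA.  The whole simulation is a pure function of
#' (config, params, bottoms): the same seed reproduces the pair bit for bit.
#'
#' @param config a \linkS4class{SceneConfig}.
#' @param params a \linkS4class{ForwardModelParams}.
#' @param bottoms a \linkS4class{BottomLibrary}.
#' @return a \linkS4class{ScenePair}.
#' @export
simulateScenePair <- function(config, params = defaultForwardParams(),
                              bottoms = defaultBottomLibrary()) {
  validObject(config)
  nr <- config@nrow; nc <- config@ncol
  set.seed(config@seed)

  landCols <- seq_len(round(config@landFraction * nc))
  nDeep <- round(config@deepFraction * nc)
  deepCols <- if (nDeep > 0) seq(nc - nDeep + 1L, nc) else integer(0)
  landMask <- matrix(FALSE, nr, nc); landMask[, landCols] <- TRUE
  deepMask <- matrix(FALSE, nr, nc); deepMask[, deepCols] <- TRUE

  depth <- .smoothField(nr, nc, config@depthSmoothness,
                        config@depthRange[1], config@depthRange[2])
  depth[deepMask] <- config@deepDepth
  depth[landMask] <- 0

  # benthic patches: nearest-centroid tessellation with class-labelled seeds
  classes <- names(config@classProportions)
  cen <- cbind(stats::runif(config@nPatches, 1, nr),
               stats::runif(config@nPatches, 1, nc))
  cenClass <- sample(classes, config@nPatches, replace = TRUE,
                     prob = config@classProportions)
  rows <- row(depth); cols <- col(depth)
  nearest <- matrix(0L, nr, nc)
  bestD <- matrix(Inf, nr, nc)
  for (i in seq_len(config@nPatches)) {
    d2 <- (rows - cen[i, 1])^2 + (cols - cen[i, 2])^2
    upd <- d2 < bestD
    nearest[upd] <- i
    bestD[upd] <- d2[upd]
  }
  truth1 <- matrix(cenClass[nearest], nr, nc)
  truth1[landMask | deepMask] <- NA_character_

  # per-pixel bottom-brightness heterogeneity (mixed-pixel effect); a fixed
  # property of the sea floor, shared by both epochs
  brightness <- if (config@bottomVariability > 0)
    matrix(exp(stats::rnorm(nr * nc, 0, config@bottomVariability)), nr, nc)
  else matrix(1, nr, nc)

  # clouds: square-ish patches until the target pixel count is covered
  cloudMask <- matrix(FALSE, nr, nc)
  target <- round(config@cloudFraction * nr * nc)
  while (sum(cloudMask) < target) {
    r0 <- sample.int(nr, 1L); c0 <- sample.int(nc, 1L)
    s <- sample(3:7, 1L)
    cloudMask[max(1, r0 - s):min(nr, r0 + s),
              max(1, c0 - s):min(nc, c0 + s)] <- TRUE
  }

  # programmed coral conversion for epoch 2 (exact bookkeeping)
  truth2 <- truth1
  coralIdx <- which(truth1 == "coral")
  nConv <- round(config@changeFraction * length(coralIdx))
  if (nConv > 0) {
    conv <- sample(coralIdx, nConv)
    truth2[conv] <- config@changeTo
  }

  quality <- matrix(0L, nr, nc)
  quality[landMask] <- 1L
  quality[cloudMask] <- bitwOr(quality[cloudMask], 2L)

  geo <- c(0, config@pixelSize, 0, 0, 0, -config@pixelSize)
  b1 <- .renderBands(truth1, depth, landMask, cloudMask, params, bottoms,
                     brightness)
  b2 <- .renderBands(truth2, depth, landMask, cloudMask, params, bottoms,
                     brightness)
  mkScene <- function(bands, epoch)
    new("Scene", bands = bands, quality = quality, geotransform = geo,
        nodata = -9999, epoch = epoch, site = "synthetic")
  new("ScenePair", epoch1 = mkScene(b1, "t0"), epoch2 = mkScene(b2, "t1"),
      depth = depth, truth1 = truth1, truth2 = truth2,
      deepMask = deepMask, landMask = landMask, config = config)
}

#' @describeIn sceneBand Extract one radiance band as a matrix.
#' @export
setGeneric("sceneBand", function(x, band) standardGeneric("sceneBand"))

#' Scene accessors
#'
#' @param x a \linkS4class{Scene}.
#' @param band band name ("B", "G", "R" or "NIR").
#' @return \code{sceneBand}: numeric matrix; \code{sceneQuality}: integer
#'   matrix of quality bit flags.
#' @export
setMethod("sceneBand", "Scene", function(x, band) {
  if (!band %in% dimnames(x@bands)[[3]])
    stop(sprintf("scene has no band '%s'", band))
  x@bands[, , band]
})

#' @rdname sceneBand-Scene-method
#' @export
sceneQuality <- function(x) x@quality

setMethod("show", "Scene", function(object) {
  d <- dim(object@bands)
  cat(sprintf("Scene [%s, epoch %s]: %d x %d pixels, bands %s\n",
              object@site, object@epoch, d[1], d[2],
              paste(dimnames(object@bands)[[3]], collapse = ",")))
  cat(sprintf("  flagged: %d land/fill, %d cloud\n",
              sum(bitwAnd(object@quality, 1L) > 0),
              sum(bitwAnd(object@quality, 2L) > 0)))
})

setMethod("show", "ScenePair", function(object) {
  cat(sprintf("ScenePair: %d x %d, %d shallow-water pixels, %d coral (t0)\n",
              nrow(object@depth), ncol(object@depth),
              sum(!is.na(object@truth1)),
              sum(object@truth1 == "coral", na.rm = TRUE)))
  cat(sprintf("  programmed conversion: %d pixels coral -> %s\n",
              sum(object@truth1 == "coral" & object@truth2 != "coral",
                  na.rm = TRUE), object@config@changeTo))
})
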