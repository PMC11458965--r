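#' @import methods
NULL

# Band naming convention used throughout: three visible channels plus NIR.
.BANDS <- c("B", "G", "R", "NIR")
.VIS <- c("B", "G", "R")

# Benthic classes carried by the simulator and the percent-cover categories
# of the ground-truth protocol (visual census style).
.BENTHIC_CLASSES <- c("coral", "sand", "algae", "rubble", "seagrass")
.GT_CATEGORIES <- c("sand", "rock", "mud", "rubble", "coral", "seagrass", "seaweed")

#' Radiative forward-model parameters
#'
#' Per-band parameters of the exponential shallow-water radiance model
#' \eqn{L_i = L_{si} + a_i r_i \exp(-f k_i z)}: \code{Ls} the mean deep-water
#' radiance (atmospheric path radiance plus surface glint, radiance units),
#' \code{a} a dimensionless constant absorbing solar irradiance, atmospheric
#' transmission and surface effects, \code{k} the diffuse attenuation
#' coefficient (per metre), \code{f} the geometric path-length factor
#' (2 for a two-flow model), and \code{noiseSD} the additive Gaussian
#' sensor-noise standard deviation per band (radiance units).
#'
#' @slot Ls named numeric, deep-water radiance per band.
#' @slot a named numeric, surface/atmosphere constant per band.
#' @slot k named numeric, attenuation coefficient per band (1/m), > 0.
#' @slot f numeric(1), geometric factor, > 0.
#' @slot noiseSD named numeric, sensor noise sd per band, >= 0.
#' @export
setClass("ForwardModelParams",
  slots = c(Ls = "numeric", a = "numeric", k = "numeric",
            f = "numeric", noiseSD = "numeric"))

setValidity("ForwardModelParams", function(object) {
  bands <- names(object@Ls)
  if (is.null(bands) || !all(nzchar(bands)))
    return("Ls must be a named numeric vector of bands")
  for (s in c("a", "k", "noiseSD"))
    if (!identical(names(slot(object, s)), bands))
      return(sprintf("'%s' must carry the same band names as 'Ls'", s))
  if (any(object@k <= 0)) return("all attenuation coefficients k must be > 0")
  if (length(object@f) != 1L || object@f <= 0) return("f must be a single value > 0")
  if (any(object@Ls < 0)) return("deep-water radiances Ls must be >= 0")
  if (any(object@noiseSD < 0)) return("noiseSD must be >= 0")
  TRUE
})

#' Bottom-reflectance library
#'
#' Dimensionless bottom reflectances in [0, 1] for each benthic class
#' (rows) and each simulated band (columns).
#'
#' @slot reflectance numeric matrix, classes x bands, values in [0, 1].
#' @export
setClass("BottomLibrary", slots = c(reflectance = "matrix"))

setValidity("BottomLibrary", function(object) {
  r <- object@reflectance
  if (is.null(rownames(r)) || is.null(colnames(r)))
    return("reflectance matrix needs class rownames and band colnames")
  if (any(r < 0 | r > 1)) return("reflectances must lie in [0, 1]")
  if (anyNA(r)) return("every class needs a reflectance for every band")
  TRUE
})

#' Synthetic-scene configuration
#'
#' Study conditions for one simulated two-epoch reef scene: raster geometry,
#' depth-field shape, benthic patch structure, masked regions and the
#' programmed coral conversion between epochs.
#'
#' @slot nrow,ncol integer raster dimensions (>= 16).
#' @slot pixelSize numeric, ground sampling distance in metres (default 30).
#' @slot depthRange numeric(2), shallow depth range in metres.
#' @slot depthSmoothness numeric, Gaussian sigma (pixels) of the depth field.
#' @slot deepDepth numeric, depth assigned to the optically deep strip (m).
#' @slot classProportions named numeric over benthic classes, sums to 1.
#' @slot nPatches integer, number of tessellation seeds for bottom patches.
#' @slot deepFraction,landFraction,cloudFraction numeric in [0, 1].
#' @slot changeFraction numeric in [0, 1], fraction of epoch-1 coral pixels
#'   converted to \code{changeTo} in epoch 2.
#' @slot changeTo character, replacement benthic class.
#' @slot bottomVariability numeric >= 0, sd (log scale) of the per-pixel
#'   bottom-brightness factor shared by all bands; emulates within-class
#'   heterogeneity of 30 m mixed pixels.  The brightness field is a fixed
#'   property of the bottom: it is drawn once per site and shared by both
#'   epochs.
#' @slot seed integer random seed; every simulator draw is a pure function
#'   of the configuration including this seed.
#' @export
setClass("SceneConfig",
  slots = c(nrow = "integer", ncol = "integer", pixelSize = "numeric",
            depthRange = "numeric", depthSmoothness = "numeric",
            deepDepth = "numeric", classProportions = "numeric",
            nPatches = "integer", deepFraction = "numeric",
            landFraction = "numeric", cloudFraction = "numeric",
            changeFraction = "numeric", changeTo = "character",
            bottomVariability = "numeric", seed = "integer"))

setValidity("SceneConfig", function(object) {
  if (object@nrow < 16L || object@ncol < 16L) return("raster must be at least 16 x 16")
  if (object@pixelSize <= 0) return("pixelSize must be > 0")
  fr <- c(object@deepFraction, object@landFraction, object@cloudFraction,
          object@changeFraction)
  if (any(fr < 0 | fr > 1)) return("fractions must lie in [0, 1]")
  if (length(object@depthRange) != 2L || diff(object@depthRange) <= 0 ||
      object@depthRange[1] <= 0)
    return("depthRange must be increasing positive depths")
  p <- object@classProportions
  if (abs(sum(p) - 1) > 1e-8) return("classProportions must sum to 1")
  if (!all(names(p) %in% .BENTHIC_CLASSES)) return("unknown benthic class in proportions")
  if (!object@changeTo %in% setdiff(.BENTHIC_CLASSES, "coral"))
    return("changeTo must be a non-coral benthic class")
  if (object@bottomVariability < 0) return("bottomVariability must be >= 0")
  TRUE
})

#' Multiband radiance scene
#'
#' A georeferenced multiband raster: radiance bands stacked in a 3-D array
#' (rows x cols x bands, band names in the third dimnames), an integer
#' quality band carrying bit flags (bit 0 = land/fill, bit 1 = cloud), a
#' 6-element GDAL-style geotransform and a nodata value.
#'
#' @slot bands 3-D numeric array with band dimnames.
#' @slot quality integer matrix of quality bit flags.
#' @slot geotransform numeric(6).
#' @slot nodata numeric(1).
#' @slot epoch character label (e.g. "t0", "t1").
#' @slot site character site label.
#' @export
setClass("Scene",
  slots = c(bands = "array", quality = "matrix", geotransform = "numeric",
            nodata = "numeric", epoch = "character", site = "character"))

setValidity("Scene", function(object) {
  d <- dim(object@bands)
  if (length(d) != 3L) return("bands must be a rows x cols x bands array")
  if (is.null(dimnames(object@bands)[[3]])) return("band names missing")
  if (!identical(dim(object@quality), d[1:2]))
    return("quality band dimensions must match the radiance bands")
  if (length(object@geotransform) != 6L) return("geotransform must have 6 elements")
  TRUE
})

#' Simulated two-epoch scene pair
#'
#' Everything the simulator knows about one site: the two radiance scenes,
#' the depth raster, the true bottom-class maps per epoch (character
#' matrices; NA over land and over the optically deep strip), and masks for
#' the deep-water strip and land.
#'
#' @slot epoch1,epoch2 \linkS4class{Scene}.
#' @slot depth numeric matrix of depths (m).
#' @slot truth1,truth2 character matrices of benthic classes.
#' @slot deepMask,landMask logical matrices.
#' @slot config the generating \linkS4class{SceneConfig}.
#' @export
setClass("ScenePair",
  slots = c(epoch1 = "Scene", epoch2 = "Scene", depth = "matrix",
            truth1 = "matrix", truth2 = "matrix", deepMask = "matrix",
            landMask = "matrix", config = "SceneConfig"))

setValidity("ScenePair", function(object) {
  d <- dim(object@depth)
  for (s in c("truth1", "truth2", "deepMask", "landMask"))
    if (!identical(dim(slot(object, s)), d))
      return(sprintf("'%s' dimensions disagree with depth raster", s))
  TRUE
})

#' Per-band mean deep-water radiance
#'
#' @slot values named numeric, mean deep-water radiance per band.
#' @slot n integer, number of contributing pixels.
#' @slot strategy character, "region" or "darkest".
#' @export
setClass("DeepWaterRadiance",
  slots = c(values = "numeric", n = "integer", strategy = "character"))

setValidity("DeepWaterRadiance", function(object) {
  if (any(object@values < 0)) return("deep-water radiances must be >= 0")
  if (object@n < 30L) return("fewer than 30 contributing pixels")
  TRUE
})

#' Log-radiance moments for one band pair
#'
#' Sample variances and covariance of the log of deep-water-corrected
#' radiances over a calibration set of uniform-bottom pixels.
#'
#' @slot bandI,bandJ character band identifiers.
#' @slot sii,sjj,sij numeric variance/covariance of the log radiances.
#' @slot n integer pixels used.
#' @export
setClass("BandPairStats",
  slots = c(bandI = "character", bandJ = "character",
            sii = "numeric", sjj = "numeric", sij = "numeric", n = "integer"))

setValidity("BandPairStats", function(object) {
  if (object@sii < 0 || object@sjj < 0) return("variances must be >= 0")
  if (object@n < 10L) return("need at least 10 calibration pixels")
  if (abs(object@sij) > sqrt(object@sii * object@sjj) * (1 + 1e-12))
    return("covariance exceeds Cauchy-Schwarz bound")
  TRUE
})

#' Attenuation-coefficient ratio estimate for one band pair
#'
#' Holds the moment statistics together with the intermediate
#' \eqn{a = (\sigma_{ii}-\sigma_{jj})/(2\sigma_{ij})} and the ratio
#' \eqn{k_i/k_j = a + \sqrt{a^2+1}}.
#'
#' @slot stats \linkS4class{BandPairStats}.
#' @slot a numeric intermediate.
#' @slot ratio numeric, the estimated attenuation ratio (> 0).
#' @export
setClass("AttenuationEstimate",
  slots = c(stats = "BandPairStats", a = "numeric", ratio = "numeric"))

setValidity("AttenuationEstimate", function(object) {
  if (object@ratio <= 0) return("attenuation ratio must be > 0")
  if (abs(object@ratio - (object@a + sqrt(object@a^2 + 1))) >
      1e-9 * max(1, object@ratio))
    return("ratio must equal a + sqrt(a^2 + 1)")
  TRUE
})

#' Stack of depth-invariant index layers
#'
#' One raster layer per configured band pair of per-pixel depth-invariant
#' indices, a joint validity mask (TRUE where every layer is defined), and
#' the attenuation estimates that produced each layer as provenance.
#'
#' @slot dii 3-D numeric array, rows x cols x pairs (pair dimnames).
#' @slot valid logical matrix.
#' @slot estimates named list of \linkS4class{AttenuationEstimate}.
#' @export
setClass("DIIStack",
  slots = c(dii = "array", valid = "matrix", estimates = "list"))

setValidity("DIIStack", function(object) {
  d <- dim(object@dii)
  if (length(d) != 3L) return("dii must be rows x cols x pairs")
  if (!identical(dim(object@valid), d[1:2])) return("valid mask dimensions disagree")
  if (d[3] != length(object@estimates)) return("one AttenuationEstimate per layer required")
  TRUE
})

#' Trained coral/non-coral classifier
#'
#' A fitted radial-basis SVM with posterior-probability output, stored with
#' the z-score standardization constants of its training features, the
#' selected hyperparameters, the cross-validation grid, and provenance.
#'
#' @slot model fitted e1071 svm object.
#' @slot center,scale named numeric standardization constants.
#' @slot gamma,cost chosen hyperparameters.
#' @slot cvAccuracy numeric, mean CV accuracy of the chosen grid point.
#' @slot grid data.frame of (gamma, cost, accuracy) over the search grid.
#' @slot features character, DII layer names expected at prediction time.
#' @slot sites character, training-site provenance.
#' @slot seed integer.
#' @export
setClass("TrainedCoralClassifier",
  slots = c(model = "ANY", center = "numeric", scale = "numeric",
            gamma = "numeric", cost = "numeric", cvAccuracy = "numeric",
            grid = "data.frame", features = "character", sites = "character",
            seed = "integer"))

#' Binary confusion matrix (coral = positive)
#'
#' @slot tp,fn,fp,tn integer counts.
#' @export
setClass("ConfusionMatrix",
  slots = c(tp = "integer", fn = "integer", fp = "integer", tn = "integer"))

setValidity("ConfusionMatrix", function(object) {
  if (any(c(object@tp, object@fn, object@fp, object@tn) < 0L))
    return("confusion counts must be >= 0")
  TRUE
})

#' Six-metric accuracy report
#'
#' Precision, recall, specificity, accuracy, F-measure and Cohen's kappa
#' for a binary coral/non-coral evaluation.  Metrics whose denominator is
#' zero are reported as NA (explicit undefined marker), never as 0.
#'
#' @slot precision,recall,specificity,accuracy,fMeasure,kappa numeric.
#' @slot n integer evaluation-set size.
#' @export
setClass("MetricsReport",
  slots = c(precision = "numeric", recall = "numeric", specificity = "numeric",
            accuracy = "numeric", fMeasure = "numeric", kappa = "numeric",
            n = "integer"))

#' ROC curve with trapezoidal AUC
#'
#' @slot points data.frame with columns fpr, tpr, ordered, endpoints (0,0)
#'   and (1,1).
#' @slot auc numeric in [0, 1].
#' @export
setClass("ROCCurve", slots = c(points = "data.frame", auc = "numeric"))

setValidity("ROCCurve", function(object) {
  p <- object@points
  if (!all(c("fpr", "tpr") %in% names(p))) return("points need fpr and tpr")
  if (is.unsorted(p$fpr) || is.unsorted(p$tpr)) return("ROC points must be monotone")
  if (object@auc < 0 || object@auc > 1) return("auc must lie in [0, 1]")
  TRUE
})

#' Per-pixel two-epoch transition raster
#'
#' Integer codes: 0 invalid, 1 coral->coral, 2 coral->non, 3 non->coral,
#' 4 non->non.
#'
#' @slot codes integer matrix.
#' @slot pixelSize numeric, pixel edge length in metres.
#' @export
setClass("ChangeRaster", slots = c(codes = "matrix", pixelSize = "numeric"))

setValidity("ChangeRaster", function(object) {
  if (!all(object@codes %in% 0:4)) return("codes must be in 0..4")
  if (object@pixelSize <= 0) return("pixelSize must be > 0")
  TRUE
})

#' Two-epoch coral-cover change report
#'
#' Transition pixel counts, initial/final coral pixel counts and areas
#' (km^2, reported to 2 decimals), percent change in coral cover (1
#' decimal) and the coral share of the valid shallow benthic area per
#' epoch (percent, 1 decimal).  Raw counts are always retained.
#'
#' @slot counts named numeric transition counts (NA when built from
#'   summary counts alone).
#' @slot initialCoral,finalCoral numeric pixel counts.
#' @slot nValid numeric, valid shallow pixels shared by both epochs.
#' @slot initialAreaKm2,finalAreaKm2 numeric (2 dp).
#' @slot percentChange numeric, (initial - final)/initial * 100 (1 dp).
#' @slot initialSharePct,finalSharePct numeric (1 dp).
#' @slot pixelSize numeric metres.
#' @export
setClass("ChangeReport",
  slots = c(counts = "numeric", initialCoral = "numeric", finalCoral = "numeric",
            nValid = "numeric", initialAreaKm2 = "numeric",
            finalAreaKm2 = "numeric", percentChange = "numeric",
            initialSharePct = "numeric", finalSharePct = "numeric",
            pixelSize = "numeric"))
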