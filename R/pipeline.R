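#' Optical conditions of the three synthetic study sites
#'
#' Site "A" is the reference (training) site with the default clear-water
#' parameters.  Sites "B" and "C" lie further along a shared regional
#' turbidity gradient — attenuation coefficients scaled per band, with the
#' shortest wavelengths most affected, as suspended matter raises
#' scattering — ordered A < B < C, with site C (emulating a turbid lagoon
#' system) beyond B, plus their own atmospheric states (surface constant
#' and path radiance rescaled) and ~5\% log-normal jitter on the class
#' bottom reflectances.  The shifts are the study's domain gap: a
#' classifier trained on A faces genuinely different optics on B and C,
#' and the pooled A+B model extrapolates a shorter optical distance to C
#' than the A-only model does.
#'
#' @param site "A", "B" or "C".
#' @param seed integer; drives the reflectance jitter draw (offset per site
#'   so sites differ even at the same seed).
#' @return list with \code{params} and \code{bottoms}.
#' @export
siteConditions <- function(site = c("A", "B", "C"), seed = 1L) {
  site <- match.arg(site)
  base <- defaultForwardParams()
  bl <- defaultBottomLibrary()
  switch(site,
    A = list(params = base, bottoms = bl),
    B = perturbSiteConditions(base, bl,
          kScale = c(B = 1.30, G = 1.25, R = 1.15, NIR = 1),
          aScale = 0.95, LsScale = 1.10, reflJitterSD = 0.05,
          seed = seed + 101L),
    C = perturbSiteConditions(base, bl,
          kScale = c(B = 1.45, G = 1.38, R = 1.22, NIR = 1),
          aScale = 1.02, LsScale = 1.05, reflJitterSD = 0.05,
          seed = seed + 202L))
}

# Ground-truth survey sizes emulating the field campaign: the training
# site has 1085 coral + 202 non-coral points, the second site a small
# survey whose minority class supports a 44-point balanced evaluation.
.SITE_GT <- list(A = list(n = 1287L, coralFraction = 1085 / 1287),
                 B = list(n = 200L, coralFraction = 0.89),
                 C = list(n = 400L, coralFraction = 0.5))

#' Simulate and preprocess one study site
#'
#' Runs the full front end for one synthetic site: simulate the two-epoch
#' scene pair, build the quality/water masks, estimate deep-water radiance
#' over the simulated deep strip, assemble per-epoch DII stacks (sand
#' pixels across depths as calibration), and sample a ground-truth survey
#' restricted to pixels with complete DII features.
#'
#' @param site "A", "B" or "C" (selects optics and survey size).
#' @param seed integer master seed for this site.
#' @param nrow,ncol scene dimensions.
#' @param changeFraction programmed coral-loss fraction for epoch 2.
#' @param cloudFraction cloud area fraction.
#' @param nGT,coralFraction optional survey-size overrides.
#' @return list with elements \code{site}, \code{pair}
#'   (\linkS4class{ScenePair}), \code{prep} (masks, deep-water estimates
#'   and \linkS4class{DIIStack}s per epoch, shared validity), \code{gt}
#'   (ground-truth table) and \code{seed}.
#' @export
simulateSite <- function(site = c("A", "B", "C"), seed = 1L, nrow = 128L,
                         ncol = 128L, changeFraction = 0.10,
                         cloudFraction = 0.02, nGT = NULL,
                         coralFraction = NULL) {
  site <- match.arg(site)
  cond <- siteConditions(site, seed)
  off <- c(A = 0L, B = 1000L, C = 2000L)[[site]]
  cfg <- sceneConfig(nrow = nrow, ncol = ncol, cloudFraction = cloudFraction,
                     changeFraction = changeFraction,
                     seed = as.integer(seed) + off)
  pair <- simulateScenePair(cfg, cond$params, cond$bottoms)
  prep <- prepareScenePair(pair)
  gtSpec <- .SITE_GT[[site]]
  if (is.null(nGT)) nGT <- gtSpec$n
  if (is.null(coralFraction)) coralFraction <- gtSpec$coralFraction
  gt <- sampleGroundTruth(pair@truth1, n = nGT, site = site,
                          coralFraction = coralFraction,
                          seed = as.integer(seed) + 7L,
                          validMask = prep$dii1@valid)
  list(site = site, pair = pair, prep = prep, gt = gt,
       seed = as.integer(seed))
}

#' Preprocess a scene pair into per-epoch DII stacks
#'
#' Quality and NIR water masks, deep-water radiance over the simulated deep
#' strip ("region" strategy, the classical mean-deep-water definition), and
#' one \linkS4class{DIIStack} per epoch calibrated on that epoch's sand
#' pixels.
#'
#' @param pair a \linkS4class{ScenePair}.
#' @param eps validity floor for dark-pixel subtraction.
#' @return list with masks, deep-water estimates, \code{dii1}, \code{dii2}
#'   and \code{sharedValid} (pixels valid in both epochs).
#' @export
prepareScenePair <- function(pair, eps = 1e-6) {
  prepOne <- function(scene, truth) {
    if (!"NIR" %in% dimnames(scene@bands)[[3]])
      stop("water-mask stage: scene lacks a NIR band")
    qm <- qualityMask(scene@quality, scene)
    wm <- waterMaskFromNIR(sceneBand(scene, "NIR"))
    mask <- qm & wm
    dw <- estimateDeepWater(scene, mask, strategy = "region",
                            region = pair@deepMask)
    calib <- !is.na(truth) & truth == "sand" & mask
    dii <- buildDIIStack(scene, mask & !pair@deepMask, dw, calib, eps = eps)
    list(mask = mask, dw = dw, dii = dii)
  }
  p1 <- prepOne(pair@epoch1, pair@truth1)
  p2 <- prepOne(pair@epoch2, pair@truth2)
  list(mask1 = p1$mask, mask2 = p2$mask, dw1 = p1$dw, dw2 = p2$dw,
       dii1 = p1$dii, dii2 = p2$dii,
       sharedValid = p1$dii@valid & p2$dii@valid)
}

# Out-of-fold posterior predictions at the chosen hyperparameters.
.cvPredictions <- function(features, labels, gamma, cost, folds = 5L,
                           seed = 1L, center = NULL, scaleV = NULL) {
  if (is.null(center)) center <- colMeans(features)
  if (is.null(scaleV)) scaleV <- apply(features, 2, stats::sd)
  X <- scale(features, center = center, scale = scaleV)
  set.seed(as.integer(seed))
  fold <- .stratifiedFolds(labels, folds)
  prob <- numeric(length(labels))
  for (f in seq_len(folds)) {
    tr <- fold != f
    set.seed(as.integer(seed) + f)
    fit <- e1071::svm(X[tr, , drop = FALSE], labels[tr], kernel = "radial",
                      gamma = gamma, cost = cost, scale = FALSE,
                      probability = TRUE)
    p <- predict(fit, X[!tr, , drop = FALSE], probability = TRUE)
    prob[!tr] <- attr(p, "probabilities")[, "coral"]
  }
  prob
}

# Balanced labelled DII features at a site's ground-truth points.
.balancedSiteSamples <- function(sim, seed, rule = "plurality") {
  fx <- extractFeatures(sim$prep$dii1, sim$gt)
  keep <- fx$valid
  labels <- binarizeGroundTruth(sim$gt[keep, , drop = FALSE], rule = rule)
  stratifiedBalancedSample(fx$features[keep, , drop = FALSE], labels,
                           seed = seed)
}

#' Single-site protocol: train, evaluate and quantify change at one site
#'
#' Executes the full chain for one (simulated) site: balanced training set
#' from the ground truth, grid-search CV training of the RBF classifier,
#' six-metric evaluation from out-of-fold CV predictions plus ROC/AUC,
#' posterior and class maps for both epochs, per-pixel change detection and
#' the change accounting.
#'
#' @param sim a site as returned by \code{\link{simulateSite}}.
#' @param threshold posterior probability threshold (default 0.5).
#' @param gamma,cost tuning grid.
#' @param folds CV folds.
#' @return list with \code{model}, \code{confusion}, \code{metrics},
#'   \code{roc}, \code{change} (a \linkS4class{ChangeReport}),
#'   \code{classMaps} and a \code{provenance} block.
#' @export
runSingleSite <- function(sim, threshold = 0.5, gamma = 2^(-7:3),
                          cost = 2^(-3:7), folds = 5L) {
  seed <- sim$seed
  bal <- .balancedSiteSamples(sim, seed + 11L)
  model <- tuneAndTrain(bal$features, bal$labels, gamma = gamma, cost = cost,
                        folds = folds, seed = seed + 13L, sites = sim$site)
  prob <- .cvPredictions(bal$features, bal$labels, model@gamma, model@cost,
                         folds = folds, seed = seed + 17L)
  predLab <- ifelse(prob >= threshold, "coral", "noncoral")
  cm <- confusionCounts(predLab, bal$labels)
  metrics <- classifierMetrics(cm)
  roc <- rocCurve(prob, bal$labels)
  prob1 <- predictPosterior(model, sim$prep$dii1)
  prob2 <- predictPosterior(model, sim$prep$dii2)
  cls1 <- thresholdClass(prob1, threshold)
  cls2 <- thresholdClass(prob2, threshold)
  change <- changeSummary(perPixelChange(cls1, cls2,
                                         valid = sim$prep$sharedValid,
                                         pixelSize = sim$pair@config@pixelSize))
  list(model = model, confusion = cm, metrics = metrics, roc = roc,
       change = change, classMaps = list(t0 = cls1, t1 = cls2),
       provenance = list(site = sim$site, seed = seed, gamma = model@gamma,
                         cost = model@cost, n_balanced = length(bal$labels),
                         threshold = threshold,
                         package = as.character(utils::packageVersion("ReefChange"))))
}

#' Cross-site protocol: train on one site, evaluate on another
#'
#' Trains on the training site's balanced ground truth and evaluates on a
#' balanced sample from the test site.  Standardization constants and
#' hyperparameters come from the training site only — no test-site leakage.
#'
#' @param trainSim,testSim sites from \code{\link{simulateSite}}.  The test
#'   site must carry ground truth; identical sample positions in the two
#'   objects (same site surveyed twice) are rejected.
#' @param threshold posterior threshold.
#' @param gamma,cost,folds tuning controls.
#' @return list with \code{model}, train-side CV accuracy, and test-side
#'   \code{confusion}, \code{metrics}, \code{balancedAccuracy}, \code{roc}.
#' @export
runCrossSite <- function(trainSim, testSim, threshold = 0.5,
                         gamma = 2^(-7:3), cost = 2^(-3:7), folds = 5L) {
  if (is.null(testSim$gt) || nrow(testSim$gt) == 0)
    stop("test site carries no ground truth")
  # leakage guard: the same scene realization surveyed twice shares pixels
  if (identical(trainSim$site, testSim$site) &&
      identical(trainSim$seed, testSim$seed)) {
    key <- function(g) paste(g$row, g$col)
    if (any(key(trainSim$gt) %in% key(testSim$gt)))
      stop("train and test samples overlap within the same site")
  }
  seed <- trainSim$seed
  balTr <- .balancedSiteSamples(trainSim, seed + 11L)
  model <- tuneAndTrain(balTr$features, balTr$labels, gamma = gamma,
                        cost = cost, folds = folds, seed = seed + 13L,
                        sites = trainSim$site)
  balTe <- .balancedSiteSamples(testSim, testSim$seed + 11L)
  prob <- predictCoralProb(model, balTe$features)
  predLab <- ifelse(prob >= threshold, "coral", "noncoral")
  cm <- confusionCounts(predLab, balTe$labels)
  list(model = model, trainCVAccuracy = model@cvAccuracy, confusion = cm,
       metrics = classifierMetrics(cm), balancedAccuracy = balancedAccuracy(cm),
       roc = rocCurve(prob, balTe$labels))
}

#' Consolidated protocol: pool sites, train one robust model, apply to a
#' third site
#'
#' Pools the balanced ground-truth samples of at least two training sites,
#' trains a single classifier on the pooled set, evaluates it on the apply
#' site's balanced ground truth and runs the two-epoch change analysis
#' there.
#'
#' @param trainSims list of >= 2 sites from \code{\link{simulateSite}}.
#' @param applySim the site the consolidated model is applied to.
#' @param threshold posterior threshold.
#' @param gamma,cost,folds tuning controls.
#' @return list with \code{model}, pooled sample size \code{nPooled},
#'   per-site balanced counts, test-side metrics and the apply-site
#'   \code{change} report.
#' @export
runConsolidated <- function(trainSims, applySim, threshold = 0.5,
                            gamma = 2^(-7:3), cost = 2^(-3:7), folds = 5L) {
  if (length(trainSims) < 2L)
    stop("the consolidated protocol needs at least two training sites")
  bals <- lapply(trainSims, function(s) .balancedSiteSamples(s, s$seed + 11L))
  features <- do.call(rbind, lapply(bals, `[[`, "features"))
  labels <- factor(unlist(lapply(bals, function(b) as.character(b$labels))),
                   levels = c("coral", "noncoral"))
  seed <- trainSims[[1]]$seed
  model <- tuneAndTrain(features, labels, gamma = gamma, cost = cost,
                        folds = folds, seed = seed + 13L,
                        sites = vapply(trainSims, `[[`, character(1), "site"))
  balTe <- .balancedSiteSamples(applySim, applySim$seed + 11L)
  prob <- predictCoralProb(model, balTe$features)
  predLab <- ifelse(prob >= threshold, "coral", "noncoral")
  cm <- confusionCounts(predLab, balTe$labels)
  prob1 <- predictPosterior(model, applySim$prep$dii1)
  prob2 <- predictPosterior(model, applySim$prep$dii2)
  change <- changeSummary(perPixelChange(thresholdClass(prob1, threshold),
                                         thresholdClass(prob2, threshold),
                                         valid = applySim$prep$sharedValid,
                                         pixelSize = applySim$pair@config@pixelSize))
  list(model = model, nPooled = length(labels),
       perSiteN = vapply(bals, function(b) length(b$labels), integer(1)),
       confusion = cm, metrics = classifierMetrics(cm),
       balancedAccuracy = balancedAccuracy(cm),
       change = change)
}

#' Cross-site generalization study for one seed
#'
#' Simulates sites A (reference optics), B and C (shifted optics), then
#' measures: within-site CV accuracy on A, balanced accuracy of the
#' A-trained model on B, and balanced accuracy on held-out C of the A-only
#' model versus the consolidated A+B model.
#'
#' @param seed integer seed.
#' @param nrow,ncol scene dimensions.
#' @param gamma,cost,folds tuning controls.
#' @return named list of the four accuracies plus the pooled sample size.
#' @export
runGeneralizationStudy <- function(seed = 1L, nrow = 128L, ncol = 128L,
                                   gamma = 2^(-7:3), cost = 2^(-3:7),
                                   folds = 5L) {
  simA <- simulateSite("A", seed, nrow, ncol)
  simB <- simulateSite("B", seed, nrow, ncol)
  simC <- simulateSite("C", seed, nrow, ncol)
  ab <- runCrossSite(simA, simB, gamma = gamma, cost = cost, folds = folds)
  balC <- .balancedSiteSamples(simC, simC$seed + 11L)
  probA <- predictCoralProb(ab$model, balC$features)
  cmA <- confusionCounts(ifelse(probA >= 0.5, "coral", "noncoral"),
                         balC$labels)
  cons <- runConsolidated(list(simA, simB), simC, gamma = gamma, cost = cost,
                          folds = folds)
  list(withinA = ab$trainCVAccuracy,
       crossAB = ab$balancedAccuracy,
       singleOnC = balancedAccuracy(cmA),
       consolidatedOnC = cons$balancedAccuracy,
       nPooled = cons$nPooled)
}

#' End-to-end change-recovery study for one seed
#'
#' Simulates site A with a programmed coral-loss fraction, runs the full
#' single-site protocol and returns the estimated percent reduction
#' alongside the programmed one.
#'
#' @param seed integer seed.
#' @param lossFraction programmed fraction of coral pixels converted.
#' @param nrow,ncol scene dimensions.
#' @param gamma,cost,folds tuning controls.
#' @return list with \code{estimated} and \code{programmed} percent
#'   reduction and the full \code{change} report.
#' @export
runChangeRecovery <- function(seed = 1L, lossFraction = 0.10, nrow = 128L,
                              ncol = 128L, gamma = 2^(-7:3), cost = 2^(-3:7),
                              folds = 5L) {
  sim <- simulateSite("A", seed, nrow, ncol, changeFraction = lossFraction)
  res <- runSingleSite(sim, gamma = gamma, cost = cost, folds = folds)
  list(estimated = res$change@percentChange,
       programmed = 100 * lossFraction, change = res$change,
       metrics = res$metrics)
}
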