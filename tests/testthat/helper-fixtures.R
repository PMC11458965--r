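# Shared fixtures: noiseless study conditions, tiny synthetic feature sets
# and independent oracles.

noiselessParams <- function() defaultForwardParams(noiseFraction = 0)

noiselessConfig <- function(seed = 5L, ...)
  sceneConfig(seed = seed, bottomVariability = 0, cloudFraction = 0, ...)

# Independent AUC oracle: exhaustive pairwise comparison (Mann-Whitney
# count), ties scored 1/2.
aucBruteForce <- function(prob, labels, positive = "coral") {
  p <- prob[labels == positive]
  q <- prob[labels != positive]
  s <- 0
  for (x in p) for (y in q) s <- s + (x > y) + 0.5 * (x == y)
  s / (length(p) * length(q))
}

# Two well-separated Gaussian clusters in feature space.
separableFeatures <- function(n = 40L, gap = 6, seed = 1L, d = 2L) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n / 2 * d), ncol = d),
             matrix(rnorm(n / 2 * d, mean = gap), ncol = d))
  colnames(x) <- paste0("f", seq_len(d))
  list(features = x,
       labels = factor(rep(c("coral", "noncoral"), each = n / 2),
                       levels = c("coral", "noncoral")))
}

# Minimal valid DIIStack built from explicit layer matrices.
makeStack <- function(layers, valid = NULL) {
  nr <- nrow(layers[[1]]); nc <- ncol(layers[[1]])
  dii <- array(NA_real_, c(nr, nc, length(layers)),
               dimnames = list(NULL, NULL, names(layers)))
  for (i in seq_along(layers)) dii[, , i] <- layers[[i]]
  if (is.null(valid)) valid <- Reduce(`&`, lapply(layers, function(m) !is.na(m)))
  est <- new("AttenuationEstimate",
             stats = new("BandPairStats", bandI = "i", bandJ = "j",
                         sii = 1, sjj = 1, sij = 0.5, n = 10L),
             a = 0, ratio = 1)
  new("DIIStack", dii = dii, valid = valid,
      estimates = stats::setNames(rep(list(est), length(layers)),
                                  names(layers)))
}

# One fully preprocessed noiseless site (cached per session: several tests
# reuse it and it is deterministic).
.noiselessSiteCache <- new.env()
noiselessSite <- function() {
  if (is.null(.noiselessSiteCache$site)) {
    pair <- simulateScenePair(noiselessConfig(), noiselessParams())
    sc <- pair@epoch1
    mask <- qualityMask(sc@quality) & waterMaskFromNIR(sceneBand(sc, "NIR"))
    dw <- estimateDeepWater(sc, mask, strategy = "region",
                            region = pair@deepMask)
    calib <- !is.na(pair@truth1) & pair@truth1 == "sand" & mask
    dii <- buildDIIStack(sc, mask & !pair@deepMask, dw, calib)
    .noiselessSiteCache$site <- list(pair = pair, scene = sc, mask = mask,
                                     dw = dw, calib = calib, dii = dii)
  }
  .noiselessSiteCache$site
}
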