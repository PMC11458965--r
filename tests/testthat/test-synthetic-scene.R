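test_that("the same seed reproduces the scene pair bit for bit", {
  cfg <- sceneConfig(nrow = 48, ncol = 48, cloudFraction = 0.03,
                     changeFraction = 0.2, seed = 11L)
  p1 <- simulateScenePair(cfg)
  p2 <- simulateScenePair(cfg)
  expect_identical(p1@epoch1@bands, p2@epoch1@bands)
  expect_identical(p1@epoch2@bands, p2@epoch2@bands)
  expect_identical(p1@truth1, p2@truth1)
  expect_identical(p1@truth2, p2@truth2)
})

test_that("zero change fraction leaves the bottom map untouched", {
  cfg <- sceneConfig(nrow = 48, ncol = 48, changeFraction = 0, seed = 2L)
  p <- simulateScenePair(cfg)
  expect_identical(p@truth1, p@truth2)
})

test_that("programmed conversions hit the exact pixel count", {
  for (frac in c(0.1, 0.25, 0.5)) {
    cfg <- sceneConfig(nrow = 64, ncol = 64, changeFraction = frac, seed = 7L)
    p <- simulateScenePair(cfg)
    nCoral <- sum(p@truth1 == "coral", na.rm = TRUE)
    converted <- sum(p@truth1 == "coral" & p@truth2 != "coral", na.rm = TRUE)
    expect_identical(converted, as.integer(round(frac * nCoral)))
    # conversions go to the configured class; nothing else moves
    expect_true(all(p@truth2[p@truth1 != p@truth2 & !is.na(p@truth1)] ==
                      cfg@changeTo))
  }
})

test_that("change fractions above one are rejected", {
  expect_error(sceneConfig(changeFraction = 1.5), "changeFraction")
})

test_that("NIR separates water from land, and clouds are flagged bright", {
  cfg <- noiselessConfig(seed = 3L)
  p <- simulateScenePair(cfg, noiselessParams())
  nir <- sceneBand(p@epoch1, "NIR")
  Ls <- noiselessParams()@Ls[["NIR"]]
  water <- !p@landMask
  expect_lt(max(nir[water]) - Ls, 1.5)        # full absorption emulation
  expect_gt(min(nir[p@landMask]), Ls + 20)    # land is bright in NIR

  cfgC <- sceneConfig(nrow = 48, ncol = 48, cloudFraction = 0.05, seed = 9L)
  pc <- simulateScenePair(cfgC)
  q <- sceneQuality(pc@epoch1)
  cloud <- bitwAnd(q, 2L) > 0
  expect_gte(sum(cloud), round(0.05 * 48 * 48))
  clear <- bitwAnd(q, 3L) == 0
  b <- sceneBand(pc@epoch1, "B")
  expect_gt(min(b[cloud]), max(b[clear]))     # overwritten with bright values
})

test_that("quality flags cover every pixel and land strips are flagged", {
  p <- simulateScenePair(sceneConfig(nrow = 48, ncol = 48, seed = 4L))
  q <- sceneQuality(p@epoch1)
  expect_false(anyNA(q))
  expect_true(all(bitwAnd(q[p@landMask], 1L) > 0))
})

test_that("depth field honours range, deep strip and land conventions", {
  cfg <- noiselessConfig(seed = 6L)
  p <- simulateScenePair(cfg, noiselessParams())
  shallow <- !p@landMask & !p@deepMask
  expect_true(all(p@depth[shallow] >= cfg@depthRange[1] - 1e-9))
  expect_true(all(p@depth[shallow] <= cfg@depthRange[2] + 1e-9))
  expect_true(all(p@depth[p@deepMask] == cfg@deepDepth))
  expect_gte(cfg@deepDepth, 40)
})

test_that("ground-truth tables emulate a percent-cover survey", {
  p <- simulateScenePair(noiselessConfig(seed = 8L), noiselessParams())
  gt <- sampleGroundTruth(p@truth1, n = 1085, site = "siteA", seed = 21L)
  expect_identical(nrow(gt), 1085L)
  cats <- c("sand", "rock", "mud", "rubble", "coral", "seagrass", "seaweed")
  expect_true(all(rowSums(gt[, cats]) == 100))
  expect_true(all(apply(gt[, cats], 1, max) >= 50))
  # positions fall inside the raster, on surveyable pixels
  expect_true(all(gt$row >= 1 & gt$row <= nrow(p@truth1)))
  expect_true(all(gt$col >= 1 & gt$col <= ncol(p@truth1)))
  expect_false(anyNA(p@truth1[cbind(gt$row, gt$col)]))
  # determinism
  gt2 <- sampleGroundTruth(p@truth1, n = 1085, site = "siteA", seed = 21L)
  expect_identical(gt, gt2)
})

test_that("the coral fraction of a survey is controllable", {
  p <- simulateScenePair(noiselessConfig(seed = 8L), noiselessParams())
  gtAll <- sampleGroundTruth(p@truth1, n = 60, coralFraction = 1, seed = 1L)
  lab <- binarizeGroundTruth(gtAll)
  expect_true(all(lab == "coral"))
  gtHalf <- sampleGroundTruth(p@truth1, n = 200, coralFraction = 0.5, seed = 1L)
  expect_identical(sum(binarizeGroundTruth(gtHalf) == "coral"), 100L)
})

test_that("surveys of unsurveyable maps are rejected", {
  empty <- matrix(NA_character_, 20, 20)
  expect_error(sampleGroundTruth(empty, n = 5), "empty water mask")
  p <- simulateScenePair(noiselessConfig(seed = 8L), noiselessParams())
  expect_error(sampleGroundTruth(p@truth1, n = 1e6), "only")
})
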