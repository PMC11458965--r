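test_that("quality mask excludes exactly the flagged union", {
  q <- matrix(0L, 10, 10)
  expect_true(all(qualityMask(q)))
  # 12 cloud pixels, 15 land pixels, 5 overlapping
  land <- sample.int(100, 15)
  cloud <- c(land[1:5], setdiff(sample.int(100, 30), land)[1:7])
  q[land] <- 1L
  q[cloud] <- bitwOr(q[cloud], 2L)
  m <- qualityMask(q)
  expect_identical(sum(!m), length(union(land, cloud)))
  expect_true(all(!m[union(land, cloud)]))
})

test_that("quality mask checks alignment with the scene", {
  p <- simulateScenePair(sceneConfig(nrow = 32, ncol = 32, seed = 1L))
  expect_error(qualityMask(matrix(0L, 5, 5), p@epoch1), "dimensions")
})

test_that("NIR water mask recovers the simulated land strip", {
  p <- simulateScenePair(noiselessConfig(seed = 3L), noiselessParams())
  wm <- waterMaskFromNIR(sceneBand(p@epoch1, "NIR"))
  expect_identical(wm, !p@landMask)
})

test_that("explicit NIR thresholds behave at the extremes", {
  nir <- matrix(runif(100, 1, 5), 10, 10)
  expect_false(any(waterMaskFromNIR(nir, threshold = 0.5)))
  expect_true(all(waterMaskFromNIR(nir, threshold = 10)))
  expect_error(waterMaskFromNIR(matrix(2, 10, 10)), "constant")
})

test_that("deep-water estimation: uniform band, darkest tail, exact recovery", {
  m <- matrix(TRUE, 10, 10)
  expect_equal(estimateDeepWaterRadiance(matrix(3.5, 10, 10), m)$value, 3.5)

  # darkest 1% against a brute-force sort on a 20x20 toy raster
  set.seed(42)
  vals <- sample(seq_len(400))
  band <- matrix(vals, 20, 20)
  est <- estimateDeepWaterRadiance(band, matrix(TRUE, 20, 20),
                                   strategy = "darkest", p = 1)
  k <- ceiling(0.01 * 400)
  expect_equal(est$value, mean(sort(vals)[seq_len(k)]))

  # noiseless scene + deep region: configured Ls recovered exactly
  s <- noiselessSite()
  expect_equal(s$dw@values, noiselessParams()@Ls, tolerance = 1e-12)
})

test_that("deep-water estimation under noise stays within 3 sd/sqrt(n)", {
  params <- defaultForwardParams()
  pair <- simulateScenePair(sceneConfig(seed = 13L), params)
  sc <- pair@epoch1
  mask <- qualityMask(sc@quality) & waterMaskFromNIR(sceneBand(sc, "NIR"))
  dw <- estimateDeepWater(sc, mask, strategy = "region", region = pair@deepMask)
  bound <- 3 * params@noiseSD / sqrt(dw@n)
  expect_true(all(abs(dw@values - params@Ls) <= bound))
})

test_that("too few deep-water candidates raise an error naming the count", {
  band <- matrix(1, 20, 20)
  mask <- matrix(FALSE, 20, 20); mask[1:12] <- TRUE
  expect_error(estimateDeepWaterRadiance(band, mask), "only 12 candidate")
})

test_that("dark-pixel subtraction flags rather than clips", {
  band <- matrix(2, 5, 5)
  all0 <- darkPixelSubtract(band, 2)
  expect_false(any(all0$valid))
  expect_true(all(all0$values == 0))          # not clipped away

  shifted <- darkPixelSubtract(band + 2, 2)
  expect_true(all(shifted$values == 2) && all(shifted$valid))

  set.seed(1)
  mixed <- matrix(rnorm(400, mean = 2, sd = 1), 20, 20)
  out <- darkPixelSubtract(mixed, 2, eps = 1e-6)
  expect_identical(sum(!out$valid), sum(mixed - 2 <= 1e-6))
})

test_that("mask composition is commutative and idempotent", {
  p <- simulateScenePair(sceneConfig(nrow = 32, ncol = 32,
                                     cloudFraction = 0.05, seed = 5L))
  qm <- qualityMask(sceneQuality(p@epoch1))
  wm <- waterMaskFromNIR(sceneBand(p@epoch1, "NIR"))
  expect_identical(qm & wm, wm & qm)
  expect_identical((qm & wm) & wm, qm & wm)
})
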