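# wrap a plain matrix as a corrected-band object (all pixels valid)
corrected <- function(m) list(values = m, valid = !is.na(m) & m > 0)

test_that("band-pair moments match a hand computation on listed numbers", {
  x <- c(0.31, 0.55, 0.93, 1.21, 1.46, 1.80, 2.02, 2.35, 2.66, 2.95,
         3.21, 3.50, 3.77, 4.05, 4.31, 4.66, 4.90, 5.21, 5.55, 5.86)
  y <- 0.5 * x
  ci <- corrected(matrix(exp(x), 4, 5))
  cj <- corrected(matrix(exp(y), 4, 5))
  st <- bandPairStats(ci, cj, matrix(TRUE, 4, 5), "i", "j")
  # moment oracle by explicit sums (n-1 convention)
  mx <- sum(x) / 20; my <- sum(y) / 20
  expect_equal(st@sii, sum((x - mx)^2) / 19)
  expect_equal(st@sjj, sum((y - my)^2) / 19)
  expect_equal(st@sij, sum((x - mx) * (y - my)) / 19)
  expect_equal(st@sij, 0.5 * st@sii)
  expect_equal(attenuationRatio(st)@a,
               (st@sii - 0.25 * st@sii) / (2 * 0.5 * st@sii))
})

test_that("identical bands give a = 0 and ratio 1; constants are rejected", {
  x <- matrix(exp(seq(0.1, 2, length.out = 20)), 4, 5)
  st <- bandPairStats(corrected(x), corrected(x), matrix(TRUE, 4, 5))
  expect_equal(st@sii, st@sjj)
  expect_equal(st@sii, st@sij)
  est <- attenuationRatio(st)
  expect_equal(est@a, 0)
  expect_equal(est@ratio, 1)
  const <- corrected(matrix(2, 4, 5))
  expect_error(bandPairStats(const, corrected(x), matrix(TRUE, 4, 5)),
               "zero variance")
  expect_error(bandPairStats(corrected(x), corrected(x), matrix(TRUE, 2, 2)),
               "dimensions")
})

test_that("attenuation ratio is exact on noiseless single-bottom pixels", {
  # ki = 0.10, kj = 0.05 over varying depth: a = 0.75, ratio = 2 exactly
  z <- matrix(seq(0.5, 12, length.out = 36), 6, 6)
  Li <- radianceForward(0.3, z, Ls = 1, a = 100, k = 0.10)
  Lj <- radianceForward(0.4, z, Ls = 2, a = 110, k = 0.05)
  st <- bandPairStats(corrected(Li - 1), corrected(Lj - 2), matrix(TRUE, 6, 6))
  est <- attenuationRatio(st)
  expect_equal(est@a, 0.75, tolerance = 1e-12)
  expect_equal(est@ratio, 2, tolerance = 1e-12)
})

test_that("swapping the band pair inverts the ratio and flips a's sign", {
  set.seed(3)
  for (i in 1:5) {
    z <- matrix(runif(30, 0.5, 15), 5, 6)
    ki <- runif(1, 0.03, 0.3); kj <- runif(1, 0.03, 0.3)
    ci <- corrected(radianceForward(0.2, z, 0, 90, ki))
    cj <- corrected(radianceForward(0.3, z, 0, 80, kj))
    one <- matrix(TRUE, 5, 6)
    fwd <- attenuationRatio(bandPairStats(ci, cj, one))
    rev <- attenuationRatio(bandPairStats(cj, ci, one))
    expect_equal(fwd@a, -rev@a, tolerance = 1e-9)
    expect_equal(fwd@ratio * rev@ratio, 1, tolerance = 1e-9)
  }
})

test_that("depth-invariant index arithmetic and invalidity propagation", {
  m2 <- matrix(2, 3, 3); m4 <- matrix(4, 3, 3)
  expect_true(all(depthInvariantIndex(corrected(m2), corrected(m2), 1)$values == 0))
  dii <- depthInvariantIndex(corrected(m2), corrected(m4), 0.5)
  expect_equal(max(abs(dii$values)), 0, tolerance = 1e-15)
  ci <- corrected(m2); ci$valid[1, 1] <- FALSE
  out <- depthInvariantIndex(ci, corrected(m4), 0.5)
  expect_true(is.na(out$values[1, 1]) && !out$valid[1, 1])
})

test_that("the index is depth-invariant for a fixed bottom", {
  # same bottom at 1 m and 10 m: identical index to <= 1e-9
  p <- noiselessParams()
  z <- matrix(c(1, 10), 5, 2, byrow = TRUE)   # needs >= 10 pixels
  z <- rbind(z, z, z)[1:15, , drop = FALSE]
  ci <- corrected(radianceForward(0.1, z, 0, p@a[["B"]], p@k[["B"]]))
  cj <- corrected(radianceForward(0.12, z, 0, p@a[["G"]], p@k[["G"]]))
  dii <- depthInvariantIndex(ci, cj, p@k[["B"]] / p@k[["G"]])
  expect_lt(diff(range(dii$values)), 1e-9)
})

test_that("the DII stack has one calibrated layer per configured pair", {
  s <- noiselessSite()
  expect_identical(dimnames(s$dii@dii)[[3]], c("B.G", "B.R", "G.R"))
  single <- buildDIIStack(s$scene, s$mask & !s$pair@deepMask, s$dw, s$calib,
                          pairs = list(c("B", "G")))
  expect_identical(dim(single@dii)[3], 1L)
  expect_identical(names(single@estimates), "B.G")

  # exact ratio recovery through the full scene pipeline
  p <- noiselessParams()
  for (nm in names(s$dii@estimates)) {
    e <- s$dii@estimates[[nm]]
    truth <- p@k[[e@stats@bandI]] / p@k[[e@stats@bandJ]]
    expect_lt(abs(e@ratio - truth) / truth, 1e-9)
  }
})

test_that("within-class DII variance is far below between-class variance", {
  # default (noisy, heterogeneous-bottom) study conditions
  pair <- simulateScenePair(sceneConfig(seed = 17L))
  prep <- prepareScenePair(pair)
  lay <- diiLayer(prep$dii1, "B.G")
  cls <- pair@truth1[prep$dii1@valid]
  val <- lay[prep$dii1@valid]
  within <- mean(tapply(val, cls, var))
  between <- var(tapply(val, cls, mean))
  expect_lt(within, between / 10)
})
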