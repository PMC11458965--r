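gtRow <- function(...) {
  cats <- c("sand", "rock", "mud", "rubble", "coral", "seagrass", "seaweed")
  z <- stats::setNames(rep(0, 7), cats)
  v <- c(...)
  z[names(v)] <- v
  as.data.frame(c(list(row = 1L, col = 1L, site = "s"), as.list(z)))
}

test_that("ground-truth binarization follows the plurality rule", {
  gt <- rbind(gtRow(coral = 60, sand = 40),
              gtRow(coral = 30, sand = 50, rubble = 20),
              gtRow(coral = 50, sand = 50))            # tie -> coral
  expect_identical(as.character(binarizeGroundTruth(gt)),
                   c("coral", "noncoral", "coral"))
  expect_identical(as.character(binarizeGroundTruth(gt, rule = "threshold",
                                                    threshold = 40)),
                   c("coral", "noncoral", "coral"))
  expect_error(binarizeGroundTruth(gtRow()), "all-zero")
})

test_that("balanced sampling undersamples the majority class deterministically", {
  x <- matrix(rnorm(2 * 1287), ncol = 2,
              dimnames = list(NULL, c("f1", "f2")))
  y <- factor(rep(c("coral", "noncoral"), c(1085, 202)),
              levels = c("coral", "noncoral"))
  bal <- stratifiedBalancedSample(x, y, seed = 4L)
  expect_identical(length(bal$labels), 404L)            # 202 per class
  expect_identical(as.vector(table(bal$labels)), c(202L, 202L))
  bal2 <- stratifiedBalancedSample(x, y, seed = 4L)
  expect_identical(bal$index, bal2$index)

  even <- stratifiedBalancedSample(x[1:20, ], factor(rep(c("coral", "noncoral"),
                                                         each = 10)), seed = 1L)
  expect_identical(even$index, 1:20)                    # balanced input unchanged
  expect_error(stratifiedBalancedSample(x, y, nPerClass = 500), "exceeds")
  expect_error(stratifiedBalancedSample(x[1:5, ],
                                        factor(rep("coral", 5),
                                               levels = c("coral", "noncoral"))),
               "both classes")
})

test_that("grid search separates separable classes and is reproducible", {
  d <- separableFeatures(n = 60, seed = 2L)
  m1 <- tuneAndTrain(d$features, d$labels, gamma = 2^(-3:1), cost = 2^(0:3),
                     seed = 9L)
  expect_equal(max(m1@grid$accuracy), 1)
  expect_equal(m1@cvAccuracy, 1)
  m2 <- tuneAndTrain(d$features, d$labels, gamma = 2^(-3:1), cost = 2^(0:3),
                     seed = 9L)
  expect_identical(c(m1@gamma, m1@cost), c(m2@gamma, m2@cost))
  # tie-break: smaller cost, then smaller gamma among equal accuracies
  top <- m1@grid
  best <- top[top$accuracy == max(top$accuracy), ]
  expect_identical(m1@cost, min(best$cost))
  expect_identical(m1@gamma, min(best$gamma[best$cost == m1@cost]))
})

test_that("degenerate features are rejected", {
  d <- separableFeatures(n = 40, seed = 2L)
  d$features[, 2] <- 1
  expect_error(tuneAndTrain(d$features, d$labels), "zero variance")
})

test_that("permuted labels yield chance-level cross-validation accuracy", {
  d <- separableFeatures(n = 60, seed = 5L)
  accs <- vapply(1:20, function(i) {
    set.seed(100 + i)
    yPerm <- sample(d$labels)
    tuneAndTrain(d$features, yPerm, gamma = 1, cost = 1, seed = i)@cvAccuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("posterior maps respect class geometry and nodata", {
  d <- separableFeatures(n = 80, gap = 8, seed = 3L)
  model <- tuneAndTrain(d$features, d$labels, gamma = 2^(-2:1), cost = 2^(0:3),
                        seed = 1L)
  # a point at each cluster centre
  centres <- rbind(coral = c(0, 0), noncoral = c(8, 8))
  colnames(centres) <- model@features
  p <- predictCoralProb(model, centres)
  expect_gt(p[1], 0.5)
  expect_lt(p[2], 0.5)

  lay1 <- matrix(0, 4, 4); lay2 <- matrix(0, 4, 4)
  lay1[1, 1] <- NA                                     # invalid pixel
  stack <- makeStack(list(f1 = lay1, f2 = lay2))
  prob <- predictPosterior(model, stack)
  expect_true(is.na(prob[1, 1]))
  expect_true(all(prob[!is.na(prob)] > 0.5))           # all-coral scene

  bad <- makeStack(list(g1 = lay1, g2 = lay2))
  expect_error(predictPosterior(model, bad), "do not match")
})

test_that("probability thresholding uses >= with ties to coral", {
  prob <- matrix(c(0.4, 0.5, 0.6, NA), 2, 2)
  cls <- thresholdClass(prob, 0.5)
  expect_identical(as.vector(cls), c(0L, 1L, 1L, NA))
  expect_true(all(thresholdClass(prob, 0)[!is.na(prob)] == 1L))
  expect_true(all(thresholdClass(prob * 0.9, 1)[!is.na(prob)] == 0L))
  expect_error(thresholdClass(prob, 1.5), "threshold")
})
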