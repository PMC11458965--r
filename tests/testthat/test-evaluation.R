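test_that("confusion counts match hand enumeration", {
  pred <- c("coral", "coral", "noncoral", "coral", "noncoral", "noncoral")
  truth <- c("coral", "noncoral", "coral", "coral", "noncoral", "coral")
  cm <- confusionCounts(pred, truth)
  expect_identical(c(cm@tp, cm@fn, cm@fp, cm@tn), c(2L, 2L, 1L, 1L))

  perfect <- confusionCounts(truth, truth)
  expect_identical(perfect@tp + perfect@tn, 6L)
  expect_identical(perfect@fp + perfect@fn, 0L)

  allCoral <- confusionCounts(rep("coral", 8),
                              rep(c("coral", "noncoral"), each = 4))
  expect_identical(c(allCoral@tp, allCoral@fp, allCoral@fn, allCoral@tn),
                   c(4L, 4L, 0L, 0L))
  expect_error(confusionCounts(pred[1:3], truth), "length")
})

test_that("the six metrics reproduce the balanced-survey worked example", {
  m <- classifierMetrics(confusionFromCounts(tp = 165, fn = 59, fp = 71,
                                             tn = 153))
  expect_equal(round(m@accuracy, 4), 0.7098)     # 318 of 448 correct
  expect_equal(round(m@precision, 4), 0.6992)
  expect_equal(round(m@recall, 4), 0.7366)
  expect_equal(round(m@specificity, 4), 0.6830)
  expect_equal(round(m@fMeasure, 4), 0.7174)
  expect_equal(round(m@kappa, 4), 0.4196)
  expect_identical(m@n, 448L)
})

test_that("perfect and undefined cases are reported honestly", {
  perfect <- classifierMetrics(confusionFromCounts(10, 0, 0, 10))
  expect_equal(c(perfect@precision, perfect@recall, perfect@specificity,
                 perfect@accuracy, perfect@fMeasure, perfect@kappa),
               rep(1, 6))
  noPos <- classifierMetrics(confusionFromCounts(0, 4, 0, 6))
  expect_true(is.na(noPos@precision))            # TP+FP = 0: undefined, not 0
  expect_true(is.na(noPos@fMeasure))
  expect_error(classifierMetrics(confusionFromCounts(0, 0, 0, 0)), "empty")
})

test_that("kappa reduces to 2*accuracy - 1 under balanced truth marginals", {
  set.seed(7)
  for (i in 1:20) {
    npos <- sample(5:50, 1)
    tp <- sample(0:npos, 1); tn <- sample(0:npos, 1)
    m <- classifierMetrics(confusionFromCounts(tp, npos - tp, npos - tn, tn))
    expect_equal(m@kappa, 2 * m@accuracy - 1, tolerance = 1e-12)
  }
})

test_that("ROC endpoints, extremes and monotonicity hold", {
  lab <- rep(c("coral", "noncoral"), each = 5)
  sep <- rocCurve(c(runif(5, 0.8, 1), runif(5, 0, 0.2)), lab)
  expect_equal(sep@auc, 1)
  flat <- rocCurve(rep(0.5, 10), lab)
  expect_equal(flat@auc, 0.5)
  expect_equal(unlist(flat@points[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(flat@points[nrow(flat@points), ]), c(fpr = 1, tpr = 1))
  expect_error(rocCurve(runif(5), rep("coral", 5)), "both classes")
  expect_error(rocCurve(c(0.5, 1.2), c("coral", "noncoral")), "\\[0, 1\\]")
})

test_that("AUC equals the exhaustive pairwise-comparison probability", {
  # 6-point toy set with a tie
  prob <- c(0.9, 0.7, 0.7, 0.4, 0.3, 0.1)
  lab <- c("coral", "coral", "noncoral", "coral", "noncoral", "noncoral")
  expect_equal(rocCurve(prob, lab)@auc, aucBruteForce(prob, lab))

  set.seed(11)
  for (i in 1:15) {
    n <- sample(6:20, 1)
    lab <- sample(rep(c("coral", "noncoral"), length.out = n))
    prob <- round(runif(n), 2)                  # rounding forces ties
    if (length(unique(lab)) < 2) next
    expect_equal(rocCurve(prob, lab)@auc, aucBruteForce(prob, lab),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(21)
  lab <- sample(rep(c("coral", "noncoral"), 15))
  prob <- runif(30)
  ours <- rocCurve(prob, lab)@auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = lab, predictor = prob,
                                        levels = c("noncoral", "coral"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("swapping the positive class maps AUC to its complement", {
  set.seed(31)
  lab <- sample(rep(c("coral", "noncoral"), 10))
  prob <- runif(20)                              # continuous: no ties
  a <- rocCurve(prob, lab)@auc
  b <- rocCurve(prob, lab, positive = "noncoral")@auc
  expect_equal(a + b, 1, tolerance = 1e-12)
})
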