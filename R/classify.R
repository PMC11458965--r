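#' Extract DII feature vectors at point positions
#'
#' @param stack a \linkS4class{DIIStack}.
#' @param points data.frame with 1-based \code{row} and \code{col} columns
#'   (e.g. a ground-truth table).
#' @return list with \code{features} (matrix, one row per point, one column
#'   per DII layer) and \code{valid} (logical, TRUE where every layer is
#'   defined at the point).
#' @export
extractFeatures <- function(stack, points) {
  layers <- dimnames(stack@dii)[[3]]
  nr <- dim(stack@dii)[1]; nc <- dim(stack@dii)[2]
  if (any(points$row < 1 | points$row > nr | points$col < 1 | points$col > nc))
    stop("point positions fall outside the raster")
  f <- vapply(seq_along(layers), function(l)
    stack@dii[cbind(points$row, points$col, l)], numeric(nrow(points)))
  f <- matrix(f, nrow = nrow(points), dimnames = list(NULL, layers))
  list(features = f, valid = stack@valid[cbind(points$row, points$col)])
}

#' Stratified balanced subsample
#'
#' Equalizes class counts by undersampling the majority class (seeded,
#' deterministic).  An already balanced input is returned unchanged.
#'
#' @param features feature matrix (rows = samples).
#' @param labels factor of class labels, both classes present.
#' @param seed integer seed.
#' @param nPerClass optional target per-class count (must not exceed the
#'   minority count).
#' @return list with \code{features}, \code{labels} and \code{index} (the
#'   rows kept, in increasing order within class).
#' @export
stratifiedBalancedSample <- function(features, labels, seed = 1L,
                                     nPerClass = NULL) {
  labels <- droplevels(as.factor(labels))
  counts <- table(labels)
  if (any(counts == 0) || length(counts) < 2L)
    stop("both classes must be present with at least one member each")
  m <- if (is.null(nPerClass)) min(counts) else nPerClass
  if (m > min(counts))
    stop(sprintf("nPerClass = %d exceeds the minority class count %d",
                 m, min(counts)))
  set.seed(as.integer(seed))
  idx <- unlist(lapply(levels(labels), function(l) {
    i <- which(labels == l)
    if (length(i) == m) i else sort(sample(i, m))
  }))
  list(features = features[idx, , drop = FALSE], labels = labels[idx],
       index = idx)
}

# Stratified fold assignment: shuffles within class, cycles fold ids.
.stratifiedFolds <- function(labels, folds) {
  fold <- integer(length(labels))
  for (l in levels(labels)) {
    i <- sample(which(labels == l))
    fold[i] <- rep_len(seq_len(folds), length(i))
  }
  fold
}

#' Tune and train the radial-basis coral classifier
#'
#' Grid search over (gamma, cost) maximizing mean stratified k-fold
#' cross-validation accuracy; ties are broken toward smaller cost, then
#' smaller gamma.  Features are z-score standardized using the training
#' statistics only (required for a radial-basis kernel; the constants are
#' stored with the model and reapplied at prediction time).  The final
#' model is refit on all samples with posterior-probability output.
#'
#' @param features training feature matrix (DII values).
#' @param labels factor with levels including "coral".
#' @param gamma,cost numeric vectors defining the search grid (log-2 spaced
#'   defaults).
#' @param folds CV fold count (>= 2); every fold contains both classes.
#' @param seed integer seed controlling fold assignment and the
#'   probability-model fit.
#' @param sites character provenance label(s).
#' @return a \linkS4class{TrainedCoralClassifier}.
#' @export
tuneAndTrain <- function(features, labels, gamma = 2^(-7:3), cost = 2^(-3:7),
                         folds = 5L, seed = 1L, sites = "unknown") {
  labels <- droplevels(as.factor(labels))
  if (length(gamma) < 1L || length(cost) < 1L) stop("empty tuning grid")
  if (folds < 2L) stop("need at least 2 cross-validation folds")
  if (min(table(labels)) < folds)
    stop("too few samples per class to fill every fold with both classes")
  sds <- apply(features, 2, stats::sd)
  if (any(sds == 0))
    stop(sprintf("degenerate feature(s) with zero variance: %s",
                 paste(colnames(features)[sds == 0], collapse = ", ")))
  center <- colMeans(features)
  X <- scale(features, center = center, scale = sds)
  set.seed(as.integer(seed))
  fold <- .stratifiedFolds(labels, folds)
  grid <- expand.grid(gamma = gamma, cost = cost)
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    mean(vapply(seq_len(folds), function(f) {
      tr <- fold != f
      fit <- e1071::svm(X[tr, , drop = FALSE], labels[tr], kernel = "radial",
                        gamma = grid$gamma[g], cost = grid$cost[g],
                        scale = FALSE)
      mean(predict(fit, X[!tr, , drop = FALSE]) == labels[!tr])
    }, numeric(1)))
  }, numeric(1))
  grid$accuracy <- acc
  best <- order(-acc, grid$cost, grid$gamma)[1]
  set.seed(as.integer(seed) + 1L)
  final <- e1071::svm(X, labels, kernel = "radial", gamma = grid$gamma[best],
                      cost = grid$cost[best], scale = FALSE,
                      probability = TRUE)
  new("TrainedCoralClassifier", model = final,
      center = center, scale = stats::setNames(sds, colnames(features)),
      gamma = grid$gamma[best], cost = grid$cost[best],
      cvAccuracy = acc[best], grid = grid,
      features = colnames(features), sites = sites, seed = as.integer(seed))
}

#' Posterior coral probability for point features
#'
#' @param model a \linkS4class{TrainedCoralClassifier}.
#' @param features feature matrix with the model's feature columns.
#' @return numeric vector of coral posterior probabilities.
#' @export
predictCoralProb <- function(model, features) {
  if (!identical(colnames(features), model@features))
    stop("feature layers do not match the training configuration")
  X <- scale(features, center = model@center, scale = model@scale)
  p <- predict(model@model, X, probability = TRUE)
  attr(p, "probabilities")[, "coral"]
}

#' Posterior coral-probability raster
#'
#' Applies the classifier to every valid pixel of a DII stack; invalid
#' pixels carry NA (nodata).
#'
#' @param model a \linkS4class{TrainedCoralClassifier}.
#' @param stack a \linkS4class{DIIStack} whose layers match the training
#'   configuration.
#' @return numeric matrix of coral probabilities in [0, 1], NA where invalid.
#' @export
predictPosterior <- function(model, stack) {
  layers <- dimnames(stack@dii)[[3]]
  if (!identical(layers, model@features))
    stop("feature layers do not match the training configuration")
  idx <- which(stack@valid)
  out <- matrix(NA_real_, nrow(stack@valid), ncol(stack@valid))
  if (length(idx)) {
    f <- vapply(layers, function(l) (stack@dii[, , l])[idx],
                numeric(length(idx)))
    f <- matrix(f, nrow = length(idx), dimnames = list(NULL, layers))
    out[idx] <- predictCoralProb(model, f)
  }
  out
}

#' Threshold a posterior-probability raster into a class raster
#'
#' Coral where probability >= threshold (ties count as coral); NA (nodata)
#' propagated.
#'
#' @param prob numeric matrix of coral probabilities.
#' @param threshold probability threshold in [0, 1], default 0.5.
#' @return integer matrix: 1 = coral, 0 = non-coral, NA = nodata.
#' @export
thresholdClass <- function(prob, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  out <- matrix(NA_integer_, nrow(prob), ncol(prob))
  ok <- !is.na(prob)
  out[ok] <- as.integer(prob[ok] >= threshold)
  out
}

setMethod("show", "TrainedCoralClassifier", function(object) {
  cat(sprintf("TrainedCoralClassifier (RBF SVM), sites: %s\n",
              paste(object@sites, collapse = "+")))
  cat(sprintf("  gamma = %g, cost = %g, CV accuracy = %.4f, features: %s\n",
              object@gamma, object@cost, object@cvAccuracy,
              paste(object@features, collapse = ", ")))
})
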