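# Simulator benthic class -> visual-census percent-cover category.
.CLASS2CAT <- c(coral = "coral", sand = "sand", algae = "seaweed",
                rubble = "rubble", seagrass = "seagrass")

#' Sample a ground-truth percent-cover table from a truth map
#'
#' Emulates a diver visual-census survey: draws pixel positions from the
#' usable water area of a simulated truth map and emits one percent-cover
#' row per position over the categories Sand, Rock, Mud, Rubble, Coral,
#' Seagrass, Seaweed.  The category matching the pixel's true bottom class
#' is dominant (share drawn in 60--90\%), the remainder is split between
#' two other categories, and every row sums to exactly 100.  When
#' \code{coralFraction} is given, \code{round(n * coralFraction)} positions
#' are drawn from coral pixels and the rest from non-coral pixels, so the
#' class mix matches the requested fraction.
#'
#' @param truth character matrix of benthic classes (NA = not surveyable).
#' @param n number of observation points.
#' @param site site identifier stored in the table.
#' @param coralFraction optional target coral fraction of the points.
#' @param seed integer seed; the same seed reproduces the table exactly.
#' @param validMask optional logical matrix restricting candidate pixels
#'   (e.g. to pixels with valid depth-invariant indices).
#' @return a data.frame with columns \code{row}, \code{col} (1-based raster
#'   indices), \code{site}, and the seven percent-cover categories.  The
#'   CSV serialization (\code{\link{writeGroundTruth}}) uses 0-based
#'   indices.
#' @export
sampleGroundTruth <- function(truth, n, site = "site1", coralFraction = NULL,
                              seed = 1L, validMask = NULL) {
  cand <- !is.na(truth)
  if (!is.null(validMask)) cand <- cand & validMask
  if (!any(cand)) stop("empty water mask: no candidate pixels to survey")
  set.seed(as.integer(seed))
  idx <- which(cand)
  if (is.null(coralFraction)) {
    if (n > length(idx))
      stop(sprintf("requested %d points but only %d candidate pixels", n, length(idx)))
    pick <- sample(idx, n)
  } else {
    nCoral <- round(n * coralFraction)
    coralIdx <- idx[truth[idx] == "coral"]
    otherIdx <- idx[truth[idx] != "coral"]
    if (nCoral > length(coralIdx))
      stop(sprintf("requested %d coral points but only %d coral pixels available",
                   nCoral, length(coralIdx)))
    if (n - nCoral > length(otherIdx))
      stop(sprintf("requested %d non-coral points but only %d available",
                   n - nCoral, length(otherIdx)))
    pick <- c(sample(coralIdx, nCoral),
              if (n - nCoral > 0) sample(otherIdx, n - nCoral))
  }
  nr <- nrow(truth)
  rows <- (pick - 1L) %% nr + 1L
  cols <- (pick - 1L) %/% nr + 1L
  cover <- matrix(0L, length(pick), length(.GT_CATEGORIES),
                  dimnames = list(NULL, .GT_CATEGORIES))
  domCat <- .CLASS2CAT[truth[pick]]
  for (i in seq_along(pick)) {
    d <- sample(60:90, 1L)
    minors <- sample(setdiff(.GT_CATEGORIES, domCat[i]), 2L)
    m1 <- sample(0:(100L - d), 1L)
    cover[i, domCat[i]] <- d
    cover[i, minors[1]] <- m1
    cover[i, minors[2]] <- 100L - d - m1
  }
  out <- data.frame(row = rows, col = cols, site = site, cover,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Binarize percent-cover ground truth to coral / non-coral labels
#'
#' Default rule: a point is coral when Coral is the plurality category
#' (a tie with another category counts as coral; documented tie-break).
#' Alternative rule \code{"threshold"}: coral when the Coral percentage is
#' at least \code{threshold}.
#'
#' @param gt a ground-truth data.frame (see \code{\link{sampleGroundTruth}}).
#' @param rule "plurality" (default) or "threshold".
#' @param threshold percent threshold for the threshold rule (default 50).
#' @return factor with levels \code{c("coral", "noncoral")}.
#' @export
binarizeGroundTruth <- function(gt, rule = c("plurality", "threshold"),
                                threshold = 50) {
  rule <- match.arg(rule)
  cover <- as.matrix(gt[, .GT_CATEGORIES])
  if (any(rowSums(cover) == 0))
    stop("all-zero percent-cover row: cannot assign a class")
  coral <- cover[, "coral"]
  isCoral <- switch(rule,
    plurality = coral >= apply(cover[, setdiff(.GT_CATEGORIES, "coral"),
                                     drop = FALSE], 1, max),
    threshold = coral >= threshold)
  factor(ifelse(isCoral, "coral", "noncoral"), levels = c("coral", "noncoral"))
}
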