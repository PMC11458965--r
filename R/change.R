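#' Per-pixel two-epoch transition raster
#'
#' Compares two aligned binary class rasters pixel by pixel.  A pixel is
#' invalid (code 0) wherever either epoch is nodata or the shared validity
#' mask is FALSE; valid pixels are partitioned into coral->coral (1),
#' coral->non (2), non->coral (3) and non->non (4).
#'
#' @param class0,class1 integer matrices (1 = coral, 0 = non-coral, NA =
#'   nodata) for the initial and final epoch.
#' @param valid optional logical matrix; FALSE forces invalid.
#' @param pixelSize pixel edge length in metres (default 30).
#' @return a \linkS4class{ChangeRaster}.
#' @export
perPixelChange <- function(class0, class1, valid = NULL, pixelSize = 30) {
  if (!identical(dim(class0), dim(class1)))
    stop("epoch rasters are not aligned (dimension mismatch)")
  ok <- !is.na(class0) & !is.na(class1)
  if (!is.null(valid)) {
    if (!identical(dim(valid), dim(class0)))
      stop("validity mask is not aligned with the class rasters")
    ok <- ok & valid
  }
  codes <- matrix(0L, nrow(class0), ncol(class0))
  c0 <- class0 == 1L; c1 <- class1 == 1L
  codes[ok & c0 & c1] <- 1L
  codes[ok & c0 & !c1] <- 2L
  codes[ok & !c0 & c1] <- 3L
  codes[ok & !c0 & !c1] <- 4L
  new("ChangeRaster", codes = codes, pixelSize = pixelSize)
}

#' Convert a pixel count to area in square kilometres
#'
#' \code{count * pixelSize^2 / 1e6}, rounded to 2 decimals for reporting
#' (e.g. 147,014 Landsat pixels at 30 m are 132.31 km^2).
#'
#' @param count pixel count, >= 0.
#' @param pixelSizeM pixel edge in metres (default 30).
#' @return area in km^2, 2 decimals.
#' @export
areaFromPixels <- function(count, pixelSizeM = 30) {
  if (any(count < 0)) stop("pixel count must be >= 0")
  round(count * pixelSizeM^2 / 1e6, 2)
}

#' Coral-cover change report from summary counts
#'
#' The paper-style accounting: initial/final coral areas (km^2, 2 dp),
#' percent change in coral cover \eqn{(initial - final)/initial \times 100}
#' (1 dp, NA when there was no initial coral), and the coral share of the
#' valid shallow benthic area per epoch (percent, 1 dp).
#'
#' @param initialCoral,finalCoral coral pixel counts per epoch.
#' @param nValid valid shallow-water pixel count shared by both epochs
#'   (NA when unknown).
#' @param pixelSize pixel edge in metres.
#' @param counts optional named transition counts to retain.
#' @return a \linkS4class{ChangeReport}.
#' @export
changeReportFromCounts <- function(initialCoral, finalCoral, nValid = NA_real_,
                                   pixelSize = 30,
                                   counts = c(coralToCoral = NA_real_,
                                              coralToNon = NA_real_,
                                              nonToCoral = NA_real_,
                                              nonToNon = NA_real_)) {
  pct <- if (initialCoral == 0) NA_real_ else
    round((initialCoral - finalCoral) / initialCoral * 100, 1)
  share <- function(x) if (is.na(nValid) || nValid == 0) NA_real_ else
    round(x / nValid * 100, 1)
  new("ChangeReport", counts = counts,
      initialCoral = initialCoral, finalCoral = finalCoral, nValid = nValid,
      initialAreaKm2 = areaFromPixels(initialCoral, pixelSize),
      finalAreaKm2 = areaFromPixels(finalCoral, pixelSize),
      percentChange = pct, initialSharePct = share(initialCoral),
      finalSharePct = share(finalCoral), pixelSize = pixelSize)
}

#' Summarize a transition raster into a change report
#'
#' Counts the transition categories (they partition the valid pixels), and
#' derives the coral-cover accounting: the initial coral count is
#' coral->coral + coral->non, the final count coral->coral + non->coral.
#'
#' @param change a \linkS4class{ChangeRaster}.
#' @return a \linkS4class{ChangeReport}.
#' @export
changeSummary <- function(change) {
  tab <- tabulate(change@codes + 1L, nbins = 5L)
  counts <- c(coralToCoral = tab[2], coralToNon = tab[3],
              nonToCoral = tab[4], nonToNon = tab[5])
  changeReportFromCounts(initialCoral = counts[["coralToCoral"]] +
                           counts[["coralToNon"]],
                         finalCoral = counts[["coralToCoral"]] +
                           counts[["nonToCoral"]],
                         nValid = sum(tab[2:5]), pixelSize = change@pixelSize,
                         counts = counts)
}

setMethod("show", "ChangeReport", function(object) {
  cat("Coral-cover change report\n")
  if (!anyNA(object@counts))
    cat(sprintf("  transitions: coral->coral %d, coral->non %d, non->coral %d, non->non %d\n",
                object@counts[["coralToCoral"]], object@counts[["coralToNon"]],
                object@counts[["nonToCoral"]], object@counts[["nonToNon"]]))
  cat(sprintf("  coral pixels: %s -> %s  (%.2f -> %.2f km^2 at %g m)\n",
              format(object@initialCoral, big.mark = ","),
              format(object@finalCoral, big.mark = ","),
              object@initialAreaKm2, object@finalAreaKm2, object@pixelSize))
  cat(sprintf("  change in coral cover: %.1f%%\n", object@percentChange))
  if (!is.na(object@initialSharePct))
    cat(sprintf("  coral share of shallow benthic area: %.1f%% -> %.1f%%\n",
                object@initialSharePct, object@finalSharePct))
})

#' Serialize a change report to a plain list
#'
#' @param x a \linkS4class{ChangeReport}.
#' @return named list suitable for JSON output.
#' @export
changeReportAsList <- function(x) {
  list(counts = as.list(x@counts),
       initial_coral_pixels = x@initialCoral,
       final_coral_pixels = x@finalCoral,
       n_valid_pixels = x@nValid,
       initial_area_km2 = x@initialAreaKm2,
       final_area_km2 = x@finalAreaKm2,
       percent_change = x@percentChange,
       initial_share_pct = x@initialSharePct,
       final_share_pct = x@finalSharePct,
       pixel_size_m = x@pixelSize)
}
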