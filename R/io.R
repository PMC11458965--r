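#' Write and read single-band rasters as ESRI ASCII grids
#'
#' Plain-text georeferenced raster interchange: a 6-line header (ncols,
#' nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed by rows of
#' values from the top row down.  Used to persist masks, class maps,
#' probability maps and truth maps without binary formats.
#'
#' @param x numeric/integer/logical matrix (NA written as nodata).
#' @param path file path.
#' @param xll,yll lower-left corner coordinates.
#' @param cellsize pixel edge length (metres).
#' @param nodata nodata sentinel value.
#' @return \code{writeAsciiGrid}: the path, invisibly.
#'   \code{readAsciiGrid}: a numeric matrix with attributes \code{xll},
#'   \code{yll}, \code{cellsize}.
#' @export
writeAsciiGrid <- function(x, path, xll = 0, yll = 0, cellsize = 30,
                           nodata = -9999) {
  m <- x
  mode(m) <- "numeric"
  m[is.na(m)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(m)), sprintf("nrows %d", nrow(m)),
           sprintf("xllcorner %.10g", xll), sprintf("yllcorner %.10g", yll),
           sprintf("cellsize %.10g", cellsize),
           sprintf("NODATA_value %.10g", nodata))
  body <- apply(m, 1, function(r) paste(format(r, trim = TRUE, digits = 10),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname writeAsciiGrid
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  vals <- stats::setNames(as.numeric(vapply(hdr, `[`, character(1), 2)),
                          vapply(hdr, `[`, character(1), 1))
  m <- do.call(rbind, lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  m[m == vals[["nodata_value"]]] <- NA
  structure(m, xll = vals[["xllcorner"]], yll = vals[["yllcorner"]],
            cellsize = vals[["cellsize"]])
}

#' Persist a scene as per-band ASCII grids
#'
#' Writes one grid per radiance band (\code{<prefix>_<band>.asc}) and the
#' quality band (\code{<prefix>_QA.asc}).
#'
#' @param scene a \linkS4class{Scene}.
#' @param prefix output path prefix.
#' @return character vector of written paths, invisibly.
#' @export
writeScene <- function(scene, prefix) {
  ps <- scene@geotransform[2]
  paths <- c(vapply(dimnames(scene@bands)[[3]], function(b) {
    p <- sprintf("%s_%s.asc", prefix, b)
    writeAsciiGrid(scene@bands[, , b], p, cellsize = ps,
                   nodata = scene@nodata)
    p
  }, character(1)),
  QA = writeAsciiGrid(scene@quality, sprintf("%s_QA.asc", prefix),
                      cellsize = ps, nodata = scene@nodata))
  invisible(paths)
}

#' Write and read ground-truth tables as CSV
#'
#' The CSV contract uses 0-based raster indices and the header
#' \code{row,col,site,sand,rock,mud,rubble,coral,seagrass,seaweed}; the
#' in-memory data.frame uses R's 1-based indices, and the reader/writer
#' convert.
#'
#' @param gt ground-truth data.frame (1-based positions).
#' @param path CSV file path.
#' @return \code{readGroundTruth}: the table with 1-based positions.
#' @export
writeGroundTruth <- function(gt, path) {
  out <- gt
  out$row <- out$row - 1L
  out$col <- out$col - 1L
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  gt <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("row", "col", "site", .GT_CATEGORIES)
  if (!all(need %in% names(gt)))
    stop("ground-truth CSV lacks required columns: ",
         paste(setdiff(need, names(gt)), collapse = ", "))
  gt$row <- gt$row + 1L
  gt$col <- gt$col + 1L
  gt
}

#' Write a pipeline run report as JSON
#'
#' Serializes the metric and change components of a protocol run (models
#' and rasters are omitted) with a provenance block sufficient to
#' reproduce the run.
#'
#' @param result a list from \code{\link{runSingleSite}} or the other
#'   protocol drivers.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
writeRunReport <- function(result, path) {
  out <- list()
  if (!is.null(result$metrics)) out$metrics <- metricsAsList(result$metrics)
  if (!is.null(result$confusion))
    out$confusion <- list(tp = result$confusion@tp, fn = result$confusion@fn,
                          fp = result$confusion@fp, tn = result$confusion@tn)
  if (!is.null(result$roc)) out$auc <- round(result$roc@auc, 4)
  if (!is.null(result$change)) out$change <- changeReportAsList(result$change)
  if (!is.null(result$provenance)) out$provenance <- result$provenance
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
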