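#' Read and write categorical rasters
#'
#' Rasters travel as single-band integer Esri ASCII grids (`.asc`): a
#' six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by rows of codes from the top row down. The CRS
#' tag is carried in a `.prj` sidecar next to the raster. The pair
#' round-trips codes, nodata and the full [GridSpec-class] losslessly.
#'
#' `readGrid` rejects rasters with non-integer cell values
#' (`ee_unsupported_raster`) and headers without a `NODATA_value`
#' (`ee_missing_nodata`): categorical accounting on a float or nodata-less
#' grid would be silently wrong.
#'
#' @param grid a [CategoricalGrid-class].
#' @param path file path (conventionally `.asc`).
#' @return `readGrid`: a [CategoricalGrid-class]. `writeGrid`: `path`,
#'   invisibly.
#' @examples
#' g <- CategoricalGrid(matrix(1:4, 2, 2))
#' f <- tempfile(fileext = ".asc")
#' writeGrid(g, f)
#' identical(gridCodes(readGrid(f)), gridCodes(g))
#' @name grid-io
NULL

prjPath <- function(path) paste0(sub("\\.[A-Za-z0-9]+$", "", path), ".prj")

#' @rdname grid-io
#' @export
writeGrid <- function(grid, path) {
  spec <- gridSpec(grid)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", spec@nCols),
    sprintf("nrows %d", spec@nRows),
    sprintf("xllcorner %.10g", spec@xmin),
    sprintf("yllcorner %.10g", spec@ymax - spec@nRows * spec@cellSize),
    sprintf("cellsize %.10g", spec@cellSize),
    sprintf("NODATA_value %d", spec@nodata)
  ), con)
  utils::write.table(gridCodes(grid), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(spec@crs, prjPath(path))
  invisible(path)
}

#' @rdname grid-io
#' @export
readGrid <- function(path) {
  lines <- readLines(path, n = 6L)
  kv <- strsplit(trimws(lines), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- vapply(kv, `[`, "", 2L)
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% keys))
    eeStop("ee_unsupported_raster",
           paste("not an ASCII grid header:", path))
  if (!"nodata_value" %in% keys)
    eeStop("ee_missing_nodata",
           paste("raster header declares no NODATA_value:", path))
  nCols <- as.integer(vals[["ncols"]])
  nRows <- as.integer(vals[["nrows"]])
  cellSize <- as.numeric(vals[["cellsize"]])
  nodata <- as.numeric(vals[["nodata_value"]])
  if (nodata != as.integer(nodata))
    eeStop("ee_unsupported_raster", "non-integer NODATA_value")
  body <- scan(path, what = numeric(), skip = 6L, quiet = TRUE)
  if (length(body) != nRows * nCols)
    eeStop("ee_unsupported_raster",
           sprintf("expected %d cells, found %d", nRows * nCols, length(body)))
  if (any(body != floor(body)))
    eeStop("ee_unsupported_raster",
           "float-valued raster; categorical grids must be integer-coded")
  crs <- if (file.exists(prjPath(path))) readLines(prjPath(path), n = 1L)
         else "local-equal-area"
  spec <- GridSpec(nRows, nCols, cellSize = cellSize,
                   xmin = as.numeric(vals[["xllcorner"]]),
                   ymax = as.numeric(vals[["yllcorner"]]) + nRows * cellSize,
                   crs = crs, nodata = as.integer(nodata))
  CategoricalGrid(matrix(as.integer(body), nRows, nCols, byrow = TRUE), spec)
}

# deterministic CSV writer used for every tabular output: fixed options so
# identical inputs give byte-identical files, and doubles at 17 significant
# digits so values round-trip through read.csv bit for bit
writeTableCsv <- function(df, path) {
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, eol = "\n",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Run the full accounting pipeline
#'
#' Ties the stages together in the fixed order fuse -> overlay ->
#' tabulate -> loss -> protection -> reporting, and writes a
#' self-describing run directory: the current-extent raster, per-type loss
#' and protection CSVs, class-by-bin count matrices, paint-by-type rasters
#' with legend CSVs, the echoed configuration and a log with package
#' version, seed and output checksums. Re-running with the same inputs
#' reproduces every CSV byte for byte.
#'
#' @param potential potential-distribution [CategoricalGrid-class], or the
#'   path of an ASCII raster.
#' @param products list of land-cover products in precedence order, each a
#'   list with `grid` (a composite-class or product-legend grid, or path),
#'   optional `crosswalk` (applied when given), optional `resampleFactor`
#'   (majority-resampled when > 1), optional `mask` (valid-extent grid or
#'   path). Alternatively pass a ready composite grid via `composite`.
#' @param hierarchy a [Hierarchy-class] or CSV path; leaves must cover the
#'   natural types on the potential map.
#' @param paMask protection mask grid or path, or a polygon list to
#'   rasterize (see [rasterizeProtection()]).
#' @param outDir run directory to create (optional: results are always
#'   returned).
#' @param composite pre-fused composite layer (alternative to `products`).
#' @param lossScheme,protScheme bin schemes (see [lossBins()],
#'   [protectionBins()]).
#' @param strictA3 closure of the criterion-A3 thresholds (see [rleA3()]).
#' @param groupLevel hierarchy level for the count matrices.
#' @param seed recorded in the log for provenance (the pipeline itself is
#'   deterministic).
#' @return invisible list with `current`, `lossTable`, `protectionTable`,
#'   `lossCounts`, `protectionCounts`, `potentialAreas`, `currentAreas`,
#'   `paint` (loss and protection paint grids + legends).
#' @examples
#' land <- simulateLandscape(simConfig(nRows = 30, nCols = 30, nTypes = 4))
#' res <- runPipeline(land$potential, composite = land$composite,
#'                    hierarchy = land$hierarchy, paMask = land$mask)
#' head(res$lossTable)
#' @export
runPipeline <- function(potential, products = NULL, hierarchy, paMask,
                        outDir = NULL, composite = NULL,
                        lossScheme = lossBins(), protScheme = protectionBins(),
                        strictA3 = TRUE, groupLevel = 1L, seed = NA_integer_) {
  asGrid <- function(x) if (is.character(x)) readGrid(x) else x
  potential <- asGrid(potential)
  if (is.character(hierarchy)) hierarchy <- loadHierarchy(hierarchy)
  if (is.null(composite)) {
    if (is.null(products) || !length(products))
      eeStop("ee_bad_argument", "supply either products or a composite layer")
    layers <- list(); masks <- list()
    for (i in seq_along(products)) {
      p <- products[[i]]
      g <- asGrid(p$grid)
      if (!is.null(p$crosswalk)) {
        xw <- if (is.character(p$crosswalk)) loadCrosswalk(p$crosswalk)
              else p$crosswalk
        g <- applyCrosswalk(g, xw)
      }
      if (!is.null(p$resampleFactor) && p$resampleFactor > 1L)
        g <- majorityResample(g, p$resampleFactor)
      stray <- setdiff(unique(as.vector(gridCodes(g))),
                       c(compositeClasses(), nodataValue(g)))
      if (length(stray))
        eeStop("ee_unmapped_class_code",
               sprintf("product %d is not in composite-class codes (is its crosswalk missing?): %s",
                       i, paste(utils::head(sort(stray), 10), collapse = ", ")))
      layers[[i]] <- g
      masks[i] <- list(if (is.null(p$mask)) NULL else asGrid(p$mask))
    }
    composite <- fuse(layers, masks)
  } else {
    composite <- asGrid(composite)
  }
  if (is.list(paMask) && !is(paMask, "CategoricalGrid"))
    paMask <- rasterizeProtection(paMask, gridSpec(potential))
  else paMask <- asGrid(paMask)

  current <- overlayCurrent(potential, composite)
  potAreas <- tabulateArea(potential)
  potAreas <- potAreas[potAreas$code < 9000L, , drop = FALSE]
  curAreas <- tabulateArea(current)
  curNatural <- curAreas[curAreas$code < 9000L, , drop = FALSE]
  lossTab <- computeLoss(potAreas, curNatural, scheme = lossScheme,
                         strict = strictA3)
  protAreas <- protectedAreasByType(current, paMask)
  protTab <- protectionRepresentation(protAreas, potAreas, curNatural,
                            scheme = protScheme)
  lossCounts <- categoryCounts(lossTab, hierarchy, groupLevel,
                               label = "loss_class")
  protCounts <- categoryCounts(protTab, hierarchy, groupLevel,
                               label = "protection_class")
  lossPaint <- withCallingHandlers(
    paintByType(potential,
                stats::setNames(lossTab$loss_fraction, lossTab$type_code),
                lossScheme),
    ee_missing_value = function(w) invokeRestart("muffleWarning"))
  protPaint <- withCallingHandlers(
    paintByType(potential,
                stats::setNames(protTab$pct_of_potential, protTab$type_code),
                protScheme),
    ee_missing_value = function(w) invokeRestart("muffleWarning"))

  res <- list(current = current, lossTable = lossTab,
              protectionTable = protTab, lossCounts = lossCounts,
              protectionCounts = protCounts,
              potentialAreas = potAreas, currentAreas = curAreas,
              paint = list(loss = lossPaint, protection = protPaint))

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeGrid(current, file.path(outDir, "current.asc"))
    writeTableCsv(potAreas, file.path(outDir, "potential_areas.csv"))
    writeTableCsv(curAreas, file.path(outDir, "current_areas.csv"))
    writeTableCsv(lossTab, file.path(outDir, "loss.csv"))
    writeTableCsv(protTab, file.path(outDir, "protection.csv"))
    writeCountsCsv(lossCounts, file.path(outDir, "loss_counts.csv"))
    writeCountsCsv(protCounts, file.path(outDir, "protection_counts.csv"))
    writeGrid(lossPaint$grid, file.path(outDir, "loss_paint.asc"))
    writeTableCsv(lossPaint$legend, file.path(outDir, "loss_paint_legend.csv"))
    writeGrid(protPaint$grid, file.path(outDir, "protection_paint.asc"))
    writeTableCsv(protPaint$legend,
                  file.path(outDir, "protection_paint_legend.csv"))
    csvs <- list.files(outDir, pattern = "\\.csv$", full.names = TRUE)
    log <- c(
      sprintf("ecoextent %s", as.character(utils::packageVersion("ecoextent"))),
      sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
      sprintf("seed %s", seed),
      sprintf("stages fuse,overlay,tabulate,loss,protection,reporting"),
      sprintf("md5 %s %s", basename(csvs), tools::md5sum(csvs))
    )
    writeLines(log, file.path(outDir, "log.txt"))
  }
  invisible(res)
}

writeCountsCsv <- function(m, path) {
  df <- data.frame(class = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  writeTableCsv(df, path)
}
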