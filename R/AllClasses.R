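#' Grid geometry of a categorical raster
#'
#' A `GridSpec` carries the lattice geometry shared by every raster layer in
#' an analysis: dimensions, cell size in metres, the projected coordinate of
#' the upper-left corner, a free-text CRS tag, and the reserved nodata code.
#' The coordinate convention is row-major from the upper-left, with the
#' centre of cell (row i, col j) at
#' `(xmin + (j - 0.5) * cellSize, ymax - (i - 0.5) * cellSize)`.
#'
#' Areas are derived from `cellSize` alone, which is only meaningful in an
#' equal-area projection; see [isEqualAreaCrs()] and [tabulateArea()].
#'
#' @slot nRows,nCols lattice dimensions.
#' @slot cellSize cell edge length in metres (the continental analyses this
#'   mirrors worked at 270-450 m).
#' @slot xmin,ymax projected coordinates of the upper-left corner.
#' @slot crs free-text tag of the coordinate reference system.
#' @slot nodata integer code reserved for missing cells; must not collide
#'   with any legend code.
#' @seealso [GridSpec()], [CategoricalGrid-class]
#' @exportClass GridSpec
setClass("GridSpec",
  slots = c(
    nRows = "integer", nCols = "integer",
    cellSize = "numeric",
    xmin = "numeric", ymax = "numeric",
    crs = "character", nodata = "integer"
  )
)

setValidity("GridSpec", function(object) {
  msgs <- character()
  if (object@nRows < 1L || object@nCols < 1L)
    msgs <- c(msgs, "nRows and nCols must be >= 1")
  if (!is.finite(object@cellSize) || object@cellSize <= 0)
    msgs <- c(msgs, "cellSize must be a positive number of metres")
  if (length(object@nodata) != 1L || is.na(object@nodata))
    msgs <- c(msgs, "nodata must be a single non-NA integer")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GridSpec
#'
#' @param nRows,nCols lattice dimensions.
#' @param cellSize cell edge length in metres. Default 270, the common grain
#'   of fused land-cover composites.
#' @param xmin,ymax projected upper-left corner coordinates.
#' @param crs free-text CRS tag. The default `"local-equal-area"` declares an
#'   equal-area projection, which area tabulation requires.
#' @param nodata reserved missing-data code.
#' @return a [GridSpec-class] object.
#' @examples
#' GridSpec(100, 100)
#' @export
GridSpec <- function(nRows, nCols, cellSize = 270, xmin = 0, ymax = NULL,
                     crs = "local-equal-area", nodata = -9999L) {
  nRows <- stopifnotScalarCount(nRows, "nRows")
  nCols <- stopifnotScalarCount(nCols, "nCols")
  if (is.null(ymax)) ymax <- nRows * cellSize
  new("GridSpec",
    nRows = nRows, nCols = nCols, cellSize = as.numeric(cellSize),
    xmin = as.numeric(xmin), ymax = as.numeric(ymax),
    crs = as.character(crs), nodata = as.integer(nodata)
  )
}

#' Integer-coded categorical raster
#'
#' The carrier for every map layer in the pipeline: potential ecosystem
#' types, composite land-conversion classes, current extent, and
#' protected-area masks. Cell values are integer legend codes or the
#' `GridSpec` nodata code; there is no notion of continuous values.
#'
#' @slot spec the shared [GridSpec-class].
#' @slot codes integer matrix, `nRows x nCols`, row 1 = northernmost row.
#' @seealso [CategoricalGrid()], [readGrid()], [writeGrid()]
#' @exportClass CategoricalGrid
setClass("CategoricalGrid",
  slots = c(spec = "GridSpec", codes = "matrix")
)

setValidity("CategoricalGrid", function(object) {
  msgs <- character()
  if (!is.integer(object@codes))
    msgs <- c(msgs, "codes must be an integer matrix")
  if (!identical(dim(object@codes),
                 c(object@spec@nRows, object@spec@nCols)))
    msgs <- c(msgs, "codes dimensions must match the GridSpec")
  if (anyNA(object@codes))
    msgs <- c(msgs, "missing cells must carry the nodata code, not NA")
  if (length(msgs)) msgs else TRUE
})

#' Construct a CategoricalGrid
#'
#' @param codes integer matrix of legend codes (row 1 is the top row).
#' @param spec a [GridSpec-class]; defaults to a spec matching the matrix
#'   dimensions at 270 m.
#' @return a [CategoricalGrid-class].
#' @examples
#' g <- CategoricalGrid(matrix(1:4, 2, 2))
#' gridCodes(g)
#' @export
CategoricalGrid <- function(codes, spec = NULL) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (is.null(spec)) spec <- GridSpec(nrow(codes), ncol(codes))
  new("CategoricalGrid", spec = spec, codes = codes)
}

# ---- accessors ----

#' Accessors for raster containers
#'
#' `gridSpec` returns the geometry, `gridCodes` the integer code matrix,
#' `nodataValue` the reserved missing code, and `cellAreaKm2` the area of one
#' cell in square kilometres.
#'
#' @param x a [CategoricalGrid-class] (or [GridSpec-class] where geometry
#'   alone suffices).
#' @return see individual descriptions.
#' @name grid-accessors
NULL

#' @rdname grid-accessors
#' @export
gridSpec <- function(x) {
  if (is(x, "GridSpec")) x else x@spec
}

#' @rdname grid-accessors
#' @export
gridCodes <- function(x) x@codes

#' @rdname grid-accessors
#' @export
nodataValue <- function(x) gridSpec(x)@nodata

#' @rdname grid-accessors
#' @export
cellAreaKm2 <- function(x) (gridSpec(x)@cellSize / 1000)^2

#' @rdname grid-accessors
#' @export
gridDim <- function(x) {
  s <- gridSpec(x)
  c(nRows = s@nRows, nCols = s@nCols)
}

#' Cell-centre coordinates
#'
#' Projected coordinates of every cell centre, in row-major order from the
#' upper-left (the package-wide convention).
#'
#' @param spec a [GridSpec-class].
#' @return a list with numeric matrices `x` and `y`, each `nRows x nCols`.
#' @export
cellCenters <- function(spec) {
  spec <- gridSpec(spec)
  cols <- seq_len(spec@nCols)
  rows <- seq_len(spec@nRows)
  x <- matrix(spec@xmin + (cols - 0.5) * spec@cellSize,
              spec@nRows, spec@nCols, byrow = TRUE)
  y <- matrix(spec@ymax - (rows - 0.5) * spec@cellSize,
              spec@nRows, spec@nCols)
  list(x = x, y = y)
}

#' Is a CRS tag declared equal-area?
#'
#' Area tabulation multiplies cell counts by a constant cell area, which is
#' only valid in an equal-area projection. A tag counts as equal-area when it
#' contains `"equal-area"` or names a standard equal-area family (Albers
#' `aea`, Lambert azimuthal `laea`, cylindrical `cea`, Mollweide, Eckert,
#' sinusoidal).
#'
#' @param crs character CRS tag (or an object with a [gridSpec()]).
#' @return logical scalar.
#' @export
isEqualAreaCrs <- function(crs) {
  if (!is.character(crs)) crs <- gridSpec(crs)@crs
  grepl("equal-area|equal_area|\\baea\\b|\\blaea\\b|\\bcea\\b|mollweide|eckert|sinusoidal",
        tolower(crs))
}

sameGridSpec <- function(a, b) {
  a <- gridSpec(a); b <- gridSpec(b)
  isTRUE(all.equal(a@cellSize, b@cellSize)) &&
    a@nRows == b@nRows && a@nCols == b@nCols &&
    isTRUE(all.equal(a@xmin, b@xmin)) && isTRUE(all.equal(a@ymax, b@ymax))
}

checkSameGridSpec <- function(a, b, what = "layers") {
  if (!sameGridSpec(a, b))
    eeStop("ee_gridspec_mismatch",
           sprintf("%s do not share one grid geometry", what))
  invisible(TRUE)
}

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d cells, %.0f m, UL (%.1f, %.1f), crs '%s', nodata %d\n",
              object@nRows, object@nCols, object@cellSize,
              object@xmin, object@ymax, object@crs, object@nodata))
})

setMethod("show", "CategoricalGrid", function(object) {
  v <- object@codes[object@codes != object@spec@nodata]
  cat(sprintf("CategoricalGrid: %d x %d cells (%.0f m), %d legend code(s)\n",
              object@spec@nRows, object@spec@nCols, object@spec@cellSize,
              length(unique(v))))
  if (length(v)) {
    u <- sort(unique(v))
    cat("  codes:", paste(utils::head(u, 12), collapse = " "),
        if (length(u) > 12) "..." else "", "\n")
  }
})
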