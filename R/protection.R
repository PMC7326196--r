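#' Protected-area mask codes
#'
#' A protection mask is a [CategoricalGrid-class] over `{0 = UNPROTECTED,
#' 1 = PROTECTED, nodata}`. IUCN management categories I-VI are dissolved
#' into the single PROTECTED state: the analysis documents representation
#' within any category, not differential levels of protection.
#'
#' @return named integer vector `c(UNPROTECTED = 0, PROTECTED = 1)`.
#' @export
maskCodes <- function() c(UNPROTECTED = 0L, PROTECTED = 1L)

#' Build a rectangle polygon
#'
#' Convenience constructor for axis-aligned protected-area polygons in
#' projected coordinates.
#'
#' @param xmin,xmax,ymin,ymax rectangle bounds.
#' @param category IUCN category label ("I".."VI").
#' @return a polygon: list with numeric `x`, `y` vertex vectors and
#'   `category`.
#' @export
rectPolygon <- function(xmin, xmax, ymin, ymax, category = "II") {
  list(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax),
       category = as.character(category))
}

# Even-odd (ray casting) point-in-polygon, vectorized over points.
# Points exactly on an edge follow the half-open crossing convention; cell
# centres in this package never coincide with integer-coordinate polygon
# edges because centres sit at half-cell offsets.
pointInPolygon <- function(px, py, vx, vy) {
  inside <- logical(length(px))
  j <- length(vx)
  for (i in seq_along(vx)) {
    denom <- vy[j] - vy[i]
    if (denom != 0) {
      crosses <- ((vy[i] > py) != (vy[j] > py)) &
        (px < (vx[j] - vx[i]) * (py - vy[i]) / denom + vx[i])
      inside <- xor(inside, crosses)
    }
    j <- i
  }
  inside
}

#' Rasterize protected-area polygons to a mask
#'
#' A cell is PROTECTED iff its centre lies inside the union of the selected
#' polygons (even-odd rule), so overlapping designations count once —
#' equivalent to dissolving the polygons first.
#'
#' @param polygons list of polygons (each a list with `x`, `y` vertex
#'   vectors and a `category` string; see [rectPolygon()]), in the grid's
#'   projection.
#' @param spec target [GridSpec-class].
#' @param categories IUCN categories to include; default all of I-VI.
#' @return a mask [CategoricalGrid-class] over [maskCodes()].
#' @examples
#' spec <- GridSpec(4, 4, cellSize = 100)
#' m <- rasterizeProtection(list(rectPolygon(0, 200, 200, 400)), spec)
#' sum(gridCodes(m) == 1L)  # 4 cells
#' @export
rasterizeProtection <- function(polygons, spec,
                                categories = c("I", "II", "III", "IV", "V", "VI")) {
  spec <- gridSpec(spec)
  keep <- vapply(polygons, function(p) {
    is.null(p$category) || p$category %in% categories
  }, logical(1))
  polygons <- polygons[keep]
  if (!length(polygons))
    eeStop("ee_empty_selection", "no polygons match the selected categories")
  ctr <- cellCenters(spec)
  px <- as.vector(ctr$x); py <- as.vector(ctr$y)
  inside <- logical(length(px))
  for (p in polygons)
    inside <- inside | pointInPolygon(px, py, p$x, p$y)
  CategoricalGrid(matrix(as.integer(inside), spec@nRows, spec@nCols), spec)
}

#' Protected area per natural type on current extent
#'
#' Tabulates, for each natural ecosystem type, the area of cells that both
#' carry that type in the current-extent grid and fall inside the protection
#' mask. Converted cells (land-use codes >= 9000) contribute to no type;
#' converted area inside protected lands is available separately via
#' [protectedConvertedArea()].
#'
#' @param current current-extent [CategoricalGrid-class] (from
#'   [overlayCurrent()]).
#' @param mask a protection mask on the same geometry.
#' @return an [areaTable()] over the natural types present in `current`
#'   (zero rows for unprotected types included).
#' @export
protectedAreasByType <- function(current, mask) {
  checkSameGridSpec(current, mask, "current extent and protection mask")
  nd <- nodataValue(current)
  cc <- gridCodes(current)
  mm <- gridCodes(mask)
  natural <- cc != nd & cc < 9000L
  types <- sort(unique(cc[natural]))
  sel <- natural & mm == maskCodes()[["PROTECTED"]]
  if (!any(sel)) return(areaTable(types, numeric(length(types))))
  counts <- table(factor(cc[sel], levels = types))
  areaTable(types, as.numeric(counts) * cellAreaKm2(current))
}

#' @rdname protectedAreasByType
#' @return `protectedConvertedArea`: a one-row data.frame with the km2 of
#'   converted (land-use) cells inside the mask.
#' @export
protectedConvertedArea <- function(current, mask) {
  checkSameGridSpec(current, mask, "current extent and protection mask")
  nd <- nodataValue(current)
  cc <- gridCodes(current)
  mm <- gridCodes(mask)
  n <- sum(cc != nd & cc >= 9000L & mm == maskCodes()[["PROTECTED"]])
  data.frame(protected_converted_km2 = n * cellAreaKm2(current))
}

#' Per-type protected-area representation records
#'
#' Joins protected, potential and current natural areas into gap-analysis
#' records: percent of potential extent protected (the headline Aichi
#' Target 11 framing), percent of current extent protected (the
#' conventional gap-analysis figure), the protection-class bin, and the 17%
#' target flags. `meets_17` keys on percent of potential;
#' `meets_17_current` is the same flag on percent of current, emitted for
#' comparison.
#'
#' @param protected [areaTable()] from [protectedAreasByType()].
#' @param potential,current [areaTable()]s of potential and current natural
#'   extent.
#' @param scheme protection-bin scheme, see [protectionBins()].
#' @param target percent threshold for the target flags (default 17).
#' @param tol relative slack for the protected <= current check.
#' @return data.frame with columns `type_code`, `protected_km2`,
#'   `pct_of_potential`, `pct_of_current`, `protection_class`, `meets_17`,
#'   `meets_17_current`.
#' @examples
#' protectionRepresentation(areaTable(101, 17), areaTable(101, 100), areaTable(101, 50))
#' @export
protectionRepresentation <- function(protected, potential, current,
                           scheme = protectionBins(), target = 17, tol = 1e-9) {
  current <- current[current$code < 9000L, , drop = FALSE]
  pro <- protected$area_km2[match(potential$code, protected$code)]
  pro[is.na(pro)] <- 0
  cur <- current$area_km2[match(potential$code, current$code)]
  cur[is.na(cur)] <- 0
  pot <- potential$area_km2
  if (any(pro > cur * (1 + tol) + tol))
    eeStop("ee_protected_exceeds_current",
           "protected area exceeds current extent for some type; inputs misaligned")
  zero <- pot <= 0
  if (any(zero))
    eeWarn("ee_zero_potential_area",
           paste("dropping types with zero potential area:",
                 paste(potential$code[zero], collapse = ", ")))
  code <- potential$code[!zero]
  pot <- pot[!zero]; cur <- cur[!zero]; pro <- pmin(pro[!zero], pmax(cur[!zero], 0))
  pctPot <- 100 * pro / pot
  pctCur <- ifelse(cur > 0, 100 * pro / cur, ifelse(pro > 0, NA_real_, NA_real_))
  data.frame(
    type_code = code,
    protected_km2 = pro,
    pct_of_potential = pctPot,
    pct_of_current = pctCur,
    protection_class = classifyProtection(pctPot, scheme),
    meets_17 = pctPot >= target,
    meets_17_current = !is.na(pctCur) & pctCur >= target,
    stringsAsFactors = FALSE
  )
}
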