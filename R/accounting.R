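#' Derive current extent from potential extent and a conversion layer
#'
#' Where the composite conversion layer reports a land-use class, the
#' ecosystem type at that cell is presumed to have been converted: the cell
#' takes the land-use code. Where the composite reports `NONE` (or has no
#' information), the potential type code stands. Nodata propagates from the
#' potential map. Type codes must stay below the reserved land-use block
#' (>= 9000) so the two legends cannot collide.
#'
#' @param potential [CategoricalGrid-class] of ecosystem type codes.
#' @param composite [CategoricalGrid-class] of composite conversion classes
#'   on the same geometry.
#' @return [CategoricalGrid-class] of current extent: natural type codes
#'   where unconverted, land-use codes where converted.
#' @examples
#' pot <- CategoricalGrid(matrix(101L, 2, 2))
#' conv <- CategoricalGrid(matrix(c(0L, 9002L, 0L, 0L), 2, 2))
#' gridCodes(overlayCurrent(pot, conv))
#' @export
overlayCurrent <- function(potential, composite) {
  checkSameGridSpec(potential, composite, "potential and composite layers")
  nd <- nodataValue(potential)
  p <- gridCodes(potential)
  if (any(p != nd & p >= 9000L))
    eeStop("ee_code_range_collision",
           "potential type codes intrude on the reserved land-use block (>= 9000)")
  cc <- gridCodes(composite)
  ok <- cc %in% c(compositeClasses(), nodataValue(composite))
  if (!all(ok))
    eeStop("ee_code_range_collision",
           "composite layer contains codes outside the composite-class legend")
  out <- p
  converted <- p != nd & cc != nodataValue(composite) & cc != 0L
  out[converted] <- cc[converted]
  CategoricalGrid(out, gridSpec(potential))
}

#' Tabulate per-code area of a categorical grid
#'
#' Counts cells per legend code and converts to square kilometres as
#' `count * (cellSize/1000)^2`. Nodata cells are excluded. Because a
#' constant cell area is only meaningful in an equal-area projection, the
#' function refuses to tabulate a grid whose CRS tag is not declared
#' equal-area (see [isEqualAreaCrs()]) unless a per-cell area matrix is
#' supplied.
#'
#' @param grid a [CategoricalGrid-class].
#' @param cellAreasKm2 optional `nRows x nCols` numeric matrix of per-cell
#'   areas in km2, required for non-equal-area grids.
#' @return an [areaTable()]: columns `code`, `area_km2`, sorted by code.
#' @examples
#' g <- CategoricalGrid(matrix(c(7L, 7L, 8L, -9999L), 2, 2))
#' tabulateArea(g)  # 2 and 1 cells at 270 m
#' @export
tabulateArea <- function(grid, cellAreasKm2 = NULL) {
  spec <- gridSpec(grid)
  codes <- gridCodes(grid)
  keep <- codes != spec@nodata
  if (is.null(cellAreasKm2)) {
    if (!isEqualAreaCrs(spec@crs))
      eeStop("ee_not_equal_area",
             sprintf("crs '%s' is not declared equal-area; supply cellAreasKm2",
                     spec@crs))
    if (!any(keep)) return(areaTable(integer(0), numeric(0)))
    counts <- table(codes[keep])
    areaTable(as.integer(names(counts)), as.numeric(counts) * cellAreaKm2(spec))
  } else {
    if (!identical(dim(cellAreasKm2), dim(codes)))
      eeStop("ee_bad_argument", "cellAreasKm2 dimensions must match the grid")
    if (!any(keep)) return(areaTable(integer(0), numeric(0)))
    agg <- rowsum(as.vector(cellAreasKm2)[keep], group = as.vector(codes)[keep])
    areaTable(as.integer(rownames(agg)), agg[, 1])
  }
}

#' Binning schemes for loss and protection fractions
#'
#' A bin scheme partitions an interval into ordered, labelled bins
#' `[lo, hi)` with the top bin closed at the upper end. `lossBins()` returns
#' the long-term-loss schemes: the default `"results"` scheme
#' (<10%, 10-30%, 30-50%, 50-70%, 70-90%, >90%) and the `"figure"` variant
#' that splits the top bin at 95% (>95% loss down to <10%).
#' `protectionBins()` returns percent-of-extent-protected schemes whose cut
#' points include the 17% Aichi Target 11 threshold; the `"top50"` variant
#' merges everything above 50% into one top bin, the `"top70"` default keeps
#' 50-70% and >70% apart.
#'
#' @param variant which published reading of the bins to use.
#' @param breaks,labels,unit for `binScheme()`: explicit cut points (length
#'   one more than `labels`), bin labels, and the unit of the binned value.
#' @return an object of class `ee_bin_scheme`.
#' @examples
#' classifyLoss(0.60)               # "50-70%"
#' classifyProtection(21.0)         # "17-30%"
#' @name bin-schemes
NULL

#' @rdname bin-schemes
#' @export
binScheme <- function(breaks, labels, unit = c("fraction", "percent")) {
  unit <- match.arg(unit)
  breaks <- as.numeric(breaks)
  if (length(labels) != length(breaks) - 1L)
    eeStop("ee_bad_argument", "need one more break than labels")
  if (is.unsorted(breaks, strictly = TRUE))
    eeStop("ee_bad_argument", "breaks must be strictly increasing")
  structure(list(breaks = breaks, labels = as.character(labels), unit = unit),
            class = "ee_bin_scheme")
}

#' @rdname bin-schemes
#' @export
lossBins <- function(variant = c("results", "figure")) {
  variant <- match.arg(variant)
  if (variant == "results")
    binScheme(c(0, .10, .30, .50, .70, .90, 1),
              c("<10%", "10-30%", "30-50%", "50-70%", "70-90%", ">90%"),
              "fraction")
  else
    binScheme(c(0, .10, .30, .50, .70, .90, .95, 1),
              c("<10%", "10-30%", "30-50%", "50-70%", "70-90%", "90-95%", ">95%"),
              "fraction")
}

#' @rdname bin-schemes
#' @export
protectionBins <- function(variant = c("top70", "top50")) {
  variant <- match.arg(variant)
  if (variant == "top70")
    binScheme(c(0, 1, 3, 5, 10, 17, 30, 50, 70, 100),
              c("0-1%", "1-3%", "3-5%", "5-10%", "10-17%", "17-30%",
                "30-50%", "50-70%", ">70%"),
              "percent")
  else
    binScheme(c(0, 1, 3, 5, 10, 17, 30, 50, 100),
              c("0-1%", "1-3%", "3-5%", "5-10%", "10-17%", "17-30%",
                "30-50%", ">50%"),
              "percent")
}

classifyBins <- function(x, scheme) {
  lo <- scheme$breaks[1]; hi <- scheme$breaks[length(scheme$breaks)]
  bad <- !is.na(x) & (x < lo | x > hi)
  if (any(bad))
    eeStop("ee_out_of_range",
           sprintf("values outside [%g, %g]: %s", lo, hi,
                   paste(utils::head(x[bad], 5), collapse = ", ")))
  i <- findInterval(x, scheme$breaks, rightmost.closed = TRUE)
  out <- rep(NA_character_, length(x))
  out[!is.na(x)] <- scheme$labels[i[!is.na(x)]]
  out
}

#' @rdname bin-schemes
#' @param fraction loss fractions in [0, 1].
#' @param scheme an `ee_bin_scheme`.
#' @export
classifyLoss <- function(fraction, scheme = lossBins()) {
  if (scheme$unit != "fraction")
    eeStop("ee_bad_argument", "scheme must bin fractions")
  classifyBins(fraction, scheme)
}

#' @rdname bin-schemes
#' @param pct percent of potential extent protected, in [0, 100].
#' @export
classifyProtection <- function(pct, scheme = protectionBins()) {
  if (scheme$unit != "percent")
    eeStop("ee_bad_argument", "scheme must bin percentages")
  classifyBins(pct, scheme)
}

#' IUCN Red List of Ecosystems criterion A3 category
#'
#' Categorises long-term (historical) reduction in distribution:
#' Critically Endangered above 90% loss, Endangered above 70%, Vulnerable
#' above 50%, otherwise not threatened under this criterion. The default
#' uses strict inequalities (a type at exactly 50% loss is not Vulnerable);
#' `strict = FALSE` switches every threshold to ">=", the closure used in
#' IUCN assessment guidance.
#'
#' @param fraction loss fractions in [0, 1].
#' @param strict logical; strict ">" thresholds (default) or ">=".
#' @return character vector over `"CR"`, `"EN"`, `"VU"`, `"NOT_THREATENED"`.
#' @examples
#' rleA3(c(0.95, 0.71, 0.51, 0.50))
#' @export
rleA3 <- function(fraction, strict = TRUE) {
  bad <- !is.na(fraction) & (fraction < 0 | fraction > 1)
  if (any(bad)) eeStop("ee_out_of_range", "loss fractions must lie in [0, 1]")
  above <- if (strict) function(x, t) x > t else function(x, t) x >= t
  out <- rep("NOT_THREATENED", length(fraction))
  out[above(fraction, 0.50)] <- "VU"
  out[above(fraction, 0.70)] <- "EN"
  out[above(fraction, 0.90)] <- "CR"
  out[is.na(fraction)] <- NA_character_
  out
}

#' Per-type long-term loss records
#'
#' Joins potential and current natural-extent area tables into per-type loss
#' records: `loss_fraction = 1 - current/potential`, the loss-class bin, and
#' the criterion-A3 category. Types absent from the current table are fully
#' converted (loss 1). A current area exceeding potential signals misaligned
#' inputs and is an error; types with zero potential area cannot be assessed
#' and are dropped with a warning.
#'
#' @param potential,current [areaTable()]s of potential and current natural
#'   extent (current restricted to natural type codes; land-use rows, codes
#'   >= 9000, are ignored here).
#' @param scheme loss-bin scheme, see [lossBins()].
#' @param strict closure of the A3 thresholds, see [rleA3()].
#' @param tol relative slack for the current <= potential check.
#' @return data.frame with columns `type_code`, `potential_km2`,
#'   `current_km2`, `loss_fraction`, `loss_class`, `rle_a3`.
#' @examples
#' pot <- areaTable(c(101, 102), c(100, 50))
#' cur <- areaTable(101, 40)
#' computeLoss(pot, cur)
#' @export
computeLoss <- function(potential, current, scheme = lossBins(),
                        strict = TRUE, tol = 1e-9) {
  current <- current[current$code < 9000L, , drop = FALSE]
  extra <- setdiff(current$code, potential$code)
  if (length(extra))
    eeStop("ee_unknown_type",
           paste("current-extent types missing from potential table:",
                 paste(extra, collapse = ", ")))
  cur <- current$area_km2[match(potential$code, current$code)]
  cur[is.na(cur)] <- 0
  pot <- potential$area_km2
  if (any(cur > pot * (1 + tol) + tol))
    eeStop("ee_current_exceeds_potential",
           "current natural extent exceeds potential extent; inputs misaligned")
  zero <- pot <= 0
  if (any(zero)) {
    eeWarn("ee_zero_potential_area",
           paste("dropping types with zero potential area:",
                 paste(potential$code[zero], collapse = ", ")))
  }
  pot2 <- pot[!zero]; cur2 <- pmin(cur[!zero], pot[!zero])
  frac <- 1 - cur2 / pot2
  frac <- pmin(pmax(frac, 0), 1)
  data.frame(
    type_code = potential$code[!zero],
    potential_km2 = pot2,
    current_km2 = cur2,
    loss_fraction = frac,
    loss_class = classifyLoss(frac, scheme),
    rle_a3 = rleA3(frac, strict),
    stringsAsFactors = FALSE
  )
}
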