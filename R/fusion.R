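#' Composite land-conversion classes
#'
#' The fused current land-use layer distinguishes four conversion classes
#' approximating urban/industrial, agricultural, ruderal and surface-water
#' cover, plus `NONE` meaning "no conversion detected here". Conversion
#' classes occupy a reserved code block (>= 9000) disjoint from ecosystem
#' type codes, so overlay cannot silently collide.
#'
#' @return named integer vector of the class codes.
#' @examples
#' compositeClasses()
#' @export
compositeClasses <- function() {
  c(NONE = 0L, DEVELOPED = 9001L, AGRICULTURE = 9002L,
    RUDERAL = 9003L, WATER = 9004L)
}

landUseCodes <- function() setdiff(compositeClasses(), 0L)

#' Load a land-cover product crosswalk
#'
#' A crosswalk maps one product's legend codes to the composite conversion
#' classes. It must be total over the product legend actually present on a
#' grid: [applyCrosswalk()] fails on any unmapped code rather than guessing.
#'
#' @param table data.frame or CSV path with columns `product`, `code`,
#'   `composite` (one of `r paste(names(compositeClasses()), collapse = ", ")`).
#' @param product optional product name to select when the table holds
#'   several products.
#' @return data.frame of class `ee_crosswalk` with attributes `product`.
#' @examples
#' xw <- loadCrosswalk(system.file("extdata", "example_crosswalk.csv",
#'                                 package = "ecoextent"), product = "globcover_like")
#' head(xw)
#' @export
loadCrosswalk <- function(table, product = NULL) {
  if (is.character(table))
    table <- utils::read.csv(table, stringsAsFactors = FALSE)
  need <- c("product", "code", "composite")
  if (!all(need %in% names(table)))
    eeStop("ee_bad_argument",
           paste("crosswalk needs columns", paste(need, collapse = ", ")))
  if (!is.null(product)) table <- table[table$product == product, , drop = FALSE]
  if (!nrow(table))
    eeStop("ee_bad_argument", "crosswalk has no rows (wrong product name?)")
  bad <- setdiff(unique(table$composite), names(compositeClasses()))
  if (length(bad))
    eeStop("ee_bad_argument",
           paste("unknown composite classes:", paste(bad, collapse = ", ")))
  if (anyDuplicated(table[c("product", "code")]))
    eeStop("ee_duplicate_code", "duplicate product codes in crosswalk")
  out <- data.frame(product = as.character(table$product),
                    code = as.integer(table$code),
                    composite = as.character(table$composite),
                    stringsAsFactors = FALSE)
  class(out) <- c("ee_crosswalk", "data.frame")
  out
}

#' Recode a product grid to composite conversion classes
#'
#' Cell-wise recode through a crosswalk; nodata passes through untouched.
#' Any non-nodata code absent from the crosswalk is an error that lists the
#' offending codes, because an unmapped class silently treated as `NONE`
#' would understate conversion.
#'
#' @param grid a [CategoricalGrid-class] in the product's legend.
#' @param xw a crosswalk from [loadCrosswalk()] (or a data.frame with
#'   columns `code`, `composite`).
#' @return a [CategoricalGrid-class] in composite-class codes.
#' @export
applyCrosswalk <- function(grid, xw) {
  nd <- nodataValue(grid)
  codes <- gridCodes(grid)
  present <- unique(codes[codes != nd])
  unmapped <- setdiff(present, xw$code)
  if (length(unmapped))
    eeStop("ee_unmapped_class_code",
           paste("product codes missing from crosswalk:",
                 paste(sort(unmapped), collapse = ", ")),
           codes = sort(unmapped))
  cc <- compositeClasses()
  lut <- cc[xw$composite]
  out <- codes
  keep <- codes != nd
  out[keep] <- lut[match(codes[keep], xw$code)]
  CategoricalGrid(out, gridSpec(grid))
}

#' Majority (modal) resampling to a coarser grid
#'
#' Aggregates `factor x factor` blocks of cells to one output cell carrying
#' the modal non-nodata code of the block; this is how 30 m land-cover
#' products are brought onto a 270 m analysis grid. Ties break to the
#' smallest code (deterministic and order-independent); all-nodata blocks
#' stay nodata. Dimensions not divisible by `factor` are padded with nodata
#' so partial edge blocks are still summarised.
#'
#' @param grid a [CategoricalGrid-class].
#' @param factor positive integer aggregation factor.
#' @return a [CategoricalGrid-class] with `cellSize * factor` geometry.
#' @examples
#' g <- CategoricalGrid(matrix(c(1, 1, 2, 2, 1, 3, 3, 3, 3), 3, 3))
#' gridCodes(majorityResample(g, 3))  # modal code of the single block
#' @export
majorityResample <- function(grid, factor) {
  factor <- stopifnotScalarCount(factor, "factor")
  if (factor == 1L) return(grid)
  spec <- gridSpec(grid)
  nd <- spec@nodata
  codes <- gridCodes(grid)
  nr <- ceiling(spec@nRows / factor)
  nc <- ceiling(spec@nCols / factor)
  padded <- matrix(nd, nr * factor, nc * factor)
  padded[seq_len(spec@nRows), seq_len(spec@nCols)] <- codes
  block <- (rep(seq_len(nr), each = factor))[row(padded)] +
    nr * ((rep(seq_len(nc), each = factor))[col(padded)] - 1L)
  v <- as.vector(padded)
  keep <- v != nd
  out <- rep(nd, nr * nc)
  if (any(keep)) {
    modal <- vapply(split(v[keep], block[keep]), function(x) {
      tab <- table(x)
      # names(tab) sorts numerically-as-character for positive ints of equal
      # width; sort codes explicitly to keep the smallest-code tie-break exact
      cand <- as.integer(names(tab)[tab == max(tab)])
      min(cand)
    }, integer(1))
    out[as.integer(names(modal))] <- modal
  }
  newSpec <- GridSpec(nr, nc, cellSize = spec@cellSize * factor,
                      xmin = spec@xmin, ymax = spec@ymax,
                      crs = spec@crs, nodata = nd)
  CategoricalGrid(matrix(out, nr, nc), newSpec)
}

#' Fuse composite layers by precedence
#'
#' Combines per-product composite conversion layers into one current
#' land-use map. Layers are given in precedence order (e.g. a national
#' product ahead of global ones); per cell, the first layer reporting a
#' class other than `NONE` wins. A cell is `NONE` when every informative
#' layer says `NONE`, and nodata only when every layer is nodata there.
#' An optional mask per layer restricts that product to its valid extent
#' (cells outside the mask are treated as nodata for that layer).
#'
#' @param layers list of [CategoricalGrid-class] in composite codes, highest
#'   precedence first.
#' @param masks optional list parallel to `layers`; each `NULL` or a grid
#'   whose non-zero, non-nodata cells mark the product's valid extent.
#' @return fused [CategoricalGrid-class] of composite classes.
#' @export
fuse <- function(layers, masks = NULL) {
  if (!length(layers)) eeStop("ee_bad_argument", "no layers to fuse")
  spec <- gridSpec(layers[[1]])
  nd <- spec@nodata
  for (l in layers) checkSameGridSpec(spec, l, "fusion layers")
  out <- matrix(nd, spec@nRows, spec@nCols)
  for (i in seq_along(layers)) {
    v <- gridCodes(layers[[i]])
    if (!is.null(masks) && !is.null(masks[[i]])) {
      checkSameGridSpec(spec, masks[[i]], "layer masks")
      m <- gridCodes(masks[[i]])
      v[m == nodataValue(masks[[i]]) | m == 0L] <- nd
    }
    informative <- v != nd
    take <- informative & v != 0L & (out == nd | out == 0L)
    out[take] <- v[take]
    toNone <- informative & v == 0L & out == nd
    out[toNone] <- 0L
  }
  CategoricalGrid(out, spec)
}
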