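#' Counts of types per hierarchy class by category bin
#'
#' The summary surface behind the "number of types per class by loss (or
#' protection) category" bar charts: rows are the nodes of a chosen coarse
#' hierarchy level (typically level 1, the physiognomic classes), columns
#' the bin labels of the applied scheme, cells the number of assessed types,
#' with row/column margins. Every assessed type is counted exactly once, so
#' the grand total equals the number of records.
#'
#' @param records a data.frame from [computeLoss()] or [protectionRepresentation()]
#'   (any data.frame with a `type_code` column and the label column).
#' @param h the [Hierarchy-class]; record type codes must be resolvable to
#'   `groupLevel` through it.
#' @param groupLevel hierarchy level for the rows (default 1).
#' @param label name of the bin-label column; defaults to `loss_class` or
#'   `protection_class`, whichever is present.
#' @param bins optional character vector fixing column order (defaults to
#'   scheme order if the labels are from a shipped scheme, else sorted).
#' @return integer matrix with named rows/columns and `Total` margins.
#' @examples
#' h <- loadHierarchy(data.frame(code = c(1, 11, 12), name = c("C", "a", "b"),
#'                               level = c(1, 2, 2), parent_code = c(NA, 1, 1)))
#' rec <- data.frame(type_code = c(11, 12), loss_class = c("<10%", ">90%"))
#' categoryCounts(rec, h, groupLevel = 1)
#' @export
categoryCounts <- function(records, h, groupLevel = 1, label = NULL,
                           bins = NULL) {
  if (is.null(label)) {
    label <- intersect(c("loss_class", "protection_class"), names(records))[1]
    if (is.na(label))
      eeStop("ee_bad_argument", "no loss_class or protection_class column found")
  }
  if (is.null(bins)) {
    # use the shipped scheme whose label set covers the records, so columns
    # come out in bin order rather than alphabetically
    schemes <- list(lossBins(), lossBins("figure"),
                    protectionBins(), protectionBins("top50"))
    bins <- sort(unique(as.character(records[[label]])))
    for (s in schemes) {
      if (all(records[[label]] %in% s$labels)) {
        bins <- s$labels[s$labels %in% records[[label]]]
        break
      }
    }
  }
  if (!nrow(records)) {
    m <- matrix(0L, 1, length(bins) + 1L,
                dimnames = list("Total", c(bins, "Total")))
    return(m)
  }
  grp <- tryCatch(
    ancestorAtLevel(h, records$type_code, groupLevel),
    ee_no_such_node = function(e)
      eeStop("ee_unresolvable_type", conditionMessage(e)),
    ee_level_not_coarser = function(e)
      eeStop("ee_unresolvable_type", conditionMessage(e))
  )
  nm <- h@nodes$name[match(grp, h@nodes$code)]
  rowOrder <- unique(h@nodes$name[h@nodes$level == groupLevel])
  rowOrder <- rowOrder[rowOrder %in% nm]
  tab <- table(factor(nm, levels = rowOrder),
               factor(records[[label]], levels = bins))
  m <- stats::addmargins(tab, FUN = list(Total = sum), quiet = TRUE)
  out <- matrix(as.integer(m), nrow(m), ncol(m), dimnames = dimnames(m))
  names(dimnames(out)) <- NULL
  out
}

#' Percent of assessed types, printed to one decimal
#'
#' The reporting arithmetic behind headline statements such as "5 types
#' (1.6%) have lost >90% of their potential extent": `100 * k / n` rendered
#' with one decimal, rounding half away from zero. An integer rendering mode
#' is available for whole-percent summaries. This single documented
#' convention can differ by up to 0.1 from published tables that mixed
#' rounding conventions.
#'
#' @param k count of types in the category (0 <= k <= n).
#' @param n total number of assessed types (> 0).
#' @param mode `"decimal"` (one decimal, default) or `"integer"`.
#' @return numeric percent, rounded per `mode`.
#' @examples
#' pctOfTypes(5, 315)    # 1.6
#' pctOfTypes(128, 315)  # 40.6
#' @export
pctOfTypes <- function(k, n, mode = c("decimal", "integer")) {
  mode <- match.arg(mode)
  if (any(n <= 0)) eeStop("ee_zero_total", "total assessed types must be > 0")
  if (any(k < 0 | k > n))
    eeStop("ee_out_of_range", "counts must satisfy 0 <= k <= n")
  x <- 100 * k / n
  d <- if (mode == "decimal") 10 else 1
  sign(x) * floor(abs(x) * d + 0.5) / d
}

#' Paint a potential-distribution map by per-type summary bins
#'
#' Recodes every cell of the potential map to the bin of its type's scalar
#' summary (loss fraction or percent protected), preserving the spatial
#' pattern of the potential distribution — the "paint-by-type" visualisation
#' of per-type loss and protection. Types with no value in `values` become
#' nodata, with a warning.
#'
#' @param potential [CategoricalGrid-class] of type codes.
#' @param values named numeric vector: names are type codes, values the
#'   per-type scalar to bin.
#' @param scheme bin scheme matching the unit of `values` (see
#'   [lossBins()], [protectionBins()]).
#' @return list with `grid` (a [CategoricalGrid-class] of 1-based bin
#'   codes) and `legend` (data.frame `bin_code`, `label`).
#' @examples
#' pot <- CategoricalGrid(matrix(c(101L, 101L, 102L, 102L), 2, 2))
#' p <- paintByType(pot, c(`101` = 0.95, `102` = 0.05))
#' gridCodes(p$grid); p$legend
#' @export
paintByType <- function(potential, values, scheme = lossBins()) {
  nd <- nodataValue(potential)
  codes <- gridCodes(potential)
  types <- sort(unique(codes[codes != nd & codes < 9000L]))
  have <- as.integer(names(values))
  missing <- setdiff(types, have)
  if (length(missing))
    eeWarn("ee_missing_value",
           paste("no value for types (painted nodata):",
                 paste(missing, collapse = ", ")))
  binOf <- classifyBins(unname(values), scheme)
  binCode <- match(binOf, scheme$labels)
  out <- matrix(nd, nrow(codes), ncol(codes))
  keep <- codes != nd & codes %in% have
  out[keep] <- binCode[match(codes[keep], have)]
  out[keep & is.na(out)] <- nd   # value present but NA
  legend <- data.frame(bin_code = seq_along(scheme$labels),
                       label = scheme$labels, stringsAsFactors = FALSE)
  list(grid = CategoricalGrid(out, gridSpec(potential)), legend = legend)
}
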