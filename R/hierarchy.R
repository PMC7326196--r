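#' The eight levels of the International Vegetation Classification
#'
#' Upper levels are physiognomic (Class, Subclass, Formation), lower levels
#' progressively floristic down to the Association. Level 5 (Macrogroup,
#' subcontinental floristics) and the group/system grain near level 6 are the
#' usual assessment units for continental extent-loss work.
#'
#' @return data.frame with columns `number` (1-8) and `name`.
#' @export
ivcLevels <- function() {
  data.frame(
    number = 1:8,
    name = c("Class", "Subclass", "Formation", "Division",
             "Macrogroup", "Group", "Alliance", "Association"),
    stringsAsFactors = FALSE
  )
}

#' Hierarchical ecosystem typology
#'
#' A validated forest of typed nodes: each node has a unique positive integer
#' code, a level 1-8, and (above level 1) a parent exactly one level coarser.
#' The leaf level is the declared assessment grain; per-type statistics
#' tabulated at the leaf level aggregate losslessly to any coarser level.
#'
#' @slot nodes data.frame with columns `code`, `name`, `level`,
#'   `parent_code` (`NA` for level-1 nodes).
#' @slot leafLevel the declared assessment level.
#' @seealso [loadHierarchy()], [aggregateArea()], [ancestorAtLevel()]
#' @exportClass Hierarchy
setClass("Hierarchy",
  slots = c(nodes = "data.frame", leafLevel = "integer")
)

setValidity("Hierarchy", function(object) {
  need <- c("code", "name", "level", "parent_code")
  if (!all(need %in% names(object@nodes)))
    return("nodes must have columns code, name, level, parent_code")
  TRUE
})

#' Load and validate a typology table
#'
#' Builds a [Hierarchy-class] from rows of `{code, name, level,
#' parent_code}` (a data.frame or the path of a CSV with those columns;
#' `parent_code` empty/NA only at level 1). Validation rejects duplicate
#' codes, self-referencing rows, parents that do not exist, and parents that
#' are not exactly one level coarser.
#'
#' @param table data.frame or CSV path.
#' @param leafLevel declared assessment level; defaults to the finest level
#'   present. All nodes at `leafLevel` form the leaf (assessment-unit) set.
#' @return a [Hierarchy-class].
#' @examples
#' csv <- system.file("extdata", "ivc_table1_chain.csv", package = "ecoextent")
#' h <- loadHierarchy(csv)
#' h
#' @export
loadHierarchy <- function(table, leafLevel = NULL) {
  if (is.character(table))
    table <- utils::read.csv(table, stringsAsFactors = FALSE)
  if (!NROW(table))
    eeStop("ee_empty_table", "typology table has no rows")
  need <- c("code", "name", "level", "parent_code")
  if (!all(need %in% names(table)))
    eeStop("ee_bad_argument",
           paste("typology table needs columns", paste(need, collapse = ", ")))
  nodes <- data.frame(
    code = as.integer(table$code),
    name = as.character(table$name),
    level = as.integer(table$level),
    parent_code = suppressWarnings(as.integer(table$parent_code)),
    stringsAsFactors = FALSE
  )
  if (anyNA(nodes$code) || any(nodes$code <= 0))
    eeStop("ee_bad_argument", "codes must be positive integers")
  if (any(nodes$level < 1L | nodes$level > 8L, na.rm = TRUE) || anyNA(nodes$level))
    eeStop("ee_bad_argument", "levels must lie in 1..8")
  dup <- unique(nodes$code[duplicated(nodes$code)])
  if (length(dup))
    eeStop("ee_duplicate_code",
           paste("duplicate type codes:", paste(dup, collapse = ", ")),
           codes = dup)
  if (any(!is.na(nodes$parent_code) & nodes$parent_code == nodes$code))
    eeStop("ee_cycle_detected", "node lists itself as its parent")
  if (any(nodes$level == 1L & !is.na(nodes$parent_code)))
    eeStop("ee_bad_argument", "level-1 nodes cannot have a parent")
  need_parent <- nodes$level > 1L
  if (any(need_parent & is.na(nodes$parent_code)))
    eeStop("ee_missing_parent", "nodes above level 1 must name a parent")
  idx <- match(nodes$parent_code[need_parent], nodes$code)
  if (anyNA(idx)) {
    bad <- unique(nodes$parent_code[need_parent][is.na(idx)])
    eeStop("ee_missing_parent",
           paste("parent codes not in table:", paste(bad, collapse = ", ")),
           codes = bad)
  }
  plevel <- nodes$level[idx]
  if (any(plevel != nodes$level[need_parent] - 1L))
    eeStop("ee_level_skip",
           "each parent must sit exactly one level above its child")
  # parent level strictly coarser everywhere => the graph is a forest;
  # cycles cannot arise once per-edge level decrease is enforced.
  if (is.null(leafLevel)) leafLevel <- max(nodes$level)
  leafLevel <- as.integer(leafLevel)
  if (!any(nodes$level == leafLevel))
    eeStop("ee_bad_argument", "no nodes at the declared leaf level")
  new("Hierarchy", nodes = nodes, leafLevel = leafLevel)
}

#' @rdname loadHierarchy
#' @param h a [Hierarchy-class].
#' @export
hierarchyNodes <- function(h) h@nodes

#' @rdname loadHierarchy
#' @export
leafLevel <- function(h) h@leafLevel

#' @rdname loadHierarchy
#' @export
leafCodes <- function(h) h@nodes$code[h@nodes$level == h@leafLevel]

setMethod("show", "Hierarchy", function(object) {
  lv <- table(factor(object@nodes$level, levels = 1:8))
  cat(sprintf("Hierarchy: %d nodes, leaf level %d (%s)\n",
              nrow(object@nodes), object@leafLevel,
              ivcLevels()$name[object@leafLevel]))
  cat("  nodes per level:",
      paste(sprintf("L%d:%d", 1:8, lv)[lv > 0], collapse = " "), "\n")
})

#' Ancestor of a node at a coarser level
#'
#' Walks parent links until the requested level. Because every parent is
#' exactly one level coarser, the ancestor at any level at or above a node's
#' own is unique; this is what lets leaf-level statistics be displayed at
#' macrogroup, division or class level.
#'
#' @param h a [Hierarchy-class].
#' @param code vector of node codes.
#' @param targetLevel level number, coarser than (numerically at most) each
#'   node's own level.
#' @return integer vector of ancestor codes, parallel to `code`.
#' @examples
#' h <- loadHierarchy(system.file("extdata", "ivc_table1_chain.csv",
#'                                package = "ecoextent"))
#' ancestorAtLevel(h, 6001, 5)  # group -> its macrogroup
#' @export
ancestorAtLevel <- function(h, code, targetLevel) {
  targetLevel <- as.integer(targetLevel)
  idx <- match(as.integer(code), h@nodes$code)
  if (anyNA(idx))
    eeStop("ee_no_such_node",
           paste("unknown codes:", paste(unique(code[is.na(idx)]), collapse = ", ")))
  if (any(h@nodes$level[idx] < targetLevel))
    eeStop("ee_level_not_coarser",
           "targetLevel must be at or above (numerically <=) each node's level")
  out <- h@nodes$code[idx]
  lev <- h@nodes$level[idx]
  while (any(lev > targetLevel)) {
    up <- lev > targetLevel
    i <- match(out[up], h@nodes$code)
    out[up] <- h@nodes$parent_code[i]
    lev[up] <- lev[up] - 1L
  }
  out
}

#' Per-type area table
#'
#' The unit of all accounting: a data.frame mapping integer type codes to
#' areas in square kilometres.
#'
#' @param code integer type codes.
#' @param area_km2 non-negative areas.
#' @return data.frame with columns `code`, `area_km2`, sorted by code.
#' @export
areaTable <- function(code, area_km2) {
  code <- as.integer(code)
  area_km2 <- as.numeric(area_km2)
  if (length(code) != length(area_km2))
    eeStop("ee_bad_argument", "code and area_km2 lengths differ")
  if (any(area_km2 < 0))
    eeStop("ee_bad_argument", "areas must be non-negative")
  if (anyDuplicated(code))
    eeStop("ee_duplicate_code", "duplicate codes in area table")
  o <- order(code)
  data.frame(code = code[o], area_km2 = area_km2[o])
}

#' Aggregate leaf-level areas up the hierarchy
#'
#' Sums a leaf-level [areaTable()] to any coarser level. Aggregation is
#' conservative: the grand total at every level equals the leaf total.
#'
#' @param h a [Hierarchy-class].
#' @param areas leaf-level area table (every code a leaf of `h`).
#' @param targetLevel the level to aggregate to (<= leaf level number).
#' @return area table keyed by target-level codes.
#' @examples
#' h <- loadHierarchy(data.frame(
#'   code = c(1, 11, 12), name = c("C", "a", "b"),
#'   level = c(1, 2, 2), parent_code = c(NA, 1, 1)))
#' aggregateArea(h, areaTable(c(11, 12), c(10, 20)), 1)
#' @export
aggregateArea <- function(h, areas, targetLevel) {
  targetLevel <- as.integer(targetLevel)
  lf <- leafCodes(h)
  unknown <- setdiff(areas$code, lf)
  if (length(unknown))
    eeStop("ee_unknown_leaf_code",
           paste("not leaf codes of the hierarchy:",
                 paste(unknown, collapse = ", ")),
           codes = unknown)
  if (targetLevel == h@leafLevel)
    return(areaTable(areas$code, areas$area_km2))
  anc <- ancestorAtLevel(h, areas$code, targetLevel)
  agg <- rowsum(areas$area_km2, group = anc)
  areaTable(as.integer(rownames(agg)), agg[, 1])
}
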