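#' Configuration for synthetic landscapes
#'
#' Bundles everything the generators need: grid geometry, number of
#' ecosystem types and Voronoi seeds per type, per-type conversion
#' intensities and mode, the mix of conversion classes, and the
#' protected-area network. All randomness flows from `seed`; each generator
#' stage derives its own stream from it, so a single config is fully
#' reproducible.
#'
#' Defaults emulate the statistical structure of a continental accounting
#' exercise at desk scale: a 100 x 100 grid of 270 m cells, 8 types as
#' multi-seed Voronoi mosaics, conversion intensities spread from near-zero
#' to severe (so all loss bins and threat categories are populated), an
#' agriculture-dominated conversion mix, and a protected-area network
#' covering 17% of the landscape in a handful of blocks.
#'
#' @param nRows,nCols,cellSize grid geometry (see [GridSpec()]).
#' @param nTypes number of ecosystem types.
#' @param seedsPerType Voronoi seeds per type; more seeds = patchier types.
#' @param conversionIntensity numeric vector of per-type conversion
#'   probabilities, named by type code or unnamed of length `nTypes`
#'   (recycled if length 1). Default spreads evenly over [0.02, 0.92].
#' @param conversionMode `"iid"` (each cell converts independently) or
#'   `"clustered"` (conversion nucleates and grows within `clusterRadius`).
#' @param clusterRadius cluster radius in cells for clustered mode.
#' @param classMix named weights over DEVELOPED, AGRICULTURE, RUDERAL,
#'   WATER; must sum to 1.
#' @param paCoverage target protected fraction of land cells (Aichi Target
#'   11's 17% by default).
#' @param paBlocks number of protected blocks.
#' @param paMode `"blocks"` (compact rectangles, like reserve networks) or
#'   `"scatter"` (iid random cells, independent of any spatial structure).
#' @param typeCodeStart first type code (codes run consecutively).
#' @param seed RNG seed; every generator is deterministic given it.
#' @return a `SimConfig` (classed list).
#' @examples
#' cfg <- simConfig(nRows = 40, nCols = 40, nTypes = 4, seed = 1)
#' @export
simConfig <- function(nRows = 100, nCols = 100, cellSize = 270,
                      nTypes = 8, seedsPerType = 3,
                      conversionIntensity = NULL,
                      conversionMode = c("iid", "clustered"),
                      clusterRadius = 3,
                      classMix = c(DEVELOPED = 0.20, AGRICULTURE = 0.60,
                                   RUDERAL = 0.10, WATER = 0.10),
                      paCoverage = 0.17, paBlocks = 6,
                      paMode = c("blocks", "scatter"),
                      typeCodeStart = 101L, seed = 1L) {
  conversionMode <- match.arg(conversionMode)
  paMode <- match.arg(paMode)
  nTypes <- stopifnotScalarCount(nTypes, "nTypes")
  typeCodes <- typeCodeStart + seq_len(nTypes) - 1L
  if (is.null(conversionIntensity))
    conversionIntensity <- seq(0.02, 0.92, length.out = nTypes)
  if (length(conversionIntensity) == 1L)
    conversionIntensity <- rep(conversionIntensity, nTypes)
  if (is.null(names(conversionIntensity))) {
    if (length(conversionIntensity) != nTypes)
      eeStop("ee_bad_argument",
             "conversionIntensity must have length 1, nTypes, or type-code names")
    names(conversionIntensity) <- typeCodes
  }
  if (any(conversionIntensity < 0 | conversionIntensity > 1))
    eeStop("ee_bad_argument", "conversion intensities must lie in [0, 1]")
  if (abs(sum(classMix) - 1) > 1e-8)
    eeStop("ee_bad_argument", "classMix weights must sum to 1")
  if (!all(names(classMix) %in% setdiff(names(compositeClasses()), "NONE")))
    eeStop("ee_bad_argument", "classMix names must be composite conversion classes")
  if (paCoverage < 0 || paCoverage > 1)
    eeStop("ee_bad_argument", "paCoverage must lie in [0, 1]")
  structure(list(
    spec = GridSpec(nRows, nCols, cellSize = cellSize),
    nTypes = nTypes, typeCodes = typeCodes,
    seedsPerType = stopifnotScalarCount(seedsPerType, "seedsPerType"),
    conversionIntensity = conversionIntensity,
    conversionMode = conversionMode, clusterRadius = clusterRadius,
    classMix = classMix,
    paCoverage = paCoverage, paBlocks = as.integer(paBlocks), paMode = paMode,
    seed = as.integer(seed)
  ), class = "SimConfig")
}

#' @export
print.SimConfig <- function(x, ...) {
  cat(sprintf("SimConfig: %d x %d @ %.0f m, %d types (%d seeds each), %s conversion, PA %s %.0f%%, seed %d\n",
              x$spec@nRows, x$spec@nCols, x$spec@cellSize, x$nTypes,
              x$seedsPerType, x$conversionMode, x$paMode,
              100 * x$paCoverage, x$seed))
  invisible(x)
}

# run fn under a stage-specific seed without disturbing the caller's RNG
withStageSeed <- function(seed, offset, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((seed + offset) %% .Machine$integer.max)
  fn()
}

#' Generate a potential-distribution mosaic
#'
#' Seeds each type at `seedsPerType` random cells and assigns every cell to
#' the nearest seed (Euclidean distance between cell centres; ties go to
#' the smallest type code), giving a multi-type Voronoi patch mosaic. All
#' types are guaranteed realised; configurations with more seeds than cells
#' are rejected.
#'
#' @param cfg a [simConfig()].
#' @return list with `grid` (the potential [CategoricalGrid-class]),
#'   `truth` (the per-type potential [areaTable()]), and `seeds`
#'   (data.frame `type_code`, `row`, `col` of the Voronoi seed cells, so the
#'   assignment can be checked externally).
#' @examples
#' pot <- genPotential(simConfig(nRows = 30, nCols = 30, nTypes = 3, seed = 7))
#' pot$truth
#' @export
genPotential <- function(cfg) {
  spec <- cfg$spec
  n <- spec@nRows * spec@nCols
  nSeeds <- cfg$nTypes * cfg$seedsPerType
  if (nSeeds > n)
    eeStop("ee_unrealizable_config", "more Voronoi seeds than cells")
  out <- withStageSeed(cfg$seed, 0L, function() {
    cells <- sample.int(n, nSeeds)
    seedType <- rep(cfg$typeCodes, each = cfg$seedsPerType)
    o <- order(seedType)             # smallest type code first for tie-break
    cells <- cells[o]; seedType <- seedType[o]
    sr <- ((cells - 1L) %% spec@nRows) + 1L
    sc <- ((cells - 1L) %/% spec@nRows) + 1L
    rows <- ((seq_len(n) - 1L) %% spec@nRows) + 1L
    cols <- ((seq_len(n) - 1L) %/% spec@nRows) + 1L
    d2 <- outer(rows, sr, function(a, b) (a - b)^2) +
      outer(cols, sc, function(a, b) (a - b)^2)
    assign <- seedType[max.col(-d2, ties.method = "first")]
    list(grid = CategoricalGrid(matrix(assign, spec@nRows, spec@nCols), spec),
         seeds = data.frame(type_code = seedType, row = sr, col = sc))
  })
  list(grid = out$grid, truth = tabulateArea(out$grid), seeds = out$seeds)
}

#' Generate a conversion layer with known per-type intensity
#'
#' In `"iid"` mode every cell of type `t` converts independently with
#' probability `p_t`; in `"clustered"` mode conversion nucleates at random
#' cells of the type and claims all same-type cells within
#' `clusterRadius`, nucleating again until the target count
#' `round(p_t * n_t)` is reached (the last cluster is trimmed by distance).
#' Converted cells draw their land-use class from `classMix`. The realized
#' per-type converted fraction is returned as truth, so downstream recovery
#' checks never re-derive it from generator internals.
#'
#' @param potential the potential grid from [genPotential()].
#' @param cfg the [simConfig()].
#' @return list with `grid` (composite-class [CategoricalGrid-class]) and
#'   `truth` (data.frame `type_code`, `n_cells`, `n_converted`,
#'   `realized_fraction`).
#' @export
genConversion <- function(potential, cfg) {
  spec <- gridSpec(potential)
  codes <- gridCodes(potential)
  nd <- spec@nodata
  types <- sort(unique(codes[codes != nd]))
  p <- cfg$conversionIntensity
  missing <- setdiff(types, as.integer(names(p)))
  if (length(missing))
    eeStop("ee_missing_intensity",
           paste("no conversion intensity for types:",
                 paste(missing, collapse = ", ")))
  cc <- compositeClasses()
  out <- withStageSeed(cfg$seed, 1L, function() {
    conv <- matrix(FALSE, spec@nRows, spec@nCols)
    if (cfg$conversionMode == "iid") {
      pr <- rep(0, length(codes))
      land <- codes != nd
      pr[land] <- p[as.character(codes[land])]
      conv[] <- stats::runif(length(codes)) < pr
      conv[!land] <- FALSE
    } else {
      rows <- row(codes); cols <- col(codes)
      for (t in types) {
        idx <- which(codes == t)
        target <- round(p[as.character(t)] * length(idx))
        if (target <= 0) next
        chosen <- logical(length(idx))
        ord <- sample(seq_along(idx))
        k <- 0L
        for (nucleus in ord) {
          if (k >= target) break
          if (chosen[nucleus]) next
          d2 <- (rows[idx] - rows[idx[nucleus]])^2 +
            (cols[idx] - cols[idx[nucleus]])^2
          cand <- which(!chosen & d2 <= cfg$clusterRadius^2)
          cand <- cand[order(d2[cand])]
          take <- utils::head(cand, target - k)
          chosen[take] <- TRUE
          k <- k + length(take)
        }
        conv[idx[chosen]] <- TRUE
      }
    }
    cls <- matrix(0L, spec@nRows, spec@nCols)
    nConv <- sum(conv)
    if (nConv) {
      pool <- unname(cc[names(cfg$classMix)])
      cls[conv] <- pool[sample.int(length(pool), nConv, replace = TRUE,
                                   prob = cfg$classMix)]
    }
    cls[codes == nd] <- nd
    list(conv = conv, cls = cls)
  })
  nCells <- vapply(types, function(t) sum(codes == t), integer(1))
  nConv <- vapply(types, function(t) sum(out$conv & codes == t), integer(1))
  list(
    grid = CategoricalGrid(out$cls, spec),
    truth = data.frame(type_code = types, n_cells = nCells,
                       n_converted = nConv,
                       realized_fraction = nConv / nCells)
  )
}

#' Generate a protected-area network with known coverage
#'
#' `"blocks"` mode drops compact rectangular reserves (overlap allowed,
#' union counted once) and keeps adding/trimming until realized coverage
#' hits the target exactly (well within the one-block-row tolerance);
#' `"scatter"` mode protects exactly `round(paCoverage * n)` uniformly
#' random cells, a mask independent of any spatial structure. Realized
#' coverage is returned as truth.
#'
#' @param cfg the [simConfig()].
#' @param potential optional potential grid; its nodata cells are excluded
#'   from the land base.
#' @return list with `mask` (a [CategoricalGrid-class] over [maskCodes()])
#'   and `truth` (data.frame with `target_coverage`, `realized_coverage`,
#'   `n_protected`, `n_land`).
#' @export
genProtected <- function(cfg, potential = NULL) {
  spec <- cfg$spec
  nd <- spec@nodata
  land <- if (is.null(potential)) {
    matrix(TRUE, spec@nRows, spec@nCols)
  } else {
    checkSameGridSpec(spec, potential, "config grid and potential layer")
    gridCodes(potential) != nd
  }
  nLand <- sum(land)
  target <- round(cfg$paCoverage * nLand)
  mask <- withStageSeed(cfg$seed, 2L, function() {
    m <- matrix(FALSE, spec@nRows, spec@nCols)
    if (target == 0) return(m)
    if (cfg$paMode == "scatter") {
      cells <- which(land)
      m[cells[sample.int(length(cells), target)]] <- TRUE
      return(m)
    }
    side <- max(1L, ceiling(sqrt(target / max(1L, cfg$paBlocks))))
    placed <- 0L
    guard <- 0L
    while (sum(m & land) < target && guard < 10000L) {
      guard <- guard + 1L
      r0 <- sample.int(max(1L, spec@nRows - side + 1L), 1L)
      c0 <- sample.int(max(1L, spec@nCols - side + 1L), 1L)
      rr <- r0:min(spec@nRows, r0 + side - 1L)
      ccols <- c0:min(spec@nCols, c0 + side - 1L)
      block <- matrix(FALSE, spec@nRows, spec@nCols)
      block[rr, ccols] <- TRUE
      newCells <- which(block & land & !m)
      need <- target - sum(m & land)
      if (length(newCells) > need) {
        # trim the final block column-major so the reserve stays compact
        newCells <- newCells[seq_len(need)]
      }
      m[newCells] <- TRUE
      placed <- placed + 1L
    }
    m
  })
  realized <- sum(mask & land)
  out <- matrix(maskCodes()[["UNPROTECTED"]], spec@nRows, spec@nCols)
  out[mask] <- maskCodes()[["PROTECTED"]]
  out[!land] <- nd
  list(
    mask = CategoricalGrid(out, spec),
    truth = data.frame(target_coverage = cfg$paCoverage,
                       realized_coverage = realized / nLand,
                       n_protected = realized, n_land = nLand)
  )
}

#' Generate a balanced toy hierarchy
#'
#' A balanced forest: `nClasses` level-1 roots, each splitting `fanout` ways
#' per level down to `depth`, giving `nClasses * fanout^(depth-1)` leaves.
#' Useful as a stand-in typology whose leaves can be bound to the type codes
#' of a synthetic landscape. The output always passes [loadHierarchy()]
#' validation.
#'
#' @param nClasses number of level-1 roots.
#' @param fanout children per node (>= 1).
#' @param depth number of levels (1-8).
#' @param seed RNG seed (reserved; construction is currently deterministic).
#' @param leafCodes optional integer codes to assign to the leaves, in
#'   order; length must equal the leaf count. Internal nodes use a 5000+
#'   code block disjoint from typical type codes.
#' @return a validated [Hierarchy-class].
#' @examples
#' h <- genHierarchy(2, 3, 2)
#' length(leafCodes(h))  # 6
#' @export
genHierarchy <- function(nClasses, fanout, depth, seed = 1L, leafCodes = NULL) {
  nClasses <- stopifnotScalarCount(nClasses, "nClasses")
  fanout <- stopifnotScalarCount(fanout, "fanout")
  depth <- stopifnotScalarCount(depth, "depth")
  if (depth > 8L) eeStop("ee_bad_argument", "depth cannot exceed 8 levels")
  nLeaves <- nClasses * fanout^(depth - 1L)
  if (!is.null(leafCodes)) {
    leafCodes <- as.integer(leafCodes)
    if (length(leafCodes) != nLeaves)
      eeStop("ee_bad_argument",
             sprintf("need %d leaf codes, got %d", nLeaves, length(leafCodes)))
  }
  rows <- list()
  nextInternal <- 5001L
  parents <- rep(NA_integer_, nClasses)
  codes <- NULL
  for (lev in seq_len(depth)) {
    nAt <- nClasses * fanout^(lev - 1L)
    isLeaf <- lev == depth
    codes <- if (isLeaf && !is.null(leafCodes)) {
      leafCodes
    } else {
      out <- nextInternal + seq_len(nAt) - 1L
      nextInternal <- nextInternal + nAt
      out
    }
    rows[[lev]] <- data.frame(
      code = codes,
      name = sprintf("L%d-%02d", lev, seq_len(nAt)),
      level = lev,
      parent_code = parents,
      stringsAsFactors = FALSE
    )
    parents <- rep(codes, each = fanout)
  }
  loadHierarchy(do.call(rbind, rows), leafLevel = depth)
}

#' Generate a complete synthetic study landscape
#'
#' Runs all generators under one config: potential mosaic, conversion
#' layer, protected-area mask, and a hierarchy whose leaves are the
#' landscape's type codes (depth 2: type codes grouped under level-1
#' classes). Optionally writes the whole set — grids as ASCII rasters,
#' truth tables and hierarchy as CSV, config echoed to YAML — to a run
#' directory.
#'
#' @param cfg a [simConfig()].
#' @param outDir optional directory to write the landscape to.
#' @param hierarchyClasses number of level-1 classes to group types under.
#' @return list with `potential`, `composite`, `mask`
#'   ([CategoricalGrid-class]s), `hierarchy`, and `truth` (list of the three
#'   generator truth tables).
#' @examples
#' land <- simulateLandscape(simConfig(nRows = 30, nCols = 30, nTypes = 4))
#' land$truth$conversion
#' @export
simulateLandscape <- function(cfg, outDir = NULL, hierarchyClasses = 2L) {
  pot <- genPotential(cfg)
  conv <- genConversion(pot$grid, cfg)
  pa <- genProtected(cfg, pot$grid)
  # depth-2 forest: pad the leaf row to a multiple of the class count
  fanout <- ceiling(cfg$nTypes / hierarchyClasses)
  leaf <- cfg$typeCodes
  extra <- hierarchyClasses * fanout - length(leaf)
  if (extra > 0) leaf <- c(leaf, max(leaf) + seq_len(extra))
  h <- genHierarchy(hierarchyClasses, fanout, 2L, seed = cfg$seed,
                    leafCodes = leaf)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeGrid(pot$grid, file.path(outDir, "potential.asc"))
    writeGrid(conv$grid, file.path(outDir, "composite.asc"))
    writeGrid(pa$mask, file.path(outDir, "pa_mask.asc"))
    writeTableCsv(hierarchyNodes(h), file.path(outDir, "hierarchy.csv"))
    writeTableCsv(pot$truth, file.path(outDir, "truth_potential.csv"))
    writeTableCsv(conv$truth, file.path(outDir, "truth_conversion.csv"))
    writeTableCsv(pa$truth, file.path(outDir, "truth_protection.csv"))
    yaml::write_yaml(simConfigToList(cfg), file.path(outDir, "sim_config.yaml"))
  }
  list(potential = pot$grid, composite = conv$grid, mask = pa$mask,
       hierarchy = h,
       truth = list(potential = pot$truth, conversion = conv$truth,
                    protection = pa$truth))
}

simConfigToList <- function(cfg) {
  list(
    nRows = cfg$spec@nRows, nCols = cfg$spec@nCols,
    cellSize = cfg$spec@cellSize,
    nTypes = cfg$nTypes, seedsPerType = cfg$seedsPerType,
    conversionIntensity = as.list(stats::setNames(
      as.numeric(cfg$conversionIntensity), names(cfg$conversionIntensity))),
    conversionMode = cfg$conversionMode, clusterRadius = cfg$clusterRadius,
    classMix = as.list(stats::setNames(as.numeric(cfg$classMix),
                                       names(cfg$classMix))),
    paCoverage = cfg$paCoverage, paBlocks = cfg$paBlocks, paMode = cfg$paMode,
    typeCodeStart = cfg$typeCodes[1], seed = cfg$seed
  )
}
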