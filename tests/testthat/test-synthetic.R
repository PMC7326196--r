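test_that("potential mosaics realize every type and are deterministic", {
  one <- genPotential(simConfig(nRows = 10, nCols = 10, nTypes = 1, seed = 2))
  expect_equal(unique(as.vector(gridCodes(one$grid))), 101L)

  cfg <- simConfig(nRows = 30, nCols = 30, nTypes = 5, seed = 99)
  a <- genPotential(cfg); b <- genPotential(cfg)
  expect_identical(gridCodes(a$grid), gridCodes(b$grid))
  expect_setequal(unique(as.vector(gridCodes(a$grid))), cfg$typeCodes)
  expect_equal(a$truth, tabulateArea(a$grid))

  expect_error(genPotential(simConfig(nRows = 2, nCols = 2, nTypes = 5)),
               class = "ee_unrealizable_config")
})

test_that("voronoi assignment matches the exhaustive nearest-seed oracle", {
  # checks the stated rule directly: nearest reported seed by cell-centre
  # euclidean distance, ties to the smallest type code
  for (s in 1:3) {
    cfg <- simConfig(nRows = 50, nCols = 50, nTypes = 5, seedsPerType = 3,
                     seed = s)
    pot <- genPotential(cfg)
    got <- gridCodes(pot$grid)
    oracle <- matrix(NA_integer_, 50, 50)
    for (r in 1:50) for (co in 1:50) {
      d2 <- (r - pot$seeds$row)^2 + (co - pot$seeds$col)^2
      oracle[r, co] <- min(pot$seeds$type_code[d2 == min(d2)])
    }
    expect_identical(got, oracle)
  }
})

test_that("iid conversion honours per-type intensities with exact truth", {
  cfg0 <- simConfig(nRows = 40, nCols = 40, nTypes = 4,
                    conversionIntensity = 0, seed = 4)
  pot <- genPotential(cfg0)
  conv0 <- genConversion(pot$grid, cfg0)
  expect_true(all(gridCodes(conv0$grid) == 0L))
  expect_true(all(conv0$truth$realized_fraction == 0))

  cfg1 <- simConfig(nRows = 40, nCols = 40, nTypes = 4,
                    conversionIntensity = c(1, 0, 0, 0), seed = 4)
  conv1 <- genConversion(pot$grid, cfg1)
  cur <- overlayCurrent(pot$grid, conv1$grid)
  loss <- computeLoss(tabulateArea(pot$grid), tabulateArea(cur))
  expect_equal(loss$loss_fraction[loss$type_code == 101L], 1.0)
  expect_equal(conv1$truth$realized_fraction[1], 1.0)

  # binomial oracle: realized fraction near p within 4 standard errors
  cfgB <- simConfig(nRows = 100, nCols = 100, nTypes = 2, seedsPerType = 1,
                    conversionIntensity = c(0.3, 0.3), seed = 12)
  potB <- genPotential(cfgB)
  convB <- genConversion(potB$grid, cfgB)
  tr <- convB$truth
  se <- sqrt(0.3 * 0.7 / tr$n_cells)
  expect_true(all(abs(tr$realized_fraction - 0.3) <= 4 * se))

  # truth table is what the composite layer actually shows
  for (i in seq_len(nrow(tr))) {
    inType <- gridCodes(potB$grid) == tr$type_code[i]
    expect_equal(sum(gridCodes(convB$grid)[inType] != 0L), tr$n_converted[i])
  }

  badCfg <- cfgB; badCfg$conversionIntensity <- c(`999` = 0.5)
  expect_error(genConversion(potB$grid, badCfg), class = "ee_missing_intensity")
})

test_that("clustered conversion hits the per-type target count", {
  cfg <- simConfig(nRows = 50, nCols = 50, nTypes = 3,
                   conversionIntensity = c(0.2, 0.5, 0.8),
                   conversionMode = "clustered", clusterRadius = 3, seed = 6)
  pot <- genPotential(cfg)
  conv <- genConversion(pot$grid, cfg)
  tr <- conv$truth
  target <- round(cfg$conversionIntensity[as.character(tr$type_code)] * tr$n_cells)
  expect_equal(tr$n_converted, unname(as.integer(target)))
})

test_that("protected-area networks hit their target coverage", {
  cfg0 <- simConfig(nRows = 30, nCols = 30, paCoverage = 0, seed = 3)
  expect_true(all(gridCodes(genProtected(cfg0)$mask) == 0L))

  cfg1 <- simConfig(nRows = 30, nCols = 30, nTypes = 3, paCoverage = 1, seed = 3)
  land <- simulateLandscape(cfg1)
  cur <- overlayCurrent(land$potential, land$composite)
  curNat <- tabulateArea(cur); curNat <- curNat[curNat$code < 9000L, ]
  rec <- protectionRepresentation(protectedAreasByType(cur, land$mask),
                                  tabulateArea(land$potential), curNat)
  expect_true(all(rec$pct_of_current == 100))

  set.seed(1)
  for (i in 1:10) {
    cov <- stats::runif(1, 0.05, 0.6)
    mode <- sample(c("blocks", "scatter"), 1)
    cfg <- simConfig(nRows = 40, nCols = 40, paCoverage = cov,
                     paBlocks = sample(2:8, 1), paMode = mode, seed = i)
    pa <- genProtected(cfg)
    expect_equal(pa$truth$n_protected, sum(gridCodes(pa$mask) == 1L))
    side <- ceiling(sqrt(pa$truth$n_protected / cfg$paBlocks))
    expect_lte(abs(pa$truth$realized_coverage - cov) * pa$truth$n_land,
               max(1, side))   # within one block row of cells
  }
})

test_that("toy hierarchies are balanced and pass validation", {
  h <- genHierarchy(2, 3, 2)
  expect_equal(length(leafCodes(h)), 6L)
  expect_equal(sum(hierarchyNodes(h)$level == 1L), 2L)

  flat <- genHierarchy(4, 1, 1)
  expect_equal(leafLevel(flat), 1L)
  expect_equal(length(leafCodes(flat)), 4L)

  withLeaves <- genHierarchy(2, 2, 3, leafCodes = 101:108)
  expect_equal(leafCodes(withLeaves), 101:108)
  expect_equal(ancestorAtLevel(withLeaves, 101L, 3), 101L)
})

test_that("truth tables round-trip through CSV bit-identically", {
  land <- simulateLandscape(simConfig(nRows = 20, nCols = 20, nTypes = 3,
                                      seed = 44), outDir = td <- tempfile())
  tr <- utils::read.csv(file.path(td, "truth_conversion.csv"))
  expect_identical(tr$realized_fraction, land$truth$conversion$realized_fraction)
  expect_identical(tr$n_converted, land$truth$conversion$n_converted)
  unlink(td, recursive = TRUE)
})
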