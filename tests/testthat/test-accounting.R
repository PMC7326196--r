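test_that("overlay presumes converted where a land-use class is reported", {
  spec <- GridSpec(2, 2)
  pot <- CategoricalGrid(matrix(c(101L, 101L, 102L, spec@nodata), 2, 2), spec)
  comp <- CategoricalGrid(matrix(c(9002L, 0L, 0L, 0L), 2, 2), spec)
  cur <- overlayCurrent(pot, comp)
  expect_equal(as.vector(gridCodes(cur)), c(9002L, 101L, 102L, spec@nodata))

  # no conversion anywhere: current equals potential
  none <- CategoricalGrid(matrix(0L, 2, 2), spec)
  expect_equal(gridCodes(overlayCurrent(pot, none)), gridCodes(pot))

  expect_error(overlayCurrent(pot, CategoricalGrid(matrix(0L, 3, 3))),
               class = "ee_gridspec_mismatch")
  badPot <- CategoricalGrid(matrix(9001L, 2, 2), spec)
  expect_error(overlayCurrent(badPot, none), class = "ee_code_range_collision")
  badComp <- CategoricalGrid(matrix(77L, 2, 2), spec)
  expect_error(overlayCurrent(pot, badComp), class = "ee_code_range_collision")
})

test_that("tabulation converts cell counts at the declared resolution", {
  spec <- GridSpec(2, 5, cellSize = 270)
  g <- CategoricalGrid(matrix(42L, 2, 5), spec)
  at <- tabulateArea(g)
  expect_equal(at$area_km2, 10 * 0.0729)

  empty <- CategoricalGrid(matrix(spec@nodata, 2, 5), spec)
  expect_equal(nrow(tabulateArea(empty)), 0L)
})

test_that("tabulation matches brute-force counting on random grids", {
  set.seed(3)
  for (i in 1:20) {
    g <- randomGrid(50, 50, codes = 101:105, nodataFrac = 0.15)
    at <- tabulateArea(g)
    oracle <- bruteCounts(g)
    expect_equal(at$code, as.integer(names(oracle)))
    expect_equal(at$area_km2, unname(oracle) * cellAreaKm2(g))
  }
})

test_that("non-equal-area grids refuse constant-cell tabulation but accept per-cell areas", {
  spec <- GridSpec(2, 2, crs = "geographic-wgs84")
  g <- CategoricalGrid(matrix(5L, 2, 2), spec)
  expect_error(tabulateArea(g), class = "ee_not_equal_area")
  at <- tabulateArea(g, cellAreasKm2 = matrix(c(1, 2, 3, 4), 2, 2))
  expect_equal(at$area_km2, 10)
})

test_that("loss fractions follow 1 - current/potential with stated edge cases", {
  pot <- areaTable(c(101, 102, 103), c(100, 50, 80))
  cur <- areaTable(c(101, 102), c(40, 50))
  rec <- computeLoss(pot, cur)
  expect_equal(rec$loss_fraction, c(0.60, 0.0, 1.0))   # missing type -> total loss
  expect_equal(rec$loss_class, c("50-70%", "<10%", ">90%"))
  expect_equal(rec$rle_a3, c("VU", "NOT_THREATENED", "CR"))

  expect_error(computeLoss(pot, areaTable(101, 120)),
               class = "ee_current_exceeds_potential")
  expect_error(computeLoss(pot, areaTable(999, 1)), class = "ee_unknown_type")
  expect_warning(
    rec0 <- computeLoss(areaTable(c(101, 102), c(0, 10)), areaTable(102, 5)),
    class = "ee_zero_potential_area")
  expect_equal(rec0$type_code, 102L)
})

test_that("loss bins partition [0,1] with the stated closures", {
  expect_equal(classifyLoss(0.60), "50-70%")
  expect_equal(classifyLoss(0.90), ">90%")    # boundary closes upward
  expect_equal(classifyLoss(0.0), "<10%")
  expect_equal(classifyLoss(1.0), ">90%")
  expect_equal(classifyLoss(0.10), "10-30%")
  expect_error(classifyLoss(1.2), class = "ee_out_of_range")

  fig <- lossBins("figure")
  expect_equal(classifyLoss(0.96, fig), ">95%")
  expect_equal(classifyLoss(0.95, fig), ">95%")
  expect_equal(classifyLoss(0.92, fig), "90-95%")
})

test_that("criterion A3 thresholds are strict as published, with a closure switch", {
  expect_equal(rleA3(c(0.95, 0.71, 0.51, 0.50, 0.0)),
               c("CR", "EN", "VU", "NOT_THREATENED", "NOT_THREATENED"))
  expect_equal(rleA3(0.90), "EN")
  expect_equal(rleA3(0.90, strict = FALSE), "CR")
  expect_equal(rleA3(0.50, strict = FALSE), "VU")
  expect_error(rleA3(-0.1), class = "ee_out_of_range")

  # monotone non-decreasing severity along increasing loss
  sev <- c(NOT_THREATENED = 0, VU = 1, EN = 2, CR = 3)
  f <- sort(stats::runif(50))
  expect_true(all(diff(sev[rleA3(f)]) >= 0))
})

test_that("per-type area is conserved through overlay: potential = natural + converted", {
  set.seed(9)
  land <- simulateLandscape(simConfig(nRows = 60, nCols = 60, nTypes = 6, seed = 5))
  cur <- overlayCurrent(land$potential, land$composite)
  pot <- tabulateArea(land$potential)
  for (t in pot$code) {
    inFoot <- gridCodes(land$potential) == t
    natural <- sum(gridCodes(cur)[inFoot] == t)
    converted <- sum(gridCodes(cur)[inFoot] >= 9000L)
    expect_equal(natural + converted, sum(inFoot))
    expect_equal((natural + converted) * cellAreaKm2(cur),
                 pot$area_km2[pot$code == t], tolerance = 1e-9)
  }
})

test_that("adding converted cells never decreases a loss fraction", {
  set.seed(21)
  spec <- GridSpec(30, 30)
  pot <- CategoricalGrid(matrix(sample(101:104, 900, TRUE), 30, 30), spec)
  compV <- ifelse(stats::runif(900) < 0.2, 9002L, 0L)
  comp1 <- CategoricalGrid(matrix(as.integer(compV), 30, 30), spec)
  compV2 <- ifelse(compV == 0L & stats::runif(900) < 0.2, 9001L, compV)
  comp2 <- CategoricalGrid(matrix(as.integer(compV2), 30, 30), spec)
  potAt <- tabulateArea(pot)
  loss1 <- computeLoss(potAt, tabulateArea(overlayCurrent(pot, comp1)))
  loss2 <- computeLoss(potAt, tabulateArea(overlayCurrent(pot, comp2)))
  expect_true(all(loss2$loss_fraction >= loss1$loss_fraction))
})
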