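test_that("rasterization protects exactly the cells whose centres fall inside", {
  spec <- GridSpec(4, 4, cellSize = 100)
  # square covering exactly the 2x2 block of cells rows 1-2, cols 1-2
  m <- rasterizeProtection(list(rectPolygon(0, 200, 200, 400)), spec)
  expect_equal(sum(gridCodes(m) == 1L), 4L)
  expect_equal(gridCodes(m)[1:2, 1:2], matrix(1L, 2, 2))

  # two identical polygons dissolve to the same mask as one
  m2 <- rasterizeProtection(list(rectPolygon(0, 200, 200, 400),
                                 rectPolygon(0, 200, 200, 400)), spec)
  expect_equal(gridCodes(m2), gridCodes(m))

  expect_error(
    rasterizeProtection(list(rectPolygon(0, 1, 0, 1, category = "X")), spec,
                        categories = c("I", "II")),
    class = "ee_empty_selection")
})

test_that("rasterized random rectangles match a point-in-rectangle oracle", {
  set.seed(13)
  spec <- GridSpec(50, 50, cellSize = 100)
  ctr <- cellCenters(spec)
  for (i in 1:10) {
    x0 <- stats::runif(3, 0, 4000); x1 <- x0 + stats::runif(3, 100, 1500)
    y0 <- stats::runif(3, 0, 4000); y1 <- y0 + stats::runif(3, 100, 1500)
    polys <- lapply(1:3, function(k) rectPolygon(x0[k], x1[k], y0[k], y1[k]))
    m <- rasterizeProtection(polys, spec)
    oracle <- matrix(FALSE, 50, 50)
    for (k in 1:3)
      oracle <- oracle | (ctr$x > x0[k] & ctr$x < x1[k] &
                          ctr$y > y0[k] & ctr$y < y1[k])
    expect_equal(gridCodes(m), matrix(as.integer(oracle), 50, 50))
  }
})

test_that("protected area tallies count natural cells inside the mask only", {
  spec <- GridSpec(2, 5)
  cur <- CategoricalGrid(matrix(c(rep(101L, 9), 9002L), 2, 5), spec)
  mv <- matrix(0L, 2, 5); mv[1, 1:3] <- 1L; mv[2, 5] <- 1L   # covers 3 nat + 1 conv
  mask <- CategoricalGrid(mv, spec)
  at <- protectedAreasByType(cur, mask)
  expect_equal(at$area_km2[at$code == 101L], 3 * 0.0729)
  expect_equal(protectedConvertedArea(cur, mask)$protected_converted_km2, 0.0729)

  empty <- CategoricalGrid(matrix(0L, 2, 5), spec)
  expect_true(all(protectedAreasByType(cur, empty)$area_km2 == 0))

  full <- CategoricalGrid(matrix(1L, 2, 5), spec)
  natTab <- tabulateArea(cur)
  natTab <- natTab[natTab$code < 9000L, ]
  expect_equal(protectedAreasByType(cur, full), natTab,
               ignore_attr = TRUE)
})

test_that("representation percentages and the 17% flag follow the definitions", {
  rec <- protectionRepresentation(areaTable(101, 17), areaTable(101, 100),
                                  areaTable(101, 50))
  expect_equal(rec$pct_of_potential, 17.0)
  expect_equal(rec$pct_of_current, 34.0)
  expect_true(rec$meets_17)
  expect_equal(rec$protection_class, "17-30%")

  zero <- protectionRepresentation(areaTable(101, 0), areaTable(101, 100),
                                   areaTable(101, 50))
  expect_equal(zero$pct_of_potential, 0)
  expect_false(zero$meets_17)

  fullp <- protectionRepresentation(areaTable(101, 80), areaTable(101, 80),
                                    areaTable(101, 80))
  expect_equal(c(fullp$pct_of_potential, fullp$pct_of_current), c(100, 100))

  expect_error(
    protectionRepresentation(areaTable(101, 60), areaTable(101, 100),
                             areaTable(101, 50)),
    class = "ee_protected_exceeds_current")
})

test_that("protection bins include the Aichi cut and honour stated closures", {
  expect_equal(classifyProtection(21.0), "17-30%")
  expect_equal(classifyProtection(0.5), "0-1%")
  expect_equal(classifyProtection(17.0), "17-30%")   # boundary closes upward
  expect_equal(classifyProtection(100), ">70%")
  expect_equal(classifyProtection(55, protectionBins("top50")), ">50%")
  expect_error(classifyProtection(101), class = "ee_out_of_range")
})

test_that("growing the mask is monotone and the flag agrees with the bins", {
  set.seed(31)
  land <- simulateLandscape(simConfig(nRows = 40, nCols = 40, nTypes = 5,
                                      paCoverage = 0.10, seed = 8))
  cur <- overlayCurrent(land$potential, land$composite)
  pot <- tabulateArea(land$potential)
  curNat <- tabulateArea(cur); curNat <- curNat[curNat$code < 9000L, ]

  repAt <- function(mask) {
    protectionRepresentation(protectedAreasByType(cur, mask), pot, curNat)
  }
  r1 <- repAt(land$mask)
  grown <- gridCodes(land$mask)
  grown[1:20, ] <- 1L
  r2 <- repAt(CategoricalGrid(grown, gridSpec(land$mask)))
  expect_true(all(r2$pct_of_potential >= r1$pct_of_potential))
  expect_true(all(r2$pct_of_current >= r1$pct_of_current, na.rm = TRUE))

  # invariants: protected <= current natural <= potential; pct_pot <= pct_cur
  expect_true(all(r1$protected_km2 <=
                    curNat$area_km2[match(r1$type_code, curNat$code)] + 1e-9))
  expect_true(all(r1$pct_of_potential <= r1$pct_of_current + 1e-9, na.rm = TRUE))

  above <- c("17-30%", "30-50%", "50-70%", ">70%")
  expect_equal(r1$meets_17, r1$protection_class %in% above)
  expect_equal(r2$meets_17, r2$protection_class %in% above)
})
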