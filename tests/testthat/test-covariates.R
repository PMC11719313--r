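geom5 <- gridGeometry(5, 5, cellSize = 100)

test_that("distance rasters match closed-form and brute-force nearest-feature search", {
  ## single point at a cell center: zero there, hypot elsewhere
  p <- cbind(x = 250, y = 250)
  d <- distanceRaster(p, geom5)
  expect_equal(d[3, 3], 0)
  expected <- outer(1:5, 1:5, function(i, j)
    sqrt(((j - 0.5) * 100 - 250)^2 + ((500 - (i - 0.5) * 100) - 250)^2))
  expect_equal(d, expected)
  ## several random points: elementwise min property and brute force
  set.seed(1)
  pts <- cbind(x = runif(7, 0, 500), y = runif(7, 0, 500))
  dAll <- distanceRaster(pts, geom5)
  singles <- lapply(seq_len(7), function(i)
    distanceRaster(pts[i, , drop = FALSE], geom5))
  expect_equal(dAll, Reduce(pmin, singles))
  ## brute force on a 50x50 grid with line segments
  g50 <- gridGeometry(50, 50, cellSize = 10)
  segs <- cbind(x0 = c(0, 100), y0 = c(0, 400), x1 = c(500, 300),
                y1 = c(500, 100))
  dl <- distanceRaster(segs, g50)
  brute <- matrix(NA_real_, 50, 50)
  segd <- function(px, py, s) {
    dx <- s[3] - s[1]; dy <- s[4] - s[2]
    t <- pmin(1, pmax(0, ((px - s[1]) * dx + (py - s[2]) * dy) /
                        (dx^2 + dy^2)))
    sqrt((px - (s[1] + t * dx))^2 + (py - (s[2] + t * dy))^2)
  }
  for (i in 1:50) for (j in 1:50) {
    px <- (j - 0.5) * 10; py <- 500 - (i - 0.5) * 10
    brute[i, j] <- min(segd(px, py, segs[1, ]), segd(px, py, segs[2, ]))
  }
  expect_equal(dl, brute, tolerance = 1e-12)
})

test_that("distance rasters reject empty features and geographic CRS", {
  expect_error(distanceRaster(matrix(numeric(0), 0, 2), geom5), "empty")
  gdeg <- gridGeometry(5, 5, cellSize = 100, crs = "EPSG:4326")
  expect_error(distanceRaster(cbind(1, 1), gdeg), "projected")
})

test_that("point density equals count over the analytic neighborhood area", {
  p <- cbind(x = 250, y = 250)
  dens <- densityRaster(p, geom5, radius = 500, mode = "count")
  expect_equal(dens[3, 3], 1 / (pi * 0.5^2 * 100))
  ## far cells see nothing
  g <- gridGeometry(11, 11, cellSize = 100)
  dfar <- densityRaster(p, g, radius = 100, mode = "count")
  expect_equal(dfar[11, 11], 0)
  ## duplicating features doubles the density everywhere
  expect_equal(densityRaster(rbind(p, p), geom5, 500, "count"), 2 * dens)
  expect_error(densityRaster(p, geom5, radius = -5), "positive")
})

test_that("line density uses the clipped in-circle length", {
  ## horizontal line through the center cell: chord = full diameter
  seg <- cbind(x0 = -1000, y0 = 250, x1 = 2000, y1 = 250)
  dens <- densityRaster(seg, geom5, radius = 300, mode = "length")
  expect_equal(dens[3, 3], 600 / (pi * 0.3^2 * 100))
  expect_error(densityRaster(seg, geom5, 300, "count"), "point")
  expect_error(densityRaster(cbind(x = 1, y = 1), geom5, 300, "length"),
               "line")
})

test_that("focal texture matches the direct window formulas and is NoData-aware", {
  const <- matrix(4.2, 6, 6)
  tx <- focalTexture(const, 3)
  expect_lt(max(tx$sd), 1e-6)
  expect_true(all(tx$range == 0))
  expect_equal(tx$mean, const)
  set.seed(7)
  m <- matrix(rnorm(25), 5, 5)
  tx <- focalTexture(m, 3)
  win <- as.vector(m[2:4, 2:4])
  expect_equal(tx$mean[3, 3], mean(win))
  expect_equal(tx$sd[3, 3], sd(win))
  expect_equal(tx$min[3, 3], min(win))
  expect_equal(tx$max[3, 3], max(win))
  expect_equal(tx$range[3, 3], diff(range(win)))
  ## NoData hole: neighbors computed over valid cells only
  m[3, 3] <- NA
  tx2 <- focalTexture(m, 3)
  expect_equal(tx2$mean[2, 2], mean(m[1:3, 1:3], na.rm = TRUE))
  expect_false(is.na(tx2$sd[3, 3]))
  expect_error(focalTexture(m, 4), "odd")
  expect_error(focalTexture(m, 7), "larger")
})

test_that("resampling aggregates blocks and masking writes NoData", {
  g30 <- gridGeometry(6, 6, cellSize = 50)
  layers <- list(cont = matrix(3.14, 6, 6),
                 cnt = matrix(1, 6, 6))
  meta <- data.frame(name = c("cont", "cnt"), unit = c("m", "count"),
                     category = c("Greenness", "Population"))
  st <- covariateStack(layers, g30, meta)
  ## identity resample with an all-true mask leaves values unchanged
  same <- resampleAndMask(st, 50, matrix(TRUE, 6, 6))
  expect_identical(getLayer(same, "cont"), layers$cont)
  ## 50 m -> 100 m: constant layer stays constant (mean), counts sum
  agg <- resampleAndMask(st, 100, how = c(cnt = "sum"))
  expect_equal(gridDim(agg), c(3L, 3L))
  expect_true(all(getLayer(agg, "cont") == 3.14))
  expect_true(all(getLayer(agg, "cnt") == 4))
  ## all-false mask blanks everything
  blank <- resampleAndMask(st, 100, matrix(FALSE, 3, 3))
  expect_true(all(is.na(getLayer(blank, "cont"))))
  expect_error(resampleAndMask(st, 75), "integer multiple")
  expect_error(resampleAndMask(st, 100, matrix(TRUE, 6, 6)), "target grid")
})

test_that("engineered landscape layers respect non-negativity and alignment", {
  fx <- fixtureLandscape(seed = 5L)
  st <- landscapeStack(fx$land)
  for (nm in c("dist_city", "dist_roads", "road_density", "amenity_density",
               "population", "slope"))
    expect_true(all(getLayer(st, nm) >= 0), label = nm)
  expect_true(validObject(st))
  tx <- addTextureLayers(st, "ndvi", 3)
  expect_setequal(setdiff(layerNames(tx), layerNames(st)),
                  paste0("ndvi_tex_", c("mean", "sd", "min", "max", "range")))
  expect_true(validObject(tx))
})
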