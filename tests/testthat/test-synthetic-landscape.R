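test_that("identical config and seed give bit-identical landscapes and surveys", {
  cfg <- landscapeConfig(gridShape = c(20L, 20L), seed = 1L,
                         nPointsPerClass = c(underweight = 5L, normal = 20L,
                                             overweight_obese = 20L))
  a <- generateCovariates(cfg)
  b <- generateCovariates(cfg)
  expect_identical(landscapeStack(a)@layers, landscapeStack(b)@layers)
  expect_identical(landscapeMask(a), landscapeMask(b))
  expect_identical(landscapeRoads(a), landscapeRoads(b))
  sa <- simulateSurvey(a)
  sb <- simulateSurvey(b)
  expect_identical(surveyData(sa$points), surveyData(sb$points))
  expect_identical(sa$truth@probSurfaces, sb$truth@probSurfaces)
})

test_that("the distance-to-city layer vanishes at the designated center cell", {
  land <- generateCovariates(landscapeConfig(gridShape = c(25L, 25L), seed = 4L))
  d <- getLayer(landscapeStack(land), "dist_city")
  expect_equal(min(d), 0)
  ## the zero must sit at the cell containing the stored city center
  geom <- gridGeom(land)
  cc <- land@cityCenter
  i <- which(d == 0, arr.ind = TRUE)
  expect_equal(geom@xmin + (i[1, "col"] - 0.5) * geom@cellSize, cc[1])
  expect_equal(geom@ymax - (i[1, "row"] - 0.5) * geom@cellSize, cc[2])
})

test_that("spatialRange controls the lag-1 autocorrelation of the random fields", {
  noisy <- generateCovariates(landscapeConfig(gridShape = c(40L, 40L),
                                              seed = 9L, spatialRange = 0))
  smooth <- generateCovariates(landscapeConfig(gridShape = c(40L, 40L),
                                               seed = 9L, spatialRange = 500))
  ## ndvi is a pure random field (no deterministic gradient mixed in)
  lag1 <- function(m) {
    h <- cor(as.vector(m[, -ncol(m)]), as.vector(m[, -1]))
    v <- cor(as.vector(m[-nrow(m), ]), as.vector(m[-1, ]))
    mean(c(h, v))
  }
  expect_lt(abs(lag1(getLayer(landscapeStack(noisy), "ndvi"))), 0.1)
  expect_gt(lag1(getLayer(landscapeStack(smooth), "ndvi")), 0.5)
})

test_that("ground-truth class probabilities are conserved and respond to drivers", {
  fx <- fixtureLandscape(seed = 21L)
  s <- Reduce(`+`, fx$truth@probSurfaces)
  expect_lt(max(abs(s - 1)), 1e-9)
  expect_true(all(unlist(fx$truth@probSurfaces) >= 0))
  ## strong positive road-density effect: point-level association positive
  pd <- surveyData(fx$points)
  rd <- getLayer(landscapeStack(fx$land), "road_density")
  geom <- gridGeom(fx$land)
  cells <- fx$truth@points$cell
  rc <- cbind((cells - 1) %/% geom@ncol + 1, (cells - 1) %% geom@ncol + 1)
  r <- cor(rd[rc], as.numeric(pd$bmi_class == "overweight_obese"))
  expect_gt(r, 0)
})

test_that("with zero driver effects class frequencies match base rates within 3 SE", {
  n <- c(underweight = 60L, normal = 240L, overweight_obese = 300L)
  cfg <- landscapeConfig(gridShape = c(50L, 50L), seed = 13L,
                         nPointsPerClass = n,
                         driverEffects = list(),
                         baseRates = n / sum(n))
  land <- generateCovariates(cfg)
  sim <- simulateSurvey(land)
  tab <- table(factor(surveyData(sim$points)$bmi_class,
                      levels = c("underweight", "normal", "overweight_obese")))
  p0 <- n / sum(n)
  se <- sqrt(p0 * (1 - p0) / sum(n))
  expect_true(all(abs(as.numeric(tab) / sum(tab) - p0) <= 3 * se))
})

test_that("survey points stay in the mask, one per cell, and quotas are infeasible beyond it", {
  fx <- fixtureLandscape(seed = 8L)
  cells <- fx$truth@points$cell
  expect_false(any(duplicated(cells)))
  geom <- gridGeom(fx$land)
  rc <- cbind((cells - 1) %/% geom@ncol + 1, (cells - 1) %% geom@ncol + 1)
  expect_true(all(landscapeMask(fx$land)[rc]))
  ## BMI values always consistent with the assigned class
  expect_identical(classifyBmi(surveyData(fx$points)$bmi_kg_m2),
                   surveyData(fx$points)$bmi_class)
  big <- landscapeConfig(gridShape = c(10L, 10L), seed = 1L,
                         nPointsPerClass = c(underweight = 200L,
                                             normal = 200L,
                                             overweight_obese = 200L))
  expect_error(simulateSurvey(generateCovariates(big)), "infeasible")
})

test_that("empty point quotas give an empty survey but a valid ground truth", {
  cfg <- landscapeConfig(gridShape = c(15L, 15L), seed = 2L,
                         nPointsPerClass = c(underweight = 0L, normal = 0L,
                                             overweight_obese = 0L))
  sim <- simulateSurvey(generateCovariates(cfg))
  expect_identical(nrow(surveyData(sim$points)), 0L)
  expect_true(validObject(sim$truth))
})

test_that("config validation rejects bad geometry, rates and unknown drivers", {
  expect_error(landscapeConfig(maskFraction = 1.2), "maskFraction")
  expect_error(landscapeConfig(baseRates = c(0.5, 0.5, 0.5)), "summing to 1")
  land <- generateCovariates(landscapeConfig(gridShape = c(15L, 15L), seed = 1L))
  cfg <- landscapeConfig(gridShape = c(15L, 15L), seed = 1L,
                         driverEffects = list(overweight_obese = c(nope = 1)))
  expect_error(simulateSurvey(land, cfg), "unknown layer")
})
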