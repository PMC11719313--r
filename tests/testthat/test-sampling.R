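test_that("WHO BMI cutoffs classify values and reject non-positive input", {
  expect_identical(classifyBmi(17.0), "underweight")
  expect_identical(classifyBmi(18.5), "normal")
  expect_identical(classifyBmi(31.4), "overweight_obese")
  ## boundary convention: normal extends through 25.0 (strictly > 25.0
  ## is overweight-obese)
  expect_identical(classifyBmi(c(24.95, 25.0, 25.01)),
                   c("normal", "normal", "overweight_obese"))
  expect_error(classifyBmi(0), "positive")
  expect_error(classifyBmi(c(22, NA)), "positive")
})

test_that("survey points validate class-value consistency", {
  d <- data.frame(id = 1:2, x = c(10, 20), y = c(10, 20),
                  bmi_kg_m2 = c(17, 30), city = "a")
  sp <- surveyPoints(d)
  expect_identical(surveyData(sp)$bmi_class,
                   c("underweight", "overweight_obese"))
  bad <- surveyData(sp)
  bad$bmi_class <- c("normal", "normal")
  expect_error(validObject(new("SurveyPoints", data = bad)), "inconsistent")
})

test_that("dissimilarity index is zero at training-identical cells and bounds LOO DI", {
  fx <- sharedDesign()
  aoa <- fx$aoa
  expect_true(validObject(aoa))
  expect_true(all(dissimilarity(aoa) >= 0, na.rm = TRUE))
  ## cells holding the training points themselves have DI = 0
  d <- designData(fx$design)
  surveyRows <- d[d$role != "background", ]
  geom <- gridGeom(fx$design)
  rc <- cbind((surveyRows$cell - 1) %/% geom@ncol + 1,
              (surveyRows$cell - 1) %% geom@ncol + 1)
  expect_true(all(dissimilarity(aoa)[rc] < 1e-6))
  ## by the whisker construction, >= 75% of training points fall at or
  ## below the threshold under leave-one-out
  s0 <- buildDesign(fx$points, "overweight_obese", fx$stack)
  X <- as.matrix(designData(s0)[, covariateNames(s0)])
  sdv <- apply(X, 2, sd)
  Z <- sweep(sweep(X, 2, colMeans(X)), 2, ifelse(sdv > 0, sdv, 1), "/")
  D <- as.matrix(dist(Z))
  dbar <- mean(D[upper.tri(D)])
  diag(D) <- Inf
  loo <- apply(D, 1, min) / dbar
  expect_gte(mean(loo <= aoaThreshold(aoa)), 0.75)
})

test_that("a region shifted by 10 training SDs falls outside the area of applicability", {
  fx <- sharedDesign()
  stack <- fx$stack
  shifted <- stack@layers
  sdv <- sd(designData(fx$design)[["ndvi"]])
  shifted$ndvi[1:8, 1:8] <- shifted$ndvi[1:8, 1:8] + 10 * sdv
  stack2 <- covariateStack(shifted, stack@geometry, stack@meta)
  aoa2 <- dissimilarityIndex(buildDesign(fx$points, "overweight_obese", stack),
                             stack2)
  expect_false(any(supportedMask(aoa2)[1:8, 1:8]))
})

test_that("degenerate training sets are rejected and constants excluded", {
  covs <- data.frame(a = rep(1, 10), b = rep(2, 10))
  des <- designFromTable(covs, rep(c("presence", "absence"), 5))
  g <- gridGeometry(10, 1, cellSize = 100)
  st <- covariateStack(list(a = matrix(1, 10, 1), b = matrix(2, 10, 1)), g,
                       data.frame(name = c("a", "b"), unit = "",
                                  category = "Greenness"))
  expect_error(suppressWarnings(dissimilarityIndex(des, st)), "identical")
  covs$a <- rnorm(10)
  des2 <- designFromTable(covs, rep(c("presence", "absence"), 5))
  st2 <- covariateStack(list(a = matrix(rnorm(10), 10, 1),
                             b = matrix(2, 10, 1)), g,
                        data.frame(name = c("a", "b"), unit = "",
                                   category = "Greenness"))
  expect_warning(dissimilarityIndex(des2, st2), "zero-variance")
})

test_that("target-group background avoids survey cells and honors the AOA", {
  fx <- sharedDesign()
  occ <- designData(buildDesign(fx$points, "overweight_obese", fx$stack))$cell
  expect_false(any(fx$background$cell %in% occ))
  supp <- supportedMask(fx$aoa)
  geom <- gridGeom(fx$aoa)
  rc <- cbind((fx$background$cell - 1) %/% geom@ncol + 1,
              (fx$background$cell - 1) %% geom@ncol + 1)
  expect_true(all(supp[rc]))
  ## deterministic under seed
  pd <- surveyData(fx$points)
  pres <- surveyPoints(pd[pd$bmi_class == "overweight_obese", , drop = FALSE])
  b1 <- sampleBackground(pres, landscapeMask(fx$land), fx$aoa, 50, seed = 99L,
                         exclude = fx$points)
  b2 <- sampleBackground(pres, landscapeMask(fx$land), fx$aoa, 50, seed = 99L,
                         exclude = fx$points)
  expect_identical(b1, b2)
  ## unsupported AOA or exhausted cells raise errors
  none <- new("AOAResult", di = dissimilarity(fx$aoa),
              threshold = aoaThreshold(fx$aoa),
              supported = matrix(FALSE, geom@nrow, geom@ncol),
              geometry = geom)
  expect_error(sampleBackground(pres, landscapeMask(fx$land), none, 10),
               "no eligible")
  expect_error(sampleBackground(pres, landscapeMask(fx$land), fx$aoa, 1e6,
                                exclude = fx$points), "shortfall")
})

test_that("uniform presence with a fully supported AOA gives near-uniform background", {
  ## hand-built scenario: presences spread evenly, DI supported everywhere
  g <- gridGeometry(20, 20, cellSize = 100)
  set.seed(31)
  pres <- surveyPoints(data.frame(
    id = 1:100, x = runif(100, 0, 2000), y = runif(100, 0, 2000),
    bmi_kg_m2 = runif(100, 26, 35), city = "u"))
  aoa <- new("AOAResult", di = matrix(0, 20, 20), threshold = 1,
             supported = matrix(TRUE, 20, 20), geometry = g)
  bg <- sampleBackground(pres, matrix(TRUE, 20, 20), aoa, n = 250,
                         seed = 5L, exclude = pres)
  ## chi-square GOF over the four grid quadrants
  qx <- ifelse(bg$x < 1000, 0, 1) + 2 * ifelse(bg$y < 1000, 0, 1)
  obs <- tabulate(qx + 1, nbins = 4)
  p <- suppressWarnings(chisq.test(obs, p = rep(0.25, 4))$p.value)
  expect_gt(p, 0.01)
})

test_that("design tables assemble presence, absence and background correctly", {
  ## 10/10/10 toy: target yields 10 presences and 20 absences
  g <- gridGeometry(6, 6, cellSize = 100)
  layers <- list(v = matrix(seq_len(36) * 1.0, 6, 6, byrow = TRUE))
  st <- covariateStack(layers, g, data.frame(name = "v", unit = "",
                                             category = "Greenness"))
  cells <- 1:30
  xs <- ((cells - 1) %% 6 + 0.5) * 100
  ys <- 600 - ((cells - 1) %/% 6 + 0.5) * 100
  pts <- surveyPoints(data.frame(
    id = 1:30, x = xs, y = ys,
    bmi_kg_m2 = rep(c(17, 22, 30), each = 10), city = "t"))
  des <- buildDesign(pts, "overweight_obese", st)
  expect_identical(sum(designData(des)$role == "presence"), 10L)
  expect_identical(sum(designData(des)$role == "absence"), 20L)
  ## extraction matches the grid values exactly
  expect_equal(designData(des)$v, as.numeric(cells))
  ## NoData cells are dropped with a message
  layers$v[1, 1] <- NA
  st2 <- covariateStack(layers, g, st@meta)
  expect_message(des2 <- buildDesign(pts, "underweight", st2), "NoData")
  expect_identical(nrow(designData(des2)), 29L)
  ## no survey point of the target class at all
  few <- surveyPoints(data.frame(id = 1, x = 50, y = 550,
                                 bmi_kg_m2 = 22, city = "t"))
  expect_error(buildDesign(few, "overweight_obese", st), "no presence")
})

test_that("one record per cell holds across presence, absence and background", {
  fx <- sharedDesign()
  expect_false(any(duplicated(designData(fx$design)$cell)))
  expect_true(validObject(fx$design))
})
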