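test_that("decorrelation removes duplicates and enforces the correlation cap", {
  fx <- sharedDesign()
  des <- fx$design
  ## add an exact copy of road_density to the table
  d <- designData(des)
  d$road_copy <- d$road_density
  des2 <- new("DesignTable", data = d, targetClass = targetClass(des),
              covariates = c(covariateNames(des), "road_copy"),
              covariateMeta = rbind(des@covariateMeta,
                                    data.frame(name = "road_copy",
                                               category = "Road Density")),
              geometry = gridGeom(des))
  res <- decorrelate(des2, learnerSpec("maxent_lq", seed = 2), rMax = 0.8)
  expect_false(all(c("road_density", "road_copy") %in% res$retained))
  expect_true(any(c("road_density", "road_copy") %in% res$retained))
  ## post-condition: no retained pair exceeds the cap
  C <- abs(cor(designData(des2)[, res$retained]))
  diag(C) <- 0
  expect_lte(max(C), 0.8)
  expect_gt(length(res$retained), 0)
  expect_lt(length(res$retained), length(covariateNames(des2)))
})

test_that("independent variables pass decorrelation untouched", {
  set.seed(12)
  covs <- as.data.frame(matrix(rnorm(200 * 4), 200))
  names(covs) <- paste0("v", 1:4)
  des <- designFromTable(covs, rep(c("presence", "absence", "background",
                                     "background"), 50))
  res <- decorrelate(des, learnerSpec("maxent_lq", seed = 1), rMax = 0.8)
  expect_setequal(res$retained, names(covs))
  expect_identical(nrow(res$log), 0L)
})

test_that("decorrelation keeps the true driver among correlated pairs", {
  ## driver x drives the outcome; proxy is x + noise, correlated > 0.8
  hits <- 0
  for (r in 1:5) {
    set.seed(100 + r)
    n <- 150
    x <- rnorm(n)
    proxy <- x + rnorm(n, 0, 0.35)
    y <- rbinom(n, 1, plogis(2 * x))
    roles <- ifelse(y == 1, "presence", "absence")
    des <- designFromTable(data.frame(driver = x, proxy = proxy), roles)
    res <- decorrelate(des, learnerSpec("random_forest", seed = r),
                       rMax = 0.8)
    if (identical(res$retained, "driver")) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("jack-knife importance scores every variable and flags failures", {
  fx <- sharedDesign()
  jk <- jackknifeImportance(fx$design, learnerSpec("random_forest", seed = 2))
  expect_identical(nrow(jk), length(covariateNames(fx$design)))
  expect_equal(jk$auc100, 100 * jk$auc)
  expect_true(all(jk$category %in% c(
    "Nightlights", "House to City", "House to Roads", "House to Amenities",
    "Road Density", "Greenness", "Population", "Building density",
    "Topography")))
  ## the sole true driver tops a driver + noise comparison, noise ~ 0.5
  set.seed(41)
  n <- 200
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(2.5 * x))
  roles <- ifelse(y == 1, "presence", "absence")
  des <- designFromTable(data.frame(driver = x, noise = rnorm(n)), roles)
  jk2 <- jackknifeImportance(des, learnerSpec("random_forest", seed = 3))
  expect_identical(jk2$variable[which.max(jk2$auc)], "driver")
  expect_lt(abs(jk2$auc[jk2$variable == "noise"] - 0.5), 0.1)
})

test_that("permutation importance normalizes to 100% and isolates the driver", {
  set.seed(55)
  n <- 300
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(2.5 * x))
  roles <- ifelse(y == 1, "presence", "absence")
  des <- designFromTable(data.frame(driver = x, n1 = rnorm(n), n2 = rnorm(n)),
                         roles)
  fit <- fitPresenceAbsence(des, learnerSpec("boosted_trees", seed = 5),
                            folds = 3)
  pm <- permutationImportance(fit, des, iterations = 10, seed = 6)
  expect_equal(sum(pm$contribution), 100, tolerance = 0.5)
  expect_gt(pm$contribution[pm$variable == "driver"], 50)
  expect_lt(pm$contribution[pm$variable == "n1"], 5)
  ## a constant model yields uniform contributions with a warning
  cfit <- fitMaxent(design1D(40, seed = 2),
                    learnerSpec("maxent_lq", grid = list(lambda = 1e6)),
                    folds = 3)
  des1 <- design1D(40, seed = 2)
  dd <- designData(des1)
  dd$role[dd$role == "background"] <- "absence"
  desPA <- new("DesignTable", data = dd, targetClass = "overweight_obese",
               covariates = "x1",
               covariateMeta = data.frame(name = "x1",
                                          category = "Road Density"),
               geometry = gridGeom(des1))
  expect_warning(pmc <- permutationImportance(cfit, desPA, iterations = 2),
                 "uniform")
  expect_equal(pmc$contribution, 100)
})

test_that("category aggregation averages jack-knife and renormalizes permutation", {
  imp <- data.frame(variable = c("a", "b", "c"),
                    auc = c(0.8, 0.8, 0.6), auc100 = c(80, 80, 60),
                    category = c("Greenness", "Greenness", "Topography"))
  agg <- aggregateByCategory(imp)
  expect_equal(agg$auc[agg$category == "Greenness"], 0.8)
  expect_equal(agg$auc[agg$category == "Topography"], 0.6)
  pim <- data.frame(variable = c("a", "b", "c"),
                    contribution = c(30, 20, 50),
                    category = c("Greenness", "Greenness", "Topography"))
  pagg <- aggregateByCategory(pim)
  expect_equal(sum(pagg$contribution), 100)
  expect_equal(pagg$contribution[pagg$category == "Greenness"], 50)
  ## identity when every variable owns its category
  solo <- data.frame(variable = "a", contribution = 100,
                     category = "Greenness")
  expect_equal(aggregateByCategory(solo)$contribution, 100)
  bad <- data.frame(variable = "a", contribution = 1, category = "Nope")
  expect_error(aggregateByCategory(bad), "unknown category")
})

test_that("cross-city consistency reproduces hand-computed correlations", {
  mk <- function(v) data.frame(category = c("Greenness", "Topography",
                                            "Population"),
                               contribution = v)
  same <- list(a = mk(c(1, 2, 3)), b = mk(c(1, 2, 3)), c = mk(c(1, 2, 3)))
  expect_equal(crossCityConsistency(same)$mean_abs_r, 1.0)
  three <- list(a = mk(c(1, 2, 3)), b = mk(c(2, 4, 6)), c = mk(c(3, 2, 1)))
  res <- crossCityConsistency(three)
  expect_equal(sort(res$pairs$r), c(-1, -1, 1))
  expect_equal(res$mean_abs_r, 1.0)
  orth <- list(a = mk(c(1, 0, -1)), b = mk(c(0, 1, 0) - mean(c(0, 1, 0))))
  expect_equal(crossCityConsistency(orth)$pairs$r, 0, tolerance = 1e-12)
  flat <- list(a = mk(c(1, 1, 1)), b = mk(c(1, 2, 3)))
  expect_warning(expect_error(crossCityConsistency(flat), "no valid"),
                 "zero-variance")
})

test_that("response curves are flat for ignored variables and bounded", {
  ## a fully penalized MaxEnt ignores its covariate: flat curve
  des <- design1D(50, seed = 3)
  cfit <- fitMaxent(des, learnerSpec("maxent_lq", grid = list(lambda = 1e6)),
                    folds = 3)
  rc <- responseCurve(cfit, des, "x1", nGrid = 20)
  expect_lt(diff(range(rc$mean)), 1e-6)
  expect_true(all(rc$mean >= 0 & rc$mean <= 1))
  ## zero-range variables are rejected
  d <- designData(des)
  d$x1 <- 1
  dflat <- new("DesignTable", data = d, targetClass = "overweight_obese",
               covariates = "x1",
               covariateMeta = data.frame(name = "x1",
                                          category = "Road Density"),
               geometry = gridGeom(des))
  expect_error(responseCurve(cfit, dflat, "x1"), "zero range")
  expect_error(responseCurve(cfit, des, "nope"), "not in the model")
})
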