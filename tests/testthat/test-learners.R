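test_that("MaxEnt-style fits recover monotone and unimodal niches", {
  des <- design1D(n = 80, seed = 5)
  fit <- fitMaxent(des, learnerSpec("maxent_lq", seed = 1), folds = 3)
  grid <- matrix(seq(0.05, 0.95, length.out = 30), ncol = 1,
                 dimnames = list(NULL, "x1"))
  p <- predictLearner(fit, grid)
  expect_true(all(p >= 0 & p <= 1))
  ## presences cluster at high x: prediction rises over the data range
  expect_gt(cor(grid[, 1], p, method = "spearman"), 0.9)
  ## quadratic niche: presences at mid-range give a unimodal curve
  desQ <- design1D(n = 80, seed = 6, quadratic = TRUE)
  fitQ <- fitMaxent(desQ, learnerSpec("maxent_lq", seed = 1), folds = 3)
  pq <- predictLearner(fitQ, grid)
  peak <- which.max(pq)
  expect_gt(peak, 5)
  expect_lt(peak, 26)
  expect_true(all(diff(pq[1:peak]) >= -1e-8))
  expect_true(all(diff(pq[peak:30]) <= 1e-8))
})

test_that("an overwhelming penalty shrinks MaxEnt to the presence fraction", {
  des <- design1D(n = 60, seed = 7)
  fit <- fitMaxent(des, learnerSpec("maxent_lq", grid = list(lambda = 1e6),
                                    seed = 1), folds = 3)
  grid <- matrix(seq(0, 1, length.out = 11), ncol = 1,
                 dimnames = list(NULL, "x1"))
  p <- predictLearner(fit, grid)
  frac <- mean(designData(des)$label)
  expect_true(all(abs(p - frac) < 1e-3))
})

test_that("presence-absence learners separate a linearly separable toy", {
  des <- designSeparable(n = 40)
  X <- as.matrix(designData(des)[, covariateNames(des)])
  y <- designData(des)$label
  for (fam in c("random_forest", "boosted_trees", "neural_net")) {
    fit <- fitPresenceAbsence(des, learnerSpec(fam, seed = 4), folds = 4)
    p <- predictLearner(fit, X)
    expect_equal(aucScore(p[y == 1], p[y == 0]), 1.0,
                 label = paste(fam, "training AUC"))
  }
})

test_that("shuffled labels give chance-level CV AUC", {
  set.seed(9)
  n <- 120
  x <- data.frame(a = rnorm(n), b = rnorm(n))
  roles <- sample(rep(c("presence", "absence"), n / 2))
  des <- designFromTable(x, roles)
  fit <- fitPresenceAbsence(des, learnerSpec("random_forest", seed = 2),
                            folds = 5)
  expect_lt(abs(cvAUC(fit) - 0.5), 0.15)
})

test_that("fits are deterministic under a fixed seed", {
  des <- sharedDesign()$design
  for (fam in c("random_forest", "neural_net", "maxent_lqh")) {
    s <- learnerSpec(fam, seed = 31)
    f1 <- tuneLearner(des, s, folds = 3)
    f2 <- tuneLearner(des, s, folds = 3)
    expect_identical(oofPredictions(f1), oofPredictions(f2), label = fam)
    expect_identical(cvAUC(f1), cvAUC(f2), label = fam)
  }
})

test_that("grid search returns the winner of the logged grid", {
  des <- sharedDesign()$design
  ## size-1 grid: the returned hyperparameters are that grid point
  one <- tuneLearner(des, learnerSpec("boosted_trees",
                                      grid = list(nrounds = 30L,
                                                  max_depth = 3L, eta = 0.2),
                                      seed = 1), folds = 3)
  expect_identical(one@hyperparameters$nrounds, 30L)
  expect_identical(one@hyperparameters$max_depth, 3L)
  ## winner attains the maximal mean CV AUC in the grid log
  tuned <- tuneLearner(des, learnerSpec("random_forest", seed = 5), folds = 3)
  gl <- gridLog(tuned)
  expect_equal(cvAUC(tuned), max(gl$mean_cv_auc), tolerance = 0.03)
  win <- gl[gl$mean_cv_auc == max(gl$mean_cv_auc), , drop = FALSE]
  expect_true(tuned@hyperparameters$mtry_frac %in% win$mtry_frac)
  ## a degenerate setting loses to a reasonable one on signal data
  deg <- tuneLearner(des, learnerSpec(
    "boosted_trees", grid = list(nrounds = c(1L, 100L), max_depth = c(1L, 3L),
                                 eta = 0.1), seed = 5), folds = 3)
  expect_gte(deg@hyperparameters$nrounds, 100L)
})

test_that("single-class designs and wrong families are rejected", {
  des <- designFromTable(data.frame(a = rnorm(10)), rep("presence", 10))
  expect_error(fitPresenceAbsence(des, learnerSpec("random_forest")), "absence")
  expect_error(fitMaxent(des, learnerSpec("random_forest")), "maxent")
  expect_error(fitPresenceAbsence(sharedDesign()$design,
                                  learnerSpec("maxent_lq")),
               "random_forest|boosted|neural")
})

test_that("every family beats chance clearly on strong-driver synthetic data", {
  ## n = 200 presence, one strong driver; landscape-wide uniform
  ## background (the classic presence-only contrast against the full
  ## available environment) so every family sees the signal
  fx <- fixtureLandscape(
    seed = 61L, shape = c(50L, 50L),
    quotas = c(underweight = 40L, normal = 160L, overweight_obese = 200L),
    effects = list(overweight_obese = c(road_density = 2.5)))
  fx$stack <- landscapeStack(fx$land)
  set.seed(77)
  g <- gridGeom(fx$stack)
  occ <- designData(buildDesign(fx$points, "overweight_obese", fx$stack))$cell
  free <- setdiff(seq_len(g@nrow * g@ncol), occ)
  bgc <- sample(free, 400)
  bg <- data.frame(
    x = g@xmin + ((bgc - 1) %% g@ncol + 0.5) * g@cellSize,
    y = g@ymax - ((bgc - 1) %/% g@ncol + 0.5) * g@cellSize,
    cell = bgc, role = "background")
  des <- buildDesign(fx$points, "overweight_obese", fx$stack, bg)
  for (fam in c("maxent_lq", "maxent_lqh", "random_forest", "boosted_trees",
                "neural_net")) {
    fit <- tuneLearner(des, learnerSpec(fam, seed = 3), folds = 5)
    expect_gt(cvAUC(fit), 0.7)
  }
})
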