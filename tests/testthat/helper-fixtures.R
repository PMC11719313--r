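## Shared fixtures, cached across test files so expensive model fits are
## built once per run.
.fixtureCache <- new.env(parent = emptyenv())

.cached <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache)) {
    assign(key, force(expr), envir = .fixtureCache)
  }
  get(key, envir = .fixtureCache)
}

fixtureLandscape <- function(seed = 3L, shape = c(30L, 30L),
                             quotas = c(underweight = 15L, normal = 60L,
                                        overweight_obese = 60L),
                             effects = list(
                               overweight_obese = c(road_density = 1.5,
                                                    dist_city = -1.0),
                               underweight = c(dist_city = 0.5))) {
  cfg <- landscapeConfig(gridShape = shape, seed = seed,
                         nPointsPerClass = quotas, driverEffects = effects)
  land <- generateCovariates(cfg)
  sim <- simulateSurvey(land)
  list(cfg = cfg, land = land, points = sim$points, truth = sim$truth)
}

fixtureDesign <- function(seed = 3L, nbg = 250L,
                          target = "overweight_obese", ...) {
  fx <- fixtureLandscape(seed, ...)
  stack <- landscapeStack(fx$land)
  s0 <- buildDesign(fx$points, target, stack)
  aoa <- dissimilarityIndex(s0, stack, mask = landscapeMask(fx$land))
  pd <- surveyData(fx$points)
  pres <- surveyPoints(pd[pd$bmi_class == target, , drop = FALSE])
  avail <- sum(supportedMask(aoa), na.rm = TRUE) - nrow(pd)
  bg <- sampleBackground(pres, landscapeMask(fx$land), aoa,
                         n = min(nbg, avail), seed = seed + 7L,
                         exclude = fx$points)
  des <- buildDesign(fx$points, target, stack, bg)
  c(fx, list(stack = stack, design = des, aoa = aoa, background = bg))
}

## One fitted ensemble shared by the ensemble / interpretation tests.
sharedStackFit <- function() {
  .cached("stackfit", {
    fx <- .cached("design3", fixtureDesign(seed = 3L))
    list(fx = fx, model = fitStack(fx$design, folds = 5L, seed = 11L))
  })
}

sharedDesign <- function() .cached("design3", fixtureDesign(seed = 3L))

## Build a DesignTable directly from a data.frame of covariates + roles,
## for learner-level tests that need full control of the data.
designFromTable <- function(covs, roles, geom = NULL,
                            target = "overweight_obese",
                            categories = NULL) {
  covs <- as.data.frame(covs)
  n <- nrow(covs)
  if (is.null(geom)) geom <- gridGeometry(n, 1, cellSize = 100)
  if (is.null(categories))
    categories <- rep("Road Density", ncol(covs))
  d <- data.frame(x = geom@xmin + 50, y = geom@ymax - (seq_len(n) - 0.5) * 100,
                  cell = seq_len(n), role = roles,
                  label = as.integer(roles == "presence"))
  d <- cbind(d, covs)
  new("DesignTable", data = d, targetClass = target,
      covariates = names(covs),
      covariateMeta = data.frame(name = names(covs), category = categories),
      geometry = geom)
}

## 1-D presence/background design: presences clustered at high x.
design1D <- function(n = 60L, seed = 5L, quadratic = FALSE) {
  set.seed(seed)
  xb <- runif(n, 0, 1)
  xp <- if (quadratic) rnorm(n, 0.5, 0.08) else rbeta(n, 6, 1.2)
  xp <- pmin(1, pmax(0, xp))
  designFromTable(data.frame(x1 = c(xp, xb)),
                  rep(c("presence", "background"), each = n))
}

## Linearly separable presence/absence toy.
designSeparable <- function(n = 40L, seed = 2L) {
  set.seed(seed)
  x <- c(runif(n / 2, 0.6, 1), runif(n / 2, 0, 0.4))
  x2 <- runif(n)
  designFromTable(data.frame(a = x, b = x2),
                  rep(c("presence", "absence"), each = n / 2))
}
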