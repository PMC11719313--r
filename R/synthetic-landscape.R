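#' @include AllClasses.R utils.R
NULL

#' Configure a synthetic study landscape
#'
#' Builds the configuration of a seeded synthetic study area: a regular
#' 1-ha grid with spatially autocorrelated covariate fields, a
#' built-up/older-adults mask, a synthetic road network and amenity
#' points, and a 3-class multinomial outcome model whose class
#' probabilities respond to named covariate drivers.
#'
#' Defaults encode the study regime the package targets: underweight is
#' rare (base rate 10\%), and overweight-obese probability rises with
#' road density and falls with distance to the city center.
#'
#' @param gridShape integer (rows, cols); default 60 x 60 cells.
#' @param cellSize cell edge in meters (default 100 m, i.e. 1 ha cells).
#' @param seed integer master seed; identical configuration and seed give
#'   bit-identical landscapes and surveys.
#' @param nPointsPerClass named integer vector of per-class point quotas.
#' @param driverEffects named list: for each non-reference class
#'   (\code{overweight_obese}, \code{underweight}) a named numeric vector
#'   of coefficients on standardized covariate layers (log-odds scale,
#'   reference class \code{normal}).
#' @param baseRates length-3 numeric (underweight, normal,
#'   overweight_obese) base class rates, realized when all driver effects
#'   are zero; must sum to 1.
#' @param spatialRange autocorrelation length (m) of the random fields.
#' @param maskFraction fraction of cells designated built-up/older-adult.
#' @return a \linkS4class{LandscapeConfig}.
#' @examples
#' cfg <- landscapeConfig(gridShape = c(30, 30), seed = 7)
#' cfg
#' @export
landscapeConfig <- function(gridShape = c(60L, 60L), cellSize = 100,
                            seed = 1L,
                            nPointsPerClass = c(underweight = 50L,
                                                normal = 250L,
                                                overweight_obese = 250L),
                            driverEffects = list(
                              overweight_obese = c(road_density = 1.5,
                                                   dist_city = -1.0),
                              underweight = c(dist_city = 0.5)),
                            baseRates = c(underweight = 0.10, normal = 0.45,
                                          overweight_obese = 0.45),
                            spatialRange = 500, maskFraction = 0.35) {
  np <- nPointsPerClass
  if (is.null(names(np))) names(np) <- .bmiClasses
  br <- as.numeric(baseRates)
  names(br) <- if (is.null(names(baseRates))) .bmiClasses else names(baseRates)
  new("LandscapeConfig", gridShape = as.integer(gridShape),
      cellSize = as.numeric(cellSize), seed = as.integer(seed),
      nPointsPerClass = stats::setNames(as.integer(np[.bmiClasses]), .bmiClasses),
      driverEffects = driverEffects,
      baseRates = br[.bmiClasses],
      spatialRange = as.numeric(spatialRange),
      maskFraction = as.numeric(maskFraction))
}

## Synthetic road network: radial spokes out of the city center plus a
## rectangular street grid in the urban quadrant, giving the density and
## distance covariates an urban-rural contrast.
.makeRoads <- function(geom, center, nSpokes = 8L) {
  W <- geom@ncol * geom@cellSize
  H <- geom@nrow * geom@cellSize
  reach <- sqrt(W^2 + H^2)
  ang <- seq(0, 2 * pi, length.out = nSpokes + 1L)[-(nSpokes + 1L)] +
    stats::runif(nSpokes, -0.15, 0.15)
  spokes <- cbind(x0 = center[1], y0 = center[2],
                  x1 = center[1] + reach * cos(ang),
                  y1 = center[2] + reach * sin(ang))
  ## street grid: box of ~40% of the extent around the center, 500 m pitch
  bw <- 0.4 * min(W, H)
  xs <- seq(center[1] - bw / 2, center[1] + bw / 2, by = 500)
  ys <- seq(center[2] - bw / 2, center[2] + bw / 2, by = 500)
  grid <- rbind(
    cbind(x0 = xs, y0 = min(ys), x1 = xs, y1 = max(ys)),
    cbind(x0 = min(xs), y0 = ys, x1 = max(xs), y1 = ys))
  segs <- rbind(spokes, grid)
  ## clip endpoints to the study extent
  segs[, c("x0", "x1")] <- pmin(pmax(segs[, c("x0", "x1")], geom@xmin),
                                geom@xmin + W)
  segs[, c("y0", "y1")] <- pmin(pmax(segs[, c("y0", "y1")], geom@ymax - H),
                                geom@ymax)
  segs
}

#' Generate the synthetic covariate stack and vector layers
#'
#' Produces a landscape with at least eight covariate layers spanning the
#' canonical categories (distance to city center, distance to roads, road
#' density, amenity distance/density, an NDVI-like greenness field,
#' elevation and slope, population, nightlights, building density). The
#' random fields are Gaussian-smoothed white noise (kernel width
#' \code{spatialRange / cellSize}); the city-center distance is a
#' deterministic gradient anchored at a designated cell center. Road and
#' amenity vector layers are returned so the covariate-engineering
#' operations can be exercised end to end.
#'
#' @param config a \linkS4class{LandscapeConfig}.
#' @return a \linkS4class{SyntheticLandscape}.
#' @examples
#' land <- generateCovariates(landscapeConfig(gridShape = c(20, 20), seed = 1))
#' layerNames(landscapeStack(land))
#' @export
generateCovariates <- function(config) {
  stopifnot(is(config, "LandscapeConfig"))
  validObject(config)
  geom <- gridGeometry(config@gridShape[1], config@gridShape[2],
                       cellSize = config@cellSize)
  .withSeed(config@seed, {
    W <- geom@ncol * geom@cellSize
    H <- geom@nrow * geom@cellSize
    ## city center snapped to a cell center in the upper-left (urban) quadrant
    ccell <- .cellFromXY(geom, 0.3 * W, geom@ymax - 0.3 * H)
    rc <- .rowColFromCell(geom, ccell)
    center <- c(geom@xmin + (rc[, "col"] - 0.5) * geom@cellSize,
                geom@ymax - (rc[, "row"] - 0.5) * geom@cellSize)

    roads <- .makeRoads(geom, center)
    nAmen <- max(20L, round(0.025 * geom@nrow * geom@ncol))
    amen <- cbind(
      x = c(stats::rnorm(round(0.75 * nAmen), center[1], 0.12 * W),
            stats::runif(nAmen - round(0.75 * nAmen), geom@xmin, geom@xmin + W)),
      y = c(stats::rnorm(round(0.75 * nAmen), center[2], 0.12 * H),
            stats::runif(nAmen - round(0.75 * nAmen), geom@ymax - H, geom@ymax)))
    amen[, "x"] <- pmin(pmax(amen[, "x"], geom@xmin + 1), geom@xmin + W - 1)
    amen[, "y"] <- pmin(pmax(amen[, "y"], geom@ymax - H + 1), geom@ymax - 1)

    sigma <- config@spatialRange / config@cellSize
    field <- function() {
      z <- .gaussianSmooth(matrix(stats::rnorm(geom@nrow * geom@ncol),
                                  geom@nrow, geom@ncol), sigma)
      (z - mean(z)) / stats::sd(z)
    }

    distCity <- distanceRaster(matrix(center, 1, 2,
                                      dimnames = list(NULL, c("x", "y"))), geom)
    distRoads <- distanceRaster(roads, geom)
    roadDens <- densityRaster(roads, geom, radius = 300, mode = "length")
    distAmen <- distanceRaster(amen, geom)
    amenDens <- densityRaster(amen, geom, radius = 500, mode = "count")

    urban <- -(distCity - mean(distCity)) / stats::sd(distCity)  # high near center
    ndvi <- stats::plogis(1.2 * field())           # pure autocorrelated field
    elev <- 80 + 40 * field() + 20 * (distCity / max(distCity))
    slope <- .slopeFromElevation(elev, geom@cellSize)
    popul <- exp(0.6 * field() + 1.2 * urban); popul <- 250 * popul / max(popul)
    lights <- 63 * stats::plogis(0.6 * field() + 1.5 * urban)
    bldg <- exp(0.5 * field() + 1.4 * urban); bldg <- 40 * bldg / max(bldg)

    layers <- list(dist_city = distCity, dist_roads = distRoads,
                   road_density = roadDens, dist_amenities = distAmen,
                   amenity_density = amenDens, ndvi = ndvi,
                   elevation = elev, slope = slope, population = popul,
                   nightlights = lights, building_density = bldg)
    meta <- data.frame(
      name = names(layers),
      unit = c("m", "m", "m/ha", "m", "count/ha", "index", "m", "degrees",
               "persons", "DN", "count/ha"),
      category = c("House to City", "House to Roads", "Road Density",
                   "House to Amenities", "House to Amenities", "Greenness",
                   "Topography", "Topography", "Population", "Nightlights",
                   "Building density"),
      stringsAsFactors = FALSE)
    stack <- covariateStack(layers, geom, meta)

    ## built-up/older-adults mask: urban gradient plus an autocorrelated
    ## settlement field; top maskFraction of the score
    score <- 0.8 * field() + 1.3 * urban
    thr <- stats::quantile(score, 1 - config@maskFraction)
    mask <- score > thr

    new("SyntheticLandscape", stack = stack, mask = mask, roads = roads,
        amenities = amen, cityCenter = center, config = config)
  })
}

## Slope (degrees) by central finite differences on an elevation grid.
.slopeFromElevation <- function(elev, cellSize) {
  nr <- nrow(elev); nc <- ncol(elev)
  gx <- elev[, c(2:nc, nc)] - elev[, c(1, 1:(nc - 1))]
  dx <- matrix(2 * cellSize, nr, nc); dx[, c(1, nc)] <- cellSize
  gy <- elev[c(2:nr, nr), ] - elev[c(1, 1:(nr - 1)), ]
  dy <- matrix(2 * cellSize, nr, nc); dy[c(1, nr), ] <- cellSize
  atan(sqrt((gx / dx)^2 + (gy / dy)^2)) * 180 / pi
}

#' @describeIn generateCovariates accessors for the landscape parts.
#' @param x a \linkS4class{SyntheticLandscape}.
#' @export
landscapeStack <- function(x) x@stack
#' @rdname generateCovariates
#' @export
landscapeMask <- function(x) x@mask
#' @rdname generateCovariates
#' @export
landscapeRoads <- function(x) x@roads
#' @rdname generateCovariates
#' @export
landscapeAmenities <- function(x) x@amenities

#' Simulate a geo-located BMI survey on a synthetic landscape
#'
#' Class probabilities follow a 3-class multinomial logit on the named
#' driver covariates (standardized over the grid; reference class
#' \code{normal}, intercepts set from the configured base rates). Points
#' are placed only in mask cells, at most one point per cell; each
#' point's class is drawn from its cell's multinomial, with rejection
#' against the per-class quotas so realized counts approximately match
#' \code{nPointsPerClass} (residual quota, if the rejection budget is
#' exhausted, is filled by probability-weighted stratified draws). BMI
#' values are drawn within the class's WHO interval so value and class
#' are always consistent.
#'
#' @param landscape a \linkS4class{SyntheticLandscape}.
#' @param config a \linkS4class{LandscapeConfig}; defaults to the one the
#'   landscape was generated from.
#' @param city city identifier stored with the records.
#' @return list with elements \code{points} (\linkS4class{SurveyPoints})
#'   and \code{truth} (\linkS4class{GroundTruth}).
#' @examples
#' land <- generateCovariates(landscapeConfig(gridShape = c(25, 25), seed = 2,
#'   nPointsPerClass = c(underweight = 5, normal = 20, overweight_obese = 20)))
#' sim <- simulateSurvey(land)
#' sim$points
#' @export
simulateSurvey <- function(landscape, config = landscape@config,
                           city = "synthcity") {
  stopifnot(is(landscape, "SyntheticLandscape"))
  stack <- landscape@stack
  geom <- stack@geometry
  eff <- config@driverEffects
  refd <- unique(unlist(lapply(eff, names)))
  missing <- setdiff(refd, layerNames(stack))
  if (length(missing))
    stop("driverEffects reference unknown layer(s): ",
         paste(missing, collapse = ", "))

  ## standardized driver values per cell (row-major vectors)
  zlayer <- function(nm) {
    v <- as.vector(t(getLayer(stack, nm)))  # row-major
    (v - mean(v)) / stats::sd(v)
  }
  ncell <- geom@nrow * geom@ncol
  eta <- matrix(0, ncell, 3, dimnames = list(NULL, .bmiClasses))
  br <- config@baseRates
  for (cl in .bmiClasses) eta[, cl] <- log(br[cl] / br["normal"])
  for (cl in names(eff)) {
    for (nm in names(eff[[cl]]))
      eta[, cl] <- eta[, cl] + eff[[cl]][nm] * zlayer(nm)
  }
  pcell <- .softmax(eta)
  probSurf <- lapply(.bmiClasses, function(cl)
    matrix(pcell[, cl], geom@nrow, geom@ncol, byrow = TRUE))
  names(probSurf) <- .bmiClasses

  quotas <- config@nPointsPerClass
  total <- sum(quotas)
  maskCells <- which(as.vector(t(landscape@mask)))  # row-major cell ids
  if (total > length(maskCells))
    stop("infeasible nPointsPerClass: ", total, " points requested but only ",
         length(maskCells), " mask cells available")

  pts <- .withSeed(.subSeed(config@seed, "survey"), {
    pool <- sample(maskCells)
    left <- quotas
    selCell <- integer(0); selClass <- character(0)
    budget <- 200L * max(1L, total)
    while (sum(left) > 0L && length(pool) > 0L && budget > 0L) {
      budget <- budget - 1L
      i <- sample.int(length(pool), 1L)
      cell <- pool[i]
      cl <- sample(.bmiClasses, 1L, prob = pcell[cell, ])
      if (left[cl] > 0L) {
        selCell <- c(selCell, cell); selClass <- c(selClass, cl)
        left[cl] <- left[cl] - 1L
        pool <- pool[-i]
      }
    }
    ## fill any residual quota by direct probability-weighted draws
    for (cl in .bmiClasses) {
      if (left[cl] > 0L && length(pool) > 0L) {
        w <- pcell[pool, cl]
        if (sum(w) <= 0) w <- rep(1, length(pool))
        take <- min(left[cl], length(pool))
        i <- sample.int(length(pool), take, prob = w)
        selCell <- c(selCell, pool[i]); selClass <- c(selClass, rep(cl, take))
        pool <- pool[-i]
      }
    }
    bmi <- vapply(selClass, function(cl) switch(cl,
      underweight = stats::runif(1, 15.0, 18.4),
      normal = stats::runif(1, 18.6, 24.9),
      overweight_obese = min(45, 25.1 + stats::rgamma(1, shape = 2, scale = 2.5))),
      numeric(1))
    list(cell = selCell, class = selClass, bmi = bmi)
  })

  if (length(pts$cell)) {
    rc <- .rowColFromCell(geom, pts$cell)
    x <- geom@xmin + (rc[, "col"] - 0.5) * geom@cellSize
    y <- geom@ymax - (rc[, "row"] - 0.5) * geom@cellSize
  } else x <- y <- numeric(0)

  sp <- new("SurveyPoints", data = data.frame(
    id = seq_along(pts$cell), x = x, y = y,
    bmi_kg_m2 = as.numeric(pts$bmi),
    bmi_class = as.character(pts$class), city = rep(city, length(pts$cell)),
    stringsAsFactors = FALSE))
  gt <- new("GroundTruth", probSurfaces = probSurf,
            driverEffects = eff,
            points = data.frame(x = x, y = y, cell = pts$cell,
                                class = as.character(pts$class),
                                stringsAsFactors = FALSE))
  list(points = sp, truth = gt)
}
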