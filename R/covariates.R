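#' @include AllClasses.R utils.R
NULL

#' Construct a covariate stack
#'
#' @param layers named list of numeric matrices sharing one geometry.
#' @param geometry a \linkS4class{GridGeometry}.
#' @param meta data.frame with columns \code{name}, \code{unit},
#'   \code{category}; defaults assign empty units and require explicit
#'   categories.
#' @return a \linkS4class{CovariateStack}.
#' @export
covariateStack <- function(layers, geometry, meta) {
  if (missing(meta))
    stop("meta with a category tag per layer is required")
  new("CovariateStack", geometry = geometry, layers = layers, meta = meta)
}

.checkMetricCRS <- function(geom) {
  if (grepl("4326|degree|longlat|WGS ?84$", geom@crs, ignore.case = TRUE))
    stop("grid CRS '", geom@crs, "' appears geographic (degrees); ",
         "distance and density layers require a projected CRS in meters")
}

## features: 2-column matrix (points x,y) or 4-column matrix (segments
## x0,y0,x1,y1)
.featureKind <- function(features) {
  if (!is.matrix(features) || nrow(features) == 0L)
    stop("feature set is empty")
  if (ncol(features) == 2L) "point"
  else if (ncol(features) == 4L) "line"
  else stop("features must have 2 (points) or 4 (segments) columns")
}

#' Euclidean distance-to-nearest-feature raster
#'
#' Each cell value is the planar distance in meters from the cell center
#' to the nearest feature (point or line segment). Distances are computed
#' on the projected plane, matching the proximity products the covariate
#' roster emulates.
#'
#' @param features 2-column matrix of points (x, y) or 4-column matrix of
#'   segments (x0, y0, x1, y1), meters.
#' @param geom target \linkS4class{GridGeometry} (projected, meters).
#' @return numeric matrix (nrow x ncol) of distances (m), >= 0.
#' @examples
#' g <- gridGeometry(5, 5, cellSize = 100)
#' d <- distanceRaster(cbind(x = 250, y = 250), g)
#' d[3, 3]  # cell centered on the feature: 0 m
#' @export
distanceRaster <- function(features, geom) {
  .checkMetricCRS(geom)
  kind <- .featureKind(features)
  ctr <- .cellCenters(geom)
  if (kind == "point") {
    ## chunked nearest-point distance
    best <- rep(Inf, nrow(ctr))
    step <- 512L
    for (s in seq(1L, nrow(features), by = step)) {
      e <- min(nrow(features), s + step - 1L)
      dx <- outer(ctr[, "x"], features[s:e, 1], "-")
      dy <- outer(ctr[, "y"], features[s:e, 2], "-")
      best <- pmin(best, sqrt(do.call(pmin, c(
        lapply(seq_len(e - s + 1L), function(j) dx[, j]^2 + dy[, j]^2)))))
    }
  } else {
    best <- rep(Inf, nrow(ctr))
    for (i in seq_len(nrow(features)))
      best <- pmin(best, .pointSegmentDistance(
        ctr[, "x"], ctr[, "y"],
        features[i, 1], features[i, 2], features[i, 3], features[i, 4]))
  }
  matrix(best, geom@nrow, geom@ncol, byrow = TRUE)
}

#' Neighborhood feature-density raster
#'
#' Count of point features (mode \code{"count"}) or clipped line length in
#' meters (mode \code{"length"}) within a circular neighborhood around
#' each cell center, divided by the neighborhood area in hectares. This
#' realizes the road-density (length of roads per neighborhood area) and
#' amenity-density (number of amenities per neighborhood area) covariates
#' over the 100-1000 m neighborhood radii of the roster.
#'
#' @param features point (2-col) or segment (4-col) matrix, meters.
#' @param geom target \linkS4class{GridGeometry}.
#' @param radius neighborhood radius in meters (> 0; the roster uses
#'   100-1000 m).
#' @param mode \code{"count"} (points) or \code{"length"} (line features
#'   only).
#' @return numeric matrix of densities (count/ha or m/ha), >= 0.
#' @examples
#' g <- gridGeometry(5, 5, cellSize = 100)
#' densityRaster(cbind(x = 250, y = 250), g, radius = 500)[3, 3]
#' # = 1 feature / (pi * 0.5^2 km^2 = 78.54 ha)
#' @export
densityRaster <- function(features, geom, radius,
                          mode = c("count", "length")) {
  mode <- match.arg(mode)
  if (radius <= 0) stop("radius must be positive (meters)")
  .checkMetricCRS(geom)
  kind <- .featureKind(features)
  if (mode == "length" && kind != "line")
    stop("mode 'length' requires line (segment) features")
  if (mode == "count" && kind != "point")
    stop("mode 'count' requires point features")
  ctr <- .cellCenters(geom)
  areaHa <- pi * radius^2 / 1e4
  if (mode == "count") {
    acc <- rep(0, nrow(ctr))
    for (i in seq_len(nrow(features))) {
      d2 <- (ctr[, "x"] - features[i, 1])^2 + (ctr[, "y"] - features[i, 2])^2
      acc <- acc + (d2 <= radius^2)
    }
  } else {
    acc <- rep(0, nrow(ctr))
    for (i in seq_len(nrow(features))) {
      ## cheap reject: segment's bounding box vs cell centers
      xr <- range(features[i, c(1, 3)]); yr <- range(features[i, c(2, 4)])
      near <- ctr[, "x"] >= xr[1] - radius & ctr[, "x"] <= xr[2] + radius &
        ctr[, "y"] >= yr[1] - radius & ctr[, "y"] <= yr[2] + radius
      idx <- which(near)
      if (!length(idx)) next
      acc[idx] <- acc[idx] + vapply(idx, function(j)
        .segmentLengthInCircle(features[i, 1], features[i, 2],
                               features[i, 3], features[i, 4],
                               ctr[j, "x"], ctr[j, "y"], radius),
        numeric(1))
    }
  }
  matrix(acc / areaHa, geom@nrow, geom@ncol, byrow = TRUE)
}

#' Focal texture statistics of a layer
#'
#' Five moving-window texture layers (mean, standard deviation, minimum,
#' maximum, range) over an odd square window, NoData-aware: each output
#' cell is computed over the valid cells of its window; cells whose whole
#' window is NoData stay NoData. Used for the NDVI texture covariates.
#'
#' @param layer numeric matrix (NA = NoData).
#' @param window odd window edge in cells, >= 3.
#' @return named list of five matrices: \code{mean}, \code{sd},
#'   \code{min}, \code{max}, \code{range}.
#' @examples
#' m <- matrix(1, 5, 5)
#' tx <- focalTexture(m, 3)
#' all(tx$sd == 0)
#' @export
focalTexture <- function(layer, window = 3L) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be an odd integer >= 3")
  if (window > min(dim(layer)))
    stop("window (", window, ") larger than the grid (",
         paste(dim(layer), collapse = " x "), ")")
  half <- window %/% 2L
  nr <- nrow(layer); nc <- ncol(layer)
  n <- s <- s2 <- matrix(0, nr, nc)
  mn <- matrix(Inf, nr, nc); mx <- matrix(-Inf, nr, nc)
  for (dr in -half:half) for (dc in -half:half) {
    rs <- max(1L, 1L - dr):min(nr, nr - dr)      # destination rows
    cs <- max(1L, 1L - dc):min(nc, nc - dc)
    src <- layer[rs + dr, cs + dc, drop = FALSE]
    ok <- !is.na(src)
    v <- ifelse(ok, src, 0)
    n[rs, cs] <- n[rs, cs] + ok
    s[rs, cs] <- s[rs, cs] + v
    s2[rs, cs] <- s2[rs, cs] + v^2
    mn[rs, cs] <- pmin(mn[rs, cs], ifelse(ok, src, Inf))
    mx[rs, cs] <- pmax(mx[rs, cs], ifelse(ok, src, -Inf))
  }
  none <- n == 0
  mean <- s / n
  ## sample sd over the valid window cells; single-cell windows give 0
  var <- (s2 - s^2 / n) / pmax(n - 1, 1)
  sd <- sqrt(pmax(var, 0))
  mean[none] <- sd[none] <- NA
  mn[none] <- NA; mx[none] <- NA
  list(mean = mean, sd = sd, min = mn, max = mx, range = mx - mn)
}

#' Append NDVI-style texture layers to a stack
#'
#' Convenience wrapper adding the five \code{\link{focalTexture}}
#' statistics of one layer as new stack layers, inheriting its category.
#'
#' @param stack a \linkS4class{CovariateStack}.
#' @param layer name of the source layer.
#' @param window odd window size in cells.
#' @return the extended \linkS4class{CovariateStack}.
#' @export
addTextureLayers <- function(stack, layer = "ndvi", window = 3L) {
  tx <- focalTexture(getLayer(stack, layer), window)
  m <- layerMeta(stack)
  cat0 <- m$category[m$name == layer]
  unit0 <- m$unit[m$name == layer]
  newNames <- paste0(layer, "_tex_", names(tx))
  layers <- c(stack@layers, stats::setNames(tx, newNames))
  meta <- rbind(stack@meta, data.frame(name = newNames, unit = unit0,
                                       category = cat0))
  covariateStack(layers, stack@geometry, meta)
}

#' Resample a stack to a target cell size and apply the older-adults mask
#'
#' Block-aggregates every layer to the target grid (the target cell must
#' be an integer multiple of the source cell): continuous layers by the
#' NoData-aware block mean, count-like layers by the block sum,
#' categorical layers by the block-center value. Cells where the mask is
#' \code{FALSE} are set to NoData.
#'
#' @param stack a \linkS4class{CovariateStack}.
#' @param targetCell target cell edge (m), default 100.
#' @param mask logical matrix on the target geometry (TRUE = keep), or
#'   \code{NULL} for no masking.
#' @param how named character vector per layer: \code{"mean"} (default),
#'   \code{"sum"}, or \code{"nearest"}.
#' @return a \linkS4class{CovariateStack} on the target grid.
#' @export
resampleAndMask <- function(stack, targetCell = 100, mask = NULL, how = NULL) {
  if (targetCell <= 0) stop("targetCell must be > 0")
  g <- stack@geometry
  f <- targetCell / g@cellSize
  if (abs(f - round(f)) > 1e-9)
    stop("targetCell must be an integer multiple of the source cell size")
  f <- as.integer(round(f))
  if (f > 1L) {
    nr <- g@nrow %/% f; nc <- g@ncol %/% f
    if (nr < 1L || nc < 1L) stop("target cell larger than the grid")
  } else { nr <- g@nrow; nc <- g@ncol }
  tg <- gridGeometry(nr, nc, xmin = g@xmin, ymax = g@ymax,
                     cellSize = targetCell, crs = g@crs)
  if (!is.null(mask)) {
    if (!is.matrix(mask) || !identical(dim(mask), c(nr, nc)))
      stop("mask geometry does not match the target grid (",
           nr, " x ", nc, ")")
  }
  agg <- function(m, rule) {
    if (f == 1L) return(m)
    out <- matrix(NA_real_, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      blk <- m[((i - 1L) * f + 1L):(i * f), ((j - 1L) * f + 1L):(j * f)]
      out[i, j] <- switch(rule,
        mean = if (all(is.na(blk))) NA_real_ else mean(blk, na.rm = TRUE),
        sum = if (all(is.na(blk))) NA_real_ else sum(blk, na.rm = TRUE),
        nearest = blk[(f + 1L) %/% 2L, (f + 1L) %/% 2L])
    }
    out
  }
  layers <- lapply(names(stack@layers), function(nm) {
    rule <- if (!is.null(how) && nm %in% names(how)) how[[nm]] else "mean"
    m <- agg(stack@layers[[nm]], rule)
    if (!is.null(mask)) m[!mask] <- NA_real_
    m
  })
  names(layers) <- names(stack@layers)
  covariateStack(layers, tg, stack@meta)
}
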