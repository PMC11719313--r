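#' @include AllClasses.R utils.R
NULL

#' Read and write rasters as Esri ASCII grids
#'
#' Plain-text raster interchange: the standard six-line Esri ASCII grid
#' header (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value)
#' followed by the cell values row by row from the top. \code{NA} maps to
#' the NoData value.
#'
#' @param mat numeric matrix (rows from the top).
#' @param geom the layer's \linkS4class{GridGeometry}.
#' @param path file path (conventionally \code{.asc}).
#' @param nodata NoData sentinel written for \code{NA} cells.
#' @return \code{readAsciiGrid}: list with \code{matrix} and
#'   \code{geometry}; \code{writeAsciiGrid}: the path, invisibly.
#' @export
writeAsciiGrid <- function(mat, geom, path, nodata = -9999) {
  stopifnot(is.matrix(mat), is(geom, "GridGeometry"))
  con <- file(path, "w")
  on.exit(close(con))
  yll <- geom@ymax - geom@nrow * geom@cellSize
  writeLines(c(
    paste("ncols", geom@ncol), paste("nrows", geom@nrow),
    paste("xllcorner", format(geom@xmin, scientific = FALSE)),
    paste("yllcorner", format(yll, scientific = FALSE)),
    paste("cellsize", format(geom@cellSize, scientific = FALSE)),
    paste("NODATA_value", nodata)), con)
  m <- mat
  m[is.na(m)] <- nodata
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeAsciiGrid
#' @export
readAsciiGrid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  val <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  m <- as.matrix(utils::read.table(path, skip = 6L))
  dimnames(m) <- NULL
  m[m == val[["nodata_value"]]] <- NA
  geom <- gridGeometry(val[["nrows"]], val[["ncols"]],
                       xmin = val[["xllcorner"]],
                       ymax = val[["yllcorner"]] +
                         val[["nrows"]] * val[["cellsize"]],
                       cellSize = val[["cellsize"]])
  list(matrix = m, geometry = geom)
}

#' Write and read a covariate stack as ASCII grids plus a YAML sidecar
#'
#' One \code{.asc} file per layer and a \code{stack.yml} sidecar holding
#' layer order, units and category tags.
#'
#' @param stack a \linkS4class{CovariateStack}.
#' @param dir directory (created if needed).
#' @return \code{readStack}: a \linkS4class{CovariateStack};
#'   \code{writeStack}: the directory, invisibly.
#' @export
writeStack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- layerMeta(stack)
  for (nm in layerNames(stack))
    writeAsciiGrid(getLayer(stack, nm), stack@geometry,
                   file.path(dir, paste0(nm, ".asc")))
  yaml::write_yaml(list(
    crs = stack@geometry@crs,
    layers = lapply(seq_len(nrow(m)), function(i)
      list(name = m$name[i], unit = m$unit[i], category = m$category[i]))),
    file.path(dir, "stack.yml"))
  invisible(dir)
}

#' @rdname writeStack
#' @export
readStack <- function(dir) {
  side <- yaml::read_yaml(file.path(dir, "stack.yml"))
  meta <- do.call(rbind, lapply(side$layers, function(l)
    data.frame(name = l$name, unit = l$unit, category = l$category)))
  layers <- list(); geom <- NULL
  for (nm in meta$name) {
    g <- readAsciiGrid(file.path(dir, paste0(nm, ".asc")))
    layers[[nm]] <- g$matrix
    geom <- g$geometry
  }
  geom@crs <- side$crs
  covariateStack(layers, geom, meta)
}

#' Survey points as CSV
#'
#' Columns \code{id}, \code{x}, \code{y}, \code{bmi_kg_m2},
#' \code{bmi_class}, \code{city}.
#'
#' @param points a \linkS4class{SurveyPoints}.
#' @param path CSV file path.
#' @return \code{readSurveyCSV}: a \linkS4class{SurveyPoints}.
#' @export
writeSurveyCSV <- function(points, path) {
  utils::write.csv(surveyData(points), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSurveyCSV
#' @export
readSurveyCSV <- function(path) {
  surveyPoints(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write vector features as GeoJSON
#'
#' Line segments (4-column matrix) become LineString features; points
#' (2-column matrix) become Point features. Coordinates are written as-is
#' in the projected CRS.
#'
#' @param features 2- or 4-column coordinate matrix.
#' @param path output file.
#' @param crs CRS identifier recorded as a foreign member.
#' @export
writeGeoJSON <- function(features, path, crs = "local-metric") {
  features <- as.matrix(features)
  mk <- if (ncol(features) == 4L) function(i) list(
    type = "Feature", properties = list(id = i),
    geometry = list(type = "LineString",
                    coordinates = list(c(features[i, 1], features[i, 2]),
                                       c(features[i, 3], features[i, 4]))))
  else if (ncol(features) == 2L) function(i) list(
    type = "Feature", properties = list(id = i),
    geometry = list(type = "Point",
                    coordinates = c(features[i, 1], features[i, 2])))
  else stop("features must have 2 (points) or 4 (segments) columns")
  gj <- list(type = "FeatureCollection", crs = crs,
             features = lapply(seq_len(nrow(features)), mk))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Landscape configuration as YAML
#'
#' @param config a \linkS4class{LandscapeConfig}.
#' @param path YAML file path.
#' @return \code{readLandscapeConfig}: a \linkS4class{LandscapeConfig}.
#' @export
writeLandscapeConfig <- function(config, path) {
  yaml::write_yaml(list(
    grid_shape = as.integer(config@gridShape),
    cell_size = config@cellSize, seed = config@seed,
    n_points_per_class = as.list(config@nPointsPerClass),
    driver_effects = lapply(config@driverEffects, as.list),
    base_rates = as.list(config@baseRates),
    spatial_range = config@spatialRange,
    mask_fraction = config@maskFraction), path)
  invisible(path)
}

#' @rdname writeLandscapeConfig
#' @export
readLandscapeConfig <- function(path) {
  y <- yaml::read_yaml(path)
  landscapeConfig(
    gridShape = unlist(y$grid_shape), cellSize = y$cell_size, seed = y$seed,
    nPointsPerClass = unlist(y$n_points_per_class),
    driverEffects = lapply(y$driver_effects, unlist),
    baseRates = unlist(y$base_rates),
    spatialRange = y$spatial_range, maskFraction = y$mask_fraction)
}
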