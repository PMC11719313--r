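#' @include AllClasses.R
NULL

#' Delineate two-tier probability hotspots
#'
#' Hotspot 2 collects the cells whose class probability is strictly above
#' the threshold; Hotspot 1 additionally requires the cell to be inside
#' the area of applicability (sample-supported), so it excludes
#' under-sampled areas. NoData cells never count as hotspot.
#'
#' @param surface an \linkS4class{EnsembleSurface}.
#' @param aoa optional \linkS4class{AOAResult} on the same grid;
#'   \code{NULL} makes Hotspot 1 identical to Hotspot 2.
#' @param threshold probability cutoff in (0, 1), default 0.8, strict
#'   \code{>}.
#' @return a \linkS4class{HotspotReport} (unit table empty until
#'   \code{\link{summarizeByUnit}}).
#' @export
delineateHotspots <- function(surface, aoa = NULL, threshold = 0.8) {
  stopifnot(is(surface, "EnsembleSurface"))
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly inside (0, 1)")
  p <- probLayer(surface)
  h2 <- p > threshold          # NA propagates: NoData stays NoData
  if (!is.null(aoa)) {
    if (!identical(dim(supportedMask(aoa)), dim(p)))
      stop("surface and AOA must share one grid")
    h1 <- h2 & supportedMask(aoa)
    h1[is.na(h2)] <- NA  # NoData propagates to both tiers
  } else h1 <- h2
  new("HotspotReport", hotspot1 = h1, hotspot2 = h2,
      threshold = threshold, classLabel = surface@classLabel,
      unitTable = data.frame(), geometry = surface@geometry)
}

#' Summarize hotspot areas per administrative unit
#'
#' Assigns each grid cell to the first polygon containing its center
#' (boundary ties go to the first unit in list order) and reports hotspot
#' areas in hectares per unit (cell count x cell area; 1 cell = 1 ha at
#' 100 m). Cells covered by no polygon are reported under
#' \code{"unassigned"}. The table is sorted by Hotspot 1 area descending,
#' giving an intervention priority ranking.
#'
#' @param report a \linkS4class{HotspotReport}.
#' @param units named list of polygons, each a 2-column matrix/data.frame
#'   of vertex coordinates (m).
#' @return the \linkS4class{HotspotReport} with its \code{unitTable}
#'   filled.
#' @export
summarizeByUnit <- function(report, units) {
  stopifnot(is(report, "HotspotReport"))
  if (!length(units)) stop("no administrative units supplied")
  if (is.null(names(units)) || any(!nzchar(names(units))))
    names(units) <- paste0("unit", seq_along(units))
  geom <- report@geometry
  for (nm in names(units)) {
    poly <- as.matrix(units[[nm]])
    if (!is.numeric(poly) || ncol(poly) != 2L || nrow(poly) < 3L ||
        anyNA(poly))
      stop("invalid polygon geometry for unit '", nm, "'")
  }
  ctr <- .cellCenters(geom)
  assign <- rep(NA_character_, nrow(ctr))
  for (nm in names(units)) {
    poly <- as.matrix(units[[nm]])
    free <- is.na(assign)
    if (!any(free)) break
    inp <- pracma::inpolygon(ctr[free, "x"], ctr[free, "y"],
                             poly[, 1], poly[, 2], boundary = TRUE)
    assign[free][inp] <- nm
  }
  assign[is.na(assign)] <- "unassigned"
  haPerCell <- geom@cellSize^2 / 1e4
  h1 <- as.vector(t(report@hotspot1)); h1[is.na(h1)] <- FALSE
  h2 <- as.vector(t(report@hotspot2)); h2[is.na(h2)] <- FALSE
  lvls <- unique(c(names(units), "unassigned"))
  f <- factor(assign, levels = lvls)
  tab <- data.frame(
    unit = lvls,
    hotspot1_ha = as.numeric(tapply(h1, f, sum, default = 0)) * haPerCell,
    hotspot2_ha = as.numeric(tapply(h2, f, sum, default = 0)) * haPerCell,
    stringsAsFactors = FALSE)
  if (!"unassigned" %in% assign)
    tab <- tab[tab$unit != "unassigned" | tab$hotspot1_ha > 0 |
                 tab$hotspot2_ha > 0, , drop = FALSE]
  tab <- tab[order(-tab$hotspot1_ha), , drop = FALSE]
  rownames(tab) <- NULL
  methods::initialize(report, unitTable = tab)
}

#' Quadrant administrative units for a grid
#'
#' Convenience constructor of four rectangular units covering the grid,
#' used for synthetic hotspot summaries.
#'
#' @param geom a \linkS4class{GridGeometry}.
#' @return named list of 4 polygon matrices.
#' @export
quadrantUnits <- function(geom) {
  W <- geom@ncol * geom@cellSize; H <- geom@nrow * geom@cellSize
  x0 <- geom@xmin; x1 <- geom@xmin + W
  y0 <- geom@ymax - H; y1 <- geom@ymax
  xm <- (x0 + x1) / 2; ym <- (y0 + y1) / 2
  rect <- function(xa, xb, ya, yb)
    cbind(c(xa, xb, xb, xa), c(ya, ya, yb, yb))
  list(NW = rect(x0, xm, ym, y1), NE = rect(xm, x1, ym, y1),
       SW = rect(x0, xm, y0, ym), SE = rect(xm, x1, y0, ym))
}
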