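#' @include AllClasses.R utils.R
NULL

#' WHO BMI classification for older adults
#'
#' Maps BMI values (kg/m^2) to the three WHO classes: underweight
#' (< 18.5), normal (18.5-24.9), overweight-obese (> 25.0). The WHO
#' cutoffs leave the interval (24.9, 25.0] unassigned; this implementation
#' adopts the convention that \code{normal} extends up to and including
#' 25.0, so overweight-obese is strictly > 25.0.
#'
#' @param bmi numeric vector of BMI values in kg/m^2; must be positive.
#' @return character vector of class labels.
#' @examples
#' classifyBmi(c(17.0, 18.5, 31.4))
#' @export
classifyBmi <- function(bmi) {
  if (any(is.na(bmi)) || any(bmi <= 0))
    stop("BMI values must be positive and non-missing")
  ifelse(bmi < 18.5, "underweight",
         ifelse(bmi > 25.0, "overweight_obese", "normal"))
}

#' Construct survey points
#'
#' @param data data.frame with columns \code{id}, \code{x}, \code{y},
#'   \code{bmi_kg_m2} (optional, may be NA), \code{bmi_class} (optional if
#'   BMI values are present), \code{city}.
#' @return a \linkS4class{SurveyPoints}.
#' @export
surveyPoints <- function(data) {
  if (!"bmi_class" %in% names(data)) {
    data$bmi_class <- classifyBmi(data$bmi_kg_m2)
  }
  if (!"bmi_kg_m2" %in% names(data)) data$bmi_kg_m2 <- NA_real_
  if (!"city" %in% names(data)) data$city <- "city1"
  if (!"id" %in% names(data)) data$id <- seq_len(nrow(data))
  new("SurveyPoints", data = data[, c("id", "x", "y", "bmi_kg_m2",
                                      "bmi_class", "city")])
}

#' Dissimilarity index and area of applicability
#'
#' Per-cell dissimilarity in standardized, importance-weighted covariate
#' space: the distance to the nearest training point divided by the mean
#' pairwise distance among training points. The support threshold is the
#' upper whisker (Q3 + 1.5 IQR) of the training points' own leave-one-out
#' DI values; cells at or below the threshold (intersected with the
#' older-adults mask, when given) form the area of applicability, and the
#' remainder is flagged as under-sampled.
#'
#' @param train a \linkS4class{DesignTable} whose rows are the training
#'   points (covariates already extracted).
#' @param stack the \linkS4class{CovariateStack} to score.
#' @param weights named non-negative importance weights per covariate;
#'   default all 1. Zero-variance covariates are excluded with a warning.
#' @param mask optional logical matrix (older-adults mask) intersected
#'   into the supported mask.
#' @return an \linkS4class{AOAResult}.
#' @export
dissimilarityIndex <- function(train, stack, weights = NULL, mask = NULL) {
  stopifnot(is(train, "DesignTable"), is(stack, "CovariateStack"))
  vars <- intersect(train@covariates, layerNames(stack))
  if (length(vars) < 1L) stop("no shared covariates between design and stack")
  X <- as.matrix(designData(train)[, vars, drop = FALSE])
  if (nrow(X) < 2L) stop("need at least 2 training points")
  sdv <- apply(X, 2, stats::sd)
  drop <- !is.finite(sdv) | sdv == 0
  if (all(drop)) stop("all training points are identical in covariate space")
  if (any(drop)) {
    warning("excluding zero-variance covariate(s) from DI: ",
            paste(vars[drop], collapse = ", "))
    vars <- vars[!drop]
    X <- X[, vars, drop = FALSE]
  }
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(vars)), vars)
  w <- weights[vars]
  if (any(is.na(w))) stop("weights must cover every covariate used")
  if (any(w < 0)) stop("weights must be >= 0")

  std <- .standardize(X)
  Zt <- sweep(std$x, 2, w, "*")
  ## mean pairwise training distance
  dtr <- as.matrix(stats::dist(Zt))
  dbar <- mean(dtr[upper.tri(dtr)])
  if (dbar == 0) stop("all training points are identical in covariate space")

  ## leave-one-out DI of the training points themselves
  diag(dtr) <- Inf
  looDI <- apply(dtr, 1, min) / dbar
  q <- stats::quantile(looDI, c(0.25, 0.75), names = FALSE)
  threshold <- q[2] + 1.5 * (q[2] - q[1])

  geom <- stack@geometry
  ncell <- geom@nrow * geom@ncol
  ## covariate matrix over cells (row-major), standardized by training stats
  C <- vapply(vars, function(nm) as.vector(t(getLayer(stack, nm))),
              numeric(ncell))
  valid <- rowSums(is.na(C)) == 0L
  di <- rep(NA_real_, ncell)
  if (any(valid)) {
    Zc <- sweep(.standardize(C[valid, , drop = FALSE],
                             center = std$center[vars],
                             scale = std$scale[vars])$x, 2, w, "*")
    ## chunked nearest-training-point distance
    best <- rep(Inf, nrow(Zc))
    step <- 4096L
    tZt <- t(Zt)
    nt2 <- colSums(tZt^2)
    for (s in seq(1L, nrow(Zc), by = step)) {
      e <- min(nrow(Zc), s + step - 1L)
      blk <- Zc[s:e, , drop = FALSE]
      d2 <- outer(rowSums(blk^2), nt2, "+") - 2 * blk %*% tZt
      best[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
    }
    di[valid] <- best / dbar
  }
  diM <- matrix(di, geom@nrow, geom@ncol, byrow = TRUE)
  supp <- !is.na(diM) & diM <= threshold
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(diM)))
      stop("mask geometry does not match the stack")
    supp <- supp & mask
  }
  new("AOAResult", di = diM, threshold = as.numeric(threshold),
      supported = supp, geometry = geom)
}

#' Target-group background sampling
#'
#' Draws background cells (without replacement) from the eligible area --
#' older-adults mask intersected with the AOA-supported mask, excluding
#' every cell that already contains a survey point -- with sampling
#' weights proportional to a Gaussian kernel-density surface of the
#' presence points (Scott's-rule bandwidth). This gives the background
#' the same spatial distribution as the presences, cancelling the survey
#' bias of convenience sampling.
#'
#' @param presence a \linkS4class{SurveyPoints} holding the target-class
#'   points whose spatial density the background should follow.
#' @param mask logical older-adults matrix on the AOA grid.
#' @param aoa an \linkS4class{AOAResult}; only supported cells are
#'   eligible.
#' @param n number of background cells to draw (>= 1).
#' @param seed integer seed; draws are deterministic under it.
#' @param exclude optional \linkS4class{SurveyPoints} of all survey
#'   records (any class) whose cells must not be used; defaults to
#'   \code{presence}.
#' @return data.frame with columns \code{x}, \code{y}, \code{cell},
#'   \code{role} (= "background").
#' @export
sampleBackground <- function(presence, mask, aoa, n, seed = 1L,
                             exclude = presence) {
  stopifnot(is(presence, "SurveyPoints"), is(aoa, "AOAResult"), n >= 1)
  geom <- aoa@geometry
  if (!identical(dim(mask), dim(aoa@supported)))
    stop("mask geometry does not match the AOA grid")
  elig <- mask & aoa@supported
  if (!any(elig, na.rm = TRUE))
    stop("no eligible background cells: AOA supports none of the mask")
  eligCells <- which(as.vector(t(elig)))
  exd <- surveyData(exclude)
  if (nrow(exd)) {
    occ <- .cellFromXY(geom, exd$x, exd$y)
    eligCells <- setdiff(eligCells, occ[!is.na(occ)])
  }
  if (length(eligCells) < n)
    stop("only ", length(eligCells), " eligible background cells for n = ", n,
         " (shortfall ", n - length(eligCells), ")")
  pd <- surveyData(presence)
  if (!nrow(pd)) stop("presence set is empty")
  rc <- .rowColFromCell(geom, eligCells)
  cx <- geom@xmin + (rc[, "col"] - 0.5) * geom@cellSize
  cy <- geom@ymax - (rc[, "row"] - 0.5) * geom@cellSize
  ## Gaussian product-kernel density of the presences at the eligible
  ## cell centers; bandwidth per dimension by Scott's rule
  np <- nrow(pd)
  bw <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) s <- geom@cellSize
    s * np^(-1 / 6)
  }
  hx <- bw(pd$x); hy <- bw(pd$y)
  dens <- rep(0, length(eligCells))
  for (i in seq_len(np))
    dens <- dens + exp(-0.5 * (((cx - pd$x[i]) / hx)^2 +
                               ((cy - pd$y[i]) / hy)^2))
  if (sum(dens) <= 0) dens <- rep(1, length(eligCells))
  sel <- .withSeed(seed,
    sample(seq_along(eligCells), n, replace = FALSE, prob = dens))
  cells <- eligCells[sel]
  data.frame(x = cx[sel], y = cy[sel], cell = cells, role = "background",
             stringsAsFactors = FALSE)
}

#' Build the presence/absence/background design table for one class
#'
#' Presence rows are the survey points of the target class; absence rows
#' are exactly the points of the other two classes; background rows (from
#' \code{\link{sampleBackground}}) are attached with label 0. Covariates
#' are extracted at each row's grid cell; rows landing on NoData cells are
#' dropped with a message, and duplicate cells keep their first record.
#'
#' @param points a \linkS4class{SurveyPoints} with all classes.
#' @param target the class modelled as presence.
#' @param stack the aligned \linkS4class{CovariateStack}.
#' @param background optional data.frame from
#'   \code{\link{sampleBackground}}.
#' @return a \linkS4class{DesignTable}.
#' @export
buildDesign <- function(points, target, stack, background = NULL) {
  stopifnot(is(points, "SurveyPoints"), is(stack, "CovariateStack"))
  target <- match.arg(target, .bmiClasses)
  geom <- stack@geometry
  d <- surveyData(points)
  if (!any(d$bmi_class == target))
    stop("no presence rows: no survey point has class '", target, "'")
  cell <- .cellFromXY(geom, d$x, d$y)
  if (any(is.na(cell)))
    stop(sum(is.na(cell)), " survey point(s) fall outside the study grid")
  role <- ifelse(d$bmi_class == target, "presence", "absence")
  rows <- data.frame(x = d$x, y = d$y, cell = cell, role = role,
                     stringsAsFactors = FALSE)
  if (!is.null(background) && nrow(background)) {
    bg <- background[, c("x", "y", "cell")]
    bg$role <- "background"
    clash <- bg$cell %in% rows$cell
    if (any(clash)) {
      message("dropping ", sum(clash),
              " background row(s) sharing a cell with a survey point")
      bg <- bg[!clash, , drop = FALSE]
    }
    rows <- rbind(rows, bg)
  }
  dup <- duplicated(rows$cell)
  if (any(dup)) {
    message("dropping ", sum(dup), " duplicate row(s) sharing a grid cell")
    rows <- rows[!dup, , drop = FALSE]
  }
  vars <- layerNames(stack)
  for (nm in vars)
    rows[[nm]] <- .valueAtCell(getLayer(stack, nm), geom, rows$cell)
  bad <- rowSums(is.na(rows[, vars, drop = FALSE])) > 0L
  if (any(bad)) {
    message("dropping ", sum(bad), " row(s) on NoData cells")
    rows <- rows[!bad, , drop = FALSE]
  }
  if (!any(rows$role == "presence"))
    stop("no presence rows remain after NoData filtering")
  rows$label <- as.integer(rows$role == "presence")
  rows <- rows[, c("x", "y", "cell", "role", "label", vars)]
  rownames(rows) <- NULL
  new("DesignTable", data = rows, targetClass = target, covariates = vars,
      covariateMeta = stack@meta[, c("name", "category")], geometry = geom)
}

#' Restrict a design table to a covariate roster
#'
#' @param design a \linkS4class{DesignTable}.
#' @param roster character vector of covariates to keep.
#' @return the restricted \linkS4class{DesignTable}.
#' @export
restrictDesign <- function(design, roster) {
  miss <- setdiff(roster, design@covariates)
  if (length(miss)) stop("unknown covariate(s): ", paste(miss, collapse = ", "))
  d <- designData(design)[, c("x", "y", "cell", "role", "label", roster)]
  new("DesignTable", data = d, targetClass = design@targetClass,
      covariates = roster,
      covariateMeta = design@covariateMeta[
        design@covariateMeta$name %in% roster, , drop = FALSE],
      geometry = design@geometry)
}
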