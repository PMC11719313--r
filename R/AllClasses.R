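#' @import methods
NULL

## Canonical covariate categories used for importance aggregation.
## These mirror the sub-categories commonly used for built-environment
## rosters (nightlights, proximities, densities, greenness, topography).
.malnutCategories <- c(
  "Nightlights", "House to City", "House to Roads", "House to Amenities",
  "Road Density", "Greenness", "Population", "Building density", "Topography"
)

.bmiClasses <- c("underweight", "normal", "overweight_obese")

#' Grid geometry of a raster layer
#'
#' Describes a regular raster grid on a projected (metric) coordinate
#' system: number of rows/columns, upper-left corner, and square cell size
#' in meters. Cell values refer to cell centers; traversal is row-major
#' from the upper-left corner.
#'
#' @slot nrow,ncol integer grid dimensions.
#' @slot xmin,ymax coordinates (m) of the upper-left grid corner.
#' @slot cellSize cell edge length in meters (100 m = 1 ha cells).
#' @slot crs free-text identifier of the projected CRS.
#' @export
setClass("GridGeometry",
  representation(nrow = "integer", ncol = "integer",
                 xmin = "numeric", ymax = "numeric",
                 cellSize = "numeric", crs = "character"),
  prototype(crs = "local-metric")
)

setValidity("GridGeometry", function(object) {
  msg <- NULL
  if (length(object@nrow) != 1L || object@nrow < 1L) msg <- c(msg, "nrow must be a positive integer")
  if (length(object@ncol) != 1L || object@ncol < 1L) msg <- c(msg, "ncol must be a positive integer")
  if (length(object@cellSize) != 1L || object@cellSize <= 0) msg <- c(msg, "cellSize must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' Aligned stack of environmental covariate layers
#'
#' Named 2-D float grids sharing one \linkS4class{GridGeometry}, with
#' per-layer metadata (unit and a category tag used when importance values
#' are aggregated). \code{NA} encodes NoData.
#'
#' @slot geometry common \linkS4class{GridGeometry}.
#' @slot layers named list of numeric matrices (nrow x ncol).
#' @slot meta data.frame with columns \code{name}, \code{unit},
#'   \code{category}; one row per layer.
#' @export
setClass("CovariateStack",
  representation(geometry = "GridGeometry", layers = "list", meta = "data.frame")
)

setValidity("CovariateStack", function(object) {
  g <- object@geometry
  msg <- NULL
  if (length(object@layers) == 0L) msg <- c(msg, "stack has no layers")
  nm <- names(object@layers)
  if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm)))
    msg <- c(msg, "layers must have unique non-empty names")
  bad <- vapply(object@layers, function(m)
    !is.matrix(m) || nrow(m) != g@nrow || ncol(m) != g@ncol, logical(1))
  if (any(bad))
    msg <- c(msg, sprintf("layers with wrong geometry: %s",
                          paste(nm[bad], collapse = ", ")))
  if (!all(c("name", "unit", "category") %in% names(object@meta)))
    msg <- c(msg, "meta needs columns name, unit, category")
  else {
    if (!setequal(object@meta$name, nm))
      msg <- c(msg, "meta rows must match layer names")
    unk <- setdiff(object@meta$category, .malnutCategories)
    if (length(unk))
      msg <- c(msg, sprintf("unknown category tag(s): %s", paste(unk, collapse = ", ")))
  }
  if (is.null(msg)) TRUE else msg
})

#' Geo-located survey records with BMI class
#'
#' Point records on the projected plane with an optional BMI value
#' (kg/m^2), an assigned BMI class, and a city identifier. When both BMI
#' and class are present the class must agree with the WHO cutoffs as
#' implemented by \code{\link{classifyBmi}}.
#'
#' @slot data data.frame with columns \code{id}, \code{x}, \code{y},
#'   \code{bmi_kg_m2} (may be \code{NA}), \code{bmi_class}, \code{city}.
#' @export
setClass("SurveyPoints", representation(data = "data.frame"))

setValidity("SurveyPoints", function(object) {
  d <- object@data
  need <- c("id", "x", "y", "bmi_kg_m2", "bmi_class", "city")
  if (!all(need %in% names(d)))
    return(sprintf("data needs columns: %s", paste(need, collapse = ", ")))
  if (nrow(d)) {
    if (!all(d$bmi_class %in% .bmiClasses))
      return("bmi_class outside {underweight, normal, overweight_obese}")
    has <- !is.na(d$bmi_kg_m2)
    if (any(has)) {
      expect <- classifyBmi(d$bmi_kg_m2[has])
      if (!all(expect == d$bmi_class[has]))
        return("bmi_class inconsistent with bmi_kg_m2 under the WHO cutoffs")
    }
  }
  TRUE
})

#' Presence/absence/background design table for one target class
#'
#' Rows are grid cells carrying a role (presence, absence, or background)
#' and the covariate values extracted at that cell; at most one row per
#' cell. Absences are exactly the survey points of the two non-target
#' classes.
#'
#' @slot data data.frame: \code{x}, \code{y}, \code{cell}, \code{role},
#'   \code{label} (1 for presence, 0 otherwise), then covariate columns.
#' @slot targetClass the BMI class modelled as presence.
#' @slot covariates character vector of covariate column names.
#' @slot covariateMeta data.frame \code{name}/\code{category} for the roster.
#' @slot geometry extraction grid.
#' @export
setClass("DesignTable",
  representation(data = "data.frame", targetClass = "character",
                 covariates = "character", covariateMeta = "data.frame",
                 geometry = "GridGeometry")
)

setValidity("DesignTable", function(object) {
  d <- object@data
  msg <- NULL
  if (!all(c("x", "y", "cell", "role", "label") %in% names(d)))
    msg <- c(msg, "data needs x, y, cell, role, label columns")
  else {
    if (anyDuplicated(d$cell)) msg <- c(msg, "two rows share a grid cell")
    if (!all(d$role %in% c("presence", "absence", "background")))
      msg <- c(msg, "role outside {presence, absence, background}")
  }
  if (!all(object@covariates %in% names(d)))
    msg <- c(msg, "covariate columns missing from data")
  if (is.null(msg)) TRUE else msg
})

#' Area-of-applicability result
#'
#' Dissimilarity-index surface, its outlier threshold, and the resulting
#' supported mask (DI below threshold, intersected with the older-adults
#' mask when one is supplied).
#'
#' @slot di numeric matrix of dissimilarity-index values (unitless, >= 0).
#' @slot threshold upper whisker (Q3 + 1.5 IQR) of the training points'
#'   leave-one-out DI values.
#' @slot supported logical matrix: cell is inside the area of applicability.
#' @slot geometry grid of both layers.
#' @export
setClass("AOAResult",
  representation(di = "matrix", threshold = "numeric",
                 supported = "matrix", geometry = "GridGeometry")
)

setValidity("AOAResult", function(object) {
  if (!identical(dim(object@di), dim(object@supported)))
    return("di and supported must share dimensions")
  ok <- object@di[!is.na(object@di)]
  if (length(ok) && any(ok < 0)) return("DI values must be >= 0")
  TRUE
})

#' A tuned, cross-validated base (or meta) learner
#'
#' One learner family with its grid-search-selected hyperparameters,
#' per-fold fitted states, out-of-fold predictions and CV AUC, plus the
#' full grid log.
#'
#' @slot family one of \code{maxent_lq}, \code{maxent_lqh},
#'   \code{random_forest}, \code{boosted_trees}, \code{neural_net}.
#' @slot hyperparameters chosen grid point (named list).
#' @slot foldModels list of fitted states, one per CV fold.
#' @slot finalModel fitted state trained on all rows (used for mapping).
#' @slot rowIndex integer indices of the design rows this learner used.
#' @slot foldAssign fold id per used row.
#' @slot oofPred out-of-fold probability per used row.
#' @slot foldAUC held-out AUC per fold; \code{cvAUC} is their mean.
#' @slot variables covariate roster the learner was fitted on.
#' @slot gridLog data.frame of every grid point and its mean CV AUC.
#' @slot seed integer seed governing the fit.
#' @export
setClass("FittedLearner",
  representation(family = "character", hyperparameters = "list",
                 foldModels = "list", finalModel = "ANY",
                 rowIndex = "integer", foldAssign = "integer",
                 oofPred = "numeric", foldAUC = "numeric", cvAUC = "numeric",
                 variables = "character", gridLog = "data.frame",
                 seed = "integer")
)

setValidity("FittedLearner", function(object) {
  msg <- NULL
  if (!object@family %in% .learnerFamilies())
    msg <- c(msg, sprintf("unknown family '%s'", object@family))
  p <- object@oofPred[!is.na(object@oofPred)]
  if (length(p) && (min(p) < 0 || max(p) > 1))
    msg <- c(msg, "out-of-fold predictions must lie in [0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' Stacked-generalization ensemble
#'
#' Five base learners plus a random-forest meta-learner trained on their
#' out-of-fold predictions (no leakage: the meta-design only ever contains
#' predictions made by models that did not see the row).
#'
#' @slot baseLearners named list of five \linkS4class{FittedLearner}s.
#' @slot metaFoldModels per-fold random-forest meta states.
#' @slot metaFinal meta random forest trained on the full meta-design.
#' @slot metaDesign the out-of-fold meta-design (one column per base
#'   learner, plus label/fold bookkeeping).
#' @slot metaHyperparameters grid-search-selected meta-forest settings
#'   (mode, mtry, nodesize); \code{metaGridLog} records every candidate
#'   with its mean CV AUC.
#' @slot metaGridLog data.frame of the meta-learner tuning grid.
#' @slot foldMetrics per-fold held-out AUC, max-TSS and its threshold for
#'   the stacked predictions; \code{cvAUC}/\code{cvTSS} are fold means.
#' @slot variables covariate roster shared by the base learners.
#' @slot seed integer seed.
#' @export
setClass("EnsembleModel",
  representation(baseLearners = "list", metaFoldModels = "list",
                 metaFinal = "ANY", metaDesign = "data.frame",
                 metaHyperparameters = "list", metaGridLog = "data.frame",
                 foldMetrics = "data.frame", cvAUC = "numeric",
                 cvTSS = "numeric", variables = "character", seed = "integer")
)

setValidity("EnsembleModel", function(object) {
  msg <- NULL
  if (length(object@baseLearners) != 5L)
    msg <- c(msg, "an ensemble stacks exactly five base learners")
  pcols <- setdiff(grep("^pred_", names(object@metaDesign), value = TRUE),
                   "pred_ensemble")
  if (nrow(object@metaDesign) && length(pcols) != length(object@baseLearners))
    msg <- c(msg, "meta-learner input dimension must equal the number of base learners")
  if (is.null(msg)) TRUE else msg
})

#' Per-class ensemble probability surface
#'
#' Probability of the target class per masked cell together with the
#' across-base-learner standard deviation layer. NoData exactly where the
#' older-adults mask is false.
#'
#' @slot prob probability matrix in [0, 1] (NA = NoData).
#' @slot sd per-cell standard deviation of the five base-learner layers.
#' @slot classLabel,city labels for bookkeeping.
#' @slot geometry grid of both layers.
#' @export
setClass("EnsembleSurface",
  representation(prob = "matrix", sd = "matrix", classLabel = "character",
                 city = "character", geometry = "GridGeometry")
)

setValidity("EnsembleSurface", function(object) {
  if (!identical(dim(object@prob), dim(object@sd)))
    return("prob and sd must share dimensions")
  p <- object@prob[!is.na(object@prob)]
  if (length(p) && (min(p) < -1e-9 || max(p) > 1 + 1e-9))
    return("probabilities must lie in [0, 1]")
  s <- object@sd[!is.na(object@sd)]
  if (length(s) && min(s) < -1e-9) return("sd must be >= 0")
  if (!identical(is.na(object@prob), is.na(object@sd)))
    return("prob and sd must share the NoData pattern")
  TRUE
})

#' Two-tier hotspot delineation
#'
#' Hotspot 2 = cells with class probability strictly above the threshold;
#' Hotspot 1 = Hotspot 2 additionally restricted to the area of
#' applicability. Includes the per-administrative-unit area table when
#' \code{\link{summarizeByUnit}} has been applied.
#'
#' @slot hotspot1,hotspot2 logical matrices (NA = NoData; never counted).
#' @slot threshold probability cutoff used (strict \code{>}).
#' @slot classLabel class the surface maps.
#' @slot unitTable data.frame \code{unit}, \code{hotspot1_ha},
#'   \code{hotspot2_ha}, sorted by \code{hotspot1_ha} descending.
#' @slot geometry grid of the masks.
#' @export
setClass("HotspotReport",
  representation(hotspot1 = "matrix", hotspot2 = "matrix",
                 threshold = "numeric", classLabel = "character",
                 unitTable = "data.frame", geometry = "GridGeometry")
)

setValidity("HotspotReport", function(object) {
  h1 <- object@hotspot1; h2 <- object@hotspot2
  if (!identical(dim(h1), dim(h2))) return("masks must share dimensions")
  both <- !is.na(h1) & !is.na(h2)
  if (any(h1[both] & !h2[both])) return("hotspot1 must be a subset of hotspot2")
  TRUE
})

#' Cross-validation metric report
#'
#' Per-fold held-out AUC, threshold-maximized TSS and the maximizing
#' threshold, with their means.
#'
#' @slot folds data.frame \code{fold}, \code{auc}, \code{tss},
#'   \code{threshold}.
#' @slot meanAUC,meanTSS fold means.
#' @export
setClass("MetricReport",
  representation(folds = "data.frame", meanAUC = "numeric", meanTSS = "numeric")
)

setValidity("MetricReport", function(object) {
  f <- object@folds
  if (!all(c("fold", "auc", "tss", "threshold") %in% names(f)))
    return("folds needs fold, auc, tss, threshold columns")
  a <- f$auc[!is.na(f$auc)]
  if (length(a) && (min(a) < 0 || max(a) > 1)) return("AUC must lie in [0, 1]")
  t <- f$tss[!is.na(f$tss)]
  if (length(t) && (min(t) < -1 || max(t) > 1)) return("TSS must lie in [-1, 1]")
  TRUE
})

#' Configuration of a synthetic study landscape
#'
#' Defines grid shape and resolution, the autocorrelation length of the
#' random covariate fields, the built-up/older-adults mask fraction, the
#' per-class point quotas, the class base rates, and the driver
#' coefficients of the 3-class multinomial outcome model.
#'
#' @slot gridShape integer (rows, cols).
#' @slot cellSize cell edge, meters.
#' @slot seed integer master seed; identical config + seed gives
#'   bit-identical output.
#' @slot nPointsPerClass named integer quota per BMI class.
#' @slot driverEffects named list per non-reference class of named
#'   coefficient vectors on standardized covariates (reference class:
#'   normal).
#' @slot baseRates length-3 class base rates (sum 1) realized when all
#'   driver effects are zero.
#' @slot spatialRange autocorrelation length of the random fields, meters.
#' @slot maskFraction fraction of cells designated built-up/older-adult.
#' @export
setClass("LandscapeConfig",
  representation(gridShape = "integer", cellSize = "numeric", seed = "integer",
                 nPointsPerClass = "integer", driverEffects = "list",
                 baseRates = "numeric", spatialRange = "numeric",
                 maskFraction = "numeric")
)

setValidity("LandscapeConfig", function(object) {
  msg <- NULL
  if (length(object@gridShape) != 2L || any(object@gridShape < 2L))
    msg <- c(msg, "gridShape must be two integers >= 2")
  if (object@cellSize <= 0) msg <- c(msg, "cellSize must be > 0")
  if (object@maskFraction <= 0 || object@maskFraction >= 1)
    msg <- c(msg, "maskFraction must lie in (0, 1)")
  if (!setequal(names(object@nPointsPerClass), .bmiClasses))
    msg <- c(msg, "nPointsPerClass must name all three BMI classes")
  if (any(object@nPointsPerClass < 0L)) msg <- c(msg, "point quotas must be >= 0")
  if (length(object@baseRates) != 3L || abs(sum(object@baseRates) - 1) > 1e-9)
    msg <- c(msg, "baseRates must be three probabilities summing to 1")
  if (object@spatialRange < 0) msg <- c(msg, "spatialRange must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Synthetic landscape: covariates, mask, vector layers
#'
#' The generated covariate stack together with the older-adults mask, the
#' synthetic road network (line segments), amenity points, and the city
#' center, so that both the simulation and the covariate-engineering
#' operations can be exercised end to end.
#'
#' @slot stack \linkS4class{CovariateStack}.
#' @slot mask logical matrix: built-up/older-adults cells.
#' @slot roads matrix with columns x0, y0, x1, y1 (segment endpoints, m).
#' @slot amenities matrix with columns x, y.
#' @slot cityCenter numeric (x, y) of the designated center.
#' @slot config the \linkS4class{LandscapeConfig} used.
#' @export
setClass("SyntheticLandscape",
  representation(stack = "CovariateStack", mask = "matrix", roads = "matrix",
                 amenities = "matrix", cityCenter = "numeric",
                 config = "LandscapeConfig")
)

#' Ground truth of a simulated survey
#'
#' The per-cell class-probability surfaces of the generating multinomial
#' model (summing to 1 per cell), the driver effects used, and the
#' simulated point locations with their true classes.
#'
#' @slot probSurfaces named list of three probability matrices.
#' @slot driverEffects the coefficients used.
#' @slot points data.frame \code{x}, \code{y}, \code{cell}, \code{class}.
#' @export
setClass("GroundTruth",
  representation(probSurfaces = "list", driverEffects = "list",
                 points = "data.frame")
)

setValidity("GroundTruth", function(object) {
  if (!setequal(names(object@probSurfaces), .bmiClasses))
    return("probSurfaces must name all three BMI classes")
  s <- Reduce(`+`, object@probSurfaces)
  if (max(abs(s - 1), na.rm = TRUE) > 1e-9)
    return("class probabilities must sum to 1 per cell")
  rng <- range(unlist(object@probSurfaces), na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) return("probabilities must lie in [0, 1]")
  TRUE
})
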