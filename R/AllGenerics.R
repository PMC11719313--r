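#' @include AllClasses.R
NULL

#' @describeIn GridGeometry constructor.
#' @param nrow,ncol grid dimensions.
#' @param xmin,ymax upper-left corner (m).
#' @param cellSize cell edge (m); 100 m gives 1 ha cells.
#' @param crs projected CRS identifier.
#' @export
gridGeometry <- function(nrow, ncol, xmin = 0, ymax = nrow * cellSize,
                         cellSize = 100, crs = "local-metric") {
  new("GridGeometry", nrow = as.integer(nrow), ncol = as.integer(ncol),
      xmin = as.numeric(xmin), ymax = as.numeric(ymax),
      cellSize = as.numeric(cellSize), crs = crs)
}

#' Accessors for grid-backed objects
#'
#' \code{gridGeom} returns the \linkS4class{GridGeometry}; \code{cellSize}
#' its cell edge in meters; \code{gridDim} the (rows, cols) dimensions.
#'
#' @param x a grid-backed object.
#' @return \code{gridGeom}: a \linkS4class{GridGeometry};
#'   \code{cellSize}: numeric; \code{gridDim}: integer(2).
#' @aliases gridGeom cellSize gridDim
#' @name grid-accessors
NULL

#' @rdname grid-accessors
#' @export
setGeneric("gridGeom", function(x) standardGeneric("gridGeom"))
#' @rdname grid-accessors
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))
#' @rdname grid-accessors
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' @rdname grid-accessors
setMethod("gridGeom", "GridGeometry", function(x) x)
#' @rdname grid-accessors
setMethod("gridGeom", "CovariateStack", function(x) x@geometry)
#' @rdname grid-accessors
setMethod("gridGeom", "AOAResult", function(x) x@geometry)
#' @rdname grid-accessors
setMethod("gridGeom", "EnsembleSurface", function(x) x@geometry)
#' @rdname grid-accessors
setMethod("gridGeom", "HotspotReport", function(x) x@geometry)
#' @rdname grid-accessors
setMethod("gridGeom", "DesignTable", function(x) x@geometry)
#' @rdname grid-accessors
setMethod("gridGeom", "SyntheticLandscape", function(x) x@stack@geometry)

#' @rdname grid-accessors
setMethod("cellSize", "GridGeometry", function(x) x@cellSize)
#' @rdname grid-accessors
setMethod("cellSize", "ANY", function(x) gridGeom(x)@cellSize)

#' @rdname grid-accessors
setMethod("gridDim", "GridGeometry", function(x) c(x@nrow, x@ncol))
#' @rdname grid-accessors
setMethod("gridDim", "ANY", function(x) gridDim(gridGeom(x)))

#' Accessors for covariate stacks
#'
#' @param x a \linkS4class{CovariateStack}.
#' @param name layer name.
#' @return \code{layerNames}: character; \code{nLayers}: integer;
#'   \code{getLayer}: numeric matrix; \code{layerMeta}: data.frame.
#' @name stack-accessors
NULL

#' @rdname stack-accessors
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))
#' @rdname stack-accessors
#' @export
setGeneric("nLayers", function(x) standardGeneric("nLayers"))
#' @rdname stack-accessors
#' @export
setGeneric("getLayer", function(x, name) standardGeneric("getLayer"))
#' @rdname stack-accessors
#' @export
setGeneric("layerMeta", function(x) standardGeneric("layerMeta"))

#' @rdname stack-accessors
setMethod("layerNames", "CovariateStack", function(x) names(x@layers))
#' @rdname stack-accessors
setMethod("nLayers", "CovariateStack", function(x) length(x@layers))
#' @rdname stack-accessors
setMethod("getLayer", "CovariateStack", function(x, name) {
  if (!name %in% names(x@layers)) stop("no layer named '", name, "'")
  x@layers[[name]]
})
#' @rdname stack-accessors
setMethod("layerMeta", "CovariateStack", function(x)
  x@meta[match(names(x@layers), x@meta$name), , drop = FALSE])

#' Accessors for survey points and design tables
#'
#' @param x a \linkS4class{SurveyPoints} or \linkS4class{DesignTable}.
#' @return \code{surveyData}/\code{designData}: the underlying data.frame;
#'   \code{targetClass}/\code{covariateNames}: character.
#' @name table-accessors
NULL

#' @rdname table-accessors
#' @export
setGeneric("surveyData", function(x) standardGeneric("surveyData"))
#' @rdname table-accessors
setMethod("surveyData", "SurveyPoints", function(x) x@data)

#' @rdname table-accessors
#' @export
setGeneric("designData", function(x) standardGeneric("designData"))
#' @rdname table-accessors
setMethod("designData", "DesignTable", function(x) x@data)

#' @rdname table-accessors
#' @export
setGeneric("targetClass", function(x) standardGeneric("targetClass"))
#' @rdname table-accessors
setMethod("targetClass", "DesignTable", function(x) x@targetClass)

#' @rdname table-accessors
#' @export
setGeneric("covariateNames", function(x) standardGeneric("covariateNames"))
#' @rdname table-accessors
setMethod("covariateNames", "DesignTable", function(x) x@covariates)

#' Accessors for AOA results
#'
#' @param x an \linkS4class{AOAResult}.
#' @return \code{dissimilarity}: DI matrix; \code{supportedMask}: logical
#'   matrix; \code{aoaThreshold}: numeric.
#' @name aoa-accessors
NULL

#' @rdname aoa-accessors
#' @export
setGeneric("dissimilarity", function(x) standardGeneric("dissimilarity"))
#' @rdname aoa-accessors
setMethod("dissimilarity", "AOAResult", function(x) x@di)
#' @rdname aoa-accessors
#' @export
setGeneric("supportedMask", function(x) standardGeneric("supportedMask"))
#' @rdname aoa-accessors
setMethod("supportedMask", "AOAResult", function(x) x@supported)
#' @rdname aoa-accessors
#' @export
setGeneric("aoaThreshold", function(x) standardGeneric("aoaThreshold"))
#' @rdname aoa-accessors
setMethod("aoaThreshold", "AOAResult", function(x) x@threshold)

#' Accessors for fitted learners and ensembles
#'
#' @param x a \linkS4class{FittedLearner}, \linkS4class{EnsembleModel} or
#'   \linkS4class{MetricReport}.
#' @return \code{cvAUC}/\code{cvTSS}: mean cross-validated metric;
#'   \code{gridLog}: the tuning table; \code{baseLearners}: named list;
#'   \code{oofPredictions}: out-of-fold probabilities.
#' @name model-accessors
NULL

#' @rdname model-accessors
#' @export
setGeneric("cvAUC", function(x) standardGeneric("cvAUC"))
#' @rdname model-accessors
setMethod("cvAUC", "FittedLearner", function(x) x@cvAUC)
#' @rdname model-accessors
setMethod("cvAUC", "EnsembleModel", function(x) x@cvAUC)
#' @rdname model-accessors
setMethod("cvAUC", "MetricReport", function(x) x@meanAUC)

#' @rdname model-accessors
#' @export
setGeneric("cvTSS", function(x) standardGeneric("cvTSS"))
#' @rdname model-accessors
setMethod("cvTSS", "EnsembleModel", function(x) x@cvTSS)
#' @rdname model-accessors
setMethod("cvTSS", "MetricReport", function(x) x@meanTSS)

#' @rdname model-accessors
#' @export
setGeneric("gridLog", function(x) standardGeneric("gridLog"))
#' @rdname model-accessors
setMethod("gridLog", "FittedLearner", function(x) x@gridLog)

#' @rdname model-accessors
#' @export
setGeneric("baseLearners", function(x) standardGeneric("baseLearners"))
#' @rdname model-accessors
setMethod("baseLearners", "EnsembleModel", function(x) x@baseLearners)

#' @rdname model-accessors
#' @export
setGeneric("oofPredictions", function(x) standardGeneric("oofPredictions"))
#' @rdname model-accessors
setMethod("oofPredictions", "FittedLearner", function(x) x@oofPred)

#' Accessors for ensemble surfaces and hotspot reports
#'
#' @param x an \linkS4class{EnsembleSurface} or \linkS4class{HotspotReport}.
#' @return \code{probLayer}/\code{sdLayer}: numeric matrices;
#'   \code{hotspotMask}: logical matrix for the requested tier;
#'   \code{unitTable}: per-administrative-unit area table.
#' @param tier 1 (threshold and AOA) or 2 (threshold only).
#' @name surface-accessors
NULL

#' @rdname surface-accessors
#' @export
setGeneric("probLayer", function(x) standardGeneric("probLayer"))
#' @rdname surface-accessors
setMethod("probLayer", "EnsembleSurface", function(x) x@prob)
#' @rdname surface-accessors
#' @export
setGeneric("sdLayer", function(x) standardGeneric("sdLayer"))
#' @rdname surface-accessors
setMethod("sdLayer", "EnsembleSurface", function(x) x@sd)

#' @rdname surface-accessors
#' @export
setGeneric("hotspotMask", function(x, tier = 1) standardGeneric("hotspotMask"))
#' @rdname surface-accessors
setMethod("hotspotMask", "HotspotReport", function(x, tier = 1) {
  stopifnot(tier %in% c(1, 2))
  if (tier == 1) x@hotspot1 else x@hotspot2
})

#' @rdname surface-accessors
#' @export
setGeneric("unitTable", function(x) standardGeneric("unitTable"))
#' @rdname surface-accessors
setMethod("unitTable", "HotspotReport", function(x) x@unitTable)

## ---- show methods -------------------------------------------------------

setMethod("show", "GridGeometry", function(object) {
  cat(sprintf("GridGeometry: %d x %d cells, %.6g m cells, origin (%.6g, %.6g), crs '%s'\n",
              object@nrow, object@ncol, object@cellSize,
              object@xmin, object@ymax, object@crs))
})

setMethod("show", "CovariateStack", function(object) {
  g <- object@geometry
  cat(sprintf("CovariateStack: %d layer(s) on %d x %d grid (%.6g m cells)\n",
              length(object@layers), g@nrow, g@ncol, g@cellSize))
  m <- layerMeta(object)
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %-24s [%s] %s\n", m$name[i], m$category[i], m$unit[i]))
})

setMethod("show", "SurveyPoints", function(object) {
  d <- object@data
  cat(sprintf("SurveyPoints: %d record(s)\n", nrow(d)))
  if (nrow(d)) {
    tab <- table(factor(d$bmi_class, levels = .bmiClasses))
    cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
})

setMethod("show", "DesignTable", function(object) {
  d <- object@data
  tab <- table(factor(d$role, levels = c("presence", "absence", "background")))
  cat(sprintf("DesignTable (target: %s): %s; %d covariate(s)\n",
              object@targetClass,
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", "),
              length(object@covariates)))
})

setMethod("show", "AOAResult", function(object) {
  cat(sprintf("AOAResult: DI threshold %.4g; %d / %d cells supported\n",
              object@threshold, sum(object@supported, na.rm = TRUE),
              sum(!is.na(object@supported))))
})

setMethod("show", "FittedLearner", function(object) {
  hp <- paste(sprintf("%s=%s", names(object@hyperparameters),
                      vapply(object@hyperparameters, format, character(1))),
              collapse = ", ")
  cat(sprintf("FittedLearner <%s>: mean CV AUC %.3f over %d fold(s)\n  %s\n",
              object@family, object@cvAUC, length(object@foldModels), hp))
})

setMethod("show", "EnsembleModel", function(object) {
  cat(sprintf("EnsembleModel: %d base learners + RF meta-learner\n",
              length(object@baseLearners)))
  for (bl in object@baseLearners)
    cat(sprintf("  %-14s CV AUC %.3f\n", bl@family, bl@cvAUC))
  cat(sprintf("  stacked        CV AUC %.3f, CV max-TSS %.3f\n",
              object@cvAUC, object@cvTSS))
})

setMethod("show", "EnsembleSurface", function(object) {
  p <- object@prob
  cat(sprintf("EnsembleSurface [%s, %s]: %d masked cell(s), prob range %.3f-%.3f\n",
              object@city, object@classLabel, sum(!is.na(p)),
              suppressWarnings(min(p, na.rm = TRUE)),
              suppressWarnings(max(p, na.rm = TRUE))))
})

setMethod("show", "HotspotReport", function(object) {
  cat(sprintf("HotspotReport [%s, > %.2f]: hotspot1 %.6g ha, hotspot2 %.6g ha\n",
              object@classLabel, object@threshold,
              sum(object@hotspot1, na.rm = TRUE) *
                (object@geometry@cellSize^2 / 1e4),
              sum(object@hotspot2, na.rm = TRUE) *
                (object@geometry@cellSize^2 / 1e4)))
  if (nrow(object@unitTable))
    cat(sprintf("  %d administrative unit(s) summarized\n", nrow(object@unitTable)))
})

setMethod("show", "MetricReport", function(object) {
  cat(sprintf("MetricReport: %d folds, mean AUC %.3f, mean max-TSS %.3f\n",
              nrow(object@folds), object@meanAUC, object@meanTSS))
})

setMethod("show", "LandscapeConfig", function(object) {
  cat(sprintf("LandscapeConfig: %d x %d cells @ %.6g m, seed %d, mask %.0f%%, range %.6g m\n",
              object@gridShape[1], object@gridShape[2], object@cellSize,
              object@seed, 100 * object@maskFraction, object@spatialRange))
  cat("  quotas:", paste(sprintf("%s=%d", names(object@nPointsPerClass),
                                 object@nPointsPerClass), collapse = ", "), "\n")
})

setMethod("show", "SyntheticLandscape", function(object) {
  cat(sprintf("SyntheticLandscape: %d covariate layer(s), %d road segment(s), %d amenit(ies)\n",
              nLayers(object@stack), nrow(object@roads), nrow(object@amenities)))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: 3 class-probability surfaces, %d simulated point(s)\n",
              nrow(object@points)))
})
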