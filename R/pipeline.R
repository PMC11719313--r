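#' @include AllClasses.R synthetic-landscape.R sampling.R ensemble.R
#' @include interpretation.R hotspots.R io.R
NULL

#' Configure an end-to-end pipeline run
#'
#' Bundles every pipeline constant with its default: 5 CV folds, a 0.8
#' decorrelation cutoff, a 0.8 hotspot probability threshold, and 10
#' permutation iterations, together with the landscape configuration (or
#' input paths), the classes to model, and the output directory.
#'
#' @param landscape a \linkS4class{LandscapeConfig} for synthetic input,
#'   or a list with elements \code{stackDir} and \code{surveyCSV} naming
#'   on-disk inputs.
#' @param classes BMI classes to model (default all three).
#' @param city city identifier for outputs.
#' @param folds CV folds (default 5).
#' @param rMax decorrelation correlation cutoff (default 0.8).
#' @param hotspotThreshold hotspot probability cutoff (default 0.8).
#' @param permIterations permutation-importance iterations (default 10).
#' @param backgroundN background size; \code{NULL} = 10 x presence count
#'   (capped by eligible cells).
#' @param textureWindow odd window (cells) for the NDVI texture layers;
#'   \code{0} skips texture engineering.
#' @param decorrelate logical; run the decorrelation stage.
#' @param seed master seed.
#' @param outdir output directory.
#' @return a list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(landscape = landscapeConfig(),
                           classes = c("underweight", "normal",
                                       "overweight_obese"),
                           city = "synthcity", folds = 5L, rMax = 0.8,
                           hotspotThreshold = 0.8, permIterations = 10L,
                           backgroundN = NULL, textureWindow = 3L,
                           decorrelate = TRUE, seed = 1L,
                           outdir = tempfile("malnutmap_run")) {
  classes <- match.arg(classes, .bmiClasses, several.ok = TRUE)
  structure(list(landscape = landscape, classes = classes, city = city,
                 folds = as.integer(folds), rMax = rMax,
                 hotspotThreshold = hotspotThreshold,
                 permIterations = as.integer(permIterations),
                 backgroundN = backgroundN,
                 textureWindow = as.integer(textureWindow),
                 decorrelate = isTRUE(decorrelate),
                 seed = as.integer(seed), outdir = outdir),
            class = "PipelineConfig")
}

## Run one stage with RDS caching under <outdir>/cache for resume.
.stage <- function(name, manifest, resume, fun) {
  cache <- file.path(manifest$outdir, "cache", paste0(name, ".rds"))
  if (resume && file.exists(cache)) {
    manifest$stages[[name]] <- list(status = "resumed", cache = cache)
    return(list(value = readRDS(cache), manifest = manifest))
  }
  value <- fun()
  dir.create(dirname(cache), showWarnings = FALSE, recursive = TRUE)
  saveRDS(value, cache)
  manifest$stages[[name]] <- list(status = "done", cache = cache)
  list(value = value, manifest = manifest)
}

#' Run the full mapping pipeline
#'
#' Executes, per configured class: simulate (or ingest) inputs, engineer
#' texture covariates, decorrelate the roster, compute the area of
#' applicability, draw target-group background, build the design table,
#' tune and stack the five base learners, evaluate, compute jack-knife
#' and permutation importance with response curves, predict the
#' probability and standard-deviation surfaces, and delineate two-tier
#' hotspots with per-unit summaries. Every artifact is written under
#' \code{outdir} and recorded in a JSON manifest; stages are cached so a
#' rerun with \code{resume = TRUE} reuses completed stages.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param resume reuse cached stage results when present.
#' @return the manifest (list), invisibly; its \code{results} element
#'   holds the per-class models, metric tables, surfaces and hotspot
#'   reports.
#' @export
runPipeline <- function(config, resume = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(outdir = outdir, seed = config$seed,
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   parameters = list(folds = config$folds, rMax = config$rMax,
                                     hotspotThreshold = config$hotspotThreshold,
                                     permIterations = config$permIterations),
                   stages = list(), results = list())

  ## ---- inputs ----------------------------------------------------------
  st <- .stage("inputs", manifest, resume, function() {
    if (is(config$landscape, "LandscapeConfig")) {
      land <- generateCovariates(config$landscape)
      sim <- simulateSurvey(land, city = config$city)
      writeStack(land@stack, file.path(outdir, "stack"))
      writeSurveyCSV(sim$points, file.path(outdir, "survey.csv"))
      writeGeoJSON(land@roads, file.path(outdir, "roads.geojson"))
      writeGeoJSON(land@amenities, file.path(outdir, "amenities.geojson"))
      writeLandscapeConfig(config$landscape, file.path(outdir, "landscape.yml"))
      writeAsciiGrid(matrix(as.numeric(land@mask), nrow(land@mask)),
                     land@stack@geometry, file.path(outdir, "mask.asc"))
      list(stack = land@stack, mask = land@mask, points = sim$points,
           truth = sim$truth)
    } else {
      stack <- readStack(config$landscape$stackDir)
      points <- readSurveyCSV(config$landscape$surveyCSV)
      mask <- if (!is.null(config$landscape$maskAsc))
        readAsciiGrid(config$landscape$maskAsc)$matrix > 0
      else matrix(TRUE, stack@geometry@nrow, stack@geometry@ncol)
      list(stack = stack, mask = mask, points = points, truth = NULL)
    }
  })
  manifest <- st$manifest; inputs <- st$value

  ## ---- covariate engineering ------------------------------------------
  st <- .stage("covariates", manifest, resume, function() {
    stack <- inputs$stack
    if (config$textureWindow >= 3L && "ndvi" %in% layerNames(stack))
      stack <- addTextureLayers(stack, "ndvi", config$textureWindow)
    stack
  })
  manifest <- st$manifest; stack <- st$value

  for (cls in config$classes) {
    tag <- paste0(config$city, "_", cls)

    st <- .stage(paste0("design_", tag), manifest, resume, function() {
      surveyDesign <- buildDesign(inputs$points, cls, stack)
      ## survey-only design has no background rows yet, so the
      ## sensitivity refits use a presence-absence family
      roster <- if (config$decorrelate)
        decorrelate(surveyDesign,
                    spec = learnerSpec("random_forest",
                                       seed = .subSeed(config$seed, "dec")),
                    rMax = config$rMax)$retained
      else surveyDesign@covariates
      surveyDesign <- restrictDesign(surveyDesign, roster)
      aoa <- dissimilarityIndex(surveyDesign, stack, mask = inputs$mask)
      writeAsciiGrid(dissimilarity(aoa), stack@geometry,
                     file.path(outdir, paste0(tag, "_di.asc")))
      nPres <- sum(designData(surveyDesign)$role == "presence")
      nbg <- if (is.null(config$backgroundN)) 10L * nPres
      else config$backgroundN
      pres <- surveyPoints(surveyData(inputs$points)[
        surveyData(inputs$points)$bmi_class == cls, , drop = FALSE])
      avail <- sum(supportedMask(aoa) & inputs$mask, na.rm = TRUE) -
        nrow(surveyData(inputs$points))
      nbg <- min(nbg, max(1L, avail))
      if (nbg < nPres)
        warning("only ", nbg, " eligible background cells for ", nPres,
                " presences; consider a larger landscape or smaller quotas")
      bg <- sampleBackground(pres, inputs$mask, aoa, n = nbg,
                             seed = .subSeed(config$seed, paste0("bg", cls)),
                             exclude = inputs$points)
      design <- restrictDesign(buildDesign(inputs$points, cls, stack, bg),
                               roster)
      utils::write.csv(designData(design),
                       file.path(outdir, paste0(tag, "_design.csv")),
                       row.names = FALSE)
      list(design = design, aoa = aoa, roster = roster)
    })
    manifest <- st$manifest
    design <- st$value$design; aoa <- st$value$aoa

    st <- .stage(paste0("fit_", tag), manifest, resume, function() {
      fitStack(design, specs = defaultLearnerSpecs(config$seed),
               folds = config$folds, seed = .subSeed(config$seed, tag))
    })
    manifest <- st$manifest; model <- st$value

    st <- .stage(paste0("interpret_", tag), manifest, resume, function() {
      jk <- jackknifeImportance(design,
        spec = learnerSpec("maxent_lq", seed = .subSeed(config$seed, "jk")))
      pm <- permutationImportance(model, design,
                                  iterations = config$permIterations,
                                  seed = .subSeed(config$seed, "perm"))
      utils::write.csv(jk, file.path(outdir, paste0(tag, "_jackknife.csv")),
                       row.names = FALSE)
      utils::write.csv(pm, file.path(outdir, paste0(tag, "_permutation.csv")),
                       row.names = FALSE)
      list(jackknife = jk, permutation = pm,
           jackknife_category = aggregateByCategory(jk),
           permutation_category = aggregateByCategory(pm))
    })
    manifest <- st$manifest; interp <- st$value

    st <- .stage(paste0("map_", tag), manifest, resume, function() {
      surf <- predictSurface(model, stack, inputs$mask, classLabel = cls,
                             city = config$city)
      writeAsciiGrid(probLayer(surf), stack@geometry,
                     file.path(outdir, paste0(tag, "_prob.asc")))
      writeAsciiGrid(sdLayer(surf), stack@geometry,
                     file.path(outdir, paste0(tag, "_sd.asc")))
      hs <- delineateHotspots(surf, aoa, config$hotspotThreshold)
      hs <- summarizeByUnit(hs, quadrantUnits(stack@geometry))
      utils::write.csv(unitTable(hs),
                       file.path(outdir, paste0(tag, "_hotspots.csv")),
                       row.names = FALSE)
      list(surface = surf, hotspots = hs)
    })
    manifest <- st$manifest

    metrics <- data.frame(city = config$city, class = cls,
                          model = c(names(baseLearners(model)), "ensemble"),
                          auc = c(vapply(baseLearners(model), cvAUC,
                                         numeric(1)), cvAUC(model)),
                          tss = c(rep(NA_real_, 5), cvTSS(model)))
    manifest$results[[tag]] <- list(
      model = model, design = design, aoa = aoa, metrics = metrics,
      importance = interp, surface = st$value$surface,
      hotspots = st$value$hotspots)
  }

  allMetrics <- do.call(rbind, lapply(manifest$results, `[[`, "metrics"))
  utils::write.csv(allMetrics, file.path(outdir, "metrics.csv"),
                   row.names = FALSE)
  manifest$metricsCSV <- file.path(outdir, "metrics.csv")
  jsonlite::write_json(
    list(seed = config$seed, parameters = manifest$parameters,
         stages = lapply(manifest$stages, `[[`, "status"),
         outputs = list.files(outdir, pattern = "\\.(csv|asc|yml|geojson)$")),
    file.path(outdir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
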