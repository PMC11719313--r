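#' @include synthetic-landscape.R sampling.R
NULL

#' Reference synthetic benchmark design
#'
#' The package's standard benchmark: a 100 x 100 cell (1 ha) landscape
#' with one dominant driver -- road density with coefficient 2 on the
#' logit scale for overweight-obese -- surveyed with 200 presence
#' (overweight-obese) and 200 absence points, plus 2000 target-group
#' background cells drawn inside the area of applicability. Used to
#' check that the stacked ensemble clears the better-than-chance bars
#' (AUC > 0.7, TSS > 0.5).
#'
#' @param seed integer master seed for the landscape, survey and
#'   background draws.
#' @return list with \code{design} (\linkS4class{DesignTable}),
#'   \code{aoa}, \code{landscape}, \code{survey}, and \code{truth}.
#' @export
syntheticBenchmarkDesign <- function(seed = 42L) {
  cfg <- landscapeConfig(
    gridShape = c(100L, 100L), seed = as.integer(seed),
    nPointsPerClass = c(underweight = 40L, normal = 160L,
                        overweight_obese = 200L),
    driverEffects = list(overweight_obese = c(road_density = 2)))
  land <- generateCovariates(cfg)
  sim <- simulateSurvey(land)
  stack <- landscapeStack(land)
  survey <- buildDesign(sim$points, "overweight_obese", stack)
  aoa <- dissimilarityIndex(survey, stack, mask = landscapeMask(land))
  pd <- surveyData(sim$points)
  pres <- surveyPoints(pd[pd$bmi_class == "overweight_obese", , drop = FALSE])
  bg <- sampleBackground(pres, landscapeMask(land), aoa, n = 2000L,
                         seed = .subSeed(seed, "bg"), exclude = sim$points)
  design <- buildDesign(sim$points, "overweight_obese", stack, bg)
  list(design = design, aoa = aoa, landscape = land, survey = sim$points,
       truth = sim$truth)
}
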