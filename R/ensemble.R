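#' @include AllClasses.R learners.R evaluation.R
NULL

#' Fit the stacked-generalization ensemble
#'
#' Trains the five base learners with grid-search tuning under one shared
#' fold assignment, assembles their out-of-fold predictions at the
#' presence and absence rows into the meta-design, and fits the
#' random-forest meta-learner on it. The meta-learner only ever sees
#' predictions made by base models that did not train on the row, so the
#' stack is leakage-free by construction; its own cross-validated metrics
#' are computed by refitting the meta forest per fold. Ensemble
#' performance is reported as the fold-mean held-out AUC and
#' threshold-maximized TSS of the stacked predictions.
#'
#' @param design a \linkS4class{DesignTable} with presence, absence and
#'   background rows.
#' @param specs named list of five \code{\link{learnerSpec}}s (default
#'   \code{\link{defaultLearnerSpecs}}).
#' @param folds number of shared CV folds, default 5.
#' @param seed integer master seed (fold split, meta forest, and the
#'   default specs' sub-seeds).
#' @param metaGrid data.frame of meta-forest candidates (columns
#'   \code{mode}, \code{mtry}, \code{nodesize}); the meta-learner is
#'   grid-searched by the same shared-fold mean CV AUC rule as the base
#'   learners. \code{NULL} uses a small default grid.
#' @return an \linkS4class{EnsembleModel}.
#' @export
fitStack <- function(design, specs = defaultLearnerSpecs(seed), folds = 5L,
                     seed = 1L, metaGrid = NULL) {
  stopifnot(is(design, "DesignTable"))
  if (!setequal(names(specs), .learnerFamilies()))
    stop("specs must cover exactly the five base-learner families")
  d <- designData(design)
  for (role in c("presence", "absence", "background"))
    if (!any(d$role == role))
      stop("design has no ", role, " rows; the stack needs all three roles")

  ## shared fold assignment, stratified by role so every fold carries
  ## presences, absences and background
  roleCode <- match(d$role, c("presence", "absence", "background"))
  fa <- .stratifiedFolds(roleCode, folds, .subSeed(seed, "stackfolds"))

  base <- lapply(.learnerFamilies(), function(fam) {
    bl <- tryCatch(
      tuneLearner(design, specs[[fam]], folds = folds, foldAssign = fa),
      error = function(e)
        stop("base learner '", fam, "' failed: ", conditionMessage(e),
             call. = FALSE))
    bl
  })
  names(base) <- .learnerFamilies()

  ## meta-design at the presence + absence rows: out-of-fold predictions
  metaRows <- which(d$role %in% c("presence", "absence"))
  mf <- fa[metaRows]
  meta <- data.frame(row = metaRows, fold = mf, label = d$label[metaRows])
  X <- as.matrix(d[metaRows, design@covariates, drop = FALSE])
  for (fam in .learnerFamilies()) {
    bl <- base[[fam]]
    p <- rep(NA_real_, length(metaRows))
    inBl <- match(metaRows, bl@rowIndex)
    has <- !is.na(inBl)
    p[has] <- bl@oofPred[inBl[has]]
    ## rows the learner never trained on (absences, for the MaxEnt
    ## variants): predict them with the model of their own fold, which
    ## also never saw them
    if (any(!has)) {
      for (i in unique(mf[!has])) {
        sel <- !has & mf == i
        p[sel] <- .predictFamily(bl@foldModels[[i]], X[sel, , drop = FALSE])
      }
    }
    meta[[paste0("pred_", fam)]] <- p
  }

  pcols <- paste0("pred_", .learnerFamilies())
  M <- as.matrix(meta[, pcols, drop = FALSE])

  ## the meta random forest gets the same grid-search treatment as the
  ## base learners: mode (probability forest vs regression on the 0/1
  ## label), mtry and nodesize, chosen by shared-fold mean CV AUC
  if (is.null(metaGrid))
    metaGrid <- expand.grid(mode = c("classification", "regression"),
                            mtry = c(1L, 2L), nodesize = c(5L, 30L, 80L),
                            stringsAsFactors = FALSE)
  evalMeta <- function(hp, keepModels = FALSE) {
    fmods <- vector("list", folds)
    ensP <- rep(NA_real_, nrow(meta))
    fm <- data.frame(fold = seq_len(folds), auc = NA_real_, tss = NA_real_,
                     threshold = NA_real_)
    for (i in seq_len(folds)) {
      tr <- meta$fold != i
      m <- .fitMetaRF(M[tr, , drop = FALSE], meta$label[tr], hp,
                      .subSeed(seed, paste0("meta", i)))
      if (keepModels) fmods[[i]] <- m
      if (any(!tr)) {
        p <- .metaPredictRF(m, M[!tr, , drop = FALSE])
        ensP[!tr] <- p
        yte <- meta$label[!tr]
        if (length(unique(yte)) == 2L) {
          fm$auc[i] <- aucScore(p[yte == 1L], p[yte == 0L])
          mt <- maxTSS(p, yte)
          fm$tss[i] <- mt$tss; fm$threshold[i] <- mt$threshold
        }
      }
    }
    list(models = fmods, pred = ensP, foldMetrics = fm,
         meanAUC = mean(fm$auc, na.rm = TRUE))
  }
  metaAUC <- vapply(seq_len(nrow(metaGrid)), function(g)
    evalMeta(as.list(metaGrid[g, , drop = FALSE]))$meanAUC, numeric(1))
  cxMeta <- metaGrid$mtry / metaGrid$nodesize  # lower = simpler
  metaGridLog <- cbind(metaGrid, mean_cv_auc = metaAUC, complexity = cxMeta)
  best <- which(metaAUC == max(metaAUC, na.rm = TRUE))
  best <- best[order(cxMeta[best])][1]
  metaHP <- as.list(metaGrid[best, , drop = FALSE])
  win <- evalMeta(metaHP, keepModels = TRUE)
  meta$pred_ensemble <- win$pred
  metaFinal <- .fitMetaRF(M, meta$label, metaHP, .subSeed(seed, "metafinal"))

  new("EnsembleModel", baseLearners = base, metaFoldModels = win$models,
      metaFinal = metaFinal, metaDesign = meta,
      metaHyperparameters = metaHP, metaGridLog = metaGridLog,
      foldMetrics = win$foldMetrics,
      cvAUC = mean(win$foldMetrics$auc, na.rm = TRUE),
      cvTSS = mean(win$foldMetrics$tss, na.rm = TRUE),
      variables = design@covariates, seed = as.integer(seed))
}

.fitMetaRF <- function(x, y, hp, seed) {
  .withSeed(seed, {
    if (hp$mode == "classification")
      randomForest::randomForest(x = x, y = factor(y, levels = c(0, 1)),
                                 ntree = 500L, mtry = hp$mtry,
                                 nodesize = hp$nodesize)
    else
      suppressWarnings(randomForest::randomForest(
        x = x, y = as.numeric(y), ntree = 500L, mtry = hp$mtry,
        nodesize = hp$nodesize))
  })
}

.metaPredictRF <- function(m, x) {
  p <- if (m$type == "classification")
    stats::predict(m, x, type = "prob")[, "1"]
  else stats::predict(m, x)
  pmin(1, pmax(0, as.numeric(p)))
}

## Predict ensemble probability (and the across-base-learner sd) for a
## covariate matrix; fold = NULL uses the final models.
.ensemblePredict <- function(model, X, fold = NULL) {
  fams <- names(model@baseLearners)
  B <- vapply(fams, function(fam) {
    bl <- model@baseLearners[[fam]]
    m <- if (is.null(fold)) bl@finalModel else bl@foldModels[[fold]]
    .predictFamily(m, X)
  }, numeric(nrow(X)))
  if (!is.matrix(B)) B <- matrix(B, nrow = 1, dimnames = list(NULL, fams))
  colnames(B) <- paste0("pred_", fams)
  meta <- if (is.null(fold)) model@metaFinal else model@metaFoldModels[[fold]]
  p <- .metaPredictRF(meta, B)
  list(prob = p, sd = apply(B, 1, stats::sd), base = B)
}

#' Predict the per-class probability surface of an ensemble
#'
#' Evaluates every base learner and the meta-learner over the masked
#' cells of the covariate stack, in chunks so memory stays bounded on
#' large grids. The standard-deviation layer is the per-cell standard
#' deviation of the five base-learner probabilities. Cells outside the
#' mask, or with any NoData covariate, are NoData in both layers.
#'
#' @param model an \linkS4class{EnsembleModel}.
#' @param stack a \linkS4class{CovariateStack} covering the model's
#'   covariate roster (extra layers ignored).
#' @param mask logical older-adults matrix on the stack grid; \code{NULL}
#'   predicts everywhere.
#' @param classLabel,city labels stored on the surface.
#' @param chunk cells per evaluation block.
#' @return an \linkS4class{EnsembleSurface}.
#' @export
predictSurface <- function(model, stack, mask = NULL,
                           classLabel = "overweight_obese", city = "city1",
                           chunk = 5000L) {
  stopifnot(is(model, "EnsembleModel"), is(stack, "CovariateStack"))
  miss <- setdiff(model@variables, layerNames(stack))
  if (length(miss))
    stop("stack is missing covariate layer(s): ", paste(miss, collapse = ", "))
  geom <- stack@geometry
  ncell <- geom@nrow * geom@ncol
  C <- vapply(model@variables, function(nm) as.vector(t(getLayer(stack, nm))),
              numeric(ncell))
  if (!is.matrix(C)) C <- matrix(C, nrow = ncell)
  colnames(C) <- model@variables
  use <- rowSums(is.na(C)) == 0L
  if (!is.null(mask)) {
    if (!identical(dim(mask), c(geom@nrow, geom@ncol)))
      stop("mask geometry does not match the stack")
    use <- use & as.vector(t(mask))
  }
  prob <- sdv <- rep(NA_real_, ncell)
  idx <- which(use)
  if (length(idx)) {
    for (s in seq(1L, length(idx), by = chunk)) {
      e <- min(length(idx), s + chunk - 1L)
      blk <- idx[s:e]
      pr <- .ensemblePredict(model, C[blk, , drop = FALSE])
      prob[blk] <- pr$prob
      sdv[blk] <- pr$sd
    }
  }
  new("EnsembleSurface",
      prob = matrix(prob, geom@nrow, geom@ncol, byrow = TRUE),
      sd = matrix(sdv, geom@nrow, geom@ncol, byrow = TRUE),
      classLabel = classLabel, city = city, geometry = geom)
}
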