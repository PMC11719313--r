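#' @include AllClasses.R utils.R evaluation.R
NULL

.learnerFamilies <- function()
  c("maxent_lq", "maxent_lqh", "random_forest", "boosted_trees", "neural_net")

.presenceOnlyFamilies <- function() c("maxent_lq", "maxent_lqh")

#' Specify a base learner and its tuning grid
#'
#' The five families are two MaxEnt-style presence-background models
#' (penalized logistic regression on expanded feature classes: linear +
#' quadratic, optionally + hinge) and three presence-absence learners
#' (random forest, gradient-boosted trees, single-hidden-layer neural
#' network). Default grids are deliberately small (<= 8 combinations) and
#' user-configurable.
#'
#' @param family one of \code{maxent_lq}, \code{maxent_lqh},
#'   \code{random_forest}, \code{boosted_trees}, \code{neural_net}.
#' @param grid named list of hyperparameter candidate vectors; defaults
#'   per family when \code{NULL}.
#' @param seed integer seed for stochastic fits.
#' @return a list of class \code{LearnerSpec}.
#' @export
learnerSpec <- function(family, grid = NULL, seed = 1L) {
  family <- match.arg(family, .learnerFamilies())
  if (is.null(grid)) grid <- .defaultGrid(family)
  if (!length(grid) || !all(lengths(grid) >= 1L))
    stop("grid must be a non-empty named list of candidate values")
  structure(list(family = family, grid = grid, seed = as.integer(seed)),
            class = "LearnerSpec")
}

.defaultGrid <- function(family) {
  switch(family,
    maxent_lq = list(lambda = c(0.0005, 0.005, 0.05)),
    maxent_lqh = list(lambda = c(0.0005, 0.005, 0.05)),
    random_forest = list(ntree = 300L, mtry_frac = c(1 / 3, 0.6),
                         nodesize = c(1L, 5L)),
    boosted_trees = list(nrounds = c(50L, 150L), max_depth = c(2L, 4L),
                         eta = 0.1),
    neural_net = list(size = c(3L, 6L), decay = c(0.01, 0.1)))
}

#' Default specs for all five base learners
#'
#' @param seed integer seed shared by the family-specific sub-seeds.
#' @return named list of \code{LearnerSpec}s.
#' @export
defaultLearnerSpecs <- function(seed = 1L) {
  fams <- .learnerFamilies()
  stats::setNames(lapply(fams, function(f)
    learnerSpec(f, seed = .subSeed(seed, f))), fams)
}

## Lower = simpler; used to break AUC ties toward the least complex fit.
.complexity <- function(family, hp) {
  switch(family,
    maxent_lq = -hp$lambda,
    maxent_lqh = -hp$lambda,
    random_forest = hp$ntree * hp$mtry_frac / hp$nodesize,
    boosted_trees = hp$nrounds * hp$max_depth * hp$eta,
    neural_net = hp$size / hp$decay)
}

## ---- feature expansion for the MaxEnt-style families -------------------

## Linear + quadratic (+ hinge) expansion on standardized columns.
## Hinge knots at the 25/50/75% quantiles of each standardized variable,
## in both directions, mirroring the maxnet feature classes.
.maxentFeatures <- function(Z, hinge, knots = NULL) {
  p <- ncol(Z)
  feats <- list(Z, Z^2)
  nms <- c(paste0(colnames(Z), "_l"), paste0(colnames(Z), "_q"))
  if (hinge) {
    if (is.null(knots))
      knots <- lapply(seq_len(p), function(j)
        unique(stats::quantile(Z[, j], c(0.25, 0.5, 0.75), names = FALSE)))
    hf <- list(); hn <- character(0)
    for (j in seq_len(p)) for (ki in seq_along(knots[[j]])) {
      k <- knots[[j]][ki]
      hf <- c(hf, list(pmax(0, Z[, j] - k)), list(pmax(0, k - Z[, j])))
      hn <- c(hn, paste0(colnames(Z)[j], "_h", ki, c("u", "d")))
    }
    feats <- c(feats, hf)
    nms <- c(nms, hn)
  }
  F <- do.call(cbind, lapply(feats, as.matrix))
  colnames(F) <- nms
  attr(F, "knots") <- if (hinge) knots else NULL
  F
}

## ---- family-specific fit / predict -------------------------------------

.fitFamily <- function(family, X, y, hp, seed) {
  X <- as.matrix(X)
  keep <- apply(X, 2, function(v) stats::sd(v) > 0)
  if (!all(keep)) {
    warning("dropping constant covariate(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  if (ncol(X) == 0L) stop("no non-constant covariates to fit")
  state <- switch(family,
    maxent_lq = , maxent_lqh = {
      std <- .standardize(X)
      F <- .maxentFeatures(std$x, hinge = family == "maxent_lqh")
      knots <- attr(F, "knots")
      ok <- apply(F, 2, function(v) stats::sd(v) > 0)
      Fu <- F[, ok, drop = FALSE]
      if (ncol(Fu) < 2L) Fu <- cbind(Fu, .dup = Fu[, 1])  # glmnet needs >= 2
      fit <- .withSeed(seed, glmnet::glmnet(
        Fu, y, family = "binomial", alpha = 1, lambda = hp$lambda,
        standardize = FALSE))
      list(fit = fit, center = std$center, scale = std$scale,
           featKeep = ok, knots = knots, padded = ncol(F[, ok, drop = FALSE]) < 2L)
    },
    random_forest = {
      mtry <- max(1L, floor(hp$mtry_frac * ncol(X)))
      .withSeed(seed, randomForest::randomForest(
        x = X, y = factor(y, levels = c(0, 1)), ntree = hp$ntree,
        mtry = mtry, nodesize = hp$nodesize))
    },
    boosted_trees = {
      .withSeed(seed, xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = hp$max_depth,
                      eta = hp$eta, nthread = 1),
        data = xgboost::xgb.DMatrix(X, label = y), nrounds = hp$nrounds,
        verbose = 0))
    },
    neural_net = {
      std <- .standardize(X)
      fit <- .withSeed(seed, nnet::nnet(
        x = std$x, y = y, size = hp$size, decay = hp$decay, maxit = 400,
        entropy = TRUE, trace = FALSE))
      list(fit = fit, center = std$center, scale = std$scale)
    })
  list(family = family, state = state, vars = colnames(X), hp = hp)
}

.predictFamily <- function(model, X) {
  X <- as.matrix(X)[, model$vars, drop = FALSE]
  p <- switch(model$family,
    maxent_lq = , maxent_lqh = {
      st <- model$state
      Z <- .standardize(X, center = st$center, scale = st$scale)$x
      F <- .maxentFeatures(Z, hinge = model$family == "maxent_lqh",
                           knots = st$knots)
      Fu <- F[, st$featKeep, drop = FALSE]
      if (st$padded || ncol(Fu) < 2L) Fu <- cbind(Fu, .dup = Fu[, 1])
      as.numeric(stats::predict(st$fit, Fu, type = "response"))
    },
    random_forest =
      as.numeric(stats::predict(model$state, X, type = "prob")[, "1"]),
    boosted_trees =
      as.numeric(stats::predict(model$state, xgboost::xgb.DMatrix(X))),
    neural_net = {
      st <- model$state
      Z <- .standardize(X, center = st$center, scale = st$scale)$x
      as.numeric(stats::predict(st$fit, Z))
    })
  pmin(1, pmax(0, p))
}

## Rows of the design a family trains on: presence-background for the
## MaxEnt-style models, presence-absence for the ML classifiers.
.familyRows <- function(design, family) {
  d <- designData(design)
  roles <- if (family %in% .presenceOnlyFamilies())
    c("presence", "background") else c("presence", "absence")
  which(d$role %in% roles)
}

## ---- tuning -------------------------------------------------------------

#' Grid-search tuning of one base learner by k-fold CV AUC
#'
#' Evaluates every hyperparameter combination of the spec's grid by
#' k-fold mean held-out AUC on the design rows the family uses
#' (presence + background for the MaxEnt variants, presence + absence for
#' the classifiers). The winner (ties broken toward the least complex
#' setting, then grid order) is refitted per fold -- retaining fold
#' states and out-of-fold predictions -- and on all rows for mapping.
#' The full grid table is kept in \code{gridLog}.
#'
#' @param design a \linkS4class{DesignTable}.
#' @param spec a \code{\link{learnerSpec}}.
#' @param folds number of CV folds (>= 2), default 5.
#' @param foldAssign optional integer fold id per design row (length =
#'   total design rows) to share folds across learners; built internally
#'   when \code{NULL}.
#' @return a \linkS4class{FittedLearner}.
#' @export
tuneLearner <- function(design, spec, folds = 5L, foldAssign = NULL) {
  stopifnot(inherits(spec, "LearnerSpec"), folds >= 2L)
  d <- designData(design)
  rows <- .familyRows(design, spec$family)
  if (length(unique(d$label[rows])) < 2L)
    stop(spec$family, ": design rows contain a single class")
  vars <- design@covariates
  X <- as.matrix(d[rows, vars, drop = FALSE])
  y <- d$label[rows]
  if (is.null(foldAssign)) {
    fa <- integer(nrow(d))
    fa[rows] <- .stratifiedFolds(y, folds, .subSeed(spec$seed, "folds"))
  } else {
    stopifnot(length(foldAssign) == nrow(d))
    fa <- foldAssign
  }
  f <- fa[rows]

  gridTab <- expand.grid(spec$grid, KEEP.OUT.ATTRS = FALSE,
                         stringsAsFactors = FALSE)
  cvOne <- function(hp) {
    aucs <- vapply(seq_len(folds), function(i) {
      tr <- f != i
      if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L)
        return(NA_real_)
      m <- .fitFamily(spec$family, X[tr, , drop = FALSE], y[tr], hp,
                      .subSeed(spec$seed, paste0("f", i)))
      p <- .predictFamily(m, X[!tr, , drop = FALSE])
      aucScore(p[y[!tr] == 1L], p[y[!tr] == 0L])
    }, numeric(1))
    if (anyNA(aucs))
      warning(spec$family, ": ", sum(is.na(aucs)),
              " fold(s) held a single class; excluded from the mean")
    mean(aucs, na.rm = TRUE)
  }
  meanAUC <- vapply(seq_len(nrow(gridTab)), function(g)
    cvOne(as.list(gridTab[g, , drop = FALSE])), numeric(1))
  cx <- vapply(seq_len(nrow(gridTab)), function(g)
    .complexity(spec$family, as.list(gridTab[g, , drop = FALSE])), numeric(1))
  gridLog <- cbind(gridTab, mean_cv_auc = meanAUC, complexity = cx)
  best <- which(meanAUC == max(meanAUC, na.rm = TRUE))
  best <- best[order(cx[best])][1]
  hp <- as.list(gridTab[best, , drop = FALSE])

  ## refit the winner per fold, collecting out-of-fold predictions
  foldModels <- vector("list", folds)
  oof <- rep(NA_real_, length(rows))
  foldAUC <- rep(NA_real_, folds)
  for (i in seq_len(folds)) {
    tr <- f != i
    foldModels[[i]] <- .fitFamily(spec$family, X[tr, , drop = FALSE], y[tr],
                                  hp, .subSeed(spec$seed, paste0("f", i)))
    if (any(!tr)) {
      p <- .predictFamily(foldModels[[i]], X[!tr, , drop = FALSE])
      oof[!tr] <- p
      if (length(unique(y[!tr])) == 2L)
        foldAUC[i] <- aucScore(p[y[!tr] == 1L], p[y[!tr] == 0L])
    }
  }
  finalModel <- .fitFamily(spec$family, X, y, hp,
                           .subSeed(spec$seed, "final"))
  new("FittedLearner", family = spec$family, hyperparameters = hp,
      foldModels = foldModels, finalModel = finalModel,
      rowIndex = as.integer(rows), foldAssign = as.integer(f),
      oofPred = oof, foldAUC = foldAUC,
      cvAUC = mean(foldAUC, na.rm = TRUE), variables = vars,
      gridLog = gridLog, seed = spec$seed)
}

#' Fit a MaxEnt-style presence-background learner
#'
#' Penalized (L1) logistic discrimination of presence against background
#' on expanded features: \code{maxent_lq} uses linear + quadratic terms,
#' \code{maxent_lqh} adds hinge features; the penalty weight is the tuned
#' hyperparameter. The logistic output is a relative occurrence
#' probability in [0, 1]. As the penalty grows the fit degenerates
#' gracefully to the constant presence fraction, so complete separation
#' cannot diverge.
#'
#' @inheritParams tuneLearner
#' @return a \linkS4class{FittedLearner}.
#' @export
fitMaxent <- function(design, spec, folds = 5L, foldAssign = NULL) {
  if (!spec$family %in% .presenceOnlyFamilies())
    stop("fitMaxent requires a maxent_lq or maxent_lqh spec")
  d <- designData(design)
  if (!any(d$role == "presence") || !any(d$role == "background"))
    stop("need at least one presence and one background row")
  tuneLearner(design, spec, folds, foldAssign)
}

#' Fit a presence-absence classifier
#'
#' Trains random forest, gradient-boosted trees, or a single-hidden-layer
#' neural network to output presence probability; deterministic under the
#' spec's seed.
#'
#' @inheritParams tuneLearner
#' @return a \linkS4class{FittedLearner}.
#' @export
fitPresenceAbsence <- function(design, spec, folds = 5L, foldAssign = NULL) {
  if (spec$family %in% .presenceOnlyFamilies())
    stop("fitPresenceAbsence requires random_forest, boosted_trees or neural_net")
  d <- designData(design)
  if (!any(d$role == "presence") || !any(d$role == "absence"))
    stop("need both presence and absence rows")
  tuneLearner(design, spec, folds, foldAssign)
}

#' Predict presence probability from a fitted learner
#'
#' A pure function of the fitted state and the covariates: applies the
#' learner's final model to new covariate rows.
#'
#' @param object a \linkS4class{FittedLearner}.
#' @param newdata matrix or data.frame holding the learner's covariates.
#' @param fold optional fold id; when given, the fold model (trained
#'   without that fold) is used instead of the final model.
#' @return numeric probabilities in [0, 1].
#' @export
predictLearner <- function(object, newdata, fold = NULL) {
  stopifnot(is(object, "FittedLearner"))
  m <- if (is.null(fold)) object@finalModel else object@foldModels[[fold]]
  .predictFamily(m, as.matrix(as.data.frame(newdata)[, object@variables,
                                                     drop = FALSE]))
}
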