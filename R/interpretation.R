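#' @include AllClasses.R learners.R evaluation.R
NULL

## Quick mean CV AUC of one family (first grid point) on a covariate
## roster; the workhorse behind decorrelation and jack-knife scans.
.cvAUCQuick <- function(design, spec, roster, folds = 3L) {
  d <- designData(design)
  rows <- .familyRows(design, spec$family)
  X <- as.matrix(d[rows, roster, drop = FALSE])
  y <- d$label[rows]
  f <- .stratifiedFolds(y, folds, .subSeed(spec$seed, "quickcv"))
  hp <- lapply(spec$grid, `[`, 1L)
  aucs <- vapply(seq_len(folds), function(i) {
    tr <- f != i
    if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L)
      return(NA_real_)
    m <- tryCatch(suppressWarnings(
      .fitFamily(spec$family, X[tr, , drop = FALSE], y[tr], hp,
                 .subSeed(spec$seed, paste0("q", i)))),
      error = function(e) NULL)
    if (is.null(m)) return(NA_real_)
    p <- .predictFamily(m, X[!tr, , drop = FALSE])
    aucScore(p[y[!tr] == 1L], p[y[!tr] == 0L])
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' Pairwise variable decorrelation by model sensitivity
#'
#' Iteratively resolves covariate pairs whose absolute Pearson
#' correlation exceeds \code{rMax} (largest |r| first): for each member
#' of the pair the reference model is refitted without that variable, and
#' the variable whose removal causes the larger CV-AUC drop -- the one
#' the model is more sensitive to -- is kept, the other dropped. Repeats
#' until no pair exceeds the cutoff. Constant variables are removed first
#' with a warning.
#'
#' @param design a \linkS4class{DesignTable}.
#' @param spec reference \code{\link{learnerSpec}} used for the
#'   sensitivity refits (first grid point; default a fast MaxEnt-lq).
#' @param rMax correlation cutoff, default 0.8.
#' @param folds CV folds for the sensitivity AUCs, default 3.
#' @return list with \code{retained} (character roster) and \code{log}
#'   (data.frame of pair decisions).
#' @export
decorrelate <- function(design, spec = learnerSpec("maxent_lq"), rMax = 0.8,
                        folds = 3L) {
  d <- designData(design)
  roster <- design@covariates
  if (length(roster) < 2L) stop("need at least 2 variables to decorrelate")
  X <- as.matrix(d[, roster, drop = FALSE])
  const <- apply(X, 2, function(v) stats::sd(v) == 0 || !is.finite(stats::sd(v)))
  if (any(const)) {
    warning("removing constant variable(s): ",
            paste(roster[const], collapse = ", "))
    roster <- roster[!const]
  }
  log <- data.frame(kept = character(0), dropped = character(0),
                    r = numeric(0), auc_without_kept = numeric(0),
                    auc_without_dropped = numeric(0))
  repeat {
    if (length(roster) < 2L) break
    cm <- stats::cor(X[, roster, drop = FALSE])
    diag(cm) <- 0
    am <- abs(cm)
    if (max(am) <= rMax) break
    ij <- which(am == max(am), arr.ind = TRUE)[1, ]
    v1 <- roster[ij[1]]; v2 <- roster[ij[2]]
    aucWo <- function(v) .cvAUCQuick(design, spec, setdiff(roster, v), folds)
    a1 <- aucWo(v1)  # AUC without v1: low value = v1 is the sensitive one
    a2 <- aucWo(v2)
    if (!is.finite(a1) || !is.finite(a2))
      stop("sensitivity AUC undefined for pair ", v1, "/", v2,
           "; does the design hold the rows the '", spec$family,
           "' family needs?")
    keep <- if (a1 < a2) v1 else if (a2 < a1) v2 else sort(c(v1, v2))[1]
    dropv <- setdiff(c(v1, v2), keep)
    log <- rbind(log, data.frame(
      kept = keep, dropped = dropv, r = cm[ij[1], ij[2]],
      auc_without_kept = if (keep == v1) a1 else a2,
      auc_without_dropped = if (keep == v1) a2 else a1))
    roster <- setdiff(roster, dropv)
  }
  list(retained = roster, log = log)
}

#' Jack-knife variable importance
#'
#' Fits one single-variable model per roster variable and records its
#' mean CV AUC as the variable's importance (displayed x 100). A failed
#' single-variable fit is recorded as AUC 0.5 with a flag.
#'
#' @param design a \linkS4class{DesignTable}.
#' @param spec \code{\link{learnerSpec}} for the single-variable fits
#'   (first grid point).
#' @param folds CV folds, default 3.
#' @return data.frame: \code{variable}, \code{auc}, \code{auc100},
#'   \code{category}, \code{failed}.
#' @export
jackknifeImportance <- function(design, spec = learnerSpec("maxent_lq"),
                                folds = 3L) {
  roster <- design@covariates
  if (!length(roster)) stop("empty covariate roster")
  meta <- design@covariateMeta
  rows <- lapply(roster, function(v) {
    a <- tryCatch(suppressWarnings(.cvAUCQuick(design, spec, v, folds)),
                  error = function(e) NA_real_)
    failed <- !is.finite(a)
    if (failed) a <- 0.5
    data.frame(variable = v, auc = a, auc100 = 100 * a,
               category = meta$category[match(v, meta$name)],
               failed = failed, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## Prediction closure for either a FittedLearner or an EnsembleModel.
.importancePredict <- function(model) {
  if (is(model, "EnsembleModel"))
    function(X) .ensemblePredict(model, X)$prob
  else if (is(model, "FittedLearner"))
    function(X) .predictFamily(model@finalModel, X)
  else stop("model must be a FittedLearner or EnsembleModel")
}

.modelVariables <- function(model)
  if (is(model, "EnsembleModel")) model@variables else model@variables

#' Permutation variable importance as relative contributions
#'
#' Per iteration and variable, one covariate column of the evaluation
#' rows is shuffled and the model's AUC drop is recorded; negative drops
#' are clipped to 0 and the drops are normalized to relative
#' contributions summing to 100\% per iteration, then averaged over the
#' iterations. When every drop is zero a uniform contribution is
#' returned with a warning.
#'
#' @param model a \linkS4class{FittedLearner} or
#'   \linkS4class{EnsembleModel} (final models are used).
#' @param design a \linkS4class{DesignTable}; presence + absence rows are
#'   scored.
#' @param iterations number of shuffles per variable, default 10.
#' @param seed integer seed for the shuffles.
#' @return data.frame: \code{variable}, \code{contribution} (\%),
#'   \code{auc_drop}, \code{category}.
#' @export
permutationImportance <- function(model, design, iterations = 10L,
                                  seed = 1L) {
  stopifnot(iterations >= 1L)
  predFun <- .importancePredict(model)
  vars <- .modelVariables(model)
  d <- designData(design)
  d <- d[d$role %in% c("presence", "absence"), , drop = FALSE]
  if (length(unique(d$label)) < 2L)
    stop("need both presence and absence rows to score permutations")
  X <- as.matrix(d[, vars, drop = FALSE])
  y <- d$label
  p0 <- predFun(X)
  auc0 <- aucScore(p0[y == 1L], p0[y == 0L])
  contrib <- matrix(0, iterations, length(vars),
                    dimnames = list(NULL, vars))
  drops <- matrix(0, iterations, length(vars), dimnames = list(NULL, vars))
  .withSeed(seed, {
    for (it in seq_len(iterations)) {
      for (j in seq_along(vars)) {
        Xp <- X
        Xp[, j] <- sample(Xp[, j])
        p <- predFun(Xp)
        drops[it, j] <- max(0, auc0 - aucScore(p[y == 1L], p[y == 0L]))
      }
      tot <- sum(drops[it, ])
      contrib[it, ] <- if (tot > 0) 100 * drops[it, ] / tot
        else rep(100 / length(vars), length(vars))
    }
  })
  if (all(drops == 0))
    warning("all permutation AUC drops are zero; returning uniform contributions")
  meta <- design@covariateMeta
  data.frame(variable = vars,
             contribution = colMeans(contrib),
             auc_drop = colMeans(drops),
             category = meta$category[match(vars, meta$name)],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Aggregate variable importance to covariate categories
#'
#' Jack-knife AUCs aggregate as the category mean (an AUC is not
#' additive); permutation contributions aggregate as the category sum,
#' renormalized to 100\%.
#'
#' @param imp data.frame from \code{\link{jackknifeImportance}} or
#'   \code{\link{permutationImportance}} (detected by its columns).
#' @return data.frame with one row per category.
#' @export
aggregateByCategory <- function(imp) {
  if (!"category" %in% names(imp)) stop("importance table lacks category tags")
  unk <- setdiff(unique(imp$category), .malnutCategories)
  if (length(unk))
    stop("unknown category tag(s): ", paste(unk, collapse = ", "))
  if ("contribution" %in% names(imp)) {
    agg <- stats::aggregate(contribution ~ category, imp, sum)
    agg$contribution <- 100 * agg$contribution / sum(agg$contribution)
    agg[order(-agg$contribution), , drop = FALSE]
  } else if ("auc" %in% names(imp)) {
    agg <- stats::aggregate(cbind(auc, auc100) ~ category, imp, mean)
    agg[order(-agg$auc), , drop = FALSE]
  } else stop("importance table has neither contribution nor auc columns")
}

#' Cross-city consistency of category importance
#'
#' Pearson correlation of the category-importance vectors for every city
#' pair, and the mean absolute correlation across pairs -- the
#' consistency of spatial malnutrition patterns across cities.
#'
#' @param tables named list (>= 2 cities) of category tables from
#'   \code{\link{aggregateByCategory}}, sharing one category roster.
#' @param value column to correlate (default picks \code{contribution}
#'   or \code{auc}).
#' @return list with \code{mean_abs_r} and \code{pairs} (data.frame).
#' @export
crossCityConsistency <- function(tables, value = NULL) {
  if (length(tables) < 2L) stop("need at least two cities")
  if (is.null(value))
    value <- if ("contribution" %in% names(tables[[1]])) "contribution" else "auc"
  cats <- sort(tables[[1]]$category)
  for (t in tables)
    if (!setequal(t$category, cats))
      stop("cities must share an identical category roster")
  V <- vapply(tables, function(t) t[[value]][match(cats, t$category)],
              numeric(length(cats)))
  cities <- names(tables)
  if (is.null(cities)) cities <- paste0("city", seq_along(tables))
  pairs <- utils::combn(seq_along(tables), 2)
  res <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    if (stats::sd(V[, a]) == 0 || stats::sd(V[, b]) == 0) {
      warning("zero-variance importance vector; skipping pair ",
              cities[a], "-", cities[b])
      return(NULL)
    }
    data.frame(city_a = cities[a], city_b = cities[b],
               r = stats::cor(V[, a], V[, b]))
  })
  tab <- do.call(rbind, res)
  if (is.null(tab) || !nrow(tab)) stop("no valid city pairs")
  list(mean_abs_r = mean(abs(tab$r)), pairs = tab)
}

#' Partial-dependence response curve of one variable
#'
#' For each grid value over the variable's observed range, that variable
#' is set to the value in every evaluation row while all other covariates
#' keep their actual values; predictions are averaged. The construction
#' is repeated with each CV fold's models, giving a mean curve and a
#' min-max band across folds.
#'
#' @param model a \linkS4class{FittedLearner} or
#'   \linkS4class{EnsembleModel}.
#' @param design the \linkS4class{DesignTable} providing evaluation rows
#'   (presence + absence).
#' @param variable covariate name.
#' @param nGrid evaluation grid size, default 100.
#' @return data.frame: \code{value}, \code{mean}, \code{lo}, \code{hi}.
#' @export
responseCurve <- function(model, design, variable, nGrid = 100L) {
  vars <- .modelVariables(model)
  if (!variable %in% vars) stop("'", variable, "' is not in the model roster")
  d <- designData(design)
  rows <- if (is(model, "FittedLearner")) .familyRows(design, model@family)
  else which(d$role %in% c("presence", "absence"))
  d <- d[rows, , drop = FALSE]
  X <- as.matrix(d[, vars, drop = FALSE])
  rng <- range(X[, variable])
  if (diff(rng) == 0) stop("'", variable, "' has zero range")
  grid <- seq(rng[1], rng[2], length.out = nGrid)
  nf <- if (is(model, "EnsembleModel"))
    length(model@metaFoldModels) else length(model@foldModels)
  predAt <- function(fold, v) {
    Xi <- X
    Xi[, variable] <- v
    p <- if (is(model, "EnsembleModel"))
      .ensemblePredict(model, Xi, fold = fold)$prob
    else .predictFamily(model@foldModels[[fold]], Xi)
    mean(p)
  }
  curves <- vapply(seq_len(nf), function(f)
    vapply(grid, function(v) predAt(f, v), numeric(1)), numeric(nGrid))
  if (!is.matrix(curves)) curves <- matrix(curves, nrow = nGrid)
  data.frame(value = grid,
             mean = rowMeans(curves),
             lo = apply(curves, 1, min),
             hi = apply(curves, 1, max))
}
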