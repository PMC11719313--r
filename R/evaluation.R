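#' @include AllClasses.R utils.R
NULL

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a randomly chosen
#' positive outscores a randomly chosen negative, with ties counted one
#' half. Equivalent to trapezoidal integration of the ROC curve over all
#' score thresholds.
#'
#' @param scoresPos scores of the positive class (non-empty).
#' @param scoresNeg scores of the negative class (non-empty).
#' @return AUC in [0, 1].
#' @examples
#' aucScore(c(0.9, 0.8), c(0.1, 0.2))  # 1
#' aucScore(c(0.8, 0.4), c(0.6, 0.2))  # 0.75
#' @export
aucScore <- function(scoresPos, scoresNeg) {
  if (!length(scoresPos) || !length(scoresNeg))
    stop("AUC undefined: both classes must be non-empty")
  if (any(is.na(scoresPos)) || any(is.na(scoresNeg)))
    stop("AUC undefined for missing scores")
  np <- as.numeric(length(scoresPos)); nn <- as.numeric(length(scoresNeg))
  r <- rank(c(scoresPos, scoresNeg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' True Skill Statistic
#'
#' TSS = sensitivity - false positive rate
#' = TP/(TP+FN) - FP/(FP+TN), in [-1, 1].
#'
#' @param tp,fn,fp,tn confusion-matrix counts; both actual margins
#'   (TP+FN, FP+TN) and both predicted margins (TP+FP, FN+TN) must be
#'   positive.
#' @return TSS value.
#' @examples
#' tssScore(8, 2, 3, 7)  # 0.5
#' @export
tssScore <- function(tp, fn, fp, tn) {
  if (any(c(tp, fn, fp, tn) < 0)) stop("counts must be >= 0")
  if (tp + fn <= 0) stop("TSS undefined: no actual positives (TP+FN = 0)")
  if (fp + tn <= 0) stop("TSS undefined: no actual negatives (FP+TN = 0)")
  if (fn + tn <= 0) stop("TSS undefined: empty predicted-negative margin")
  if (tp + fp <= 0) stop("TSS undefined: empty predicted-positive margin")
  tp / (tp + fn) - fp / (fp + tn)
}

#' Threshold-maximized TSS of continuous scores
#'
#' Scans every candidate dichotomization threshold (the observed scores;
#' prediction positive when score >= threshold) and returns the maximum
#' TSS and its threshold.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels, both classes present.
#' @return list with \code{tss} and \code{threshold}.
#' @export
maxTSS <- function(scores, labels) {
  labels <- as.integer(labels)
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L)
    stop("TSS undefined: both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  ## walking the sorted scores: predicted positive = scores >= s[i]
  tp <- cumsum(y); fp <- cumsum(1L - y)
  ## collapse ties: evaluate at the last occurrence of each distinct score
  last <- !duplicated(s, fromLast = TRUE)
  sens <- tp[last] / npos
  fpr <- fp[last] / nneg
  tss <- sens - fpr
  i <- which.max(tss)
  list(tss = tss[i], threshold = s[last][i])
}

## Stratified k-fold assignment on 0/1 labels; every fold keeps both
## classes when feasible.
.stratifiedFolds <- function(labels, k, seed) {
  .withSeed(seed, {
    f <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      f[idx] <- rep_len(seq_len(k), length(idx))
    }
    f
  })
}

#' Random k-fold cross-validation of a model-fitting closure
#'
#' Randomly partitions the design rows into k folds (stratified on the
#' presence label so each fold retains both classes, re-splitting within
#' a retry budget otherwise); per fold, fits on the remaining rows and
#' scores the held-out fold; reports held-out AUC and threshold-maximized
#' TSS (threshold chosen on the held-out fold), plus their fold means.
#'
#' @param fitFun closure \code{function(trainData, covariates)} returning
#'   a prediction function \code{function(newX) -> probabilities}.
#' @param design a \linkS4class{DesignTable}.
#' @param k number of folds (>= 2; up to leave-one-out).
#' @param seed integer seed for the partition.
#' @param roles which design roles to use (default presence + absence).
#' @param retries resplit budget for degenerate folds.
#' @return a \linkS4class{MetricReport}.
#' @export
crossValidate <- function(fitFun, design, k = 5L, seed = 1L,
                          roles = c("presence", "absence"), retries = 20L) {
  stopifnot(k >= 2L)
  d <- designData(design)
  d <- d[d$role %in% roles, , drop = FALSE]
  vars <- design@covariates
  y <- d$label
  if (length(unique(y)) < 2L) stop("design must contain both classes")
  folds <- NULL
  for (r in seq_len(retries)) {
    ## stratified split first; fall back to plain random partitions when
    ## k approaches the row count (e.g. leave-one-out)
    f <- if (r == 1L) .stratifiedFolds(y, k, .subSeed(seed, "cv1"))
    else .withSeed(.subSeed(seed, paste0("cv", r)),
                   sample(rep_len(seq_len(k), length(y))))
    ok <- all(vapply(seq_len(k), function(i) {
      tr <- y[f != i]
      length(unique(tr)) == 2L && sum(f == i) > 0L
    }, logical(1)))
    if (ok) { folds <- f; break }
  }
  if (is.null(folds))
    stop("could not build ", k, " folds with both classes in ", retries,
         " attempts")
  oof <- rep(NA_real_, nrow(d))
  res <- lapply(seq_len(k), function(i) {
    tr <- d[folds != i, , drop = FALSE]
    te <- d[folds == i, , drop = FALSE]
    pred <- fitFun(tr, vars)
    p <- pred(as.matrix(te[, vars, drop = FALSE]))
    oof[folds == i] <<- p
    a <- if (length(unique(te$label)) == 2L)
      aucScore(p[te$label == 1L], p[te$label == 0L]) else NA_real_
    mt <- if (length(unique(te$label)) == 2L) maxTSS(p, te$label)
      else list(tss = NA_real_, threshold = NA_real_)
    data.frame(fold = i, auc = a, tss = mt$tss, threshold = mt$threshold)
  })
  tab <- do.call(rbind, res)
  if (anyNA(tab$auc))
    warning(sum(is.na(tab$auc)), " fold(s) held a single class; ",
            "fold-wise metrics exclude them")
  meanAUC <- mean(tab$auc, na.rm = TRUE)
  meanTSS <- mean(tab$tss, na.rm = TRUE)
  if (!is.finite(meanAUC)) {
    ## every fold degenerate (single-row folds): pool the out-of-fold
    ## predictions instead
    meanAUC <- aucScore(oof[y == 1L], oof[y == 0L])
    meanTSS <- maxTSS(oof, y)$tss
  }
  new("MetricReport", folds = tab, meanAUC = meanAUC, meanTSS = meanTSS)
}
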