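# Evaluation protocol: macro-F1, repeated stratified k-fold CV with
# per-fold seeded hyperparameter search, corrected paired t-tests and
# class-wise variable importance.

#' Macro-averaged F1 score
#'
#' The default ("macro") is the unweighted mean of the per-class F1
#' scores, the de-facto standard; a class absent from the predictions
#' scores F1 = 0 when precision + recall = 0 (no exclusion). The
#' alternative "harmonic" form -- the harmonic mean of the averaged
#' precision and averaged recall -- is available behind a flag; the two
#' differ on asymmetric errors.
#'
#' @param yTrue,yPred vectors of true and predicted labels (equal
#'   length); predicted labels must come from the universe of
#'   \code{labels}.
#' @param labels optional label universe (defaults to the union of
#'   levels of \code{yTrue} and \code{yPred}).
#' @param average "macro" (default) or "harmonic".
#' @return a score in [0, 1].
#' @examples
#' macroF1(c("A", "A", "B", "B"), c("A", "B", "B", "B"))  # 0.7333...
#' @export
macroF1 <- function(yTrue, yPred, labels = NULL,
                    average = c("macro", "harmonic")) {
  average <- match.arg(average)
  if (length(yTrue) == 0) stop("empty input", call. = FALSE)
  if (length(yTrue) != length(yPred))
    stop("'yTrue' and 'yPred' must have the same length", call. = FALSE)
  if (is.null(labels))
    labels <- union(levels(as.factor(yTrue)), levels(as.factor(yPred)))
  rep <- .classReport(yTrue, yPred, labels)
  if (average == "macro") mean(rep$f1)
  else {
    mp <- mean(rep$precision); mr <- mean(rep$recall)
    if (mp + mr == 0) 0 else 2 * mp * mr / (mp + mr)
  }
}

# Per-class precision/recall/F1 (0 where the denominator vanishes).
.classReport <- function(yTrue, yPred, labels) {
  yTrue <- as.character(yTrue); yPred <- as.character(yPred)
  out <- lapply(labels, function(cl) {
    tp <- sum(yPred == cl & yTrue == cl)
    fp <- sum(yPred == cl & yTrue != cl)
    fn <- sum(yPred != cl & yTrue == cl)
    pr <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rc <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (pr + rc == 0) 0 else 2 * pr * rc / (pr + rc)
    data.frame(class = cl, precision = pr, recall = rc, f1 = f1)
  })
  do.call(rbind, out)
}

#' Build a cross-validation configuration
#'
#' Defaults follow the studied protocol: stratified 10-fold CV repeated
#' 10 times; per fold, 60 hyperparameter-search trials each scored as the
#' mean macro-F1 over 10 independently drawn stratified validation splits
#' of 10% size.
#'
#' @param k folds.
#' @param repetitions repetitions of the entire CV procedure.
#' @param nTrials hyperparameter-search trials per fold.
#' @param nValidationSets validation splits per trial.
#' @param validationFraction validation split size as a fraction.
#' @param seed master seed; every random stage derives from it.
#' @return a [CVConfig-class].
#' @export
cvConfig <- function(k = 10L, repetitions = 10L, nTrials = 60L,
                     nValidationSets = 10L, validationFraction = 0.1,
                     seed = 1L) {
  new("CVConfig", k = as.integer(k), repetitions = as.integer(repetitions),
      nTrials = as.integer(nTrials),
      nValidationSets = as.integer(nValidationSets),
      validationFraction = as.numeric(validationFraction),
      seed = as.integer(seed))
}

#' Stratified fold assignment
#'
#' Random fold labels in 1..k constructed per class (shuffle, then deal
#' round-robin with rotating offsets), so every fold approximately
#' preserves the class frequencies (within one sample per class).
#'
#' @param labels factor of class labels.
#' @param k number of folds; every class must have at least k samples.
#' @param seed integer seed, or NULL to consume the current RNG stream.
#' @return integer vector of fold assignments, one per sample.
#' @export
stratifiedFolds <- function(labels, k, seed = NULL) {
  labels <- droplevels(as.factor(labels))
  k <- .assertScalarCount(k, "k")
  small <- table(labels) < k
  if (any(small))
    stop(sprintf(paste0("class '%s' has fewer than k = %d samples; ",
                        "use a smaller k (at most %d)"),
                 names(which(small))[1], k, min(table(labels))), call. = FALSE)
  run <- function() {
    fold <- integer(length(labels))
    offset <- 0L
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      offset <- (offset + length(idx)) %% k
    }
    fold
  }
  if (is.null(seed)) run() else .withSeed(seed, run())
}

# Stratified validation split: per class, max(1, round(frac * n)) samples.
.validationSplit <- function(labels, idx, fraction) {
  unlist(lapply(levels(droplevels(labels[idx])), function(cl) {
    own <- idx[labels[idx] == cl]
    sample(own, max(1L, round(fraction * length(own))))
  }), use.names = FALSE)
}

# -- estimator specifications ------------------------------------------------

#' Estimator specifications for the evaluation harness
#'
#' All classifiers share one estimator interface so they are
#' interchangeable in [repeatedStratifiedCV()] and the CLI.
#' \code{acfEstimator} wraps ACF and its variants (reference subsampling,
#' bias masking, covariate use); \code{knnEstimator} the brute
#' correlation KNN (optionally with random oversampling of the training
#' part of each fold); \code{dbcEstimator} the parameter-free DBC (or
#' F-DBC with \code{nRef}). When \code{params} is NULL for an estimator
#' with tunable hyperparameters, they are tuned per fold over
#' [defaultSearchSpace()].
#'
#' @param baseline baseline classifier name: "svc", "rf" or "ridge".
#' @param params fixed hyperparameters (named list), or NULL to tune.
#' @param nRef reference instances per class (F-ACF / F-DBC), or NULL.
#' @param useCovariate include the dataset covariates as extra features.
#' @param dropColumns feature-table columns to withhold from the baseline
#'   classifier (used by [classwiseImportance()]).
#' @param oversample randomly oversample minority classes to the majority
#'   count within each training fold.
#' @param bins histogram bins for DBC.
#' @return an estimator specification (list with class
#'   \code{"corrACFEstimator"}).
#' @name estimators
NULL

#' @rdname estimators
#' @export
acfEstimator <- function(baseline = "svc", params = NULL, nRef = NULL,
                         useCovariate = FALSE, dropColumns = character(0)) {
  structure(list(type = "acf", baseline = baseline, params = params,
                 nRef = nRef, useCovariate = useCovariate,
                 dropColumns = dropColumns,
                 label = paste0("ACF-", baseline,
                                if (!is.null(nRef)) sprintf(" (F-ACF n=%d)", nRef) else "",
                                if (useCovariate) " +covariate" else "")),
            class = "corrACFEstimator")
}

#' @rdname estimators
#' @export
knnEstimator <- function(params = NULL, oversample = FALSE) {
  structure(list(type = "knn", params = params, oversample = oversample,
                 label = if (oversample) "KNN+ROs" else "KNN"),
            class = "corrACFEstimator")
}

#' @rdname estimators
#' @export
dbcEstimator <- function(nRef = NULL, bins = 20L) {
  structure(list(type = "dbc", params = list(), nRef = nRef,
                 bins = as.integer(bins),
                 label = if (is.null(nRef)) "DBC" else
                   sprintf("F-DBC (n=%d)", nRef)),
            class = "corrACFEstimator")
}

#' Hyperparameter search space of an estimator
#'
#' The tuned parameters and their bounds: SVC kernel (linear/rbf), C in
#' [5e-3, 5e2] (log-uniform), rbf coefficient (scale/auto) and class
#' weights (balanced/none); random forest trees 80-300, depth 2-40,
#' feature count over the full interval and class weights; ridge
#' regularization in [1e-3, 1e4] (log-uniform) and class weights; KNN
#' K in [1, nTrain] and weights (uniform/distance).
#'
#' @param estimator an estimator specification.
#' @param nTrain training-set size (bounds K for KNN).
#' @param nFeatureColumns number of feature-table columns (bounds mtry).
#' @return list of parameter descriptors.
#' @export
defaultSearchSpace <- function(estimator, nTrain, nFeatureColumns = 3L) {
  if (estimator$type == "dbc") return(list())
  if (estimator$type == "knn")
    return(list(
      list(name = "K", type = "int", lo = 1L, hi = as.integer(nTrain)),
      list(name = "weights", type = "choice",
           values = c("uniform", "distance"))))
  base <- if (is.character(estimator$baseline)) estimator$baseline
          else estimator$baseline$name
  switch(base,
    svc = list(
      list(name = "kernel", type = "choice", values = c("linear", "rbf")),
      list(name = "C", type = "loguniform", lo = 5e-3, hi = 5e2),
      list(name = "gamma", type = "choice", values = c("scale", "auto")),
      list(name = "classWeights", type = "choice",
           values = c("balanced", "none"))),
    rf = list(
      list(name = "numTrees", type = "int", lo = 80L, hi = 300L),
      list(name = "maxDepth", type = "int", lo = 2L, hi = 40L),
      list(name = "mtry", type = "int", lo = 1L,
           hi = as.integer(nFeatureColumns)),
      list(name = "classWeights", type = "choice",
           values = c("balanced", "none"))),
    ridge = list(
      list(name = "alpha", type = "loguniform", lo = 1e-3, hi = 1e4),
      list(name = "classWeights", type = "choice",
           values = c("balanced", "none"))))
}

.sampleSpace <- function(space) {
  pick <- function(vals) vals[sample.int(length(vals), 1L)]
  out <- lapply(space, function(par) switch(par$type,
    choice     = pick(par$values),
    int        = pick(seq.int(par$lo, par$hi)),
    loguniform = exp(stats::runif(1, log(par$lo), log(par$hi))),
    uniform    = stats::runif(1, par$lo, par$hi)))
  stats::setNames(out, vapply(space, `[[`, "", "name"))
}

# -- CV engine ---------------------------------------------------------------

# Evaluation context: the full square correlation matrix (entries with NA
# where undefined), labels and optional covariates. Pairwise correlations
# do not depend on fold membership, so precomputing the full matrix and
# subsetting per fold is exact and leak-free.
.makeContext <- function(X, labels = NULL, covariates = NULL,
                         method = "pearson", minOverlap = 3L,
                         corMatrix = NULL) {
  if (is(X, "SimulatedDataset")) {
    if (is.null(labels)) labels <- X@labels
    if (is.null(covariates) && !is.null(X@covariate))
      covariates <- data.frame(covariate = X@covariate)
    X <- X@data
  }
  if (is.null(labels)) stop("labels are required", call. = FALSE)
  labels <- droplevels(as.factor(labels))
  if (is.null(corMatrix))
    corMatrix <- trainCorrelationMatrix(X, method = method,
                                        minOverlap = minOverlap)
  entries <- if (is(corMatrix, "CorrelationMatrix")) corMatrix@entries
             else as.matrix(corMatrix)
  if (length(labels) != nrow(entries))
    stop("labels do not match the correlation matrix", call. = FALSE)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(labels))
      stop("covariate rows do not match the samples", call. = FALSE)
  }
  list(R = entries, labels = labels, covariates = covariates)
}

# ACF feature table from the context: rows x (classes + covariates).
.ctxFeatures <- function(ctx, rowsIdx, colsIdx, excludeSelf, useCovariate,
                         dropColumns = character(0)) {
  sub <- ctx$R[rowsIdx, colsIdx, drop = FALSE]
  selfCol <- if (excludeSelf) match(rowsIdx, colsIdx) else NULL
  feats <- .classAverages(sub, droplevels(ctx$labels[colsIdx]), selfCol)
  df <- as.data.frame(feats)
  rownames(df) <- as.character(rowsIdx)
  if (useCovariate && !is.null(ctx$covariates))
    df <- cbind(df, ctx$covariates[rowsIdx, , drop = FALSE])
  if (length(dropColumns)) df <- df[, setdiff(colnames(df), dropColumns),
                                    drop = FALSE]
  df
}

# Fit on trainIdx and predict predictIdx (disjoint from trainIdx), under
# given hyperparameters. Consumes the current RNG stream.
.foldFitPredict <- function(est, ctx, trainIdx, predictIdx, params) {
  lev <- levels(ctx$labels)
  trainLab <- droplevels(ctx$labels[trainIdx])
  if (est$type == "acf") {
    baseline <- .normalizeBaseline(
      if (is.null(params)) est$baseline
      else list(name = if (is.character(est$baseline)) est$baseline
                       else est$baseline$name,
                params = params))
    colsIdx <- trainIdx
    if (!is.null(est$nRef)) {
      refs <- selectReferences(trainLab, est$nRef,
                               seed = sample.int(.Machine$integer.max, 1))
      colsIdx <- trainIdx[sort(unlist(refs, use.names = FALSE))]
    }
    ftr <- .ctxFeatures(ctx, trainIdx, colsIdx, TRUE, est$useCovariate,
                        est$dropColumns)
    fte <- .ctxFeatures(ctx, predictIdx, colsIdx, FALSE, est$useCovariate,
                        est$dropColumns)
    fit <- .fitBaseline(baseline, ftr, trainLab,
                        seed = sample.int(.Machine$integer.max, 1))
    pred <- .predictBaseline(baseline, fit, fte)
    return(factor(as.character(pred), levels = lev))
  }
  if (est$type == "knn") {
    cols <- trainIdx
    if (isTRUE(est$oversample))
      cols <- randomOversample(trainLab, indices = trainIdx,
                               seed = sample.int(.Machine$integer.max, 1))
    K <- min(as.integer(params$K), length(cols))
    pred <- knnPredict(ctx$R[predictIdx, cols, drop = FALSE],
                       ctx$labels[cols], K = K,
                       weights = if (is.null(params$weights)) "uniform"
                                 else params$weights)
    return(factor(as.character(pred), levels = lev))
  }
  if (est$type == "dbc") {
    dist <- estimateClassDistributions(
      ctx$R[trainIdx, trainIdx, drop = FALSE], trainLab,
      nRef = est$nRef, bins = est$bins,
      seed = sample.int(.Machine$integer.max, 1))
    refCols <- trainIdx[.dbcReferenceColumns(dist)]
    pred <- dbcPredict(ctx$R[predictIdx, refCols, drop = FALSE],
                       ctx$labels[refCols], dist)
    return(factor(as.character(pred), levels = lev))
  }
  stop("unknown estimator type", call. = FALSE)
}

.needsTuning <- function(est) {
  est$type %in% c("acf", "knn") && is.null(est$params)
}

# Random-search HPO on trainIdx: each trial is scored as the mean
# macro-F1 over freshly drawn stratified validation splits. Failed trials
# score -Inf and the search continues. Returns best params + trial log.
.hpoSearch <- function(est, ctx, trainIdx, nTrials, nValidationSets,
                       validationFraction, space = NULL) {
  lev <- levels(ctx$labels)
  # K ranges over [1, n_Train] with n_Train the number of training
  # instances; oversampling duplicates indices but adds no instances
  if (is.null(space))
    space <- defaultSearchSpace(est, nTrain = length(trainIdx),
                                nFeatureColumns = nlevels(ctx$labels) +
                                  if (isTRUE(est$useCovariate) &&
                                      !is.null(ctx$covariates))
                                    ncol(ctx$covariates) else 0L)
  best <- NULL; bestScore <- -Inf
  log <- vector("list", nTrials)
  for (t in seq_len(nTrials)) {
    params <- .sampleSpace(space)
    score <- tryCatch({
      vals <- vapply(seq_len(nValidationSets), function(v) {
        val <- .validationSplit(ctx$labels, trainIdx, validationFraction)
        sub <- setdiff(trainIdx, val)
        pred <- .foldFitPredict(est, ctx, sub, val, params)
        macroF1(ctx$labels[val], pred, labels = lev)
      }, numeric(1))
      mean(vals)
    }, error = function(e) -Inf)
    log[[t]] <- list(trial = t, score = score, params = params)
    if (score > bestScore) { bestScore <- score; best <- params }
  }
  if (is.null(best))
    stop("hyperparameter search failed for every trial", call. = FALSE)
  list(best = best, score = bestScore, trials = log)
}

#' Tune an estimator's hyperparameters
#'
#' Seeded random search over [defaultSearchSpace()]: each candidate is
#' scored as the mean macro-F1 over independently drawn stratified
#' validation splits (the classifier is retrained on the remainder for
#' each split); the argmax is returned together with the full trial log.
#' A candidate whose fit fails is scored as failed (worst) and the search
#' continues.
#'
#' @param estimator an estimator specification (see [estimators]).
#' @param X an [OmicsMatrix-class], matrix or [SimulatedDataset-class].
#' @param labels class labels (taken from \code{X} if a SimulatedDataset).
#' @param covariates optional covariate data.frame.
#' @param nTrials,nValidationSets,validationFraction search protocol.
#' @param seed integer seed; identical seeds give identical trial
#'   sequences and winners.
#' @param method,minOverlap correlation options.
#' @param corMatrix optional precomputed square [CorrelationMatrix-class].
#' @param space search space (list of parameter descriptors as in
#'   [defaultSearchSpace()]); defaults to the estimator's standard space.
#' @return list with \code{best} (named parameter list), \code{score} and
#'   \code{trials}.
#' @export
tuneHyperparameters <- function(estimator, X, labels = NULL,
                                covariates = NULL, nTrials = 60L,
                                nValidationSets = 10L,
                                validationFraction = 0.1, seed = 1L,
                                method = "pearson", minOverlap = 3L,
                                corMatrix = NULL, space = NULL) {
  ctx <- .makeContext(X, labels, covariates, method, minOverlap, corMatrix)
  .withSeed(seed,
    .hpoSearch(estimator, ctx, seq_along(ctx$labels), nTrials,
               nValidationSets, validationFraction, space = space))
}

#' Repeated stratified cross-validation with per-fold tuning
#'
#' The measurement protocol: stratified k-fold CV; within every fold,
#' hyperparameters are tuned on the k-1 training sets only (validation
#' splits drawn from them; the held-out fold never touches the search),
#' the best configuration is retrained on the full k-1 sets and scored on
#' the held-out fold with macro-F1. The entire procedure is repeated
#' \code{repetitions} times with re-randomized folds, yielding k x
#' repetitions scores. Estimators with fixed \code{params} (and the
#' parameter-free DBC) skip the search.
#'
#' @param X an [OmicsMatrix-class], matrix or [SimulatedDataset-class].
#' @param estimator an estimator specification (see [estimators]).
#' @param labels class labels (taken from \code{X} if a SimulatedDataset).
#' @param covariates optional covariate data.frame (taken from a
#'   SimulatedDataset's covariate if present).
#' @param config a [CVConfig-class].
#' @param method,minOverlap correlation options.
#' @param corMatrix optional precomputed square [CorrelationMatrix-class]
#'   of all samples (pairwise correlations are fold-independent, so
#'   precomputing is exact and leak-free).
#' @param audit record per-fold index bookkeeping for the leakage audit.
#' @return a [CVResult-class].
#' @export
repeatedStratifiedCV <- function(X, estimator, labels = NULL,
                                 covariates = NULL, config = cvConfig(),
                                 method = "pearson", minOverlap = 3L,
                                 corMatrix = NULL, audit = FALSE) {
  stopifnot(inherits(estimator, "corrACFEstimator"))
  ctx <- .makeContext(X, labels, covariates, method, minOverlap, corMatrix)
  n <- length(ctx$labels)
  lev <- levels(ctx$labels)
  repSeeds <- .deriveSeeds(config@seed, config@repetitions)
  scoreRows <- list(); classRows <- list(); auditLog <- list()
  for (r in seq_len(config@repetitions)) {
    .withSeed(repSeeds[r], {
      folds <- stratifiedFolds(ctx$labels, config@k)
      for (fd in seq_len(config@k)) {
        testIdx <- which(folds == fd)
        trainIdx <- which(folds != fd)
        params <- estimator$params
        hpoScore <- NA_real_
        if (.needsTuning(estimator)) {
          tuned <- .hpoSearch(estimator, ctx, trainIdx, config@nTrials,
                              config@nValidationSets,
                              config@validationFraction)
          params <- tuned$best
          hpoScore <- tuned$score
        }
        pred <- .foldFitPredict(estimator, ctx, trainIdx, testIdx, params)
        sc <- macroF1(ctx$labels[testIdx], pred, labels = lev)
        row <- data.frame(rep = r, fold = fd, macroF1 = sc,
                          nTrain = length(trainIdx),
                          nTest = length(testIdx), hpoScore = hpoScore)
        row$params <- I(list(params))
        scoreRows[[length(scoreRows) + 1L]] <- row
        cr <- .classReport(ctx$labels[testIdx], pred, lev)
        cr$rep <- r; cr$fold <- fd
        classRows[[length(classRows) + 1L]] <- cr
        if (audit)
          auditLog[[length(auditLog) + 1L]] <- list(
            rep = r, fold = fd, testIdx = testIdx, hpoIdx = trainIdx)
      }
    })
  }
  new("CVResult", scores = do.call(rbind, scoreRows),
      perClass = do.call(rbind, classRows),
      estimator = estimator$label, config = config, audit = auditLog)
}

#' Per-repetition mean scores of a CVResult
#'
#' @param x a [CVResult-class].
#' @return numeric vector: mean macro-F1 per repetition (folds averaged).
#' @export
setGeneric("repMeans", function(x) standardGeneric("repMeans"))

#' @rdname repMeans
#' @export
setMethod("repMeans", "CVResult", function(x)
  as.numeric(tapply(x@scores$macroF1, x@scores$rep, mean)))

setMethod("show", "CVResult", function(object) {
  rm <- repMeans(object)
  cat(sprintf("CVResult [%s]: %d x %d-fold CV\n", object@estimator,
              object@config@repetitions, object@config@k))
  cat(sprintf("  mean macro-F1 = %.3f (SD over repetitions = %.3f)\n",
              mean(rm), if (length(rm) > 1) stats::sd(rm) else NA_real_))
})

#' Corrected right-tailed paired t-test for CV score comparison
#'
#' Paired comparison of per-split scores from the same CV splits, with
#' the resampled-t variance correction: the variance of the score
#' differences is inflated by (1/n + nTest/nTrain), compensating the
#' dependence among overlapping training sets. Right-tailed: the
#' alternative is mean(scoresA) > mean(scoresB). The p-value is
#' multiplied by \code{nComparisons} (Bonferroni) and capped at 1. A zero
#' variance with zero mean difference returns p = 1 by convention.
#'
#' @param scoresA,scoresB equal-length paired score vectors.
#' @param nTrain,nTest the training/test sizes of the folds (the actual
#'   fold sizes; about n/10 test per fold for 10-fold).
#' @param nComparisons Bonferroni multiplier.
#' @return list: statistic, df, p (one-sided), pAdjusted.
#' @export
correctedPairedTTest <- function(scoresA, scoresB, nTrain, nTest,
                                 nComparisons = 1L) {
  if (length(scoresA) != length(scoresB))
    stop("paired score vectors must have equal length", call. = FALSE)
  d <- scoresA - scoresB
  n <- length(d)
  if (n < 2) stop("at least 2 paired scores are required", call. = FALSE)
  vd <- stats::var(d)
  md <- mean(d)
  if (vd == 0) {
    p <- if (md > 0) 0 else 1
    return(list(statistic = if (md == 0) 0 else sign(md) * Inf,
                df = n - 1, p = if (md == 0) 1 else p,
                pAdjusted = min(1, (if (md == 0) 1 else p) * nComparisons)))
  }
  tstat <- md / sqrt(vd * (1 / n + nTest / nTrain))
  p <- stats::pt(tstat, df = n - 1, lower.tail = FALSE)
  list(statistic = tstat, df = n - 1, p = p,
       pAdjusted = min(1, p * nComparisons))
}

#' Class-wise variable importance of the ACF feature columns
#'
#' Importance of each average-correlation (or covariate) column for the
#' prediction of each class: the decrease of the mean per-class F1 score
#' under repeated stratified CV when the column is withheld from the
#' baseline classifier, relative to the full feature table. Positive
#' importance of another class's average-correlation column is the
#' signature of a discriminative cross-correlation.
#'
#' @param X an [OmicsMatrix-class], matrix or [SimulatedDataset-class].
#' @param labels class labels.
#' @param covariates optional covariate data.frame.
#' @param baseline fixed-parameter baseline classifier; defaults to the
#'   reference configuration (SVC, C = 100, rbf kernel, balanced class
#'   weights).
#' @param config a [CVConfig-class] (hyperparameters are fixed, so
#'   nTrials is ignored).
#' @param useCovariate include covariates among the rated columns.
#' @param method,minOverlap,corMatrix correlation options.
#' @return numeric matrix classes x feature columns of F1 decreases.
#' @export
classwiseImportance <- function(X, labels = NULL, covariates = NULL,
                                baseline = list(name = "svc",
                                  params = list(C = 100, kernel = "rbf",
                                                classWeights = "balanced")),
                                config = cvConfig(repetitions = 3L),
                                useCovariate = !is.null(covariates),
                                method = "pearson", minOverlap = 3L,
                                corMatrix = NULL) {
  ctx <- .makeContext(X, labels, covariates, method, minOverlap, corMatrix)
  if (is(X, "SimulatedDataset") && is.null(covariates) &&
      !is.null(ctx$covariates) && missing(useCovariate))
    useCovariate <- TRUE
  baseline <- .normalizeBaseline(baseline)
  cols <- paste0("mu_", levels(ctx$labels))
  if (useCovariate && !is.null(ctx$covariates))
    cols <- c(cols, colnames(ctx$covariates))
  if (length(cols) < 2)
    stop("the feature table needs >= 2 columns", call. = FALSE)
  runCV <- function(drop) {
    est <- acfEstimator(baseline = baseline, params = baseline$params,
                        useCovariate = useCovariate, dropColumns = drop)
    res <- repeatedStratifiedCV(X, est, labels = labels,
                                covariates = covariates, config = config,
                                method = method, minOverlap = minOverlap,
                                corMatrix = corMatrix)
    tapply(res@perClass$f1, res@perClass$class, mean)
  }
  full <- runCV(character(0))
  out <- sapply(cols, function(cl) full[levels(ctx$labels)] -
                  runCV(cl)[levels(ctx$labels)])
  rownames(out) <- levels(ctx$labels)
  out
}
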