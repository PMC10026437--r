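# ACF: average correlations as features, with F-ACF (reference
# subsampling) and B-ACF (bias masking) variants.

# Core averaging over a correlation submatrix. `entries` has NA where
# undefined; `mask` marks additional entries to omit (TRUE = biased).
# `selfCol` maps each row to its own column index (NA = no self column).
# Returns the samples x classes matrix of mean correlations; errors on
# any empty contributing set, naming sample and class.
.classAverages <- function(entries, colLabels, selfCol = NULL, mask = NULL,
                           statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  if (!is.null(mask)) entries[mask] <- NA_real_
  if (!is.null(selfCol)) {
    has <- which(!is.na(selfCol))
    entries[cbind(has, selfCol[has])] <- NA_real_
  }
  classes <- levels(colLabels)
  out <- matrix(NA_real_, nrow(entries), length(classes),
                dimnames = list(rownames(entries), paste0("mu_", classes)))
  for (k in seq_along(classes)) {
    sub <- entries[, colLabels == classes[k], drop = FALSE]
    cnt <- rowSums(!is.na(sub))
    if (any(cnt == 0)) {
      bad <- which(cnt == 0)[1]
      id <- rownames(entries)[bad]
      stop(sprintf(paste0("no defined, unmasked correlation available to average ",
                          "for sample '%s' and class '%s'"),
                   if (is.null(id)) as.character(bad) else id, classes[k]),
           call. = FALSE)
    }
    out[, k] <- if (statistic == "mean") rowMeans(sub, na.rm = TRUE)
                else apply(sub, 1, stats::median, na.rm = TRUE)
  }
  out
}

#' Class-wise average correlations
#'
#' Step 1/3 of the ACF procedure: for every target sample (row of
#' \code{C}), the average of its defined, unmasked correlations to the
#' training members of each class. Self-correlations never contribute
#' (they carry no information and would bias the class mean), undefined
#' correlations are skipped rather than zero-filled, and a cell whose
#' contributing set is empty is a hard error naming sample and class.
#'
#' @param C a [CorrelationMatrix-class]; rows = target samples, columns =
#'   training samples.
#' @param labels class label per training sample (column).
#' @param excludeSelf if TRUE, a row's correlation to the training column
#'   with the same sample id is excluded (use for training features).
#' @param mask optional logical matrix aligned to \code{C}; \code{TRUE}
#'   entries are biased and omitted from the averaging (B-ACF).
#' @param covariates optional data.frame of covariates (one row per target
#'   sample), appended unchanged after the average-correlation columns.
#' @param statistic aggregation statistic; the default "mean" is the
#'   studied configuration, "median" is available but untested against
#'   the reference behaviour.
#' @return a [ClasswiseFeatureTable-class].
#' @examples
#' C <- matrix(c(1, .8, .2, .4, .8, 1, .3, .1,
#'               .2, .3, 1, .6, .4, .1, .6, 1), 4, 4,
#'             dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
#' cm <- new("CorrelationMatrix", entries = C, defined = !is.na(C),
#'           method = "pearson", minOverlap = 3L)
#' classwiseAverages(cm, factor(c("A", "A", "B", "B")), excludeSelf = TRUE)
#' @export
classwiseAverages <- function(C, labels, excludeSelf = FALSE, mask = NULL,
                              covariates = NULL,
                              statistic = c("mean", "median")) {
  stopifnot(is(C, "CorrelationMatrix"))
  labels <- as.factor(labels)
  labels <- droplevels(labels)
  if (length(labels) != ncol(C@entries))
    stop("one label per training column is required", call. = FALSE)
  selfCol <- NULL
  if (excludeSelf) {
    rid <- rownames(C@entries); cid <- colnames(C@entries)
    if (is.null(rid) || is.null(cid))
      stop("excludeSelf requires row and column sample ids", call. = FALSE)
    selfCol <- match(rid, cid)
  }
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    if (!identical(dim(mask), dim(C@entries)))
      stop("bias mask must be aligned to the correlation matrix", call. = FALSE)
  }
  feats <- .classAverages(C@entries, labels, selfCol, mask, statistic)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != nrow(feats))
      stop("covariates must have one row per target sample", call. = FALSE)
  }
  new("ClasswiseFeatureTable", features = feats, covariates = covariates,
      classOrder = levels(labels))
}

#' Draw per-class reference instance sets (F-ACF / F-DBC)
#'
#' For each class, a uniform random subset of \code{min(nRef, class size)}
#' training indices, reproducible under \code{seed}.
#'
#' @param labels factor of training class labels.
#' @param nRef requested number of reference instances per class.
#' @param seed integer seed.
#' @return named list of integer index vectors, one per class.
#' @export
selectReferences <- function(labels, nRef, seed = 1L) {
  labels <- as.factor(labels)
  nRef <- .assertScalarCount(nRef, "nRef")
  .withSeed(seed, {
    refs <- lapply(levels(labels), function(cl) {
      idx <- which(labels == cl)
      if (length(idx) <= nRef) idx else sort(sample(idx, nRef))
    })
    names(refs) <- levels(labels)
    refs
  })
}

#' Same-batch bias mask (B-ACF)
#'
#' Batch effects in multiplexed experiments bias the correlations between
#' samples measured in the same batch. The mask marks exactly those
#' entries: \code{mask[i, j]} is \code{TRUE} iff the two samples share a
#' batch and \code{i != j}. With one batch id vector the mask is the
#' square, symmetric train-train mask; with \code{colBatches} given it is
#' the rectangular target-to-train mask (self pairs identified by
#' position are only excluded in the square case).
#'
#' @param batches batch id per (row) sample; \code{NULL} or length 0
#'   yields an all-FALSE mask (B-ACF then equals plain ACF).
#' @param colBatches optional batch id per column sample, for rectangular
#'   test-to-train masks.
#' @param n number of samples when \code{batches} is NULL/empty.
#' @return a logical matrix.
#' @examples
#' sameBatchMask(c(1, 1, 2, 2))
#' @export
sameBatchMask <- function(batches, colBatches = NULL, n = NULL) {
  if (is.null(batches) || length(batches) == 0) {
    if (is.null(n)) stop("'n' is required for an empty batch vector", call. = FALSE)
    nc <- if (is.null(colBatches)) n else length(colBatches)
    return(matrix(FALSE, n, nc))
  }
  batches <- as.character(batches)
  if (is.null(colBatches)) {
    m <- outer(batches, batches, "==")
    diag(m) <- FALSE
    m
  } else {
    outer(batches, as.character(colBatches), "==")
  }
}

#' Fit an ACF classifier
#'
#' Computes the train-train pairwise-deletion correlation matrix, builds
#' the class-wise average-correlation feature table (self-correlations
#' excluded; biased entries masked for B-ACF; only reference instances
#' used for F-ACF) and trains the chosen baseline classifier on it, with
#' any covariates appended unchanged.
#'
#' @param X training samples, an [OmicsMatrix-class] or plain matrix.
#' @param labels class label per training sample; at least 2 classes with
#'   at least 2 samples each.
#' @param baseline baseline classifier: "svc", "rf" or "ridge", or a list
#'   \code{list(name =, params = list(...))} with hyperparameters (see
#'   [defaultSearchSpace()] for the tunable ones).
#' @param covariates optional data.frame (or named vector) of per-sample
#'   covariates; row names must match the sample ids.
#' @param method correlation method, "pearson" (default) or "spearman".
#' @param minOverlap minimum pairwise overlap for a defined correlation.
#' @param nRef number of reference instances per class (F-ACF); NULL uses
#'   all training samples. Training features are also computed against
#'   the sampled reference sets only.
#' @param batches optional training batch ids; same-batch correlations are
#'   masked from the averages (B-ACF).
#' @param biasMask optional explicit logical train-train mask (TRUE =
#'   omit); overrides \code{batches}.
#' @param statistic aggregation statistic for the class averages.
#' @param seed integer seed for reference sampling and the baseline fit.
#' @return an [ACFModel-class].
#' @seealso [acfPredict()]
#' @export
acfFit <- function(X, labels, baseline = "svc", covariates = NULL,
                   method = c("pearson", "spearman"), minOverlap = 3L,
                   nRef = NULL, batches = NULL, biasMask = NULL,
                   statistic = c("mean", "median"), seed = 1L) {
  method <- match.arg(method)
  statistic <- match.arg(statistic)
  if (!is(X, "OmicsMatrix")) X <- omicsMatrix(X)
  labels <- droplevels(as.factor(labels))
  if (length(labels) != nrow(X@values))
    stop("one label per training sample is required", call. = FALSE)
  if (nlevels(labels) < 2) stop("at least 2 classes are required", call. = FALSE)
  if (any(table(labels) < 2)) {
    bad <- names(which(table(labels) < 2))
    stop(sprintf("class '%s' has fewer than 2 training samples", bad[1]), call. = FALSE)
  }
  baseline <- .normalizeBaseline(baseline)
  covariates <- .alignCovariates(covariates, sampleIDs(X))
  minOverlap <- .assertScalarCount(minOverlap, "minOverlap")
  seed <- as.integer(seed)

  if (!is.null(nRef)) {
    nRef <- .assertScalarCount(nRef, "nRef")
    references <- selectReferences(labels, nRef, seed = seed)
  } else {
    references <- split(seq_along(labels), labels)
    nRef <- NA_integer_
  }
  refIdx <- sort(unlist(references, use.names = FALSE))

  if (is.null(biasMask) && !is.null(batches)) {
    if (length(batches) != length(labels))
      stop("one batch id per training sample is required", call. = FALSE)
    biasMask <- sameBatchMask(batches)
  }

  Ctr <- crossCorrelationMatrix(X, X[refIdx, ], method = method,
                                minOverlap = minOverlap)
  maskSub <- if (is.null(biasMask)) NULL else biasMask[, refIdx, drop = FALSE]
  feat <- classwiseAverages(Ctr, labels[refIdx], excludeSelf = TRUE,
                            mask = maskSub, covariates = covariates,
                            statistic = statistic)
  fit <- .fitBaseline(baseline, as.data.frame(feat), labels, seed = seed)

  new("ACFModel", train = X, labels = labels, method = method,
      minOverlap = minOverlap, nRef = nRef, references = references,
      biasMask = biasMask, batches = if (is.null(batches)) NULL else
        as.character(batches),
      baseline = baseline, fit = fit,
      covariateNames = if (is.null(covariates)) character(0) else
        colnames(covariates),
      classOrder = levels(labels), seed = seed)
}

#' Predict classes with a fitted ACF model
#'
#' Computes the average correlations of each test sample to the (reference
#' instances of the) training samples per class, appends covariates, and
#' applies the fitted baseline classifier. With F-ACF, exactly
#' \code{sum over classes of |reference set|} correlations are computed
#' per test sample, independent of the training-set size.
#'
#' @param model an [ACFModel-class] from [acfFit()].
#' @param XTest test samples; features must be aligned to the training
#'   features.
#' @param covariates optional covariates for the test samples (required
#'   when the model was fitted with covariates).
#' @param batches optional test batch ids; same-batch test-to-train
#'   correlations are masked (B-ACF).
#' @return factor of predicted class labels, named by test sample id.
#' @export
acfPredict <- function(model, XTest, covariates = NULL, batches = NULL) {
  stopifnot(is(model, "ACFModel"))
  if (!is(XTest, "OmicsMatrix")) XTest <- omicsMatrix(XTest)
  covariates <- .alignCovariates(covariates, sampleIDs(XTest))
  if (length(model@covariateNames)) {
    if (is.null(covariates) ||
        !all(model@covariateNames %in% colnames(covariates)))
      stop("the model was fitted with covariates; matching test covariates are required",
           call. = FALSE)
    covariates <- covariates[, model@covariateNames, drop = FALSE]
  } else covariates <- NULL

  refIdx <- sort(unlist(model@references, use.names = FALSE))
  Cte <- crossCorrelationMatrix(XTest, model@train[refIdx, ],
                                method = model@method,
                                minOverlap = model@minOverlap)
  mask <- NULL
  if (!is.null(batches) && !is.null(model@batches)) {
    if (length(batches) != nrow(XTest@values))
      stop("one batch id per test sample is required", call. = FALSE)
    mask <- sameBatchMask(as.character(batches), model@batches[refIdx])
  }
  feat <- classwiseAverages(Cte, model@labels[refIdx], excludeSelf = FALSE,
                            mask = mask, covariates = covariates)
  pred <- .predictBaseline(model@baseline, model@fit, as.data.frame(feat))
  names(pred) <- sampleIDs(XTest)
  pred
}

setMethod("show", "ACFModel", function(object) {
  cat(sprintf("ACFModel (%s baseline, %s correlations)\n",
              object@baseline$name, object@method))
  cat(sprintf("  %d training samples, classes [%s]\n", length(object@labels),
              paste(object@classOrder, collapse = ", ")))
  if (!is.na(object@nRef))
    cat(sprintf("  F-ACF with %d reference instance(s) per class\n", object@nRef))
  if (!is.null(object@biasMask))
    cat(sprintf("  B-ACF: %d biased train-train entries masked\n",
                sum(object@biasMask)))
  if (length(object@covariateNames))
    cat(sprintf("  covariates: %s\n", paste(object@covariateNames, collapse = ", ")))
})

# -- helpers -----------------------------------------------------------------

.alignCovariates <- function(covariates, ids) {
  if (is.null(covariates)) return(NULL)
  if (is.atomic(covariates) && is.null(dim(covariates)))
    covariates <- data.frame(covariate = covariates,
                             row.names = if (!is.null(names(covariates)))
                               names(covariates) else ids)
  covariates <- as.data.frame(covariates)
  if (!is.null(rownames(covariates)) &&
      !all(rownames(covariates) == as.character(seq_len(nrow(covariates))))) {
    missing <- setdiff(ids, rownames(covariates))
    if (length(missing))
      stop(sprintf("covariates missing for sample(s): %s",
                   paste(utils::head(missing, 5), collapse = ", ")), call. = FALSE)
    covariates <- covariates[ids, , drop = FALSE]
  } else if (nrow(covariates) != length(ids)) {
    stop("covariate rows do not match the sample ids", call. = FALSE)
  }
  rownames(covariates) <- ids
  covariates
}
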