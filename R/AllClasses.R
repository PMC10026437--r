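#' @import methods
NULL

#' OmicsMatrix: a samples-by-features matrix with first-class missing values
#'
#' Thin S4 container for a numeric samples x features matrix in which
#' missing entries (any non-finite value on input) are represented as
#' \code{NA}. Sample and feature identifiers are kept as dimnames and must
#' be unique; every sample must have at least one observed feature.
#'
#' @slot values numeric matrix, samples in rows, features in columns,
#'   \code{NA} marking missing entries.
#'
#' @seealso [omicsMatrix()] for construction from plain matrices,
#'   [trainCorrelationMatrix()] for pairwise-deletion correlations.
#' @export
setClass("OmicsMatrix", representation(values = "matrix"))

setValidity("OmicsMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("'values' must be a numeric matrix")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("sample and feature identifiers are required (dimnames)")
  if (anyDuplicated(rownames(v))) return("duplicated sample identifiers")
  if (anyDuplicated(colnames(v))) return("duplicated feature identifiers")
  if (nrow(v) < 2) return("at least 2 samples are required")
  if (any(rowSums(is.finite(v)) == 0))
    return(paste0("sample(s) without any observed feature: ",
                  paste(rownames(v)[rowSums(is.finite(v)) == 0], collapse = ", ")))
  TRUE
})

#' CorrelationMatrix: pairwise correlations under pairwise deletion
#'
#' Holds a rows x cols matrix of pairwise sample correlations together with
#' a logical mask of which entries are defined. An entry is undefined (and
#' never silently imputed) when the observed overlap between the two
#' samples has fewer than \code{minOverlap} features or zero variance in
#' either subvector. For the square train case the matrix is symmetric
#' with unit diagonal where defined.
#'
#' @slot entries numeric matrix of correlations; \code{NA} where undefined.
#' @slot defined logical matrix, \code{TRUE} where the entry is defined.
#' @slot method "pearson" or "spearman".
#' @slot minOverlap minimum number of jointly observed features.
#'
#' @export
setClass("CorrelationMatrix",
         representation(entries = "matrix", defined = "matrix",
                        method = "character", minOverlap = "integer"))

setValidity("CorrelationMatrix", function(object) {
  e <- object@entries; d <- object@defined
  if (!identical(dim(e), dim(d))) return("'entries' and 'defined' must share dimensions")
  if (!object@method %in% c("pearson", "spearman"))
    return("method must be 'pearson' or 'spearman'")
  if (length(object@minOverlap) != 1L || object@minOverlap < 1L)
    return("minOverlap must be a positive integer")
  vals <- e[d]
  if (length(vals) && any(!is.finite(vals))) return("defined entries must be finite")
  if (length(vals) && any(vals < -1 - 1e-8 | vals > 1 + 1e-8))
    return("defined entries must lie in [-1, 1]")
  if (any(is.na(e) & d)) return("defined entries cannot be NA")
  TRUE
})

#' ClasswiseFeatureTable: per-sample average correlations to each class
#'
#' The input of the ACF baseline classifier: one average-correlation column
#' per class (in fixed class order), optionally followed by covariate
#' columns. Average-correlation values always lie in [-1, 1].
#'
#' @slot features numeric matrix, one row per sample, columns
#'   \code{mu_<class>} in the fixed class order.
#' @slot covariates data.frame of covariates aligned to the rows, or NULL.
#' @slot classOrder character vector of class labels fixing column order.
#'
#' @export
setClass("ClasswiseFeatureTable",
         representation(features = "matrix", covariates = "ANY",
                        classOrder = "character"))

setValidity("ClasswiseFeatureTable", function(object) {
  f <- object@features
  if (ncol(f) != length(object@classOrder))
    return("one feature column per class is required")
  if (any(!is.finite(f))) return("feature cells must be defined (no NA)")
  if (any(f < -1 - 1e-8 | f > 1 + 1e-8))
    return("average correlations must lie in [-1, 1]")
  cov <- object@covariates
  if (!is.null(cov) && nrow(cov) != nrow(f))
    return("covariate rows must align with feature rows")
  TRUE
})

#' ACFModel: a fitted average-correlations-as-features classifier
#'
#' Bundles the training data reference, correlation options, per-class
#' reference sets (F-ACF), bias mask (B-ACF), the fitted baseline
#' classifier and the covariate schema.
#'
#' @slot train the training [OmicsMatrix-class].
#' @slot labels factor of training class labels.
#' @slot method correlation method, "pearson" or "spearman".
#' @slot minOverlap minimum pairwise overlap.
#' @slot nRef number of reference instances per class, or NA for all.
#' @slot references named list of per-class training row indices used as
#'   reference instances.
#' @slot biasMask logical matrix marking biased train-train correlations
#'   (TRUE = omit from averaging), or NULL.
#' @slot batches character vector of training batch identifiers, or NULL.
#' @slot baseline list: baseline classifier name and hyperparameters.
#' @slot fit the fitted baseline classifier object.
#' @slot covariateNames character vector of covariate column names.
#' @slot classOrder class label order of the feature columns.
#' @slot seed integer seed used for reference sampling / baseline fitting.
#'
#' @export
setClass("ACFModel",
         representation(train = "OmicsMatrix", labels = "factor",
                        method = "character", minOverlap = "integer",
                        nRef = "integer", references = "list",
                        biasMask = "ANY", batches = "ANY",
                        baseline = "list", fit = "ANY",
                        covariateNames = "character",
                        classOrder = "character", seed = "integer"))

setValidity("ACFModel", function(object) {
  if (nlevels(object@labels) < 2) return("at least 2 classes are required")
  if (any(table(object@labels) < 2)) return("every class needs >= 2 training samples")
  for (cl in names(object@references)) {
    idx <- object@references[[cl]]
    if (!all(object@labels[idx] == cl))
      return("reference sets must be subsets of their class's training indices")
  }
  TRUE
})

#' ClassCorrelationDistributions: DBC's per-class-pair histograms
#'
#' For each ordered class pair (Ci, Cj), a normalized histogram (fixed
#' binning over [-1, 1]) of the pairwise correlations between training
#' members of Ci and Cj, self-correlations excluded. Model histograms are
#' additively smoothed with one pseudo-count per bin.
#'
#' @slot breaks numeric vector of bin edges over [-1, 1].
#' @slot classes class labels.
#' @slot hist 3-d array [class i, class j, bin] of normalized histograms.
#' @slot labels factor of training labels the distributions were built from.
#' @slot references per-class reference index list (F-DBC), or full classes.
#'
#' @export
setClass("ClassCorrelationDistributions",
         representation(breaks = "numeric", classes = "character",
                        hist = "array", labels = "factor",
                        references = "list"))

setValidity("ClassCorrelationDistributions", function(object) {
  h <- object@hist
  if (length(dim(h)) != 3) return("'hist' must be a 3-d array")
  if (any(abs(apply(h, c(1, 2), sum) - 1) > 1e-8))
    return("each histogram must be normalized to sum 1")
  TRUE
})

#' SimulationConfig: parameters of the block-correlation data generator
#'
#' @slot nFeatures number of features (default 10000).
#' @slot cCenters symmetric positive-definite correlation matrix of the
#'   class centers.
#' @slot sigmaFeature per-feature Gaussian noise SD around the centers.
#' @slot classSizes named integer vector of samples per class.
#' @slot missingFraction MCAR missing-value proportion in [0, 1).
#' @slot covariate NULL, or list(centers = per-class numeric, sd = numeric)
#'   for an optional Gaussian covariate.
#' @slot seed integer seed; all randomness of the generator flows from it.
#'
#' @export
setClass("SimulationConfig",
         representation(nFeatures = "integer", cCenters = "matrix",
                        sigmaFeature = "numeric", classSizes = "integer",
                        missingFraction = "numeric", covariate = "ANY",
                        seed = "integer"))

setValidity("SimulationConfig", function(object) {
  C <- object@cCenters
  if (nrow(C) != ncol(C) || max(abs(C - t(C))) > 1e-8)
    return("cCenters must be a symmetric matrix")
  if (max(abs(diag(C) - 1)) > 1e-8) return("cCenters must have unit diagonal")
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    return(sprintf("cCenters is not positive definite (min eigenvalue %.3g)", min(ev)))
  if (length(object@classSizes) != nrow(C))
    return("class count must equal the dimension of cCenters")
  if (is.null(names(object@classSizes)) || anyDuplicated(names(object@classSizes)))
    return("classSizes must carry unique class names")
  if (object@missingFraction < 0 || object@missingFraction >= 1)
    return("missingFraction must be in [0, 1)")
  if (object@sigmaFeature < 0) return("sigmaFeature must be >= 0")
  if (object@nFeatures < 2) return("nFeatures must be >= 2")
  cov <- object@covariate
  if (!is.null(cov)) {
    if (!is.list(cov) || is.null(cov$centers) || is.null(cov$sd))
      return("covariate must be list(centers=, sd=)")
    if (length(cov$centers) != length(object@classSizes))
      return("one covariate center per class is required")
    if (cov$sd < 0) return("covariate sd must be >= 0")
  }
  TRUE
})

#' SimulatedDataset: output of the data-generating process
#'
#' @slot data the simulated [OmicsMatrix-class] (with MCAR missingness).
#' @slot labels factor of ground-truth class labels.
#' @slot covariate numeric covariate per sample, or NULL.
#' @slot centers the ground-truth class-center matrix (classes x features).
#' @slot config the [SimulationConfig-class] that produced the dataset.
#'
#' @export
setClass("SimulatedDataset",
         representation(data = "OmicsMatrix", labels = "factor",
                        covariate = "ANY", centers = "matrix",
                        config = "SimulationConfig"))

setValidity("SimulatedDataset", function(object) {
  if (length(object@labels) != nrow(object@data@values))
    return("one label per sample is required")
  sz <- object@config@classSizes
  obs <- table(object@labels)[names(sz)]
  if (!all(obs == sz)) return("per-class sample counts must equal classSizes")
  TRUE
})

#' CVConfig: protocol parameters of repeated stratified cross-validation
#'
#' @slot k number of folds.
#' @slot repetitions number of repetitions of the whole CV procedure.
#' @slot nTrials hyperparameter-search trials per fold.
#' @slot nValidationSets validation splits per trial.
#' @slot validationFraction fraction of the training part held out per
#'   validation split.
#' @slot seed master seed; fold assignment, search and validation splits
#'   all derive from it.
#'
#' @export
setClass("CVConfig",
         representation(k = "integer", repetitions = "integer",
                        nTrials = "integer", nValidationSets = "integer",
                        validationFraction = "numeric", seed = "integer"))

setValidity("CVConfig", function(object) {
  if (object@k < 2) return("k must be >= 2")
  if (object@repetitions < 1) return("repetitions must be >= 1")
  if (object@validationFraction <= 0 || object@validationFraction >= 1)
    return("validationFraction must be in (0, 1)")
  if (object@nTrials < 1 || object@nValidationSets < 1)
    return("nTrials and nValidationSets must be >= 1")
  TRUE
})

#' CVResult: per-repetition, per-fold cross-validation scores
#'
#' @slot scores data.frame with one row per repetition x fold: macro-F1,
#'   fold sizes and the selected hyperparameters (list column).
#' @slot perClass data.frame of per-class precision/recall/F1 per fold.
#' @slot estimator short description of the evaluated estimator.
#' @slot config the [CVConfig-class] used.
#' @slot audit list of index bookkeeping per fold (test indices and the
#'   union of all HPO indices) used by the leakage audit, or empty.
#'
#' @export
setClass("CVResult",
         representation(scores = "data.frame", perClass = "data.frame",
                        estimator = "character", config = "CVConfig",
                        audit = "list"))

#' LabeledDataset: matrix plus labels (and optional covariates / batches)
#'
#' @slot data an [OmicsMatrix-class].
#' @slot labels factor of class labels named by sample id.
#' @slot covariates data.frame of per-sample covariates, or NULL.
#' @slot batches character vector of batch identifiers, or NULL.
#'
#' @export
setClass("LabeledDataset",
         representation(data = "OmicsMatrix", labels = "factor",
                        covariates = "ANY", batches = "ANY"))

setValidity("LabeledDataset", function(object) {
  ids <- rownames(object@data@values)
  if (length(object@labels) != length(ids)) return("one label per sample is required")
  if (!identical(names(object@labels), ids))
    return("labels must be named by, and aligned to, the sample ids")
  cov <- object@covariates
  if (!is.null(cov) && !identical(rownames(cov), ids))
    return("covariate rows must align with sample ids")
  b <- object@batches
  if (!is.null(b) && length(b) != length(ids))
    return("one batch id per sample is required")
  TRUE
})
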