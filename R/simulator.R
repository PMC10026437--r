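# Data-generating process: datasets with block-structured correlation
# matrices, controlled noise and MCAR missingness, plus diagnostics.

#' Default class-center correlation matrix
#'
#' The three-class center correlation matrix used throughout the
#' simulation studies: classes A and B are closely correlated (0.9) but
#' strongly differ in their correlation to class C (0.6 vs 0.8), the
#' minimal example of a discriminative cross-correlation.
#'
#' @return a 3 x 3 symmetric positive-definite correlation matrix.
#' @export
defaultCenters <- function() {
  matrix(c(1.0, 0.9, 0.6,
           0.9, 1.0, 0.8,
           0.6, 0.8, 1.0), 3, 3,
         dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
}

#' Build a simulation configuration
#'
#' Parameters of the data-generating process. The defaults are the
#' studied conditions: 10,000 features, the [defaultCenters()] matrix,
#' per-feature noise SD 2.0, class sizes 70/30/50 and no missing values.
#' The optional covariate follows a Gaussian around per-class centers
#' (0.15/0.2/0.25, sd 0.015 in the studied configuration; see
#' \code{covariate = "default"}).
#'
#' @param nFeatures number of features.
#' @param cCenters symmetric positive-definite class-center correlation
#'   matrix; its row names (or \code{classNames}) name the classes.
#' @param sigmaFeature per-feature Gaussian noise SD around the centers.
#' @param classSizes samples per class (named, or named via `cCenters`).
#' @param missingFraction MCAR missing proportion in [0, 1).
#' @param covariate NULL, "default" (centers 0.15/0.2/0.25, sd 0.015) or
#'   list(centers =, sd =).
#' @param seed mandatory integer seed.
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(nFeatures = 10000L, cCenters = defaultCenters(),
                             sigmaFeature = 2.0,
                             classSizes = c(A = 70L, B = 30L, C = 50L),
                             missingFraction = 0, covariate = NULL,
                             seed) {
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  cCenters <- as.matrix(cCenters)
  if (is.null(rownames(cCenters)))
    rownames(cCenters) <- colnames(cCenters) <-
      LETTERS[seq_len(nrow(cCenters))]
  if (is.null(names(classSizes))) names(classSizes) <- rownames(cCenters)
  if (identical(covariate, "default"))
    covariate <- list(centers = stats::setNames(
      seq(0.15, by = 0.05, length.out = length(classSizes)),
      names(classSizes)), sd = 0.015)
  new("SimulationConfig", nFeatures = as.integer(nFeatures),
      cCenters = cCenters, sigmaFeature = as.numeric(sigmaFeature),
      classSizes = stats::setNames(as.integer(classSizes), names(classSizes)),
      missingFraction = as.numeric(missingFraction), covariate = covariate,
      seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0("SimulationConfig: %d features, classes [%s] sizes [%s],\n",
                     "  sigmaFeature = %g, missingFraction = %g, seed = %d%s\n"),
              object@nFeatures, paste(names(object@classSizes), collapse = ", "),
              paste(object@classSizes, collapse = ", "), object@sigmaFeature,
              object@missingFraction, object@seed,
              if (is.null(object@covariate)) "" else ", with covariate"))
})

#' Correlated class centers via Cholesky mixing
#'
#' Draws i.i.d. standard-normal feature vectors (one per class) and mixes
#' them with the Cholesky factor of \code{cCenters}, producing unit-
#' variance class centers whose empirical pairwise Pearson correlations
#' approximate \code{cCenters} (the tolerance shrinks as the number of
#' features grows; very small feature counts run but with large
#' deviations).
#'
#' @param cCenters symmetric positive-definite correlation matrix.
#' @param nFeatures number of features.
#' @param seed integer seed.
#' @return classes x features matrix of centers.
#' @export
correlatedCenters <- function(cCenters, nFeatures, seed = 1L) {
  cCenters <- as.matrix(cCenters)
  L <- tryCatch(t(chol(cCenters)), error = function(e)
    stop("cCenters is not positive definite: Cholesky decomposition failed",
         call. = FALSE))
  k <- nrow(cCenters)
  .withSeed(seed, {
    Z <- matrix(stats::rnorm(k * nFeatures), k, nFeatures)
    centers <- L %*% Z
    rownames(centers) <- rownames(cCenters)
    centers
  })
}

#' Generate a simulated dataset
#'
#' Each sample is its class center plus i.i.d. Gaussian noise of SD
#' \code{sigmaFeature} per feature; afterwards a fixed expected fraction
#' of entries is deleted completely at random (per-entry Bernoulli). The
#' optional covariate is drawn per its spec. Identical configs (same
#' seed) give bit-identical datasets. Should MCAR deletion leave a sample
#' with no observed feature, one randomly chosen entry is restored.
#'
#' @param config a [SimulationConfig-class].
#' @return a [SimulatedDataset-class].
#' @examples
#' cfg <- simulationConfig(nFeatures = 200, classSizes = c(A = 5, B = 5, C = 5),
#'                         seed = 7)
#' d <- generateDataset(cfg)
#' table(datasetLabels(d))
#' @export
generateDataset <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  p <- config@nFeatures
  sizes <- config@classSizes
  n <- sum(sizes)
  .withSeed(config@seed, {
    centers <- {
      L <- t(chol(config@cCenters))
      Z <- matrix(stats::rnorm(nrow(L) * p), nrow(L), p)
      out <- L %*% Z; rownames(out) <- names(sizes); out
    }
    lab <- factor(rep(names(sizes), sizes), levels = names(sizes))
    X <- centers[as.integer(lab), , drop = FALSE] +
      matrix(stats::rnorm(n * p, sd = config@sigmaFeature), n, p)
    if (config@missingFraction > 0) {
      drop <- matrix(stats::runif(n * p) < config@missingFraction, n, p)
      allGone <- rowSums(!drop) == 0
      if (any(allGone))
        drop[cbind(which(allGone),
                   sample.int(p, sum(allGone), replace = TRUE))] <- FALSE
      X[drop] <- NA_real_
    }
    rownames(X) <- paste0("S", seq_len(n))
    colnames(X) <- paste0("F", seq_len(p))
    cov <- NULL
    if (!is.null(config@covariate)) {
      cc <- config@covariate
      cov <- stats::rnorm(n, mean = cc$centers[as.integer(lab)], sd = cc$sd)
      names(cov) <- rownames(X)
    }
    new("SimulatedDataset", data = new("OmicsMatrix", values = X),
        labels = stats::setNames(lab, rownames(X)), covariate = cov,
        centers = centers, config = config)
  })
}

setMethod("show", "SimulatedDataset", function(object) {
  cat("SimulatedDataset\n  ")
  show(object@data)
  cat(sprintf("  classes: %s\n",
              paste(sprintf("%s=%d", names(object@config@classSizes),
                            object@config@classSizes), collapse = ", ")))
})

#' Accessors for SimulatedDataset
#'
#' @param x a [SimulatedDataset-class].
#' @name SimulatedDataset-accessors
NULL

#' @rdname SimulatedDataset-accessors
#' @export
setGeneric("datasetMatrix", function(x) standardGeneric("datasetMatrix"))

#' @rdname SimulatedDataset-accessors
#' @export
setMethod("datasetMatrix", "SimulatedDataset", function(x) x@data)

#' @rdname SimulatedDataset-accessors
#' @export
setGeneric("datasetLabels", function(x) standardGeneric("datasetLabels"))

#' @rdname SimulatedDataset-accessors
#' @export
setMethod("datasetLabels", "SimulatedDataset", function(x) x@labels)

#' @rdname SimulatedDataset-accessors
#' @export
setGeneric("datasetCovariate", function(x) standardGeneric("datasetCovariate"))

#' @rdname SimulatedDataset-accessors
#' @export
setMethod("datasetCovariate", "SimulatedDataset", function(x) x@covariate)

#' Block statistics of a labeled correlation matrix
#'
#' Mean and SD of the defined, non-self correlations of every class pair
#' (blocks of the correlation matrix). On simulated data the per-block
#' SDs are approximately equal; their mean serves as the noise SD
#' entering the relative noise [relativeNoise()].
#'
#' @param C a square [CorrelationMatrix-class] (or matrix).
#' @param labels class label per sample.
#' @return data.frame with columns classA, classB, mean, sd, n (one row
#'   per unordered class pair).
#' @export
blockStats <- function(C, labels) {
  entries <- if (is(C, "CorrelationMatrix")) C@entries else as.matrix(C)
  labels <- droplevels(as.factor(labels))
  if (length(labels) != ncol(entries) || nrow(entries) != ncol(entries))
    stop("a square correlation matrix with one label per sample is required",
         call. = FALSE)
  lev <- levels(labels)
  rows <- list()
  for (i in seq_along(lev)) for (j in i:length(lev)) {
    bi <- which(labels == lev[i]); bj <- which(labels == lev[j])
    block <- entries[bi, bj, drop = FALSE]
    if (i == j) block <- block[row(block) != col(block)]
    v <- block[is.finite(block)]
    if (!length(v))
      stop(sprintf("empty correlation block for classes '%s'/'%s'",
                   lev[i], lev[j]), call. = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      classA = lev[i], classB = lev[j],
      mean = mean(v), sd = stats::sd(v), n = length(v))
  }
  do.call(rbind, rows)
}

.blockLookup <- function(stats, a, b) {
  hit <- (stats$classA == a & stats$classB == b) |
         (stats$classA == b & stats$classB == a)
  if (!any(hit)) stop(sprintf("no block for classes '%s'/'%s'", a, b),
                      call. = FALSE)
  stats[which(hit)[1], ]
}

#' Average relative noise of a block correlation matrix
#'
#' \eqn{\sigma_{rel} = \sigma / (\mu_{AA} - \mu_{AB})}: the common block
#' noise SD (mean of the per-block SDs, which are approximately equal on
#' simulated data) divided by the gap between the intra-class mean of
#' class A and the inter-class mean of the A-B block. By default, A and B
#' are the two most-correlated distinct classes.
#'
#' @param stats output of [blockStats()].
#' @param classA,classB the class pair defining the denominator; default
#'   picks the two classes with the largest inter-class block mean.
#' @return the relative noise (non-negative scalar).
#' @export
relativeNoise <- function(stats, classA = NULL, classB = NULL) {
  inter <- stats[stats$classA != stats$classB, ]
  if (is.null(classA) || is.null(classB)) {
    top <- inter[which.max(inter$mean), ]
    classA <- top$classA; classB <- top$classB
  }
  sigma <- mean(stats$sd)
  muAA <- .blockLookup(stats, classA, classA)$mean
  muAB <- .blockLookup(stats, classA, classB)$mean
  gap <- muAA - muAB
  if (abs(gap) < 1e-12)
    stop("intra- and inter-class block means coincide; relative noise undefined",
         call. = FALSE)
  sigma / gap
}

#' Calibrate the MCAR missing fraction to a target relative noise
#'
#' The missing fraction determines the noise SD on the correlation matrix
#' (and therefore the relative noise) monotonically but non-linearly;
#' no closed form is available, so the fraction realizing a target
#' relative noise is found by bisection, measuring sigma_rel on a pilot
#' dataset of the full configured size at every step.
#'
#' @param config a [SimulationConfig-class]; its missingFraction is
#'   ignored.
#' @param targetSigmaRel target relative noise (>= 0).
#' @param tolerance acceptable |measured - target| (default 0.1).
#' @param seed seed for the pilot datasets.
#' @param maxIter bisection iteration cap.
#' @param upper upper bound of the searched fraction (default 0.995).
#' @return the calibrated missing fraction, with attributes
#'   \code{sigmaRel} (measured value) and \code{iterations}.
#' @export
calibrateMissingFraction <- function(config, targetSigmaRel, tolerance = 0.1,
                                     seed = 1L, maxIter = 25L, upper = 0.995) {
  stopifnot(is(config, "SimulationConfig"))
  if (targetSigmaRel < 0) stop("targetSigmaRel must be >= 0", call. = FALSE)
  seeds <- .deriveSeeds(seed, maxIter + 2L)
  measure <- function(f, s) {
    cfg <- config
    cfg@missingFraction <- f
    cfg@seed <- s
    d <- generateDataset(cfg)
    cm <- trainCorrelationMatrix(d@data, method = "pearson")
    # fractions so extreme that pairwise overlaps vanish leave most
    # entries undefined; block statistics are then meaningless, so such
    # pilots are flagged unmeasurable (NA) rather than trusted
    off <- cm@defined; diag(off) <- TRUE
    if (mean(off) < 0.9) return(NA_real_)
    tryCatch({
      sr <- relativeNoise(blockStats(cm, d@labels))
      # a negative ratio means the estimated block-mean gap flipped sign,
      # i.e. the pilot is noise-dominated: also unmeasurable
      if (is.finite(sr) && sr >= 0) sr else NA_real_
    }, error = function(e) NA_real_)
  }
  lo <- 0; hi <- upper
  srLo <- measure(lo, seeds[1])
  if (targetSigmaRel <= srLo + tolerance) {
    out <- 0
    attr(out, "sigmaRel") <- srLo; attr(out, "iterations") <- 1L
    return(out)
  }
  srHi <- measure(hi, seeds[2])
  while (is.na(srHi) && hi > 0.5) {   # walk down to a measurable bracket
    hi <- hi - 0.005
    srHi <- measure(hi, seeds[2])
  }
  if (is.na(srHi))
    stop("no measurable missing fraction found below the upper bound",
         call. = FALSE)
  if (srHi < targetSigmaRel - tolerance)
    stop(sprintf(paste0("target relative noise %.3g unachievable: sigma_rel is ",
                        "%.3g at fraction %g and %.3g at fraction %g"),
                 targetSigmaRel, srLo, lo, srHi, hi), call. = FALSE)
  mid <- NA; srMid <- NA
  for (it in seq_len(maxIter)) {
    mid <- (lo + hi) / 2
    srMid <- measure(mid, seeds[it + 2L])
    if (is.na(srMid)) { hi <- mid; next }   # unmeasurable: come down
    if (abs(srMid - targetSigmaRel) <= tolerance) break
    if (srMid < targetSigmaRel) lo <- mid else hi <- mid
  }
  if (is.na(srMid) || abs(srMid - targetSigmaRel) > tolerance)
    stop(sprintf("bisection did not reach target %.3g within %d iterations (last %.3g)",
                 targetSigmaRel, maxIter, srMid), call. = FALSE)
  out <- mid
  attr(out, "sigmaRel") <- srMid; attr(out, "iterations") <- it
  out
}

#' Normality of block residuals (D'Agostino-Pearson omnibus test)
#'
#' Because correlations are bounded in [-1, 1], the Gaussian-noise
#' assumption for the correlation-matrix blocks only holds when the block
#' means stay away from the boundaries. For each class-pair block this
#' computes the D'Agostino-Pearson K-squared omnibus p-value of the block
#' residuals (entries minus the block mean); blocks with fewer than 20
#' entries are an error.
#'
#' @param C a square [CorrelationMatrix-class] (or matrix).
#' @param labels class label per sample.
#' @return data.frame with classA, classB, statistic, p.
#' @seealso [dagostinoPearsonTest()]
#' @export
residualNormality <- function(C, labels) {
  entries <- if (is(C, "CorrelationMatrix")) C@entries else as.matrix(C)
  labels <- droplevels(as.factor(labels))
  lev <- levels(labels)
  rows <- list()
  for (i in seq_along(lev)) for (j in i:length(lev)) {
    bi <- which(labels == lev[i]); bj <- which(labels == lev[j])
    block <- entries[bi, bj, drop = FALSE]
    if (i == j) block <- block[row(block) != col(block)]
    v <- block[is.finite(block)]
    if (length(v) < 20)
      stop(sprintf("block '%s'/'%s' has %d entries; >= 20 are required",
                   lev[i], lev[j], length(v)), call. = FALSE)
    tst <- dagostinoPearsonTest(v - mean(v))
    rows[[length(rows) + 1L]] <- data.frame(
      classA = lev[i], classB = lev[j],
      statistic = tst$statistic, p = tst$p)
  }
  do.call(rbind, rows)
}
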