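# Correlation-based comparator classifiers: brute-force KNN (optionally
# with random oversampling) and distribution-based classification (DBC)
# with its reference-subsampled variant F-DBC.

#' KNN prediction on a test-to-train correlation matrix
#'
#' Majority vote among the K most-correlated training samples (nearest =
#' highest correlation; brute search). Undefined correlations are ranked
#' last, never raised as errors. With \code{weights = "distance"},
#' correlation r is converted to the distance d = 1 - r and votes are
#' weighted by 1/d (d floored at a small epsilon). Vote ties are broken
#' toward the class with the larger summed correlation among the tied
#' neighbors, then by label order.
#'
#' @param C a rectangular [CorrelationMatrix-class] (or plain matrix),
#'   test samples in rows, training samples in columns.
#' @param labels class label per training column. When training indices
#'   were oversampled, pass the oversampled label vector (and matching
#'   columns).
#' @param K number of neighbors, 1 <= K <= n train columns.
#' @param weights "uniform" (default) or "distance".
#' @return factor of predicted labels, one per test row.
#' @examples
#' C <- matrix(c(.9, .8, .7), 1, 3)
#' knnPredict(C, c("A", "B", "B"), K = 1)  # A
#' knnPredict(C, c("A", "B", "B"), K = 3)  # B
#' @export
knnPredict <- function(C, labels, K, weights = c("uniform", "distance")) {
  weights <- match.arg(weights)
  entries <- if (is(C, "CorrelationMatrix")) C@entries else as.matrix(C)
  labels <- droplevels(as.factor(labels))
  if (length(labels) != ncol(entries))
    stop("one label per training column is required", call. = FALSE)
  K <- .assertScalarCount(K, "K")
  if (K > ncol(entries))
    stop(sprintf("K = %d exceeds the number of training samples (%d)",
                 K, ncol(entries)), call. = FALSE)
  lev <- levels(labels)
  eps <- 1e-8
  pred <- apply(entries, 1, function(r) {
    r[!is.finite(r)] <- -Inf           # undefined: ranked last
    ord <- order(r, decreasing = TRUE)[seq_len(K)]
    nl <- labels[ord]; nr <- r[ord]
    votes <- if (weights == "uniform") rep(1, K) else 1 / pmax(1 - nr, eps)
    votes[!is.finite(votes)] <- 0      # -Inf correlations get no vote weight
    tot <- vapply(lev, function(cl) sum(votes[nl == cl]), numeric(1))
    top <- which(tot == max(tot))
    if (length(top) > 1) {             # tie: larger summed correlation wins
      rsum <- vapply(lev[top], function(cl) {
        v <- nr[nl == cl & is.finite(nr)]
        if (length(v)) sum(v) else -Inf
      }, numeric(1))
      top <- top[which.max(rsum)]      # which.max: first (label order) on ties
    }
    lev[top[1]]
  })
  factor(pred, levels = lev)
}

#' Random oversampling to the majority class
#'
#' Returns a training index multiset in which every class is brought up to
#' the majority-class count by sampling its own indices with replacement;
#' already-balanced input is returned unchanged (original order). Applied
#' within training folds only, never across the cross-validation boundary.
#'
#' @param labels factor of training class labels.
#' @param seed integer seed.
#' @param indices optional index vector the labels refer to (defaults to
#'   \code{seq_along(labels)}).
#' @return integer vector of (possibly repeated) training indices.
#' @export
randomOversample <- function(labels, seed = 1L, indices = seq_along(labels)) {
  labels <- droplevels(as.factor(labels))
  tab <- table(labels)
  if (any(tab < 1)) stop("every class needs at least one sample", call. = FALSE)
  nMax <- max(tab)
  if (all(tab == nMax)) return(as.integer(indices))
  .withSeed(seed, {
    extra <- unlist(lapply(levels(labels), function(cl) {
      own <- indices[labels == cl]
      need <- nMax - length(own)
      if (need > 0) sample(own, need, replace = TRUE) else integer(0)
    }), use.names = FALSE)
    as.integer(c(indices, extra))
  })
}

.corHist <- function(v, breaks, pseudo = 0) {
  v <- v[is.finite(v)]
  nb <- length(breaks) - 1L
  if (!length(v) && pseudo == 0)
    stop("degenerate (empty) correlation histogram", call. = FALSE)
  idx <- findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  h <- tabulate(idx, nb) + pseudo
  h / sum(h)
}

#' Estimate per-class-pair correlation distributions (DBC / F-DBC)
#'
#' For every ordered class pair (Ci, Cj), the normalized histogram (fixed
#' equal-width binning over [-1, 1], additive smoothing of one
#' pseudo-count per bin) of all defined pairwise correlations between
#' training members of Ci and Cj, excluding self-correlations. With
#' \code{nRef}, the distributions are approximated using only a fixed
#' random number of reference instances per class (F-DBC);
#' \code{nRef = NULL} reproduces the naive DBC distributions.
#'
#' @param C a square train [CorrelationMatrix-class] (or plain matrix).
#' @param labels class label per training sample; each class needs >= 2.
#' @param nRef reference instances per class, or NULL for all.
#' @param bins number of equal-width histogram bins on [-1, 1].
#' @param seed seed for the reference sampling.
#' @return a [ClassCorrelationDistributions-class].
#' @export
estimateClassDistributions <- function(C, labels, nRef = NULL, bins = 20L,
                                       seed = 1L) {
  entries <- if (is(C, "CorrelationMatrix")) C@entries else as.matrix(C)
  labels <- droplevels(as.factor(labels))
  if (length(labels) != ncol(entries) || nrow(entries) != ncol(entries))
    stop("a square train correlation matrix with one label per sample is required",
         call. = FALSE)
  if (any(table(labels) < 2))
    stop("every class needs >= 2 training samples", call. = FALSE)
  bins <- .assertScalarCount(bins, "bins")
  refs <- if (is.null(nRef)) split(seq_along(labels), labels)
          else selectReferences(labels, nRef, seed = seed)
  lev <- levels(labels)
  breaks <- seq(-1, 1, length.out = bins + 1L)
  H <- array(NA_real_, c(length(lev), length(lev), bins),
             dimnames = list(lev, lev, NULL))
  for (i in seq_along(lev)) for (j in seq_along(lev)) {
    ri <- refs[[lev[i]]]; rj <- refs[[lev[j]]]
    block <- entries[ri, rj, drop = FALSE]
    if (i == j) block[cbind(seq_along(ri), match(ri, rj))] <- NA_real_
    v <- block[is.finite(block)]
    if (!length(v))
      stop(sprintf("no defined correlations between classes '%s' and '%s'",
                   lev[i], lev[j]), call. = FALSE)
    H[i, j, ] <- .corHist(v, breaks, pseudo = 1)
  }
  new("ClassCorrelationDistributions", breaks = breaks, classes = lev,
      hist = H, labels = labels, references = refs)
}

setMethod("show", "ClassCorrelationDistributions", function(object) {
  cat(sprintf("ClassCorrelationDistributions: %d classes [%s], %d bins on [-1, 1]\n",
              length(object@classes), paste(object@classes, collapse = ", "),
              dim(object@hist)[3]))
})

#' Kullback-Leibler distance between two normalized histograms
#'
#' \eqn{\sum_i p_i \log(p_i / q_i)} in nats, non-negative by the Gibbs
#' inequality, and 0 iff p = q. Both histograms must share the same
#' binning; \code{q} must carry smoothing so it has no empty support
#' where \code{p > 0} (as guaranteed by [estimateClassDistributions()]).
#'
#' @param p,q normalized histograms (non-negative, summing to 1).
#' @return non-negative KL distance in nats.
#' @examples
#' klDistance(c(.5, .5), c(.9, .1))  # about 0.5108
#' @export
klDistance <- function(p, q) {
  if (length(p) != length(q))
    stop("histograms must share the same binning", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6)
    stop("histograms must be normalized to sum 1", call. = FALSE)
  ok <- p > 0
  if (any(q[ok] <= 0))
    stop("q has empty support where p > 0; apply smoothing to q", call. = FALSE)
  sum(p[ok] * log(p[ok] / q[ok]))
}

#' DBC prediction from class-correlation distributions
#'
#' For each test sample, per-class histograms of its correlations to the
#' (reference) training members are built (unsmoothed) and compared with
#' each candidate class's model profile: the candidate minimizing the
#' mean KL distance over classes is assigned. Classes contribute equally
#' to the decision statistic regardless of their abundance, which makes
#' DBC robust to class imbalance. Indistinguishable profiles are resolved
#' deterministically toward the first class in label order. DBC is
#' parameter-free at the user level.
#'
#' @param C a rectangular [CorrelationMatrix-class] (or matrix), test
#'   samples in rows, training samples in columns -- the same training
#'   set the distributions were built from.
#' @param labels class label per training column.
#' @param distributions a [ClassCorrelationDistributions-class].
#' @return factor of predicted labels.
#' @export
dbcPredict <- function(C, labels, distributions) {
  stopifnot(is(distributions, "ClassCorrelationDistributions"))
  entries <- if (is(C, "CorrelationMatrix")) C@entries else as.matrix(C)
  labels <- droplevels(as.factor(labels))
  if (length(labels) != ncol(entries))
    stop("one label per training column is required", call. = FALSE)
  lev <- distributions@classes
  if (!identical(levels(labels), lev))
    stop("distributions were built from a different class set", call. = FALSE)
  breaks <- distributions@breaks
  refCols <- lapply(lev, function(cl) which(labels == cl))
  pred <- apply(entries, 1, function(r) {
    ph <- lapply(seq_along(lev), function(j) {
      v <- r[refCols[[j]]]
      if (!any(is.finite(v)))
        stop("degenerate (empty) test histogram: no defined correlation to class ",
             lev[j], call. = FALSE)
      .corHist(v, breaks, pseudo = 0)
    })
    D <- vapply(seq_along(lev), function(ci) {
      mean(vapply(seq_along(lev), function(j)
        klDistance(ph[[j]], distributions@hist[ci, j, ]), numeric(1)))
    }, numeric(1))
    lev[which.min(D)]  # which.min: first class in label order on ties
  })
  factor(pred, levels = lev)
}

# Restrict a test-to-train correlation matrix and labels to the reference
# columns of a distribution object (F-DBC prediction path).
.dbcReferenceColumns <- function(distributions) {
  sort(unlist(distributions@references, use.names = FALSE))
}
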