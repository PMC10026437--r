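# Pairwise-deletion correlation engine.
#
# Pearson correlations over all sample pairs are assembled from five
# cross-products of the zero-filled data and the observation-indicator
# matrices, which yields, for every pair, the sums over exactly the
# features observed in BOTH samples. Spearman re-ranks each overlap
# (fractional ranks), so it falls back to a per-pair loop unless the data
# are complete.

# Relative tolerance below which an overlap subvector counts as constant.
.VAR_TOL <- 1e-12

.pearsonBlock <- function(A, B, minOverlap, symmetric = FALSE) {
  MA <- is.finite(A); MB <- is.finite(B)
  A0 <- ifelse(MA, A, 0); B0 <- ifelse(MB, B, 0)
  mA <- MA * 1; mB <- MB * 1
  n   <- tcrossprod(mA, mB)
  Sx  <- tcrossprod(A0, mB)
  Sy  <- tcrossprod(mA, B0)
  Sxy <- tcrossprod(A0, B0)
  Sxx <- tcrossprod(A0 * A0, mB)
  Syy <- tcrossprod(mA, B0 * B0)
  num <- n * Sxy - Sx * Sy
  dX  <- n * Sxx - Sx * Sx
  dY  <- n * Syy - Sy * Sy
  # a subvector is constant when its (scaled) variance vanishes relative
  # to its raw sum of squares
  constX <- dX <= .VAR_TOL * pmax(n * Sxx, 1)
  constY <- dY <= .VAR_TOL * pmax(n * Syy, 1)
  defined <- n >= minOverlap & !constX & !constY
  r <- matrix(NA_real_, nrow(A), nrow(B))
  r[defined] <- num[defined] / sqrt(dX[defined] * dY[defined])
  r[defined] <- pmin(pmax(r[defined], -1), 1)
  if (symmetric) {
    r <- (r + t(r)) / 2
    d <- diag(r); d[diag(defined)] <- 1; diag(r) <- d
    defined <- defined & t(defined)
  }
  .countCorrelations(nrow(A) * nrow(B))
  list(entries = r, defined = defined)
}

.rankRow <- function(x) rank(x, ties.method = "average")

.spearmanBlock <- function(A, B, minOverlap, symmetric = FALSE) {
  if (!anyNA(A) && !anyNA(B)) {
    # complete data: whole-row ranks equal per-pair overlap ranks
    Ar <- t(apply(A, 1, .rankRow)); Br <- t(apply(B, 1, .rankRow))
    if (nrow(A) == 1) Ar <- matrix(Ar, nrow = 1)
    if (nrow(B) == 1) Br <- matrix(Br, nrow = 1)
    return(.pearsonBlock(Ar, Br, minOverlap, symmetric))
  }
  n1 <- nrow(A); n2 <- nrow(B)
  r <- matrix(NA_real_, n1, n2)
  defined <- matrix(FALSE, n1, n2)
  for (i in seq_len(n1)) {
    jj <- if (symmetric) i:n2 else seq_len(n2)
    for (j in jj) {
      s <- .pairCor(A[i, ], B[j, ], "spearman", minOverlap)
      r[i, j] <- s
      defined[i, j] <- !is.na(s)
      if (symmetric && j != i) { r[j, i] <- s; defined[j, i] <- defined[i, j] }
    }
  }
  if (symmetric) { d <- diag(r); d[diag(defined)] <- 1; diag(r) <- d }
  .countCorrelations(n1 * n2)
  list(entries = r, defined = defined)
}

# Scalar pairwise-deletion correlation of two vectors; NA when undefined.
.pairCor <- function(x, y, method, minOverlap) {
  ok <- is.finite(x) & is.finite(y)
  m <- sum(ok)
  if (m < minOverlap) return(NA_real_)
  xs <- x[ok]; ys <- y[ok]
  if (method == "spearman") { xs <- .rankRow(xs); ys <- .rankRow(ys) }
  dx <- xs - mean(xs); dy <- ys - mean(ys)
  sxx <- sum(dx * dx); syy <- sum(dy * dy)
  if (sxx <= .VAR_TOL * max(sum(xs * xs), 1) ||
      syy <= .VAR_TOL * max(sum(ys * ys), 1)) return(NA_real_)
  min(max(sum(dx * dy) / sqrt(sxx * syy), -1), 1)
}

#' Pairwise-deletion correlation of two feature vectors
#'
#' Computes the correlation of two samples using only the features
#' observed (finite) in both. The result is undefined -- returned as
#' \code{NA}, never an error -- when the overlap has fewer than
#' \code{minOverlap} points or zero variance in either subvector. Spearman
#' ranks are recomputed on the overlap with fractional (average) ranks.
#'
#' @param x,y numeric vectors of equal length; non-finite entries are
#'   missing.
#' @param method "pearson" (default) or "spearman".
#' @param minOverlap minimum number of jointly observed features for the
#'   correlation to be defined (default 3).
#' @return a correlation in [-1, 1], or \code{NA} if undefined.
#' @examples
#' pairwiseCorrelation(c(1, 2, 3, NA), c(1, 2, 3, 10))   # exactly 1
#' pairwiseCorrelation(c(1, 2, 3), c(3, 2, 1))           # exactly -1
#' @export
pairwiseCorrelation <- function(x, y, method = c("pearson", "spearman"),
                                minOverlap = 3L) {
  method <- match.arg(method)
  if (length(x) != length(y))
    stop("'x' and 'y' must have the same length", call. = FALSE)
  if (length(x) < 1) stop("vectors must have length >= 1", call. = FALSE)
  minOverlap <- .assertScalarCount(minOverlap, "minOverlap")
  .countCorrelations(1)
  .pairCor(as.numeric(x), as.numeric(y), method, minOverlap)
}

#' Train correlation matrix under pairwise deletion
#'
#' All pairwise correlations between training samples. The result is
#' symmetric with unit diagonal wherever a sample has at least
#' \code{minOverlap} observed features of nonzero variance; undefined
#' entries are masked, never imputed.
#'
#' @param X an [OmicsMatrix-class] (or plain matrix) of training samples.
#' @param method "pearson" or "spearman".
#' @param minOverlap minimum pairwise overlap (default 3).
#' @return a square [CorrelationMatrix-class].
#' @examples
#' X <- omicsMatrix(matrix(rnorm(60), 6, 10))
#' trainCorrelationMatrix(X)
#' @export
trainCorrelationMatrix <- function(X, method = c("pearson", "spearman"),
                                   minOverlap = 3L) {
  method <- match.arg(method)
  if (!is(X, "OmicsMatrix")) X <- omicsMatrix(X)
  minOverlap <- .assertScalarCount(minOverlap, "minOverlap")
  v <- X@values
  blk <- if (method == "pearson") .pearsonBlock(v, v, minOverlap, symmetric = TRUE)
         else .spearmanBlock(v, v, minOverlap, symmetric = TRUE)
  dimnames(blk$entries) <- dimnames(blk$defined) <-
    list(rownames(v), rownames(v))
  new("CorrelationMatrix", entries = blk$entries, defined = blk$defined,
      method = method, minOverlap = minOverlap)
}

#' Test-to-train cross-correlation matrix
#'
#' Pairwise-deletion correlations between every test sample (rows) and
#' every training sample (columns). Both matrices must share the same
#' features in the same order.
#'
#' @param XTest,XTrain [OmicsMatrix-class] objects with identical
#'   \code{featureIDs}.
#' @inheritParams trainCorrelationMatrix
#' @return a rectangular [CorrelationMatrix-class], test samples in rows.
#' @export
crossCorrelationMatrix <- function(XTest, XTrain,
                                   method = c("pearson", "spearman"),
                                   minOverlap = 3L) {
  method <- match.arg(method)
  if (!is(XTest, "OmicsMatrix")) XTest <- omicsMatrix(XTest)
  if (!is(XTrain, "OmicsMatrix")) XTrain <- omicsMatrix(XTrain)
  if (!identical(colnames(XTest@values), colnames(XTrain@values)))
    stop("test and train matrices must share identical features in identical order",
         call. = FALSE)
  minOverlap <- .assertScalarCount(minOverlap, "minOverlap")
  a <- XTest@values; b <- XTrain@values
  blk <- if (method == "pearson") .pearsonBlock(a, b, minOverlap)
         else .spearmanBlock(a, b, minOverlap)
  dimnames(blk$entries) <- dimnames(blk$defined) <-
    list(rownames(a), rownames(b))
  new("CorrelationMatrix", entries = blk$entries, defined = blk$defined,
      method = method, minOverlap = minOverlap)
}
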