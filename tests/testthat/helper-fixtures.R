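# Shared fixtures, built in code at test time.

# The worked 4-sample toy correlation matrix (classes A, A, B, B).
toyCorrelationMatrix <- function() {
  C <- matrix(c(1.0, 0.8, 0.2, 0.4,
                0.8, 1.0, 0.3, 0.1,
                0.2, 0.3, 1.0, 0.6,
                0.4, 0.1, 0.6, 1.0), 4, 4, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  new("CorrelationMatrix", entries = C, defined = matrix(TRUE, 4, 4),
      method = "pearson", minOverlap = 3L)
}

toyLabels <- function() factor(c("A", "A", "B", "B"))

# Random matrix with controlled missingness for oracle comparisons.
randomMissingMatrix <- function(n, p, fMissing, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  if (fMissing > 0) X[matrix(runif(n * p) < fMissing, n, p)] <- NA
  # guarantee >= 1 observed feature per sample
  bad <- rowSums(is.finite(X)) == 0
  X[bad, 1] <- rnorm(sum(bad))
  rownames(X) <- paste0("S", seq_len(n))
  colnames(X) <- paste0("F", seq_len(p))
  X
}

# Independent per-pair oracle: stats::cor on the extracted overlap.
oraclePairCor <- function(x, y, method = "pearson", minOverlap = 3) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < minOverlap) return(NA_real_)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  suppressWarnings(stats::cor(x[ok], y[ok], method = method))
}

# Small separable dataset: zero feature noise, default centers.
separableDataset <- function(sizes = c(A = 10, B = 10, C = 10),
                             nFeatures = 300, seed = 21) {
  generateDataset(simulationConfig(nFeatures = nFeatures,
                                   classSizes = sizes, sigmaFeature = 0,
                                   missingFraction = 0, seed = seed))
}
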