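# D'Agostino-Pearson omnibus normality test.
#
# Combines the D'Agostino (1970) skewness z-test with the Anscombe-Glynn
# (1983) kurtosis z-test into the K^2 = z1^2 + z2^2 statistic, chi-square
# with 2 df under normality. Sample-moment conventions follow the common
# omnibus-test definition (biased moment estimators g1, g2).

.skewTestZ <- function(x) {
  n <- length(x)
  if (n < 8) stop("skewness test requires n >= 8", call. = FALSE)
  d <- x - mean(x)
  m2 <- mean(d^2); m3 <- mean(d^3)
  b1 <- m3 / m2^1.5
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(W2))
  alpha <- sqrt(2 / (W2 - 1))
  delta * asinh(y / alpha)
}

.kurtTestZ <- function(x) {
  n <- length(x)
  if (n < 5) stop("kurtosis test requires n >= 5", call. = FALSE)
  d <- x - mean(x)
  m2 <- mean(d^2); m4 <- mean(d^4)
  b2 <- m4 / m2^2
  Eb2 <- 3 * (n - 1) / (n + 1)
  varb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  z <- (b2 - Eb2) / sqrt(varb2)
  sqrtBeta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqrtBeta1 * (2 / sqrtBeta1 + sqrt(1 + 4 / sqrtBeta1^2))
  denom <- 1 + z * sqrt(2 / (A - 4))
  term <- sign(denom) * (abs((1 - 2 / A) / denom))^(1 / 3)
  ((1 - 2 / (9 * A)) - term) / sqrt(2 / (9 * A))
}

#' D'Agostino-Pearson omnibus test of normality
#'
#' Tests departure from normality via standardized sample skewness and
#' kurtosis: K-squared = z1^2 + z2^2 is chi-square distributed with 2
#' degrees of freedom under the null of a normal population.
#'
#' @param x numeric vector, n >= 20 recommended (n >= 8 required).
#' @return list with elements \code{statistic} (K-squared) and \code{p}.
#' @examples
#' set.seed(1)
#' dagostinoPearsonTest(rnorm(200))$p    # typically > 0.05
#' dagostinoPearsonTest(rexp(200))$p     # typically << 0.05
#' @export
dagostinoPearsonTest <- function(x) {
  x <- x[is.finite(x)]
  z1 <- .skewTestZ(x)
  z2 <- .kurtTestZ(x)
  k2 <- z1^2 + z2^2
  list(statistic = k2, p = stats::pchisq(k2, df = 2, lower.tail = FALSE))
}
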