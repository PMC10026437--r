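# Interchangeable baseline classifiers for the ACF feature table.
#
# The three conventional baselines are a support-vector classifier
# (e1071), a random forest (ranger) and a ridge classifier (closed-form
# regularized least squares on one-hot +-1 targets, intercept
# unpenalized). Each entry defines default parameters, a fit and a
# predict routine on a plain data.frame of features. Covariates are
# passed unscaled; users of scale-sensitive baselines (the SVC in
# particular) should pre-standardize covariates living on very different
# scales than correlations.

.BASELINES <- c("svc", "rf", "ridge")

.normalizeBaseline <- function(baseline) {
  if (is.character(baseline) && length(baseline) == 1)
    baseline <- list(name = baseline, params = list())
  if (!is.list(baseline) || is.null(baseline$name))
    stop("baseline must be a name or list(name=, params=)", call. = FALSE)
  if (!baseline$name %in% .BASELINES)
    stop(sprintf("unknown baseline '%s' (supported: %s)", baseline$name,
                 paste(.BASELINES, collapse = ", ")), call. = FALSE)
  if (is.null(baseline$params)) baseline$params <- list()
  baseline$params <- utils::modifyList(.defaultParams(baseline$name),
                                       baseline$params)
  baseline
}

.defaultParams <- function(name) {
  switch(name,
    svc   = list(kernel = "rbf", C = 1, gamma = "scale", classWeights = "none"),
    rf    = list(numTrees = 150L, maxDepth = 20L, mtry = NULL,
                 classWeights = "none"),
    ridge = list(alpha = 1, classWeights = "none"))
}

.balancedWeights <- function(y) {
  tab <- table(y)
  w <- length(y) / (nlevels(y) * tab)
  stats::setNames(as.numeric(w), names(tab))
}

.fitBaseline <- function(baseline, X, y, seed = 1L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  p <- baseline$params
  balanced <- identical(p$classWeights, "balanced")
  switch(baseline$name,
    svc = {
      gamma <- if (identical(p$gamma, "auto")) 1 / ncol(X)
               else 1 / (ncol(X) * max(stats::var(as.vector(X)), 1e-12))
      e1071::svm(X, y,
                 kernel = if (identical(p$kernel, "linear")) "linear" else "radial",
                 cost = p$C, gamma = gamma, scale = FALSE,
                 class.weights = if (balanced) .balancedWeights(y) else NULL)
    },
    rf = {
      mtry <- if (is.null(p$mtry)) max(1L, floor(sqrt(ncol(X))))
              else min(as.integer(p$mtry), ncol(X))
      df <- data.frame(X, check.names = FALSE)
      df$.class <- y
      ranger::ranger(dependent.variable.name = ".class", data = df,
                     num.trees = as.integer(p$numTrees),
                     max.depth = as.integer(p$maxDepth), mtry = mtry,
                     class.weights = if (balanced)
                       as.numeric(.balancedWeights(y)[levels(y)]) else NULL,
                     seed = seed, num.threads = 1L)
    },
    ridge = .ridgeFit(X, y, alpha = p$alpha,
                      weights = if (balanced)
                        as.numeric(.balancedWeights(y)[y]) else NULL))
}

.predictBaseline <- function(baseline, fit, X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  switch(baseline$name,
    svc = stats::predict(fit, X),
    rf = {
      df <- data.frame(X, check.names = FALSE)
      stats::predict(fit, data = df, num.threads = 1L)$predictions
    },
    ridge = .ridgePredict(fit, X))
}

# Ridge classifier: regularized least squares on {-1, +1} one-hot targets,
# prediction by argmax of the linear scores. Optional per-sample weights
# implement balanced class weights.
.ridgeFit <- function(X, y, alpha, weights = NULL) {
  lev <- levels(y)
  Y <- matrix(-1, nrow(X), length(lev), dimnames = list(NULL, lev))
  Y[cbind(seq_along(y), as.integer(y))] <- 1
  Xa <- cbind(`(Intercept)` = 1, X)
  if (is.null(weights)) weights <- rep(1, nrow(X))
  Xw <- Xa * weights
  G <- crossprod(Xw, Xa)
  pen <- diag(c(0, rep(alpha, ncol(X))))  # intercept unpenalized
  W <- solve(G + pen, crossprod(Xw, Y))
  list(coef = W, levels = lev)
}

.ridgePredict <- function(fit, X) {
  sc <- cbind(1, X) %*% fit$coef
  factor(fit$levels[max.col(sc, ties.method = "first")], levels = fit$levels)
}
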