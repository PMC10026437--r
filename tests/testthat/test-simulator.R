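# Data-generating process and its diagnostics.

test_that("correlated centers approximate the requested correlation matrix", {
  cen <- correlatedCenters(defaultCenters(), 10000, seed = 3)
  emp <- cor(t(cen))
  expect_lt(abs(emp["A", "B"] - 0.9), 0.03)
  expect_lt(abs(emp["A", "C"] - 0.6), 0.03)
  expect_lt(abs(emp["B", "C"] - 0.8), 0.03)
  # identity: near-zero empirical correlations
  cenI <- correlatedCenters(diag(3), 10000, seed = 4)
  empI <- cor(t(cenI))
  expect_lt(max(abs(empI[upper.tri(empI)])), 0.05)
  # tiny feature count runs (documented boundary), non-PD errors
  expect_silent(correlatedCenters(defaultCenters(), 2, seed = 1))
  bad <- matrix(c(1, 1, 1, 1), 2, 2)
  expect_error(correlatedCenters(bad, 10, seed = 1), "positive definite")
})

test_that("zero-noise datasets duplicate their centers with unit intra-class correlation", {
  d <- separableDataset(sizes = c(A = 4, B = 4, C = 4), seed = 15)
  X <- values(datasetMatrix(d))
  expect_equal(unname(X[1, ]), unname(d@centers["A", ]))
  cm <- corValues(trainCorrelationMatrix(datasetMatrix(d)))
  intra <- cm[1:4, 1:4]
  expect_equal(unname(intra), matrix(1, 4, 4))
})

test_that("MCAR injection hits the configured fraction and the covariate its centers", {
  cfg <- simulationConfig(nFeatures = 10000,
                          classSizes = c(A = 10, B = 10, C = 10),
                          missingFraction = 0.3, covariate = "default",
                          seed = 90)
  d <- generateDataset(cfg)
  expect_lt(abs(missingFraction(datasetMatrix(d)) - 0.3), 0.01)
  cov <- datasetCovariate(d)
  centers <- c(A = 0.15, B = 0.2, C = 0.25)
  for (cl in names(centers)) {
    v <- cov[datasetLabels(d) == cl]
    se <- 0.015 / sqrt(length(v))
    expect_lt(abs(mean(v) - centers[[cl]]), 3 * se + 1e-9)
  }
})

test_that("identical configs give bit-identical datasets", {
  cfg <- simulationConfig(nFeatures = 300, classSizes = c(A = 5, B = 5, C = 5),
                          missingFraction = 0.4, covariate = "default",
                          seed = 42)
  d1 <- generateDataset(cfg); d2 <- generateDataset(cfg)
  expect_identical(values(datasetMatrix(d1)), values(datasetMatrix(d2)))
  expect_identical(datasetCovariate(d1), datasetCovariate(d2))
})

test_that("block statistics reproduce the toy block mean and degenerate SDs", {
  bs <- blockStats(toyCorrelationMatrix(), toyLabels())
  expect_equal(bs$mean[bs$classA == "A" & bs$classB == "B"], 0.25)
  d <- separableDataset(sizes = c(A = 4, B = 4, C = 4), seed = 2)
  bs0 <- blockStats(trainCorrelationMatrix(datasetMatrix(d)),
                    datasetLabels(d))
  expect_true(all(bs0$sd < 1e-8))
})

test_that("block SDs increase with the missing fraction (paired replicates)", {
  wins <- 0L
  for (s in 1:10) {
    base <- simulationConfig(nFeatures = 4000,
                             classSizes = c(A = 10, B = 10, C = 10),
                             sigmaFeature = 2, missingFraction = 0.1,
                             seed = 500 + s)
    hi <- base; hi@missingFraction <- 0.5
    sdLo <- mean(blockStats(trainCorrelationMatrix(
      datasetMatrix(generateDataset(base))), rep(c("A", "B", "C"), each = 10))$sd)
    sdHi <- mean(blockStats(trainCorrelationMatrix(
      datasetMatrix(generateDataset(hi))), rep(c("A", "B", "C"), each = 10))$sd)
    if (sdLo < sdHi) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("relative noise follows its definition and picks the most-correlated pair", {
  stats <- data.frame(classA = c("A", "A", "A", "B", "B", "C"),
                      classB = c("A", "B", "C", "B", "C", "C"),
                      mean = c(0.2, 0.18, 0.12, 0.2, 0.16, 0.2),
                      sd = rep(0.05, 6), n = 100)
  expect_equal(relativeNoise(stats), 0.05 / (0.2 - 0.18))
  expect_equal(relativeNoise(stats, "A", "C"), 0.05 / (0.2 - 0.12))
  stats0 <- stats; stats0$sd <- 0
  expect_equal(relativeNoise(stats0), 0)
  statsEq <- stats; statsEq$mean <- 0.2
  expect_error(relativeNoise(statsEq), "coincide")
})

test_that("missing-fraction calibration is monotone and hits its target", {
  cfg <- simulationConfig(nFeatures = 10000,
                          classSizes = c(A = 50, B = 50, C = 50),
                          sigmaFeature = 2, seed = 7)
  expect_equal(as.numeric(calibrateMissingFraction(cfg, 0, seed = 1)), 0)
  fs <- vapply(c(1.5, 2.2, 2.9), function(t)
    as.numeric(calibrateMissingFraction(cfg, t, tolerance = 0.12, seed = 2)),
    numeric(1))
  expect_true(all(diff(fs) > 0))
  # regenerate at the calibrated fraction with fresh seeds; the mean
  # measured relative noise (3 datasets, controlling Monte-Carlo error)
  # must stay near the target
  srs <- vapply(1:3, function(s) {
    cfg2 <- cfg; cfg2@missingFraction <- fs[3]; cfg2@seed <- 990L + s
    d <- generateDataset(cfg2)
    relativeNoise(blockStats(trainCorrelationMatrix(datasetMatrix(d)),
                             datasetLabels(d)))
  }, numeric(1))
  expect_lt(abs(mean(srs) - 2.9), 0.3)
  cfgSmall <- simulationConfig(nFeatures = 2000,
                               classSizes = c(A = 15, B = 15, C = 15),
                               sigmaFeature = 2, seed = 7)
  expect_error(calibrateMissingFraction(cfgSmall, 500, seed = 3),
               "unachievable|measurable")
})

test_that("the omnibus normality test matches its reference implementation", {
  # frozen oracle values (scipy.stats.normaltest on the same vectors)
  t1 <- dagostinoPearsonTest((1:30)^1.5)
  expect_equal(t1$statistic, 5.064157813283076, tolerance = 1e-12)
  expect_equal(t1$p, 0.07949358863762432, tolerance = 1e-12)
  t2 <- dagostinoPearsonTest(sin(1:40))
  expect_equal(t2$statistic, 29.726817367994965, tolerance = 1e-12)
  expect_equal(t2$p, 3.506740476883423e-07, tolerance = 1e-10)
})

test_that("the normality test is calibrated and has power", {
  set.seed(33)
  pGauss <- replicate(200, dagostinoPearsonTest(rnorm(80))$p)
  expect_lt(mean(pGauss < 0.05), 0.12)     # near-nominal rejection
  pExp <- replicate(50, dagostinoPearsonTest(rexp(80))$p)
  expect_gt(mean(pExp < 0.05), 0.9)        # strongly skewed: rejected
})

test_that("block residuals look Gaussian at low means, non-Gaussian near the boundary", {
  lowRej <- 0L; hiRej <- 0L; nBlocks <- 0L
  for (s in 1:3) {
    low <- generateDataset(simulationConfig(nFeatures = 4000,
      classSizes = c(A = 12, B = 12, C = 12), sigmaFeature = 2,
      missingFraction = 0.3, seed = 700 + s))
    rn <- residualNormality(trainCorrelationMatrix(datasetMatrix(low)),
                            datasetLabels(low))
    lowRej <- lowRej + sum(rn$p < 0.05); nBlocks <- nBlocks + nrow(rn)
    hiCfg <- simulationConfig(nFeatures = 4000,
      classSizes = c(A = 12, B = 12, C = 12), sigmaFeature = 0.05,
      missingFraction = 0.3, seed = 700 + s)
    hi <- generateDataset(hiCfg)
    rnHi <- residualNormality(trainCorrelationMatrix(datasetMatrix(hi)),
                              datasetLabels(hi))
    hiRej <- hiRej + sum(rnHi$p < 0.05)
  }
  expect_lt(lowRej / nBlocks, 0.35)
  expect_gt(hiRej, lowRej)
})

test_that("sigmaFeature rescales block means but not block SDs", {
  sizes <- c(A = 12, B = 12, C = 12)
  labs <- rep(c("A", "B", "C"), each = 12)
  for (f in c(0, 0.2)) {
    b2 <- blockStats(trainCorrelationMatrix(datasetMatrix(generateDataset(
      simulationConfig(nFeatures = 10000, classSizes = sizes, sigmaFeature = 2,
                       missingFraction = f, seed = 811)))), labs)
    b3 <- blockStats(trainCorrelationMatrix(datasetMatrix(generateDataset(
      simulationConfig(nFeatures = 10000, classSizes = sizes, sigmaFeature = 3,
                       missingFraction = f, seed = 811)))), labs)
    # attenuation 1/(1+9) vs 1/(1+4): means scale by 0.5
    expect_equal(b3$mean, b2$mean * 0.5, tolerance = 0.12)
    if (f > 0)
      expect_lt(abs(mean(b3$sd) - mean(b2$sd)) / mean(b2$sd), 0.25)
  }
})
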