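# Evaluation protocol: macro-F1, stratified CV, tuning, corrected t-test,
# variable importance.

test_that("macro-F1 matches hand-computed examples", {
  expect_equal(macroF1(c("A", "A"), c("A", "A")), 1.0)
  expect_equal(macroF1(c("A", "A", "B", "B"), c("A", "B", "B", "B")),
               (2 / 3 + 4 / 5) / 2, tolerance = 1e-12)
  expect_equal(macroF1(c("A", "B"), c("B", "A")), 0.0)
  expect_error(macroF1(character(0), character(0)), "empty")
})

test_that("macro-F1 is invariant under class relabeling", {
  set.seed(12)
  for (rep in 1:20) {
    yt <- sample(c("A", "B", "C"), 30, replace = TRUE)
    yp <- sample(c("A", "B", "C"), 30, replace = TRUE)
    perm <- setNames(sample(c("X", "Y", "Z")), c("A", "B", "C"))
    expect_equal(macroF1(yt, yp), macroF1(perm[yt], perm[yp]),
                 tolerance = 1e-12)
  }
})

test_that("the harmonic macro variant differs on asymmetric errors", {
  yt <- c("A", "A", "A", "B"); yp <- c("A", "A", "B", "B")
  m <- macroF1(yt, yp)
  h <- macroF1(yt, yp, average = "harmonic")
  expect_false(isTRUE(all.equal(m, h)))
  expect_equal(macroF1(yt, yt, average = "harmonic"), 1)
})

test_that("stratified folds preserve class frequencies within one sample", {
  labs <- factor(rep(c("A", "B", "C"), c(40, 25, 15)))
  folds <- stratifiedFolds(labs, 5, seed = 6)
  for (fd in 1:5) for (cl in levels(labs)) {
    inFold <- sum(labs[folds == fd] == cl)
    expect_lte(abs(inFold - sum(labs == cl) / 5), 1)
  }
  expect_error(stratifiedFolds(factor(rep(c("A", "B"), c(30, 3))), 5),
               "smaller k")
})

test_that("a constant majority-class predictor scores as computed by hand", {
  # labels {A x 8, B x 2}, k = 2: each fold tests 4 A + 1 B;
  # per fold macro-F1 = (8/9 + 0) / 2 = 4/9
  labs <- factor(rep(c("A", "B"), c(8, 2)))
  folds <- stratifiedFolds(labs, 2, seed = 3)
  scores <- vapply(1:2, function(fd) {
    yt <- labs[folds == fd]
    macroF1(yt, factor(rep("A", length(yt)), levels = c("A", "B")),
            labels = c("A", "B"))
  }, numeric(1))
  expect_equal(mean(scores), 4 / 9, tolerance = 1e-12)
  rep1 <- corrACF:::.classReport(labs[folds == 1],
                                 rep("A", 5), c("A", "B"))
  expect_equal(rep1$f1, c(8 / 9, 0))
})

test_that("repeated CV has the right shape and never leaks test folds into tuning", {
  d <- generateDataset(simulationConfig(nFeatures = 300,
    classSizes = c(A = 12, B = 12, C = 12), sigmaFeature = 2,
    missingFraction = 0.2, seed = 3))
  cfg <- cvConfig(k = 4, repetitions = 2, nTrials = 3, nValidationSets = 2,
                  seed = 11)
  res <- repeatedStratifiedCV(d, acfEstimator("ridge"), config = cfg,
                              audit = TRUE)
  expect_equal(nrow(res@scores), 4 * 2)
  expect_true(all(res@scores$macroF1 >= 0 & res@scores$macroF1 <= 1))
  expect_equal(length(repMeans(res)), 2)
  # leakage audit: HPO indices never intersect the held-out fold
  for (entry in res@audit) {
    expect_length(intersect(entry$testIdx, entry$hpoIdx), 0)
    expect_setequal(c(entry$testIdx, entry$hpoIdx), seq_len(36))
  }
})

test_that("CV is reproducible under its master seed", {
  d <- generateDataset(simulationConfig(nFeatures = 200,
    classSizes = c(A = 8, B = 8, C = 8), sigmaFeature = 1,
    missingFraction = 0.1, seed = 5))
  cfg <- cvConfig(k = 3, repetitions = 2, nTrials = 2, nValidationSets = 2,
                  seed = 21)
  r1 <- repeatedStratifiedCV(d, knnEstimator(), config = cfg)
  r2 <- repeatedStratifiedCV(d, knnEstimator(), config = cfg)
  expect_identical(r1@scores$macroF1, r2@scores$macroF1)
  expect_identical(r1@scores$params, r2@scores$params)
})

test_that("hyperparameter search finds the winning configuration", {
  d <- separableDataset(sizes = c(A = 12, B = 12, C = 12), seed = 9)
  # separable data: the tuned SVC must reach a perfect validation score
  tuned <- tuneHyperparameters(acfEstimator("svc"), d, nTrials = 6,
                               nValidationSets = 2, seed = 2)
  expect_equal(tuned$score, 1.0)
  expect_length(tuned$trials, 6)
  # determinism: identical seed, identical trial sequence and winner
  tuned2 <- tuneHyperparameters(acfEstimator("svc"), d, nTrials = 6,
                                nValidationSets = 2, seed = 2)
  expect_identical(tuned$best, tuned2$best)
  expect_identical(vapply(tuned$trials, `[[`, 0, "score"),
                   vapply(tuned2$trials, `[[`, 0, "score"))
})

test_that("a single-point space returns that point", {
  d <- separableDataset(sizes = c(A = 8, B = 8, C = 8), seed = 14)
  space <- list(list(name = "K", type = "choice", values = 3L),
                list(name = "weights", type = "choice", values = "uniform"))
  tuned <- tuneHyperparameters(knnEstimator(), d, nTrials = 1,
                               nValidationSets = 2, seed = 5, space = space)
  expect_equal(tuned$best$K, 3L)
  expect_equal(tuned$best$weights, "uniform")
})

test_that("the search space bounds are as specified", {
  sp <- defaultSearchSpace(acfEstimator("svc"), nTrain = 100)
  C <- sp[[which(vapply(sp, `[[`, "", "name") == "C")]]
  expect_equal(c(C$lo, C$hi), c(5e-3, 5e2))
  sp <- defaultSearchSpace(acfEstimator("rf"), nTrain = 100)
  trees <- sp[[which(vapply(sp, `[[`, "", "name") == "numTrees")]]
  expect_equal(c(trees$lo, trees$hi), c(80L, 300L))
  depth <- sp[[which(vapply(sp, `[[`, "", "name") == "maxDepth")]]
  expect_equal(c(depth$lo, depth$hi), c(2L, 40L))
  sp <- defaultSearchSpace(acfEstimator("ridge"), nTrain = 100)
  alpha <- sp[[which(vapply(sp, `[[`, "", "name") == "alpha")]]
  expect_equal(c(alpha$lo, alpha$hi), c(1e-3, 1e4))
  sp <- defaultSearchSpace(knnEstimator(), nTrain = 135)
  K <- sp[[which(vapply(sp, `[[`, "", "name") == "K")]]
  expect_equal(c(K$lo, K$hi), c(1L, 135L))
  expect_length(defaultSearchSpace(dbcEstimator(), nTrain = 100), 0)
})

test_that("the corrected paired t-test behaves as specified", {
  s <- c(0.8, 0.85, 0.9, 0.8)
  eq <- correctedPairedTTest(s, s, nTrain = 90, nTest = 10)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p, 1)   # zero variance, zero mean difference convention
  a <- c(0.9, 0.85, 0.92, 0.88, 0.91); b <- c(0.8, 0.82, 0.85, 0.8, 0.83)
  res <- correctedPairedTTest(a, b, nTrain = 90, nTest = 10)
  tStd <- t.test(a, b, paired = TRUE, alternative = "greater")
  expect_lt(abs(res$statistic), abs(tStd$statistic))  # correction shrinks t
  expect_gt(res$p, tStd$p.value)
  # equally performing methods (mean-zero paired differences): t = 0, p = 0.5
  diffs <- rep(c(0.001, -0.001), 5)
  sym <- correctedPairedTTest(0.8 + diffs, rep(0.8, 10), 90, 10)
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p, 0.5)
  # identical score vectors: documented zero-variance convention
  expect_equal(correctedPairedTTest(0.8 + diffs, 0.8 + diffs, 90, 10)$p, 1)
  # Bonferroni capping
  capped <- correctedPairedTTest(c(0.8, 0.81), c(0.8, 0.80), 90, 10,
                                 nComparisons = 10)
  expect_lte(capped$pAdjusted, 1)
  expect_equal(min(1, capped$p * 10), capped$pAdjusted)
})

test_that("class-wise importance flags discriminative columns, not constants", {
  d <- separableDataset(sizes = c(A = 10, B = 10, C = 10), seed = 30)
  const <- data.frame(dummy = rep(1, 30),
                      row.names = sampleIDs(datasetMatrix(d)))
  imp <- classwiseImportance(datasetMatrix(d), datasetLabels(d),
                             covariates = const, useCovariate = TRUE,
                             config = cvConfig(k = 3, repetitions = 2,
                                               seed = 8))
  expect_equal(dim(imp), c(3L, 4L))
  expect_true(all(abs(imp[, "dummy"]) < 1e-8))
})

test_that("a discriminative cross-correlation earns positive importance", {
  # construct blocks where A and B coincide in mu_A, mu_B and only the
  # correlation to C separates them
  set.seed(44)
  labs <- factor(rep(c("A", "B", "C"), each = 10))
  mu <- rbind(A = c(A = 0.2, B = 0.2, C = 0.08),
              B = c(A = 0.2, B = 0.2, C = 0.32),
              C = c(A = 0.08, B = 0.32, C = 0.2))
  R <- mu[labs, labs] + matrix(rnorm(900, 0, 0.02), 30, 30)
  R <- (R + t(R)) / 2; diag(R) <- 1
  dimnames(R) <- list(paste0("S", 1:30), paste0("S", 1:30))
  cm <- new("CorrelationMatrix", entries = pmin(pmax(R, -1), 1),
            defined = matrix(TRUE, 30, 30), method = "pearson",
            minOverlap = 3L)
  imp <- classwiseImportance(matrix(0, 30, 2,
                                    dimnames = list(rownames(R), NULL)),
                             labs, corMatrix = cm,
                             config = cvConfig(k = 3, repetitions = 2,
                                               seed = 9))
  expect_gt(max(imp[c("A", "B"), "mu_C"]), 0)
})
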