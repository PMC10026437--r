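# ACF estimator: class-wise averages, reference subsampling, bias masks.

test_that("classwise averages reproduce the hand-computed toy values", {
  ft <- classwiseAverages(toyCorrelationMatrix(), toyLabels(),
                          excludeSelf = TRUE)
  f <- ft@features
  expect_equal(unname(f["s1", ]), c(0.8, 0.3))          # mu_A, mu_B
  expect_equal(unname(f["s3", ]), c((0.2 + 0.3) / 2, 0.6))
  # prediction-side (no self exclusion)
  ftp <- classwiseAverages(toyCorrelationMatrix(), toyLabels())
  expect_equal(unname(ftp@features["s1", "mu_A"]), (1 + 0.8) / 2)
})

test_that("a single-member class with self exclusion is a hard error naming the cell", {
  cm <- toyCorrelationMatrix()
  labs <- factor(c("A", "B", "B", "B"))
  expect_error(classwiseAverages(cm, labs, excludeSelf = TRUE),
               "sample 's1'.*class 'A'")
})

test_that("bias masks remove entries from the averages", {
  mask <- matrix(FALSE, 4, 4)
  mask[1, 3] <- TRUE   # omit (s1, s3)
  ft <- classwiseAverages(toyCorrelationMatrix(), toyLabels(),
                          excludeSelf = TRUE, mask = mask)
  expect_equal(unname(ft@features["s1", "mu_B"]), 0.4)  # only s4 contributes
  # undefined correlations are skipped like masked ones, not zero-filled
  cm <- toyCorrelationMatrix()
  cm@entries[1, 3] <- NA; cm@defined[1, 3] <- FALSE
  ft2 <- classwiseAverages(cm, toyLabels(), excludeSelf = TRUE)
  expect_equal(unname(ft2@features["s1", "mu_B"]), 0.4)
})

test_that("a fully masked class average errors rather than imputing", {
  mask <- matrix(FALSE, 4, 4); mask[1, 3] <- mask[1, 4] <- TRUE
  expect_error(classwiseAverages(toyCorrelationMatrix(), toyLabels(),
                                 excludeSelf = TRUE, mask = mask),
               "s1.*class 'B'")
})

test_that("selectReferences follows the min(nRef, class size) rule and is seeded", {
  labs <- factor(rep(c("A", "B", "C"), c(70, 30, 50)))
  refs <- selectReferences(labs, 10, seed = 4)
  expect_equal(lengths(refs), c(A = 10L, B = 10L, C = 10L))
  expect_identical(refs, selectReferences(labs, 10, seed = 4))
  refsAll <- selectReferences(labs, 100, seed = 4)
  expect_equal(lengths(refsAll), c(A = 70L, B = 30L, C = 50L))
  expect_equal(refsAll$B, which(labs == "B"))
  for (cl in levels(labs)) expect_true(all(labs[refs[[cl]]] == cl))
})

test_that("sameBatchMask marks exactly the within-batch off-diagonal pairs", {
  m <- sameBatchMask(c(1, 1, 2, 2))
  expect_equal(sum(m), 4)
  expect_true(all(m[1, 2] && m[2, 1] && m[3, 4] && m[4, 3]))
  expect_false(any(diag(m)))
  expect_equal(m, t(m))
  # empty batch info: all-false mask
  expect_false(any(sameBatchMask(NULL, n = 5)))
  # rectangular test-to-train variant
  r <- sameBatchMask(c("x", "y"), colBatches = c("x", "x", "y"))
  expect_equal(r, rbind(c(TRUE, TRUE, FALSE), c(FALSE, FALSE, TRUE)))
})

test_that("ACF memorizes a separable dataset and a toy table", {
  d <- separableDataset()
  m <- acfFit(datasetMatrix(d), datasetLabels(d), baseline = "svc", seed = 2)
  expect_equal(unname(acfPredict(m, datasetMatrix(d))),
               unname(datasetLabels(d)))
  # maximum-depth tree-ensemble baseline memorizes the 4-sample toy
  X <- randomMissingMatrix(4, 50, 0, seed = 31)
  labs <- toyLabels()
  mt <- acfFit(X, labs, baseline = list(name = "rf",
                                        params = list(numTrees = 200,
                                                      maxDepth = 30)),
               seed = 7)
  expect_equal(as.character(acfPredict(mt, X)), as.character(labs))
})

test_that("F-ACF with nRef >= class sizes is identical to plain ACF", {
  d <- separableDataset(sizes = c(A = 6, B = 6, C = 6), seed = 41)
  X <- datasetMatrix(d); labs <- datasetLabels(d)
  m1 <- acfFit(X, labs, baseline = "svc", seed = 3)
  m2 <- acfFit(X, labs, baseline = "svc", nRef = 50, seed = 3)
  expect_identical(m1@fit$SV, m2@fit$SV)
  expect_identical(acfPredict(m1, X), acfPredict(m2, X))
})

test_that("B-ACF with an all-false mask is identical to ACF", {
  X <- randomMissingMatrix(12, 60, 0.2, seed = 55)
  labs <- factor(rep(c("A", "B"), each = 6))
  m0 <- acfFit(X, labs, baseline = "ridge", seed = 9)
  m1 <- acfFit(X, labs, baseline = "ridge",
               biasMask = matrix(FALSE, 12, 12), seed = 9)
  expect_identical(m0@fit$coef, m1@fit$coef)
  expect_identical(acfPredict(m0, X), acfPredict(m1, X))
})

test_that("same-batch masking changes training features exactly as the mask dictates", {
  X <- randomMissingMatrix(8, 100, 0.1, seed = 66)
  labs <- factor(rep(c("A", "B"), each = 4))
  batches <- rep(c("b1", "b2"), 4)
  cm <- trainCorrelationMatrix(X)
  ftMasked <- classwiseAverages(cm, labs, excludeSelf = TRUE,
                                mask = sameBatchMask(batches))
  # hand-recompute one cell: s1 (A, b1) to class B excludes b1 members of B
  bCols <- which(labs == "B")
  keep <- bCols[batches[bCols] != "b1"]
  expect_equal(unname(ftMasked@features[1, "mu_B"]),
               mean(corValues(cm)[1, keep]))
})

test_that("F-ACF computes a fixed number of correlations per prediction", {
  for (nTrain in c(30, 60)) {
    sizes <- stats::setNames(rep(nTrain / 3, 3), c("A", "B", "C"))
    d <- generateDataset(simulationConfig(nFeatures = 200,
                                          classSizes = sizes,
                                          sigmaFeature = 1,
                                          missingFraction = 0.1,
                                          seed = nTrain))
    m <- acfFit(datasetMatrix(d), datasetLabels(d), baseline = "ridge",
                nRef = 5, seed = 1)
    XTest <- datasetMatrix(d)[1:4, ]
    resetCorrelationCount()
    acfPredict(m, XTest)
    expect_equal(correlationCount() / 4, 3 * 5)  # independent of nTrain
  }
})

test_that("fitted models round-trip exactly through serialization", {
  d <- separableDataset(sizes = c(A = 5, B = 5, C = 5), seed = 77)
  m <- acfFit(datasetMatrix(d), datasetLabels(d), baseline = "ridge",
              nRef = 3, seed = 13)
  path <- tempfile(fileext = ".rds")
  saveRDS(m, path)
  m2 <- readRDS(path)
  expect_equal(m, m2)
  expect_identical(acfPredict(m, datasetMatrix(d)),
                   acfPredict(m2, datasetMatrix(d)))
  unlink(path)
})

test_that("degenerate inputs are rejected with informative errors", {
  X <- randomMissingMatrix(4, 20, 0, seed = 1)
  expect_error(acfFit(X, factor(c("A", "A", "A", "B"))), "fewer than 2")
  expect_error(acfFit(X, factor(rep("A", 4))), "at least 2 classes")
  d <- separableDataset(sizes = c(A = 5, B = 5, C = 5), seed = 8)
  m <- acfFit(datasetMatrix(d), datasetLabels(d),
              covariates = data.frame(
                age = seq_len(15),
                row.names = sampleIDs(datasetMatrix(d))))
  expect_error(acfPredict(m, datasetMatrix(d)), "covariates")
})
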