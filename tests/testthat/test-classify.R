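test_that("the pipeline fits separable data perfectly and guards collinearity", {
  te <- makeSeparableTable(1)
  model <- fitPipeline(te, featureSubset(c("FOS_Mean", "FOS_Variance")))
  pr <- predict(model, te)
  expect_equal(mean(pr$class == imageLabels(te)), 1.0)
  # duplicated feature columns leave the decision function unchanged
  mat <- featureMatrix(te)
  dup <- rbind(mat, mat["FOS_Mean", , drop = FALSE])
  rownames(dup)[3] <- "FOS_Skewness"
  te2 <- textureExperiment(dup, imageLabels(te))
  m2 <- fitPipeline(te2, featureSubset(rownames(dup)))
  pr2 <- predict(m2, te2)
  expect_equal(pr2$class, pr$class)
  # a subset feature absent from the table is a validation error
  expect_error(fitPipeline(te, featureSubset("GLCM_Contrast")), "missing")
})

test_that("macro ROC-AUC follows the rank-sum definition", {
  expect_equal(rocAucMacro(c(1, 2, 3, 10, 11, 12),
                           rep(c("a", "b"), each = 3)), 1.0)
  expect_equal(rocAucMacro(rep(0.5, 8), rep(c("a", "b"), 4)), 0.5)
  expect_equal(rocAucMacro(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(rocAucMacro(1:4, rep("a", 4)), "both classes")
  # agreement with an independent ROC implementation on random scores
  skip_if_not_installed("pROC")
  set.seed(8)
  sc <- rnorm(60); lb <- factor(sample(c("x", "y"), 60, TRUE))
  ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, levels = c("x", "y"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(rocAucMacro(sc, lb), ref, tolerance = 1e-12)
})

test_that("repeated k-fold produces the expected fold count, determinism and conservation", {
  te <- makePlantedTable(3, nPerClass = 30L,
                         features = featureNames()[1:10],
                         planted = "FOS_Mean", shiftSd = 3)
  rep1 <- evaluateRepeatedKFold(te, featureSubset(rownames(te)),
                                nSplits = 10L, nRepeats = 3L, seed = 5L)
  expect_length(rep1@foldAccuracy, 30L)
  expect_equal(sum(reportConfusion(rep1)), 3L * ncol(te))
  rep2 <- evaluateRepeatedKFold(te, featureSubset(rownames(te)),
                                nSplits = 10L, nRepeats = 3L, seed = 5L)
  expect_identical(rep1@foldAccuracy, rep2@foldAccuracy)
  # perfectly separable data: every fold is exact
  sep <- makeSeparableTable(2, nPerClass = 25L)
  repS <- evaluateRepeatedKFold(sep, featureSubset("FOS_Mean"),
                                nSplits = 5L, nRepeats = 1L, seed = 1L)
  expect_equal(reportAccuracy(repS), 1.0)
  expect_equal(repS@accuracySd, 0)
  # class smaller than k is an explicit error
  expect_error(evaluateRepeatedKFold(makeSeparableTable(3, nPerClass = 4L),
                                     featureSubset("FOS_Mean"),
                                     nSplits = 10L), "reduce k")
})

test_that("holdout evaluation stratifies at the image level and conserves counts", {
  te <- makePlantedTable(4, nPerClass = 150L,
                         features = featureNames()[1:6],
                         planted = "FOS_Mean", shiftSd = 3)
  rep <- evaluateHoldout(te, featureSubset(rownames(te)),
                         testFraction = 0.33, seed = 1L)
  conf <- reportConfusion(rep)
  expect_equal(sum(conf), 2L * round(150L * 0.33))
  expect_true(all(rowSums(conf) > 0))        # both classes in the test set
  cm <- reportClassMetrics(rep)
  expect_equal(cm$class, c("control", "remodeled"))
  expect_true(all(cm$precision >= 0 & cm$precision <= 1))
  # accuracy from the confusion matrix is (TP + TN) / N exactly
  expect_equal(reportAccuracy(rep), sum(diag(conf)) / sum(conf))
  expect_error(evaluateHoldout(te, featureSubset("FOS_Mean"),
                               testFraction = 1.2), "testFraction")
})

test_that("a label-randomization canary shows no leakage through the pipeline", {
  set.seed(99)
  mat <- matrix(rnorm(20 * 200), 20,
                dimnames = list(featureNames()[1:20], NULL))
  labels <- sample(rep(c("control", "remodeled"), each = 100))
  te <- textureExperiment(mat, labels)
  rep <- evaluateRepeatedKFold(te, function(tr) anovaFSelect(tr, k = 5L),
                               nSplits = 10L, nRepeats = 3L, seed = 4L)
  expect_gte(reportAccuracy(rep), 0.4)
  expect_lte(reportAccuracy(rep), 0.6)
})
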