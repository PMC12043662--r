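test_that("ANOVA F selection ranks by the between/within variance ratio", {
  # class A = 1,2,3 and class B = 4,5,6 give F = 13.5
  mat <- matrix(rnorm(5 * 6, 0, 1), 5,
                dimnames = list(featureNames()[1:5], NULL))
  mat[1, ] <- c(1, 2, 3, 4, 5, 6)
  te <- textureExperiment(mat, rep(c("control", "remodeled"), each = 3))
  sub <- anovaFSelect(te, k = 5L)
  expect_equal(unname(sub@scores["FOS_Mean"]), 13.5)
  # a constant feature scores 0 and never outranks a varying one
  mat[2, ] <- 7
  te2 <- textureExperiment(mat, rep(c("control", "remodeled"), each = 3))
  s2 <- anovaFSelect(te2, k = 4L)
  expect_false("FOS_Variance" %in% subsetFeatures(s2))
  # exact subset size on the full 80-feature panel
  big <- makePlantedTable(1, nPerClass = 15L)
  expect_length(anovaFSelect(big, k = 10L), 10L)
  expect_error(anovaFSelect(big, k = 0L), "between 1")
})

test_that("RFE returns exact sizes and the identity subset at full size", {
  te <- makePlantedTable(2, nPerClass = 20L,
                         features = featureNames()[1:20],
                         planted = c("FOS_Mean", "GLCM_Contrast"))
  s7 <- rfeSelect(te, nFeatures = 7L, seed = 1L)
  expect_length(s7, 7L)
  sAll <- rfeSelect(te, nFeatures = 20L)
  expect_equal(subsetFeatures(sAll), rownames(te))
  expect_error(rfeSelect(te, nFeatures = 21L), "between 1")
  # deterministic under a fixed seed
  expect_equal(subsetFeatures(rfeSelect(te, nFeatures = 5L, seed = 3L)),
               subsetFeatures(rfeSelect(te, nFeatures = 5L, seed = 3L)))
})

test_that("automatic RFE keeps jointly necessary features until accuracy drops", {
  # two complementary markers: each resolves only one subtype of the
  # remodeled class, so dropping either one costs real accuracy
  hits <- 0L; total <- 0L
  for (seed in 1:5) {
    set.seed(seed)
    nms <- featureNames()[1:25]
    n <- 80L
    labels <- rep(c("control", "remodeled"), each = 40L)
    mat <- matrix(rnorm(25 * n), 25, n, dimnames = list(nms, NULL))
    mat["FOS_Mean", ] <- rnorm(n, 0, 0.3)
    mat["GLCM_Contrast", ] <- rnorm(n, 0, 0.3)
    mat["FOS_Mean", 41:60] <- mat["FOS_Mean", 41:60] + 2
    mat["GLCM_Contrast", 61:80] <- mat["GLCM_Contrast", 61:80] + 2
    te <- textureExperiment(mat, labels)
    sub <- rfeSelect(te, seed = seed)
    hits <- hits + sum(c("FOS_Mean", "GLCM_Contrast") %in%
                         subsetFeatures(sub))
    total <- total + 2L
  }
  expect_gte(hits / total, 0.8)
})

test_that("permutation importance separates signal from pure noise", {
  te <- makePlantedTable(5, nPerClass = 50L,
                         features = featureNames()[1:15],
                         planted = "GLCM_Contrast", shiftSd = 4)
  sub <- permutationSelect(te, nRepeats = 30L, seed = 2L)
  # the separating feature carries the largest mean accuracy drop
  expect_true("GLCM_Contrast" %in% subsetFeatures(sub))
  expect_equal(names(which.max(sub@scores)), "GLCM_Contrast")
  # fixed seed reproduces identical scores
  sub2 <- permutationSelect(te, nRepeats = 30L, seed = 2L)
  expect_identical(sub@scores, sub2@scores)
  expect_error(permutationSelect(te, nRepeats = 1L), "nRepeats")
})

test_that("interclass CV follows its closed form and threshold boundary", {
  mat <- matrix(1, 3, 8, dimnames = list(featureNames()[1:3], NULL))
  labels <- rep(c("control", "remodeled"), each = 4)
  mat[1, labels == "remodeled"] <- 2    # class means 1 vs 2 -> CV = 1/3
  mat[2, ] <- 5                         # equal class means -> CV = 0
  mat[3, labels == "remodeled"] <- 1.0001
  te <- textureExperiment(mat, labels)
  sub <- covSelect(te, threshold = 0.08)
  expect_equal(unname(sub@scores[["FOS_Mean"]]), 0.5 / 1.5,
               tolerance = 1e-12)
  expect_false("FOS_Variance" %in% subsetFeatures(sub))
  expect_false("FOS_Skewness" %in% subsetFeatures(sub))
  # threshold 0 admits every feature with unequal class means
  s0 <- covSelect(te, threshold = 0)
  expect_true(all(c("FOS_Mean", "FOS_Skewness") %in% subsetFeatures(s0)))
})

test_that("pooling panels is a registry-ordered union with algebraic properties", {
  panels <- airwayPanels()
  expect_equal(lengths(lapply(panels, subsetFeatures)),
               c(anova_f = 10L, permutation = 9L, rfe = 7L, cov = 17L))
  pooled <- poolSubsets(panels)
  expect_length(pooled, 33L)
  expect_equal(subsetFeatures(pooled),
               fibrotex:::orderByRegistry(subsetFeatures(pooled)))
  # idempotent / commutative / associative
  expect_equal(subsetFeatures(poolSubsets(list(panels[[1]], panels[[1]]))),
               subsetFeatures(panels[[1]]))
  expect_equal(subsetFeatures(poolSubsets(panels[c(1, 2)])),
               subsetFeatures(poolSubsets(panels[c(2, 1)])))
  ab_c <- poolSubsets(list(poolSubsets(panels[c(1, 2)]), panels[[3]]))
  a_bc <- poolSubsets(list(panels[[1]], poolSubsets(panels[c(2, 3)])))
  expect_equal(subsetFeatures(ab_c), subsetFeatures(a_bc))
  # disjoint subsets add their sizes
  d1 <- featureSubset(featureNames()[1:4])
  d2 <- featureSubset(featureNames()[11:13])
  expect_length(poolSubsets(list(d1, d2)), 7L)
})

test_that("subsets survive a JSON round trip", {
  sub <- anovaFSelect(makePlantedTable(7, nPerClass = 10L), k = 6L)
  path <- tempfile(fileext = ".json")
  writeSubset(sub, path)
  back <- readSubset(path)
  expect_equal(subsetFeatures(back), subsetFeatures(sub))
  expect_equal(subsetMethod(back), "anova_f")
})
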