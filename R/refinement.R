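## The four feature-refinement strategies (filter / wrapper / embedded /
## statistical) plus the pooled union. All selectors consume a
## TextureExperiment with a two-level label factor and return a
## FeatureSubset ordered canonically; all tie-breaking falls back to
## registry order so runs are reproducible across platforms.

.checkTwoClasses <- function(x, minPerClass = 2L) {
  lab <- droplevels(imageLabels(x))
  if (nlevels(lab) != 2L)
    stop("exactly two classes are required", call. = FALSE)
  if (any(table(lab) < minPerClass))
    stop("each class needs at least ", minPerClass, " samples", call. = FALSE)
  lab
}

# Samples-by-features data.frame for the model-based selectors.
.samplesFrame <- function(x, features = rownames(x)) {
  df <- as.data.frame(t(featureMatrix(x)[features, , drop = FALSE]))
  df
}

#' ANOVA F-test feature filter
#'
#' Ranks every feature by its one-way ANOVA F statistic (between-class mean
#' square over within-class mean square) and keeps the top \code{k}.
#' Features with zero within-class variance but distinct class means are
#' ranked first (infinite F); ties break by registry order.
#'
#' @param x A \code{\linkS4class{TextureExperiment}} with two classes.
#' @param k Number of features to keep (default 10).
#' @return A \code{\linkS4class{FeatureSubset}} with method \code{anova_f}
#'   and the F statistics as scores.
#' @export
anovaFSelect <- function(x, k = 10L) {
  lab <- .checkTwoClasses(x)
  mat <- featureMatrix(x)
  k <- as.integer(k)
  if (k < 1L || k > nrow(mat))
    stop("'k' must be between 1 and the number of features", call. = FALSE)
  n <- ncol(mat)
  g <- split(seq_len(n), lab)
  Fstat <- apply(mat, 1L, function(v) {
    means <- vapply(g, function(idx) mean(v[idx]), numeric(1))
    grand <- mean(v)
    ssb <- sum(lengths(g) * (means - grand)^2)
    ssw <- sum(vapply(g, function(idx) sum((v[idx] - mean(v[idx]))^2),
                      numeric(1)))
    msb <- ssb / (length(g) - 1)
    msw <- ssw / (n - length(g))
    if (msw == 0) { if (msb == 0) 0 else Inf } else msb / msw
  })
  ord <- order(-Fstat, seq_along(Fstat))   # registry order breaks ties
  sel <- rownames(mat)[ord[seq_len(k)]]
  featureSubset(sel, method = "anova_f", scores = Fstat[sel],
                params = list(k = k))
}

#' Recursive feature elimination with a decision-tree learner
#'
#' Backward elimination: a decision tree is fit on the current feature set,
#' the feature with the lowest importance is dropped, and the tree is refit,
#' one feature at a time. With \code{nFeatures = NULL} ("auto") the returned
#' subset is the smallest one whose cross-validated accuracy is within one
#' standard error of the best accuracy observed along the elimination path
#' (the point just before a drop in model accuracy); an explicit
#' \code{nFeatures} returns the subset of exactly that size.
#'
#' @param x A \code{\linkS4class{TextureExperiment}} with two classes.
#' @param nFeatures Target subset size, or \code{NULL} for the
#'   one-standard-error stopping rule.
#' @param nFolds Folds for the internal cross-validation (default 5).
#' @param seed RNG seed controlling the internal folds.
#' @return A \code{\linkS4class{FeatureSubset}} with method \code{rfe}.
#' @export
rfeSelect <- function(x, nFeatures = NULL, nFolds = 5L, seed = 1L) {
  lab <- .checkTwoClasses(x)
  feats <- rownames(x)
  if (length(feats) < 2L) stop("at least 2 features required", call. = FALSE)
  if (!is.null(nFeatures)) {
    nFeatures <- as.integer(nFeatures)
    if (nFeatures < 1L || nFeatures > length(feats))
      stop("'nFeatures' must be between 1 and the number of features",
           call. = FALSE)
    if (nFeatures == length(feats))
      return(featureSubset(feats, method = "rfe",
                           params = list(nFeatures = nFeatures)))
  }
  df <- .samplesFrame(x)
  df$.label <- lab
  auto <- is.null(nFeatures)
  folds <- if (auto) .stratifiedFolds(lab, nFolds, seed) else NULL

  cvAccuracy <- function(features) {
    accs <- vapply(seq_len(nFolds), function(f) {
      tr <- folds != f
      fit <- rpart::rpart(.label ~ ., data = df[tr, c(features, ".label")],
                          method = "class")
      pred <- predict(fit, df[!tr, features, drop = FALSE], type = "class")
      mean(pred == lab[!tr])
    }, numeric(1))
    c(mean(accs), stats::sd(accs) / sqrt(nFolds))
  }

  current <- feats
  path <- list()
  while (length(current) >= 1L) {
    rec <- list(features = current)
    if (auto) rec$cv <- cvAccuracy(current)
    path[[length(path) + 1L]] <- rec
    if (!auto && length(current) == nFeatures) break
    if (length(current) == 1L) break
    fit <- rpart::rpart(.label ~ ., data = df[, c(current, ".label")],
                        method = "class")
    imp <- stats::setNames(numeric(length(current)), current)
    vi <- fit$variable.importance
    if (!is.null(vi)) imp[names(vi)] <- vi
    ## drop the least important feature; ties drop the latest in registry
    ## order so elimination is deterministic
    worst <- max(which(imp == min(imp)))
    current <- current[-worst]
  }
  if (!auto) {
    sel <- path[[length(path)]]$features
    return(featureSubset(sel, method = "rfe",
                         params = list(nFeatures = nFeatures, seed = seed)))
  }
  ## walk the elimination path (large -> small) and stop at the first
  ## subset whose CV accuracy drops more than one standard error below the
  ## best accuracy observed so far; return the subset just before the drop
  accs <- vapply(path, function(p) p$cv[1L], numeric(1))
  ses <- vapply(path, function(p) p$cv[2L], numeric(1))
  pick <- length(path)
  bestIdx <- 1L
  for (i in seq_along(path)) {
    if (accs[i] > accs[bestIdx]) bestIdx <- i
    if (accs[i] < accs[bestIdx] - ses[bestIdx]) { pick <- i - 1L; break }
  }
  pick <- max(pick, 1L)
  featureSubset(path[[pick]]$features, method = "rfe",
                params = list(nFeatures = NULL, nFolds = nFolds, seed = seed,
                              cvAccuracy = accs[pick]))
}

#' Permutation-importance feature selection
#'
#' A random forest is trained on a stratified training portion and its
#' accuracy measured on the held-out validation portion. Each feature's
#' column in the validation data is then permuted \code{nRepeats} times
#' independently; the importance score is the mean accuracy drop. Features
#' whose mean drop exceeds zero by more than one standard deviation of
#' their drops are selected (or the top \code{topK} by mean drop when
#' given). If no feature clears the cutoff the single highest-scoring
#' feature is returned, keeping the subset non-empty.
#'
#' @param x A \code{\linkS4class{TextureExperiment}} with two classes.
#' @param nRepeats Permutations per feature (default 100; must be >= 2).
#' @param seed RNG seed for the split, forest and permutations.
#' @param valFraction Fraction held out for validation (default 0.3).
#' @param nTrees Random-forest size (default 200).
#' @param topK Optional override: select the top-k by mean drop.
#' @return A \code{\linkS4class{FeatureSubset}} with method
#'   \code{permutation} and mean accuracy drops as scores.
#' @export
permutationSelect <- function(x, nRepeats = 100L, seed = 1L,
                              valFraction = 0.3, nTrees = 200L,
                              topK = NULL) {
  if (nRepeats < 2L) stop("'nRepeats' must be >= 2", call. = FALSE)
  lab <- .checkTwoClasses(x)
  feats <- rownames(x)
  mat <- t(featureMatrix(x))           # samples x features
  withSeed(seed, {
    val <- unlist(lapply(split(seq_along(lab), lab), function(idx)
      sample(idx, max(1L, round(length(idx) * valFraction)))))
    tr <- setdiff(seq_along(lab), val)
    rf <- randomForest::randomForest(mat[tr, , drop = FALSE], lab[tr],
                                     ntree = as.integer(nTrees))
    valX <- mat[val, , drop = FALSE]
    valY <- lab[val]
    baseline <- mean(predict(rf, valX) == valY)
    nv <- length(val)
    drops <- matrix(NA_real_, nRepeats, length(feats),
                    dimnames = list(NULL, feats))
    for (f in feats) {
      ## stack all permuted copies and predict in one call
      perm <- replicate(nRepeats, sample(valX[, f]))
      big <- valX[rep(seq_len(nv), nRepeats), , drop = FALSE]
      big[, f] <- as.vector(perm)
      pred <- predict(rf, big)
      acc <- colMeans(matrix(pred == rep(valY, nRepeats), nv, nRepeats))
      drops[, f] <- baseline - acc
    }
  })
  meanDrop <- colMeans(drops)
  sdDrop <- apply(drops, 2L, stats::sd)
  if (!is.null(topK)) {
    ord <- order(-meanDrop, seq_along(meanDrop))
    sel <- feats[ord[seq_len(as.integer(topK))]]
  } else {
    sel <- feats[meanDrop > sdDrop & meanDrop > 0]
    if (!length(sel)) sel <- feats[which.max(meanDrop)]
  }
  featureSubset(sel, method = "permutation", scores = meanDrop[sel],
                params = list(nRepeats = nRepeats, seed = seed,
                              valFraction = valFraction, nTrees = nTrees,
                              baseline = baseline))
}

#' Interclass coefficient-of-variation filter
#'
#' For each feature the interclass CV is the population standard deviation
#' of the two class means divided by the absolute grand mean of the class
#' means (for two classes: |m1 - m2| / |m1 + m2|). Features with CV at or
#' above \code{threshold} are kept. A small epsilon guards features whose
#' class means cancel to zero. If no feature reaches the threshold the
#' single feature with the largest CV is returned.
#'
#' @param x A \code{\linkS4class{TextureExperiment}} with two classes.
#' @param threshold CV selection threshold (default 0.08, i.e. 8\%).
#' @param eps Guard for a zero grand mean (default 1e-12).
#' @return A \code{\linkS4class{FeatureSubset}} with method \code{cov} and
#'   the CVs as scores.
#' @export
covSelect <- function(x, threshold = 0.08, eps = 1e-12) {
  lab <- .checkTwoClasses(x, minPerClass = 1L)
  mat <- featureMatrix(x)
  idx <- split(seq_len(ncol(mat)), lab)
  m1 <- rowMeans(mat[, idx[[1L]], drop = FALSE])
  m2 <- rowMeans(mat[, idx[[2L]], drop = FALSE])
  cv <- (abs(m1 - m2) / 2) / pmax(abs(m1 + m2) / 2, eps)
  sel <- rownames(mat)[cv >= threshold]
  if (!length(sel)) sel <- rownames(mat)[which.max(cv)]
  featureSubset(sel, method = "cov", scores = cv[sel],
                params = list(threshold = threshold))
}

#' Pool several feature subsets
#'
#' Set union of the given subsets, keyed by canonical feature name and
#' returned in registry order with method tag \code{pooled}. The operation
#' is idempotent, commutative and associative.
#'
#' @param subsets A list of \code{\linkS4class{FeatureSubset}} objects
#'   (at least 2).
#' @return A \code{\linkS4class{FeatureSubset}}.
#' @export
poolSubsets <- function(subsets) {
  if (!is.list(subsets) || length(subsets) < 2L)
    stop("at least two subsets are required", call. = FALSE)
  feats <- unique(unlist(lapply(subsets, subsetFeatures)))
  featureSubset(feats, method = "pooled",
                params = list(methods = vapply(subsets, subsetMethod,
                                               character(1))))
}

#' Write / read a feature subset as JSON
#'
#' @param subset A \code{\linkS4class{FeatureSubset}}.
#' @param path Output (input) JSON path.
#' @return \code{writeSubset} returns \code{path} invisibly;
#'   \code{readSubset} returns the reconstructed subset.
#' @export
writeSubset <- function(subset, path) {
  jsonlite::write_json(list(method = subset@method,
                            features = subset@features,
                            scores = as.list(subset@scores),
                            params = subset@params),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSubset
#' @export
readSubset <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  featureSubset(o$features, method = o$method,
                scores = unlist(o$scores) %||% numeric(),
                params = as.list(o$params))
}
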