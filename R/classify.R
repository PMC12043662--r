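## Classification stage: feature subsetting -> per-feature standardization
## -> Fisher linear discriminant projection to one dimension -> linear
## support-vector machine (cost 1, equal class weights). Two validation
## protocols are provided: repeated stratified k-fold (10 splits x 3
## repeats by default) and a stratified holdout split (66/33). Selection
## can run inside each training fold ("fold-safe", pass a selector
## function) or once on the full table ("panel-parity", pass a fixed
## FeatureSubset).

# Stratified fold assignment: within each class, samples are shuffled and
# dealt round-robin into nFolds folds.
.stratifiedFolds <- function(labels, nFolds, seed) {
  folds <- integer(length(labels))
  withSeed(seed, {
    for (idx in split(seq_along(labels), labels)) {
      idx <- sample(idx)
      folds[idx] <- rep_len(seq_len(nFolds), length(idx))
    }
  })
  folds
}

#' Fit the standardize + LDA + linear-SVM pipeline
#'
#' Restricts the table to the subset's features, standardizes each feature
#' (center/scale estimated on the training data only), projects onto the
#' one-dimensional Fisher discriminant (computed with a pseudo-inverse of
#' the pooled within-class covariance, so duplicated or collinear features
#' are harmless), and trains a linear SVM with cost 1 and equal class
#' weights on the projected score.
#'
#' @param x A \code{\linkS4class{TextureExperiment}} (training data; two
#'   classes, each with >= 2 samples).
#' @param subset A \code{\linkS4class{FeatureSubset}} (or character vector
#'   of canonical names).
#' @param cost SVM margin cost (default 1).
#' @return An object of class \code{fibrotexModel}.
#' @export
fitPipeline <- function(x, subset, cost = 1) {
  lab <- .checkTwoClasses(x)
  feats <- if (is.character(subset)) orderByRegistry(subset)
           else subsetFeatures(subset)
  missing <- setdiff(feats, rownames(x))
  if (length(missing))
    stop("subset feature(s) missing from the table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  X <- t(featureMatrix(x)[feats, , drop = FALSE])   # samples x features
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  scale[scale == 0] <- 1
  Xs <- sweep(sweep(X, 2L, center), 2L, scale, "/")
  ## Fisher discriminant direction via pseudo-inverse of the pooled
  ## within-class covariance
  idx <- split(seq_len(nrow(Xs)), lab)
  mu <- lapply(idx, function(i) colMeans(Xs[i, , drop = FALSE]))
  Sw <- Reduce(`+`, lapply(idx, function(i) {
    d <- sweep(Xs[i, , drop = FALSE], 2L, colMeans(Xs[i, , drop = FALSE]))
    crossprod(d)
  })) / (nrow(Xs) - 2L)
  w <- MASS::ginv(Sw) %*% (mu[[2L]] - mu[[1L]])
  w <- w / sqrt(sum(w^2))
  score <- as.vector(Xs %*% w)
  ## orient so the second class level has the higher mean score
  if (mean(score[idx[[2L]]]) < mean(score[idx[[1L]]])) w <- -w
  score <- as.vector(Xs %*% w)
  svmFit <- e1071::svm(x = matrix(score, ncol = 1L), y = lab,
                       kernel = "linear", cost = cost, scale = FALSE)
  structure(list(features = feats, center = center, scale = scale, w = w,
                 levels = levels(lab), svm = svmFit),
            class = "fibrotexModel")
}

#' Predict with a fitted pipeline
#'
#' @param object A \code{fibrotexModel} from \code{\link{fitPipeline}}.
#' @param newdata A \code{\linkS4class{TextureExperiment}} or a features x
#'   samples numeric matrix.
#' @param ... Unused.
#' @return A list with \code{class} (factor of predicted labels) and
#'   \code{score} (numeric; larger values favor the second class level).
#' @export
predict.fibrotexModel <- function(object, newdata, ...) {
  mat <- if (is(newdata, "TextureExperiment")) featureMatrix(newdata)
         else as.matrix(newdata)
  X <- t(mat[object$features, , drop = FALSE])
  Xs <- sweep(sweep(X, 2L, object$center), 2L, object$scale, "/")
  score <- as.vector(Xs %*% object$w)
  pred <- predict(object$svm, matrix(score, ncol = 1L),
                  decision.values = TRUE)
  dv <- as.vector(attr(pred, "decision.values"))
  ## e1071's decision value is positive for the first label of its
  ## colname pair; re-orient so larger = second class level
  dvName <- colnames(attr(pred, "decision.values"))[1L]
  if (identical(dvName, paste(object$levels[1L], object$levels[2L],
                              sep = "/"))) dv <- -dv
  list(class = factor(as.character(pred), levels = object$levels),
       score = dv, ldaScore = score)
}

#' Macro-averaged ROC-AUC
#'
#' One-vs-rest AUC per class (midrank tie handling), averaged over the
#' classes; for a binary problem both one-vs-rest AUCs coincide with the
#' AUC of the decision score for the second class level.
#'
#' @param scores Numeric decision scores (larger favors the second level).
#' @param labels Two-level factor (or coercible).
#' @return The macro-averaged AUC in [0, 1].
#' @examples
#' rocAucMacro(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))   # 0.75
#' @export
rocAucMacro <- function(scores, labels) {
  labels <- droplevels(factor(labels))
  if (nlevels(labels) < 2L)
    stop("both classes must be present", call. = FALSE)
  aucOne <- function(s, positive) {
    pos <- labels == positive
    r <- rank(s)                       # midranks
    (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
  }
  mean(c(aucOne(-scores, levels(labels)[1L]),
         aucOne(scores, levels(labels)[2L])))
}

# Confusion matrix (rows = truth, cols = predicted) and per-class
# precision/recall/F1 with the 0/0 -> 0 convention.
.confusion <- function(truth, pred, lev) {
  table(truth = factor(truth, levels = lev),
        predicted = factor(pred, levels = lev))
}

.classMetrics <- function(conf) {
  lev <- rownames(conf)
  prec <- diag(conf) / pmax(colSums(conf), 1)
  rec <- diag(conf) / pmax(rowSums(conf), 1)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  data.frame(class = lev, precision = as.vector(prec),
             recall = as.vector(rec), f1 = as.vector(f1),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Resolve the subset argument: a fixed FeatureSubset/character vector is
# used as-is ("panel-parity"); a function is called on the training table
# inside every fold ("fold-safe" selection).
.resolveSubset <- function(subset, train) {
  if (is.function(subset)) subset(train) else subset
}

#' Repeated stratified k-fold evaluation
#'
#' The full pipeline (standardization, LDA projection and SVM — plus
#' feature selection when \code{subset} is a selector function) is refit
#' inside every training fold; accuracy and macro ROC-AUC are computed on
#' each held-out fold.
#'
#' @param x A \code{\linkS4class{TextureExperiment}}.
#' @param subset A \code{\linkS4class{FeatureSubset}}, character vector, or
#'   a function \code{function(train) -> FeatureSubset} for fold-safe
#'   selection.
#' @param nSplits Folds per repeat (default 10).
#' @param nRepeats Repeats (default 3).
#' @param seed Seed controlling the fold assignments.
#' @param cost SVM cost (default 1).
#' @return An \code{\linkS4class{EvaluationReport}} with
#'   \code{nSplits * nRepeats} fold accuracies.
#' @export
evaluateRepeatedKFold <- function(x, subset, nSplits = 10L, nRepeats = 3L,
                                  seed = 1L, cost = 1) {
  lab <- .checkTwoClasses(x)
  if (any(table(lab) < nSplits))
    stop("smallest class has fewer samples than nSplits; reduce k",
         call. = FALSE)
  accs <- aucs <- numeric(0)
  conf <- NULL
  featsUsed <- character(0)
  for (rep_ in seq_len(nRepeats)) {
    folds <- .stratifiedFolds(lab, nSplits, deriveSeed(seed, rep_))
    for (f in seq_len(nSplits)) {
      tr <- which(folds != f); te <- which(folds == f)
      train <- x[, tr]
      sub <- .resolveSubset(subset, train)
      model <- fitPipeline(train, sub, cost = cost)
      pr <- predict(model, x[, te])
      truth <- lab[te]
      accs <- c(accs, mean(pr$class == truth))
      aucs <- c(aucs, rocAucMacro(pr$score, truth))
      cm <- .confusion(truth, pr$class, levels(lab))
      conf <- if (is.null(conf)) cm else conf + cm
      featsUsed <- union(featsUsed, if (is.character(sub)) sub
                         else subsetFeatures(sub))
    }
  }
  new("EvaluationReport", protocol = "repeated_kfold", foldAccuracy = accs,
      accuracyMean = mean(accs), accuracySd = stats::sd(accs),
      classMetrics = .classMetrics(unclass(conf)),
      aucMacro = mean(aucs), aucSd = stats::sd(aucs),
      confusion = unclass(conf), subset = orderByRegistry(featsUsed),
      seed = as.integer(seed))
}

#' Stratified holdout evaluation
#'
#' Splits the images into a stratified train/test partition at the image
#' level (default 66/33), fits the pipeline on the training portion and
#' reports per-class precision/recall/F1, the confusion matrix and the
#' macro ROC-AUC on the test portion.
#'
#' @inheritParams evaluateRepeatedKFold
#' @param testFraction Fraction held out for testing, in (0, 1)
#'   (default 0.33).
#' @param seed Seed for the stratified split (default 1).
#' @return An \code{\linkS4class{EvaluationReport}}.
#' @export
evaluateHoldout <- function(x, subset, testFraction = 0.33, seed = 1L,
                            cost = 1) {
  if (testFraction <= 0 || testFraction >= 1)
    stop("'testFraction' must lie in (0, 1)", call. = FALSE)
  lab <- .checkTwoClasses(x)
  te <- withSeed(seed, unlist(lapply(split(seq_along(lab), lab),
    function(idx) sample(idx, max(1L, round(length(idx) * testFraction))))))
  tr <- setdiff(seq_along(lab), te)
  train <- x[, tr]
  sub <- .resolveSubset(subset, train)
  model <- fitPipeline(train, sub, cost = cost)
  pr <- predict(model, x[, te])
  truth <- lab[te]
  conf <- .confusion(truth, pr$class, levels(lab))
  acc <- mean(pr$class == truth)
  new("EvaluationReport", protocol = "holdout", foldAccuracy = acc,
      accuracyMean = acc, accuracySd = 0,
      classMetrics = .classMetrics(unclass(conf)),
      aucMacro = rocAucMacro(pr$score, truth), aucSd = 0,
      confusion = unclass(conf),
      subset = if (is.character(sub)) orderByRegistry(sub)
               else subsetFeatures(sub),
      seed = as.integer(seed))
}
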