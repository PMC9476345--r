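# SVM classification of OA severity with fivefold out-of-fold scoring,
# ROC/AUC (trapezoidal, equal to the tie-corrected concordant-pair
# statistic), stratified-bootstrap AUC confidence intervals, and the
# Youden-threshold metric panel (accuracy / sensitivity / specificity /
# F1). Standardization is re-fit inside each training fold: the test
# fold never leaks into the scaling.

#' Classification task definitions
#'
#' The four severity contrasts; each names its two groups and the
#' positive class.
#' @return Named list of lists (groups, positive).
#' @export
taskDefinitions <- function() {
  list(
    normal_vs_oa = list(groups = c("normal", "mild", "advanced"),
                        positive = c("mild", "advanced")),
    mild_vs_advanced = list(groups = c("mild", "advanced"),
                            positive = "advanced"),
    normal_vs_advanced = list(groups = c("normal", "advanced"),
                              positive = "advanced"),
    normal_vs_mild = list(groups = c("normal", "mild"),
                          positive = "mild"))
}

.kernelMap <- c(linear = "linear", rbf = "radial", cubic = "polynomial",
                sigmoid = "sigmoid")

#' Out-of-fold SVM decision scores
#'
#' Stratified k-fold cross-validation: per fold, features are
#' standardized on the training part, an SVM is fit (C = 1; RBF/sigmoid
#' gamma = 1 / (p x mean feature variance) of the standardized training
#' block; cubic = polynomial of degree 3) and decision values are
#' collected for the held-out part. Scores are oriented so that larger
#' means more likely positive.
#'
#' @param x Numeric matrix (subjects x features), unstandardized.
#' @param y Binary outcome: logical or two-class factor/character
#'   (second sorted level = positive).
#' @param kernel One of "linear", "rbf", "cubic", "sigmoid".
#' @param folds Number of folds (default 5).
#' @param seed Fold-assignment seed.
#' @param cost SVM cost parameter C.
#' @return Numeric vector of out-of-fold scores (one per subject), with
#'   attribute \code{"folds"}.
#' @export
crossValidatedScores <- function(x, y, kernel = "rbf", folds = 5L,
                                 seed = 1L, cost = 1) {
  x <- as.matrix(x)
  y <- .asBinary(y)
  if (!kernel %in% names(.kernelMap))
    stop("kernel must be one of ", paste(names(.kernelMap),
                                         collapse = ", "))
  tab <- table(y)
  if (min(tab) < folds)
    stop("class '", names(tab)[which.min(tab)], "' has ", min(tab),
         " members, fewer than ", folds, " folds")
  fid <- .stratifiedFolds(y, folds, seed)
  scores <- numeric(length(y))
  yf <- factor(ifelse(y, "pos", "neg"), levels = c("neg", "pos"))
  for (f in seq_len(folds)) {
    tr <- fid != f; te <- fid == f
    ctr <- colMeans(x[tr, , drop = FALSE])
    scl <- apply(x[tr, , drop = FALSE], 2, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    xtr <- scale(x[tr, , drop = FALSE], ctr, scl)
    xte <- scale(x[te, , drop = FALSE], ctr, scl)
    gamma <- 1 / (ncol(x) * max(mean(apply(xtr, 2, stats::var)), 1e-12))
    fit <- .withSeed(.deriveSeed(seed, paste0("svm", f)),
      e1071::svm(xtr, yf[tr], kernel = .kernelMap[[kernel]],
                 degree = 3, cost = cost, gamma = gamma,
                 scale = FALSE))
    pr <- stats::predict(fit, xte, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    # e1071 orients decision values toward the first named class
    s <- if (grepl("^pos", colnames(dv)[1])) dv[, 1] else -dv[, 1]
    scores[te] <- s
  }
  attr(scores, "folds") <- fid
  scores
}

#' ROC curve and trapezoidal AUC
#'
#' Full threshold sweep over the unique scores; with ties the curve
#' takes diagonal steps, so the trapezoidal area equals the
#' concordant-pair (Mann-Whitney) statistic with half credit for tied
#' pairs.
#'
#' @param scores Numeric decision scores (larger = more positive).
#' @param labels Binary outcome.
#' @return List: \code{auc}, \code{points} (data.frame fpr/tpr from
#'   (0,0) to (1,1), nondecreasing in both).
#' @export
rocAuc <- function(scores, labels) {
  y <- .asBinary(labels)
  if (length(unique(y)) < 2L)
    stop("both classes must be present to form a ROC curve")
  np <- sum(y); nn <- sum(!y)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  last <- !duplicated(ss, fromLast = TRUE)   # last index per tied block
  tpr <- c(0, cumsum(ys)[last] / np)
  fpr <- c(0, cumsum(!ys)[last] / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(auc = auc, points = data.frame(fpr = fpr, tpr = tpr),
       thresholds = c(Inf, ss[last]))
}

#' Stratified-bootstrap confidence interval for the AUC
#'
#' Percentile interval over \code{nBoot} stratified resamples (each
#' class resampled within itself, so no resample is degenerate).
#'
#' @param scores,labels As in \code{\link{rocAuc}}.
#' @param nBoot Number of resamples (default 2000).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @return Numeric c(low, high).
#' @export
aucConfidenceInterval <- function(scores, labels, nBoot = 2000L,
                                  seed = 1L, level = 0.95) {
  y <- .asBinary(labels)
  if (min(table(y)) < 10L)
    warning("fewer than 10 subjects in a class; bootstrap interval ",
            "may be unstable")
  ip <- which(y); im <- which(!y)
  aucs <- .withSeed(seed, vapply(seq_len(nBoot), function(b) {
    idx <- c(sample(ip, replace = TRUE), sample(im, replace = TRUE))
    rocAuc(scores[idx], y[idx])$auc
  }, numeric(1)))
  a <- (1 - level) / 2
  unname(stats::quantile(aucs, c(a, 1 - a), type = 7))
}

#' Confusion-matrix metrics at the Youden-optimal threshold
#'
#' The operating point maximizes sensitivity + specificity - 1 on the
#' ROC of the supplied (out-of-fold) scores; predicted positive means
#' score >= threshold.
#'
#' @param scores,labels As in \code{\link{rocAuc}}.
#' @return List: threshold, accuracy, sensitivity, specificity, f1
#'   (0 with a flag when no positive calls are made), confusion (2x2).
#' @export
thresholdMetrics <- function(scores, labels) {
  y <- .asBinary(labels)
  roc <- rocAuc(scores, y)
  youden <- roc$points$tpr - roc$points$fpr
  best <- which.max(youden)
  thrBest <- roc$thresholds[best]
  pred <- scores >= thrBest
  tp <- sum(pred & y); fp <- sum(pred & !y)
  fn <- sum(!pred & y); tn <- sum(!pred & !y)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- tp / (tp + fn)
  f1 <- if (is.na(prec) || prec + rec == 0) 0
        else 2 * prec * rec / (prec + rec)
  list(threshold = thrBest,
       accuracy = (tp + tn) / length(y),
       sensitivity = rec,
       specificity = tn / (tn + fp),
       f1 = f1,
       noPositiveCalls = tp + fp == 0,
       confusion = matrix(c(tp, fn, fp, tn), 2, 2,
                          dimnames = list(c("predPos", "predNeg"),
                                          c("pos", "neg"))))
}

#' Full classifier report for one task
#'
#' @param x Feature matrix.
#' @param y Binary outcome.
#' @param task Task name (labeling only).
#' @param kernel SVM kernel.
#' @param folds,seed,cost,nBoot As in the underlying functions.
#' @return List of class \code{ClassifierReport}: auc, ci, accuracy,
#'   sensitivity, specificity, f1, rocPoints, kernel, task, scores.
#' @export
classifierReport <- function(x, y, task = "task", kernel = "rbf",
                             folds = 5L, seed = 1L, cost = 1,
                             nBoot = 2000L) {
  sc <- crossValidatedScores(x, y, kernel, folds, seed, cost)
  roc <- rocAuc(sc, y)
  ci <- suppressWarnings(
    aucConfidenceInterval(sc, y, nBoot = nBoot,
                          seed = .deriveSeed(seed, "boot")))
  tm <- thresholdMetrics(sc, y)
  structure(list(task = task, kernel = kernel, auc = roc$auc,
                 aucCiLow = min(ci[1], roc$auc),
                 aucCiHigh = max(ci[2], roc$auc),
                 accuracy = tm$accuracy, sensitivity = tm$sensitivity,
                 specificity = tm$specificity, f1 = tm$f1,
                 rocPoints = roc$points, scores = as.numeric(sc),
                 folds = attr(sc, "folds")),
            class = "ClassifierReport")
}

#' @export
print.ClassifierReport <- function(x, ...) {
  cat(sprintf(paste0("ClassifierReport [%s, %s kernel]\n  AUC %.3f ",
                     "(%.3f-%.3f)  acc %.3f  sens %.3f  spec %.3f  ",
                     "F1 %.3f\n"),
              x$task, x$kernel, x$auc, x$aucCiLow, x$aucCiHigh,
              x$accuracy, x$sensitivity, x$specificity, x$f1))
  invisible(x)
}

#' Compare SVM kernels on identical folds
#'
#' @param x,y,task,folds,seed,cost,nBoot As in
#'   \code{\link{classifierReport}}.
#' @param kernels Kernels to compare.
#' @return Named list of \code{ClassifierReport}s (paired: same folds
#'   and seed for every kernel).
#' @export
compareKernels <- function(x, y, task = "task",
                           kernels = c("linear", "rbf", "cubic",
                                       "sigmoid"),
                           folds = 5L, seed = 1L, cost = 1,
                           nBoot = 500L) {
  stats::setNames(lapply(kernels, function(k)
    classifierReport(x, y, task, k, folds, seed, cost, nBoot)), kernels)
}

#' Side-by-side panel of radiomics vs trabecular models
#'
#' @param radiomics,trabecular \code{ClassifierReport}s of the same
#'   task on the same subjects.
#' @return data.frame with one row per metric and a column per feature
#'   source.
#' @export
compareModels <- function(radiomics, trabecular) {
  stopifnot(inherits(radiomics, "ClassifierReport"),
            inherits(trabecular, "ClassifierReport"))
  if (length(radiomics$scores) != length(trabecular$scores))
    stop("reports cover different subject sets (",
         length(radiomics$scores), " vs ", length(trabecular$scores),
         ")")
  metrics <- c("auc", "aucCiLow", "aucCiHigh", "accuracy",
               "sensitivity", "specificity", "f1")
  data.frame(metric = metrics,
             radiomics = vapply(metrics, function(m)
               radiomics[[m]], numeric(1)),
             trabecular = vapply(metrics, function(m)
               trabecular[[m]], numeric(1)))
}
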