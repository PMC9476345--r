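# The feature-selection chain: z-scoring, LASSO with cross-validated
# penalty, Mann-Whitney retention at raw P < 0.05 (no multiplicity
# correction, by design), and |r| > 0.90 correlation pruning with the
# Mann-Whitney P as tie-break. Plus the structure-feature correlation
# analysis and the age-adjusted group comparison of parameters.

#' Selection configuration
#'
#' @param cvFolds Cross-validation folds for the LASSO penalty (>= 2).
#' @param cvIterations Optimizer iteration budget for the LASSO path
#'   (default 10000).
#' @param alphaRetain Mann-Whitney retention threshold (two-sided P).
#' @param pruneR Absolute Pearson correlation above which one of a
#'   feature pair is eliminated.
#' @param seed Integer seed (fold assignment).
#' @return List of class \code{SelectionConfig}.
#' @export
selectionConfig <- function(cvFolds = 5L, cvIterations = 10000L,
                            alphaRetain = 0.05, pruneR = 0.90,
                            seed = 1L) {
  if (cvFolds < 2L) stop("cvFolds must be >= 2")
  if (alphaRetain <= 0 || alphaRetain >= 1)
    stop("alphaRetain must be in (0, 1)")
  if (pruneR <= 0 || pruneR > 1) stop("pruneR must be in (0, 1]")
  structure(list(cvFolds = as.integer(cvFolds),
                 cvIterations = as.integer(cvIterations),
                 alphaRetain = alphaRetain, pruneR = pruneR,
                 seed = as.integer(seed)),
            class = "SelectionConfig")
}

#' Z-score standardize a feature matrix
#'
#' Columns become mean 0, sample SD 1; constant columns are dropped
#' with a warning naming them.
#'
#' @param x Numeric matrix or data.frame of features.
#' @return List: \code{x} (standardized matrix), \code{center},
#'   \code{scale}, \code{dropped} (names of constant columns).
#' @export
zscoreFeatures <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need >= 2 rows to standardize")
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sds == 0 | !is.finite(sds)]
  if (length(dropped)) {
    warning("dropping ", length(dropped), " constant column(s): ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
    x <- x[, !(colnames(x) %in% dropped), drop = FALSE]
  }
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  list(x = scale(x, center = ctr, scale = scl), center = ctr,
       scale = scl, dropped = dropped)
}

# stratified fold assignment, reproducible from seed
.stratifiedFolds <- function(y, k, seed) {
  folds <- integer(length(y))
  .withSeed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' LASSO feature selection with cross-validated penalty
#'
#' L1-penalized logistic regression over the standardized feature
#' matrix; the penalty is chosen by stratified k-fold cross-validated
#' deviance and features with nonzero coefficients at that penalty are
#' selected.
#'
#' @param x Standardized numeric matrix (subjects x features).
#' @param y Binary outcome: logical, or factor/character with exactly
#'   two classes; TRUE (or the second level) is the positive class.
#' @param cfg A \code{\link{selectionConfig}}.
#' @return List of class \code{SelectionResult}: \code{selected},
#'   \code{lambda}, \code{coefficients} (named, nonzero only),
#'   \code{perRegionCounts}, \code{provenance} (per-feature audit
#'   data.frame, extended by the later stages).
#' @export
lassoSelect <- function(x, y, cfg = selectionConfig()) {
  x <- as.matrix(x)
  y <- .asBinary(y)
  if (length(unique(y)) < 2L) stop("outcome is degenerate (one class)")
  if (min(table(y)) < cfg$cvFolds)
    stop("fewer members in a class (", min(table(y)),
         ") than cross-validation folds (", cfg$cvFolds, ")")
  if (anyNA(x)) stop("feature matrix contains missing values")
  foldid <- .stratifiedFolds(y, cfg$cvFolds, cfg$seed)
  cvfit <- .withSeed(cfg$seed,
    glmnet::cv.glmnet(x, factor(y), family = "binomial", alpha = 1,
                      foldid = foldid, maxit = cfg$cvIterations,
                      standardize = FALSE))
  co <- as.matrix(stats::coef(cvfit, s = "lambda.min"))[-1, 1]
  sel <- names(co)[co != 0]
  res <- list(selected = sel, lambda = cvfit$lambda.min,
              coefficients = co[co != 0],
              perRegionCounts = .regionCounts(sel),
              provenance = data.frame(
                feature = colnames(x),
                survivedLasso = colnames(x) %in% sel,
                mwuP = NA_real_, survivedMwu = NA, survivedPrune = NA))
  class(res) <- "SelectionResult"
  res
}

.asBinary <- function(y) {
  if (is.logical(y)) return(y)
  u <- sort(unique(as.character(y)))
  if (length(u) != 2L) stop("outcome must have exactly two classes, got {",
                            paste(u, collapse = ", "), "}")
  as.character(y) == u[2]
}

.regionCounts <- function(nms) {
  rg <- sub("\\|.*$", "", nms)
  rg[!rg %in% names(regionCodes())] <- "other"
  tab <- table(factor(rg, levels = c(names(regionCodes()), "other")))
  cnt <- as.integer(tab)
  names(cnt) <- names(tab)
  cnt[cnt > 0 | names(cnt) != "other"]
}

#' Mann-Whitney retention filter
#'
#' Two-sided Mann-Whitney U test per feature between the two classes;
#' features with P below \code{alpha} are retained. The exact null
#' distribution is used for total n <= 20 without ties, otherwise the
#' tie-corrected normal approximation.
#'
#' @param x Feature matrix (columns = features under consideration).
#' @param y Binary outcome (as in \code{\link{lassoSelect}}).
#' @param alpha Retention threshold (default 0.05).
#' @return List: \code{retained} (names), \code{p} (named P values),
#'   \code{emptied} (flag: every feature removed).
#' @export
mannwhitneyFilter <- function(x, y, alpha = 0.05) {
  x <- as.matrix(x)
  y <- .asBinary(y)
  n <- length(y)
  p <- vapply(seq_len(ncol(x)), function(j) {
    a <- x[y, j]; b <- x[!y, j]
    exact <- n <= 20 && !anyDuplicated(c(a, b))
    suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = !exact)$p.value)
  }, numeric(1))
  names(p) <- colnames(x)
  retained <- names(p)[p < alpha]
  list(retained = retained, p = p, emptied = length(retained) == 0L)
}

#' Correlation pruning of near-duplicate features
#'
#' All feature pairs with |Pearson r| above \code{pruneR} are visited
#' in order of decreasing |r| (ties broken lexicographically by name
#' pair); in each pair whose members both survive so far, the member
#' with the larger Mann-Whitney P is dropped (P ties broken by
#' dropping the lexicographically later name). Deterministic.
#'
#' @param x Feature matrix of the candidate features.
#' @param p Named Mann-Whitney P values for those features.
#' @param pruneR Threshold on |r| (default 0.90).
#' @return Character vector of surviving feature names.
#' @export
correlationPrune <- function(x, p, pruneR = 0.90) {
  x <- as.matrix(x)
  nms <- colnames(x)
  if (ncol(x) < 2L) return(nms)
  r <- stats::cor(x)
  pairs <- which(upper.tri(r) & abs(r) > pruneR, arr.ind = TRUE)
  if (nrow(pairs) == 0L) return(nms)
  ord <- order(-abs(r[pairs]), nms[pairs[, 1]], nms[pairs[, 2]])
  pairs <- pairs[ord, , drop = FALSE]
  alive <- stats::setNames(rep(TRUE, length(nms)), nms)
  for (q in seq_len(nrow(pairs))) {
    a <- nms[pairs[q, 1]]; b <- nms[pairs[q, 2]]
    if (!alive[a] || !alive[b]) next
    drop <- if (p[a] > p[b]) a
            else if (p[b] > p[a]) b
            else max(a, b)
    alive[drop] <- FALSE
  }
  nms[alive[nms]]
}

#' Run the full selection chain for one classification task
#'
#' z-score -> LASSO (CV penalty) -> Mann-Whitney retention ->
#' correlation pruning, with a per-feature audit trail.
#'
#' @param features data.frame or matrix of raw feature columns.
#' @param y Binary outcome.
#' @param cfg A \code{\link{selectionConfig}}.
#' @return A \code{SelectionResult} whose \code{selected} are the final
#'   survivors; \code{provenance} records each stage.
#' @export
selectFeatures <- function(features, y, cfg = selectionConfig()) {
  z <- zscoreFeatures(features)
  res <- lassoSelect(z$x, y, cfg)
  prov <- res$provenance
  if (length(res$selected)) {
    mw <- mannwhitneyFilter(z$x[, res$selected, drop = FALSE], y,
                            cfg$alphaRetain)
    prov$mwuP[match(res$selected, prov$feature)] <-
      mw$p[res$selected]
    prov$survivedMwu <- prov$survivedLasso &
      prov$feature %in% mw$retained
    final <- if (length(mw$retained))
      correlationPrune(z$x[, mw$retained, drop = FALSE],
                       mw$p[mw$retained], cfg$pruneR)
    else character(0)
  } else final <- character(0)
  prov$survivedPrune <- prov$feature %in% final
  res$selected <- final
  res$perRegionCounts <- .regionCounts(final)
  res$provenance <- prov
  res$zscore <- list(center = z$center, scale = z$scale,
                     dropped = z$dropped)
  res
}

#' @export
print.SelectionResult <- function(x, ...) {
  cat(sprintf("SelectionResult: %d feature(s), lambda = %.4g\n",
              length(x$selected), x$lambda))
  if (length(x$perRegionCounts))
    cat("  per region:",
        paste(sprintf("%s=%d", names(x$perRegionCounts),
                      x$perRegionCounts), collapse = ", "), "\n")
  invisible(x)
}

#' Correlate features with trabecular parameters
#'
#' Pearson r and two-sided P per (feature, parameter) pair; the report
#' keeps features with at least one moderate significant correlation
#' (|r| > rMin and P < alpha).
#'
#' @param features data.frame/matrix of feature columns (matched rows).
#' @param params data.frame with columns bvtv, tb_th_mm, tb_sp_mm,
#'   tb_n_per_mm (one row per matching subject).
#' @param rMin,alpha Report filter (defaults 0.4 and 0.05).
#' @return List: \code{records} (all pairs: feature, parameter, r, p),
#'   \code{report} (filtered records, possibly empty).
#' @export
correlateWithStructure <- function(features, params, rMin = 0.4,
                                   alpha = 0.05) {
  features <- as.matrix(features)
  pnames <- c("bvtv", "tb_th_mm", "tb_sp_mm", "tb_n_per_mm")
  stopifnot(all(pnames %in% colnames(params)),
            nrow(features) == nrow(params))
  if (nrow(features) < 3L) stop("need >= 3 matched subjects")
  rec <- list()
  for (f in colnames(features)) for (pn in pnames) {
    ct <- stats::cor.test(features[, f], params[[pn]])
    rec[[length(rec) + 1L]] <- data.frame(
      feature = f, parameter = pn, r = unname(ct$estimate),
      p = ct$p.value)
  }
  rec <- do.call(rbind, rec)
  hit <- rec$feature[abs(rec$r) > rMin & rec$p < alpha]
  list(records = rec,
       report = rec[rec$feature %in% hit, , drop = FALSE])
}

#' Age-adjusted group comparison of a parameter
#'
#' Linear model \code{value ~ group + age} with pairwise adjusted group
#' contrasts. If age is constant the model degrades to a one-way ANOVA
#' (with a message).
#'
#' @param value Numeric response (one trabecular parameter).
#' @param group Factor/character of >= 2 groups.
#' @param age Numeric covariate (years).
#' @return List: \code{model} (lm fit), \code{groupP} (group effect P,
#'   age-adjusted), \code{contrasts} (data.frame of pairwise adjusted
#'   differences with P values).
#' @export
groupCompareAncova <- function(value, group, age) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need >= 2 groups")
  stopifnot(length(value) == length(group), length(age) == length(group))
  useAge <- stats::sd(age) > 0
  if (!useAge)
    message("age is constant; falling back to unadjusted ANOVA")
  df <- data.frame(value = value, group = group, age = age)
  fit <- if (useAge) stats::lm(value ~ age + group, data = df)
         else stats::lm(value ~ group, data = df)
  an <- stats::anova(fit)
  groupP <- an["group", "Pr(>F)"]
  emm <- emmeans::emmeans(fit, "group")
  prs <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "none"))
  list(model = fit, groupP = groupP,
       contrasts = data.frame(contrast = prs$contrast,
                              estimate = prs$estimate,
                              p = prs$p.value))
}
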