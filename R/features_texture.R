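# The five texture-matrix classes and their 75 features (24 GLCM +
# 16 GLRLM + 16 GLSZM + 5 NGTDM + 14 GLDM), computed from a discretized
# level map. Matrices are built in compiled code (13 unique distance-1
# 3D directions; 26-connected zones/neighborhoods); feature formulas
# follow the standard radiomics definitions, with entropies in log2.
#
# GLCM and GLRLM features are computed per direction and averaged.
# Degenerate regions (single gray level) return documented constants:
# probabilities concentrate in one cell, so e.g. MaximumProbability = 1
# and all contrasts/variances are 0; GLCM Correlation and MCC are
# defined as 1 on a constant region.

#' Build the five texture matrices of a level map
#'
#' @param levels Integer 3D array: 0 outside the mask, 1..ng inside.
#' @param ng Number of gray levels.
#' @param alpha GLDM dependence tolerance (gray levels), default 0.
#' @return List of class \code{TextureMatrices}: \code{glcm}
#'   (ng x ng x 13 counts), \code{glrlm} (list of 13 ng x Nr count
#'   matrices), \code{glszm} (ng x Ns counts), \code{ngtdm} (ng x 2:
#'   n_i and s_i), \code{gldm} (ng x Nd counts), \code{nVoxels},
#'   \code{ng}.
#' @export
textureMatrices <- function(levels, ng, alpha = 0L) {
  stopifnot(length(dim(levels)) == 3L, ng >= 1L)
  storage.mode(levels) <- "integer"
  dims <- as.integer(dim(levels))
  structure(list(
    glcm = cpp_glcm(as.vector(levels), dims, as.integer(ng)),
    glrlm = cpp_glrlm(as.vector(levels), dims, as.integer(ng)),
    glszm = cpp_glszm(as.vector(levels), dims, as.integer(ng)),
    ngtdm = cpp_ngtdm(as.vector(levels), dims, as.integer(ng)),
    gldm = cpp_gldm(as.vector(levels), dims, as.integer(ng),
                    as.integer(alpha)),
    nVoxels = sum(levels > 0L), ng = as.integer(ng)),
    class = "TextureMatrices")
}

#' Texture feature names per class
#' @return Named list of character vectors (glcm, glrlm, glszm, ngtdm,
#'   gldm) with 24/16/16/5/14 entries.
#' @export
textureFeatureNames <- function() {
  list(
    glcm = c("Autocorrelation", "ClusterProminence", "ClusterShade",
             "ClusterTendency", "Contrast", "Correlation",
             "DifferenceAverage", "DifferenceEntropy",
             "DifferenceVariance", "Id", "Idm", "Idmn", "Idn", "Imc1",
             "Imc2", "InverseVariance", "JointAverage", "JointEnergy",
             "JointEntropy", "MCC", "MaximumProbability", "SumAverage",
             "SumEntropy", "SumSquares"),
    glrlm = c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
              "GrayLevelVariance", "HighGrayLevelRunEmphasis",
              "LongRunEmphasis", "LongRunHighGrayLevelEmphasis",
              "LongRunLowGrayLevelEmphasis", "LowGrayLevelRunEmphasis",
              "RunEntropy", "RunLengthNonUniformity",
              "RunLengthNonUniformityNormalized", "RunPercentage",
              "RunVariance", "ShortRunEmphasis",
              "ShortRunHighGrayLevelEmphasis",
              "ShortRunLowGrayLevelEmphasis"),
    glszm = c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
              "GrayLevelVariance", "HighGrayLevelZoneEmphasis",
              "LargeAreaEmphasis", "LargeAreaHighGrayLevelEmphasis",
              "LargeAreaLowGrayLevelEmphasis", "LowGrayLevelZoneEmphasis",
              "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
              "SmallAreaEmphasis", "SmallAreaHighGrayLevelEmphasis",
              "SmallAreaLowGrayLevelEmphasis", "ZoneEntropy",
              "ZonePercentage", "ZoneVariance"),
    ngtdm = c("Busyness", "Coarseness", "Complexity", "Contrast",
              "Strength"),
    gldm = c("DependenceEntropy", "DependenceNonUniformity",
             "DependenceNonUniformityNormalized", "DependenceVariance",
             "GrayLevelNonUniformity", "GrayLevelVariance",
             "HighGrayLevelEmphasis", "LargeDependenceEmphasis",
             "LargeDependenceHighGrayLevelEmphasis",
             "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
             "SmallDependenceEmphasis",
             "SmallDependenceHighGrayLevelEmphasis",
             "SmallDependenceLowGrayLevelEmphasis"))
}

#' The full feature registry
#'
#' @return data.frame with columns \code{class} and \code{feature};
#'   18 + 24 + 16 + 16 + 5 + 14 = 93 rows.
#' @export
featureRegistry <- function() {
  tn <- textureFeatureNames()
  rbind(data.frame(class = "firstorder", feature = firstOrderNames()),
        data.frame(class = "glcm", feature = tn$glcm),
        data.frame(class = "glrlm", feature = tn$glrlm),
        data.frame(class = "glszm", feature = tn$glszm),
        data.frame(class = "ngtdm", feature = tn$ngtdm),
        data.frame(class = "gldm", feature = tn$gldm))
}

.entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# 24 features of one normalized symmetric co-occurrence matrix
.glcmDirFeatures <- function(P, ng) {
  gi <- seq_len(ng)
  I <- row(P); J <- col(P)
  px <- rowSums(P)                       # == py by symmetry
  ux <- sum(gi * px)
  sx2 <- sum((gi - ux)^2 * px)
  ks <- 2:(2 * ng)
  psum <- vapply(ks, function(k) sum(P[I + J == k]), numeric(1))
  kd <- 0:(ng - 1)
  pdiff <- vapply(kd, function(k) sum(P[abs(I - J) == k]), numeric(1))
  da <- sum(kd * pdiff)
  hxy <- .entropy2(P)
  hx <- .entropy2(px)
  pos <- P > 0
  hxy1 <- -sum(P[pos] * log2(px[I[pos]] * px[J[pos]]))
  ppxy <- outer(px, px)
  hxy2 <- .entropy2(ppxy)
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
  corr <- if (sx2 > 0) (sum(I * J * P) - ux^2) / sx2 else 1
  mcc <- if (ng == 1L) 1 else {
    keep <- px > 0
    if (sum(keep) < 2L) 1 else {
      Ps <- P[keep, keep, drop = FALSE]
      pxs <- px[keep]
      A <- Ps / pxs                      # rows / px(i)
      B <- sweep(Ps, 2, pxs, "/")        # cols / py(k)
      ev <- sort(Re(eigen(A %*% t(B), only.values = TRUE)$values),
                 decreasing = TRUE)
      sqrt(max(ev[2], 0))
    }
  }
  c(Autocorrelation = sum(I * J * P),
    ClusterProminence = sum((I + J - 2 * ux)^4 * P),
    ClusterShade = sum((I + J - 2 * ux)^3 * P),
    ClusterTendency = sum((I + J - 2 * ux)^2 * P),
    Contrast = sum((I - J)^2 * P),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = .entropy2(pdiff),
    DifferenceVariance = sum((kd - da)^2 * pdiff),
    Id = sum(pdiff / (1 + kd)),
    Idm = sum(pdiff / (1 + kd^2)),
    Idmn = sum(pdiff / (1 + kd^2 / ng^2)),
    Idn = sum(pdiff / (1 + kd / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(pdiff[kd > 0] / kd[kd > 0]^2),
    JointAverage = ux,
    JointEnergy = sum(P^2),
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = max(P),
    SumAverage = sum(ks * psum),
    SumEntropy = .entropy2(psum),
    SumSquares = sx2)
}

# shared formula family for (gray level x size) count matrices:
# GLRLM runs, GLSZM zones, GLDM dependencies
.sizeMatrixFeatures <- function(Praw, nTotalVox) {
  ng <- nrow(Praw); ns <- ncol(Praw)
  N <- sum(Praw)
  p <- Praw / N
  gi <- seq_len(ng); sj <- seq_len(ns)
  pg <- rowSums(p); ps <- colSums(p)
  G2 <- matrix(gi^2, ng, ns)
  S2 <- matrix(sj^2, ng, ns, byrow = TRUE)
  mug <- sum(pg * gi); mus <- sum(ps * sj)
  list(smallEmph = sum(ps / sj^2),
       largeEmph = sum(ps * sj^2),
       gln = sum(rowSums(Praw)^2) / N,
       glnn = sum(rowSums(Praw)^2) / N^2,
       sizeNonUnif = sum(colSums(Praw)^2) / N,
       sizeNonUnifNorm = sum(colSums(Praw)^2) / N^2,
       percentage = N / nTotalVox,
       glVar = sum(pg * (gi - mug)^2),
       sizeVar = sum(ps * (sj - mus)^2),
       entropy = .entropy2(p),
       lowGl = sum(pg / gi^2),
       highGl = sum(pg * gi^2),
       smallLow = sum(p / (G2 * S2)),
       smallHigh = sum(p * G2 / S2),
       largeLow = sum(p * S2 / G2),
       largeHigh = sum(p * G2 * S2))
}

.glrlmDirFeatures <- function(Praw, nVox) {
  f <- .sizeMatrixFeatures(Praw, nVox)
  c(GrayLevelNonUniformity = f$gln,
    GrayLevelNonUniformityNormalized = f$glnn,
    GrayLevelVariance = f$glVar,
    HighGrayLevelRunEmphasis = f$highGl,
    LongRunEmphasis = f$largeEmph,
    LongRunHighGrayLevelEmphasis = f$largeHigh,
    LongRunLowGrayLevelEmphasis = f$largeLow,
    LowGrayLevelRunEmphasis = f$lowGl,
    RunEntropy = f$entropy,
    RunLengthNonUniformity = f$sizeNonUnif,
    RunLengthNonUniformityNormalized = f$sizeNonUnifNorm,
    RunPercentage = f$percentage,
    RunVariance = f$sizeVar,
    ShortRunEmphasis = f$smallEmph,
    ShortRunHighGrayLevelEmphasis = f$smallHigh,
    ShortRunLowGrayLevelEmphasis = f$smallLow)
}

.glszmFeatures <- function(Praw, nVox) {
  f <- .sizeMatrixFeatures(Praw, nVox)
  c(GrayLevelNonUniformity = f$gln,
    GrayLevelNonUniformityNormalized = f$glnn,
    GrayLevelVariance = f$glVar,
    HighGrayLevelZoneEmphasis = f$highGl,
    LargeAreaEmphasis = f$largeEmph,
    LargeAreaHighGrayLevelEmphasis = f$largeHigh,
    LargeAreaLowGrayLevelEmphasis = f$largeLow,
    LowGrayLevelZoneEmphasis = f$lowGl,
    SizeZoneNonUniformity = f$sizeNonUnif,
    SizeZoneNonUniformityNormalized = f$sizeNonUnifNorm,
    SmallAreaEmphasis = f$smallEmph,
    SmallAreaHighGrayLevelEmphasis = f$smallHigh,
    SmallAreaLowGrayLevelEmphasis = f$smallLow,
    ZoneEntropy = f$entropy,
    ZonePercentage = f$percentage,
    ZoneVariance = f$sizeVar)
}

.ngtdmFeatures <- function(mat, ng) {
  ni <- mat[, 1]; si <- mat[, 2]
  nv <- sum(ni)
  if (nv == 0)   # no voxel has an in-mask neighbor
    return(c(Busyness = 0, Coarseness = 1e6, Complexity = 0,
             Contrast = 0, Strength = 0))
  pi_ <- ni / nv
  gi <- seq_len(ng)
  act <- which(pi_ > 0)
  ngp <- length(act)
  coars <- {
    den <- sum(pi_ * si)
    if (den == 0) 1e6 else min(1 / den, 1e6)
  }
  contr <- if (ngp <= 1L) 0 else {
    sum(outer(pi_[act], pi_[act]) * outer(gi[act], gi[act], "-")^2) /
      (ngp * (ngp - 1)) * sum(si) / nv
  }
  busy <- {
    # double sum over ordered pairs of occupied levels
    den <- sum(abs(outer(gi[act] * pi_[act], gi[act] * pi_[act], "-")))
    if (den == 0) 0 else sum(pi_ * si) / den
  }
  compl <- {
    tot <- 0
    for (a in act) for (b in act)
      tot <- tot + abs(gi[a] - gi[b]) *
        (pi_[a] * si[a] + pi_[b] * si[b]) / (pi_[a] + pi_[b])
    tot / nv
  }
  stren <- {
    den <- sum(si)
    if (den == 0) 0 else {
      tot <- 0
      for (a in act) for (b in act)
        tot <- tot + (pi_[a] + pi_[b]) * (gi[a] - gi[b])^2
      tot / den
    }
  }
  c(Busyness = busy, Coarseness = coars, Complexity = compl,
    Contrast = contr, Strength = stren)
}

.gldmFeatures <- function(Praw, nVox) {
  f <- .sizeMatrixFeatures(Praw, nVox)
  c(DependenceEntropy = f$entropy,
    DependenceNonUniformity = f$sizeNonUnif,
    DependenceNonUniformityNormalized = f$sizeNonUnifNorm,
    DependenceVariance = f$sizeVar,
    GrayLevelNonUniformity = f$gln,
    GrayLevelVariance = f$glVar,
    HighGrayLevelEmphasis = f$highGl,
    LargeDependenceEmphasis = f$largeEmph,
    LargeDependenceHighGrayLevelEmphasis = f$largeHigh,
    LargeDependenceLowGrayLevelEmphasis = f$largeLow,
    LowGrayLevelEmphasis = f$lowGl,
    SmallDependenceEmphasis = f$smallEmph,
    SmallDependenceHighGrayLevelEmphasis = f$smallHigh,
    SmallDependenceLowGrayLevelEmphasis = f$smallLow)
}

#' Compute the 75 texture features from built matrices
#'
#' GLCM and GLRLM features are averaged over the 13 directions
#' (directions without any voxel pair are skipped).
#'
#' @param mats A \code{\link{textureMatrices}} result.
#' @return Named numeric vector of 75 values, names
#'   \code{<class>_<Feature>}.
#' @export
textureFeatures <- function(mats) {
  stopifnot(inherits(mats, "TextureMatrices"))
  ng <- mats$ng
  # GLCM: average per-direction features over nonempty directions
  nd <- dim(mats$glcm)[3]
  acc <- NULL; used <- 0L
  for (d in seq_len(nd)) {
    C <- mats$glcm[, , d, drop = TRUE]
    if (ng == 1L) C <- matrix(C, 1, 1)
    tot <- sum(C)
    if (tot == 0) next
    f <- .glcmDirFeatures(C / tot, ng)
    acc <- if (is.null(acc)) f else acc + f
    used <- used + 1L
  }
  glcm <- if (used > 0L) acc / used else
    stats::setNames(rep(NA_real_, 24), textureFeatureNames()$glcm)
  # GLRLM: average over directions
  racc <- NULL; rused <- 0L
  for (d in seq_along(mats$glrlm)) {
    Praw <- mats$glrlm[[d]]
    if (sum(Praw) == 0) next
    f <- .glrlmDirFeatures(Praw, mats$nVoxels)
    racc <- if (is.null(racc)) f else racc + f
    rused <- rused + 1L
  }
  glrlm <- racc / rused
  out <- c(stats::setNames(glcm, paste0("glcm_", names(glcm))),
           stats::setNames(glrlm, paste0("glrlm_", names(glrlm))),
           stats::setNames(.glszmFeatures(mats$glszm, mats$nVoxels),
                           paste0("glszm_",
                                  textureFeatureNames()$glszm)),
           stats::setNames(.ngtdmFeatures(mats$ngtdm, ng),
                           paste0("ngtdm_",
                                  textureFeatureNames()$ngtdm)),
           stats::setNames(.gldmFeatures(mats$gldm, mats$nVoxels),
                           paste0("gldm_", textureFeatureNames()$gldm)))
  out
}
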