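# Independent brute-force reference implementations used as oracles.
# These are deliberately written from the raw definitions (explicit
# loops, exhaustive enumeration) and never share code with the package.

# ---- distance / thickness ------------------------------------------------

# exact 2D EDT by exhaustive minimization over background pixels;
# pixels of a phase with no background keep distance `cap`
bruteDistMap2d <- function(bin, cap = max(dim(bin)) / 2) {
  fg <- which(bin, arr.ind = TRUE)
  bg <- which(!bin, arr.ind = TRUE)
  d <- matrix(0, nrow(bin), ncol(bin))
  if (nrow(bg) == 0L) { d[bin] <- cap; return(d) }
  for (q in seq_len(nrow(fg))) {
    d[fg[q, 1], fg[q, 2]] <-
      sqrt(min((bg[, 1] - fg[q, 1])^2 + (bg[, 2] - fg[q, 2])^2))
  }
  d
}

# local thickness by maximal inscribed disc: for each foreground pixel,
# the diameter (pixels) of the largest disc containing it that fits in
# the phase; discs are centered at foreground pixels with radius = EDT
bruteInscribedDiscThickness <- function(bin) {
  d <- bruteDistMap2d(bin)
  fg <- which(bin, arr.ind = TRUE)
  th <- matrix(0, nrow(bin), ncol(bin))
  for (q in seq_len(nrow(fg))) {
    i <- fg[q, 1]; j <- fg[q, 2]
    covered <- sqrt((fg[, 1] - i)^2 + (fg[, 2] - j)^2) <=
      d[cbind(fg[, 1], fg[, 2])]
    th[i, j] <- 2 * max(d[cbind(fg[covered, 1], fg[covered, 2])])
  }
  th
}

# ---- texture matrices (exhaustive enumeration) ---------------------------

# the 13 unique distance-1 offsets (one of each +/- pair), in the
# canonical order used throughout
oracleDirs <- function() {
  matrix(c(1, 0, 0,  0, 1, 0,  0, 0, 1,
           1, 1, 0,  1, -1, 0,  1, 0, 1,  1, 0, -1,
           0, 1, 1,  0, 1, -1,
           1, 1, 1,  1, -1, 1,  1, 1, -1,  1, -1, -1),
         ncol = 3, byrow = TRUE)
}

oracleGLCM <- function(lev, ng) {
  dims <- dim(lev)
  dirs <- oracleDirs()
  out <- array(0, c(ng, ng, nrow(dirs)))
  for (q in seq_len(nrow(dirs))) {
    o <- dirs[q, ]
    for (k in seq_len(dims[3])) for (j in seq_len(dims[2]))
      for (i in seq_len(dims[1])) {
        a <- lev[i, j, k]
        if (a == 0) next
        for (sgn in c(1, -1)) {
          i2 <- i + sgn * o[1]; j2 <- j + sgn * o[2]; k2 <- k + sgn * o[3]
          if (i2 < 1 || i2 > dims[1] || j2 < 1 || j2 > dims[2] ||
              k2 < 1 || k2 > dims[3]) next
          b <- lev[i2, j2, k2]
          if (b == 0) next
          out[a, b, q] <- out[a, b, q] + 1
        }
      }
  }
  out
}

# runs per direction: walk every maximal lattice line, rle the levels
oracleGLRLM <- function(lev, ng) {
  dims <- dim(lev)
  dirs <- oracleDirs()
  allRuns <- vector("list", nrow(dirs))
  maxlen <- 1L
  for (q in seq_len(nrow(dirs))) {
    o <- dirs[q, ]
    runs <- list()
    for (k in seq_len(dims[3])) for (j in seq_len(dims[2]))
      for (i in seq_len(dims[1])) {
        # line start: predecessor outside the volume
        ip <- i - o[1]; jp <- j - o[2]; kp <- k - o[3]
        if (ip >= 1 && ip <= dims[1] && jp >= 1 && jp <= dims[2] &&
            kp >= 1 && kp <= dims[3]) next
        seqv <- integer(0)
        ii <- i; jj <- j; kk <- k
        while (ii >= 1 && ii <= dims[1] && jj >= 1 && jj <= dims[2] &&
               kk >= 1 && kk <= dims[3]) {
          seqv <- c(seqv, lev[ii, jj, kk])
          ii <- ii + o[1]; jj <- jj + o[2]; kk <- kk + o[3]
        }
        r <- rle(seqv)
        ok <- r$values != 0
        if (any(ok))
          runs[[length(runs) + 1L]] <-
            cbind(r$values[ok], r$lengths[ok])
      }
    runs <- do.call(rbind, runs)
    allRuns[[q]] <- runs
    if (!is.null(runs)) maxlen <- max(maxlen, runs[, 2])
  }
  lapply(allRuns, function(runs) {
    m <- matrix(0, ng, maxlen)
    if (!is.null(runs))
      for (r in seq_len(nrow(runs)))
        m[runs[r, 1], runs[r, 2]] <- m[runs[r, 1], runs[r, 2]] + 1
    m
  })
}

oracleGLSZM <- function(lev, ng) {
  dims <- dim(lev)
  seen <- array(FALSE, dims)
  zones <- NULL
  idx <- which(lev != 0, arr.ind = TRUE)
  for (q in seq_len(nrow(idx))) {
    p <- idx[q, ]
    if (seen[p[1], p[2], p[3]]) next
    g <- lev[p[1], p[2], p[3]]
    queue <- list(p); seen[p[1], p[2], p[3]] <- TRUE
    size <- 0L
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      size <- size + 1L
      for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
        if (di == 0 && dj == 0 && dk == 0) next
        w <- v + c(di, dj, dk)
        if (any(w < 1) || any(w > dims)) next
        if (seen[w[1], w[2], w[3]]) next
        if (lev[w[1], w[2], w[3]] != g) next
        seen[w[1], w[2], w[3]] <- TRUE
        queue[[length(queue) + 1L]] <- w
      }
    }
    zones <- rbind(zones, c(g, size))
  }
  m <- matrix(0, ng, max(zones[, 2]))
  for (r in seq_len(nrow(zones)))
    m[zones[r, 1], zones[r, 2]] <- m[zones[r, 1], zones[r, 2]] + 1
  m
}

oracleNGTDM <- function(lev, ng) {
  dims <- dim(lev)
  out <- matrix(0, ng, 2)
  idx <- which(lev != 0, arr.ind = TRUE)
  for (q in seq_len(nrow(idx))) {
    p <- idx[q, ]
    a <- lev[p[1], p[2], p[3]]
    nb <- c()
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      if (di == 0 && dj == 0 && dk == 0) next
      w <- p + c(di, dj, dk)
      if (any(w < 1) || any(w > dims)) next
      b <- lev[w[1], w[2], w[3]]
      if (b != 0) nb <- c(nb, b)
    }
    if (!length(nb)) next
    out[a, 1] <- out[a, 1] + 1
    out[a, 2] <- out[a, 2] + abs(a - mean(nb))
  }
  out
}

oracleGLDM <- function(lev, ng, alpha = 0L) {
  dims <- dim(lev)
  deps <- NULL
  idx <- which(lev != 0, arr.ind = TRUE)
  for (q in seq_len(nrow(idx))) {
    p <- idx[q, ]
    a <- lev[p[1], p[2], p[3]]
    dep <- 1L
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      if (di == 0 && dj == 0 && dk == 0) next
      w <- p + c(di, dj, dk)
      if (any(w < 1) || any(w > dims)) next
      b <- lev[w[1], w[2], w[3]]
      if (b != 0 && abs(a - b) <= alpha) dep <- dep + 1L
    }
    deps <- rbind(deps, c(a, dep))
  }
  m <- matrix(0, ng, max(deps[, 2]))
  for (r in seq_len(nrow(deps)))
    m[deps[r, 1], deps[r, 2]] <- m[deps[r, 1], deps[r, 2]] + 1
  m
}

# ---- texture features from matrices (explicit double-entry sums) ---------

oracleGlcmFeatures <- function(counts, ng) {
  P <- counts / sum(counts)
  px <- rowSums(P); py <- colSums(P)
  ux <- 0; for (i in 1:ng) ux <- ux + i * px[i]
  uy <- 0; for (j in 1:ng) uy <- uy + j * py[j]
  sx2 <- 0; for (i in 1:ng) sx2 <- sx2 + (i - ux)^2 * px[i]
  sy2 <- 0; for (j in 1:ng) sy2 <- sy2 + (j - uy)^2 * py[j]
  psum <- rep(0, 2 * ng); pdiff <- rep(0, ng)     # index k ; k-1
  for (i in 1:ng) for (j in 1:ng) {
    psum[i + j] <- psum[i + j] + P[i, j]
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + P[i, j]
  }
  f <- list()
  acc <- cp <- cs <- ct <- con <- corrN <- 0
  je <- jent <- mp <- 0
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    acc <- acc + i * j * p
    cp <- cp + (i + j - ux - uy)^4 * p
    cs <- cs + (i + j - ux - uy)^3 * p
    ct <- ct + (i + j - ux - uy)^2 * p
    con <- con + (i - j)^2 * p
    corrN <- corrN + i * j * p
    je <- je + p^2
    if (p > 0) jent <- jent - p * log2(p)
    mp <- max(mp, p)
  }
  da <- 0; for (k in 0:(ng - 1)) da <- da + k * pdiff[k + 1]
  de <- 0; dv <- 0; id <- idm <- idmn <- idn <- iv <- 0
  for (k in 0:(ng - 1)) {
    pk <- pdiff[k + 1]
    if (pk > 0) de <- de - pk * log2(pk)
    dv <- dv + (k - da)^2 * pk
    id <- id + pk / (1 + k)
    idm <- idm + pk / (1 + k^2)
    idmn <- idmn + pk / (1 + k^2 / ng^2)
    idn <- idn + pk / (1 + k / ng)
    if (k > 0) iv <- iv + pk / k^2
  }
  hx <- 0; for (i in 1:ng) if (px[i] > 0) hx <- hx - px[i] * log2(px[i])
  hy <- 0; for (j in 1:ng) if (py[j] > 0) hy <- hy - py[j] * log2(py[j])
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    if (P[i, j] > 0) hxy1 <- hxy1 - P[i, j] * log2(px[i] * py[j])
    if (px[i] * py[j] > 0)
      hxy2 <- hxy2 - px[i] * py[j] * log2(px[i] * py[j])
  }
  imc1 <- if (max(hx, hy) > 0) (jent - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - jent))))
  sa <- 0; se <- 0
  for (k in 2:(2 * ng)) {
    sa <- sa + k * psum[k]
    if (psum[k] > 0) se <- se - psum[k] * log2(psum[k])
  }
  mcc <- if (ng == 1) 1 else {
    keep <- which(px > 0)
    if (length(keep) < 2) 1 else {
      Q <- matrix(0, length(keep), length(keep))
      for (ai in seq_along(keep)) for (bj in seq_along(keep)) {
        s <- 0
        for (kk in seq_along(keep))
          s <- s + P[keep[ai], keep[kk]] * P[keep[bj], keep[kk]] /
            (px[keep[ai]] * py[keep[kk]])
        Q[ai, bj] <- s
      }
      ev <- sort(Re(eigen(Q, only.values = TRUE)$values),
                 decreasing = TRUE)
      sqrt(max(ev[2], 0))
    }
  }
  corr <- if (sx2 > 0 && sy2 > 0) (corrN - ux * uy) / sqrt(sx2 * sy2)
          else 1
  c(Autocorrelation = acc, ClusterProminence = cp, ClusterShade = cs,
    ClusterTendency = ct, Contrast = con, Correlation = corr,
    DifferenceAverage = da, DifferenceEntropy = de,
    DifferenceVariance = dv, Id = id, Idm = idm, Idmn = idmn,
    Idn = idn, Imc1 = imc1, Imc2 = imc2, InverseVariance = iv,
    JointAverage = ux, JointEnergy = je, JointEntropy = jent,
    MCC = mcc, MaximumProbability = mp, SumAverage = sa,
    SumEntropy = se, SumSquares = sx2)
}

# the shared small/large-emphasis family, explicit loops
oracleSizeFamily <- function(Praw, nVox) {
  ng <- nrow(Praw); ns <- ncol(Praw)
  N <- sum(Praw)
  p <- Praw / N
  sm <- lg <- sl <- sh <- ll <- lh <- ent <- 0
  for (i in 1:ng) for (s in 1:ns) {
    v <- p[i, s]
    sm <- sm + v / s^2; lg <- lg + v * s^2
    sl <- sl + v / (i^2 * s^2); sh <- sh + v * i^2 / s^2
    ll <- ll + v * s^2 / i^2; lh <- lh + v * i^2 * s^2
    if (v > 0) ent <- ent - v * log2(v)
  }
  pg <- rowSums(p); ps <- colSums(p)
  mug <- sum((1:ng) * pg); mus <- sum((1:ns) * ps)
  list(smallEmph = sm, largeEmph = lg, smallLow = sl, smallHigh = sh,
       largeLow = ll, largeHigh = lh, entropy = ent,
       gln = sum(rowSums(Praw)^2) / N, glnn = sum(rowSums(Praw)^2) / N^2,
       sizeNonUnif = sum(colSums(Praw)^2) / N,
       sizeNonUnifNorm = sum(colSums(Praw)^2) / N^2,
       percentage = N / nVox,
       glVar = sum(pg * ((1:ng) - mug)^2),
       sizeVar = sum(ps * ((1:ns) - mus)^2),
       lowGl = sum(pg / (1:ng)^2), highGl = sum(pg * (1:ng)^2))
}

oracleNgtdmFeatures <- function(mat, ng) {
  ni <- mat[, 1]; si <- mat[, 2]
  nv <- sum(ni); pi_ <- ni / nv
  act <- which(pi_ > 0); ngp <- length(act)
  den <- sum(pi_ * si)
  coars <- if (den == 0) 1e6 else min(1 / den, 1e6)
  contr <- 0
  if (ngp > 1) {
    for (a in act) for (b in act)
      contr <- contr + pi_[a] * pi_[b] * (a - b)^2
    contr <- contr / (ngp * (ngp - 1)) * sum(si) / nv
  }
  bden <- 0
  for (a in act) for (b in act)
    bden <- bden + abs(a * pi_[a] - b * pi_[b])
  busy <- if (bden == 0) 0 else sum(pi_ * si) / bden
  compl <- 0
  for (a in act) for (b in act)
    compl <- compl + abs(a - b) *
      (pi_[a] * si[a] + pi_[b] * si[b]) / (pi_[a] + pi_[b])
  compl <- compl / nv
  sden <- sum(si)
  stren <- 0
  if (sden > 0) {
    for (a in act) for (b in act)
      stren <- stren + (pi_[a] + pi_[b]) * (a - b)^2
    stren <- stren / sden
  }
  c(Busyness = busy, Coarseness = coars, Complexity = compl,
    Contrast = contr, Strength = stren)
}

# full 75-feature oracle from a level map
oracleTextureFeatures <- function(lev, ng) {
  nVox <- sum(lev != 0)
  gl <- oracleGLCM(lev, ng)
  acc <- NULL; used <- 0
  for (q in seq_len(dim(gl)[3])) {
    C <- matrix(gl[, , q], ng, ng)
    if (sum(C) == 0) next
    f <- oracleGlcmFeatures(C, ng)
    acc <- if (is.null(acc)) f else acc + f
    used <- used + 1
  }
  glcm <- acc / used
  rl <- oracleGLRLM(lev, ng)
  racc <- NULL; rused <- 0
  for (m in rl) {
    if (sum(m) == 0) next
    f <- oracleSizeFamily(m, nVox)
    v <- c(GrayLevelNonUniformity = f$gln,
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
    racc <- if (is.null(racc)) v else racc + v
    rused <- rused + 1
  }
  glrlm <- racc / rused
  fz <- oracleSizeFamily(oracleGLSZM(lev, ng), nVox)
  glszm <- c(GrayLevelNonUniformity = fz$gln,
             GrayLevelNonUniformityNormalized = fz$glnn,
             GrayLevelVariance = fz$glVar,
             HighGrayLevelZoneEmphasis = fz$highGl,
             LargeAreaEmphasis = fz$largeEmph,
             LargeAreaHighGrayLevelEmphasis = fz$largeHigh,
             LargeAreaLowGrayLevelEmphasis = fz$largeLow,
             LowGrayLevelZoneEmphasis = fz$lowGl,
             SizeZoneNonUniformity = fz$sizeNonUnif,
             SizeZoneNonUniformityNormalized = fz$sizeNonUnifNorm,
             SmallAreaEmphasis = fz$smallEmph,
             SmallAreaHighGrayLevelEmphasis = fz$smallHigh,
             SmallAreaLowGrayLevelEmphasis = fz$smallLow,
             ZoneEntropy = fz$entropy,
             ZonePercentage = fz$percentage,
             ZoneVariance = fz$sizeVar)
  ngt <- oracleNgtdmFeatures(oracleNGTDM(lev, ng), ng)
  fd <- oracleSizeFamily(oracleGLDM(lev, ng), nVox)
  gldm <- c(DependenceEntropy = fd$entropy,
            DependenceNonUniformity = fd$sizeNonUnif,
            DependenceNonUniformityNormalized = fd$sizeNonUnifNorm,
            DependenceVariance = fd$sizeVar,
            GrayLevelNonUniformity = fd$gln,
            GrayLevelVariance = fd$glVar,
            HighGrayLevelEmphasis = fd$highGl,
            LargeDependenceEmphasis = fd$largeEmph,
            LargeDependenceHighGrayLevelEmphasis = fd$largeHigh,
            LargeDependenceLowGrayLevelEmphasis = fd$largeLow,
            LowGrayLevelEmphasis = fd$lowGl,
            SmallDependenceEmphasis = fd$smallEmph,
            SmallDependenceHighGrayLevelEmphasis = fd$smallHigh,
            SmallDependenceLowGrayLevelEmphasis = fd$smallLow)
  c(stats::setNames(glcm, paste0("glcm_", names(glcm))),
    stats::setNames(glrlm, paste0("glrlm_", names(glrlm))),
    stats::setNames(glszm, paste0("glszm_", names(glszm))),
    stats::setNames(ngt, paste0("ngtdm_", names(ngt))),
    stats::setNames(gldm, paste0("gldm_", names(gldm))))
}

# ---- misc oracles --------------------------------------------------------

# AUC as the tie-corrected concordant-pair (Mann-Whitney) statistic
concordantPairAuc <- function(scores, y) {
  sp <- scores[y]; sn <- scores[!y]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# exact two-sided Mann-Whitney P by enumeration of all assignments
exactMwuP <- function(a, b) {
  pool <- c(a, b); n <- length(pool); na <- length(a)
  uObs <- sum(vapply(a, function(x) sum(x > b) + 0.5 * sum(x == b),
                     numeric(1)))
  combs <- utils::combn(n, na)
  us <- apply(combs, 2, function(ix) {
    aa <- pool[ix]; bb <- pool[-ix]
    sum(vapply(aa, function(x) sum(x > bb) + 0.5 * sum(x == bb),
               numeric(1)))
  })
  mu <- na * (n - na) / 2
  mean(abs(us - mu) >= abs(uObs - mu) - 1e-9)
}

# small random level map with an out-of-mask border sprinkled in
randomLevelMap <- function(dims, ng, seed, maskFrac = 0.85) {
  set.seed(seed)
  lev <- array(sample(0:ng, prod(dims), replace = TRUE,
                      prob = c(1 - maskFrac,
                               rep(maskFrac / ng, ng))),
               dims)
  if (all(lev == 0)) lev[1] <- 1L
  storage.mode(lev) <- "integer"
  lev
}
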