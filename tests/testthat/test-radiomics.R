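mk3 <- function(v, d) array(v, d)

test_that("fixed-bin-width discretization follows the floor formula", {
  a <- mk3(c(0, 24, 25, 50, 99, 99, 99, 99), c(2, 2, 2))
  m <- mk3(c(rep(TRUE, 4), rep(FALSE, 4)), c(2, 2, 2))
  d <- discretize(a, m, discretizationConfig(binWidth = 25))
  expect_identical(d$levels[m], c(1L, 1L, 2L, 3L))
  expect_identical(d$ng, 3L)

  expect_warning(
    dc <- discretize(mk3(rep(7, 8), c(2, 2, 2)),
                     mk3(rep(TRUE, 8), c(2, 2, 2))),
    "degenerate")
  expect_true(dc$constant)

  # uniform 0..255 with bin width 32: eight equally filled levels
  a2 <- mk3(rep(0:255, length.out = 256), c(8, 8, 4))
  d2 <- discretize(a2, mk3(rep(TRUE, 256), c(8, 8, 4)),
                   discretizationConfig(binWidth = 32))
  expect_identical(d2$ng, 8L)
  expect_true(all(tabulate(d2$levels[d2$levels > 0]) == 32L))
})

test_that("first-order features match their definitions", {
  f <- firstOrderFeatures(c(1, 2, 3), c(1L, 1L, 2L))
  expect_equal(unname(f["Mean"]), 2)
  expect_equal(unname(f["Median"]), 2)
  expect_equal(unname(f["Range"]), 2)

  # four equiprobable levels: entropy = 2 bits, uniformity = 1/4
  f4 <- firstOrderFeatures(c(10, 20, 30, 40), 1:4)
  expect_equal(unname(f4["Entropy"]), 2)
  expect_equal(unname(f4["Uniformity"]), 0.25)

  # moments against direct formula transcription
  set.seed(77)
  x <- rnorm(1000)
  mu <- sum(x) / 1000
  m2 <- sum((x - mu)^2) / 1000
  skew <- (sum((x - mu)^3) / 1000) / m2^1.5
  kurt <- (sum((x - mu)^4) / 1000) / m2^2
  fx <- firstOrderFeatures(x, rep(1L, 1000))
  expect_equal(unname(fx["Skewness"]), skew, tolerance = 1e-12)
  expect_equal(unname(fx["Kurtosis"]), kurt, tolerance = 1e-12)
  expect_equal(unname(fx["Variance"]), m2, tolerance = 1e-12)

  # single voxel: dispersion zero, moments at documented constants
  f1 <- firstOrderFeatures(5, 1L)
  expect_equal(unname(f1["Variance"]), 0)
  expect_equal(unname(f1["Skewness"]), 0)
})

test_that("the LoG filter behaves like a Laplacian of a Gaussian", {
  sp <- c(0.5, 0.5, 1)
  # constant image: exactly zero response
  v <- VoxelVolume(mk3(rep(3, 20^3), c(20, 20, 20)), sp)
  expect_equal(max(abs(voxelData(logFilter(v, 1)))), 0)

  # impulse response equals the separable kernel expansion
  imp <- array(0, c(41, 41, 21)); imp[21, 21, 11] <- 1
  out <- voxelData(logFilter(VoxelVolume(imp, sp), 1.5))
  g <- function(s) { r <- max(1, ceiling(4 * s)); x <- (-r):r
    k <- exp(-x^2 / (2 * s^2)); k / sum(k) }
  g2 <- function(s) { r <- max(2, ceiling(4 * s)); x <- (-r):r
    gg <- exp(-x^2 / (2 * s^2)); gg <- gg / sum(gg)
    k <- (x^2 - s^2) / s^4 * gg; k - mean(k) }
  sv <- 1.5 / sp
  expected <- 0
  for (ax in 1:3) {
    ks <- lapply(1:3, function(b) if (b == ax) sv[b]^2 * g2(sv[b])
                 else g(sv[b]))
    full <- outer(outer(ks[[1]], ks[[2]]), ks[[3]])
    r <- (dim(full) - 1) / 2
    pad <- array(0, dim(imp))
    pad[21 + (-r[1]:r[1]), 21 + (-r[2]:r[2]), 11 + (-r[3]:r[3])] <-
      full
    expected <- expected + pad
  }
  expect_equal(out, expected, tolerance = 1e-10)

  # matched bright blob: most negative response at the center
  n <- 32; ctr <- 16.5
  co <- expand.grid(i = 1:n, j = 1:n, k = 1:n)
  blob <- exp(-(((co$i - ctr))^2 + (co$j - ctr)^2 + (co$k - ctr)^2) /
                (2 * 4^2))
  vb <- VoxelVolume(array(blob, c(n, n, n)), c(1, 1, 1))
  resp <- voxelData(logFilter(vb, 4))
  expect_true(min(resp) == min(resp[16:17, 16:17, 16:17]))

  expect_warning(logFilter(VoxelVolume(imp, c(1, 1, 1)), 0.2),
                 "under-resolved")
  expect_error(filterConfig(logSigmasMm = c(2, 1)), "increasing")
})

test_that("a hand-enumerated 2x2 co-occurrence case is reproduced", {
  lev <- mk3(c(1L, 2L, 1L, 2L), c(2, 2, 1))  # rows (1,1) / (2,2)
  tm <- textureMatrices(lev, 2L)
  # the in-plane column direction pairs (1,1) and (2,2), twice each
  # after symmetrization
  horiz <- tm$glcm[, , 2]
  expect_equal(horiz, matrix(c(2, 0, 0, 2), 2, 2))
  expect_equal(horiz / sum(horiz),
               matrix(c(0.5, 0, 0, 0.5), 2, 2))
})

test_that("constant regions give the documented degenerate values", {
  lev <- mk3(rep(1L, 27), c(3, 3, 3))
  tm <- textureMatrices(lev, 1L)
  tf <- textureFeatures(tm)
  expect_equal(unname(tf["glcm_MaximumProbability"]), 1)
  expect_equal(unname(tf["glcm_Contrast"]), 0)
  expect_equal(unname(tf["gldm_GrayLevelVariance"]), 0)
  # dependence variance vanishes only when every voxel has the same
  # neighborhood size (boundary voxels of a cube do not)
  single <- mk3(1L, c(1, 1, 1))
  tf1 <- textureFeatures(textureMatrices(single, 1L))
  expect_equal(unname(tf1["gldm_DependenceVariance"]), 0)
  # one 26-connected zone of size 27
  expect_equal(dim(tm$glszm), c(1L, 27L))
  expect_equal(tm$glszm[1, 27], 1)
  # runs are per lattice line: direction (1,0,0) has 9 runs of length 3
  expect_equal(tm$glrlm[[1]][1, 3], 9)
})

test_that("matrices and all 75 features match the brute-force oracle", {
  for (seed in 1:6) {
    ng <- sample(2:4, 1)
    lev <- randomLevelMap(c(5, 5, 2), ng, seed)
    ng <- max(max(lev), ng)
    tm <- textureMatrices(lev, ng)
    expect_equal(unclass(tm$glcm)[seq_along(tm$glcm)],
                 oracleGLCM(lev, ng)[seq_along(tm$glcm)],
                 tolerance = 1e-12)
    oR <- oracleGLRLM(lev, ng)
    for (q in seq_along(oR)) {
      a <- tm$glrlm[[q]]; b <- oR[[q]]
      nc <- max(ncol(a), ncol(b))
      pad <- function(m) cbind(m, matrix(0, nrow(m), nc - ncol(m)))
      expect_equal(pad(a), pad(b), ignore_attr = TRUE)
    }
    expect_equal(as.numeric(tm$glszm),
                 as.numeric(oracleGLSZM(lev, ng)), tolerance = 1e-12)
    expect_equal(as.numeric(tm$ngtdm),
                 as.numeric(oracleNGTDM(lev, ng)), tolerance = 1e-12)
    expect_equal(as.numeric(tm$gldm),
                 as.numeric(oracleGLDM(lev, ng)), tolerance = 1e-12)
    expect_equal(textureFeatures(tm), oracleTextureFeatures(lev, ng),
                 tolerance = 1e-10)
  }
  # a 2D map exercised the same way
  lev2 <- randomLevelMap(c(6, 6, 1), 3, 99)
  ng2 <- max(lev2)
  expect_equal(textureFeatures(textureMatrices(lev2, ng2)),
               oracleTextureFeatures(lev2, ng2), tolerance = 1e-10)
})

test_that("matrix normalizations satisfy their accounting identities", {
  lev <- randomLevelMap(c(7, 6, 3), 4, 123)
  ng <- max(lev)
  tm <- textureMatrices(lev, ng)
  nVox <- sum(lev > 0)
  for (q in seq_len(dim(tm$glcm)[3])) {
    tot <- sum(tm$glcm[, , q])
    if (tot > 0)
      expect_equal(sum(tm$glcm[, , q] / tot), 1)
  }
  # zone sizes sum to the voxel count; dependence counts cover voxels
  expect_equal(sum(tm$glszm %*% seq_len(ncol(tm$glszm))), nVox)
  expect_equal(sum(tm$gldm), nVox)
})

test_that("feature extraction yields the full deterministic grid", {
  co <- generateCohort(cohortSpec(nPerGroup = c(2, 2, 2),
                                  regionShape = c(14, 14, 5)))
  s <- co$subjects[[1]]
  f <- suppressWarnings(extractFeatures(s$volume, s$mask))
  expect_length(f, 4 * 5 * 93)
  expect_true(all(is.finite(f)))
  parts <- strsplit(names(f), "|", fixed = TRUE)
  expect_true(all(lengths(parts) == 4L))
  cls <- table(vapply(parts, `[[`, "", 3))
  expect_equal(as.integer(cls[c("firstorder", "glcm", "glrlm", "glszm",
                                "ngtdm", "gldm")]) / 20L,
               c(18L, 24L, 16L, 16L, 5L, 14L))

  f2 <- suppressWarnings(extractFeatures(s$volume, s$mask))
  expect_identical(f, f2)

  fo <- suppressWarnings(
    extractFeatures(s$volume, s$mask,
                    filterCfg = filterConfig(logSigmasMm = 1.0,
                                             includeOriginal = FALSE)))
  expect_length(fo, 4 * 1 * 93)
})

test_that("features are invariant to intensity shifts except location
          statistics", {
  ph <- gaussianFieldPhantom(phantomSpec(kind = "gaussian_field",
                                         targetBvtv = 0.3,
                                         shape = c(16, 16, 6),
                                         noiseSd = 4, seed = 3))
  fc <- filterConfig(logSigmasMm = numeric(0))
  a <- extractFeatures(ph$volume, ph$mask, codes = "LF",
                       filterCfg = fc)
  shifted <- VoxelVolume(voxelData(ph$volume) + 500,
                         spacing(ph$volume))
  b <- extractFeatures(shifted, ph$mask, codes = "LF", filterCfg = fc)
  loc <- grepl("Minimum|Maximum|Mean$|Median|Percentile|Energy|RMS|RootMeanSquared",
               names(a))
  expect_equal(a[!loc], b[!loc], tolerance = 1e-9)
  expect_equal(unname(b["LF|original|firstorder|Mean"] -
                        a["LF|original|firstorder|Mean"]), 500,
               tolerance = 1e-9)
})

test_that("mean intensity falls as bone fraction rises (bright marrow)", {
  means <- vapply(c(0.5, 0.8, 1.1), function(t) {
    ph <- platePhantom(phantomSpec(plateThicknessMm = t,
                                   plateSeparationMm = 1.5,
                                   shape = c(48, 48, 4), noiseSd = 2,
                                   seed = 1))
    ex <- extractRegion(ph$volume, ph$mask, 1L)
    mean(voxelData(ex$volume)[ex$inRegion])
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})
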