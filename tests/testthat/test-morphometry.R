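test_that("noiseless plates binarize to the generating slab pattern", {
  ph <- platePhantom(phantomSpec(plateThicknessMm = 0.6,
                                 plateSeparationMm = 1.2,
                                 shape = c(48, 48, 6), noiseSd = 0))
  ex <- extractRegion(ph$volume, ph$mask, 1L)
  bone <- binarizeAdaptive(ex$volume, ex$inRegion)
  inm <- maskLabels(ph$mask) != 0
  rng <- lapply(1:3, function(ax) range(which(apply(inm, ax, any))))
  pat <- ph$bonePattern[rng[[1]][1]:rng[[1]][2],
                        rng[[2]][1]:rng[[2]][2],
                        rng[[3]][1]:rng[[3]][2]]
  expect_identical(bone[ex$inRegion], (pat & ex$inRegion)[ex$inRegion])
})

test_that("degenerate binarization inputs are handled", {
  v <- VoxelVolume(array(42, c(20, 20, 3)), c(0.234, 0.234, 1.5))
  m <- array(TRUE, c(20, 20, 3))
  bone <- binarizeAdaptive(v, m)
  expect_false(any(bone))  # constant image: tie goes to marrow

  # mask smaller than the window: global-threshold fallback with warning
  small <- array(FALSE, c(20, 20, 3)); small[9:12, 9:12, 2] <- TRUE
  vv <- VoxelVolume(array(rnorm(1200, 150, 30), c(20, 20, 3)),
                    c(0.234, 0.234, 1.5))
  expect_warning(binarizeAdaptive(vv, small), "global")
})

test_that("noisy plates binarize with < 5% voxel disagreement", {
  # noise at 10% of the bone/marrow contrast
  ph <- platePhantom(phantomSpec(plateThicknessMm = 0.6,
                                 plateSeparationMm = 1.2,
                                 shape = c(48, 48, 6), noiseSd = 10,
                                 seed = 4))
  ex <- extractRegion(ph$volume, ph$mask, 1L)
  bone <- binarizeAdaptive(ex$volume, ex$inRegion)
  inm <- maskLabels(ph$mask) != 0
  rng <- lapply(1:3, function(ax) range(which(apply(inm, ax, any))))
  pat <- ph$bonePattern[rng[[1]][1]:rng[[1]][2],
                        rng[[2]][1]:rng[[2]][2],
                        rng[[3]][1]:rng[[3]][2]] & ex$inRegion
  expect_lt(mean(bone[ex$inRegion] != pat[ex$inRegion]), 0.05)
})

test_that("slab and disc thickness follow the analytic diameters", {
  # infinite slab, 5 pixels wide, in-plane spacing 0.234 mm
  phase <- array(FALSE, c(24, 24, 1))
  phase[10:14, , 1] <- TRUE
  lt <- localThickness(phase, c(0.234, 0.234, 1.5))
  expect_false(lt$empty)
  expect_lte(abs(mean(lt$values) - 5 * 0.234), 0.234)

  # disc of radius 7: central skeleton value = 2 r pixels
  disc <- array(FALSE, c(31, 31, 1))
  ctr <- 16
  for (i in 1:31) for (j in 1:31)
    if ((i - ctr)^2 + (j - ctr)^2 <= 7^2) disc[i, j, 1] <- TRUE
  ltd <- localThickness(disc, c(1, 1, 1))
  expect_lte(abs(max(ltd$values) - 2 * 7), 2)

  # empty phase is flagged
  expect_true(localThickness(array(FALSE, c(4, 4, 1)),
                             c(1, 1, 1))$empty)
})

test_that("skeleton thickness agrees with the inscribed-disc oracle
          where the two notions coincide", {
  # slabs and long rectangles: both definitions give the width
  for (w in c(3, 5, 8)) {
    sl <- matrix(FALSE, 40, 40); sl[10:(9 + w), 3:38] <- TRUE
    lt <- localThickness(array(sl, c(40, 40, 1)), c(1, 1, 1))
    oracle <- bruteInscribedDiscThickness(sl)
    expect_lte(abs(mean(lt$values) - mean(oracle[sl])), 1.0)
  }
  # two well-separated discs: per-blob maxima match the diameters
  dd <- matrix(FALSE, 48, 48)
  for (i in 1:48) for (j in 1:48) {
    if ((i - 12)^2 + (j - 12)^2 <= 5^2) dd[i, j] <- TRUE
    if ((i - 34)^2 + (j - 34)^2 <= 9^2) dd[i, j] <- TRUE
  }
  lt <- localThickness(array(dd, c(48, 48, 1)), c(1, 1, 1))
  oracle <- bruteInscribedDiscThickness(dd)
  expect_lte(abs(max(lt$values) - max(oracle)), 2.0)
})

test_that("covering-disc thickness dominates the distance-ridge value
          on arbitrary blobs", {
  # on branched shapes the maximal covering disc through a skeleton
  # pixel is at least as large as twice its boundary distance
  for (seed in 1:3) {
    set.seed(seed)
    f <- matrix(rnorm(40 * 40), 40, 40)
    f <- gaussianSmooth(array(f, c(40, 40, 1)), 3, c(1, 1, 1))[, , 1]
    blob <- f > quantile(f, 0.7)
    lt <- localThickness(array(blob, c(40, 40, 1)), c(1, 1, 1))
    oracle <- bruteInscribedDiscThickness(blob)
    sk <- lt$skeleton[, , 1]
    expect_true(all(oracle[sk] >= lt$map[, , 1][sk] - 1e-9))
    # and the skeleton reaches into the thickest structure
    expect_gte(max(lt$values), 0.5 * max(oracle))
  }
})

test_that("plate parameters are recovered within one in-plane pixel", {
  ph <- platePhantom(phantomSpec(plateThicknessMm = 0.5,
                                 plateSeparationMm = 1.5,
                                 shape = c(64, 64, 8), noiseSd = 5,
                                 seed = 9))
  m <- subjectMorphometry(ph$volume, ph$mask)
  expect_lte(abs(m$bvtv - 0.25), 0.02)
  expect_lte(abs(m$tb_th_mm - 0.5), 0.234)
  expect_lte(abs(m$tb_sp_mm - 1.5), 0.234)
  expect_equal(m$tb_n_per_mm, m$bvtv / m$tb_th_mm)
})

test_that("degenerate regions give flagged single-phase parameters", {
  inm <- array(FALSE, c(10, 10, 2)); inm[3:8, 3:8, ] <- TRUE
  allBone <- inm
  p <- trabecularParams(allBone, inm, c(0.234, 0.234, 1.5))
  expect_equal(p$bvtv, 1.0)
  expect_equal(p$tb_sp_mm, 0)
  expect_true("no_marrow_phase" %in% attr(p, "flags"))
  expect_error(trabecularParams(allBone, array(FALSE, c(10, 10, 2)),
                                c(1, 1, 1)), "empty")
})

test_that("parameters respond monotonically to the plate geometry", {
  ts <- seq(0.5, 1.5, length.out = 5)
  bv <- vapply(ts, function(t) {
    ph <- platePhantom(phantomSpec(plateThicknessMm = t,
                                   plateSeparationMm = 1.5,
                                   shape = c(48, 48, 4), noiseSd = 0))
    subjectMorphometry(ph$volume, ph$mask)$bvtv
  }, numeric(1))
  expect_true(all(diff(bv) > 0))

  ss <- seq(0.8, 2.4, length.out = 5)
  sp <- vapply(ss, function(s) {
    ph <- platePhantom(phantomSpec(plateThicknessMm = 0.6,
                                   plateSeparationMm = s,
                                   shape = c(64, 64, 4), noiseSd = 0))
    subjectMorphometry(ph$volume, ph$mask)$tb_sp_mm
  }, numeric(1))
  expect_true(all(diff(sp) > 0))
})
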