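# Synthetic trabecular phantoms with analytically known parameters.
#
# Intensity convention throughout: trabecular bone is DARK and marrow is
# BRIGHT, emulating a balanced fast-field-echo acquisition in which
# marrow is signal-rich and trabeculae are signal-poor. Downstream
# binarization must be told which phase is bone (`boneIsDark`).

#' Reference group-level trabecular statistics
#'
#' Mean and standard deviation of the four trabecular parameters per
#' region (LF/MF/LT/MT) and severity group (normal / mild / advanced),
#' at the scale reported for subchondral bone on 3T knee MRI. Used as
#' the cohort generator's default group distributions.
#'
#' @return A data.frame with one row per (region, group) and columns
#'   \code{<param>_mean} / \code{<param>_sd} for bvtv, tbth, tbsp, tbn.
#' @export
referenceTrabecularStats <- function() {
  tab <- rbind(
    c("LF", "normal",   0.269, 0.005, 0.166, 0.004, 0.452, 0.008, 1.615, 0.031),
    c("LF", "mild",     0.269, 0.005, 0.166, 0.004, 0.452, 0.008, 1.615, 0.030),
    c("LF", "advanced", 0.273, 0.006, 0.168, 0.004, 0.448, 0.013, 1.621, 0.040),
    c("MF", "normal",   0.269, 0.006, 0.162, 0.004, 0.442, 0.010, 1.652, 0.032),
    c("MF", "mild",     0.269, 0.005, 0.163, 0.004, 0.444, 0.010, 1.644, 0.034),
    c("MF", "advanced", 0.273, 0.005, 0.164, 0.003, 0.437, 0.009, 1.662, 0.029),
    c("LT", "normal",   0.266, 0.006, 0.162, 0.004, 0.449, 0.009, 1.633, 0.029),
    c("LT", "mild",     0.267, 0.005, 0.164, 0.006, 0.451, 0.011, 1.625, 0.042),
    c("LT", "advanced", 0.268, 0.006, 0.166, 0.005, 0.452, 0.009, 1.617, 0.033),
    c("MT", "normal",   0.264, 0.006, 0.159, 0.004, 0.443, 0.011, 1.660, 0.035),
    c("MT", "mild",     0.264, 0.005, 0.159, 0.004, 0.442, 0.009, 1.664, 0.035),
    c("MT", "advanced", 0.269, 0.005, 0.163, 0.004, 0.442, 0.008, 1.651, 0.027))
  out <- data.frame(region = tab[, 1], group = tab[, 2],
                    stringsAsFactors = FALSE)
  vals <- matrix(as.numeric(tab[, -(1:2)]), nrow = nrow(tab))
  colnames(vals) <- c("bvtv_mean", "bvtv_sd", "tbth_mean", "tbth_sd",
                      "tbsp_mean", "tbsp_sd", "tbn_mean", "tbn_sd")
  cbind(out, as.data.frame(vals))
}

#' Reference age structure per severity group
#'
#' @return data.frame with group, age mean and sd (years).
#' @export
referenceAgeStats <- function() {
  data.frame(group = c("normal", "mild", "advanced"),
             age_mean = c(37.2, 56.5, 64.7),
             age_sd = c(9.4, 9.9, 9.9))
}

#' Default acquisition spacing (mm)
#'
#' In-plane resolution 0.234 x 0.234 mm, slice thickness 1.5 mm — the
#' BFFE-like grid the generators and tests assume by default.
#' @return Numeric triple.
#' @export
defaultSpacing <- function() c(0.234, 0.234, 1.5)

#' Phantom specification
#'
#' @param kind \code{"parallel_plate"}, \code{"rod_lattice"} or
#'   \code{"gaussian_field"}.
#' @param plateThicknessMm,plateSeparationMm Plate model geometry (mm).
#' @param targetBvtv Bone volume fraction in (0,1) (gaussian_field).
#' @param shape Integer triple of voxel counts.
#' @param spacingMm Positive voxel spacing triple (mm).
#' @param boneIntensity,marrowIntensity Phase intensities; bone must be
#'   darker than marrow.
#' @param noiseSd Additive Gaussian noise SD (intensity units).
#' @param structureScaleMm Smoothing scale of the gaussian_field kind.
#' @param seed Integer seed.
#' @return List of class \code{PhantomSpec}.
#' @export
phantomSpec <- function(kind = c("parallel_plate", "gaussian_field",
                                 "rod_lattice"),
                        plateThicknessMm = 0.5, plateSeparationMm = 1.5,
                        targetBvtv = 0.27, shape = c(64, 64, 16),
                        spacingMm = defaultSpacing(),
                        boneIntensity = 100, marrowIntensity = 200,
                        noiseSd = 0, structureScaleMm = 0.4, seed = 1L) {
  kind <- match.arg(kind)
  if (any(!is.finite(spacingMm)) || any(spacingMm <= 0))
    stop("spacingMm must be positive: got (",
         paste(signif(spacingMm, 4), collapse = ", "), ")")
  if (boneIntensity >= marrowIntensity)
    stop("bone must be darker than marrow (boneIntensity < marrowIntensity)")
  if (noiseSd < 0) stop("noiseSd must be nonnegative")
  structure(list(kind = kind, plateThicknessMm = plateThicknessMm,
                 plateSeparationMm = plateSeparationMm,
                 targetBvtv = targetBvtv, shape = as.integer(shape),
                 spacingMm = as.numeric(spacingMm),
                 boneIntensity = boneIntensity,
                 marrowIntensity = marrowIntensity, noiseSd = noiseSd,
                 structureScaleMm = structureScaleMm,
                 seed = as.integer(seed)),
            class = "PhantomSpec")
}

# interior-box mask: margins of `margin` voxels in-plane and marginZ slices
.interiorMask <- function(shape, code, margin = 3L, marginZ = 1L) {
  lab <- array(0L, shape)
  i <- (margin + 1L):(shape[1] - margin)
  j <- (margin + 1L):(shape[2] - margin)
  k <- (marginZ + 1L):max(marginZ + 1L, shape[3] - marginZ)
  lab[i, j, k] <- as.integer(code)
  lab
}

#' Parallel-plate phantom with analytic ground truth
#'
#' Alternating bone/marrow slabs perpendicular to the first in-plane
#' axis. The plate model gives closed-form parameters:
#' BV/TV = t/(t+s), Tb.Th = t, Tb.Sp = s, Tb.N = BV/TV / Tb.Th.
#'
#' @param spec A \code{\link{phantomSpec}} with kind "parallel_plate".
#' @param regionCode Mask label for the interior band (default LF).
#' @return List: \code{volume}, \code{mask}, \code{bonePattern} (logical
#'   array of the generating slab phase), \code{truth} (data.frame with
#'   bvtv, tb_th_mm, tb_sp_mm, tb_n_per_mm).
#' @examples
#' p <- platePhantom(phantomSpec(plateThicknessMm = 0.5,
#'                               plateSeparationMm = 1.5))
#' p$truth  # BV/TV = 0.25
#' @export
platePhantom <- function(spec, regionCode = 1L) {
  stopifnot(inherits(spec, "PhantomSpec"))
  if (spec$kind != "parallel_plate")
    stop("spec kind must be 'parallel_plate'")
  t <- spec$plateThicknessMm; s <- spec$plateSeparationMm
  finest <- min(spec$spacingMm)
  if (t < 2 * finest || s < 2 * finest)
    stop(sprintf(paste0("plate thickness/separation (%.3g/%.3g mm) below ",
                        "resolvability: each must be >= 2 x finest spacing ",
                        "(%.3g mm)"), t, s, 2 * finest))
  shape <- spec$shape
  sp1 <- spec$spacingMm[1]
  margin <- 3L
  # the mask band along the slab axis covers a whole number of pattern
  # periods, so the voxelized bone fraction matches t/(t+s) without a
  # partial-slab truncation bias
  nAvail <- shape[1] - 2L * margin
  period <- t + s
  K <- floor(nAvail * sp1 / period)
  if (K < 1L)
    stop("volume too small along the slab axis for one full period")
  n1 <- round(K * period / sp1)
  i0 <- margin + 1L
  # pattern phase anchored at the left edge of the mask band
  x <- (seq_len(shape[1]) - i0 + 0.5) * sp1
  boneLine <- (x %% period) < t & x > 0
  bone <- array(rep(boneLine, times = prod(shape[2:3])), shape)
  arr <- ifelse(bone, spec$boneIntensity, spec$marrowIntensity)
  if (spec$noiseSd > 0)
    arr <- arr + .withSeed(spec$seed,
                           array(stats::rnorm(prod(shape), 0, spec$noiseSd),
                                 shape))
  lab <- .interiorMask(shape, regionCode, margin = margin)
  lab[-(i0:(i0 + n1 - 1L)), , ] <- 0L
  truth <- data.frame(bvtv = t / (t + s), tb_th_mm = t, tb_sp_mm = s,
                      tb_n_per_mm = (t / (t + s)) / t)
  list(volume = VoxelVolume(arr, spec$spacingMm),
       mask = RegionMask(lab, spec$spacingMm),
       bonePattern = bone, truth = truth)
}

#' Correlated Gaussian random-field phantom
#'
#' White noise smoothed at \code{structureScaleMm} and thresholded at the
#' quantile that yields exactly \code{targetBvtv} bone voxels inside the
#' mask (to one-voxel quantization), so the BV/TV truth holds by
#' construction.
#'
#' @param spec A \code{\link{phantomSpec}} with kind "gaussian_field".
#' @param regionCode Mask label for the interior band.
#' @return List: \code{volume}, \code{mask}, \code{bonePattern},
#'   \code{truth} (achieved in-mask BV/TV; thickness/separation have no
#'   closed form for this kind and are reported NA).
#' @export
gaussianFieldPhantom <- function(spec, regionCode = 1L) {
  stopifnot(inherits(spec, "PhantomSpec"))
  if (spec$kind != "gaussian_field")
    stop("spec kind must be 'gaussian_field'")
  if (!is.finite(spec$targetBvtv) || spec$targetBvtv <= 0 ||
      spec$targetBvtv >= 1)
    stop("targetBvtv must lie in (0, 1)")
  shape <- spec$shape
  field <- .withSeed(spec$seed,
                     array(stats::rnorm(prod(shape)), shape))
  field <- gaussianSmooth(field, spec$structureScaleMm, spec$spacingMm)
  if (stats::sd(field) < 1e-12)
    stop("degenerate (constant) random field")
  lab <- .interiorMask(shape, regionCode)
  inMask <- lab != 0L
  q <- stats::quantile(field[inMask], probs = spec$targetBvtv, type = 1)
  bone <- field <= q             # bone dark <-> low field values
  achieved <- sum(bone & inMask) / sum(inMask)
  arr <- ifelse(bone, spec$boneIntensity, spec$marrowIntensity)
  if (spec$noiseSd > 0)
    arr <- arr + .withSeed(.deriveSeed(spec$seed, "noise"),
                           array(stats::rnorm(prod(shape), 0, spec$noiseSd),
                                 shape))
  truth <- data.frame(bvtv = achieved, tb_th_mm = NA_real_,
                      tb_sp_mm = NA_real_, tb_n_per_mm = NA_real_)
  list(volume = VoxelVolume(arr, spec$spacingMm),
       mask = RegionMask(lab, spec$spacingMm), bonePattern = bone,
       truth = truth)
}
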