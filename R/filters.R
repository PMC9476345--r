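# Separable convolution machinery and the Laplacian-of-Gaussian filter.
#
# Sigma is specified in millimetres and converted to voxels per axis, so
# the filter has the same physical scale on anisotropic grids (no
# resampling; morphometry and radiomics stay on identical grids).
# Boundaries are handled by mirror reflection. The response is
# scale-normalized (multiplied by sigma^2), so blobs of matching scale
# give comparable magnitudes across sigmas.

# Reflect-padded 1D convolution along `axis` of a 3D array.
.convolveAxis <- function(arr, kernel, axis) {
  r <- (length(kernel) - 1L) %/% 2L
  if (r == 0L) return(arr * kernel)
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  x <- aperm(arr, perm)
  dp <- dim(x)
  n <- dp[1]
  # mirror index (edge repeated): ... c b a | a b c ... | c b a ...
  pos <- (1L - r):(n + r)
  m <- ((pos - 1L) %% (2L * n))
  m <- ifelse(m >= n, 2L * n - 1L - m, m) + 1L
  xm <- matrix(x[m, , ], nrow = n + 2L * r)
  out <- matrix(0, nrow = n, ncol = ncol(xm))
  for (j in seq_along(kernel))
    out <- out + kernel[j] * xm[j:(j + n - 1L), , drop = FALSE]
  dim(out) <- dp
  aperm(out, order(perm))
}

.gaussKernel <- function(sigmaVox) {
  r <- max(1L, ceiling(4 * sigmaVox))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigmaVox^2))
  k / sum(k)
}

# Sampled second derivative of a Gaussian, adjusted to annihilate
# constants exactly (discrete zero-sum).
.gaussD2Kernel <- function(sigmaVox) {
  r <- max(2L, ceiling(4 * sigmaVox))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigmaVox^2))
  g <- g / sum(g)
  k <- (x^2 - sigmaVox^2) / sigmaVox^4 * g
  k - mean(k)
}

#' Gaussian smoothing with physical-units sigma
#'
#' @param x A \linkS4class{VoxelVolume} or 3D array.
#' @param sigmaMm Gaussian scale in mm (scalar).
#' @param spacingMm Voxel spacing (ignored when \code{x} is a VoxelVolume).
#' @return Same type as \code{x}.
#' @export
gaussianSmooth <- function(x, sigmaMm, spacingMm = NULL) {
  isVol <- is(x, "VoxelVolume")
  arr <- if (isVol) voxelData(x) else x
  sp <- if (isVol) spacing(x) else spacingMm
  stopifnot(length(sp) == 3L, sigmaMm > 0)
  for (ax in 1:3)
    arr <- .convolveAxis(arr, .gaussKernel(sigmaMm / sp[ax]), ax)
  if (isVol) VoxelVolume(arr, sp) else arr
}

#' Laplacian-of-Gaussian filter
#'
#' Band-pass edge-enhancing filter: the image is smoothed with a Gaussian
#' of physical scale \code{sigmaMm} and the Laplacian is taken, as one
#' separable pass per axis. A bright blob of matching scale yields the
#' most negative response at its center.
#'
#' @param volume A \linkS4class{VoxelVolume}.
#' @param sigmaMm Filter scale in mm (> 0).
#' @return A \linkS4class{VoxelVolume} of the same shape and spacing.
#' @examples
#' v <- VoxelVolume(array(rnorm(27e2), c(30, 30, 3)), c(0.234, 0.234, 1.5))
#' f <- logFilter(v, 1.0)
#' @export
logFilter <- function(volume, sigmaMm) {
  stopifnot(is(volume, "VoxelVolume"))
  if (!is.numeric(sigmaMm) || length(sigmaMm) != 1L || sigmaMm <= 0)
    stop("sigmaMm must be a single positive number")
  sp <- spacing(volume)
  if (sigmaMm < min(sp) / 2)
    warning(sprintf("LoG sigma %.3g mm is under-resolved on spacing (%s) mm",
                    sigmaMm, paste(signif(sp, 3), collapse = ", ")))
  arr <- voxelData(volume)
  out <- array(0, dim(arr))
  for (ax in 1:3) {
    sVox <- sigmaMm / sp
    part <- arr
    for (bx in setdiff(1:3, ax))
      part <- .convolveAxis(part, .gaussKernel(sVox[bx]), bx)
    # sigma^2-normalized second derivative in physical units:
    # sigma_mm^2 * (1/spacing^2) d2/di2 == sigmaVox^2 * d2/di2
    part <- .convolveAxis(part, sVox[ax]^2 * .gaussD2Kernel(sVox[ax]), ax)
    out <- out + part
  }
  VoxelVolume(out, sp, origin = volume@origin)
}

#' Filter configuration for radiomics extraction
#'
#' @param logSigmasMm Positive increasing LoG scales in mm.
#' @param includeOriginal Extract from the unfiltered image too?
#' @return A list of class \code{FilterConfig}.
#' @export
filterConfig <- function(logSigmasMm = c(1.0, 1.5, 2.0, 2.5),
                         includeOriginal = TRUE) {
  if (length(logSigmasMm) &&
      (any(logSigmasMm <= 0) || is.unsorted(logSigmasMm, strictly = TRUE)))
    stop("logSigmasMm must be strictly positive and increasing")
  structure(list(logSigmasMm = logSigmasMm,
                 includeOriginal = isTRUE(includeOriginal)),
            class = "FilterConfig")
}
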