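# Fixed-bin-width gray-level discretization, the prerequisite of every
# texture matrix. The gray axis is re-anchored at the in-mask minimum of
# the region on the image being analyzed, so texture features are
# invariant to adding a constant to the image.

#' Discretization configuration
#'
#' @param binWidth Positive bin width on the intensity axis (default 25
#'   intensity units).
#' @param minLevels Guard: warn if fewer than this many levels result.
#' @return List of class \code{DiscretizationConfig}.
#' @export
discretizationConfig <- function(binWidth = 25, minLevels = 2L) {
  if (!is.numeric(binWidth) || binWidth <= 0)
    stop("binWidth must be positive")
  structure(list(binWidth = binWidth, minLevels = as.integer(minLevels)),
            class = "DiscretizationConfig")
}

#' Discretize in-mask intensities into gray levels
#'
#' level(x) = floor((x - min_in_mask) / binWidth) + 1; out-of-mask
#' voxels get level 0 and never contribute to texture matrices.
#'
#' @param x 3D numeric array or \linkS4class{VoxelVolume}.
#' @param inMask Logical array of the same shape; must be nonempty.
#' @param cfg A \code{\link{discretizationConfig}}.
#' @return List: \code{levels} (integer array, 0 outside the mask),
#'   \code{ng} (number of levels), \code{constant} (flag: single-level
#'   region).
#' @examples
#' a <- array(c(0, 24, 25, 50, 0, 0, 0, 0), c(2, 2, 2))
#' m <- array(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
#'            c(2, 2, 2))
#' discretize(a, m, discretizationConfig(binWidth = 25))$ng  # 3
#' @export
discretize <- function(x, inMask, cfg = discretizationConfig()) {
  if (is(x, "VoxelVolume")) x <- voxelData(x)
  stopifnot(identical(dim(x), dim(inMask)), is.logical(inMask))
  if (!any(inMask)) stop("mask is empty")
  lev <- array(0L, dim(x))
  v <- x[inMask]
  lev[inMask] <- as.integer(floor((v - min(v)) / cfg$binWidth)) + 1L
  ng <- max(lev)
  if (ng < cfg$minLevels)
    warning("region discretized to ", ng,
            " gray level(s); texture features take their degenerate values")
  list(levels = lev, ng = ng, constant = ng == 1L)
}
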