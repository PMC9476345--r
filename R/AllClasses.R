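#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib boneRadiomics, .registration = TRUE
NULL

#' Region code vocabulary
#'
#' Integer label codes for the four subchondral regions of interest:
#' lateral/medial femoral condyle (LF/MF) and lateral/medial tibial
#' plateau (LT/MT).
#'
#' @return Named integer vector mapping region names to mask label codes.
#' @export
regionCodes <- function() {
  c(LF = 1L, MF = 2L, LT = 3L, MT = 4L)
}

#' VoxelVolume: a 3D intensity grid with physical spacing
#'
#' Container for a scalar 3D image on an (optionally anisotropic) voxel
#' grid. Axis order is (slice-plane row, slice-plane column, slice);
#' \code{spacing} gives the voxel edge length in mm per axis in the same
#' order.
#'
#' @slot data 3D numeric array of intensities.
#' @slot spacing Numeric triple, voxel spacing in mm (all > 0).
#' @slot origin Numeric triple, physical origin in mm.
#' @export
setClass("VoxelVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric"))

setValidity("VoxelVolume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, sprintf("spacing must be 3 positive finite values (got %s)",
                          paste(signif(object@spacing, 4), collapse = ", ")))
  if (length(object@origin) != 3L)
    msg <- c(msg, "origin must have length 3")
  if (anyNA(object@data) || any(!is.finite(object@data)))
    msg <- c(msg, "data contains non-finite values")
  if (length(msg)) msg else TRUE
})

#' Construct a VoxelVolume
#'
#' @param data 3D numeric array.
#' @param spacing Numeric triple of voxel spacings in mm.
#' @param origin Numeric triple, defaults to zeros.
#' @return A \linkS4class{VoxelVolume}.
#' @examples
#' v <- VoxelVolume(array(rnorm(8), c(2, 2, 2)), spacing = c(0.234, 0.234, 1.5))
#' spacing(v)
#' @export
VoxelVolume <- function(data, spacing, origin = c(0, 0, 0)) {
  new("VoxelVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' RegionMask: integer region labels aligned to a VoxelVolume
#'
#' @slot labels 3D integer array; 0 = background, other values must be in
#'   the code map.
#' @slot spacing Numeric triple, voxel spacing in mm.
#' @slot codeMap Named integer vector mapping region names to label codes.
#' @export
setClass("RegionMask",
  representation(labels = "array", spacing = "numeric", codeMap = "integer"))

setValidity("RegionMask", function(object) {
  msg <- character()
  if (length(dim(object@labels)) != 3L)
    msg <- c(msg, "labels must be a 3D array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive values")
  bad <- setdiff(unique(as.integer(object@labels)), c(0L, object@codeMap))
  if (length(bad))
    msg <- c(msg, sprintf("labels outside vocabulary: {%s}",
                          paste(sort(bad), collapse = ", ")))
  if (is.null(names(object@codeMap)) || anyDuplicated(object@codeMap))
    msg <- c(msg, "codeMap must be a named vector of distinct codes")
  if (length(msg)) msg else TRUE
})

#' Construct a RegionMask
#'
#' @param labels 3D integer (or coercible) array of region labels.
#' @param spacing Numeric triple of voxel spacings in mm.
#' @param codeMap Named integer vector of allowed codes;
#'   default \code{regionCodes()}.
#' @return A \linkS4class{RegionMask}.
#' @export
RegionMask <- function(labels, spacing, codeMap = regionCodes()) {
  storage.mode(labels) <- "integer"
  new("RegionMask", labels = labels, spacing = as.numeric(spacing),
      codeMap = codeMap)
}

#' @describeIn VoxelVolume-class voxel spacing in mm
#' @param x A VoxelVolume or RegionMask.
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @export
setMethod("spacing", "VoxelVolume", function(x) x@spacing)

#' @export
setMethod("spacing", "RegionMask", function(x) x@spacing)

#' Intensity array of a VoxelVolume
#' @param x A VoxelVolume.
#' @return The 3D numeric array.
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @export
setMethod("voxelData", "VoxelVolume", function(x) x@data)

#' Label array of a RegionMask
#' @param x A RegionMask.
#' @return The 3D integer array of labels.
#' @export
setGeneric("maskLabels", function(x) standardGeneric("maskLabels"))

#' @export
setMethod("maskLabels", "RegionMask", function(x) x@labels)

#' Code map of a RegionMask
#' @param x A RegionMask.
#' @export
setGeneric("codeMap", function(x) standardGeneric("codeMap"))

#' @export
setMethod("codeMap", "RegionMask", function(x) x@codeMap)

setMethod("show", "VoxelVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("VoxelVolume %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(signif(object@spacing, 4), collapse = " x ")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "RegionMask", function(object) {
  d <- dim(object@labels)
  cnt <- table(factor(object@labels[object@labels != 0L],
                      levels = object@codeMap,
                      labels = names(object@codeMap)))
  cat(sprintf("RegionMask %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(signif(object@spacing, 4), collapse = " x ")))
  cat("  voxels per region:",
      paste(sprintf("%s=%d", names(cnt), as.integer(cnt)), collapse = ", "),
      "\n")
})

#' @export
setMethod("dim", "VoxelVolume", function(x) dim(x@data))

#' @export
setMethod("dim", "RegionMask", function(x) dim(x@labels))
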