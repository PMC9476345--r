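# NIfTI reading/writing and geometric consistency checks.
# On-disk format is NIfTI-1 (.nii / .nii.gz); masks are integer-typed.

#' Read a 3D volume from NIfTI
#'
#' Spacing is taken from the file header (\code{pixdim}). A trailing
#' singleton 4th dimension (as written by some tools) is squeezed.
#'
#' @param path Path to a .nii or .nii.gz file.
#' @return A \linkS4class{VoxelVolume}.
#' @export
readVolume <- function(path) {
  arr <- .readNiftiArray(path)
  VoxelVolume(arr$data, spacing = arr$spacing)
}

#' Read a region mask from NIfTI
#'
#' @param path Path to a .nii or .nii.gz file holding integer labels.
#' @param codeMap Named integer vector of allowed codes.
#' @return A \linkS4class{RegionMask}.
#' @export
readMask <- function(path, codeMap = regionCodes()) {
  arr <- .readNiftiArray(path)
  lab <- arr$data
  if (any(lab != round(lab)))
    stop("mask file '", path, "' contains non-integer labels")
  RegionMask(lab, spacing = arr$spacing, codeMap = codeMap)
}

.readNiftiArray <- function(path) {
  if (!file.exists(path))
    stop("file not found: '", path, "'")
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop("failed to read NIfTI '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  data <- array(as.vector(img), dim(img))
  d <- dim(data)
  if (length(d) == 4L && d[4] == 1L) {
    data <- array(data, d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L)
    stop("'", path, "' is not a 3D volume (dims: ",
         paste(d, collapse = "x"), ")")
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("'", path, "' has nonpositive voxel spacing: ",
         paste(signif(sp, 4), collapse = ", "))
  list(data = data, spacing = sp)
}

#' Write a VoxelVolume to NIfTI
#'
#' @param x A \linkS4class{VoxelVolume}.
#' @param path Output path (.nii or .nii.gz).
#' @param datatype NIfTI storage type; \code{"float"} for intensities.
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(x, path, datatype = "float") {
  img <- RNifti::asNifti(voxelData(x))
  RNifti::pixdim(img) <- spacing(x)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write a RegionMask to NIfTI (integer-typed)
#'
#' @param x A \linkS4class{RegionMask}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeMask <- function(x, path) {
  img <- RNifti::asNifti(maskLabels(x))
  RNifti::pixdim(img) <- spacing(x)
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' Check that a volume and mask form a consistent pair
#'
#' Passes iff shapes match, spacings agree within \code{tol} mm, and all
#' nonzero mask labels are in the mask's code map. Each violation is
#' reported with the offending values.
#'
#' @param volume A \linkS4class{VoxelVolume}.
#' @param mask A \linkS4class{RegionMask}.
#' @param tol Spacing agreement tolerance in mm.
#' @return Invisibly, a list with the validated pair.
#' @export
validatePair <- function(volume, mask, tol = 1e-6) {
  stopifnot(is(volume, "VoxelVolume"), is(mask, "RegionMask"))
  msg <- character()
  if (!identical(dim(volume), dim(mask)))
    msg <- c(msg, sprintf("shape mismatch: volume %s vs mask %s",
                          paste(dim(volume), collapse = "x"),
                          paste(dim(mask), collapse = "x")))
  dsp <- abs(spacing(volume) - spacing(mask))
  if (any(dsp > tol))
    msg <- c(msg, sprintf("spacing mismatch: volume (%s) vs mask (%s)",
                          paste(spacing(volume), collapse = ", "),
                          paste(spacing(mask), collapse = ", ")))
  bad <- setdiff(unique(as.integer(maskLabels(mask))), c(0L, codeMap(mask)))
  if (length(bad))
    msg <- c(msg, sprintf("mask labels outside vocabulary: {%s}",
                          paste(sort(bad), collapse = ", ")))
  if (length(msg))
    stop("volume/mask pair invalid:\n  ", paste(msg, collapse = "\n  "))
  invisible(list(volume = volume, mask = mask))
}

#' Crop a volume and mask to one region's bounding box
#'
#' Returns the sub-volume and a logical sub-mask flagging all and only
#' the voxels carrying \code{code}; spacing is preserved.
#'
#' @param volume A \linkS4class{VoxelVolume}.
#' @param mask A \linkS4class{RegionMask}.
#' @param code Integer region code or region name (e.g. \code{"LF"}).
#' @return List with \code{volume} (VoxelVolume cropped), \code{inRegion}
#'   (logical array, same dims) and \code{code}.
#' @export
extractRegion <- function(volume, mask, code) {
  validatePair(volume, mask)
  cm <- codeMap(mask)
  if (is.character(code)) {
    if (!code %in% names(cm))
      stop("unknown region name '", code, "'")
    code <- cm[[code]]
  }
  code <- as.integer(code)
  if (!code %in% cm)
    stop("region code ", code, " not in vocabulary {",
         paste(cm, collapse = ", "), "}")
  hit <- maskLabels(mask) == code
  if (!any(hit))
    stop("region absent: no voxels labeled ", code, " (",
         names(cm)[match(code, cm)], ")")
  rng <- lapply(1:3, function(ax) {
    pr <- apply(hit, ax, any)
    range(which(pr))
  })
  sub <- voxelData(volume)[rng[[1]][1]:rng[[1]][2],
                           rng[[2]][1]:rng[[2]][2],
                           rng[[3]][1]:rng[[3]][2], drop = FALSE]
  subHit <- hit[rng[[1]][1]:rng[[1]][2],
                rng[[2]][1]:rng[[2]][2],
                rng[[3]][1]:rng[[3]][2], drop = FALSE]
  list(volume = VoxelVolume(sub, spacing(volume)),
       inRegion = subHit, code = code)
}
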