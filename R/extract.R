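# Full radiomics extraction: per region x image type (original + LoG
# scales), the 93 registry features, deterministically named and ordered
# "region|image|class|feature".

.imageTypeName <- function(sigmaMm) sprintf("log%.1fmm", sigmaMm)

#' Extract all radiomics features of one subject
#'
#' For every requested region and every image type (original and each
#' LoG scale), intensities are taken inside the region, re-anchored and
#' discretized per (region, image), and the 18 first-order + 75 texture
#' features are computed: 93 values per (region, image type).
#'
#' @param volume A \linkS4class{VoxelVolume}.
#' @param mask A \linkS4class{RegionMask}.
#' @param codes Region names to extract (default: all in the code map);
#'   regions absent from the mask are skipped with a warning.
#' @param filterCfg A \code{\link{filterConfig}}.
#' @param discCfg A \code{\link{discretizationConfig}}.
#' @return Named numeric vector; names are
#'   \code{region|image|class|feature}, e.g.
#'   \code{"LF|original|glcm|Imc1"}.
#' @export
extractFeatures <- function(volume, mask, codes = NULL,
                            filterCfg = filterConfig(),
                            discCfg = discretizationConfig()) {
  validatePair(volume, mask)
  cm <- codeMap(mask)
  if (is.null(codes)) codes <- names(cm)
  present <- unique(as.integer(maskLabels(mask)))
  sp <- spacing(volume)
  voxVol <- prod(sp)
  images <- list()
  if (filterCfg$includeOriginal) images[["original"]] <- volume
  for (s in filterCfg$logSigmasMm)
    images[[.imageTypeName(s)]] <- logFilter(volume, s)
  out <- numeric(0)
  for (rg in codes) {
    if (!cm[[rg]] %in% present) {
      warning("region ", rg, " absent from mask; block omitted")
      next
    }
    for (im in names(images)) {
      ex <- extractRegion(images[[im]], mask, rg)
      vals <- voxelData(ex$volume)[ex$inRegion]
      dz <- discretize(voxelData(ex$volume), ex$inRegion, cfg = discCfg)
      fo <- firstOrderFeatures(vals, dz$levels[ex$inRegion], voxVol)
      tx <- textureFeatures(textureMatrices(dz$levels, dz$ng))
      block <- c(fo, tx)
      cls <- c(rep("firstorder", length(fo)),
               sub("_.*$", "", names(tx)))
      feat <- c(names(fo), sub("^[a-z]+_", "", names(tx)))
      names(block) <- paste(rg, im, cls, feat, sep = "|")
      out <- c(out, block)
    }
  }
  out
}

#' Extract features for every subject of a cohort
#'
#' @param cohort A \code{Cohort} from \code{\link{generateCohort}}.
#' @param filterCfg,discCfg Extraction configuration.
#' @return data.frame: subject_id, group, age, then one column per
#'   feature (syntactic names are not enforced; columns keep the
#'   \code{region|image|class|feature} names).
#' @export
cohortFeatures <- function(cohort, filterCfg = filterConfig(),
                           discCfg = discretizationConfig()) {
  stopifnot(inherits(cohort, "Cohort"))
  rows <- lapply(cohort$subjects, function(s)
    extractFeatures(s$volume, s$mask, filterCfg = filterCfg,
                    discCfg = discCfg))
  feats <- do.call(rbind, rows)
  meta <- data.frame(
    subject_id = vapply(cohort$subjects, `[[`, "", "id"),
    group = vapply(cohort$subjects, `[[`, "", "group"),
    age = vapply(cohort$subjects, `[[`, 0, "age"))
  out <- cbind(meta, as.data.frame(feats, check.names = FALSE))
  rownames(out) <- NULL
  out
}
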