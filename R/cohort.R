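# Multi-subject synthetic cohorts: per-subject volumes holding four
# region phantoms (LF/MF/LT/MT blocks side by side), with group/age
# structure matching the reference cohort scale (n = 32/27/29; ages
# 37.2 +- 9.4 / 56.5 +- 9.9 / 64.7 +- 9.9 years).
#
# Per-region parameters are drawn independently across regions given the
# group (no cross-region covariance is specified by the reference
# statistics). Each region is a correlated-field phantom whose target
# BV/TV is the drawn value — BV/TV is therefore exact by construction —
# and whose correlation scale follows the drawn thickness/separation.

#' Cohort specification
#'
#' @param nPerGroup Named or positional integer triple
#'   (normal, mild, advanced).
#' @param paramStats Per-(region, group) parameter means/sds, shaped like
#'   \code{\link{referenceTrabecularStats}()} (the default).
#' @param ageStats Per-group age mean/sd (years), default
#'   \code{\link{referenceAgeStats}()}.
#' @param regionShape Voxel dimensions of each region block.
#' @param spacingMm Voxel spacing (mm).
#' @param boneIntensity,marrowIntensity Phase intensities (bone darker).
#' @param noiseSd Additive Gaussian noise SD.
#' @param seed Global integer seed; every subject/region seed derives
#'   from it.
#' @return List of class \code{CohortSpec}.
#' @export
cohortSpec <- function(nPerGroup = c(normal = 32L, mild = 27L,
                                     advanced = 29L),
                       paramStats = referenceTrabecularStats(),
                       ageStats = referenceAgeStats(),
                       regionShape = c(32L, 32L, 32L),
                       spacingMm = defaultSpacing(),
                       boneIntensity = 100, marrowIntensity = 200,
                       noiseSd = 5, seed = 1L) {
  nPerGroup <- as.integer(nPerGroup)
  if (length(nPerGroup) != 3L || any(nPerGroup < 2L))
    stop("nPerGroup must give >= 2 subjects for each of the three groups")
  sdCols <- grep("_sd$", names(paramStats), value = TRUE)
  if (any(as.matrix(paramStats[, sdCols]) < 0) || any(ageStats$age_sd < 0))
    stop("all standard deviations must be nonnegative")
  if (any(paramStats$bvtv_mean <= 0 | paramStats$bvtv_mean >= 1))
    stop("group BV/TV means must lie in (0, 1): got ",
         paste(signif(paramStats$bvtv_mean[
           paramStats$bvtv_mean <= 0 | paramStats$bvtv_mean >= 1], 4),
           collapse = ", "))
  structure(list(nPerGroup = stats::setNames(nPerGroup,
                                             c("normal", "mild", "advanced")),
                 paramStats = paramStats, ageStats = ageStats,
                 regionShape = as.integer(regionShape),
                 spacingMm = as.numeric(spacingMm),
                 boneIntensity = boneIntensity,
                 marrowIntensity = marrowIntensity,
                 noiseSd = noiseSd, seed = as.integer(seed)),
            class = "CohortSpec")
}

#' Generate a synthetic cohort
#'
#' @param spec A \code{\link{cohortSpec}}.
#' @return List of class \code{Cohort}: \code{subjects} (each with
#'   \code{id}, \code{group}, \code{age}, \code{volume}, \code{mask}),
#'   \code{truth} (data.frame of per-subject per-region drawn and
#'   achieved ground-truth parameters) and \code{spec}.
#' @examples
#' \donttest{
#' co <- generateCohort(cohortSpec(nPerGroup = c(3, 3, 3),
#'                                 regionShape = c(16, 16, 8)))
#' length(co$subjects)
#' }
#' @export
generateCohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  groups <- rep(names(spec$nPerGroup), times = spec$nPerGroup)
  n <- length(groups)
  ids <- sprintf("S%03d", seq_len(n))
  codes <- regionCodes()
  rs <- spec$regionShape
  ages <- numeric(n)
  subjects <- vector("list", n)
  truth <- vector("list", n)
  for (si in seq_len(n)) {
    g <- groups[si]
    ag <- spec$ageStats[spec$ageStats$group == g, ]
    ages[si] <- .withSeed(.deriveSeed(spec$seed, paste0("age", si)),
                          stats::rnorm(1, ag$age_mean, ag$age_sd))
    vol <- array(0, c(rs[1], rs[2] * length(codes), rs[3]))
    lab <- array(0L, dim(vol))
    rows <- vector("list", length(codes))
    for (ri in seq_along(codes)) {
      rg <- names(codes)[ri]
      st <- spec$paramStats[spec$paramStats$region == rg &
                              spec$paramStats$group == g, ]
      if (nrow(st) != 1L)
        stop("paramStats must have exactly one row for region ", rg,
             ", group ", g)
      dseed <- .deriveSeed(spec$seed, paste0("draw", si, rg))
      draw <- .withSeed(dseed, c(
        bvtv = stats::rnorm(1, st$bvtv_mean, st$bvtv_sd),
        tbth = stats::rnorm(1, st$tbth_mean, st$tbth_sd),
        tbsp = stats::rnorm(1, st$tbsp_mean, st$tbsp_sd)))
      draw["bvtv"] <- min(max(draw["bvtv"], 0.01), 0.99)
      ph <- gaussianFieldPhantom(
        phantomSpec(kind = "gaussian_field", targetBvtv = draw[["bvtv"]],
                    shape = rs, spacingMm = spec$spacingMm,
                    boneIntensity = spec$boneIntensity,
                    marrowIntensity = spec$marrowIntensity,
                    noiseSd = spec$noiseSd,
                    structureScaleMm = (draw[["tbth"]] + draw[["tbsp"]]) / 4,
                    seed = .deriveSeed(spec$seed, paste0("field", si, rg))),
        regionCode = codes[[ri]])
      jr <- ((ri - 1L) * rs[2] + 1L):(ri * rs[2])
      vol[, jr, ] <- voxelData(ph$volume)
      lab[, jr, ] <- maskLabels(ph$mask)
      rows[[ri]] <- data.frame(
        subject_id = ids[si], group = g, region = rg,
        bvtv = ph$truth$bvtv, tb_th_mm = draw[["tbth"]],
        tb_sp_mm = draw[["tbsp"]],
        tb_n_per_mm = ph$truth$bvtv / draw[["tbth"]])
    }
    subjects[[si]] <- list(id = ids[si], group = g, age = ages[si],
                           volume = VoxelVolume(vol, spec$spacingMm),
                           mask = RegionMask(lab, spec$spacingMm))
    truth[[si]] <- do.call(rbind, rows)
  }
  tr <- do.call(rbind, truth)
  tr$age <- ages[match(tr$subject_id, ids)]
  structure(list(subjects = subjects, truth = tr, spec = spec),
            class = "Cohort")
}

#' @export
print.Cohort <- function(x, ...) {
  tab <- table(vapply(x$subjects, `[[`, "", "group"))
  cat(sprintf("Synthetic cohort: %d subjects (%s)\n", length(x$subjects),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Writes per-subject volume/mask NIfTI pairs and a subjects.csv with
#' columns subject_id, group, age, seed.
#'
#' @param cohort A \code{Cohort}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "Cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- do.call(rbind, lapply(cohort$subjects, function(s)
    data.frame(subject_id = s$id, group = s$group, age = s$age,
               seed = cohort$spec$seed)))
  for (s in cohort$subjects) {
    writeVolume(s$volume, file.path(dir, paste0(s$id, "_vol.nii.gz")))
    writeMask(s$mask, file.path(dir, paste0(s$id, "_mask.nii.gz")))
  }
  utils::write.csv(meta, file.path(dir, "subjects.csv"), row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
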