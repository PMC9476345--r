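# End-to-end orchestration: simulate -> morphometry -> features ->
# select -> classify, as one reproducible run driven by a single config
# and one global seed. Artifacts (params.csv, features.csv,
# selection.json, report.json, run.log) are written deterministically:
# rerunning the same config reproduces them byte for byte.

#' Default (demo-scale) run configuration
#'
#' 24 subjects (8 per group), 32^3-voxel region blocks, default
#' binarization/filter/discretization/selection settings, RBF kernel,
#' all four tasks.
#'
#' @param seed Global seed.
#' @return Nested list of class \code{RunConfig}.
#' @export
demoRunConfig <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    cohort = list(nPerGroup = c(8L, 8L, 8L),
                  regionShape = c(32L, 32L, 32L)),
    binarization = list(windowVoxels = 15L, offset = 10,
                        boneIsDark = TRUE),
    filters = list(logSigmasMm = c(1.0, 1.5, 2.0, 2.5),
                   includeOriginal = TRUE),
    discretization = list(binWidth = 25),
    selection = list(cvFolds = 5L, cvIterations = 10000L,
                     alphaRetain = 0.05, pruneR = 0.90),
    classification = list(kernel = "rbf", folds = 5L, cost = 1,
                          nBoot = 500L),
    tasks = names(taskDefinitions())),
    class = "RunConfig")
}

#' Load a run configuration from YAML
#'
#' Fields present in the file override the demo defaults block-wise;
#' unknown blocks raise an error naming them.
#'
#' @param path YAML file path.
#' @return A \code{RunConfig}.
#' @export
loadRunConfig <- function(path) {
  usr <- yaml::read_yaml(path)
  base <- demoRunConfig()
  bad <- setdiff(names(usr), names(base))
  if (length(bad))
    stop("unknown config block(s): ", paste(bad, collapse = ", "))
  for (nm in names(usr)) {
    if (is.list(base[[nm]]) && is.list(usr[[nm]]))
      base[[nm]] <- utils::modifyList(base[[nm]], usr[[nm]])
    else base[[nm]] <- usr[[nm]]
  }
  base
}

.asJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

#' Run the full pipeline
#'
#' Generates the synthetic cohort, computes trabecular parameters and
#' radiomics features for every subject, runs the selection chain and
#' trains/evaluates the radiomics-based and trabecular-parameter-based
#' SVM models for each task.
#'
#' @param config A \code{RunConfig} (see \code{\link{demoRunConfig}},
#'   \code{\link{loadRunConfig}}).
#' @param outDir Output directory for the artifacts (created).
#' @param writeVolumes Also write the NIfTI volume/mask pairs?
#' @return Invisibly, a list with cohort, params, features, selection
#'   and reports; artifacts are written under \code{outDir}.
#' @export
runPipeline <- function(config = demoRunConfig(), outDir,
                        writeVolumes = FALSE) {
  stopifnot(is.list(config))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(outDir, "run.log")
  logCon <- file(logPath, open = "wt")
  on.exit(close(logCon))
  logf <- function(fmt, ...) {
    writeLines(sprintf(fmt, ...), logCon)
  }
  seed <- as.integer(config$seed)
  logf("pipeline start; global seed %d", seed)
  t0 <- proc.time()["elapsed"]

  stage <- "simulate"
  res <- tryCatch({
    cspec <- do.call(cohortSpec,
                     c(config$cohort,
                       list(seed = .deriveSeed(seed, "cohort"))))
    cohort <- generateCohort(cspec)
    logf("simulate: %d subjects (%.1fs)", length(cohort$subjects),
         proc.time()["elapsed"] - t0)
    if (writeVolumes) writeCohort(cohort, file.path(outDir, "images"))

    stage <- "morphometry"
    bcfg <- do.call(binarizationConfig, config$binarization)
    params <- do.call(rbind, lapply(cohort$subjects, function(s) {
      p <- withCallingHandlers(
        subjectMorphometry(s$volume, s$mask, bcfg),
        warning = function(w) {
          logf("warning [morphometry %s]: %s", s$id,
               conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      cbind(data.frame(subject_id = s$id), p)
    }))
    utils::write.csv(params, file.path(outDir, "params.csv"),
                     row.names = FALSE)
    logf("morphometry: %d rows (%.1fs)", nrow(params),
         proc.time()["elapsed"] - t0)

    stage <- "features"
    fcfg <- do.call(filterConfig, config$filters)
    dcfg <- do.call(discretizationConfig, config$discretization)
    feats <- withCallingHandlers(
      cohortFeatures(cohort, fcfg, dcfg),
      warning = function(w) {
        logf("warning [features]: %s", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    utils::write.csv(feats, file.path(outDir, "features.csv"),
                     row.names = FALSE)
    logf("features: %d x %d (%.1fs)", nrow(feats), ncol(feats) - 3L,
         proc.time()["elapsed"] - t0)

    meta <- feats[, c("subject_id", "group", "age")]
    fx <- as.matrix(feats[, -(1:3), drop = FALSE])
    # wide measured-parameter matrix: one column per region x parameter
    pw <- stats::reshape(params, idvar = "subject_id",
                         timevar = "region", direction = "wide")
    pw <- pw[match(meta$subject_id, pw$subject_id), , drop = FALSE]
    px <- as.matrix(pw[, -1, drop = FALSE])

    stage <- "select+classify"
    ccfg <- config$classification
    selOut <- list()
    reports <- list()
    for (task in config$tasks) {
      td <- taskDefinitions()[[task]]
      keep <- meta$group %in% td$groups
      y <- meta$group[keep] %in% td$positive
      scfg <- do.call(selectionConfig,
                      c(config$selection,
                        list(seed = .deriveSeed(seed,
                                                paste0("sel_", task)))))
      sel <- withCallingHandlers(
        selectFeatures(fx[keep, , drop = FALSE], y, scfg),
        warning = function(w) {
          logf("warning [select %s]: %s", task, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      selOut[[task]] <- list(
        selected = as.list(sel$selected),
        lambda = sel$lambda,
        perRegionCounts = as.list(sel$perRegionCounts),
        nLasso = sum(sel$provenance$survivedLasso),
        nAfterMwu = sum(sel$provenance$survivedMwu, na.rm = TRUE),
        nFinal = length(sel$selected))
      xr <- cbind(fx[keep, sel$selected, drop = FALSE],
                  age = meta$age[keep])
      if (!length(sel$selected))
        logf("note [%s]: no radiomics features selected; age only",
             task)
      xt <- cbind(px[keep, , drop = FALSE], age = meta$age[keep])
      cseed <- .deriveSeed(seed, paste0("clf_", task))
      rRad <- classifierReport(xr, y, task, ccfg$kernel, ccfg$folds,
                               cseed, ccfg$cost, ccfg$nBoot)
      rTrab <- classifierReport(xt, y, task, ccfg$kernel, ccfg$folds,
                                cseed, ccfg$cost, ccfg$nBoot)
      reports[[task]] <- list(radiomics = rRad, trabecular = rTrab,
                              panel = compareModels(rRad, rTrab))
      logf("%s: AUC radiomics %.3f, trabecular %.3f (%.1fs)", task,
           rRad$auc, rTrab$auc, proc.time()["elapsed"] - t0)
    }
    .asJson(selOut, file.path(outDir, "selection.json"))
    .asJson(lapply(reports, function(r) list(
      radiomics = r$radiomics[c("auc", "aucCiLow", "aucCiHigh",
                                "accuracy", "sensitivity",
                                "specificity", "f1")],
      trabecular = r$trabecular[c("auc", "aucCiLow", "aucCiHigh",
                                  "accuracy", "sensitivity",
                                  "specificity", "f1")],
      rocRadiomics = r$radiomics$rocPoints,
      rocTrabecular = r$trabecular$rocPoints)),
      file.path(outDir, "report.json"))
    logf("done (%.1fs)", proc.time()["elapsed"] - t0)
    list(cohort = cohort, params = params, features = feats,
         selection = selOut, reports = reports)
  }, error = function(e) {
    logf("FAILED at stage %s: %s", stage, conditionMessage(e))
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(res)
}
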