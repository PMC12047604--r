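#' Subset a cohort by subject
#'
#' @param cohort a [LesionCohort-class].
#' @param idx integer indices or subject ids.
#' @return A [LesionCohort-class] in the given order.
#' @export
subsetCohort <- function(cohort, idx) {
  if (is.character(idx)) idx <- match(idx, cohort@subjectIds)
  newCohort(cohort@voxels[, idx, drop = FALSE], cohort@grid,
            cohort@subjectIds[idx], cohort@scores[idx])
}

#' Experiment configuration
#'
#' Assembles every knob of a simulation experiment: cohort generation,
#' ROI placement, score model (regional weights, noise fraction),
#' cross-validation, per-model training configs and evaluation settings.
#' The desk-scale defaults run the full pipeline on one CPU: an
#' 18x22x18 grid at 10 mm (a 1/10-scale head volume), 200 subjects,
#' three 3x3x3-voxel ROIs, and small CNN/FNN configs. `masterSeed` fully
#' determines every random draw through [deriveSeed()] per stage.
#'
#' @param n cohort size.
#' @param grid a [VolumeGrid-class].
#' @param medianMl,iqrMl,lambda cohort volume model (see
#'   [generateCohort()]).
#' @param manifest optional manifest path/data.frame: load instead of
#'   simulate.
#' @param nRois,roiSizeVox,minPrevalence ROI placement (see
#'   [placeROIs()]).
#' @param weights per-ROI contribution weights.
#' @param nf noise fraction in `[0,1]`.
#' @param models subset of `c("svr", "fnn", "cnn")`.
#' @param folds outer CV fold count.
#' @param cnnConfig,fnnConfig [trainingConfig()] objects.
#' @param cnnArch `"simple"` or `"regularized"`.
#' @param svrGrid optional SVR hyperparameter grid.
#' @param selectionAlpha,selectionMinCount mass-univariate selection for
#'   the SVR/FNN path.
#' @param occlusionWindow,occlusionStride occlusion geometry (voxels).
#' @param thresholdFrac,dilationMm attribution evaluation settings.
#' @param outputDir optional artifact directory.
#' @param masterSeed master seed.
#' @return A named list with class `"experimentConfig"`.
#' @export
experimentConfig <- function(n = 200,
                             grid = volumeGrid(c(18L, 22L, 18L), 10,
                                               "desk-MNI152-like"),
                             medianMl = 8, iqrMl = c(3.2, 20.9), lambda = 4,
                             manifest = NULL,
                             nRois = 3, roiSizeVox = 2, minPrevalence = 10,
                             weights = rep(1, nRois), nf = 0,
                             models = c("svr", "fnn", "cnn"), folds = 5,
                             cnnConfig = trainingConfig(
                               epochs = 40, batchSize = 8, lr = 1e-3,
                               channels = c(2L, 4L), seed = 1L),
                             fnnConfig = trainingConfig(
                               epochs = 300, batchSize = 32, lr = 5e-3,
                               weightDecay = 1, seed = 1L),
                             cnnArch = "simple", svrGrid = NULL,
                             selectionAlpha = 0.05, selectionMinCount = 10,
                             occlusionWindow = c(2, 2, 2),
                             occlusionStride = c(2, 2, 2),
                             thresholdFrac = 0.1, dilationMm = 5,
                             outputDir = NULL, masterSeed = 1L) {
  if (length(weights) != nRois) stop("weights length must equal nRois")
  if (nf < 0 || nf > 1) stop("nf must lie in [0,1]")
  models <- match.arg(models, c("svr", "fnn", "cnn"), several.ok = TRUE)
  cfg <- list(n = n, grid = grid, medianMl = medianMl, iqrMl = iqrMl,
              lambda = lambda, manifest = manifest, nRois = nRois,
              roiSizeVox = roiSizeVox, minPrevalence = minPrevalence,
              weights = weights, nf = nf, models = models, folds = folds,
              cnnConfig = cnnConfig, fnnConfig = fnnConfig,
              cnnArch = cnnArch, svrGrid = svrGrid,
              selectionAlpha = selectionAlpha,
              selectionMinCount = selectionMinCount,
              occlusionWindow = occlusionWindow,
              occlusionStride = occlusionStride,
              thresholdFrac = thresholdFrac, dilationMm = dilationMm,
              outputDir = outputDir, masterSeed = as.integer(masterSeed))
  class(cfg) <- "experimentConfig"
  cfg
}

configSnapshot <- function(cfg) {
  list(n = cfg$n, grid = list(dim = cfg$grid@dim, spacing = cfg$grid@spacing),
       nRois = cfg$nRois, weights = cfg$weights, nf = cfg$nf,
       folds = cfg$folds, masterSeed = cfg$masterSeed,
       thresholdFrac = cfg$thresholdFrac, dilationMm = cfg$dilationMm)
}

stageStep <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("experiment stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run a full simulation experiment
#'
#' End to end: generate (or load) the cohort, build the prevalence map,
#' place ROIs, simulate scores (weighted lesion loads, min-max
#' normalization, optional noise), run outer k-fold cross-validation per
#' model with per-fold preprocessing, concatenate test-fold predictions,
#' build individual and group attribution maps, and evaluate. Every
#' random draw derives from `cfg$masterSeed`.
#'
#' @param cfg an [experimentConfig()].
#' @param verbose print stage progress.
#' @return list with elements `reports` (per-model
#'   [EvaluationReport-class]), `predictions`, `scores`, `rois`,
#'   `cohort`, `groupAttribution` (per model), `folds`.
#' @export
runExperiment <- function(cfg, verbose = FALSE) {
  ms <- cfg$masterSeed
  say <- function(...) if (verbose) message(...)

  say("stage: cohort")
  cohort <- stageStep("cohort", {
    if (!is.null(cfg$manifest)) loadCohort(cfg$manifest)
    else generateCohort(cfg$n, cfg$grid, cfg$medianMl, cfg$iqrMl,
                        seed = deriveSeed(ms, "cohort"),
                        lambda = cfg$lambda)
  })
  n <- nSubjects(cohort)

  say("stage: prevalence + ROIs")
  prev <- stageStep("prevalence", buildPrevalenceMap(cohort))
  rois <- stageStep("rois", placeROIs(prev, cfg$nRois, cfg$roiSizeVox,
                                      cfg$minPrevalence,
                                      seed = deriveSeed(ms, "rois")))
  roiWeights(rois) <- cfg$weights

  say("stage: scores")
  scores <- stageStep("scores",
    simulateScores(cohort, rois, weights = cfg$weights, nf = cfg$nf,
                   seed = deriveSeed(ms, "noise")))
  y <- scoreValues(scores)

  fold <- stageStep("folds", makeFolds(n, cfg$folds,
                                       seed = deriveSeed(ms, "folds")))
  mask <- analysisMask(prev)

  corrected <- NULL
  if (any(cfg$models %in% c("svr", "fnn")))
    corrected <- volumeCorrect(cohort)

  predictions <- list()
  groupMaps <- list()
  models <- list()
  indivList <- list()
  metricsList <- list()
  reports <- list()

  for (model in cfg$models) {
    say("stage: model ", model)
    predVec <- rep(NA_real_, n)
    r2 <- numeric(cfg$folds)
    foldModels <- list()
    foldMaps <- list()       # svr/fnn: per-fold attribution maps
    indivMaps <- list()      # cnn: per-subject occlusion maps
    for (f in seq_len(cfg$folds)) {
      tr <- which(fold != f); te <- which(fold == f)
      if (model %in% c("svr", "fnn")) {
        selMask <- stageStep("feature-selection", {
          m <- massUnivariateSelect(subsetCohort(cohort, tr), y[tr],
                                    cfg$selectionMinCount,
                                    cfg$selectionAlpha)
          if (!any(m@selected))  # no voxel survives the screen
            m <- lesionSupportMask(subsetCohort(cohort, tr),
                                   cfg$selectionMinCount)
          m
        })
        Xtr <- flattenSelected(corrected[, tr, drop = FALSE], selMask)
        Xte <- flattenSelected(corrected[, te, drop = FALSE], selMask)
        if (model == "svr") {
          fitted <- stageStep("train-svr",
            trainSVR(Xtr, y[tr], paramGrid = cfg$svrGrid,
                     seed = deriveSeed(ms, sprintf("svr-fold%d", f))))
          foldMaps[[f]] <- svrBetaMap(fitted)
        } else {
          fcfg <- cfg$fnnConfig
          fcfg$seed <- deriveSeed(ms, sprintf("fnn-fold%d", f))
          fitted <- stageStep("train-fnn", trainFNN(Xtr, y[tr], fcfg))
          foldMaps[[f]] <- fnnWeightMap(fitted)
        }
        predVec[te] <- predictScores(fitted, Xte)
      } else {
        ccfg <- cfg$cnnConfig
        ccfg$seed <- deriveSeed(ms, sprintf("cnn-fold%d", f))
        fitted <- stageStep("train-cnn",
          trainCNN(subsetCohort(cohort, tr), y[tr], arch = cfg$cnnArch,
                   cfg = ccfg))
        predVec[te] <- predictScores(fitted, subsetCohort(cohort, te))
        for (i in te) {
          indivMaps[[subjectIds(cohort)[i]]] <- stageStep("occlusion",
            occlusionAttribution(fitted, getMap(cohort, i),
                                 cfg$occlusionWindow, cfg$occlusionStride))
        }
      }
      foldModels[[f]] <- fitted
      r2[f] <- r2OLS(predVec[te], y[te])
    }
    gmap <- if (model == "cnn") groupAttribution(indivMaps)
            else groupAttribution(foldMaps)
    metrics <- stageStep("evaluation",
      evaluateAttribution(gmap, rois, mask, cfg$thresholdFrac,
                          cfg$dilationMm))
    predictions[[model]] <- predVec
    groupMaps[[model]] <- gmap
    models[[model]] <- foldModels
    indivList[[model]] <- if (model == "cnn") indivMaps else foldMaps
    metricsList[[model]] <- metrics
    reports[[model]] <- evaluationReport(model, r2, metrics,
                                         configSnapshot(cfg))
  }

  result <- list(reports = reports, predictions = predictions,
                 scores = scores, rois = rois, cohort = cohort,
                 prevalence = prev, groupAttribution = groupMaps,
                 attributionMaps = indivList, models = models,
                 metrics = metricsList, folds = fold, config = cfg)
  if (!is.null(cfg$outputDir)) writeExperimentArtifacts(result)
  result
}

writeExperimentArtifacts <- function(result) {
  dir <- result$config$outputDir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeROISet(result$rois, file.path(dir, "rois.json"))
  utils::write.csv(
    data.frame(subject_id = subjectIds(result$cohort),
               score = scoreValues(result$scores),
               fold = result$folds,
               do.call(cbind, result$predictions)),
    file.path(dir, "scores_predictions.csv"), row.names = FALSE)
  for (model in names(result$reports)) {
    reportToJSON(result$reports[[model]],
                 file.path(dir, paste0("report_", model, ".json")))
    writeVolume(result$groupAttribution[[model]],
                file.path(dir, paste0("group_attr_", model, ".nii.gz")))
    utils::write.csv(result$metrics[[model]]$prCurve,
                     file.path(dir, paste0("pr_curve_", model, ".csv")),
                     row.names = FALSE)
    mdir <- file.path(dir, "models")
    dir.create(mdir, showWarnings = FALSE)
    for (f in seq_along(result$models[[model]])) {
      fitted <- result$models[[model]][[f]]
      saveModel(fitted, file.path(mdir, sprintf("%s_fold%d.rds", model, f)))
      if (is(fitted, "FNNModel") || is(fitted, "CNNModel"))
        writeTrainingCurve(fitted, file.path(
          mdir, sprintf("%s_fold%d_curve.csv", model, f)))
    }
    adir <- file.path(dir, "attributions")
    dir.create(adir, showWarnings = FALSE)
    maps <- result$attributionMaps[[model]]
    for (i in seq_along(maps)) {
      m <- maps[[i]]
      nm <- if (m@subjectId %in% c("group", "")) sprintf("fold%d", i)
            else m@subjectId
      writeVolume(m, file.path(adir, sprintf("%s_%s_attr.nii.gz",
                                             nm, m@method)))
    }
  }
  writeScalarMap(as.array(result$prevalence), getGrid(result$prevalence),
                 file.path(dir, "prevalence.nii.gz"))
  invisible(dir)
}

#' Compare evaluation reports side by side
#'
#' @param reports list of [EvaluationReport-class] objects (>= 2) from
#'   runs with a matching configuration family (same ROI count).
#' @return data.frame, one row per report, with R2 mean/sd, PR-AUC,
#'   ratios and Dice.
#' @export
compareReports <- function(reports) {
  if (length(reports) < 2) stop("need at least 2 reports to compare")
  nroiSet <- unique(vapply(reports, function(r)
    length(r@config$weights) %||% NA_integer_, numeric(1)))
  if (length(nroiSet) > 1) stop("incompatible reports: differing n_rois")
  out <- do.call(rbind, lapply(reports, function(r)
    data.frame(model = r@model, r2_mean = mean(r@r2Folds),
               r2_sd = stats::sd(r@r2Folds), pr_auc = r@prAUC,
               ratio = r@attributionRatio, dilated_ratio = r@dilatedRatio,
               dilation_factor = r@dilationFactor, dice = r@dice,
               n_false_negative = length(r@falseNegativeROIs))))
  rownames(out) <- NULL
  out
}
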