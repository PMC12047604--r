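smallConfig <- function(masterSeed = 5, ...) {
  experimentConfig(
    n = 60,
    grid = volumeGrid(c(14L, 16L, 14L), 12, "mini"),
    minPrevalence = 6, roiSizeVox = 2,
    cnnConfig = trainingConfig(epochs = 6, batchSize = 8, lr = 2e-3,
                               channels = c(2L, 3L), seed = 1),
    fnnConfig = trainingConfig(epochs = 60, batchSize = 16, lr = 5e-3,
                               weightDecay = 1, seed = 1),
    svrGrid = expand.grid(cost = c(1, 10), gamma = 0.1, epsilon = 0.1),
    masterSeed = masterSeed, ...)
}

test_that("an experiment run produces the full structural contract", {
  res <- memo("miniExp", runExperiment(smallConfig()))
  expect_named(res$reports, c("svr", "fnn", "cnn"))
  for (r in res$reports) {
    expect_s4_class(r, "EvaluationReport")
    expect_length(r@r2Folds, 5)
    expect_true(all(is.finite(r@r2Folds)))
    expect_true(r@prAUC >= 0 && r@prAUC <= 1)
    expect_true(r@dice >= 0 && r@dice <= 1)
  }
  # cross-validation coverage: exactly one test prediction per subject
  for (p in res$predictions) {
    expect_length(p, 60)
    expect_false(any(is.na(p)))
  }
  # every subject appears in exactly one test fold
  expect_equal(sort(unique(res$folds)), 1:5)
  expect_equal(length(res$folds), 60)
  # group maps exist per model and live on the experiment grid
  for (gm in res$groupAttribution)
    expect_true(sameGrid(gm, res$cohort))
})

test_that("identical config and master seed reproduce reports byte-identically", {
  res1 <- memo("miniExp", runExperiment(smallConfig()))
  res2 <- runExperiment(smallConfig())
  for (m in names(res1$reports))
    expect_identical(reportToJSON(res1$reports[[m]]),
                     reportToJSON(res2$reports[[m]]))
  expect_identical(res1$predictions, res2$predictions)
  expect_identical(scoreValues(res1$scores), scoreValues(res2$scores))
})

test_that("experiment artifacts are written and re-loadable", {
  dir <- tempfile()
  cfg <- smallConfig(masterSeed = 5, models = "fnn", outputDir = dir)
  res <- runExperiment(cfg)
  expect_true(file.exists(file.path(dir, "rois.json")))
  rois <- readROISet(file.path(dir, "rois.json"))
  expect_identical(rois@lo, res$rois@lo)
  csv <- read.csv(file.path(dir, "scores_predictions.csv"))
  expect_equal(nrow(csv), 60)
  expect_true(file.exists(file.path(dir, "report_fnn.json")))
  expect_true(file.exists(file.path(dir, "group_attr_fnn.nii.gz")))
  rep <- jsonlite::read_json(file.path(dir, "report_fnn.json"))
  expect_equal(rep$model, "fnn")
  # per-fold models reload and predict; training curves logged
  mPath <- file.path(dir, "models", "fnn_fold1.rds")
  expect_true(file.exists(mPath))
  m <- loadModel(mPath)
  expect_s4_class(m, "FNNModel")
  curve <- read.csv(file.path(dir, "models", "fnn_fold1_curve.csv"))
  expect_equal(nrow(curve), m@config$epochs)
  # per-fold weight maps written with the naming convention
  expect_true(file.exists(file.path(dir, "attributions",
                                    "fold1_fnn_weights_attr.nii.gz")))
})

test_that("report comparison validates its inputs", {
  res <- memo("miniExp", runExperiment(smallConfig()))
  tab <- compareReports(res$reports)
  expect_equal(nrow(tab), 3)
  expect_true(all(c("model", "r2_mean", "pr_auc", "ratio", "dice") %in%
                    names(tab)))
  expect_error(compareReports(res$reports[1]), "at least 2")
})

test_that("config validation rejects inconsistent settings", {
  expect_error(experimentConfig(nRois = 3, weights = c(1, 1)), "length")
  expect_error(experimentConfig(nf = 1.5), "nf")
})
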