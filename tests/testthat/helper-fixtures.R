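# Shared fixtures. Heavy end-to-end runs are memoized so several
# acceptance checks can share one experiment.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

toyGrid <- function(d = c(8L, 8L, 8L), spacing = 1) {
  volumeGrid(d, spacing, "toy")
}

# deterministic toy map: lesion in a corner block
toyMap <- function(grid = toyGrid(), id = "s1") {
  a <- array(0, gridDim(grid))
  a[2:4, 2:4, 2:4] <- 1
  lesionMap(a, grid, id)
}

# small random binary cohort as a plain matrix
toyCohortMatrix <- function(nvox, n, p = 0.2, seed = 1) {
  withr::with_seed(seed, matrix(rbinom(nvox * n, 1, p), nvox, n))
}

toyCohort <- function(grid = toyGrid(), n = 20, p = 0.2, seed = 1) {
  X <- toyCohortMatrix(prod(gridDim(grid)), n, p, seed)
  wmhlsm:::newCohort(X, grid, sprintf("s%02d", seq_len(n)))
}

deskGrid <- function() volumeGrid(c(18L, 22L, 18L), 10, "desk-MNI152-like")

# Experiment-1 replica at study scale (n = 200, all models); shared by
# several acceptance checks
deskExperiment1 <- function() {
  memo("exp1", runExperiment(experimentConfig(n = 200, masterSeed = 11)))
}

# the matching weighted run ({1,4,1}, CNN only, same master seed so the
# cohort, ROIs and folds are identical)
deskExperiment2 <- function() {
  memo("exp2", runExperiment(
    experimentConfig(n = 200, weights = c(1, 4, 1), models = "cnn",
                     masterSeed = 11)))
}

roiMeanAttribution <- function(gmap, rois) {
  idx <- wmhlsm:::roiIndexList(rois)
  vapply(idx, function(i) mean(as.array(gmap)[i]), numeric(1))
}
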