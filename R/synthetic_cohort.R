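#' Default lesion-seeding prior
#'
#' Builds a smooth propensity field that emulates the periventricular-
#' dominant spatial distribution of white matter hyperintensities: mass is
#' concentrated in a band around two deep, mirrored ellipsoidal shells
#' (one per hemisphere, standing in for the lateral ventricle walls), with
#' a mild seeded low-frequency modulation so different seeds give
#' different but equally plausible populations. Intensity outside the band
#' is exactly zero (values below 1% of the maximum are truncated).
#'
#' @param grid a [VolumeGrid-class].
#' @param seed integer seed; the field is a pure function of (grid, seed).
#' @param bandwidth radial Gaussian falloff of each lobe in normalized
#'   elliptical radius units (default 0.5; larger spreads lesions wider).
#' @return A [LesionPriorField-class].
#' @export
defaultLesionPrior <- function(grid, seed = 1L, bandwidth = 0.5) {
  d <- grid@dim
  # normalized coordinates in [-1, 1] per axis
  cx <- (seq_len(d[1]) - (d[1] + 1) / 2) / (d[1] / 2)
  cy <- (seq_len(d[2]) - (d[2] + 1) / 2) / (d[2] / 2)
  cz <- (seq_len(d[3]) - (d[3] + 1) / 2) / (d[3] / 2)
  X <- array(rep(cx, times = d[2] * d[3]), d)
  Y <- array(rep(rep(cy, each = d[1]), times = d[3]), d)
  Z <- array(rep(cz, each = d[1] * d[2]), d)

  # four periventricular caps (left/right x anterior/posterior horns)
  # joined by a weaker body band along each lateral ventricle
  bw <- max(bandwidth, 1e-3)
  cap <- function(x0, y0) {
    q <- sqrt(((X - x0) / 0.25)^2 + ((Y - y0) / 0.25)^2 + (Z / 0.25)^2)
    exp(-0.5 * (q / bw)^2)
  }
  body <- function(x0) {
    q <- sqrt(((X - x0) / 0.25)^2 + (Y / 0.5)^2 + (Z / 0.25)^2)
    exp(-0.5 * (q / bw)^2)
  }
  g <- cap(-0.3, -0.35) + cap(0.3, -0.35) + cap(-0.3, 0.35) +
    cap(0.3, 0.35) + 0.4 * (body(-0.3) + body(0.3))

  # seeded low-frequency modulation (fixed small set of cosine modes),
  # mirror-symmetrized in x so both hemispheres stay balanced
  mod <- with_seed(seed, {
    a <- stats::runif(6, -0.1, 0.1)
    ph <- stats::runif(6, 0, 2 * pi)
    m <- function(XX) 1 + a[1] * cos(pi * XX + ph[1]) +
      0.5 * a[2] * cos(pi * Y + ph[2]) + a[3] * cos(pi * Z + ph[3]) +
      a[4] * cos(2 * pi * XX + ph[4]) +
      0.5 * a[5] * cos(2 * pi * Y + ph[5]) + a[6] * cos(2 * pi * Z + ph[6])
    (m(X) + m(-X)) / 2
  })
  g <- g * pmax(mod, 0.1)
  # stay inside a brain-like ellipsoid
  brain <- (X / 0.95)^2 + (Y / 0.95)^2 + (Z / 0.95)^2 <= 1
  g[!brain] <- 0
  g[g < 0.01 * max(g)] <- 0
  new("LesionPriorField", grid = grid, intensity = g)
}

# lognormal (meanlog, sdlog) matched to a target median and IQR
lognormalFromMedianIQR <- function(medianMl, iqrMl) {
  stopifnot(length(iqrMl) == 2L, iqrMl[2] > iqrMl[1], medianMl > 0)
  meanlog <- log(medianMl)
  sdlog <- (log(iqrMl[2]) - log(iqrMl[1])) / (2 * stats::qnorm(0.75))
  c(meanlog = meanlog, sdlog = sdlog)
}

#' Sample one spatially clustered binary lesion map
#'
#' Lesions are grown from seed voxels drawn proportionally to the prior
#' using seeded region growing with 6-connectivity: at each step a
#' frontier voxel is accreted with probability proportional to its prior
#' intensity, producing confluent WMH-like blobs. The number of seeds is
#' `1 + Poisson(lambda)`. Growth stops at the rounded target voxel count,
#' so the realized volume matches the target up to voxel rounding.
#'
#' @param prior a [LesionPriorField-class].
#' @param targetVolumeMl target lesion volume in ml (0 gives an empty map).
#' @param seed integer seed; output is a pure function of the arguments.
#' @param lambda Poisson mean for the extra-seed count (default 4).
#' @param concentration exponent applied to the prior when weighting seed
#'   placement and accretion (default 3): higher values concentrate
#'   lesions in the high-prevalence core, mimicking the strong
#'   periventricular predominance of WMH.
#' @param subjectId id stamped on the returned map.
#' @return A [LesionMap-class].
#' @export
sampleLesionMap <- function(prior, targetVolumeMl, seed, lambda = 4,
                            concentration = 3, subjectId = "sim") {
  grid <- prior@grid
  # accretion weights are concentration-sharpened; seed placement uses the
  # prior itself so all high-prevalence foci are seeded evenly
  seedw <- as.numeric(prior@intensity)
  intens <- seedw^concentration
  pos <- which(intens > 0)
  vml <- voxelVolumeMl(grid)
  targetVox <- round(targetVolumeMl / vml)
  if (targetVox > 0.5 * length(pos))
    stop("unreachable target volume: ", targetVolumeMl,
         " ml exceeds half the positive-prior volume")
  les <- logical(length(intens))
  if (targetVox >= 1) {
    d <- grid@dim
    nxy <- d[1] * d[2]
    with_seed(seed, {
      nSeeds <- min(1 + stats::rpois(1, lambda), targetVox)
      seeds <- sample(pos, nSeeds, prob = seedw[pos]^2)
      les[seeds] <- TRUE
      grown <- sum(les)
      # frontier: unlesioned positive-prior 6-neighbors of the region
      neighbors <- function(idx) {
        i0 <- idx - 1L
        x <- i0 %% d[1]; y <- (i0 %/% d[1]) %% d[2]; z <- i0 %/% nxy
        nb <- c(idx[x > 0] - 1L, idx[x < d[1] - 1L] + 1L,
                idx[y > 0] - d[1], idx[y < d[2] - 1L] + d[1],
                idx[z > 0] - nxy, idx[z < d[3] - 1L] + nxy)
        unique(nb)
      }
      frontier <- setdiff(neighbors(seeds), seeds)
      frontier <- frontier[intens[frontier] > 0]
      while (grown < targetVox) {
        if (!length(frontier)) {
          # region boxed in: restart growth from a fresh seed
          rest <- pos[!les[pos]]
          if (!length(rest)) break
          nxt <- if (length(rest) == 1L) rest else
            sample(rest, 1L, prob = intens[rest])
        } else {
          nxt <- if (length(frontier) == 1L) frontier else
            sample(frontier, 1L, prob = intens[frontier])
        }
        les[nxt] <- TRUE
        grown <- grown + 1L
        frontier <- c(frontier[frontier != nxt],
                      setdiff(neighbors(nxt), which(les)))
        frontier <- unique(frontier[intens[frontier] > 0 & !les[frontier]])
      }
    })
  }
  lesionMap(as.numeric(les), grid, subjectId)
}

#' Generate a synthetic WMH cohort
#'
#' Per-subject target volumes are drawn from a log-normal distribution
#' parameterized by its median and interquartile range on the ml scale
#' (moment matching on the log scale), reflecting the right-skewed volume
#' distribution of WMH cohorts; defaults emulate a memory-clinic
#' population (median 8 ml, IQR 3.2-20.9 ml). Each map is grown on the
#' shared prior with [sampleLesionMap()].
#'
#' @param n number of subjects.
#' @param grid a [VolumeGrid-class].
#' @param medianMl median target lesion volume (ml).
#' @param iqrMl length-2 interquartile range (ml).
#' @param seed master seed; the cohort is a pure function of the inputs.
#' @param lambda Poisson mean for extra lesion seeds per subject.
#' @param prior optional [LesionPriorField-class]; defaults to
#'   [defaultLesionPrior()] on the same seed.
#' @return A [LesionCohort-class] (scores NA).
#' @export
generateCohort <- function(n, grid, medianMl = 8, iqrMl = c(3.2, 20.9),
                           seed = 1L, lambda = 4, prior = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (is.null(prior))
    prior <- defaultLesionPrior(grid, deriveSeed(seed, "prior"))
  par <- lognormalFromMedianIQR(medianMl, iqrMl)
  capMl <- floor(0.5 * sum(prior@intensity > 0)) * voxelVolumeMl(grid)
  vols <- with_seed(deriveSeed(seed, "volumes"),
                    stats::rlnorm(n, par["meanlog"], par["sdlog"]))
  vols <- pmin(vols, capMl)
  ids <- sprintf("sub%03d", seq_len(n))
  vox <- vapply(seq_len(n), function(i) {
    m <- sampleLesionMap(prior, vols[i], deriveSeed(seed, 1000L + i),
                         lambda = lambda, subjectId = ids[i])
    as.numeric(m@data)
  }, numeric(prod(grid@dim)))
  newCohort(vox, grid, ids)
}
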