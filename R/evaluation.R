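#' Out-of-sample R-squared through ordinary least squares
#'
#' The R-squared of the OLS regression of the true scores on the
#' predicted scores (intercept + slope), i.e. the squared Pearson
#' correlation. A constant prediction has no linear explanatory power and
#' scores 0.
#'
#' @param pred predicted scores.
#' @param truth ground-truth scores (non-constant, n >= 3).
#' @return R-squared in `[0, 1]`.
#' @export
r2OLS <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  if (length(truth) < 3) stop("need at least 3 observations")
  if (stats::sd(truth) == 0) stop("constant truth")
  if (stats::sd(pred) == 0) return(0)
  stats::cor(pred, truth)^2
}

#' Default analysis mask: voxels lesioned anywhere in the cohort
#'
#' Restricts attribution evaluation to voxels with population lesion
#' prevalence of at least `minCount`, the voxels to which the models
#' could attribute anything at all.
#'
#' @param prev a [PrevalenceMap-class] (or [LesionCohort-class]).
#' @param minCount minimum subject count (default 1).
#' @return 3D logical array.
#' @export
analysisMask <- function(prev, minCount = 1) {
  if (is(prev, "LesionCohort")) prev <- buildPrevalenceMap(prev)
  prev@counts >= minCount
}

#' Precision-recall curve of an attribution map against ROI ground truth
#'
#' Descending thresholds over the attribution values inside the analysis
#' mask binarize the map; ROI voxels are the positive ground truth.
#' Precision and recall are recorded at every threshold (all unique
#' values, capped at `maxThresholds` evenly spaced quantiles) and the
#' AUC is the step-wise area of precision over recall. The AUC is
#' invariant to strictly monotone transforms of the attribution values.
#'
#' @param attr a positive (group) [AttributionMap-class].
#' @param rois the ground-truth [ROISet-class].
#' @param mask 3D logical analysis mask (default [analysisMask()] needs a
#'   prevalence map, so pass one explicitly here).
#' @param maxThresholds cap on the threshold count (default 512).
#' @return list with `curve` (data.frame threshold/precision/recall) and
#'   `auc`.
#' @export
prAUC <- function(attr, rois, mask, maxThresholds = 512L) {
  if (!sameGrid(attr, rois)) stop("grid mismatch")
  mask <- as.logical(mask)
  if (!any(mask)) stop("empty analysis mask")
  v <- as.numeric(attr@data)[mask]
  if (all(v == 0)) stop("all-zero attribution map")
  truth <- as.numeric(roiMask(rois))[mask] > 0
  P <- sum(truth)
  if (P == 0) stop("no ROI voxels inside the analysis mask")
  thr <- sort(unique(v), decreasing = TRUE)
  if (length(thr) > maxThresholds)
    thr <- sort(unique(stats::quantile(thr, seq(0, 1, length.out =
                                                  maxThresholds),
                                       type = 1, names = FALSE)),
                decreasing = TRUE)
  prec <- rec <- numeric(length(thr))
  ord <- order(v, decreasing = TRUE)
  cumTP <- cumsum(truth[ord])
  vsorted <- v[ord]
  for (i in seq_along(thr)) {
    npred <- findInterval(-thr[i], -vsorted)  # count of v >= thr
    prec[i] <- cumTP[npred] / npred
    rec[i] <- cumTP[npred] / P
  }
  # step-wise (right-continuous) precision over increasing recall
  auc <- sum(diff(c(0, rec)) * prec)
  list(curve = data.frame(threshold = thr, precision = prec, recall = rec),
       auc = auc)
}

#' In/out-ROI attribution ratio with millimetre dilation
#'
#' Keeps voxels whose attribution exceeds `thresholdFrac` of the map
#' maximum (default 10%), then forms the ratio of kept attribution mass
#' inside the ROIs to kept mass outside. The dilated variant counts a
#' `dilationMm` Euclidean neighbourhood of the ROIs (default 5 mm) as
#' inside, and `factor = dilatedRatio / ratio` reports how much of the
#' outside mass hugs the ROI borders. A zero denominator yields `Inf`.
#' The ratio is invariant to positive rescaling of the map.
#'
#' @param attr a positive [AttributionMap-class] with a positive maximum.
#' @param rois the [ROISet-class].
#' @param thresholdFrac fraction of the maximum (default 0.1).
#' @param dilationMm dilation radius in mm (default 5).
#' @param aggregate `"sum"` (default) or `"mean"` of kept values.
#' @return list with `ratio`, `dilatedRatio`, `factor`.
#' @export
attributionRatio <- function(attr, rois, thresholdFrac = 0.1,
                             dilationMm = 5, aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  if (!sameGrid(attr, rois)) stop("grid mismatch")
  a <- attr@data
  mx <- max(a)
  if (mx <= 0) stop("all-zero attribution map")
  kept <- a > thresholdFrac * mx
  agg <- function(vals) {
    if (!length(vals)) return(0)
    if (aggregate == "sum") sum(vals) else mean(vals)
  }
  ratioFor <- function(inside) {
    num <- agg(a[kept & inside])
    den <- agg(a[kept & !inside])
    if (den == 0) Inf else num / den
  }
  ratio <- ratioFor(roiMask(rois))
  dil <- ratioFor(dilatedRoiMask(rois, dilationMm))
  list(ratio = ratio, dilatedRatio = dil,
       factor = dil / ratio)
}

#' Dice coefficient and false-negative ROIs
#'
#' Binarizes the attribution map at `thresholdFrac` of its maximum and
#' compares it with the ROI-union mask: `Dice = 2|A n R| / (|A| + |R|)`.
#' An ROI is false-negative when it contains no supra-threshold voxel.
#'
#' @inheritParams attributionRatio
#' @return list with `dice` and `falseNegative` (ROI ids).
#' @export
diceAndFalseNegatives <- function(attr, rois, thresholdFrac = 0.1) {
  if (!sameGrid(attr, rois)) stop("grid mismatch")
  a <- attr@data
  mx <- max(a)
  if (mx <= 0) stop("all-zero attribution map")
  A <- a > thresholdFrac * mx
  R <- roiMask(rois)
  dice <- if (sum(A) + sum(R) == 0) 0 else 2 * sum(A & R) / (sum(A) + sum(R))
  idx <- roiIndexList(rois)
  fn <- names(idx)[vapply(idx, function(i) !any(A[i]), logical(1))]
  list(dice = dice, falseNegative = fn)
}

#' Full attribution-accuracy evaluation
#'
#' PR-AUC, in/out ratios with dilation, Dice and false-negative ROIs of a
#' group attribution map against the ROI ground truth.
#'
#' @param attr a group [AttributionMap-class] (positive part is taken).
#' @param rois the [ROISet-class].
#' @param mask analysis mask (logical array).
#' @param thresholdFrac supra-threshold fraction (default 0.1).
#' @param dilationMm ROI dilation in mm (default 5).
#' @return Named list of all metrics.
#' @export
evaluateAttribution <- function(attr, rois, mask, thresholdFrac = 0.1,
                                dilationMm = 5) {
  attr <- positivePart(attr)
  pr <- prAUC(attr, rois, mask)
  ar <- attributionRatio(attr, rois, thresholdFrac, dilationMm)
  df <- diceAndFalseNegatives(attr, rois, thresholdFrac)
  list(prAUC = pr$auc, prCurve = pr$curve, ratio = ar$ratio,
       dilatedRatio = ar$dilatedRatio, dilationFactor = ar$factor,
       dice = df$dice, falseNegative = df$falseNegative)
}

evaluationReport <- function(model, r2Folds, attrMetrics, config = list()) {
  new("EvaluationReport", model = model, r2Folds = as.numeric(r2Folds),
      prAUC = as.numeric(attrMetrics$prAUC %||% NA_real_),
      attributionRatio = as.numeric(attrMetrics$ratio),
      dilatedRatio = as.numeric(attrMetrics$dilatedRatio),
      dilationFactor = as.numeric(attrMetrics$dilationFactor),
      dice = as.numeric(attrMetrics$dice),
      falseNegativeROIs = as.character(attrMetrics$falseNegative),
      config = config)
}

#' Serialize an EvaluationReport to JSON
#'
#' @param report an [EvaluationReport-class].
#' @param path output path (NULL returns the JSON string).
#' @export
reportToJSON <- function(report, path = NULL) {
  obj <- list(model = report@model,
              r2_folds = report@r2Folds,
              r2_mean = mean(report@r2Folds),
              r2_sd = stats::sd(report@r2Folds),
              pr_auc = report@prAUC,
              attribution_ratio = report@attributionRatio,
              dilated_ratio = report@dilatedRatio,
              dilation_factor = report@dilationFactor,
              dice = report@dice,
              false_negative_rois = report@falseNegativeROIs,
              config = report@config)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}
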