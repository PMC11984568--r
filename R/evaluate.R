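# Ground-truth evaluation chain: voxel-wise minimum dose, V-metrics,
# HU error statistics, logistic NTCP, population percentiles and paired
# signed-rank comparisons.

#' Voxel-wise minimum dose
#'
#' Elementwise minimum over a list of dose grids (the "VoxMin" composite on
#' which robust target coverage is assessed).
#'
#' @param doses non-empty list of numeric arrays/vectors of identical shape.
#' @return array/vector of per-voxel minima.
#' @export
voxmin <- function(doses) {
  stopIfNot(length(doses) > 0, "dose list must be non-empty")
  d1 <- doses[[1]]
  for (d in doses[-1])
    stopIfNot(identical(dim(d), dim(d1)) && length(d) == length(d1),
              "dose grids must share a shape")
  out <- doses[[1]]
  for (d in doses[-1]) out <- pmin(out, d)
  out
}

#' Volume metric V(threshold)
#'
#' Percentage of a structure's voxels receiving at least
#' `thresholdFraction * prescription` dose.
#'
#' @param dose numeric dose array/vector.
#' @param mask logical mask (non-empty), same shape as `dose`.
#' @param prescription prescribed dose in Gy.
#' @param thresholdFraction coverage threshold (default 0.94 for V94%).
#' @return percentage in [0, 100].
#' @export
vMetric <- function(dose, mask, prescription, thresholdFraction = 0.94) {
  stopIfNot(any(mask), "mask must be non-empty")
  100 * mean(dose[mask] >= thresholdFraction * prescription - 1e-9)
}

#' CT-number error statistics between two images
#'
#' Mean absolute error and mean signed error of `test` minus `reference`,
#' computed inside the external mask and excluding voxels whose reference
#' CT number is below the air threshold (air cavities).
#'
#' @param test,reference [ImageGrid-class] objects on the same grid.
#' @param external logical body mask.
#' @param airThreshold reference HU below which voxels are excluded
#'   (default -960).
#' @return named numeric `c(mae, me)` in HU.
#' @export
computeMaeMe <- function(test, reference, external, airThreshold = -960) {
  stopIfNot(identical(dim(test@values), dim(reference@values)),
            "images must share a grid")
  sel <- external & reference@values >= airThreshold
  stopIfNot(any(sel), "no voxels survive the air exclusion")
  diff <- test@values[sel] - reference@values[sel]
  c(mae = mean(abs(diff)), me = mean(diff))
}

#' Logistic NTCP
#'
#' Normal tissue complication probability from dose metrics through a
#' logistic model: NTCP = 1 / (1 + exp(-(intercept + sum coef * metric))).
#'
#' @param doseMetrics named numeric vector of dose metrics (Gy); must cover
#'   every model coefficient.
#' @param model an [NTCPModel-class].
#' @return probability as a fraction in [0, 1].
#' @export
ntcp <- function(doseMetrics, model) {
  need <- names(model@coefficients)
  missing <- setdiff(need, names(doseMetrics))
  if (length(missing))
    stop(sprintf("missing dose metric(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  s <- model@intercept + sum(model@coefficients * doseMetrics[need])
  1 / (1 + exp(-s))
}

#' Default NTCP models
#'
#' Editable logistic models in the spirit of national-protocol toxicity
#' models: xerostomia driven by parotid mean doses, dysphagia by the
#' constrictor mean dose. Coefficients are configuration, not clinical
#' truth; replace them with protocol values for any serious use.
#'
#' @return named list of [NTCPModel-class].
#' @export
defaultNTCPModels <- function() {
  list(
    xerostomia = NTCPModel("xerostomia", intercept = -2.2,
                           coefficients = c(parotid_l = 0.028,
                                            parotid_r = 0.028)),
    dysphagia = NTCPModel("dysphagia", intercept = -4.0,
                          coefficients = c(constrictor = 0.055)))
}

#' Population percentile by the worst-interpolation rule
#'
#' Sorts values from best to worst (direction set by `worse`), takes the
#' fractional rank `fraction * n` counted 1-indexed toward the worst, and
#' linearly interpolates between the flanking order statistics. For n = 23
#' and fraction 0.90 the rank is 20.7, i.e. the value interpolated between
#' the 20th and 21st worst-performing members.
#'
#' @param values numeric vector (length >= 2).
#' @param fraction percentile fraction in (0, 1), default 0.90.
#' @param worse "lower" when small values are worse (coverage-type metrics)
#'   or "higher" (NTCP-type metrics).
#' @return interpolated percentile value.
#' @export
populationPercentile <- function(values, fraction = 0.90,
                                 worse = c("lower", "higher")) {
  worse <- match.arg(worse)
  stopIfNot(length(values) >= 2, "need at least two values")
  stopIfNot(fraction > 0 && fraction < 1, "fraction must be in (0, 1)")
  sorted <- sort(values, decreasing = (worse == "lower"))
  n <- length(sorted)
  r <- fraction * n
  lo <- max(floor(r), 1)
  hi <- min(ceiling(r), n)
  if (lo == hi) return(sorted[lo])
  (hi - r) * sorted[lo] + (r - lo) * sorted[hi]
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired values. The statistic reported is
#' the sum of signed ranks of the nonzero differences (so swapping the
#' inputs flips its sign); the p-value comes from the standard test routine
#' (exact for small samples without ties). All-zero differences yield p = 1
#' with a degenerate flag and a warning.
#'
#' @param a,b paired numeric vectors of equal length >= 5.
#' @param alpha significance level (default 0.05).
#' @return list with `statistic`, `p.value`, `significant`, `degenerate`.
#' @export
pairedSignedRank <- function(a, b, alpha = 0.05) {
  stopIfNot(length(a) == length(b) && length(a) >= 5,
            "need paired vectors of equal length >= 5")
  d <- a - b
  nz <- d != 0
  if (!any(nz)) {
    warning("all paired differences are zero", call. = FALSE)
    return(list(statistic = 0, p.value = 1, significant = FALSE,
                degenerate = TRUE))
  }
  r <- rank(abs(d[nz]))
  stat <- sum(sign(d[nz]) * r)
  p <- suppressWarnings(
    stats::wilcox.test(a, b, paired = TRUE, alternative = "two.sided")$p.value)
  list(statistic = stat, p.value = p, significant = p < alpha,
       degenerate = FALSE)
}

#' Evaluate a plan on the ground truth
#'
#' Performs the forward evaluation of a plan on the ground-truth image:
#' rebuilds the dose-influence matrices on the ground-truth stopping powers
#' for the evaluation scenario set (1 mm / 3% by default), forms the
#' voxel-wise minimum dose, and reports V94% per CTV, nominal-scenario mean
#' dose per OAR, NTCP values, and optionally the planning image's HU error
#' statistics.
#'
#' @param plan a [Plan-class].
#' @param groundTruth ground-truth [ImageGrid-class].
#' @param structures ground-truth [StructureSet-class].
#' @param evalSrs,evalRrs evaluation robustness settings (default 1 mm, 3%).
#' @param models named list of [NTCPModel-class].
#' @param curve calibration curve for the ground truth.
#' @param planningImage optional [ImageGrid-class] the plan was made on;
#'   when given, MAE/ME against the ground truth are reported.
#' @param strategy label stored in the report.
#' @param objective the [objectiveConfig()] holding the prescriptions.
#' @param directions shift directions for the evaluation scenario set.
#' @return a [PlanEvalReport-class].
#' @export
evaluatePlan <- function(plan, groundTruth, structures, evalSrs = 1,
                         evalRrs = 0.03, models = defaultNTCPModels(),
                         curve = defaultCalibrationCurve(),
                         planningImage = NULL, strategy = "plan",
                         objective = objectiveConfig(),
                         directions = NULL) {
  if (is.null(directions))
    directions <- defaultDirections(length(dim(groundTruth@values)))
  rsp <- huToRsp(groundTruth, curve)
  scen <- generateScenarios(evalSrs, evalRrs, directions)
  m <- masks(structures)
  sub <- which(m$ctv_low | m$ctv_high |
                 Reduce(`|`, m[oarNames(structures)],
                        array(FALSE, dim(m[[1]]))))
  infl <- influenceSet(plan@beams, rsp, scen, voxelSubset = sub)
  w <- plan@weights
  doses <- lapply(infl, function(I) as.numeric(I@matrix %*% w))
  vmin <- voxmin(doses)
  nomIdx <- which(vapply(scen, function(s) s@label == "nominal",
                         logical(1)))[1]
  dnom <- doses[[nomIdx]]
  rowsOf <- function(mask) match(which(mask), sub)
  rH <- rowsOf(m$ctv_high); rL <- rowsOf(m$ctv_low)
  coverage <- c(
    ctv_high = 100 * mean(vmin[rH] >=
                            objective$coverageThreshold * objective$doseHigh - 1e-9),
    ctv_low = 100 * mean(vmin[rL] >=
                           objective$coverageThreshold * objective$doseLow - 1e-9))
  oarMean <- vapply(oarNames(structures), function(nm)
    mean(dnom[rowsOf(m[[nm]])]), numeric(1))
  ntcpVals <- vapply(models, function(mod) 100 * ntcp(oarMean, mod),
                     numeric(1))
  names(ntcpVals) <- vapply(models, function(mod) mod@name, character(1))
  err <- c(mae = NA_real_, me = NA_real_)
  if (!is.null(planningImage))
    err <- computeMaeMe(planningImage, groundTruth, m$external)
  new("PlanEvalReport", strategy = strategy, coverage = coverage,
      oarMean = oarMean, ntcp = ntcpVals, mae = err[["mae"]],
      me = err[["me"]])
}
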