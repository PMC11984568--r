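# Proton physics at desk scale: CT-number to stopping-power conversion,
# water-equivalent path-length ray tracing and a parametric Bragg curve.

#' Piecewise-linear HU to RSP calibration curve
#'
#' Ordered (HU, RSP) node pairs with strictly increasing HU, nonnegative and
#' non-decreasing RSP, and a water anchor node at (0, 1.0). The same curve is
#' used for CT and CBCT images.
#'
#' @slot hu numeric HU node positions (strictly increasing).
#' @slot rsp numeric RSP node values.
#' @export
setClass("CalibrationCurve",
  representation(hu = "numeric", rsp = "numeric"),
  validity = function(object) {
    if (length(object@hu) != length(object@rsp) || length(object@hu) < 2)
      return("need at least two (HU, RSP) nodes")
    if (any(diff(object@hu) <= 0))
      return("HU nodes must be strictly increasing")
    if (any(object@rsp < 0) || any(diff(object@rsp) < 0))
      return("RSP must be nonnegative and non-decreasing")
    if (!any(object@hu == 0 & object@rsp == 1))
      return("curve must contain the water anchor node (0, 1.0)")
    TRUE
  })

#' @rdname CalibrationCurve-class
#' @param hu,rsp node vectors.
#' @export
CalibrationCurve <- function(hu, rsp) {
  new("CalibrationCurve", hu = as.numeric(hu), rsp = as.numeric(rsp))
}

setMethod("show", "CalibrationCurve", function(object) {
  cat("CalibrationCurve nodes:\n")
  print(data.frame(HU = object@hu, RSP = object@rsp), row.names = FALSE)
})

#' Default calibration curve
#'
#' Representative soft-tissue/bone behaviour:
#' (-1024, 0.001), (0, 1.0), (1000, 1.55), (3071, 2.4).
#' @return a [CalibrationCurve-class].
#' @export
defaultCalibrationCurve <- function() {
  CalibrationCurve(c(-1024, 0, 1000, 3071), c(0.001, 1.0, 1.55, 2.4))
}

#' Convert CT numbers to relative stopping power
#'
#' Piecewise-linear interpolation of the calibration curve; HU values outside
#' the node range clamp to the end nodes.
#'
#' @param image an [ImageGrid-class].
#' @param curve a [CalibrationCurve-class].
#' @return an [RSPMap-class] on the same grid.
#' @export
huToRsp <- function(image, curve = defaultCalibrationCurve()) {
  validObject(curve)
  v <- stats::approx(curve@hu, curve@rsp, xout = as.vector(image@values),
                     rule = 2)$y
  RSPMap(array(v, dim(image@values)), image@spacing, image@origin)
}

#' Scale a stopping-power map
#'
#' Uniform mass-density scaling used to realize range-error scenarios: every
#' voxel is multiplied by `factor`.
#'
#' @param rsp an [RSPMap-class].
#' @param factor positive unitless scale.
#' @return scaled [RSPMap-class].
#' @export
scaleDensity <- function(rsp, factor) {
  stopIfNot(length(factor) == 1 && factor > 0, "factor must be positive")
  RSPMap(rsp@values * factor, rsp@spacing, rsp@origin)
}

#' Parametric Bragg depth-dose curve
#'
#' Analytic relative depth-dose model for a proton pencil beam: a shallow
#' entrance plateau (cosine taper, zero slope at the peak) plus a narrow
#' Gaussian peak. The curve is normalized to 1 at its maximum, the maximum
#' sits exactly at `nominalRange`, and the distal falloff is below 1% of the
#' peak by 1.2 x `nominalRange` (the peak width shrinks for short ranges to
#' preserve this contract).
#'
#' @param nominalRange Bragg-peak depth in mm water-equivalent (> 0).
#' @param depth nonnegative depth(s) in mm water-equivalent.
#' @param peakSigma nominal Gaussian peak width in mm (default 3).
#' @param plateau entrance plateau level relative to the peak (default 0.35).
#' @return relative dose values in [0, 1].
#' @export
braggCurve <- function(nominalRange, depth, peakSigma = 3, plateau = 0.35) {
  stopIfNot(length(nominalRange) == 1 && nominalRange > 0,
            "nominalRange must be positive")
  if (any(depth < 0)) stop("negative depth", call. = FALSE)
  sig <- min(peakSigma, 0.2 * nominalRange / 3.1)
  peak <- exp(-(depth - nominalRange)^2 / (2 * sig^2))
  plat <- ifelse(depth <= nominalRange,
                 plateau * 0.5 * (1 + cos(pi * depth / nominalRange)), 0)
  plat + peak
}

#' Trace water-equivalent path length along a ray
#'
#' Marches from `entry` along `direction` in steps of `step` mm, sampling the
#' stopping-power map (nearest-neighbour by default, bilinear optionally in
#' 2-D) at each midpoint, and accumulates water-equivalent depth. The
#' cumulative profile is monotone non-decreasing. A ray that never intersects
#' the grid returns an empty profile.
#'
#' @param rsp an [RSPMap-class].
#' @param entry starting point (mm), may lie outside the grid.
#' @param direction unit vector.
#' @param step sampling step in mm (> 0).
#' @param lookup "nearest" or "bilinear" voxel lookup.
#' @return data.frame with `distance` (mm from entry, at sub-interval ends)
#'   and `wepl` (cumulative mm water-equivalent).
#' @export
traceWepl <- function(rsp, entry, direction, step = 1,
                      lookup = c("nearest", "bilinear")) {
  lookup <- match.arg(lookup)
  stopIfNot(step > 0, "step must be positive")
  stopIfNot(abs(sqrt(sum(direction^2)) - 1) < 1e-6,
            "direction must be a unit vector")
  d <- dim(rsp@values)
  lo <- rsp@origin - rsp@spacing / 2
  hi <- rsp@origin + (d - 1 + 0.5) * rsp@spacing
  # slab intersection of the forward ray with the grid bounding box
  tmin <- 0; tmax <- Inf
  for (k in seq_along(d)) {
    if (abs(direction[k]) < 1e-12) {
      if (entry[k] < lo[k] || entry[k] > hi[k]) return(
        data.frame(distance = numeric(0), wepl = numeric(0)))
    } else {
      t1 <- (lo[k] - entry[k]) / direction[k]
      t2 <- (hi[k] - entry[k]) / direction[k]
      tmin <- max(tmin, min(t1, t2)); tmax <- min(tmax, max(t1, t2))
    }
  }
  if (tmax <= tmin) return(data.frame(distance = numeric(0), wepl = numeric(0)))
  nstep <- ceiling((tmax - 0) / step)
  mid <- (seq_len(nstep) - 0.5) * step
  pts <- outer(mid, direction)
  pts <- sweep(pts, 2, entry, "+")
  val <- if (lookup == "bilinear" && length(d) == 2)
    bilinearSample(rsp@values, rsp@spacing, rsp@origin, pts[, 1], pts[, 2])
  else nearestSample(rsp@values, rsp@spacing, rsp@origin, pts)
  data.frame(distance = seq_len(nstep) * step, wepl = cumsum(val * step))
}
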