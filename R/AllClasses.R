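#' @import methods
NULL

#' Regular voxel grid of CT numbers
#'
#' Container for a single-channel volumetric (or planar) image in Hounsfield
#' units on a regular grid. Carries the voxel spacing and the physical
#' coordinate of the first voxel centre, so that images, masks and beams can
#' be related in millimetres.
#'
#' @slot values numeric array (2-D matrix or 3-D array) of HU values, within
#'   [-1024, 3071].
#' @slot spacing numeric, mm per voxel along each axis (strictly positive).
#' @slot origin numeric, physical mm coordinate of the first voxel centre.
#' @export
setClass("ImageGrid",
  representation(values = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    d <- dim(object@values)
    if (is.null(d) || !(length(d) %in% 2:3))
      return("values must be a 2-D or 3-D array")
    if (length(object@spacing) != length(d) || any(object@spacing <= 0))
      return("spacing must be strictly positive, one value per axis")
    if (length(object@origin) != length(d))
      return("origin must have one value per axis")
    if (anyNA(object@values))
      return("values must not contain NA")
    rng <- range(object@values)
    if (rng[1] < -1024 || rng[2] > 3071)
      return("HU values must lie within [-1024, 3071]")
    TRUE
  })

#' Relative stopping power map
#'
#' Per-voxel relative (proton) stopping power sharing grid metadata with the
#' image it was derived from. Values are unitless ratios to water and must be
#' nonnegative.
#'
#' @slot values numeric array of RSP values (>= 0).
#' @slot spacing,origin grid metadata as in [ImageGrid-class].
#' @export
setClass("RSPMap",
  representation(values = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    d <- dim(object@values)
    if (is.null(d) || !(length(d) %in% 2:3))
      return("values must be a 2-D or 3-D array")
    if (length(object@spacing) != length(d) || any(object@spacing <= 0))
      return("spacing must be strictly positive, one value per axis")
    if (length(object@origin) != length(d))
      return("origin must have one value per axis")
    if (anyNA(object@values) || min(object@values) < 0)
      return("RSP values must be nonnegative and non-missing")
    TRUE
  })

#' Named binary structure masks on a common grid
#'
#' Holds the delineated anatomy of one phantom: the external (body) contour,
#' the nested clinical target volumes (high-dose CTV inside the elective
#' low-dose CTV), organs at risk, and optional avoidance structures (metal /
#' shoulder analogues) through which no spot may travel.
#'
#' @slot masks named list of logical arrays, all of identical dimension.
#'   Must contain "external", "ctv_high" and "ctv_low" with
#'   ctv_high subset of ctv_low subset of external, voxelwise.
#' @slot oarNames character, names of masks that are organs at risk.
#' @slot avoidanceNames character, names of avoidance masks (may be empty).
#' @export
setClass("StructureSet",
  representation(masks = "list", oarNames = "character",
                 avoidanceNames = "character"),
  validity = function(object) {
    m <- object@masks
    need <- c("external", "ctv_high", "ctv_low")
    if (!all(need %in% names(m)))
      return("masks must include external, ctv_high and ctv_low")
    d <- dim(m[[1]])
    for (nm in names(m)) {
      if (!is.logical(m[[nm]])) return(sprintf("mask '%s' must be logical", nm))
      if (!identical(dim(m[[nm]]), d))
        return("all masks must share the same dimensions")
    }
    if (any(m$ctv_high & !m$ctv_low))
      return("ctv_high must be contained in ctv_low")
    if (any(m$ctv_low & !m$external))
      return("ctv_low must be contained in external")
    if (!all(object@oarNames %in% names(m)))
      return("oarNames must refer to existing masks")
    if (!all(object@avoidanceNames %in% names(m)))
      return("avoidanceNames must refer to existing masks")
    TRUE
  })

#' One robust-optimization error scenario
#'
#' A scenario pairs a rigid isocenter shift (magnitude set by the setup
#' robustness setting, SRS) with a mass-density scaling factor (1 +/- the
#' range robustness setting, RRS). The nominal scenario has zero shift and
#' unit density scale.
#'
#' @slot shift numeric displacement vector in mm.
#' @slot densityScale unitless multiplicative factor on stopping power.
#' @slot label character, "nominal" or "shift+range".
#' @export
setClass("Scenario",
  representation(shift = "numeric", densityScale = "numeric",
                 label = "character"),
  validity = function(object) {
    if (length(object@densityScale) != 1 || object@densityScale <= 0)
      return("densityScale must be a single positive number")
    if (object@label == "nominal" &&
        (any(object@shift != 0) || object@densityScale != 1))
      return("nominal scenario must have zero shift and unit density scale")
    TRUE
  })

#' A treatment beam with its spot lattice
#'
#' Parallel-beam geometry at a fixed gantry angle. Spots live on a lattice of
#' lateral positions (mm, perpendicular to the beam axis in the image plane)
#' and nominal ranges (mm water-equivalent depth of the Bragg peak).
#'
#' @slot angle gantry angle in degrees.
#' @slot spots data.frame with columns `lateral` (mm) and `range` (mm WEPL).
#' @slot sigma lateral Gaussian spot width (mm), > 0.
#' @export
setClass("Beam",
  representation(angle = "numeric", spots = "data.frame", sigma = "numeric"),
  validity = function(object) {
    if (!all(c("lateral", "range") %in% names(object@spots)))
      return("spots must have columns lateral and range")
    if (nrow(object@spots) && any(object@spots$range <= 0))
      return("spot ranges must be positive")
    if (length(object@sigma) != 1 || object@sigma <= 0)
      return("sigma must be a single positive number")
    TRUE
  })

#' Sparse dose-influence matrix for one scenario
#'
#' Linear map from nonnegative spot weights to biologically-weighted voxel
#' doses (Gy per unit weight, RBE factor already applied) under one error
#' scenario. Stored voxels x spots in sparse column format; `voxelIndex`
#' records which linear voxel indices of the grid the rows correspond to.
#'
#' @slot matrix dgCMatrix, voxels x spots, entries >= 0.
#' @slot voxelIndex integer linear indices into the grid.
#' @slot gridDim integer grid dimensions.
#' @slot scenario the [Scenario-class] the matrix was computed under.
#' @slot rbeFactor numeric, relative biological effectiveness factor applied.
#' @slot spotInfo data.frame (beam, angle, lateral, range) per column.
#' @export
setClass("DoseInfluence",
  representation(matrix = "Matrix", voxelIndex = "integer",
                 gridDim = "integer", scenario = "Scenario",
                 rbeFactor = "numeric", spotInfo = "data.frame"),
  validity = function(object) {
    if (nrow(object@matrix) != length(object@voxelIndex))
      return("voxelIndex length must match matrix rows")
    if (ncol(object@matrix) != nrow(object@spotInfo))
      return("spotInfo rows must match matrix columns")
    if (length(object@matrix@x) && min(object@matrix@x) < 0)
      return("influence entries must be nonnegative")
    TRUE
  })

#' An optimized spot-weight plan
#'
#' @slot weights nonnegative spot weights (arbitrary units proportional to
#'   monitor units), one per surviving spot.
#' @slot beams list of [Beam-class] objects the weights refer to.
#' @slot scenarios list of [Scenario-class] used during optimization.
#' @slot srs setup robustness setting (mm).
#' @slot rrs range robustness setting (fraction).
#' @slot diagnostics list with solver information, including `feasible` and
#'   the achieved worst-case coverage.
#' @export
setClass("Plan",
  representation(weights = "numeric", beams = "list", scenarios = "list",
                 srs = "numeric", rrs = "numeric", diagnostics = "list"),
  validity = function(object) {
    if (length(object@weights) && min(object@weights) < 0)
      return("spot weights must be nonnegative")
    nspot <- sum(vapply(object@beams, function(b) nrow(b@spots), integer(1)))
    if (length(object@weights) != nspot)
      return("weights length must equal the total spot count")
    TRUE
  })

#' Logistic normal-tissue complication probability model
#'
#' NTCP = logistic(intercept + sum_k coefficient_k * metric_k), with dose
#' metrics in Gy. Coefficients are configuration, shipped as editable
#' defaults rather than hard-coded clinical truth.
#'
#' @slot name model name, e.g. "xerostomia" or "dysphagia".
#' @slot intercept numeric intercept of the linear predictor.
#' @slot coefficients named numeric, per-Gy coefficients on dose metrics
#'   (names refer to OAR mean-dose metrics).
#' @export
setClass("NTCPModel",
  representation(name = "character", intercept = "numeric",
                 coefficients = "numeric"),
  validity = function(object) {
    if (length(object@coefficients) < 1 || is.null(names(object@coefficients)))
      return("at least one named coefficient is required")
    TRUE
  })

#' Ground-truth evaluation report for one plan
#'
#' @slot strategy label of the planning strategy evaluated.
#' @slot coverage named numeric, voxel-wise-minimum V94% per CTV (percent).
#' @slot oarMean named numeric, nominal-scenario mean dose per OAR (Gy).
#' @slot ntcp named numeric, complication probabilities (percent).
#' @slot mae,me mean absolute / mean signed CT-number error of the planning
#'   image against ground truth (HU); NA when not applicable.
#' @export
setClass("PlanEvalReport",
  representation(strategy = "character", coverage = "numeric",
                 oarMean = "numeric", ntcp = "numeric",
                 mae = "numeric", me = "numeric"),
  validity = function(object) {
    if (length(object@coverage) &&
        (min(object@coverage) < 0 || max(object@coverage) > 100))
      return("coverage must be in [0, 100]")
    if (length(object@ntcp) &&
        (min(object@ntcp) < 0 || max(object@ntcp) > 100))
      return("ntcp must be percentages in [0, 100]")
    TRUE
  })
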