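#' @importClassesFrom Matrix Matrix dgCMatrix
NULL

#' Create an ImageGrid
#'
#' @param values numeric matrix (2-D) or array (3-D) of HU values.
#' @param spacing mm per voxel, recycled to the number of axes.
#' @param origin physical mm coordinate of the first voxel centre; defaults
#'   to placing the grid centre at the coordinate origin.
#' @return An [ImageGrid-class].
#' @export
ImageGrid <- function(values, spacing = 2, origin = NULL) {
  values <- as.array(values)
  spacing <- rep(as.numeric(spacing), length.out = length(dim(values)))
  if (is.null(origin)) origin <- centredOrigin(dim(values), spacing)
  new("ImageGrid", values = values, spacing = spacing,
      origin = as.numeric(origin))
}

#' Create an RSPMap
#'
#' @param values nonnegative numeric array of relative stopping powers.
#' @inheritParams ImageGrid
#' @return An [RSPMap-class].
#' @export
RSPMap <- function(values, spacing = 2, origin = NULL) {
  values <- as.array(values)
  spacing <- rep(as.numeric(spacing), length.out = length(dim(values)))
  if (is.null(origin)) origin <- centredOrigin(dim(values), spacing)
  new("RSPMap", values = values, spacing = spacing, origin = as.numeric(origin))
}

#' Create a StructureSet
#'
#' @param masks named list of logical arrays; must include `external`,
#'   `ctv_high` and `ctv_low`.
#' @param oarNames names of masks that are organs at risk.
#' @param avoidanceNames names of avoidance masks (default none).
#' @return A [StructureSet-class].
#' @export
StructureSet <- function(masks, oarNames = character(),
                         avoidanceNames = character()) {
  new("StructureSet", masks = masks, oarNames = oarNames,
      avoidanceNames = avoidanceNames)
}

#' Create a Scenario
#'
#' @param shift displacement vector in mm.
#' @param densityScale unitless stopping-power scaling factor.
#' @param label scenario label; "nominal" requires zero shift and unit scale.
#' @return A [Scenario-class].
#' @export
Scenario <- function(shift = c(0, 0), densityScale = 1,
                     label = if (all(shift == 0) && densityScale == 1)
                       "nominal" else "shift+range") {
  new("Scenario", shift = as.numeric(shift),
      densityScale = as.numeric(densityScale), label = label)
}

#' Create a Beam
#'
#' @param angle gantry angle in degrees.
#' @param spots data.frame with columns `lateral` (mm) and `range` (mm WEPL).
#' @param sigma lateral Gaussian spot width in mm.
#' @return A [Beam-class].
#' @export
Beam <- function(angle, spots, sigma = 5) {
  new("Beam", angle = as.numeric(angle), spots = spots,
      sigma = as.numeric(sigma))
}

#' Create an NTCP model
#'
#' @param name model name.
#' @param intercept intercept of the logistic linear predictor.
#' @param coefficients named numeric vector of per-Gy coefficients; names
#'   identify the dose metrics (OAR mean doses) the model consumes.
#' @return An [NTCPModel-class].
#' @export
NTCPModel <- function(name, intercept, coefficients) {
  new("NTCPModel", name = name, intercept = as.numeric(intercept),
      coefficients = coefficients)
}

# ---- accessors ----

#' Grid accessors
#'
#' `voxelValues` returns the raw array, `voxelSpacing` the mm spacing,
#' `voxelOrigin` the first voxel-centre coordinate and `gridDim` the array
#' dimensions of an [ImageGrid-class] or [RSPMap-class].
#'
#' @param x an ImageGrid or RSPMap.
#' @return the corresponding slot value.
#' @export
voxelValues <- function(x) x@values

#' @rdname voxelValues
#' @export
voxelSpacing <- function(x) x@spacing

#' @rdname voxelValues
#' @export
voxelOrigin <- function(x) x@origin

#' @rdname voxelValues
#' @export
gridDim <- function(x) dim(x@values)

#' StructureSet accessors
#'
#' @param x a [StructureSet-class].
#' @param name mask name for `structureMask`.
#' @return `masks` returns the named list of logical arrays; `structureMask`
#'   one mask; `oarNames`/`avoidanceNames` the role name vectors.
#' @export
masks <- function(x) x@masks

#' @rdname masks
#' @export
structureMask <- function(x, name) {
  stopIfNot(name %in% names(x@masks), sprintf("no mask named '%s'", name))
  x@masks[[name]]
}

#' @rdname masks
#' @export
oarNames <- function(x) x@oarNames

#' @rdname masks
#' @export
avoidanceNames <- function(x) x@avoidanceNames

#' Plan accessors
#'
#' @param x a [Plan-class].
#' @return `spotWeights` returns the nonnegative weight vector;
#'   `planDiagnostics` the solver diagnostics list.
#' @export
spotWeights <- function(x) x@weights

#' @rdname spotWeights
#' @export
planDiagnostics <- function(x) x@diagnostics

# ---- show methods ----

setMethod("show", "ImageGrid", function(object) {
  cat(sprintf("ImageGrid: %s voxels, spacing %s mm, HU range [%d, %d]\n",
              paste(dim(object@values), collapse = "x"),
              paste(object@spacing, collapse = "x"),
              round(min(object@values)), round(max(object@values))))
})

setMethod("show", "RSPMap", function(object) {
  cat(sprintf("RSPMap: %s voxels, RSP range [%.3f, %.3f]\n",
              paste(dim(object@values), collapse = "x"),
              min(object@values), max(object@values)))
})

setMethod("show", "StructureSet", function(object) {
  cat(sprintf("StructureSet: %d masks (%s); OARs: %s; avoidance: %s\n",
              length(object@masks),
              paste(names(object@masks), collapse = ", "),
              if (length(object@oarNames))
                paste(object@oarNames, collapse = ", ") else "none",
              if (length(object@avoidanceNames))
                paste(object@avoidanceNames, collapse = ", ") else "none"))
})

setMethod("show", "Scenario", function(object) {
  cat(sprintf("Scenario [%s]: shift (%s) mm, density scale %.3f\n",
              object@label, paste(signif(object@shift, 3), collapse = ", "),
              object@densityScale))
})

setMethod("show", "Beam", function(object) {
  cat(sprintf("Beam at %g deg: %d spots, sigma %.1f mm\n",
              object@angle, nrow(object@spots), object@sigma))
})

setMethod("show", "DoseInfluence", function(object) {
  cat(sprintf(
    "DoseInfluence [%s]: %d voxels x %d spots, %d nonzeros, RBE %.2f\n",
    object@scenario@label, nrow(object@matrix), ncol(object@matrix),
    length(object@matrix@x), object@rbeFactor))
})

setMethod("show", "Plan", function(object) {
  cat(sprintf(
    "Plan: %d spots over %d beams, SRS %g mm / RRS %g%%, feasible: %s\n",
    length(object@weights), length(object@beams), object@srs,
    100 * object@rrs,
    if (isTRUE(object@diagnostics$feasible)) "yes" else "no"))
})

setMethod("show", "NTCPModel", function(object) {
  cat(sprintf("NTCPModel '%s': logit = %.3f + %s\n", object@name,
              object@intercept,
              paste(sprintf("%.4f*%s", object@coefficients,
                            names(object@coefficients)), collapse = " + ")))
})

setMethod("show", "PlanEvalReport", function(object) {
  cat(sprintf("PlanEvalReport [%s]\n", object@strategy))
  cat("  VoxMin V94%:",
      paste(sprintf("%s=%.1f%%", names(object@coverage), object@coverage),
            collapse = ", "), "\n")
  if (length(object@oarMean))
    cat("  OAR mean dose:",
        paste(sprintf("%s=%.2f Gy", names(object@oarMean), object@oarMean),
              collapse = ", "), "\n")
  if (length(object@ntcp))
    cat("  NTCP:", paste(sprintf("%s=%.2f%%", names(object@ntcp),
                                 object@ntcp), collapse = ", "), "\n")
  if (!is.na(object@mae))
    cat(sprintf("  planning image MAE %.1f HU, ME %.1f HU\n",
                object@mae, object@me))
})
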