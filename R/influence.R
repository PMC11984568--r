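# Pencil-beam dose-influence engine (2-D parallel-beam geometry).
#
# For a beam at gantry angle a the propagation direction is
# d = (cos a, sin a) and the lateral axis l = (-sin a, cos a), both in grid
# (mm) coordinates. Every voxel has beam coordinates u = p.d (depth along
# the beam) and v = p.l (lateral). The water-equivalent depth of a voxel is
# the integral of RSP along its own ray, which is independent of lateral
# setup shifts; a rigid isocenter shift s therefore enters the engine as a
# lateral displacement s.l of each spot axis relative to the patient (the
# along-beam component of s is range-invariant in parallel geometry).

beamAxes <- function(angle) {
  a <- angle * pi / 180
  list(d = c(cos(a), sin(a)), l = c(-sin(a), cos(a)))
}

# per-voxel water-equivalent depth for a parallel beam.
# Returns wepl for the voxels in `voxelIndex` (linear indices), plus their
# lateral coordinates v.
weplMap <- function(rsp, angle, voxelIndex = NULL, rayStep = 1) {
  d <- dim(rsp@values)
  stopIfNot(length(d) == 2, "the influence engine supports 2-D grids")
  ax <- beamAxes(angle)
  co <- voxelCoords(d, rsp@spacing, rsp@origin)
  if (is.null(voxelIndex)) voxelIndex <- seq_len(prod(d))
  cov <- co[voxelIndex, , drop = FALSE]
  u <- cov %*% ax$d
  v <- cov %*% ax$l
  # ray grid spanning the whole image in beam coordinates
  uAll <- co %*% ax$d
  vAll <- co %*% ax$l
  dv <- min(rsp@spacing)
  vGrid <- seq(min(vAll) - dv, max(vAll) + dv, by = dv)
  du <- rayStep
  uGrid <- seq(min(uAll) - max(rsp@spacing), max(uAll) + max(rsp@spacing),
               by = du)
  pts <- cbind(rep(vGrid, each = length(uGrid)) * ax$l[1] +
                 rep(uGrid, length(vGrid)) * ax$d[1],
               rep(vGrid, each = length(uGrid)) * ax$l[2] +
                 rep(uGrid, length(vGrid)) * ax$d[2])
  sam <- nearestSample(rsp@values, rsp@spacing, rsp@origin, pts)
  sam <- matrix(sam, nrow = length(uGrid))      # [u, v-ray]
  cw <- apply(sam, 2, cumsum) * du              # wepl at end of interval
  ri <- pmin(pmax(round((v - vGrid[1]) / dv) + 1, 1), length(vGrid))
  si <- pmin(pmax(round((u - uGrid[1]) / du) + 1, 1), length(uGrid))
  wv <- cw[cbind(si, ri)] -
    (uGrid[si] + du / 2 - u) * sam[cbind(si, ri)]
  list(wepl = pmax(as.numeric(wv), 0), v = as.numeric(v),
       u = as.numeric(u), axes = ax)
}

#' Construct beams with spot lattices covering the target
#'
#' For each gantry angle, spots are laid on a lattice of lateral positions
#' (5 mm spacing by default) spanning the target's lateral extent plus a
#' margin, and nominal ranges tiling the target's water-equivalent depth
#' extent (5 mm steps) plus proximal/distal margins — a desk-scale analogue
#' of energy-layer planning.
#'
#' @param rsp planning [RSPMap-class].
#' @param structures [StructureSet-class]; spots cover `targetName`.
#' @param angles gantry angles in degrees (default the clinical 6-beam
#'   arrangement 50, 100, 160, 200, 260, 310).
#' @param sigma lateral spot width in mm.
#' @param lateralSpacing,rangeSpacing lattice spacings in mm.
#' @param lateralMargin,rangeMargin margins beyond the target extent in mm;
#'   the range margin additionally grows with `rrs` times the local depth so
#'   that density-scaled scenarios still find proximal/distal energy layers.
#' @param rrs the range robustness setting the plan will be optimized with.
#' @param targetName mask the lattice must cover.
#' @return list of [Beam-class].
#' @export
makeBeams <- function(rsp, structures,
                      angles = c(50, 100, 160, 200, 260, 310),
                      sigma = 5, lateralSpacing = 5, rangeSpacing = 5,
                      lateralMargin = 6, rangeMargin = 4, rrs = 0.03,
                      targetName = "ctv_low") {
  tmask <- structureMask(structures, targetName)
  tIdx <- which(tmask)
  stopIfNot(length(tIdx) > 0, "target mask is empty")
  lapply(angles, function(a) {
    wm <- weplMap(rsp, a, tIdx)
    lat <- seq(min(wm$v) - lateralMargin, max(wm$v) + lateralMargin,
               by = lateralSpacing)
    spots <- do.call(rbind, lapply(lat, function(x) {
      near <- abs(wm$v - x) <= lateralSpacing / 2 + lateralMargin
      if (!any(near)) return(NULL)
      w <- wm$wepl[near]
      rng <- seq(max(min(w) * (1 - rrs) - rangeMargin, 5),
                 max(w) * (1 + rrs) + rangeMargin, by = rangeSpacing)
      data.frame(lateral = x, range = rng)
    }))
    Beam(a, spots, sigma)
  })
}

#' Remove spots whose central ray crosses an avoidance structure
#'
#' A spot is removed when its central ray (nominal scenario) intersects any
#' avoidance voxel before the cumulative water-equivalent depth reaches the
#' spot's nominal range. Surviving spot order is preserved. An empty
#' avoidance set returns the beams unchanged.
#'
#' @param beams list of [Beam-class].
#' @param structures a [StructureSet-class]; masks named in
#'   `avoidanceNames(structures)` are avoided. Alternatively a plain list of
#'   logical masks.
#' @param rsp [RSPMap-class] used to convert geometric depth to
#'   water-equivalent depth along each ray.
#' @param step ray-marching step in mm.
#' @return filtered list of [Beam-class].
#' @export
filterSpots <- function(beams, structures, rsp, step = 1) {
  avoid <- if (is(structures, "StructureSet")) {
    masks(structures)[avoidanceNames(structures)]
  } else structures
  if (!length(avoid)) return(beams)
  amask <- Reduce(`|`, avoid)
  if (!any(amask)) return(beams)
  d <- dim(rsp@values)
  stopIfNot(length(d) == 2, "the influence engine supports 2-D grids")
  half <- max((d - 1) * rsp@spacing) # generous entry distance
  lapply(beams, function(b) {
    ax <- beamAxes(b@angle)
    keep <- vapply(seq_len(nrow(b@spots)), function(i) {
      v <- b@spots$lateral[i]
      entry <- v * ax$l - half * ax$d
      prof <- traceWepl(rsp, entry, ax$d, step)
      if (!nrow(prof)) return(TRUE)
      pts <- cbind(entry[1] + (prof$distance - step / 2) * ax$d[1],
                   entry[2] + (prof$distance - step / 2) * ax$d[2])
      inAvoid <- nearestSample(amask + 0, rsp@spacing, rsp@origin, pts) > 0.5
      # wepl at sample start = wepl(end) - step contribution; conservative:
      before <- prof$wepl < b@spots$range[i]
      !any(inAvoid & before)
    }, logical(1))
    Beam(b@angle, b@spots[keep, , drop = FALSE], b@sigma)
  })
}

#' Assemble the sparse dose-influence matrix for one scenario
#'
#' Each spot's dose column is the product of a lateral Gaussian (the beam's
#' sigma) centred on the shifted spot axis and the Bragg depth-dose curve
#' evaluated at each voxel's water-equivalent depth under the scenario's
#' density scaling, multiplied by the relative biological effectiveness
#' factor. Entries below `threshold` times the spot's maximum are dropped
#' and the matrix is stored sparse.
#'
#' @param beams list of [Beam-class] (must contain at least one spot).
#' @param rsp nominal [RSPMap-class]; the scenario's density scale is
#'   applied internally.
#' @param scenario a [Scenario-class].
#' @param structures optional [StructureSet-class] (unused by the engine but
#'   accepted for interface symmetry).
#' @param rbeFactor relative biological effectiveness factor (default 1.1).
#' @param threshold sparsity threshold relative to each spot's maximum.
#' @param voxelSubset optional integer linear voxel indices to compute; the
#'   default covers the whole grid.
#' @param peakSigma Bragg-peak width passed to [braggCurve()].
#' @return a [DoseInfluence-class].
#' @export
buildInfluence <- function(beams, rsp, scenario = Scenario(),
                           structures = NULL, rbeFactor = 1.1,
                           threshold = 1e-4, voxelSubset = NULL,
                           peakSigma = 3) {
  nspot <- sum(vapply(beams, function(b) nrow(b@spots), integer(1)))
  stopIfNot(nspot > 0, "no spots to compute")
  d <- dim(rsp@values)
  stopIfNot(length(d) == 2, "the influence engine supports 2-D grids")
  if (is.null(voxelSubset)) voxelSubset <- seq_len(prod(d))
  wms <- lapply(beams, function(b) weplMap(rsp, b@angle, voxelSubset))
  .assembleInfluence(beams, wms, scenario, voxelSubset, d, rbeFactor,
                     threshold, peakSigma)
}

# dense dose block for the spots of one beam under one scenario
.spotBlock <- function(b, wm, scenario, rbeFactor, threshold, peakSigma) {
  wepl <- wm$wepl * scenario@densityScale
  vEff <- b@spots$lateral + sum(scenario@shift * wm$axes$l)
  G <- exp(-outer(wm$v, vEff, "-")^2 / (2 * b@sigma^2))
  G[G < 1e-6] <- 0
  B <- vapply(seq_len(nrow(b@spots)),
              function(j) braggCurve(b@spots$range[j], wepl, peakSigma),
              numeric(length(wepl)))
  M <- G * B * rbeFactor
  mx <- apply(M, 2, max)
  M[M < rep(threshold * mx, each = nrow(M))] <- 0
  M
}

.assembleInfluence <- function(beams, wms, scenario, voxelSubset, d,
                               rbeFactor, threshold, peakSigma) {
  cols <- list(); info <- list()
  for (bi in seq_along(beams)) {
    b <- beams[[bi]]
    if (!nrow(b@spots)) next
    cols[[length(cols) + 1]] <-
      .spotBlock(b, wms[[bi]], scenario, rbeFactor, threshold, peakSigma)
    info[[length(info) + 1]] <- data.frame(beam = bi, angle = b@angle,
                                           lateral = b@spots$lateral,
                                           range = b@spots$range,
                                           sigma = b@sigma)
  }
  M <- methods::as(methods::as(Matrix::Matrix(do.call(cbind, cols),
                                              sparse = TRUE), "CsparseMatrix"),
                   "generalMatrix")
  new("DoseInfluence", matrix = M, voxelIndex = as.integer(voxelSubset),
      gridDim = as.integer(d), scenario = scenario, rbeFactor = rbeFactor,
      spotInfo = do.call(rbind, info))
}

#' Dose from spot weights
#'
#' Applies the linear influence map to a nonnegative weight vector.
#'
#' @param influence a [DoseInfluence-class].
#' @param weights numeric weights, one per spot.
#' @param full if `TRUE`, return a dose array on the whole grid (zeros
#'   outside the computed voxel subset); otherwise a vector over the subset.
#' @return numeric vector or array of doses (Gy, RBE-weighted).
#' @export
doseFrom <- function(influence, weights, full = FALSE) {
  stopIfNot(length(weights) == ncol(influence@matrix),
            "weights length must equal the spot count")
  dvec <- as.numeric(influence@matrix %*% weights)
  if (!full) return(dvec)
  out <- array(0, influence@gridDim)
  out[influence@voxelIndex] <- dvec
  out
}

#' Build one influence matrix per scenario
#'
#' Equivalent to calling [buildInfluence()] for every scenario, but the
#' per-beam WEPL map is computed once and reused: density scaling and
#' lateral spot-axis shifts are applied per scenario on top of it, which is
#' exact in parallel-beam geometry.
#'
#' @inheritParams buildInfluence
#' @param scenarios list of [Scenario-class].
#' @return list of [DoseInfluence-class], one per scenario.
#' @export
influenceSet <- function(beams, rsp, scenarios, rbeFactor = 1.1,
                         threshold = 1e-4, voxelSubset = NULL,
                         peakSigma = 3) {
  d <- dim(rsp@values)
  if (is.null(voxelSubset)) voxelSubset <- seq_len(prod(d))
  wms <- lapply(beams, function(b) weplMap(rsp, b@angle, voxelSubset))
  lapply(scenarios, function(s)
    .assembleInfluence(beams, wms, s, voxelSubset, d, rbeFactor,
                       threshold, peakSigma))
}
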