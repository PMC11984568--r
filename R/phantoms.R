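# Synthetic cohort generation: ground-truth anatomy ("CTOR" analogue),
# CBCT-like corrupted images, and an earlier planning-CT anatomy with a
# systematic inter-fraction change.

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Phantom generator configuration
#'
#' Geometry and tissue parameters for the head-and-neck-like voxel phantom.
#' The default is a single axial-slice analogue: a 128 x 128 grid at 2 mm
#' voxels holding a soft-tissue body ellipse, bony structures (vertebral
#' body and two jaw-angle bones), an internal air cavity (pharynx analogue),
#' nested clinical target volumes and three organs at risk (two parotid-like
#' glands and a constrictor-like muscle). Structure centres and semi-axes are
#' jittered per phantom under the seed.
#'
#' @param gridDim integer voxel dimensions (2-D default).
#' @param spacing voxel size in mm.
#' @param huAir,huSoft,huBone tissue CT numbers.
#' @param jitterSd per-structure centre jitter (mm, normal sd).
#' @param sizeJitter fractional semi-axis jitter (uniform half-width).
#' @param structures named list of `list(centre, semi)` ellipse definitions
#'   (mm, grid-centred coordinates) for body, bones, cavity, CTVs and OARs.
#' @param metal optional `list(centre, semi)` for a metal-implant avoidance
#'   structure (HU 3000); `NULL` for none.
#' @param scale global factor applied to all structure centres and semi-axes
#'   (to fit smaller fields of view).
#' @param textureSd optional soft-tissue HU texture noise (0 = noise-free).
#' @return list of class `PhantomConfig`.
#' @export
phantomConfig <- function(gridDim = c(128, 128), spacing = 2,
                          huAir = -1000, huSoft = 40, huBone = 700,
                          jitterSd = 2, sizeJitter = 0.08,
                          structures = list(
                            body       = list(centre = c(0, 5),    semi = c(85, 95)),
                            vertebra   = list(centre = c(0, -55),  semi = c(14, 12)),
                            jaw_l      = list(centre = c(-48, 30), semi = c(10, 14)),
                            jaw_r      = list(centre = c(48, 30),  semi = c(10, 14)),
                            air_cavity = list(centre = c(0, -25),  semi = c(10, 14)),
                            ctv_low    = list(centre = c(22, -8),  semi = c(27, 21)),
                            ctv_high   = list(centre = c(28, -6),  semi = c(13, 10)),
                            parotid_l  = list(centre = c(-56, -22), semi = c(12, 15)),
                            parotid_r  = list(centre = c(56, -22),  semi = c(12, 15)),
                            constrictor = list(centre = c(0, -44),  semi = c(16, 5))),
                          metal = NULL, scale = 1, textureSd = 0) {
  if (scale != 1) {
    structures <- lapply(structures, function(e)
      list(centre = e$centre * scale, semi = e$semi * scale))
    if (!is.null(metal))
      metal <- list(centre = metal$centre * scale, semi = metal$semi * scale)
  }
  cfg <- list(gridDim = as.integer(gridDim), spacing = spacing,
              huAir = huAir, huSoft = huSoft, huBone = huBone,
              jitterSd = jitterSd, sizeJitter = sizeJitter,
              structures = structures, metal = metal, textureSd = textureSd)
  class(cfg) <- "PhantomConfig"
  cfg
}

# jittered ellipse parameters; errors if the ellipse leaves the grid
.jitterEllipse <- function(e, cfg, name, jitter = TRUE) {
  centre <- e$centre
  semi <- e$semi
  if (jitter) {
    # truncated jitter keeps worst-case extents bounded across seeds
    d <- pmin(pmax(rnorm(length(centre), 0, cfg$jitterSd),
                   -2.5 * cfg$jitterSd), 2.5 * cfg$jitterSd)
    centre <- centre + d
    semi <- semi * (1 + runif(length(semi), -cfg$sizeJitter, cfg$sizeJitter))
  }
  half <- (cfg$gridDim - 1) / 2 * rep(cfg$spacing, length.out = length(cfg$gridDim))
  if (any(abs(centre) + semi > half))
    stop(sprintf("structure '%s' extends outside the grid", name), call. = FALSE)
  list(centre = centre, semi = semi)
}

#' Generate a seeded synthetic phantom
#'
#' Builds the ground-truth anatomy: an HU image (air background, soft-tissue
#' body, bone, internal air cavity) and the matching structure set with
#' nested CTVs, organs at risk disjoint from the high-dose CTV, and optional
#' metal avoidance. Deterministic for a fixed seed.
#'
#' @param seed integer seed controlling the per-phantom geometry jitter.
#' @param config a [phantomConfig()] list.
#' @return list with elements `image` ([ImageGrid-class]) and `structures`
#'   ([StructureSet-class]).
#' @export
#' @examples
#' ph <- generatePhantom(7)
#' ph$image
generatePhantom <- function(seed, config = phantomConfig()) {
  cfg <- config
  withSeed(seed, {
    dm <- cfg$gridDim
    sp <- rep(cfg$spacing, length.out = length(dm))
    org <- centredOrigin(dm, sp)
    ell <- list()
    for (nm in names(cfg$structures))
      ell[[nm]] <- .jitterEllipse(cfg$structures[[nm]], cfg, nm)
    mk <- function(e) ellipseMask(dm, sp, org, e$centre, e$semi)

    body <- mk(ell$body)
    bone <- mk(ell$vertebra) | mk(ell$jaw_l) | mk(ell$jaw_r)
    air <- mk(ell$air_cavity)
    ctv_low <- mk(ell$ctv_low) & body & !air & !bone
    ctv_high <- mk(ell$ctv_high) & ctv_low
    oars <- list(parotid_l = mk(ell$parotid_l), parotid_r = mk(ell$parotid_r),
                 constrictor = mk(ell$constrictor))
    oars <- lapply(oars, function(m) m & body & !ctv_high)

    img <- array(cfg$huAir, dm)
    img[body] <- cfg$huSoft
    if (cfg$textureSd > 0)
      img[body] <- img[body] + rnorm(sum(body), 0, cfg$textureSd)
    img[bone & body] <- cfg$huBone
    img[air] <- cfg$huAir

    mlist <- c(list(external = body, ctv_high = ctv_high, ctv_low = ctv_low,
                    bone = bone & body, air_cavity = air & body), oars)
    avoid <- character()
    if (!is.null(cfg$metal)) {
      em <- .jitterEllipse(cfg$metal, cfg, "metal", jitter = FALSE)
      metal <- mk(em) & body
      img[metal] <- 3000
      mlist$metal <- metal
      avoid <- "metal"
    }
    list(image = ImageGrid(clampHU(img), sp, org),
         structures = StructureSet(mlist,
                                   oarNames = names(oars),
                                   avoidanceNames = avoid))
  })
}

#' CBCT error-field parameters
#'
#' Statistical description of the CT-number error field added to a
#' ground-truth image to emulate a CBCT: a per-phantom global HU offset, a
#' spatially correlated random field, amplified errors in a band around
#' bone/air interfaces, and a small rigid intra-fraction motion residue.
#' The defaults are calibrated so that, over a default cohort, the
#' population mean of the per-phantom mean absolute error is about 145 HU
#' and the mean signed error about 22 HU inside the body (air excluded).
#'
#' @param globalOffsetMean,globalOffsetSd mean and across-phantom sd (HU) of
#'   the global CT-number elevation.
#' @param noiseAmplitude sd (HU) of the correlated random field.
#' @param noiseCorrelation correlation length (mm) of the random field.
#' @param interfaceAmplitude extra error sd (HU) inside the interface band.
#' @param interfaceRadius dilation radius (voxels) defining the band around
#'   bone and air-cavity boundaries.
#' @param motionSd sd (mm per axis) of the rigid intra-fraction displacement.
#' @return list of class `ErrorFieldParams`.
#' @export
errorFieldParams <- function(globalOffsetMean = 36, globalOffsetSd = 38,
                             noiseAmplitude = 230, noiseCorrelation = 18,
                             interfaceAmplitude = 360, interfaceRadius = 2,
                             motionSd = 0.8) {
  stopIfNot(noiseAmplitude >= 0 && interfaceAmplitude >= 0 && motionSd >= 0,
            "amplitudes must be nonnegative")
  stopIfNot(noiseCorrelation > 0, "correlation length must be positive")
  p <- list(globalOffsetMean = globalOffsetMean,
            globalOffsetSd = globalOffsetSd,
            noiseAmplitude = noiseAmplitude,
            noiseCorrelation = noiseCorrelation,
            interfaceAmplitude = interfaceAmplitude,
            interfaceRadius = interfaceRadius,
            motionSd = motionSd)
  class(p) <- "ErrorFieldParams"
  p
}

# shift a numeric array by integer voxels, filling with `fill`
shiftArray <- function(x, shift, fill) {
  d <- dim(x)
  out <- array(fill, d)
  src <- dst <- vector("list", length(d))
  for (k in seq_along(d)) {
    s <- shift[k]
    if (abs(s) >= d[k]) return(out)
    if (s >= 0) { src[[k]] <- seq_len(d[k] - s); dst[[k]] <- (s + 1):d[k] }
    else { src[[k]] <- (1 - s):d[k]; dst[[k]] <- seq_len(d[k] + s) }
  }
  out[matrixIndex(dst, d)] <- x[matrixIndex(src, d)]
  out
}

# correlated unit-variance random field (smoothed white noise, renormalized)
.correlatedField <- function(dm, sigmaVox) {
  f <- smoothGauss(array(rnorm(prod(dm)), dm), sigmaVox)
  f / sd(f)
}

#' Generate a CBCT-like corrupted image
#'
#' Adds a structured CT-number error field to a ground-truth image: a global
#' offset sampled per phantom, a correlated random field, amplified
#' correlated errors within a morphological band around bone and air-cavity
#' boundaries, and the residue of a small rigid displacement applied before
#' differencing (intra-fraction motion analogue). Output HU values are
#' clamped to [-1024, 3071]. Deterministic per seed; all-zero parameters
#' return the input unchanged.
#'
#' @param ct ground-truth [ImageGrid-class].
#' @param structures matching [StructureSet-class] (bone and air-cavity
#'   masks locate the interface band).
#' @param params an [errorFieldParams()] list.
#' @param seed integer seed.
#' @return corrupted [ImageGrid-class] on the same grid.
#' @export
generateCbct <- function(ct, structures, params = errorFieldParams(), seed) {
  stopIfNot(identical(dim(ct@values), dim(masks(structures)[[1]])),
            "ct and structures must share a grid")
  p <- params
  dm <- dim(ct@values)
  sp <- ct@spacing
  withSeed(seed, {
    vals <- ct@values
    if (p$motionSd > 0) {
      mv <- round(rnorm(length(dm), 0, p$motionSd) / sp)
      vals <- shiftArray(vals, mv, .HU_MIN + 24)  # air fill
    }
    err <- array(0, dm)
    if (p$globalOffsetSd > 0 || p$globalOffsetMean != 0)
      err <- err + rnorm(1, p$globalOffsetMean, p$globalOffsetSd)
    if (p$noiseAmplitude > 0)
      err <- err + p$noiseAmplitude * .correlatedField(dm, p$noiseCorrelation / sp)
    if (p$interfaceAmplitude > 0) {
      m <- masks(structures)
      src <- (if (!is.null(m$bone)) m$bone else array(FALSE, dm)) |
        (if (!is.null(m$air_cavity)) m$air_cavity else array(FALSE, dm))
      if (any(src)) {
        # band of voxels within `interfaceRadius` of a bone/air boundary
        band <- dilateMask(src, p$interfaceRadius) &
          dilateMask(!src, p$interfaceRadius)
        ifld <- .correlatedField(dm, p$noiseCorrelation / sp / 2)
        err[band] <- err[band] + p$interfaceAmplitude * ifld[band]
      }
    }
    ImageGrid(clampHU(vals + err), sp, ct@origin)
  })
}

#' Anatomy-change parameters for the earlier planning-CT
#'
#' Describes the systematic inter-fraction change between the earlier
#' planning anatomy and the ground truth: a rigid shift and an isotropic
#' scaling of the clinical target volumes. When `shift`/`scale` are `NULL`
#' they are sampled per phantom from the corresponding distribution.
#'
#' @param shiftSd sd (mm per axis) of the sampled CTV shift.
#' @param scaleMean,scaleSd distribution of the CTV scaling factor.
#' @param shift optional fixed shift vector (mm); overrides sampling.
#' @param scale optional fixed scaling factor; overrides sampling.
#' @return list of class `AnatomyChangeParams`.
#' @export
anatomyChangeParams <- function(shiftSd = 3, scaleMean = 1.14, scaleSd = 0.05,
                                shift = NULL, scale = NULL) {
  p <- list(shiftSd = shiftSd, scaleMean = scaleMean, scaleSd = scaleSd,
            shift = shift, scale = scale)
  class(p) <- "AnatomyChangeParams"
  p
}

# transform a mask: scale about `centre` then shift; nearest-neighbour
.transformMask <- function(mask, spacing, origin, shift, scale, centre) {
  if (all(shift == 0) && scale == 1) return(mask)
  dm <- dim(mask)
  co <- voxelCoords(dm, spacing, origin)
  src <- sweep(sweep(co, 2, centre + shift), 2, rep(scale, ncol(co)), "/")
  src <- sweep(src, 2, centre, "+")
  out <- nearestSample(mask + 0, spacing, origin, src) > 0.5
  array(out, dm)
}

#' Generate the earlier planning-CT anatomy
#'
#' Derives the anatomy used for offline planning from the ground truth by
#' shifting and scaling the clinical target volumes (the tumour is isodense
#' with soft tissue, so the HU image is unchanged). The ground truth itself
#' is never modified. Deterministic per seed; zero-change parameters return
#' an identical anatomy.
#'
#' @param ct ground-truth [ImageGrid-class].
#' @param structures ground-truth [StructureSet-class].
#' @param params an [anatomyChangeParams()] list.
#' @param seed integer seed (used when shift/scale are sampled).
#' @return list with elements `image` and `structures`.
#' @export
generatePlanningAnatomy <- function(ct, structures,
                                    params = anatomyChangeParams(), seed = 1) {
  p <- params
  m <- masks(structures)
  dm <- dim(ct@values)
  withSeed(seed, {
    shift <- if (is.null(p$shift)) rnorm(length(dm), 0, p$shiftSd) else p$shift
    scale <- if (is.null(p$scale)) max(0.5, rnorm(1, p$scaleMean, p$scaleSd)) else p$scale
    if (all(shift == 0) && scale == 1) {
      list(image = ct, structures = structures)
    } else {
      idx <- which(m$ctv_low, arr.ind = TRUE)
      centre <- colSums(sweep(sweep(idx, 2, 1), 2, ct@spacing, "*")) / nrow(idx) +
        ct@origin
      newLow <- .transformMask(m$ctv_low, ct@spacing, ct@origin, shift, scale, centre)
      newHigh <- .transformMask(m$ctv_high, ct@spacing, ct@origin, shift, scale, centre)
      if (!any(newLow))
        stop("transformed target left the grid", call. = FALSE)
      # targets must remain inside the body; reject transforms pushing them out
      lost <- sum(newLow & !m$external) / sum(newLow)
      if (lost > 0.02)
        stop("transformed target extends outside the external contour", call. = FALSE)
      m$ctv_low <- newLow & m$external
      m$ctv_high <- newHigh & m$ctv_low
      list(image = ct,
           structures = StructureSet(m, oarNames = oarNames(structures),
                                     avoidanceNames = avoidanceNames(structures)))
    }
  })
}
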