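# File interfaces: NIfTI for images and masks, CSV for cohort manifests and
# calibration curves, JSON for plans, YAML for NTCP models.

#' Read and write images as NIfTI
#'
#' Images are stored single-channel with the voxel spacing in the pixdim
#' header; 2-D grids are written as one-slice volumes and read back as 2-D.
#' The physical origin is not round-tripped through the header; grids are
#' re-centred on read (all package geometry is grid-centred).
#'
#' @param x an [ImageGrid-class].
#' @param file path to a .nii or .nii.gz file.
#' @return `writeImageGrid` returns the file path invisibly;
#'   `readImageGrid` returns an [ImageGrid-class].
#' @export
writeImageGrid <- function(x, file) {
  v <- x@values
  sp <- x@spacing
  if (length(dim(v)) == 2) {
    v <- array(v, c(dim(v), 1))
    sp <- c(sp, 1)
  }
  attr(v, "pixdim") <- sp
  RNifti::writeNifti(RNifti::asNifti(v), file)
  invisible(file)
}

#' @rdname writeImageGrid
#' @export
readImageGrid <- function(file) {
  img <- RNifti::readNifti(file)
  dm <- dim(img)
  sp <- RNifti::pixdim(img)
  v <- array(as.numeric(img), dm)
  if (length(dm) == 3 && dm[3] == 1) {
    v <- array(v, dm[1:2])
    sp <- sp[1:2]
  }
  ImageGrid(v, sp)
}

#' Read and write structure sets
#'
#' One NIfTI label file per structure plus an index CSV recording mask
#' names and roles (oar / avoidance / other).
#'
#' @param x a [StructureSet-class].
#' @param dir directory to hold the files.
#' @param spacing voxel spacing in mm used for the mask volumes.
#' @return `writeStructureSet` returns `dir` invisibly;
#'   `readStructureSet` a [StructureSet-class].
#' @export
writeStructureSet <- function(x, dir, spacing = 2) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- data.frame(name = names(masks(x)),
                    role = ifelse(names(masks(x)) %in% oarNames(x), "oar",
                                  ifelse(names(masks(x)) %in%
                                           avoidanceNames(x),
                                         "avoidance", "other")),
                    file = paste0(names(masks(x)), ".nii.gz"))
  for (i in seq_len(nrow(idx))) {
    v <- masks(x)[[idx$name[i]]] + 0L
    sp <- rep(spacing, length.out = length(dim(v)))
    if (length(dim(v)) == 2) {
      v <- array(v, c(dim(v), 1)); sp <- c(sp, 1)
    }
    attr(v, "pixdim") <- sp
    RNifti::writeNifti(RNifti::asNifti(v), file.path(dir, idx$file[i]))
  }
  utils::write.csv(idx, file.path(dir, "structures.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname writeStructureSet
#' @export
readStructureSet <- function(dir) {
  idx <- utils::read.csv(file.path(dir, "structures.csv"),
                         stringsAsFactors = FALSE)
  ms <- lapply(seq_len(nrow(idx)), function(i) {
    v <- as.array(RNifti::readNifti(file.path(dir, idx$file[i])))
    if (length(dim(v)) == 3 && dim(v)[3] == 1) v <- v[, , 1]
    v > 0.5
  })
  names(ms) <- idx$name
  StructureSet(ms, oarNames = idx$name[idx$role == "oar"],
               avoidanceNames = idx$name[idx$role == "avoidance"])
}

#' Write a cohort manifest
#'
#' A CSV table listing phantom id, seed and file paths, one row per phantom.
#'
#' @param manifest data.frame with at least `phantom` and `seed` columns.
#' @param file output CSV path.
#' @return the path, invisibly.
#' @export
writeCohortManifest <- function(manifest, file) {
  stopIfNot(all(c("phantom", "seed") %in% names(manifest)),
            "manifest needs phantom and seed columns")
  utils::write.csv(manifest, file, row.names = FALSE)
  invisible(file)
}

#' Read and write calibration curves as two-column CSV
#'
#' @param curve a [CalibrationCurve-class].
#' @param file CSV path with columns `hu` and `rsp`.
#' @return `readCalibrationCurve` returns a [CalibrationCurve-class].
#' @export
writeCalibrationCurve <- function(curve, file) {
  utils::write.csv(data.frame(hu = curve@hu, rsp = curve@rsp), file,
                   row.names = FALSE)
  invisible(file)
}

#' @rdname writeCalibrationCurve
#' @export
readCalibrationCurve <- function(file) {
  df <- utils::read.csv(file)
  CalibrationCurve(df$hu, df$rsp)
}

#' Serialize a plan to JSON
#'
#' Stores weights, beam/spot identifiers, the scenario-set provenance and
#' solver diagnostics as structured text.
#'
#' @param plan a [Plan-class].
#' @param file JSON path.
#' @return `readPlan` returns a [Plan-class].
#' @export
writePlan <- function(plan, file) {
  beams <- lapply(plan@beams, function(b)
    list(angle = b@angle, sigma = b@sigma, spots = b@spots))
  scen <- lapply(plan@scenarios, function(s)
    list(shift = s@shift, densityScale = s@densityScale, label = s@label))
  jsonlite::write_json(
    list(weights = plan@weights, beams = beams, scenarios = scen,
         srs = plan@srs, rrs = plan@rrs,
         diagnostics = plan@diagnostics[c("feasible", "coverage",
                                          "iterations")]),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname writePlan
#' @export
readPlan <- function(file) {
  p <- jsonlite::fromJSON(file, simplifyVector = FALSE)
  beams <- unname(lapply(p$beams, function(b)
    Beam(b$angle,
         data.frame(
           lateral = vapply(b$spots, function(s) s$lateral, numeric(1)),
           range = vapply(b$spots, function(s) s$range, numeric(1))),
         sigma = b$sigma)))
  scen <- unname(lapply(p$scenarios, function(s)
    new("Scenario", shift = as.numeric(unlist(s$shift)),
        densityScale = s$densityScale, label = s$label)))
  diag <- p$diagnostics
  diag$feasible <- isTRUE(diag$feasible)
  new("Plan", weights = as.numeric(unlist(p$weights)), beams = beams,
      scenarios = scen, srs = p$srs, rrs = p$rrs, diagnostics = diag)
}

#' Read and write NTCP models as YAML
#'
#' @param models named list of [NTCPModel-class].
#' @param file YAML path.
#' @return `readNTCPModels` returns a named list of [NTCPModel-class].
#' @export
writeNTCPModels <- function(models, file) {
  yaml::write_yaml(lapply(models, function(m)
    list(name = m@name, intercept = m@intercept,
         coefficients = as.list(m@coefficients))), file)
  invisible(file)
}

#' @rdname writeNTCPModels
#' @export
readNTCPModels <- function(file) {
  raw <- yaml::read_yaml(file)
  lapply(raw, function(m)
    NTCPModel(m$name, m$intercept, unlist(m$coefficients)))
}

#' Cache a dose-influence matrix as sparse triplets
#'
#' Plain-text triplet format: a header line of metadata (JSON) followed by a
#' CSV body with columns `row` (voxel subset position), `col` (spot) and
#' `value` (Gy per unit weight).
#'
#' @param influence a [DoseInfluence-class].
#' @param file output path.
#' @return `readDoseInfluence` returns a [DoseInfluence-class].
#' @export
writeDoseInfluence <- function(influence, file) {
  trip <- methods::as(influence@matrix, "TsparseMatrix")
  meta <- list(gridDim = influence@gridDim,
               voxelIndex = influence@voxelIndex,
               rbeFactor = influence@rbeFactor,
               scenario = list(shift = influence@scenario@shift,
                               densityScale = influence@scenario@densityScale,
                               label = influence@scenario@label),
               spotInfo = influence@spotInfo,
               dim = dim(influence@matrix))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("#", jsonlite::toJSON(meta, auto_unbox = TRUE,
                                          digits = NA)), con)
  utils::write.csv(data.frame(row = trip@i + 1L, col = trip@j + 1L,
                              value = trip@x),
                   con, row.names = FALSE)
  invisible(file)
}

#' @rdname writeDoseInfluence
#' @export
readDoseInfluence <- function(file) {
  hdr <- readLines(file, n = 1)
  meta <- jsonlite::fromJSON(sub("^#", "", hdr))
  body <- utils::read.csv(file, skip = 1)
  M <- Matrix::sparseMatrix(i = body$row, j = body$col, x = body$value,
                            dims = meta$dim)
  new("DoseInfluence",
      matrix = methods::as(methods::as(M, "CsparseMatrix"), "generalMatrix"),
      voxelIndex = as.integer(meta$voxelIndex),
      gridDim = as.integer(meta$gridDim),
      scenario = new("Scenario", shift = meta$scenario$shift,
                     densityScale = meta$scenario$densityScale,
                     label = meta$scenario$label),
      rbeFactor = meta$rbeFactor,
      spotInfo = as.data.frame(meta$spotInfo))
}

#' Write study results as CSV rows plus a JSON summary
#'
#' @param result a `StudyResult` from [runStudy()].
#' @param dir output directory; writes `rows.csv` and `summary.json`.
#' @param baseline baseline strategy for the summary.
#' @return `dir`, invisibly.
#' @export
writeStudyResult <- function(result, dir, baseline = "TB-Offline") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$rows, file.path(dir, "rows.csv"),
                   row.names = FALSE)
  summ <- summarizeStudy(result, baseline = baseline)
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = FALSE, digits = NA, dataframe = "rows")
  invisible(dir)
}
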