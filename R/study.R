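# Orchestration of the cohort experiment: three planning strategies
# (trigger-based offline, CBCT online across a range-robustness sweep,
# ground-truth online), forward evaluation on the ground truth, and
# population summaries.

#' End-to-end robust planning on one image
#'
#' Convenience wrapper chaining the standard pipeline: HU to stopping power,
#' spot-lattice construction, avoidance filtering, scenario generation,
#' influence assembly restricted to the planning-relevant voxels (targets,
#' ring, OARs), and mini-max optimization.
#'
#' @param image planning [ImageGrid-class].
#' @param structures planning [StructureSet-class].
#' @param srs setup robustness setting in mm.
#' @param rrs range robustness setting as a fraction.
#' @param curve calibration curve.
#' @param angles gantry angles (degrees).
#' @param sigma lateral spot width (mm).
#' @param lateralSpacing,rangeSpacing spot-lattice spacings in mm, see
#'   [makeBeams()].
#' @param objective an [objectiveConfig()].
#' @param control solver control list, see [optimizePlan()].
#' @param directions shift directions (defaults to the grid dimension's
#'   standard set).
#' @return a [Plan-class].
#' @export
planOn <- function(image, structures, srs, rrs,
                   curve = defaultCalibrationCurve(),
                   angles = c(50, 100, 160, 200, 260, 310), sigma = 5,
                   lateralSpacing = 5, rangeSpacing = 5,
                   objective = objectiveConfig(), control = list(),
                   directions = NULL) {
  if (is.null(directions))
    directions <- defaultDirections(length(dim(image@values)))
  rsp <- huToRsp(image, curve)
  beams <- makeBeams(rsp, structures, angles = angles, sigma = sigma,
                     lateralSpacing = lateralSpacing,
                     rangeSpacing = rangeSpacing, rrs = rrs)
  if (length(avoidanceNames(structures)))
    beams <- filterSpots(beams, structures, rsp)
  scen <- generateScenarios(srs, rrs, directions)
  m <- masks(structures)
  spacing <- min(image@spacing)
  ring <- dilateMask(m$ctv_low, max(objective$ringExpansion / spacing, 1)) &
    !m$ctv_low & m$external
  oarUnion <- Reduce(`|`, m[oarNames(structures)],
                     array(FALSE, dim(m[[1]])))
  sub <- which(m$ctv_low | ring | oarUnion)
  infl <- influenceSet(beams, rsp, scen, voxelSubset = sub)
  optimizePlan(infl, structures, objective, control = control, ring = ring,
               spacing = spacing)
}

#' Study configuration
#'
#' Defines the synthetic cohort and the planning strategies of the
#' experiment: TB-Offline (planned on the earlier anatomy, 3 mm / 3%),
#' CBCT-online (planned on the corrupted daily image, 1 mm SRS, RRS swept
#' over 3-12%), and CTOR-online (planned on the ground truth, 1 mm / 3%).
#' All plans are forward-evaluated on the ground truth with the 1 mm / 3%
#' evaluation scenario set. The cohort default of 23 mirrors the population
#' percentile mechanics.
#'
#' @param cohortSize number of phantoms (>= 2).
#' @param seeds integer seeds, one per phantom.
#' @param phantom a [phantomConfig()]; the study default uses a 64 x 64 grid
#'   at 3 mm voxels (geometry scaled by 0.8 to fit) for cohort-scale
#'   runtime.
#' @param errorParams an [errorFieldParams()].
#' @param anatomyParams an [anatomyChangeParams()].
#' @param rrsList CBCT-online range robustness settings (fractions).
#' @param srsOnline,srsOffline online/offline setup robustness (mm).
#' @param rrsOffline offline range robustness (fraction).
#' @param evalSrs,evalRrs evaluation scenario settings.
#' @param angles,sigma beam geometry.
#' @param lateralSpacing,rangeSpacing spot-lattice spacings (mm); the study
#'   default of 6 mm keeps the cohort runtime at desk scale.
#' @param objective an [objectiveConfig()].
#' @param control solver control list; the study default caps each
#'   prioritized level at 100 iterations.
#' @param models NTCP model list.
#' @param curve calibration curve.
#' @param cacheDir optional directory for per-cell caching; completed
#'   phantom/strategy cells are skipped on re-runs (resume).
#' @return list of class `StudyConfig`.
#' @export
studyConfig <- function(cohortSize = 23, seeds = seq_len(cohortSize),
                        phantom = phantomConfig(gridDim = c(64, 64),
                                                spacing = 3, scale = 0.8),
                        errorParams = errorFieldParams(),
                        anatomyParams = anatomyChangeParams(),
                        rrsList = c(0.03, 0.06, 0.08, 0.10, 0.12),
                        srsOnline = 1, srsOffline = 3, rrsOffline = 0.03,
                        evalSrs = 1, evalRrs = 0.03,
                        angles = c(50, 100, 160, 200, 260, 310), sigma = 5,
                        lateralSpacing = 6, rangeSpacing = 6,
                        objective = objectiveConfig(),
                        control = list(maxit = 100),
                        models = defaultNTCPModels(),
                        curve = defaultCalibrationCurve(), cacheDir = NULL) {
  stopIfNot(cohortSize >= 2, "cohort size must be at least 2")
  stopIfNot(length(rrsList) >= 1, "rrsList must be non-empty")
  stopIfNot(length(seeds) == cohortSize, "one seed per phantom is required")
  cfg <- as.list(environment())
  class(cfg) <- "StudyConfig"
  cfg
}

# strategy table for a config: one row per plan to generate
.strategyTable <- function(config) {
  rbind(
    data.frame(strategy = "TB-Offline", srs = config$srsOffline,
               rrs = config$rrsOffline),
    data.frame(strategy = "CBCT-online", srs = config$srsOnline,
               rrs = config$rrsList),
    data.frame(strategy = "CTOR-online", srs = config$srsOnline,
               rrs = config$rrsOffline))
}

.cellLabel <- function(phantom, strategy, rrs)
  sprintf("phantom%03d_%s_rrs%04.1f", phantom, gsub("[^A-Za-z]", "", strategy),
          100 * rrs)

#' Run the cohort study
#'
#' For every phantom: generates the ground truth, the paired CBCT and the
#' earlier planning anatomy; optimizes one plan per strategy; evaluates
#' every plan on the ground truth with the evaluation scenario set; and
#' assembles a long-format result table (one row per phantom x strategy).
#' Fully seeded; with a `cacheDir` the run is resumable per cell. An
#' infeasible optimization is recorded in its row, not fatal to the study.
#'
#' @param config a [studyConfig()].
#' @param verbose print progress lines.
#' @return list of class `StudyResult` with elements `rows` (data.frame)
#'   and `config`.
#' @export
runStudy <- function(config = studyConfig(), verbose = FALSE) {
  strat <- .strategyTable(config)
  if (!is.null(config$cacheDir))
    dir.create(config$cacheDir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (i in seq_len(config$cohortSize)) {
    seedP <- config$seeds[i]
    ph <- generatePhantom(seedP, config$phantom)
    cbct <- generateCbct(ph$image, ph$structures, config$errorParams,
                         seed = seedP + 500000L)
    plA <- generatePlanningAnatomy(ph$image, ph$structures,
                                   config$anatomyParams,
                                   seed = seedP + 900000L)
    for (j in seq_len(nrow(strat))) {
      lab <- .cellLabel(i, strat$strategy[j], strat$rrs[j])
      cache <- if (!is.null(config$cacheDir))
        file.path(config$cacheDir, paste0(lab, ".json")) else NULL
      if (!is.null(cache) && file.exists(cache)) {
        rows[[lab]] <- as.data.frame(jsonlite::fromJSON(cache))
        next
      }
      pimg <- switch(strat$strategy[j],
                     "TB-Offline" = plA$image,
                     "CBCT-online" = cbct,
                     "CTOR-online" = ph$image)
      pstr <- if (strat$strategy[j] == "TB-Offline") plA$structures
              else ph$structures
      row <- tryCatch({
        plan <- planOn(pimg, pstr, strat$srs[j], strat$rrs[j],
                       curve = config$curve, angles = config$angles,
                       sigma = config$sigma,
                       lateralSpacing = config$lateralSpacing,
                       rangeSpacing = config$rangeSpacing,
                       objective = config$objective,
                       control = config$control)
        rep <- evaluatePlan(plan, ph$image, ph$structures,
                            evalSrs = config$evalSrs,
                            evalRrs = config$evalRrs,
                            models = config$models, curve = config$curve,
                            planningImage = pimg,
                            strategy = strat$strategy[j],
                            objective = config$objective)
        cbind(data.frame(phantom = i, strategy = strat$strategy[j],
                         srs = strat$srs[j], rrs = strat$rrs[j],
                         feasible = isTRUE(planDiagnostics(plan)$feasible)),
              as.data.frame(as.list(c(
                setNames(rep@coverage,
                         paste0("v94_", names(rep@coverage))),
                setNames(rep@oarMean,
                         paste0("mean_", names(rep@oarMean))),
                setNames(rep@ntcp, paste0("ntcp_", names(rep@ntcp))),
                mae = rep@mae, me = rep@me))))
      }, error = function(e) {
        data.frame(phantom = i, strategy = strat$strategy[j],
                   srs = strat$srs[j], rrs = strat$rrs[j], feasible = FALSE,
                   error = conditionMessage(e))
      })
      if (verbose)
        message(sprintf("%s: %s", lab,
                        if (!is.null(row$v94_ctv_low))
                          sprintf("V94 low %.1f%%", row$v94_ctv_low)
                        else "failed"))
      if (!is.null(cache))
        jsonlite::write_json(row, cache, auto_unbox = FALSE, digits = NA)
      rows[[lab]] <- row
    }
  }
  allNames <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    r[setdiff(allNames, names(r))] <- NA
    r[allNames]
  })
  res <- list(rows = do.call(rbind, c(rows, make.row.names = FALSE)),
              config = config)
  class(res) <- "StudyResult"
  res
}

#' Summarize a study against a baseline strategy
#'
#' Per strategy/RRS cell: median and population 90th percentile of the
#' VoxMin V94% per CTV, the count of phantoms with coverage below 95%
#' (strict inequality), mean +/- sd NTCP difference versus the baseline in
#' percentage points, and paired signed-rank p-values versus the baseline.
#'
#' @param result a `StudyResult` from [runStudy()].
#' @param baseline baseline strategy label (default "TB-Offline").
#' @return data.frame, one row per strategy/RRS cell.
#' @export
summarizeStudy <- function(result, baseline = "TB-Offline") {
  rows <- result$rows
  stopIfNot(baseline %in% rows$strategy,
            sprintf("baseline strategy '%s' missing from the result", baseline))
  rows$cell <- ifelse(rows$strategy == "CBCT-online",
                      sprintf("CBCT-online (RRS %g%%)", 100 * rows$rrs),
                      rows$strategy)
  base <- rows[rows$strategy == baseline, ]
  base <- base[order(base$phantom), ]
  ntcpCols <- grep("^ntcp_", names(rows), value = TRUE)
  out <- lapply(split(rows, rows$cell), function(df) {
    df <- df[order(df$phantom), ]
    s <- data.frame(cell = df$cell[1], strategy = df$strategy[1],
                    rrs = df$rrs[1], n = nrow(df))
    for (ctv in c("ctv_high", "ctv_low")) {
      v <- df[[paste0("v94_", ctv)]]
      s[[paste0("median_v94_", ctv)]] <- median(v, na.rm = TRUE)
      s[[paste0("p90_v94_", ctv)]] <-
        populationPercentile(v[!is.na(v)], 0.90, "lower")
      s[[paste0("outliers_", ctv)]] <- sum(v < 95, na.rm = TRUE)
    }
    paired <- df$phantom %in% base$phantom & !is.na(df$v94_ctv_low)
    bsub <- base[match(df$phantom[paired], base$phantom), ]
    for (nc in ntcpCols) {
      delta <- df[[nc]][paired] - bsub[[nc]]
      s[[paste0("d", nc, "_mean_pp")]] <- mean(delta)
      s[[paste0("d", nc, "_sd_pp")]] <- sd(delta)
      s[[paste0("d", nc, "_p")]] <-
        if (all(delta == 0)) 1
        else if (length(delta) < 5) NA_real_
        else pairedSignedRank(df[[nc]][paired], bsub[[nc]])$p.value
    }
    s
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}
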