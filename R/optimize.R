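# Scenario-based mini-max robust optimization of nonnegative spot weights.
#
# The target coverage requirement (V94% > 98% of each CTV in the voxel-wise
# minimum dose over the scenario set) is non-convex; it is enforced through
# a smooth surrogate — a quadratic penalty on each voxel's shortfall below
# 94% of prescription in its worst scenario — followed by a direct V94%
# verification. Subject to coverage, organ-at-risk mean doses are minimized
# sequentially in priority order, each solved level then frozen as a
# constraint with 2% slack; total spot weight acts as a final regularizer
# (a monitor-unit analogue). OARs and the ring structure enter in the
# nominal scenario only, matching clinical practice of robustly optimizing
# targets and serial structures exclusively.

#' Objective configuration for robust plan optimization
#'
#' @param doseHigh prescription (Gy) for `ctv_high` (default 70).
#' @param doseLow prescription (Gy) for `ctv_low` (default 54.25).
#' @param coverageThreshold fraction of prescription defining coverage
#'   (default 0.94, i.e. V94%).
#' @param coverageGoal required percentage of covered voxels (default 98).
#' @param oarPriority ordered character vector of OAR mask names; defaults
#'   to the structure set's OARs at optimization time.
#' @param coverageMarginFactor internal inflation of the per-voxel coverage
#'   goal driving the smooth penalty (default 1.02); verification always
#'   uses the uninflated threshold. A quadratic penalty equilibrates
#'   slightly below its goal, so the goal sits slightly above the
#'   requirement.
#' @param ringExpansion ring structure width: expansion of `ctv_low` in mm.
#' @param ringCapFraction nominal-dose cap in the ring, as a fraction of
#'   `doseLow`.
#' @param hotspotFraction overdose cap inside the targets, as a fraction of
#'   `doseHigh`.
#' @return list of class `ObjectiveConfig`.
#' @export
objectiveConfig <- function(doseHigh = 70, doseLow = 54.25,
                            coverageThreshold = 0.94, coverageGoal = 98,
                            coverageMarginFactor = 1.02,
                            oarPriority = NULL, ringExpansion = 10,
                            ringCapFraction = 0.85, hotspotFraction = 1.07) {
  stopIfNot(doseHigh > doseLow && doseLow > 0,
            "prescriptions must satisfy doseHigh > doseLow > 0")
  cfg <- list(doseHigh = doseHigh, doseLow = doseLow,
              coverageThreshold = coverageThreshold,
              coverageGoal = coverageGoal,
              coverageMarginFactor = coverageMarginFactor,
              oarPriority = oarPriority,
              ringExpansion = ringExpansion,
              ringCapFraction = ringCapFraction,
              hotspotFraction = hotspotFraction)
  class(cfg) <- "ObjectiveConfig"
  cfg
}

#' Worst-case scenario metric
#'
#' Evaluates a dose metric for a structure in every scenario and returns the
#' worst case: the maximum over scenarios for cost-type metrics ("mean"),
#' the minimum for coverage ("coverage", V-at-threshold percent).
#'
#' @param weights nonnegative spot weights.
#' @param influences list of [DoseInfluence-class], one per scenario.
#' @param structure logical mask of the structure.
#' @param metric "mean" (Gy) or "coverage" (percent of voxels at or above
#'   `threshold * prescription`).
#' @param prescription,threshold coverage parameters (ignored for "mean").
#' @return worst-case metric value.
#' @export
worstCaseObjective <- function(weights, influences, structure,
                               metric = c("mean", "coverage"),
                               prescription = NULL, threshold = 0.94) {
  metric <- match.arg(metric)
  stopIfNot(length(influences) > 0, "at least one scenario is required")
  rows <- match(which(structure), influences[[1]]@voxelIndex)
  stopIfNot(!anyNA(rows), "structure voxels missing from the influence grid")
  vals <- vapply(influences, function(I) {
    d <- as.numeric(I@matrix[rows, , drop = FALSE] %*% weights)
    if (metric == "mean") mean(d)
    else 100 * mean(d >= threshold * prescription - 1e-9)
  }, numeric(1))
  if (metric == "mean") max(vals) else min(vals)
}

# projected Barzilai-Borwein gradient descent with nonmonotone safeguard
.solvePG <- function(fg, w0, maxit = 400, tol = 1e-5) {
  w <- pmax(w0, 0)
  r <- fg(w); f <- r$f; g <- r$g
  step <- 1 / max(sqrt(sum(g^2)), 1e-12)
  fhist <- f
  small <- 0
  for (it in seq_len(maxit)) {
    ok <- FALSE
    for (tries in seq_len(30)) {
      wn <- pmax(w - step * g, 0)
      rn <- fg(wn)
      if (rn$f <= max(tail(fhist, 5)) - 1e-12 * abs(f) ||
          sqrt(sum((wn - w)^2)) < 1e-14) { ok <- TRUE; break }
      step <- step / 2
    }
    if (!ok) break
    s <- wn - w; y <- rn$g - g
    sy <- sum(s * y)
    stepNew <- if (sy > 1e-30) sum(s * s) / sy else step * 2
    relchg <- abs(rn$f - f) / max(abs(f), 1e-12)
    w <- wn; f <- rn$f; g <- rn$g
    fhist <- c(fhist, f)
    step <- min(max(stepNew, 1e-12), 1e12)
    small <- if (relchg < tol) small + 1 else 0
    if (small >= 8 && it > 20) break
  }
  list(w = w, f = f, iterations = it)
}

# per-voxel minimum over the scenario matrices of one structure group,
# with the achieving scenario; Msub is a list of (groupRows x spots)
.groupVoxmin <- function(Msub, w) {
  D <- vapply(Msub, function(M) as.numeric(M %*% w), numeric(nrow(Msub[[1]])))
  if (is.null(dim(D))) D <- matrix(D, nrow = 1)
  idx <- max.col(-D, ties.method = "first")
  list(vmin = D[cbind(seq_len(nrow(D)), idx)], argmin = idx)
}

# coverage penalty over the worst scenario per voxel, plus its gradient;
# groups carry precomputed per-scenario submatrices
.covPenalty <- function(groups, w, nw) {
  f <- 0
  g <- numeric(nw)
  for (grp in groups) {
    t <- grp$target
    sc <- .groupVoxmin(grp$Ms, w)
    r <- pmax(0, t - sc$vmin)
    f <- f + mean(r^2) / t^2
    if (any(r > 0)) {
      coef <- -2 * r / (length(r) * t^2)
      for (s in unique(sc$argmin[r > 0])) {
        cs <- numeric(length(r))
        sel <- sc$argmin == s & r > 0
        cs[sel] <- coef[sel]
        g <- g + as.numeric(crossprod(grp$Ms[[s]], cs))
      }
    }
  }
  list(f = f, g = g)
}

# quadratic overdose penalty in the nominal scenario; Msub precomputed
.overPenalty <- function(Msub, w, cap, scaleSq) {
  if (!nrow(Msub)) return(list(f = 0, g = numeric(ncol(Msub))))
  d <- as.numeric(Msub %*% w)
  r <- pmax(0, d - cap)
  g <- if (any(r > 0))
    2 * as.numeric(crossprod(Msub, r)) / (nrow(Msub) * scaleSq)
  else numeric(ncol(Msub))
  list(f = mean(r^2) / scaleSq, g = g)
}

#' Robust mini-max optimization of spot weights
#'
#' Finds nonnegative spot weights such that, in the voxel-wise minimum dose
#' over all optimization scenarios, at least `coverageGoal` percent of each
#' CTV receives `coverageThreshold` of its prescription, and, subject to
#' that, prioritized OAR mean doses (nominal scenario) are sequentially
#' minimized with previously attained levels frozen as constraints with 2%
#' slack. Coverage is enforced through a smooth worst-case shortfall penalty
#' and verified directly; a failed verification triggers one penalty-weight
#' escalation before the plan is declared infeasible (reported in the
#' diagnostics together with the achieved worst-case coverage, never
#' silently).
#'
#' @param influences list of [DoseInfluence-class], one per scenario, on a
#'   common voxel subset covering targets, ring and OARs.
#' @param structures the [StructureSet-class].
#' @param objective an [objectiveConfig()].
#' @param control list: `maxit` (per level, default 400), `tol` (relative
#'   objective change, default 1e-5), `mu` (initial coverage penalty weight
#'   in OAR levels, default 2e4), `weightReg` (final total-weight
#'   regularizer, default 1e-3).
#' @param ring optional logical mask of the ring structure (expansion of
#'   `ctv_low` minus `ctv_low`); built from the masks with a 2 mm voxel
#'   assumption when omitted.
#' @param spacing voxel size in mm, used only to build the default ring.
#' @return a [Plan-class]; `planDiagnostics()` reports feasibility, the
#'   achieved VoxMin V94% per CTV and OAR mean doses.
#' @export
optimizePlan <- function(influences, structures, objective = objectiveConfig(),
                         control = list(), ring = NULL, spacing = 2) {
  stopIfNot(length(influences) >= 1, "at least one scenario is required")
  ctrl <- utils::modifyList(list(maxit = 400, tol = 1e-5, mu = 2e4,
                                 weightReg = 1e-3), control)
  obj <- objective
  Ms <- lapply(influences, function(I) I@matrix)
  vi <- influences[[1]]@voxelIndex
  m <- masks(structures)
  rowsOf <- function(mask) {
    r <- match(which(mask), vi)
    r[!is.na(r)]
  }
  rowsH <- rowsOf(m$ctv_high); rowsL <- rowsOf(m$ctv_low)
  stopIfNot(length(rowsH) > 0 && length(rowsL) > 0,
            "influence grid must cover the targets")
  cm <- obj$coverageMarginFactor
  # per-structure submatrices are extracted once; all per-iteration work is
  # plain sparse matvecs/crossprods
  # dense per-structure blocks: small enough to hold, and dense BLAS
  # matvecs beat sparse dispatch at these sizes
  MsH <- lapply(Ms, function(M) as.matrix(M[rowsH, , drop = FALSE]))
  MsL <- lapply(Ms, function(M) as.matrix(M[rowsL, , drop = FALSE]))
  groups <- list(
    list(Ms = MsH, target = cm * obj$coverageThreshold * obj$doseHigh),
    list(Ms = MsL, target = cm * obj$coverageThreshold * obj$doseLow))

  if (is.null(ring))
    ring <- dilateMask(m$ctv_low, max(obj$ringExpansion / spacing, 1)) &
      !m$ctv_low & m$external
  oarPrio <- obj$oarPriority
  if (is.null(oarPrio)) oarPrio <- oarNames(structures)
  nomI <- which(vapply(influences, function(I)
    I@scenario@label == "nominal", logical(1)))[1]
  Mnom <- Ms[[nomI]]
  nw <- ncol(Mnom)
  MnomH <- MsH[[nomI]]; MnomL <- MsL[[nomI]]
  MnomR <- as.matrix(Mnom[rowsOf(ring), , drop = FALSE])
  MnomOar <- lapply(oarPrio, function(nm)
    as.matrix(Mnom[rowsOf(m[[nm]]), , drop = FALSE]))
  names(MnomOar) <- oarPrio

  # infeasible geometry: a target voxel no spot can reach
  reach <- as.numeric(MnomL %*% rep(1, nw))
  if (any(reach <= 0))
    stop("infeasible geometry: target voxels unreachable by any spot",
         call. = FALSE)

  scaleSq <- obj$doseLow^2
  ringCap <- obj$ringCapFraction * obj$doseLow
  hotCap <- obj$hotspotFraction * obj$doseHigh

  qualityTerms <- function(w) {
    rg <- .overPenalty(MnomR, w, ringCap, scaleSq)
    hot <- .overPenalty(MnomL, w, hotCap, scaleSq)
    # prescription adherence: two-sided pull of the nominal high-CTV dose
    # toward its prescription (plan homogeneity / monitor-unit analogue)
    rAdh <- as.numeric(MnomH %*% w) - obj$doseHigh
    fAdh <- mean(rAdh^2) / obj$doseHigh^2
    gAdh <- 2 * as.numeric(crossprod(MnomH, rAdh)) /
      (nrow(MnomH) * obj$doseHigh^2)
    list(f = 0.05 * rg$f + 0.05 * hot$f + 0.2 * fAdh,
         g = 0.05 * rg$g + 0.05 * hot$g + 0.2 * gAdh)
  }

  # level 1: drive the worst-case coverage penalty to zero
  verify <- function(w) {
    c(ctv_high = 100 * mean(.groupVoxmin(MsH, w)$vmin >=
                              obj$coverageThreshold * obj$doseHigh - 1e-9),
      ctv_low = 100 * mean(.groupVoxmin(MsL, w)$vmin >=
                             obj$coverageThreshold * obj$doseLow - 1e-9))
  }
  w0 <- rep(1, nw)
  w0 <- w0 * obj$doseHigh / max(mean(as.numeric(MnomH %*% w0)), 1e-9)
  fg1 <- function(w) {
    cp <- .covPenalty(groups, w, nw)
    qt <- qualityTerms(w)
    list(f = cp$f + qt$f, g = cp$g + qt$g)
  }
  # solved in chunks so the (cheaper) direct verification can stop the
  # (dearer) penalty grind once coverage holds with a one-point margin
  w <- w0
  iterations <- 0
  budget <- 3 * ctrl$maxit
  while (budget > 0) {
    sol <- .solvePG(fg1, w, maxit = min(60, budget), tol = ctrl$tol / 10)
    w <- sol$w
    iterations <- iterations + sol$iterations
    budget <- budget - 60
    if (all(verify(w) >= pmin(obj$coverageGoal + 1, 100) - 1e-9)) break
    if (sol$iterations < 60) break  # solver converged on its own
  }
  wBest <- w
  feasible <- all(verify(w) >= obj$coverageGoal)

  # levels 2+: prioritized OAR mean doses under frozen coverage
  oarAchieved <- numeric(0)
  if (feasible && length(MnomOar)) {
    frozen <- list()
    for (nm in names(MnomOar)) {
      Moar <- MnomOar[[nm]]
      if (!nrow(Moar)) next
      gOar <- as.numeric(crossprod(
        Moar, rep(1 / nrow(Moar), nrow(Moar)))) / obj$doseLow
      mu <- ctrl$mu
      for (attempt in 1:2) {
        fg <- function(wv) {
          cp <- .covPenalty(groups, wv, nw)
          qt <- qualityTerms(wv)
          f <- mean(as.numeric(Moar %*% wv)) / obj$doseLow + mu * cp$f +
            qt$f + ctrl$weightReg * mean(wv)
          g <- gOar + mu * cp$g + qt$g + ctrl$weightReg / length(wv)
          for (fr in frozen) {
            r <- max(0, mean(as.numeric(fr$M %*% wv)) - fr$cap)
            if (r > 0) {
              f <- f + 50 * (r / obj$doseLow)^2
              g <- g + 100 * r / obj$doseLow * fr$g
            }
          }
          list(f = f, g = g)
        }
        solk <- .solvePG(fg, w, maxit = ctrl$maxit, tol = ctrl$tol)
        iterations <- iterations + solk$iterations
        if (all(verify(solk$w) >= obj$coverageGoal)) {
          w <- solk$w; wBest <- w
          break
        }
        mu <- mu * 10 # one escalation before falling back
      }
      achieved <- mean(as.numeric(Moar %*% wBest))
      frozen[[length(frozen) + 1]] <-
        list(M = Moar, cap = 1.02 * achieved,
             g = gOar) # gradient of the frozen mean, reused
      oarAchieved[nm] <- achieved
      w <- wBest
    }
  }
  w <- wBest
  cov <- verify(w)
  feasible <- all(cov >= obj$coverageGoal)
  if (!feasible)
    warning(sprintf(
      "plan infeasible: achieved VoxMin coverage %.1f%% (ctv_high), %.1f%% (ctv_low)",
      cov["ctv_high"], cov["ctv_low"]), call. = FALSE)

  scen <- lapply(influences, function(I) I@scenario)
  shifts <- vapply(scen, function(s) sqrt(sum(s@shift^2)), numeric(1))
  scales <- vapply(scen, function(s) abs(s@densityScale - 1), numeric(1))
  info <- influences[[1]]@spotInfo
  beams <- lapply(split(info, info$beam), function(df)
    Beam(df$angle[1], data.frame(lateral = df$lateral, range = df$range),
         sigma = df$sigma[1]))
  new("Plan", weights = as.numeric(w), beams = beams, scenarios = scen,
      srs = max(shifts), rrs = max(scales),
      diagnostics = list(feasible = feasible, coverage = cov,
                         oarMean = oarAchieved, iterations = iterations,
                         objective = obj))
}
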