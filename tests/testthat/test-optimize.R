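# Builds a hand-sized influence object for solver unit tests.
tinyInfluence <- function(mat, scenario = Scenario(), rbe = 1.1) {
  M <- methods::as(methods::as(Matrix::Matrix(mat, sparse = TRUE),
                               "CsparseMatrix"), "generalMatrix")
  new("DoseInfluence", matrix = M,
      voxelIndex = seq_len(nrow(mat)), gridDim = c(nrow(mat), 1L),
      scenario = scenario, rbeFactor = rbe,
      spotInfo = data.frame(beam = 1, angle = 0,
                            lateral = seq_len(ncol(mat)), range = 50,
                            sigma = 5))
}

tinyStructures <- function(nvox, target = seq_len(nvox)) {
  m <- array(FALSE, c(nvox, 1))
  m[target, 1] <- TRUE
  ext <- array(TRUE, c(nvox, 1))
  StructureSet(list(external = ext, ctv_high = m, ctv_low = m))
}

test_that("single-spot closed form: optimal weight is prescription over influence", {
  I <- tinyInfluence(matrix(0.5, 1, 1))
  st <- tinyStructures(1)
  plan <- optimizePlan(list(I), st,
                       objectiveConfig(doseHigh = 2, doseLow = 1,
                                       ringExpansion = 0),
                       control = list(maxit = 2000, tol = 1e-10))
  expect_equal(spotWeights(plan), 4.0, tolerance = 1e-4)
  expect_true(planDiagnostics(plan)$feasible)
})

test_that("worst-case objective equals brute force on hand-built grids", {
  set.seed(9)
  mats <- replicate(3, matrix(runif(8), 4, 2), simplify = FALSE)
  infl <- lapply(mats, tinyInfluence)
  st <- tinyStructures(4, target = c(1, 3))
  w <- c(2, 1)
  mask <- masks(st)$ctv_high

  doses <- lapply(mats, function(M) M %*% w)
  expect_equal(
    worstCaseObjective(w, infl, mask, "mean"),
    max(vapply(doses, function(d) mean(d[c(1, 3)]), numeric(1))))
  expect_equal(
    worstCaseObjective(w, infl, mask, "coverage", prescription = 1),
    min(vapply(doses, function(d) 100 * mean(d[c(1, 3)] >= 0.94),
               numeric(1))))

  # single scenario equals the plain metric; duplication changes nothing
  expect_equal(worstCaseObjective(w, infl[1], mask, "mean"),
               mean(doses[[1]][c(1, 3)]))
  expect_equal(worstCaseObjective(w, c(infl, infl), mask, "mean"),
               worstCaseObjective(w, infl, mask, "mean"))
  expect_error(worstCaseObjective(w, list(), mask, "mean"), "at least one")
})

test_that("weights stay nonnegative and the solver is deterministic", {
  ph <- smallPhantom()
  p1 <- suppressWarnings(smallPlan(ph))
  p2 <- suppressWarnings(smallPlan(ph))
  expect_true(all(spotWeights(p1) >= 0))
  expect_identical(spotWeights(p1), spotWeights(p2))
})

test_that("robust plans meet the coverage constraint on their own scenario set", {
  ph <- smallPhantom()
  plan <- smallPlan(ph, control = list(maxit = 100))
  d <- planDiagnostics(plan)
  expect_true(d$feasible)
  expect_gte(d$coverage["ctv_high"], 98)
  expect_gte(d$coverage["ctv_low"], 98)
  # self-consistency: evaluation on the optimized image with the same
  # settings reproduces at least the verified coverage
  rep <- evaluatePlan(plan, ph$image, ph$structures)
  expect_gte(rep@coverage["ctv_high"], d$coverage["ctv_high"] - 1e-9)
  expect_gte(rep@coverage["ctv_low"], d$coverage["ctv_low"] - 1e-9)
})

test_that("unreachable targets are declared infeasible, not silently returned", {
  I <- tinyInfluence(matrix(c(0.5, 0), 2, 1))  # voxel 2 unreachable
  st <- tinyStructures(2)
  expect_error(optimizePlan(list(I), st,
                            objectiveConfig(doseHigh = 2, doseLow = 1,
                                            ringExpansion = 0)),
               "infeasible geometry")
})

test_that("optimizing over a scenario subset never worsens the OAR objective", {
  # feasible-set nesting: dropping scenarios weakens the coverage
  # constraints, so the attainable OAR mean can only improve. Asserted on
  # seeded instances small enough for the solver to reach the optimum (the
  # truncated prioritized solver on full phantoms is path-dependent and
  # does not inherit the property per instance).
  mkStruct <- function() {
    ext <- array(TRUE, c(3, 1))
    ctv <- array(c(TRUE, TRUE, FALSE), c(3, 1))
    oar <- array(c(FALSE, FALSE, TRUE), c(3, 1))
    StructureSet(list(external = ext, ctv_high = ctv, ctv_low = ctv,
                      oar1 = oar), oarNames = "oar1")
  }
  for (s in 1:10) {
    set.seed(100 + s)
    nominal <- matrix(runif(9, 0.2, 1), 3, 3)
    shifted <- lapply(1:2, function(i)
      nominal * matrix(runif(9, 0.9, 1), 3, 3))
    scen <- c(list(Scenario()),
              lapply(1:2, function(i)
                Scenario(shift = c(1, 0), densityScale = 1.03,
                         label = "shift+range")))
    infl <- mapply(function(M, sc) tinyInfluence(M, sc),
                   c(list(nominal), shifted), scen, SIMPLIFY = FALSE)
    obj <- objectiveConfig(doseHigh = 2, doseLow = 1, ringExpansion = 0,
                           hotspotFraction = 1.6, oarPriority = "oar1")
    ctl <- list(maxit = 3000, tol = 1e-11)
    pFull <- suppressWarnings(optimizePlan(infl, mkStruct(), obj, ctl))
    pSub <- suppressWarnings(optimizePlan(infl[1], mkStruct(), obj, ctl))
    if (planDiagnostics(pFull)$feasible && planDiagnostics(pSub)$feasible)
      expect_lte(planDiagnostics(pSub)$oarMean[["oar1"]],
                 planDiagnostics(pFull)$oarMean[["oar1"]] + 1e-3)
  }
})
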