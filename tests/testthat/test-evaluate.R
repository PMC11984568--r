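test_that("voxmin equals the brute-force elementwise minimum", {
  set.seed(4)
  doses <- replicate(5, matrix(runif(9), 3, 3), simplify = FALSE)
  got <- voxmin(doses)
  brute <- matrix(NA_real_, 3, 3)
  for (i in 1:3) for (j in 1:3)
    brute[i, j] <- min(vapply(doses, function(d) d[i, j], numeric(1)))
  expect_equal(got, brute)

  expect_equal(voxmin(list(doses[[1]], doses[[1]])), doses[[1]])
  zero <- matrix(0, 3, 3)
  expect_equal(voxmin(c(doses, list(zero))), zero)
  for (d in doses) expect_true(all(got <= d))
  expect_error(voxmin(list()), "non-empty")
  expect_error(voxmin(list(matrix(0, 2, 2), matrix(0, 3, 3))), "shape")
})

test_that("V94 metric counts voxels at the fractional threshold", {
  mask <- c(TRUE, TRUE, TRUE, TRUE)
  expect_equal(vMetric(c(2, 1.9, 1.8, 1.0), mask, 2), 50)  # cutoff 1.88 Gy
  expect_equal(vMetric(rep(2, 4), mask, 2), 100)
  expect_equal(vMetric(rep(0, 4), mask, 2), 0)
  expect_error(vMetric(1, FALSE, 2), "non-empty")
})

test_that("MAE/ME follow the masking rules and hand arithmetic", {
  v <- matrix(40, 4, 4)
  ref <- ImageGrid(v, 2)
  expect_equal(unname(computeMaeMe(ref, ref, matrix(TRUE, 4, 4))), c(0, 0))

  shifted <- ImageGrid(v + 50, 2)
  expect_equal(unname(computeMaeMe(shifted, ref, matrix(TRUE, 4, 4))),
               c(50, 50))

  # 3 surviving voxels with diffs +10, -20, +30; one air voxel excluded
  ext <- matrix(FALSE, 4, 4); ext[1, 1:4] <- TRUE
  refv <- v; refv[1, 4] <- -1000  # below the -960 air threshold
  test <- refv; test[1, 1:3] <- test[1, 1:3] + c(10, -20, 30)
  err <- computeMaeMe(ImageGrid(test, 2), ImageGrid(refv, 2), ext)
  expect_equal(unname(err["mae"]), 20)
  expect_equal(unname(err["me"]), 20 / 3)

  expect_error(computeMaeMe(ImageGrid(matrix(-1000, 2, 2), 2),
                            ImageGrid(matrix(-1000, 2, 2), 2),
                            matrix(TRUE, 2, 2)), "air exclusion")
})

test_that("logistic NTCP matches hand computation and is monotone", {
  m <- NTCPModel("toy", intercept = -4, coefficients = c(mean_dose = 0.1))
  expect_equal(ntcp(c(mean_dose = 60), m), 1 / (1 + exp(-2)))
  expect_equal(round(ntcp(c(mean_dose = 60), m), 4), 0.8808)
  expect_equal(ntcp(c(mean_dose = 40), m), 0.5)  # linear predictor 0
  d <- seq(0, 80, by = 5)
  p <- vapply(d, function(x) ntcp(c(mean_dose = x), m), numeric(1))
  expect_true(all(diff(p) >= 0))
  expect_error(ntcp(c(other = 1), m), "missing dose metric")
})

test_that("population percentile follows the 20th/21st-of-23 interpolation rule", {
  # coverage-type: lower is worse; best-to-worst is 23..1
  expect_equal(populationPercentile(1:23, 0.90, "lower"), 3.3)
  # NTCP-delta-type: higher is worse
  expect_equal(populationPercentile(1:23, 0.90, "higher"), 20.7)
  expect_equal(populationPercentile(rep(7, 10), 0.90, "lower"), 7)
  # order invariance
  set.seed(3)
  v <- rnorm(23)
  expect_equal(populationPercentile(sample(v), 0.9, "lower"),
               populationPercentile(v, 0.9, "lower"))
  # direction equivariance: negating values swaps the worse direction
  expect_equal(populationPercentile(-v, 0.9, "higher"),
               -populationPercentile(v, 0.9, "lower"))
  expect_error(populationPercentile(1:23, 1.2), "fraction")
  expect_error(populationPercentile(3), "at least two")
})

test_that("signed-rank test agrees with exhaustive sign enumeration", {
  a <- c(11, 12, 13, 14, 15, 16)
  b <- a - c(1, 2, 3, 4, 5, 6)    # differences 1..6, no ties
  res <- pairedSignedRank(a, b)

  # independent oracle: enumerate all 2^6 sign assignments of ranks 1..6
  ranks <- 1:6
  wplus <- apply(expand.grid(rep(list(c(0, 1)), 6)), 1,
                 function(s) sum(ranks[s == 1]))
  wobs <- sum(ranks)  # all differences positive
  pExact <- mean(wplus >= wobs | wplus <= sum(ranks) - wobs)
  expect_equal(res$p.value, pExact)
  expect_true(res$significant)

  # swapping the inputs flips the statistic sign, p unchanged
  swp <- pairedSignedRank(b, a)
  expect_equal(swp$statistic, -res$statistic)
  expect_equal(swp$p.value, res$p.value)

  expect_warning(id <- pairedSignedRank(1:6, 1:6), "zero")
  expect_equal(id$p.value, 1)
  expect_false(id$significant)
  expect_true(id$degenerate)
})

test_that("plan evaluation reports coverage, OAR dose and NTCP on ground truth", {
  ph <- smallPhantom()
  plan <- suppressWarnings(smallPlan(ph))

  # zero-weight plan: no dose anywhere, NTCP collapses to logistic(beta0)
  zplan <- new("Plan", weights = rep(0, length(spotWeights(plan))),
               beams = plan@beams, scenarios = plan@scenarios,
               srs = plan@srs, rrs = plan@rrs, diagnostics = list())
  z <- evaluatePlan(zplan, ph$image, ph$structures)
  expect_equal(unname(z@coverage), c(0, 0))
  expect_equal(unname(z@oarMean), rep(0, 3))
  models <- defaultNTCPModels()
  expect_equal(unname(z@ntcp["xerostomia"]),
               100 / (1 + exp(-models$xerostomia@intercept)))

  # an error-free "CBCT" yields a report identical to the ground-truth one
  r1 <- evaluatePlan(plan, ph$image, ph$structures, planningImage = ph$image)
  zeroErr <- errorFieldParams(globalOffsetMean = 0, globalOffsetSd = 0,
                              noiseAmplitude = 0, interfaceAmplitude = 0,
                              motionSd = 0)
  cb <- generateCbct(ph$image, ph$structures, zeroErr, seed = 1)
  r2 <- evaluatePlan(plan, cb, ph$structures, planningImage = cb)
  expect_equal(r1@coverage, r2@coverage)
  expect_equal(r1@oarMean, r2@oarMean)
  expect_equal(r1@mae, 0)
  expect_equal(r1@me, 0)

  # VoxMin coverage can never beat nominal-scenario coverage
  rsp <- huToRsp(ph$image)
  scen <- generateScenarios(1, 0.03, defaultDirections(2))
  m <- masks(ph$structures)
  sub <- which(m$ctv_low)
  infl <- influenceSet(plan@beams, rsp, scen, voxelSubset = sub)
  doses <- lapply(infl, function(I) as.numeric(I@matrix %*% spotWeights(plan)))
  vm <- voxmin(doses)
  nom <- doses[[1]]
  mk <- rep(TRUE, length(sub))
  expect_lte(vMetric(vm, mk, 54.25), vMetric(nom, mk, 54.25))
})
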