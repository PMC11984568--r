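test_that("phantom generation is seeded-deterministic and respects nesting", {
  a <- generatePhantom(7)
  b <- generatePhantom(7)
  expect_identical(voxelValues(a$image), voxelValues(b$image))
  expect_identical(masks(a$structures), masks(b$structures))

  m <- masks(a$structures)
  expect_true(all(!m$ctv_high | m$ctv_low))   # ctv_high subset of ctv_low
  expect_true(all(!m$ctv_low | m$external))   # ctv_low subset of external
  expect_gte(length(oarNames(a$structures)), 2)
  for (nm in oarNames(a$structures))
    expect_false(any(m[[nm]] & m$ctv_high))   # OARs disjoint from ctv_high

  # different seeds give different jittered geometry
  c <- generatePhantom(8)
  expect_false(identical(masks(c$structures)$ctv_low, m$ctv_low))
})

test_that("tissue HU values appear exactly in the noise-free image", {
  cfg <- phantomConfig(huBone = 700)
  ph <- generatePhantom(3, cfg)
  m <- masks(ph$structures)
  v <- voxelValues(ph$image)
  expect_true(all(v[m$bone] == 700))
  expect_true(all(v[m$air_cavity] == -1000))
  expect_true(all(v[m$ctv_low] == 40))  # tumour isodense with soft tissue
})

test_that("a structure placed outside the grid is rejected", {
  cfg <- phantomConfig(gridDim = c(32, 32), spacing = 2) # 64 mm FOV
  expect_error(generatePhantom(1, cfg), "outside the grid")
})

test_that("error fields vanish with zero amplitudes and add exact offsets", {
  ph <- smallPhantom()
  zero <- errorFieldParams(globalOffsetMean = 0, globalOffsetSd = 0,
                           noiseAmplitude = 0, interfaceAmplitude = 0,
                           motionSd = 0)
  cb0 <- generateCbct(ph$image, ph$structures, zero, seed = 1)
  expect_identical(voxelValues(cb0), voxelValues(ph$image))

  off <- errorFieldParams(globalOffsetMean = 50, globalOffsetSd = 0,
                          noiseAmplitude = 0, interfaceAmplitude = 0,
                          motionSd = 0)
  cb <- generateCbct(ph$image, ph$structures, off, seed = 1)
  err <- computeMaeMe(cb, ph$image, masks(ph$structures)$external)
  expect_equal(unname(err["mae"]), 50)
  expect_equal(unname(err["me"]), 50)
})

test_that("CBCT generation is deterministic per seed and clamps HU", {
  ph <- smallPhantom()
  a <- generateCbct(ph$image, ph$structures, seed = 42)
  b <- generateCbct(ph$image, ph$structures, seed = 42)
  expect_identical(voxelValues(a), voxelValues(b))
  expect_gte(min(voxelValues(a)), -1024)
  expect_lte(max(voxelValues(a)), 3071)
  c <- generateCbct(ph$image, ph$structures, seed = 43)
  expect_false(identical(voxelValues(a), voxelValues(c)))
})

test_that("default error-field calibration reproduces the target HU error statistics", {
  # population mean of per-phantom MAE within +-10% of the 145 HU target
  # over a >=100-phantom cohort (default parameters, default grid)
  n <- 100
  res <- vapply(seq_len(n), function(i) {
    ph <- generatePhantom(i)
    cb <- generateCbct(ph$image, ph$structures, seed = i + 500000L)
    computeMaeMe(cb, ph$image, masks(ph$structures)$external)
  }, numeric(2))
  expect_gt(mean(res["mae", ]), 145 * 0.9)
  expect_lt(mean(res["mae", ]), 145 * 1.1)
  # signed error centred near the reported global elevation
  expect_gt(mean(res["me", ]), 22 - 45)
  expect_lt(mean(res["me", ]), 22 + 45)
})

test_that("planning anatomy: identity, determinism and centroid shifts", {
  ph <- smallPhantom()
  idp <- anatomyChangeParams(shift = c(0, 0), scale = 1)
  same <- generatePlanningAnatomy(ph$image, ph$structures, idp, seed = 1)
  expect_identical(masks(same$structures), masks(ph$structures))
  expect_identical(voxelValues(same$image), voxelValues(ph$image))

  a <- generatePlanningAnatomy(ph$image, ph$structures, seed = 11)
  b <- generatePlanningAnatomy(ph$image, ph$structures, seed = 11)
  expect_identical(masks(a$structures), masks(b$structures))

  # pure 3 mm shift displaces the ctv_low centroid by 3 mm within voxel
  # rounding (4 mm voxels here)
  sh <- anatomyChangeParams(shift = c(3, 0), scale = 1)
  moved <- generatePlanningAnatomy(ph$image, ph$structures, sh, seed = 1)
  cen <- function(mask) {
    idx <- which(mask, arr.ind = TRUE)
    colMeans(idx) * 4
  }
  d <- cen(masks(moved$structures)$ctv_low) - cen(masks(ph$structures)$ctv_low)
  expect_lt(abs(d[1] - 3), 4 + 1e-9)
  expect_lt(abs(d[2]), 4 + 1e-9)
  # ground truth untouched
  expect_identical(voxelValues(ph$image), voxelValues(generatePhantom(5, smallPhantomConfig())$image))
})

test_that("anatomy transforms that leave the body are rejected", {
  ph <- smallPhantom()
  bad <- anatomyChangeParams(shift = c(200, 0), scale = 1)
  expect_error(generatePlanningAnatomy(ph$image, ph$structures, bad, seed = 1))
})
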