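test_that("influence is a nonnegative linear map with RBE weighting", {
  rsp <- uniformRsp(1, n = 31, spacing = 2)
  beams <- list(Beam(0, data.frame(lateral = c(-5, 0, 5),
                                   range = c(30, 40, 50)), sigma = 5))
  I <- buildInfluence(beams, rsp)
  expect_s4_class(I, "DoseInfluence")
  expect_true(all(I@matrix@x >= 0))

  w1 <- c(1, 2, 0.5); w2 <- c(0.3, 0, 4)
  expect_equal(doseFrom(I, w1 + w2), doseFrom(I, w1) + doseFrom(I, w2))
  expect_equal(doseFrom(I, 2 * w1), 2 * doseFrom(I, w1))
  expect_true(all(doseFrom(I, c(0, 0, 0)) == 0))

  # biologically-weighted / physical influence = RBE factor, entrywise
  Iphys <- buildInfluence(beams, rsp, rbeFactor = 1.0)
  expect_equal(I@matrix@x / Iphys@matrix@x, rep(1.1, length(I@matrix@x)))
})

test_that("spot peaks sit at the nominal range and move shallower when density rises", {
  rsp <- uniformRsp(1, n = 41, spacing = 2)  # 82 mm extent
  beams <- list(Beam(0, data.frame(lateral = 0, range = 50), sigma = 5))
  co <- minimaxPT:::voxelCoords(c(41, 41), c(2, 2), c(-40, -40))
  peakDepth <- function(scenario) {
    I <- buildInfluence(beams, rsp, scenario)
    d <- doseFrom(I, 1, full = TRUE)
    co[which.max(d), 1] - (-41)  # depth from the entry face
  }
  d0 <- peakDepth(Scenario())
  expect_lt(abs(d0 - 50), 2.1)  # within a voxel of the nominal range
  dUp <- peakDepth(Scenario(densityScale = 1.1, label = "shift+range"))
  expect_lte(dUp, d0)           # denser tissue pulls the peak shallower
  dDn <- peakDepth(Scenario(densityScale = 0.9, label = "shift+range"))
  expect_gte(dDn, d0)
})

test_that("setup shifts displace the dose laterally by the shift amount", {
  rsp <- uniformRsp(1, n = 41, spacing = 2)
  beams <- list(Beam(0, data.frame(lateral = 0, range = 40), sigma = 5))
  I0 <- buildInfluence(beams, rsp)
  Is <- buildInfluence(beams, rsp,
                       Scenario(shift = c(0, 6), densityScale = 1,
                                label = "shift+range"))
  d0 <- doseFrom(I0, 1, full = TRUE)
  ds <- doseFrom(Is, 1, full = TRUE)
  # profile along the lateral axis at the peak depth row
  row <- which.max(apply(d0, 1, max))
  expect_equal(which.max(ds[row, ]) - which.max(d0[row, ]), 3) # 6 mm / 2 mm
})

test_that("sparsity thresholding changes spot totals by less than 0.5%", {
  ph <- smallPhantom()
  rsp <- huToRsp(ph$image)
  beams <- makeBeams(rsp, ph$structures, angles = c(50, 200),
                     lateralSpacing = 6, rangeSpacing = 6)
  Ifull <- buildInfluence(beams, rsp, threshold = 0)
  Ithr <- buildInfluence(beams, rsp, threshold = 1e-4)
  tot <- Matrix::colSums(Ifull@matrix)
  dif <- Matrix::colSums(Ifull@matrix) - Matrix::colSums(Ithr@matrix)
  expect_true(all(dif / pmax(tot, 1e-12) < 0.005))
})

test_that("beam lattices tile the target and empty spot sets error", {
  ph <- smallPhantom()
  rsp <- huToRsp(ph$image)
  beams <- makeBeams(rsp, ph$structures)
  expect_length(beams, 6)
  expect_true(all(vapply(beams, function(b) nrow(b@spots) > 0, logical(1))))
  emptyBeam <- Beam(0, data.frame(lateral = numeric(0), range = numeric(0)))
  expect_error(buildInfluence(list(emptyBeam), rsp), "no spots")
})

test_that("spot filtering removes exactly the rays blocked by avoidance", {
  n <- 40
  rsp <- uniformRsp(1, n = n, spacing = 2)  # 80 mm
  avoid <- matrix(FALSE, n, n)
  avoid[1:10, 15:26] <- TRUE  # block on the low-x side, central lateral band
  beams <- list(Beam(0, data.frame(lateral = rep(seq(-30, 30, by = 5), 2),
                                   range = rep(c(30, 70),
                                               each = 13)), sigma = 5),
                Beam(180, data.frame(lateral = seq(-30, 30, by = 5),
                                     range = 30), sigma = 5))

  kept <- filterSpots(beams, list(block = avoid), rsp)

  # independent brute-force ray marching oracle
  oracle <- function(angle, lateral, range) {
    a <- angle * pi / 180
    d <- c(cos(a), sin(a)); l <- c(-sin(a), cos(a))
    start <- lateral * l - 100 * d
    wepl <- 0
    for (t in seq(0, 250, by = 0.2)) {
      p <- start + t * d
      i <- round((p[1] + 39) / 2) + 1; j <- round((p[2] + 39) / 2) + 1
      inside <- i >= 1 && i <= n && j >= 1 && j <= n
      if (inside && wepl < range && avoid[i, j]) return(FALSE)
      if (inside) wepl <- wepl + 1 * 0.2
      if (wepl >= range) break
    }
    TRUE
  }
  for (bi in 1:2) {
    expKeep <- vapply(seq_len(nrow(beams[[bi]]@spots)), function(k)
      oracle(beams[[bi]]@angle, beams[[bi]]@spots$lateral[k],
             beams[[bi]]@spots$range[k]), logical(1))
    expect_equal(kept[[bi]]@spots, beams[[bi]]@spots[expKeep, ],
                 ignore_attr = TRUE)
  }
  expect_lt(nrow(kept[[1]]@spots), nrow(beams[[1]]@spots))

  # empty avoidance: unchanged; full-grid avoidance: nothing survives
  expect_identical(filterSpots(beams, list(), rsp), beams)
  all <- filterSpots(beams, list(a = matrix(TRUE, n, n)), rsp)
  expect_equal(sum(vapply(all, function(b) nrow(b@spots), integer(1))), 0)
})

test_that("metal implants become avoidance structures that prune spots", {
  cfg <- phantomConfig(gridDim = c(48, 48), spacing = 4, scale = 0.8,
                       metal = list(centre = c(-38, -25), semi = c(10, 10)))
  ph <- generatePhantom(5, cfg)
  expect_equal(avoidanceNames(ph$structures), "metal")
  m <- masks(ph$structures)
  expect_true(all(voxelValues(ph$image)[m$metal] == 3000))

  rsp <- huToRsp(ph$image)
  beams <- makeBeams(rsp, ph$structures, angles = c(50, 160, 260),
                     lateralSpacing = 6, rangeSpacing = 6)
  kept <- filterSpots(beams, ph$structures, rsp)
  n0 <- sum(vapply(beams, function(b) nrow(b@spots), integer(1)))
  n1 <- sum(vapply(kept, function(b) nrow(b@spots), integer(1)))
  expect_lt(n1, n0)
  expect_gt(n1, 0)
})
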