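# Small-cohort study configurations keep these tests fast; the full-size
# default study is exercised in the acceptance suite.
tinyStudyConfig <- function(..., cohortSize = 2, seeds = c(4, 6)) {
  studyConfig(cohortSize = cohortSize, seeds = seeds,
              phantom = smallPhantomConfig(),
              rrsList = c(0.03, 0.10),
              angles = c(50, 160, 260),
              control = list(maxit = 60), ...)
}

test_that("identical seeds reproduce the study table exactly", {
  cfg <- tinyStudyConfig()
  r1 <- suppressWarnings(runStudy(cfg))
  r2 <- suppressWarnings(runStudy(cfg))
  expect_identical(r1$rows, r2$rows)
  expect_equal(nrow(r1$rows), 2 * 4)  # phantoms x (offline + 2 rrs + ctor)
})

test_that("without HU errors or anatomy change, online strategies coincide", {
  zeroErr <- errorFieldParams(globalOffsetMean = 0, globalOffsetSd = 0,
                              noiseAmplitude = 0, interfaceAmplitude = 0,
                              motionSd = 0)
  noChange <- anatomyChangeParams(shift = c(0, 0), scale = 1)
  cfg <- tinyStudyConfig(errorParams = zeroErr, anatomyParams = noChange)
  res <- suppressWarnings(runStudy(cfg))
  cb <- res$rows[res$rows$strategy == "CBCT-online" & res$rows$rrs == 0.03, ]
  ct <- res$rows[res$rows$strategy == "CTOR-online", ]
  expect_equal(cb$v94_ctv_high, ct$v94_ctv_high, tolerance = 1e-6)
  expect_equal(cb$v94_ctv_low, ct$v94_ctv_low, tolerance = 1e-6)
  expect_equal(cb$ntcp_xerostomia, ct$ntcp_xerostomia, tolerance = 1e-6)
  expect_true(all(cb$mae == 0))
})

test_that("caching makes the study resumable per cell", {
  td <- withr::local_tempdir()
  cfg <- tinyStudyConfig(cacheDir = td)
  r1 <- suppressWarnings(runStudy(cfg))
  nfiles <- length(list.files(td))
  expect_equal(nfiles, nrow(r1$rows))
  # second run reads every cell from cache and reproduces the table
  r2 <- suppressWarnings(runStudy(cfg))
  expect_equal(r2$rows$v94_ctv_low, r1$rows$v94_ctv_low)
})

test_that("summaries match hand computation on a hand-built table", {
  mk <- function(strategy, rrs, v94, ntcp) {
    data.frame(phantom = seq_along(v94), strategy = strategy, srs = 1,
               rrs = rrs, feasible = TRUE,
               v94_ctv_high = v94, v94_ctv_low = v94,
               ntcp_xerostomia = ntcp)
  }
  rows <- rbind(mk("TB-Offline", 0.03, c(98, 94, 99), c(20, 22, 24)),
                mk("CBCT-online", 0.03, c(96, 91, 94.9), c(18, 21, 20)))
  res <- list(rows = rows, config = NULL)
  class(res) <- "StudyResult"
  s <- summarizeStudy(res)
  off <- s[s$strategy == "TB-Offline", ]
  cb <- s[s$strategy == "CBCT-online", ]
  expect_equal(off$median_v94_ctv_low, 98)
  expect_equal(cb$median_v94_ctv_low, 94.9)
  # strict inequality for the < 95% outlier count
  expect_equal(off$outliers_ctv_low, 1)
  expect_equal(cb$outliers_ctv_low, 2)
  expect_equal(off$dntcp_xerostomia_mean_pp, 0)  # baseline vs itself
  expect_equal(cb$dntcp_xerostomia_mean_pp, mean(c(-2, -1, -4)))
  expect_equal(cb$dntcp_xerostomia_sd_pp, sd(c(-2, -1, -4)))
  # boundary value 95 is not an outlier under the strict rule
  rows2 <- rbind(mk("TB-Offline", 0.03, c(95, 95, 95), c(1, 1, 1)))
  res2 <- list(rows = rows2, config = NULL); class(res2) <- "StudyResult"
  expect_equal(summarizeStudy(res2)$outliers_ctv_low, 0)
  expect_error(summarizeStudy(res, baseline = "nope"), "missing")
})
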