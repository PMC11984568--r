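# Shared fixtures: tiny grids and a small cached phantom so expensive
# generation happens once per test run.

uniformRsp <- function(value = 1, n = 25, spacing = 2) {
  RSPMap(matrix(value, n, n), spacing)
}

smallPhantomConfig <- function() {
  phantomConfig(gridDim = c(48, 48), spacing = 4, scale = 0.8)
}

# one small phantom reused across tests
.fixtureEnv <- new.env()
smallPhantom <- function(seed = 5) {
  key <- paste0("ph", seed)
  if (is.null(.fixtureEnv[[key]]))
    .fixtureEnv[[key]] <- generatePhantom(seed, smallPhantomConfig())
  .fixtureEnv[[key]]
}

# quick robust plan on a small phantom (few beams, loose solver)
smallPlan <- function(ph, srs = 1, rrs = 0.03, angles = c(50, 160, 260),
                      control = list(maxit = 60)) {
  planOn(ph$image, ph$structures, srs, rrs, angles = angles,
         lateralSpacing = 6, rangeSpacing = 6, control = control)
}
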