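# Robust-optimization and robust-evaluation scenario sets.

#' Default isocenter-shift directions
#'
#' In 3-D the standard 14-point set: the 6 cube-face directions (+-each axis)
#' plus the 8 cube-vertex directions normalized to unit length, so every
#' shift has magnitude exactly SRS. In 2-D the planar analogue: 4 axis
#' directions plus 4 normalized diagonals.
#'
#' @param dimension 2 or 3.
#' @return list of unit vectors.
#' @export
defaultDirections <- function(dimension) {
  stopIfNot(length(dimension) == 1 && dimension %in% c(2, 3),
            "dimension must be 2 or 3")
  if (dimension == 2) {
    axes <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
    diag <- lapply(list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)),
                   function(v) v / sqrt(2))
    c(axes, diag)
  } else {
    axes <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))
    sg <- expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))
    vert <- lapply(seq_len(nrow(sg)), function(i) as.numeric(sg[i, ]) / sqrt(3))
    c(axes, vert)
  }
}

#' Construct a scenario set from SRS and RRS
#'
#' Builds the nominal scenario plus, for every shift direction, two
#' shift+range scenarios combining the SRS-magnitude isocenter shift with a
#' density scaling of 1 - RRS and 1 + RRS. With the default 14 directions in
#' 3-D this yields the 29-scenario robust set (nominal + 14 shifts x +-range);
#' the 2-D default (8 directions) yields 17. Range errors occur only in
#' combination with shifts; there are no pure-range scenarios. The same
#' constructor serves both optimization and evaluation settings.
#'
#' @param srs setup robustness setting: shift magnitude in mm (>= 0).
#' @param rrs range robustness setting: density-scaling fraction in [0, 1).
#' @param directions list of unit shift vectors; may be empty only when
#'   `srs = 0` and `rrs = 0` collapse the set to the nominal scenario.
#' @return list of [Scenario-class], length `1 + 2 * length(directions)`.
#' @export
#' @examples
#' length(generateScenarios(1, 0.03, defaultDirections(3)))  # 29
generateScenarios <- function(srs, rrs, directions = defaultDirections(2)) {
  stopIfNot(srs >= 0, "srs must be nonnegative")
  stopIfNot(rrs >= 0 && rrs < 1, "rrs must be in [0, 1)")
  scen <- list(Scenario(shift = rep(0, if (length(directions))
    length(directions[[1]]) else 2), densityScale = 1, label = "nominal"))
  for (d in directions) {
    d <- as.numeric(d)
    for (s in c(1 - rrs, 1 + rrs)) {
      scen[[length(scen) + 1]] <-
        new("Scenario", shift = srs * d, densityScale = s,
            label = "shift+range")
    }
  }
  scen
}
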