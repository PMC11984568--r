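Package: minimaxPT
Title: Scenario-Based Mini-Max Robust Proton Plan Optimization on Synthetic CBCT Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study cone-beam-CT (CBCT) driven online-adaptive
    intensity-modulated proton therapy at desk scale. Generates seeded
    head-and-neck-like voxel phantoms with paired CBCT images whose CT-number
    error statistics emulate clinically reported magnitudes, converts CT
    numbers to relative stopping power, traces water-equivalent path lengths,
    assembles sparse pencil-beam dose-influence matrices per error scenario,
    and optimizes nonnegative spot weights by scenario-based mini-max robust
    optimization under voxel-wise-minimum target-coverage constraints with
    prioritized organ-at-risk objectives. Includes the full evaluation chain:
    voxel-wise minimum dose, V94% coverage, HU error statistics, logistic
    normal-tissue complication probability models, population percentiles and
    paired signed-rank comparisons, plus an orchestrated multi-strategy study
    over a synthetic cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    Matrix,
    RNifti,
    jsonlite,
    yaml,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
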