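---
title: "Range-robust proton planning on CBCT-quality images: methods and design"
author: "minimaxPT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Range-robust proton planning on CBCT-quality images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Online-adaptive intensity-modulated proton therapy (IMPT) re-optimizes the
treatment plan on an image of the daily anatomy. Cone-beam CT (CBCT) is the
practical in-room modality, but its CT numbers (HU) are substantially less
accurate than diagnostic CT. Since proton range is computed from HU through a
calibration to relative stopping power (RSP), HU errors become range errors,
and a plan optimized on a CBCT can miss or underdose the target when the dose
is recomputed on the true anatomy.

`minimaxPT` implements, at desk scale and on fully synthetic data, the
computational strategy of *inflating the range robustness setting* (RRS) in
scenario-based mini-max robust optimization so that daily CBCT-based plans
tolerate HU errors, while the small setup robustness setting (SRS) permitted
by online adaptation keeps organ-at-risk (OAR) doses low. The package
contains the complete chain: phantom cohort generation, CBCT error
simulation, HU-to-RSP conversion, water-equivalent path-length (WEPL)
tracing, a parametric pencil-beam dose engine, scenario construction,
mini-max spot-weight optimization, and the evaluation machinery
(voxel-wise-minimum coverage, HU error statistics, logistic NTCP, population
percentiles, paired signed-rank tests) needed to compare planning strategies
over a cohort.

## Scenario model

A scenario combines a rigid isocenter shift of magnitude SRS (mm) with a
mass-density scaling of the whole RSP map by `1 - RRS` or `1 + RRS`. The
robust set consists of the nominal scenario plus, for each shift direction,
both density scalings: `1 + 2 x |directions|` scenarios in total. In 3-D the
standard 14-direction set (6 cube faces + 8 normalized vertices) gives 29
scenarios; the planar analogue used by the 2-D default geometry (4 axes + 4
normalized diagonals) gives 17. There are no pure-range scenarios: range
errors always ride on a shift, which is what the 29-count arithmetic
implies. The same constructor builds optimization and evaluation sets, so
the two can never drift apart; evaluation always uses 1 mm / 3%.

The nominal scenario participates in the constraint set like any other
member. Whether the clinical system weights it specially is unknown to us;
treating it uniformly is the simplest defensible choice and is stated here
rather than hidden.

## Dose engine

The engine is deliberately minimal but honest about proton mechanics:

* **Geometry.** Parallel beams at the clinical six gantry angles (50, 100,
  160, 200, 260, 310 degrees) on a 2-D axial-slice analogue. Source
  divergence, couch rotations, range shifters and energy-layer hardware are
  out of scope. The engine raises a clear error for 3-D grids; phantoms,
  scenarios and all evaluation primitives are dimension-agnostic.
* **WEPL.** Per-voxel water-equivalent depth is the integral of RSP along
  the voxel's own ray, computed by marching a ray grid and interpolating.
  Because the geometry is parallel-beam, a rigid setup shift leaves every
  voxel's WEPL unchanged and acts purely as a lateral displacement of the
  spot axes relative to the patient; a uniform density scaling scales WEPL
  exactly. Both facts are exploited so that one WEPL map per beam serves all
  scenarios.
* **Depth dose.** An analytic Bragg curve: a cosine-tapered entrance
  plateau (35% of peak at the surface, zero slope at the peak position)
  plus a Gaussian peak of width 3 mm, normalized to 1 exactly at the
  nominal range, falling below 1% of peak by 1.2 x range (the width shrinks
  automatically for short ranges to preserve this). Nuclear halo and
  scattering depth dependence are not modelled.
* **Spots.** Lateral Gaussian profiles (sigma 5 mm) on a lattice: lateral
  positions every 5 mm across the target plus margin, nominal ranges tiling
  the target's WEPL extent every 5 mm, with margins that grow with the
  planned RRS so density-scaled scenarios still find energy layers. Spots
  whose central ray crosses an avoidance structure (metal analogue) before
  reaching their range are removed before optimization.
* **Influence matrices.** One sparse voxels-by-spots matrix per scenario;
  entries below 1e-4 of each spot's maximum are dropped (verified in the
  tests to change spot totals by well under 0.5%). A constant RBE factor of
  1.1 converts physical to biologically-weighted dose.

## Optimization

The clinical requirement is V94% > 98% for both CTVs — at least 98% of
voxels receiving 94% of prescription (70 Gy high-dose CTV nested in the
54.25 Gy elective CTV) — in the voxel-wise minimum dose (VoxMin) over the
scenario set. This is non-convex, so the optimizer uses a smooth surrogate:
a quadratic penalty on each voxel's shortfall below its coverage goal in
its worst scenario, minimized by a projected Barzilai-Borwein gradient
method with nonnegativity projection. Three numerical choices matter:

* The penalty goal is inflated by 2% over the true threshold
  (`coverageMarginFactor`): a quadratic penalty equilibrates slightly below
  its goal, so aiming exactly at the threshold leaves voxels marginally
  uncovered. Verification always uses the true 94% threshold.
* Verification is direct: after solving, V94% is computed on the VoxMin of
  the actual scenario doses. A failed verification triggers one
  penalty-weight escalation (x10) before the plan is declared infeasible;
  infeasibility is reported with the achieved coverage, never silently.
* The full prioritized clinical wish-list is not public; it is replaced by
  a two-level scheme that preserves its lexicographic spirit: first
  coverage feasibility (with a weak prescription-adherence pull of the
  nominal high-CTV dose toward 70 Gy, a ring-overdose penalty 10 mm around
  the elective CTV, and a 107% hotspot cap), then OAR mean doses minimized
  one priority level at a time, each attained level frozen as a constraint
  with 2% slack, with total spot weight as a final regularizer standing in
  for monitor units. OARs and the ring enter in the nominal scenario only,
  mirroring the clinical practice of robustly optimizing only targets and
  serial structures.

The solver is deterministic: uniform initialization scaled to the
prescription, no stochastic restarts. Iteration caps and tolerances
(`maxit`, default 400 per level; relative objective change 1e-5) are
configuration.

## Synthetic cohort

**What the phantoms emulate.** A head-and-neck axial slice: a soft-tissue
body ellipse (40 HU), vertebral and jaw bone (700 HU), a pharyngeal air
cavity (-1000 HU), a lateralized pair of nested CTVs, two parotid-like
glands, and a constrictor-like muscle. Structure centres and sizes are
jittered per seed to create inter-phantom variability. The tumour is
isodense with soft tissue, so target masks carry no HU signature.

**CBCT error model.** The corrupted daily image adds four components chosen
to mimic the qualitative structure of iteratively reconstructed CBCT
errors: a global per-scan HU elevation, a long-range correlated random
field (low-pass filtered white noise, correlation length 18 mm), amplified
errors in a 2-voxel morphological band around bone and air interfaces, and
the residue of a small rigid intra-fraction displacement applied before
differencing. Amplitudes were calibrated once, jointly, so that the
population statistics of the default cohort match the clinically reported
magnitudes (population mean MAE about 145 HU and mean error about 22 HU
inside the body, excluding reference voxels below -960 HU); the individual
parameter values are not separately interpretable (the offset mean exceeds
the target ME because the motion residue biases ME negative at the body
edge). No projection-domain physics, scatter, or reconstruction is
simulated; consequently the error field has the right statistics but not
the streak/cupping morphology of real CBCT.

**Planning anatomy.** The earlier planning-CT used by the offline strategy
derives from the ground truth by shifting (sd 3 mm per axis) and scaling
(mean 1.14, sd 0.05) the CTVs. The magnitude of clinical inter-fraction
change is unknown to us; the growth factor reflects that head-and-neck
target volumes commonly shrink by tens of percent over a treatment course,
so a planning CT acquired weeks earlier systematically over-covers. The
values are chosen so that adaptation is visibly beneficial while the
offline strategy remains clinically plausible (median coverage near 98%
with occasional outliers), and they are labelled synthetic wherever they
surface.

**What passing tests do and do not show.** The cohort reproduces the
*mechanisms* — HU errors degrade unprotected CBCT plans, inflated RRS
mitigates the degradation, small SRS spares OARs — and the package asserts
them as population trends. It cannot reproduce patient-level dosimetric
values; nothing in the package claims otherwise. One instructive detail
carries over: the constrictor-like OAR sits against the air cavity where
interface HU errors concentrate, and its mean dose does *not* reliably
improve under CBCT-based planning — the aggregate OAR benefit is carried
by the parotid-like structures, echoing the clinical observation that one
airway-adjacent organ resists improvement.

## Study design and scale choices

`runStudy()` evaluates three strategies per phantom, all forward-evaluated
on the ground truth with the 1 mm / 3% evaluation set: TB-Offline (planned
on the earlier anatomy at 3 mm / 3%), CBCT-online (planned on the corrupted
image at 1 mm SRS with RRS swept over 3, 6, 8, 10, 12%), and CTOR-online
(planned on the ground truth at 1 mm / 3%, the online-adaptation ceiling).
The cohort size defaults to 23 so that the population 90th percentile is
the value interpolated between the 20th and 21st worst-performing members,
the convention also used by `populationPercentile()`. "Worst" is
metric-specific: low coverage is bad, high NTCP is bad; this direction
convention is a documented package choice.

Problem sizes are the package's own desk-scale choices: single-phantom work
uses a 128 x 128 grid at 2 mm voxels with a 5 mm spot lattice; the cohort
study uses 64 x 64 at 3 mm (geometry scaled by 0.8), a 6 mm lattice, and a
100-iteration cap per prioritized level, which keeps a full 23-phantom,
7-plan-per-phantom study within a desk session while leaving every
mechanism intact.

NTCP models are logistic in OAR mean doses with editable coefficients
(xerostomia from the parotid means, dysphagia from the constrictor mean).
The shipped numbers are placeholders in the spirit of national-protocol
models, not clinical truth; the pipeline treats them as opaque parameters,
and NTCP differences are reported in percentage points.

## Degenerate inputs and edge behaviour

Zero-amplitude error fields return the input image bit-identically;
zero-change anatomy parameters return the identical anatomy. Rays that miss
the grid return empty WEPL profiles. Empty structure masks, non-monotone
calibration curves, negative depths, non-unit directions, empty scenario
lists and empty spot sets are rejected with explicit errors. All paired
differences equal to zero in the signed-rank test yield p = 1 with a
degenerate flag and a warning rather than an error.

## Known limitations

* 2-D engine; no Monte Carlo transport, scatter, or multiple-Coulomb
  depth dependence; parametric Bragg curve rather than measured depth-dose
  data.
* CBCT errors are statistical, not physical; real CBCT artifacts are
  spatially structured in ways the model does not capture.
* The prioritized objective is a stand-in for the proprietary clinical
  wish-list; absolute OAR doses and NTCP values are therefore
  package-specific, and only differences between strategies are
  meaningful.
* No dose accumulation over fractions, no re-planning trigger logic, no
  registration or contour propagation — contours are assumed transferable
  between images of one phantom.
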