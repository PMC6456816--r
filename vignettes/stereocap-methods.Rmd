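---
title: "Design-based stereology of white-matter capillaries: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design-based stereology of white-matter capillaries: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereocap)
```

## The problem

Design-based stereology infers three-dimensional quantities — reference
volume, and the total length, volume and surface area of a capillary
network — from counts made on two-dimensional sections, using randomized
probe designs whose expectations are exactly the target quantities. The
catch is that the unbiasedness claims are distributional statements about
the sampling design, and with real tissue they can never be checked: the
truth is unknown. `stereocap` replaces the tissue with synthetic phantoms
whose truth is known in closed form, so every estimator in the chain can
be validated end to end, and miscalibrated designs (for example,
non-isotropic sections over anisotropic vasculature) can be shown to fail.

The study design the package emulates is a two-group comparison:
wild-type mice versus Tg2576 transgenic mice (an amyloid-precursor-protein
model of early Alzheimer's disease), with white-matter capillary totals as
the structural variables and Morris-water-maze escape latency as the
behavioural variable. Default calibration targets — group means and SDs
for the white-matter volume and the three capillary totals, and the
structure-behaviour correlation table — are the published reference values
bundled in `defaultCalibration()`.

## The estimators

All internal lengths are millimetres; totals are converted to display
units (metres for length) only at reporting.

* **Cavalieri volume.** `V = t * a(p) * sum(P)`, with `t` the slab
  thickness (1 mm by default), `a(p)` the area represented by one grid
  point (0.59 mm² by default) and `sum(P)` the total count of grid points
  hitting the reference space over systematic sections with a uniform
  random start. Unbiased for any region shape.
* **Length density.** `Lv = 2 * sum(Q) / sum(A)`: on isotropic uniform
  random (IUR) planes the expected number of capillary transects per unit
  area is `Lv / 2`. `sum(Q)` comes from unbiased counting frames.
* **Volume density.** `Vv = sum(P_cap) / sum(P_ref)` (Delesse): the areal
  fraction of test points falling in capillary profiles estimates the
  volume fraction on sections of *any* orientation.
* **Surface density.** `Sv = 2 * sum(I) / sum(L)`: on isotropic test
  lines the expected number of boundary intersections per unit line
  length is `Sv / 2`. Lines are drawn with uniform random in-plane
  orientation on IUR planes, which makes them isotropic in 3D.
* **Totals.** Each density times the reference volume; absolute totals
  avoid the reference-space trap when reference volumes differ between
  groups.

Pooling across sections and fields is ratio-of-sums (sum all counts, sum
all probe areas/lengths, divide once), the literal reading of the summed
quantities in the density formulas; the suite demonstrates that
mean-of-ratios differs on unequal frame areas.

## The phantom

A white-matter region is an axis-aligned box (or union of disjoint boxes)
with exact membership tests and closed-form volume; the estimators are
shape-agnostic, so nothing is lost by not imitating anatomy. The capillary
network is a set of straight cylinder segments: midpoints uniform in the
region, directions uniform on the unit sphere (or all along one axis in
the anisotropic mode used for bias demonstrations), fixed 50 µm segment
length with the last segment trimmed so the total length hits its target
exactly. Ground truth is computed from the realized cylinders:
`L = sum(l_i)`, `V = sum(pi r_i^2 l_i)`, `S = sum(2 pi r_i l_i)`.

**Radii.** Totals constrain the radius distribution through its first two
moments: `V = pi E[r^2] L` and `S = 2 pi E[r] L`. `calibrateRadius()`
solves these for a lognormal mean and CV; the wild-type calibration gives
`E[r] = 1.37 µm` with CV 0.47, the Tg2576 calibration `E[r] = 1.42 µm`
with CV 0.69. Radii are truncated below the 10 µm capillary diameter
cutoff; because truncation would otherwise shave up to 13% off `E[r^2]`
for the wide Tg distribution, the generator solves for
truncation-corrected lognormal parameters so the realized moments match
the calibration.

**Cylinder ends.** A cylinder's full length counts toward truth wherever
its midpoint lies; ends may protrude from the region. Probe fields are
sampled from the region eroded by a fixed margin (0.47 mm by default,
sized to the plane offset, field jitter, field diagonal and a guard of
half a segment length). For uniformly distributed midpoints the expected
length/volume/surface density at any interior point — farther than half a
segment from the boundary — equals exactly total/volume, so interior-only
field sampling keeps the probe estimators exactly unbiased; the deficit
is confined to a boundary shell the fields never touch. This replaces an
O(segment/region) boundary-bias accounting with an exact argument.

**Cohort.** Each animal carries one standard-normal structural driver
that scales its three capillary totals comonotonically as mean-one
lognormal factors with the group CVs (the published dispersions by
default); white-matter volume varies independently. Escape latency on day
`d` is `intercept_d - slope * z` with `z` the within-group standardized
total length, per-trial Gaussian noise, and clamping to the 60 s trial
cutoff; because latency is linear in `L`, the noise-free correlation with
total length is exactly −1. Intercepts decrease over the six training
days (a learning curve); the Tg group has larger intercepts (slower
learning) on top of its smaller capillary totals. Defaults (slope 8 s per
SD, 6 s per-trial noise, so 3 s noise on the 4-trial day mean) put the
final-day correlation magnitude near 0.93, inside the 0.82–0.98 range of
the reference table, and were fixed from this design calculation before
the validation experiments were run.

## Sampling design

The simulated histology chain mirrors the laboratory one: systematic 1 mm
slabs with a uniform random start; per slab, a random-offset point grid
on a cross-section and 3–4 hits sampled without replacement as tissue
blocks; per block, one isector plane — normal uniform on the sphere
(`z ~ U(-1,1)`, azimuth uniform), offset uniform along the normal — with
a deterministic Gram–Schmidt in-plane frame so results are seed-stable;
per section, a set of photograph fields jittered uniformly in-plane, each
counted with the unbiased frame, a fine point grid, and test lines.

Sectioning is by ideal planes. The 4 µm physical section thickness is
treated as metadata: the density formulas assume planar probes, and
overprojection of ~3 µm vessels in a 4 µm section is a real-data effect
the phantom deliberately does not model. Profiles are emitted only where
the plane crosses the cylinder axis strictly between its endpoints;
end-cap ellipse truncation is ignored (relative error of order r/length,
below 0.01%). Cylinders lying exactly in the plane are a measure-zero
event and are skipped.

The counting frame defaults to the full Gundersen rule (forbidden bottom
and left edges plus the upward extension of the left edge and the
downward extension of the right edge line), which counts every convex
profile exactly once per frame tiling whatever its size; the
`paper_simple` rule (plain top/right inclusion, bottom/left prohibition)
is retained because published descriptions often state only that much.
For profiles far smaller than the frame the two agree almost always; the
suite constructs the thin, tilted corner-spanning profile on which they
differ. At exact edge contact forbidden wins. The point-grid test point
is the grid node itself (drawn at the upper-right corner of the printed
cross); a node scores once per profile it falls inside, so the count
estimates the summed profile area, matching the summed-cylinder truth.

## Default probe dimensions

Published sources rarely state frame areas or grid spacings, so defaults
are chosen by the usual coefficient-of-error budgeting and exposed in
`probeDefaults()`: ~17 sections per animal (5 slabs × 3–4 blocks), 10
fields per section, 110 µm counting frames inside 140 µm fields, 3 µm
point grid, 6 µm test-line spacing. A default wild-type animal yields
roughly 1000 counted profiles, ~2700 capillary point hits and ~2500 line
intersections, i.e. per-animal CEs of a few percent — ordinary
stereological practice — and group-mean recovery errors comfortably
inside the 5% validation tolerance.

## Reference volume in totals

`estimateCohort()` can multiply densities by either the Cavalieri
estimate (`vwm = "cavalieri"`, the full laboratory chain) or the
phantom's analytic volume (`vwm = "true"`). The recovery experiments use
`"true"`: they are designed to isolate probe error, while Cavalieri error
is characterized separately by `cavalieriExperiment()` (500 replicate
designs). On box phantoms the Cavalieri variance is dominated by the
discrete count of section planes, so single-design relative errors of
several percent are expected even though the estimator is exactly
unbiased; real brains, with tapering cross-sections and more slices,
behave better at the same `t`.

## Statistics

Stereological variables are compared with the pooled-variance unpaired t
test (`stats::t.test`); escape latencies with a two-factor mixed
repeated-measures ANOVA (group between, day within, `stats::aov` with an
`Error(animal)` stratum; no sphericity correction, matching the plain
repeated-measures analysis named in the reference protocol); and
structure-behaviour association with Pearson correlation, its p-value
from the `t = r sqrt(n-2)/sqrt(1-r^2)` transform. Correlations use
final-day escape latency: the reference description ("latency adjusted by
the stereological measurements") names no defined adjustment, and plain
pairwise correlation is the only reading consistent with a table of six
(r, p) pairs. The stereological group size is likewise unstated in the
reference; n = 7 is the only size at which all six printed (r, p) pairs
are mutually consistent under the t-transform, so the cohort defaults to
7 per group with `n` exposed in the configuration. Degenerate inputs
resolve by convention: zero pooled variance gives p = 1 (equal means) or
p = 0 (unequal), flat ANOVA strata give F = 0, p = 1, zero-variance
correlations are NA with a warning.

## Validation experiments and problem sizes

The package ships its evidence as re-runnable experiments (also executed
by `scripts/acceptance.R`):

* `cavalieriExperiment()` — 500 replicate Cavalieri designs on a
  wild-type-sized region; the mean must sit within 2% of truth.
* `recoveryExperiment()` — a cohort of 7 phantoms per group pinned at the
  group calibration targets (between-animal CVs set to zero, so cohort
  sampling wobble does not mask probe error), surveyed with ~35 IUR
  sections × 12 fields × 3 pooled replicate surveys per animal (0.5 mm
  block-sampling pitch: probe noise is dominated by shared local density
  fluctuation per section and, for capillary volume, by the heavy-tailed
  profile areas of the wide Tg radius distribution; this sampling depth
  holds the group-mean Monte-Carlo error near 1.5%); group-mean length,
  volume and surface recovery within 5%.
* `anisotropyExperiment()` — a fibre-aligned network sectioned with
  axis-aligned planes (length bias near +100%, because every fibre
  crosses every transverse plane) versus isotropic planes (bias within
  2%). For a fixed-axis network the per-plane profile intensity is
  `Lv |cos θ|`, whose 58% CV would swamp a 2% bias measurement under
  independently drawn orientations, so this experiment draws its
  isotropic orientations as a randomly rotated spherical Fibonacci
  lattice — exactly isotropic in expectation, orientation-stratified so
  the measurement error is counting-dominated — and lays one counting
  frame per plane so pooled counts stay near-Poisson. A large phantom
  (160,000 segments) keeps the finite-realization fluctuation of the
  sampled interior density below the counting noise.
* `significanceExperiment()` — 200 replicate cohorts at the published
  means/SDs; rates at which the t tests reproduce the reference
  significance pattern. A noncentral-t power calculation at these group
  parameters puts the capillary-volume test (p < 0.05 at n = 7) near 76%
  power and the probability of a non-significant white-matter comparison
  near 78%, so those two rates cannot reach 95% under the published
  dispersions — the experiment reports the observed rates rather than
  forcing them.

These sizes were chosen so each experiment's Monte-Carlo error is several
times smaller than its tolerance.

## What passing does and does not show

The phantom validates the estimators, not the biology. It does not model
section thickness or overprojection, staining artefacts, lost caps or
guard zones, vessel curvature, branching topology or flow, tissue
shrinkage during processing (estimates refer to the processed geometry),
or amyloid pathology. Cylinders may overlap in space (truth is the sum
over segments, and the probes count per profile, consistently). The
behavioural model is a linear latency-structure coupling with Gaussian
noise — a device to give the correlation machinery a known target, not a
learning model. Passing the suite therefore shows that the counting
rules, the sampling designs and the estimator algebra are correct under
the stated geometric model; with real sections, bias sources excluded
here (above all overprojection over thin vessels and reference-space
delineation) still require the usual methodological care.
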