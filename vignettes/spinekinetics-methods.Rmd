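---
title: "Methods: simulating and analysing spine flexibility tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing spine flexibility tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinekinetics)
```

## The measurement model

A pure-moment flexibility test applies a moment `M` swept between
`±limit` (default 6 Nm) across a functional spinal unit while all other
degrees of freedom stay free, and records the intervertebral rotation
`θ` (degrees). Five measures summarise the resulting moment–rotation
curve:

* range of motion, `ROM = θ(+limit) − θ(−limit)`;
* the neutral zone (NZ), the lax central region bounded by the curve's
  inflections, located as local extrema of the second derivative of the
  smoothed curve; its width is the NZ size;
* the NZ stiffness, the ordinary least-squares slope of `M` on `θ`
  between the detected bounds;
* the elastic-zone stiffnesses EZS₁ and EZS₂, the least-squares slopes
  over the `+4.5…+6` Nm and `−4.5…−6` Nm moment bands.

The sign convention is positive = extension, left lateral bending or
left axial rotation, depending on the loading plane.

## The synthetic backbone

`solve_backbone()` realises a prescribed set of the five measures as an
explicit `θ → M` function with five zones: a central NZ of width
`nz_size` and slope `nz_stiffness` centred at `center_offset` (where
`M = 0`), one constant-slope transition zone per side, and outer elastic
zones with slopes `ezs_pos`/`ezs_neg` covering the moments from the
elastic-zone band's lower bound (`band_low`, 4.5 Nm) to the limit.

The construction is fully determined by two budgets. The moment budget
fixes the NZ-edge moment `M₀ = nz_stiffness · nz_size / 2` and requires
the transitions to carry the moment from `M₀` up to the elastic-zone
band. The rotation budget requires the total span to equal `rom`
exactly:

```
w_pos + w_neg = rom − nz_size − (limit − band_low)/ezs_pos
                              − (limit − band_low)/ezs_neg
```

which must be strictly positive. The two transition widths split this
total in proportion to the elastic-zone compliances
(`w_pos : w_neg = 1/ezs_pos : 1/ezs_neg`) — any positive split would
satisfy the budgets; the compliance-proportional one keeps the curve
shape plausible and the construction deterministic.

A three-zone construction (NZ directly abutting the elastic zones)
cannot satisfy five independent measures simultaneously; the two
transition zones are exactly the free parameters that make all five
exact at once. Each of the four slope corners is blended over
`± fillet_halfwidth` (default `0.05 · nz_size`) with a smoothstep slope
profile `s(u) = s_L + (s_R − s_L)(3u² − 2u³)`, so `d²M/dθ²` is one
single-peaked bump centred exactly on each corner and zero elsewhere —
this is what makes the curvature-based NZ detection recover the true
bounds exactly on noiseless data. Because the smoothstep integrates to
the same moment as the sharp corner, the blend moves no zone-boundary
moment. The inner corners sit exactly at `center_offset ± nz_size/2`;
the outer corners are pulled inward by the fillet allowance (corner
moment `band_low − ezs · f`) so the blend finishes exactly at 4.5 Nm,
leaving the whole elastic-zone fit band exactly linear. The feasibility
conditions (positive net transition widths, transition slopes strictly
between the NZ and EZ slopes, non-overlapping fillets) are checked and
violations are reported with the violated inequality; all nine
reference cells in `reference_kinetics()` are feasible.

Hysteresis loops are modelled as a uniform moment offset: the loading
branch is the backbone shifted down by `h`, the unloading branch up by
`h`, each sampled over the rotation range where its moments span the
full `±limit` so the loop closes at the moment limits. This is the
simplest loop that preserves every slope-based measure on each branch
exactly and whose branch-averaged ROM equals the backbone's ROM
exactly; its enclosed area is `2·h·ROM`. It does not attempt to model
viscoelastic rate dependence.

## The cohort model

`generate_cohort()` emulates a paired design: each of `n_specimens`
(default 8) specimens is tested in every condition (intact, defect,
treated) and loading plane. Per-cell parameters are lognormal with
exactly the configured cell mean and SD (defaults: the ovine L4L5
reference table), via `μ = log(m²/√(m²+s²))`, `σ² = log(1 + s²/m²)`.
The underlying normal deviate is `ρ·z_specimen + √(1−ρ²)·z_cell`, where
`z_specimen` is shared by a specimen across conditions; the default
within-specimen correlation is `ρ = 0.8`, a typical value for paired
biomechanical specimens, and the log scale keeps all stiffnesses
positive. Draws violating the backbone feasibility conditions are
redrawn (cell residual first, then the whole specimen, both bounded).

Two consequences are worth knowing. First, the published axial-rotation
SDs are large enough that a substantial fraction of independent draws
is geometrically infeasible (for example, an NZ stiffness draw above
the achievable transition slope); conditioning on feasibility therefore
shifts the realised axial-rotation means away from the configured ones
(most visibly NZ stiffness). The test suite checks the bending-plane
cells against the configured means directly and the axial cells against
an independent brute-force feasibility-conditioned sampler. Second,
measurement noise is additive Gaussian on both rotation and moment,
independent per sample — defaults `σ_θ = 0.02°`, `σ_M = 0.02` Nm, with
`σ_θ` tripled for axial rotation to emulate that plane's lower
signal-to-noise ratio. These magnitudes are free parameters of the
simulator (no instrument specification fixes them) and are exposed in
the cohort configuration. The generator does not simulate
pre-conditioning cycles, creep, or coupled off-axis rotations; passing
tests on these synthetic curves show the pipeline recovers the measures
*as defined*, not that real marker-based angle reconstruction is this
clean.

Default sampling is uniform in rotation at 0.005° for the bending
planes and 0.001° for axial rotation, whose neutral zone is an order of
magnitude narrower.

## Numerical choices in the extraction

**Preparation.** One monotone branch is selected (for loops, both are
processed and the five measures averaged — the measures are defined on
a single curve and averaging cancels the hysteresis offset exactly in
the elastic zones), samples are sorted by rotation and bin-averaged on
the curve's nominal uniform grid (step = span/(n−1)). On noiseless
curves binning is the identity; under rotation noise it is essential:
sorting noisy rotations produces near-coincident abscissae whose tiny
gaps make any finite-difference derivative explode.

**Smoothing.** Local quadratic least squares (Savitzky–Golay on a
possibly non-uniform grid), vectorised via running power sums re-centred
at each evaluation point, with the global linear trend removed first so
round-off cannot masquerade as curvature. Window default: 5% of the
sample count, rounded to odd. Quadratic-preserving smoothing does not
move the curvature bumps' centres.

**Curvature for NZ detection.** The second derivative is a central
three-point difference that is exact for quadratics at any stencil
stride. Detection uses its own smoothing window (7.5% of samples) and a
stride of half that window, so the curvature is estimated at the
smoothing scale: differencing *adjacent* samples of a smoothed noisy
sequence amplifies the sample-scale jitter smoothing leaves behind
(measured: jitter tens of times the signal at any window), while
differencing at the smoothing scale suppresses it. Samples whose
smoothing window or stencil is truncated at the curve ends are excluded
from the search — shrunken end windows leave the outer corners locally
unsmoothed and produce spurious in-band curvature far larger than the
NZ bumps.

**Bound selection.** Within the central band (`|M| < 4.5` Nm, the
natural inner edge of the elastic zones), local extrema whose absolute
curvature exceeds `prominence_fraction` (default 0.25) times the
largest in-band curvature *peak* qualify; normalising by peaks rather
than raw values keeps the monotone flank of an out-of-band corner from
masking the NZ bumps. On an ascending curve the lower bound is a
curvature minimum and the upper bound a maximum; the innermost
qualifying extremum on each side of the zero-moment crossing is taken,
with a noise-split cluster of above-threshold extrema treated as one
peak (its extremum is the bound). An exactly linear curve has in-band
curvature below a round-off floor (`10⁻⁶ ·` moment span / rotation
span²) and raises a "neutral zone undetectable" error, as does any
curve with no qualifying extremum on one side. The 0.25 prominence
default was chosen so that, at the simulator's default noise, the gate
sits several noise standard deviations above the curvature noise floor
while every reference cell's weaker NZ bump (≥ 0.6 of the stronger one)
still qualifies.

**Fits and ROM.** The NZ and EZ slopes and the ROM are computed on the
*prepared, unsmoothed* curve; smoothing feeds only the curvature. With
the default window, fitting the smoothed curve would bias the
elastic-zone slopes by a few percent because the window half-width is
comparable to the elastic zones' rotation extent. The NZ fit uses
everything between the detected bounds, fillets included — this is the
dominant noiseless error, about +0.2–0.5% across the reference cells,
inside the 1% round-trip tolerance. ROM interpolates rotation against
moment linearly within the outermost monotone run (exact samples are
used when present; a recorded extreme left marginally short of the
limit by noise is linearly extrapolated from that run's outer segment).

## Statistics

Per (measure, modality): Anderson–Darling normality per condition group
(direct order-statistic formula for the composite-normal case with the
standard small-sample correction, valid from n = 5 and cross-checked
against `nortest`), Levene's test on absolute deviations from the group
mean (Brown–Forsythe median variant selectable; via `car`), one-way
within-subjects ANOVA (`F = MS_condition/MS_error` on `(k−1, (k−1)(n−1))`
degrees of freedom, sums of squares via `aov` with an `Error(specimen)`
stratum; no sphericity correction by default since with three levels
Tukey on the pooled error is the conventional follow-up), Tukey HSD on
the within-subjects error mean square via the studentized range, and
percent changes of defect/treated relative to intact. Degenerate
decompositions are guarded (`F = 0, p = 1` for a zero condition effect;
`F = ∞, p = 0` for zero error). Failed normality or variance checks are
reported, never acted on. Percent change defaults to the ratio of group
means; a specimen-paired convention (mean of per-specimen percent
changes) is selectable, because the two differ whenever specimens vary
— published reports often use the paired convention. One-sample t-tests
compare an ex-vivo group (the sample) against a single in-vivo
measurement (the hypothesised mean); the reverse orientation is
undefined for n = 1.

No multiplicity correction is applied across the 15 (measure, modality)
cells: each cell is its own ANOVA with Tukey-adjusted pairwise
comparisons, mirroring per-measure reporting practice.

## Problem sizes in the test suite

The suite regenerates everything it tests: the nine-cell noiseless
round trip at full resolution; 200-replicate noise-robustness runs for
the flexion–extension reference cell; 1000 null-cohort replicates for
the repeated-measures ANOVA and Tukey type-I rates and for Levene, 500
of n = 2000 for Anderson–Darling; 200 cohort replicates for the
lateral-bending power check; and cohorts of 2–200 specimens elsewhere.
These sizes keep every stochastic check's binomial or 3-SE band tight
enough to be meaningful while the whole suite runs in a few minutes.

## Known limitations

* **Axial rotation under default noise is not analysable per curve.**
  With `σ_θ = 0.06°` against a ~0.28° neutral zone, the curvature
  signal-to-noise ratio is below 1 at every admissible smoothing scale,
  so NZ detection fails or returns noise; `extract_kinetics(on_error =
  "na")` (used by `run_study()`) records such curves as `NA` with the
  staged error message. This mirrors the lower signal-to-noise reported
  for axial-rotation flexibility data; analysing real axial curves
  requires either lower noise or cycle averaging upstream.
* **Elastic-zone slopes are attenuated under rotation noise.** Rotation
  noise blurs the curve in `θ`, mixing transition-zone slopes into the
  inner edge of the fixed 4.5–6 Nm band; at default noise the
  flexion–extension EZS estimates run about 3–6% low. This is a
  property of the prescribed estimator (OLS of moment on rotation over
  a moment-selected band), not removable without knowing the noise
  level.
* **NZ stiffness carries a deterministic +0.2–0.5% fillet bias**, far
  inside the 1% tolerance but visible whenever an estimator's variance
  is smaller than its bias.
* **Feasibility conditioning** shifts the realised axial-rotation cell
  means relative to the configured ones (see the cohort section).
* The simulator's noise model is white and Gaussian; real motion-capture
  noise is temporally correlated, and real curves carry viscoelastic
  creep between cycles. Passing recovery tests here demonstrates
  correctness of the measure definitions and detection algorithm, not
  robustness to every artefact of a physical rig.
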