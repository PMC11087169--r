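---
title: "Plan-quality scoring and adaptive-course simulation: methods"
author: "aptscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plan-quality scoring and adaptive-course simulation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aptscore)
```

## The problem

Proton therapy for head-and-neck (HN) cancer is delivered over 30-36 daily
fractions, and the anatomy the plan was designed on — the planning CT — is not
the anatomy the beam traverses a month later: post-operative edema resolves,
tumors shrink, weight changes, and the daily setup varies. Because the Bragg
peak position depends on the tissue along the beam path, these changes degrade
target coverage and organ-at-risk (OAR) sparing. Clinics respond with
*adaptive* proton therapy (APT): *offline*, a replan on a periodic QA CT that
takes about a week to reach treatment; or *online*, a replan on the daily
in-room image before the fraction is delivered.

`aptscore` packages the analysis layer needed to quantify what adaptation
buys: dose-volume endpoint extraction, a calibrated plan-quality score, and a
fraction-wise course simulator in which none/offline/online policies can be
compared on equal footing.

## Endpoint metrics

All metrics are computed on an axis-aligned voxel dose grid (`DoseGrid`, dose
in Gy-RBE, RBE = 1.1 for protons) with boolean structure masks pre-resampled
to the same grid:

* **V100** — % of a target's own volume receiving at least 100% of its own
  prescription. The comparison is inclusive (`>=`), matching the planning-goal
  wording "receives >= 100%".
* **D98** — the minimal dose covering the best-covered 98% of the structure,
  reported as % of prescription. Computed bin-free from the sorted voxel
  doses, with linear interpolation on the cumulative DVH between adjacent
  voxel doses; `volumePct = 100` returns the structure minimum.
* **Dmax** — the maximum voxel dose in the structure (not a small-volume
  surrogate; the near-maximum D0.03cc is a separate metric).
* **Dmean** — arithmetic mean over the mask (uniform voxel volumes).
* **D0.03cc** — the minimal dose inside the hottest 0.03 cm³: voxel doses are
  sorted in descending order and voxel volumes accumulated; the voxel in which
  the boundary falls reports its full dose (a conservative partial-voxel rule;
  no sub-voxel dose model).

The clinical system these definitions emulate does not document whether it
interpolates D98 or D0.03cc; the rules above are *declared* package choices,
fixed once and tested against independent brute-force voxel-enumeration
oracles. The cumulative DVH curve (default bin 0.01 Gy-RBE) is for display
only; every metric is computed from the sorted voxel doses directly.

## The scoring system

Plan quality is summarized by an equally-weighted sum of per-criterion scores,
one per institutional planning goal:

| criterion | goal | type |
|---|---|---|
| CTV-High / Mid / Low V100 | >= 98% | coverage (one shared function) |
| CTV-High Dmax | <= 107% | hot-spot |
| parotid Dmean (each side) | <= 26 Gy-RBE | mean-dose |
| oral cavity Dmean | <= 35 Gy-RBE | mean-dose |
| brainstem / cord D0.03cc | <= 63 / 54 Gy-RBE | serial-organ step |

Each non-serial criterion is a continuous piecewise-linear function of its
metric, capped at 7, non-decreasing for coverage and non-increasing for dose
metrics, with a knot at the clinical-goal abscissa. Unlike the original
plan-competition rubric this variant (i) shifts the coverage and hot-spot
goals to 98%/107%, (ii) awards serial organs the same full score of 7 inside
tolerance (with the original -150 penalty above it, configurable), and
(iii) lets scores run arbitrarily negative beyond the goal so that badly
degraded courses remain comparable.

**Calibration instead of transcription.** The published figure of the scoring
functions is not machine-readable, but the published endpoint and score tables
over-determine the segments. `calibrateScoringFunctions()` therefore fits each
function by least squares on a hinge basis pinned at the goal:

$$\mathrm{score}(x) = \min\!\big(7,\; a + s_\mathrm{good}\,[x - g]_\mp - s_\mathrm{bad}\,[x-g]_\pm\big),$$

where $g$ is the goal, $a$ the fitted score at the goal, and the two slopes
are fitted from all printed (endpoint, score) pairs that are not saturated at
the cap. The cap onset is placed where the fitted good-side segment reaches 7
(clamped to 100 for V100, since full coverage must earn the full score). One
shared coverage function is fitted for all three CTV levels — verified, not
assumed, by per-level residuals. The fitted functions reproduce every usable
printed pair to within about 0.06 score points (the tables print one decimal)
and are frozen as the package defaults, re-derived deterministically from the
packaged tables at first use.

Four table cells conflict with the values quoted in the source's running text
(two saturated parotid/cord cells and two that differ by 0.2-0.3 Gy-RBE);
they are flagged in `calibrationPairs()` and excluded from the fit rather than
resolved.

**Rounding.** Criterion scores are computed unrounded; totals are the sum of
the present (non-missing) criteria, rounded once to 0.1 for reporting. A
missing structure drops its criterion from the sum (it is not scored zero).
Published totals appear to sum the *rounded* criterion cells; the difference
is at most ~0.15 points and the package keeps the unrounded convention.

## Course machinery

Daily evaluation follows the online-APT workflow's decision rule: recompute
the in-use plan's dose on the day's anatomy, extract endpoints, and trigger
adaptation when **any goal fails** *or* the total score falls more than
`dropThreshold` below the nominal plan's total. The source quantifies
"substantially worse" only qualitatively; the default threshold of 3 score
points is a package choice, exposed as a parameter.

Policies:

* **none** — the nominal plan is delivered throughout;
* **offline** — evaluation only at QACT fractions (`qactInterval = 10`,
  i.e. bi-weekly at 5 fractions/week) with the new plan applied `replanLag = 5`
  fractions later ("about a week"), using the standard 3 mm setup margin;
* **online** — evaluation every fraction before delivery; a triggered replan
  applies to the same fraction and uses a 1.5 mm margin, since the daily image
  captures the actual treatment position and only intra-fraction motion and
  spot-position uncertainty remain.

Accumulation is a voxel-wise weighted sum of per-fraction doses already mapped
to the reference frame (`accumulateDose()`), with equal weights for uniform
fractionation. The deformable registration used clinically is out of scope;
interfaces accept pre-mapped grids, and `resampleToFrame()` provides the
rigid-shift trilinear mapping used for setup errors.

## The synthetic course generator

`simulateCourse()` exercises the full pipeline with no clinical data. The
phantom is a set of analytic ellipsoids on a 4 mm grid (44 x 44 x 36 voxels):
nested CTV-High/Mid/Low of about 33/85/250 cm³ — inside the 10-520 cm³ range
of the published cohort — plus parotids, oral cavity, brainstem and cord,
prescribed 70/63/56 Gy-RBE over 35 fractions. The mock plan is an analytic
conformal field: each target level receives its prescription inside the
margin-expanded target with Gaussian lateral falloff (sigma 5 mm) outside, a
2 Gy background floor, and the voxel dose is the maximum over levels. It is a
dose *surrogate*, not a proton transport model: the analysis layer consumes
only dose grids, so the package's claims about protons are limited to what the
scoring reproduces from printed endpoints.

Anatomy drift scales each primitive by the cube root of a per-fraction volume
ratio (defaults emulate the published courses: ~15% target shrinkage over 35
fractions; the largest published case shrank 18.5% over 30) and translates
centroids at ~0.35 mm/fraction. Setup errors are isotropic Gaussian draws
(sigma 1.5 mm, truncated at 5 mm — a conservative default; the source cites
immobilization within 1 mm but reports no cohort statistics). All randomness
is seeded, and all policies replay the *same* anatomy and error stream
(common random numbers), so score differences are attributable to the policy
alone.

Dose accumulation in the simulator uses a per-structure affine correspondence
(centroid translation plus isotropic scale from the volume ratio) in place of
deformable registration; background voxels map rigidly. A plan delivered the
same fraction it was designed on (online adaptation) was designed on the
in-position daily anatomy, so no setup misalignment applies to that fraction;
every other delivery sees the day's full setup error. The mapped field is
discontinuous at structure boundaries where neighboring transforms disagree —
an accepted artifact of the surrogate that does not affect per-structure
endpoints.

**What passing simulations do and do not show.** The generator reproduces the
*mechanisms* (coverage loss from drift beyond the margin, OAR dose growth,
late offline correction) but none of the image-formation, registration or
optimization errors of real adaptive courses; the policy-ordering results
(online >= offline >= none under drift, exact ties on static anatomy) validate
the machinery, not clinical effect sizes.

## Numerical choices and degenerate inputs

* Inclusive comparisons use a 1e-9 dose tolerance.
* `doseAtVolume` clamps volume fractions below one voxel to the maximum dose.
* `doseAtCc` rejects volumes exceeding the structure volume; empty masks and
  shape mismatches are errors, while structures explicitly absent from a
  patient produce missing (NA) endpoint rows that propagate to dropped
  criteria.
* Unicode minus signs and dashes in the packaged transcribed tables are
  normalized to ASCII on read; fixtures keep the printed glyphs.
* Calibration refuses to guess: a function side without non-saturated pairs
  aborts as under-determined rather than extrapolating.

## Problem sizes

The shipped analyses are desk-scale by design: endpoint scoring of the
packaged tables is instantaneous; DVH oracle checks run on 50 seeded ~500-voxel
grids; policy suites run ten 35-fraction courses on the 70k-voxel phantom
(a few seconds each). Test-suite variants use a smaller 26 x 26 x 20 phantom
with 5-8 fraction courses where full length adds nothing.

## Worked example

```{r example, eval = FALSE}
library(aptscore)

# score the packaged ten-patient endpoint tables with the calibrated system
sc <- scoreEndpointTable(endpointTable3())
cmp <- compareCourses(sc)
round(cmp$averages, 1)

# simulate one adaptive course under all three policies
res <- simulateCourse(model = randomDriftModel(7), seed = 7)
sapply(res, function(x) totalScore(x@scorecard))
```

## Known limitations

* No dose calculation, robust optimization, deformable registration, or
  CBCT modelling — upstream steps of the clinical workflow are represented by
  their outputs (dose grids, masks) or by analytic surrogates.
* No DICOM-RT adapter in this R implementation; grids move through NRRD
  (ascii/raw) and tables through CSV.
* The serial-organ function's shape near tolerance cannot be determined from
  printed data; the step form (7 / -150) is used.
* Scores weight all criteria equally; no per-structure weighting, and no
  TCP/NTCP outcome modelling.
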