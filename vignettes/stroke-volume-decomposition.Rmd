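---
title: "Decomposing left-ventricular stroke volume from cine-CMR contours"
author: "svdecomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing left-ventricular stroke volume from cine-CMR contours}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

In a beating left ventricle the stroke volume (SV = EDV − ESV) is generated
by three distinguishable wall motions: the systolic descent of the
atrioventricular (AV) plane toward the apex (longitudinal function), the
inward motion of the free wall, and the motion of the interventricular
septum.  In dyssynchronous ventricles — typically with left bundle branch
block — the septum may move *toward the right ventricle* in systole, so its
contribution is signed and can be negative.  `svdecomp` quantifies the three
contributions from segmented short-axis cine-CMR contours at end diastole
(ED) and end systole (ES), plus the long-axis AV-plane landmarks, and
carries the companion cohort statistics used to relate them to reverse
remodeling after cardiac resynchronization therapy (CRT).

All geometry is processed in physical patient space in millimetres.  Slice
index 0 is the most basal slice; the long axis runs from the centroid of
the six ED AV-plane landmarks to the ED apex reference, and positions along
it increase toward the apex.  Contours are stored counterclockwise as seen
from the apex, which fixes every sign convention downstream; loaders
normalize orientation on read.

## The decomposition

**Global volumetrics.**  Cavity and myocardial volumes are slice summations:
contour area × (slice thickness + gap), over the slices that carry the
relevant contour.  There is no partial-basal-slice weighting — whether the
basal slice belongs to the ventricle at a phase is delegated to which slices
carry contours, as in clinical delineation practice.  LV mass is the ED
myocardial volume times the muscle density 1.05 g/ml.  EF = SV/EDV is kept
as a fraction internally and rendered as percent; cardiac output is
SV × heart rate / 1000 (l/min).

**Longitudinal contribution.**  The AV-plane displacement (AVPD) is the mean
over the six landmarks of the ED→ES displacement projected onto the ED long
axis, positive toward the apex.  Projection (rather than Euclidean
distance) makes the measure insensitive to in-plane landmark slippage.  The
volume swept by the descending AV plane is AVPD times a basal epicardial
area: the mean of the two largest ED epicardial short-axis areas among the
slices whose plane position lies in the closed interval between the mean ED
and mean ES AV-plane positions.  With exactly one slice in that band its
area is used; with none, the most basal delineated slice's area is used and
the result is flagged.

**Radial contributions.**  On every eligible slice the ED and ES epicardial
contours are split at the right-ventricular insertion points into a septal
arc and a free-wall arc.  Insertion points are snapped to the nearest
delineated vertex — no vertex is inserted, so arcs remain subsets of the
delineated points and the snapping error is below one vertex spacing.  The
septal arc is the shorter of the two arcs (the septum spans well under half
the circumference in anatomy and in all phantoms here); a per-slice
`septal_hint` point can override this for pathological shapes, and exactly
antipodal insertions require an explicit RV-side tie-break point.  The
region enclosed by the ED arc, the straight connectors between
corresponding insertion points, and the reversed ES arc has a signed
shoelace area: with the counterclockwise-from-apex orientation it is
positive exactly when the ES arc lies displaced toward the ED epicardial
centroid (motion toward the LV) and negative toward the RV.  When the two
arcs genuinely cross (e.g. a septal bulge partially offset by inward
motion) the region is non-simple; the signed-area sum then performs the
physically correct partial cancellation and the slice is flagged.

Eligible slices are those with epicardial contours and insertion points at
both phases that lie *apical* to the ES AV-plane position.  This rule
prevents double counting: the band between the ED and ES AV-plane positions
is exactly the volume already attributed to the longitudinal term.  Summing
the signed areas times the slice spacing gives SV_sept and SV_lat in ml.

**Assembly.**  Percentages are taken against the slice-summation SV (not
against the sum of the components), and the shortfall
`100 − (SV_long% + SV_lat% + SV_sept%)` is reported as a residual, never
redistributed.  The method is not exactly conservative — basal-area
averaging and slice discretization each contribute a few percent — which is
why the residual is part of the result.  `sv_decompose()` returns a classed
fit with `print`, `summary`, `coef` (the three percentages), `residuals`
(the residual percentage) and `plot` methods.

```{r}
library(svdecomp)
ph <- generate_phantom(phantom_spec(avpd_mm = 12, lateral_mm = 3, septal_mm = -2))
fit <- sv_decompose(ph$stack)
fit
coef(fit)
```

## The phantom generator and its ground truth

Because no segmented patient data are distributed, every stage is
exercised on analytic deforming-ventricle phantoms.  The ED geometry is a
cylinder or a truncated half-ellipsoid (epicardial base radius 30 mm,
long-axis length 90 mm, wall 8 mm by default — a dilated-ventricle scale).
ES geometry applies three independent motions:

* the AV plane (landmarks and basal band) moves apically by `avpd_mm`;
  slices whose centers are basal to the ES AV plane lose their ES contours,
  emulating the vacated basal band that delineators leave out at ES;
* the free-wall epicardial arc moves radially inward by `lateral_mm` and
  the septal arc by the signed `septal_mm` (positive toward the LV), with a
  10° smoothstep transition at the insertion angles so contours stay
  simple; displacements are specified at the base radius and scale with the
  local radius, which keeps the tapering ellipsoid valid near the apex;
* the cylinder's ES endocardium is scaled so that myocardial volume is
  identical at both phases.  Wall-volume conservation is what makes the
  bookkeeping exact: with it, the analytic longitudinal + lateral + septal
  swept volumes equal EDV − ESV exactly, so the truth consistency of the
  generator is itself testable.  The ellipsoid applies the same relative
  inward scaling to the endocardium without a global conservation
  constraint; its truth is computed by midpoint quadrature at 100× the
  slice resolution (the angular displacement profile is integrated
  numerically in both cases).

Delineation noise is emulated as radial (border-placement) jitter in the
slice plane, truncated at 3σ: radial jitter preserves the angular order of
vertices, so a star-shaped contour provably remains a simple polygon at any
stated σ, whereas isotropic jitter at 0.5 mm already crosses adjacent edges
on the small ES endocardium.  Landmark jitter is 3-D.  What the phantoms do
*not* emulate: through-plane motion within a slice, wall thickening
heterogeneity, trabeculation, breath-hold misregistration between slices,
and observer-dependent basal-slice choices.  Passing the recovery tests
therefore validates the geometry engine and its conventions, not the
clinical accuracy of delineation.

Default problem sizes — 30 slices of 3 mm, 96 vertices per contour, and a
75-phantom recovery grid (AVPD 4–16 mm, septal −4…+4 mm, lateral 0–6 mm) —
keep each contribution within 5% (or 1 ml) of its analytic truth; the
dominant residual error is the half-slice quantization of where the ES
ventricle begins.

## The synthetic cohort

The outcome statistics operate on a 65-patient cohort (37 responders / 28
non-responders, CRT response = LVESV reduction ≥ 15% at follow-up, boundary
inclusive).  In exact-count mode the generator reproduces the published
2×2 margins exactly — ischemic etiology 14/18, LBBB 34/22, QRS ≥ 150 ms
34/23, male sex 27/19, LGE 23/17, mechanical dyssynchrony 15/12 with two
non-assessable patients, negative septal contribution 16/12 — while the
assignment of covariates to patients within a response class is a seeded
permutation, so joint structure is randomized but every margin is exact.
Continuous measures are drawn per response class (AVPD 8.0 ± 3.1 vs
8.8 ± 3.2 mm, SV_long% 53 ± 18 vs 53 ± 19, SV_lat% 38 ± 15 vs 45 ± 16); the
septal percentage is drawn with the sign dictated by the negative-septal
flag, and the follow-up LVESV is constructed from the baseline and a
per-class relative change that respects the −15% boundary strictly.  These
marginal draws emulate the *count and moment structure* of a CRT cohort;
they carry no within-patient correlation between the regional measures, so
only the count-derived statistics are exactly reproducible.

Statistics follow the conventions that reproduce the printed values:
Woolf (Wald) confidence intervals on ln OR with the normal 1.96 quantile;
the Haldane–Anscombe 0.5 correction for zero cells (flagged); Pearson
chi-squared without continuity correction, with Fisher's exact test when
any expected cell is below 5; classic equal-variance Student t-tests;
univariable logistic screening with the p < 0.25 entry rule and p < 0.05
retention, fitted by IRLS with a 1e-12 relative convergence tolerance and
separation reported as a non-finite OR; `SV_sept% = 0` classified with the
positive (non-dyssynchronous) side.  The unequal-allocation two-sample
t-test sample size iterates the noncentral-t power equation for the
smallest adequate experimental-group n (control group = ratio × n).  With
δ = 7, σ = 16, allocation 28/37, α = 0.05 and power 0.8 the iteration gives
n = 97 — the printed inputs of the original power computation cannot be
reconstructed uniquely, so agreement with the published n = 96 for the
lateral contribution is treated as a tolerance check, not an exact target.

## Design decisions that were genuinely open

* *Slice band "encompassed by the AVPD motion"*: taken as the closed
  interval between the mean ED and ES AV-plane positions, with the 1-slice
  and 0-slice fallbacks described above; no selection formula is published.
* *Basal areas from ED epicardial contours*, not from intermediate frames:
  the ED short-axis area is the stated measurand and only ED/ES are
  segmented here (the analysis is deliberately not time-resolved).
* *Apical truncation of the radial slice set at the ES AV-plane position*:
  prevents double counting against the longitudinal term; using the ED
  position instead would re-count the vacated band.
* *Snapping insertion points to the nearest vertex* rather than inserting
  vertices: arcs remain subsets of delineated points; the error is below
  the vertex spacing and far below delineation noise.
* *Planarity tolerance 0.5 mm* (sub-voxel) for contours against their slice
  plane; the best-fit plane falls back to a least-squares normal for
  degenerate polygons.
* *Percentages against the slice-summation SV* with an explicit residual:
  redistributing the residual would hide discretization error inside the
  contributions.

## Known limitations

Only ED and ES are analyzed, so septal motion occurring strictly between
the two phases (e.g. post-systolic shortening) is invisible, exactly as in
the underlying measurement.  The slice-summation volumetry carries the
usual half-slice basal ambiguity.  The cohort generator cannot reproduce
patient-level means and SDs of quantities whose raw data were never
published — it emulates their distributional shape for pipeline testing.
The dyssynchrony-flag odds ratio is not exactly derivable from the
published counts because of the two non-assessable patients; the generator
carries the missingness so the dropped-record accounting is exercised, but
no exact target is claimed for that ratio.

## Reproducing the headline numbers

`scripts/acceptance.R --seed 1 --out results/acceptance.json` regenerates
the exact-count cohort and the phantom grid and recomputes every quantity
reported in the README from scratch; the test suite
(`testthat::test_dir("tests/testthat")`) asserts the same properties with
fixed tolerances.
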