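# svdecomp

Regional contributions to left-ventricular stroke volume from segmented
cine-CMR contours.

In heart failure with electrical dyssynchrony — the population selected for
cardiac resynchronization therapy (CRT) — the stroke volume is generated by
an abnormal mix of wall motions: the systolic descent of the
atrioventricular (AV) plane is reduced, the septum may move paradoxically
toward the right ventricle, and the lateral free wall compensates.
`svdecomp` quantifies this from short-axis epicardial/endocardial contours
at end diastole (ED) and end systole (ES) plus six long-axis AV-plane
landmarks, for imaging scientists and cardiology researchers working with
segmented cine-CMR geometry.

The decomposition, with SV = EDV − ESV from slice summation:

* **Longitudinal** — SV_long = AVPD × A_basal, where AVPD is the mean ED→ES
  displacement of the six AV-plane landmarks projected on the long axis and
  A_basal is the mean of the two largest ED epicardial short-axis areas
  inside the band swept by the AV plane; SV_long% = 100 · SV_long / SV.
* **Septal / lateral** — on each slice apical to the ES AV-plane position,
  the epicardial contours are split at the RV insertion points; the signed
  area enclosed between the ED and ES septal (resp. free-wall) arcs,
  positive toward the LV centroid, is summed × slice spacing.  SV_sept% is
  negative when the septum moves net toward the RV — a sign of
  dyssynchrony.
* **Residual** — 100 − (SV_long% + SV_lat% + SV_sept%), reported, never
  redistributed.

The package also ships slice-summation volumetrics (EDV, ESV, EF, LV mass
at 1.05 g/ml, cardiac output), analytic deforming-ventricle phantoms with
closed-form ground truth, a synthetic CRT cohort generator with exact-count
contingency layout, and the outcome statistics used around this
measurement: responder classification (LVESV reduction ≥ 15%), odds ratios
with Woolf 95% CIs, chi-squared/Fisher and Student-t group comparisons,
univariable→multivariable logistic screening (entry p < 0.25, retention
p < 0.05), and noncentral-t sample sizes at unequal allocation.

## Worked example

A dyssynchrony-like phantom: AV plane descends 12 mm, free wall moves 3 mm
inward, septum bulges 2 mm toward the RV:

```r
library(svdecomp)
ph  <- generate_phantom(phantom_spec(avpd_mm = 12, lateral_mm = 3, septal_mm = -2))
fit <- sv_decompose(ph$stack)
fit
#> Stroke-volume decomposition — subject phantom-cylinder-seed1
#>   EDV 136.8 ml  ESV 85.0 ml  SV 51.8 ml  EF 37.9%
#>   AVPD 12.0 mm  basal SA area 28.3 cm^2
#>   longitudinal     33.9 ml    65.5%
#>   lateral          27.5 ml    53.1%
#>   septal           -9.6 ml   -18.6%
#>   residual                   0.0%
#>   flags: septal swept region self-intersects (signed-area sum used) [26 slice(s)]
```

The AV-plane descent accounts for 33.9 ml (65.5% of SV), the free wall for
27.5 ml, and the RV-ward septal bulge *subtracts* 9.6 ml (−18.6%) — the
signed septal contribution that distinguishes dyssynchronous ventricles.
The flag records that the septal ED/ES arcs cross (bulge against inward
smoothing transition), so the enclosed area was evaluated as a signed sum.
The phantom's analytic truth (`ph$truth`) puts the three swept volumes at
33.9, 27.6 and −9.7 ml.  `coef(fit)` returns the three percentages,
`residuals(fit)` the residual, `plot(fit)` a contribution bar chart.

Cohort statistics on the exact-count synthetic cohort:

```r
co <- generate_cohort(cohort_spec(seed = 1))
odds_ratio(build_table2x2(co, ~ischemic))
#> OR 0.34 (95% CI 0.12-0.94)
sample_size_t(7, 16, ratio = 28/37)
#> Two-sample t-test sample size: n = 97 (experimental), control = 73.4 (ratio 0.757)
#>   delta 7, sd 16, alpha 0.05, power 0.800 (achieved 0.803)
```

A command-line wrapper (`inst/scripts/svdecomp`) exposes
`phantom generate`, `regional compute`, `cohort simulate`,
`cohort analyze` and `stats power`.

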