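Package: svdecomp
Title: Regional Contributions to Left Ventricular Stroke Volume from Cine CMR Contours
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes the left-ventricular stroke volume measured by
    short-axis cine cardiac magnetic resonance into longitudinal
    (atrioventricular-plane-displacement driven), lateral free-wall and
    signed septal contributions, from segmented epicardial and endocardial
    contours at end diastole and end systole.  Provides slice-summation
    volumetrics (EDV, ESV, SV, EF, LV mass, cardiac output), an analytic
    deforming-ventricle phantom generator with closed-form ground truth, a
    synthetic CRT cohort generator with exact-count contingency layout, and
    the accompanying outcome statistics: responder classification by
    end-systolic volume reduction, 2x2 odds ratios with Woolf confidence
    intervals, group comparisons, univariable/multivariable logistic
    screening, and noncentral-t sample-size computation at unequal
    allocation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
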