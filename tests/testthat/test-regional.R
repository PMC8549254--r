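# Regional stroke-volume decomposition: AVPD, basal area selection, and the
# longitudinal / lateral / septal contributions.

test_that("AVPD is the mean landmark displacement projected on the long axis", {
  st <- toy_stack(rep(20, 6), avpd = 15.3)
  av <- compute_avpd(st)
  expect_equal(av$mean_mm, 15.3, tolerance = 1e-9)
  expect_equal(unname(av$per_landmark_mm), rep(15.3, 6), tolerance = 1e-9)

  # zero motion
  expect_equal(compute_avpd(toy_stack(rep(20, 6), avpd = 0))$mean_mm, 0,
               tolerance = 1e-12)

  # purely in-plane landmark motion projects to zero
  ed <- ring_landmarks(28, 0)
  es <- lapply(ed, function(p) p + c(3, -2, 0))
  lms <- landmark_set(ed, es, apex = c(0, 0, -100))
  st2 <- toy_stack(rep(20, 6))
  st2$landmarks <- lms
  expect_equal(compute_avpd(st2)$mean_mm, 0, tolerance = 1e-9)

  # missing landmark named in the error
  lm_bad <- st$landmarks
  lm_bad$ES$anteroseptal <- NULL
  st$landmarks <- lm_bad
  expect_error(compute_avpd(st), "anteroseptal")
})

test_that("basal epicardial area averages the two largest in-band ED areas", {
  mk <- function(areas_cm2, avpd) {
    toy_stack(rep(15, length(areas_cm2)), epi_ed_radii = radius_for_cm2(areas_cm2),
              spacing = 10, avpd = avpd, n = 1024)
  }
  # slice centers at 5, 15, 25, ... mm below the base
  a <- basal_epicardial_area(mk(c(50, 52, 48, 45), avpd = 25))   # band holds slices 1-2
  expect_equal(as.numeric(a), 51, tolerance = 1e-3)
  expect_false(attr(a, "fallback"))

  a2 <- basal_epicardial_area(mk(c(34, 40, 45), avpd = 12))      # only slice 1 in band
  expect_equal(as.numeric(a2), 34, tolerance = 1e-3)

  a3 <- basal_epicardial_area(mk(c(30, 40, 50, 45), avpd = 30))  # slices 1-3: two largest 40, 50
  expect_equal(as.numeric(a3), 45, tolerance = 1e-3)

  a4 <- basal_epicardial_area(mk(c(36, 40, 45), avpd = 2))       # empty band: basal fallback
  expect_equal(as.numeric(a4), 36, tolerance = 1e-3)
  expect_true(attr(a4, "fallback"))
})

test_that("longitudinal contribution is AVPD times basal area", {
  st <- toy_stack(rep(15, 5), epi_ed_radii = rep(radius_for_cm2(50), 5),
                  spacing = 10, avpd = 25, n = 1024)
  lo <- sv_longitudinal(st, sv_ml = 100)
  expect_equal(lo$ml, 25 * 50 / 10, tolerance = 0.01)  # mm x cm^2 / 10 = ml
  expect_equal(lo$pct, 100 * lo$ml / 100, tolerance = 0.01)

  lo0 <- sv_longitudinal(toy_stack(rep(15, 5), avpd = 0), sv_ml = 50)
  expect_equal(lo0$ml, 0, tolerance = 1e-9)
  expect_equal(lo0$pct, 0, tolerance = 1e-9)

  # SV <= 0: percentage undefined, ml still returned
  lo_na <- sv_longitudinal(st, sv_ml = 0)
  expect_true(is.na(lo_na$pct))
  expect_gt(lo_na$ml, 0)
})

# one ED/ES slice pair with a stepwise-deformed ES epicardium
radial_pair <- function(r = 30, sept_in = 0, lat_in = 0, span_deg = 120, n = 720) {
  th <- -(seq_len(n) - 1) / n * 2 * pi
  half <- span_deg * pi / 360
  fold <- abs(((th + pi) %% (2 * pi)) - pi)
  disp <- ifelse(fold <= half, sept_in, lat_in)
  at <- function(deg, rr) c(rr * cos(deg * pi / 180), rr * sin(deg * pi / 180), 0)
  mkslice <- function(red, res) {
    epi <- list(ED = planar_contour(cbind(red * cos(th), red * sin(th), 0),
                                    validate = FALSE),
                ES = planar_contour(cbind(res * cos(th), res * sin(th), 0),
                                    "epicardial", "ES", validate = FALSE))
    lv_slice(0L, c(0, 0, 0), c(0, 0, -1), epicardial = epi,
             insertions = list(ED = list(anterior = at(60, r), inferior = at(-60, r)),
                               ES = list(anterior = at(60, r - (sept_in + lat_in) / 2),
                                         inferior = at(-60, r - (sept_in + lat_in) / 2))))
  }
  mkslice(rep(r, n), r - disp)
}

test_that("radial swept areas carry the LV-ward positive sign convention", {
  axis <- list(direction = c(0, 0, -1), base = c(0, 0, 0))
  # septal arc 2 mm toward the LV centroid, free wall unchanged
  s <- radial_pair(sept_in = 2)
  r <- radial_slice_areas(s, s, axis)
  expect_gt(r$septal_mm2, 0)
  # free wall unchanged up to insertion-snapping resolution (< one vertex sliver)
  expect_lt(abs(r$lateral_mm2), 1.5)

  # septal arc toward the RV: negative septal area
  s2 <- radial_pair(sept_in = -2)
  r2 <- radial_slice_areas(s2, s2, axis)
  expect_lt(r2$septal_mm2, 0)

  # concentric 1 mm inward displacement of a circle r = 30:
  # total signed area 2 pi r - pi, split in proportion to arc angle
  s3 <- radial_pair(sept_in = 1, lat_in = 1)
  r3 <- radial_slice_areas(s3, s3, axis)
  total <- 2 * pi * 30 * 1 - pi * 1^2
  expect_rel_equal(r3$septal_mm2 + r3$lateral_mm2, total, 1e-3)
  expect_rel_equal(r3$septal_mm2, total * 120 / 360, 2e-2)
  expect_rel_equal(r3$lateral_mm2, total * 240 / 360, 2e-2)
})

test_that("decompose recovers phantom motion patterns", {
  control <- sv_decompose(generate_phantom(
    phantom_spec(avpd_mm = 15, lateral_mm = 2, septal_mm = 1.5))$stack)
  s <- control$sv_long_pct + control$sv_lat_pct + control$sv_sept_pct
  expect_gt(s, 90); expect_lt(s, 110)
  expect_equal(control$residual_pct, 100 - s, tolerance = 1e-9)

  patient <- sv_decompose(generate_phantom(
    phantom_spec(avpd_mm = 9, lateral_mm = 4, septal_mm = -2))$stack)
  expect_lt(patient$sv_sept_pct, 0)
  expect_gt(patient$sv_lat_pct, control$sv_lat_pct)

  # percentage fields are 100 * ml / SV
  expect_equal(patient$sv_lat_pct,
               100 * patient$sv_lat_ml / patient$volumetrics$sv_ml,
               tolerance = 1e-9)

  rigid <- sv_decompose(generate_phantom(phantom_spec(avpd_mm = 0))$stack)
  expect_equal(rigid$volumetrics$sv_ml, 0, tolerance = 1e-6)
  expect_equal(rigid$sv_long_ml, 0, tolerance = 1e-6)
  expect_equal(rigid$sv_lat_ml, 0, tolerance = 1e-6)
  expect_true(is.na(rigid$sv_long_pct))
  expect_match(rigid$flags, "SV <= 0", all = FALSE)
})

test_that("a pure-longitudinal cylinder yields SV_long% of 100 within 2", {
  ph <- generate_phantom(phantom_spec(avpd_mm = 12, lateral_mm = 0, septal_mm = 0))
  dec <- sv_decompose(ph$stack)
  expect_lt(abs(dec$sv_long_pct - 100), 2)
  expect_lt(abs(dec$sv_lat_pct), 2)
  expect_lt(abs(dec$sv_sept_pct), 2)
})

test_that("septal antisymmetry and longitudinal linearity hold on phantoms", {
  plus <- sv_decompose(generate_phantom(phantom_spec(avpd_mm = 9, septal_mm = 3))$stack)
  minus <- sv_decompose(generate_phantom(phantom_spec(avpd_mm = 9, septal_mm = -3))$stack)
  expect_gt(plus$sv_sept_ml, 0)
  expect_lt(minus$sv_sept_ml, 0)
  # magnitudes agree to the quadratic annulus term O(p/R)
  expect_equal(plus$sv_sept_ml, -minus$sv_sept_ml, tolerance = 0.12)

  d6 <- sv_decompose(generate_phantom(phantom_spec(avpd_mm = 6))$stack)
  d12 <- sv_decompose(generate_phantom(phantom_spec(avpd_mm = 12))$stack)
  expect_equal(d12$sv_long_ml / d6$sv_long_ml, 2, tolerance = 1e-3)
})

test_that("contributions in ml track analytic truth over a phantom grid", {
  grid <- expand.grid(avpd = c(4, 10, 16), sept = c(-4, 0, 4), lat = c(0, 6))
  for (i in seq_len(nrow(grid))) {
    ph <- generate_phantom(phantom_spec(avpd_mm = grid$avpd[i],
                                        septal_mm = grid$sept[i],
                                        lateral_mm = grid$lat[i],
                                        seed = i))
    dec <- sv_decompose(ph$stack)
    chk <- function(got, want) expect_lt(abs(got - want),
                                         max(0.05 * abs(want), 1))
    chk(dec$sv_long_ml, ph$truth$long_ml)
    chk(dec$sv_lat_ml, ph$truth$lateral_ml)
    chk(dec$sv_sept_ml, ph$truth$septal_ml)
  }
})

test_that("model-object methods expose the fit", {
  dec <- sv_decompose(generate_phantom(phantom_spec(avpd_mm = 12, lateral_mm = 3,
                                                    septal_mm = 1))$stack)
  cf <- coef(dec)
  expect_named(cf, c("sv_long_pct", "sv_lat_pct", "sv_sept_pct"))
  expect_equal(unname(residuals(dec)), 100 - sum(cf), tolerance = 1e-9)
  sm <- summary(dec)
  expect_s3_class(sm, "data.frame")
  expect_equal(sm$sv_ml, dec$volumetrics$sv_ml)
  expect_output(print(dec), "longitudinal")
})
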