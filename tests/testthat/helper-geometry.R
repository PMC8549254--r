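# Shared fixture builders: all geometry is generated in code at test time.

# Closed circular contour of radius r in the z = z0 plane, counterclockwise
# as seen from an apex on the negative z side (i.e. clockwise about +z).
circle_contour <- function(r, z0 = 0, n = 96, surface = "epicardial",
                           phase = "ED", center = c(0, 0)) {
  th <- -(seq_len(n) - 1) / n * 2 * pi
  planar_contour(cbind(center[1] + r * cos(th), center[2] + r * sin(th), z0),
                 surface, phase, validate = FALSE)
}

# Six AV-plane landmarks on a circle of radius r at z = z0.
ring_landmarks <- function(r = 30, z0 = 0) {
  ang <- c(0, 180, 60, 240, 120, 300) * pi / 180
  stats::setNames(lapply(ang, function(a) c(r * cos(a), r * sin(a), z0)),
                  svdecomp:::LANDMARK_LABELS)
}

# Minimal stack: one endocardial circle per slice at each phase, landmarks
# translating by `avpd` along -z, apex at -length_mm.
toy_stack <- function(endo_ed_radii, endo_es_radii = endo_ed_radii,
                      epi_ed_radii = endo_ed_radii + 8,
                      spacing = 10, avpd = 0, length_mm = 100,
                      heart_rate = NULL, n = 64) {
  slices <- lapply(seq_along(endo_ed_radii), function(i) {
    z <- -(i - 0.5) * spacing
    endo <- list(ED = circle_contour(endo_ed_radii[i], z, n, "endocardial", "ED"))
    if (!is.na(endo_es_radii[i]))
      endo$ES <- circle_contour(endo_es_radii[i], z, n, "endocardial", "ES")
    lv_slice(index = i - 1L, origin = c(0, 0, z), normal = c(0, 0, -1),
             epicardial = list(ED = circle_contour(epi_ed_radii[i], z, n)),
             endocardial = endo)
  })
  lms <- landmark_set(ring_landmarks(max(epi_ed_radii), 0),
                      lapply(ring_landmarks(max(epi_ed_radii), 0), function(p) p - c(0, 0, avpd)),
                      apex = c(0, 0, -length_mm))
  contour_stack("toy", slices, slice_thickness_mm = spacing, slice_gap_mm = 0,
                landmarks = lms, heart_rate_bpm = heart_rate)
}

# Radius (mm) giving a circle of the requested area in cm^2.
radius_for_cm2 <- function(a_cm2) sqrt(a_cm2 * 100 / pi)

expect_rel_equal <- function(object, expected, rel_tol) {
  expect_true(abs(object - expected) <= rel_tol * abs(expected),
              label = sprintf("%.6g within %.3g%% of %.6g", object,
                              100 * rel_tol, expected))
}
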