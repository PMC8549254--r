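# Analytic deforming-ventricle phantoms.
#
# ED geometry: a cylinder or truncated half-ellipsoid of epicardial radius R
# and long-axis length L (base plane at axial position s = 0, apex at
# s = L), wall thickness w.  ES geometry is obtained by (i) moving the AV
# plane — landmarks and the basal band — apically by AVPD, so slices whose
# centers lie basal to the ES AV plane lose their ES contours (the vacated
# band), (ii) displacing the free-wall epicardial arc radially inward by the
# lateral displacement and the septal arc by the signed septal displacement
# (positive toward the LV), with a 10 degree smoothed transition at the
# insertion angles.  Displacements are specified at the base radius and
# scale with the local radius (so the taper toward the apex of an ellipsoid
# keeps contours valid); for the cylinder this reduces to a plain offset.
#
# The cylinder phantom conserves wall volume between phases: the ES
# endocardium is scaled so the myocardial volume is phase-invariant, which
# makes the analytic longitudinal + lateral + septal swept volumes equal
# EDV - ESV exactly.  The ellipsoid applies the same relative inward
# scaling to the endocardium (no exact conservation); its ground truth is
# computed by midpoint quadrature at 100x the slice resolution.

SEPTAL_SMOOTH_DEG <- 10

#' Specify a synthetic deforming-ventricle phantom
#'
#' @param shape `"cylinder"` or `"half_ellipsoid"`.
#' @param base_radius_mm epicardial radius at the base (mm).
#' @param length_mm long-axis length base-to-apex (mm).
#' @param wall_mm wall thickness (mm), `0 < wall < radius`.
#' @param n_slices number of short-axis slices (>= 4); slice spacing is
#'   `length_mm / n_slices` with zero gap.
#' @param n_vertices vertices per contour (>= 36).
#' @param avpd_mm true atrioventricular plane displacement (mm, apexward).
#' @param lateral_mm inward displacement of the free-wall epicardial arc at
#'   the base radius (mm).
#' @param septal_mm signed displacement of the septal arc (mm, positive
#'   toward the LV, negative toward the RV).
#' @param septal_span_deg angular span of the septum, in (0, 180).
#' @param landmark_jitter_mm standard deviation of 3-D landmark jitter
#'   (truncated at 3 sigma).
#' @param contour_noise_mm standard deviation of in-plane contour vertex
#'   jitter (truncated at 3 sigma), applied after deformation.
#' @param seed integer seed; generation is deterministic given identical
#'   parameters and seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c("cylinder", "half_ellipsoid"),
                         base_radius_mm = 30, length_mm = 90, wall_mm = 8,
                         n_slices = 30, n_vertices = 96,
                         avpd_mm = 10, lateral_mm = 0, septal_mm = 0,
                         septal_span_deg = 120,
                         landmark_jitter_mm = 0, contour_noise_mm = 0,
                         seed = 1L) {
  shape <- match.arg(shape)
  if (!(base_radius_mm > wall_mm && wall_mm > 0))
    stop("phantom spec requires radius > wall thickness > 0")
  if (n_slices < 4L) stop("phantom spec requires at least 4 slices")
  if (n_vertices < 36L) stop("phantom spec requires at least 36 vertices per contour")
  if (!(septal_span_deg > 0 && septal_span_deg < 180))
    stop("septal span must lie in (0, 180) degrees")
  if (avpd_mm < 0) stop("AVPD must be non-negative")
  if (avpd_mm >= length_mm) stop("AVPD must be smaller than the long-axis length")
  if (max(abs(septal_mm), abs(lateral_mm)) >= 0.8 * base_radius_mm)
    stop("radial displacement too large: contours would collapse")
  structure(list(shape = shape, base_radius_mm = base_radius_mm,
                 length_mm = length_mm, wall_mm = wall_mm,
                 n_slices = as.integer(n_slices), n_vertices = as.integer(n_vertices),
                 avpd_mm = avpd_mm, lateral_mm = lateral_mm, septal_mm = septal_mm,
                 septal_span_deg = septal_span_deg,
                 landmark_jitter_mm = landmark_jitter_mm,
                 contour_noise_mm = contour_noise_mm,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Evaluate an expression with a private, restored RNG state.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env)
  on.exit(if (had) assign(".Random.seed", old, envir = env)
          else if (exists(".Random.seed", envir = env, inherits = FALSE))
            rm(".Random.seed", envir = env))
  set.seed(seed)
  expr
}

rnorm_trunc3 <- function(n, sd) {
  if (sd <= 0) return(rep(0, n))
  pmin(pmax(stats::rnorm(n, 0, sd), -3 * sd), 3 * sd)
}

# Inward displacement (mm, at base radius) as a function of contour angle.
# Septum centered at theta = 0 with half-span phi2; smoothstep transition of
# total width SEPTAL_SMOOTH_DEG centered on each insertion angle.
radial_profile <- function(theta, septal_mm, lateral_mm, septal_span_deg) {
  phi2 <- septal_span_deg * pi / 360
  w <- SEPTAL_SMOOTH_DEG * pi / 360          # half-width of the transition
  a <- abs(((theta + pi) %% (2 * pi)) - pi)  # |angle| folded to [0, pi]
  t <- pmin(pmax((a - (phi2 - w)) / (2 * w), 0), 1)
  h <- t * t * (3 - 2 * t)
  septal_mm + (lateral_mm - septal_mm) * h
}

# Integrals over the septal / free-wall angular regions of
# q(theta) = 2 u - u^2 with u = delta(theta) / R; fine midpoint rule.
profile_integrals <- function(spec, n_grid = 20000L) {
  th <- (seq_len(n_grid) - 0.5) / n_grid * 2 * pi - pi
  dth <- 2 * pi / n_grid
  u <- radial_profile(th, spec$septal_mm, spec$lateral_mm, spec$septal_span_deg) /
    spec$base_radius_mm
  q <- 2 * u - u^2
  phi2 <- spec$septal_span_deg * pi / 360
  sept <- abs(th) <= phi2
  list(I_sept = sum(q[sept]) * dth, I_lat = sum(q[!sept]) * dth)
}

# Epicardial / endocardial ED radius at axial position s (mm from base).
epi_radius <- function(spec, s) {
  if (spec$shape == "cylinder") rep(spec$base_radius_mm, length(s))
  else spec$base_radius_mm * sqrt(pmax(1 - (s / spec$length_mm)^2, 0))
}

endo_radius <- function(spec, s) {
  r <- spec$base_radius_mm - spec$wall_mm
  if (spec$shape == "cylinder") rep(r, length(s))
  else {
    le <- spec$length_mm - spec$wall_mm
    ifelse(s < le, r * sqrt(pmax(1 - (s / le)^2, 0)), NA_real_)
  }
}

#' Generate a deforming-ventricle phantom with analytic ground truth
#'
#' @param spec a [phantom_spec].
#' @return An object of class `lv_phantom`: list with `stack` (a
#'   [contour_stack]), `truth` (analytic EDV, ESV, SV and longitudinal /
#'   lateral / septal swept volumes, ml) and the `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, build_phantom(spec))
}

build_phantom <- function(spec) {
  R <- spec$base_radius_mm; L <- spec$length_mm; w <- spec$wall_mm
  n <- spec$n_slices; nv <- spec$n_vertices; a <- spec$avpd_mm
  dz <- L / n
  centers <- (seq_len(n) - 0.5) * dz
  # clockwise about +z = counterclockwise seen from the apex at z = -L
  theta <- -(seq_len(nv) - 1) / nv * 2 * pi
  phi2 <- spec$septal_span_deg * pi / 360
  delta <- radial_profile(theta, spec$septal_mm, spec$lateral_mm, spec$septal_span_deg)
  if (any(1 - delta / R <= 0.05))
    stop("radial displacement produces non-simple (collapsed) contours")

  ring <- function(radii, z) cbind(radii * cos(theta), radii * sin(theta), rep(z, nv))
  # delineation noise: radial (border-placement) jitter in the slice plane,
  # truncated at 3 sigma — keeps every star-shaped contour a simple polygon
  noisy <- function(V) {
    if (spec$contour_noise_mm <= 0) return(V)
    ctr <- colMeans(V)
    d <- cbind(V[, 1] - ctr[1], V[, 2] - ctr[2])
    len <- sqrt(rowSums(d^2))
    eps <- rnorm_trunc3(nrow(V), spec$contour_noise_mm) / pmax(len, 1e-9)
    V[, 1] <- V[, 1] + d[, 1] * eps
    V[, 2] <- V[, 2] + d[, 2] * eps
    V
  }
  mk <- function(V, surface, phase)
    planar_contour(noisy(V), surface, phase, validate = spec$contour_noise_mm > 0)

  vacated <- centers <= a + 1e-9
  k <- sum(vacated)
  if (k >= n) stop("AVPD vacates the whole stack: no ES slices remain")

  # cylinder wall conservation: ES endocardial area chosen so that the
  # discrete myocardial volume is identical at both phases
  epi_ed_area <- polygon_area(ring(rep(R, nv), 0))
  endo_ed_area <- polygon_area(ring(rep(R - w, nv), 0))
  epi_es_area <- polygon_area(ring(epi_radius(spec, 1)[1] * (1 - delta / R), 0))
  if (spec$shape == "cylinder") {
    endo_es_area <- epi_es_area - n * (epi_ed_area - endo_ed_area) / (n - k)
    if (endo_es_area <= 0)
      stop("wall-volume conservation leaves no ES cavity: reduce AVPD or displacements")
    endo_scale <- sqrt(endo_es_area / epi_es_area)
  }

  ins_angles <- c(anterior = phi2, inferior = -phi2)
  slices <- vector("list", n)
  for (i in seq_len(n)) {
    s <- centers[i]; z <- -s
    Re <- epi_radius(spec, s)[1]
    Ri <- endo_radius(spec, s)[1]
    epi <- list(ED = mk(ring(rep(Re, nv), z), "epicardial", "ED"))
    endo <- list()
    if (!is.na(Ri) && Ri > 0.5)
      endo$ED <- mk(ring(rep(Ri, nv), z), "endocardial", "ED")
    ins <- list(ED = list(anterior = c(Re * cos(ins_angles[1]), Re * sin(ins_angles[1]), z),
                          inferior = c(Re * cos(ins_angles[2]), Re * sin(ins_angles[2]), z)))
    if (!vacated[i]) {
      re_es <- Re * (1 - delta / R)
      epi$ES <- mk(ring(re_es, z), "epicardial", "ES")
      if (spec$shape == "cylinder") {
        Ves <- ring(re_es, z)
        ctr <- colMeans(Ves)
        Ves <- sweep(Ves, 2, ctr) * endo_scale
        Ves <- sweep(Ves, 2, ctr, "+")
        Ves[, 3] <- z
        endo$ES <- mk(Ves, "endocardial", "ES")
      } else if (!is.na(Ri) && Ri > 0.5) {
        endo$ES <- mk(ring(Ri * (1 - delta / R), z), "endocardial", "ES")
      }
      dmid <- radial_profile(ins_angles, spec$septal_mm, spec$lateral_mm,
                             spec$septal_span_deg)
      re_ins <- Re * (1 - dmid / R)
      ins$ES <- list(anterior = c(re_ins[1] * cos(ins_angles[1]),
                                  re_ins[1] * sin(ins_angles[1]), z),
                     inferior = c(re_ins[2] * cos(ins_angles[2]),
                                  re_ins[2] * sin(ins_angles[2]), z))
    }
    slices[[i]] <- lv_slice(index = i - 1L, origin = c(0, 0, z), normal = c(0, 0, -1),
                            epicardial = epi, endocardial = endo, insertions = ins)
  }

  lm_angles <- c(0, 180, 60, 240, 120, 300) * pi / 180
  jit <- function(p) p + rnorm_trunc3(3, spec$landmark_jitter_mm)
  Ra_es <- epi_radius(spec, a)[1]
  ed_lm <- es_lm <- list()
  for (j in seq_along(LANDMARK_LABELS)) {
    ed_lm[[LANDMARK_LABELS[j]]] <- jit(c(R * cos(lm_angles[j]), R * sin(lm_angles[j]), 0))
    es_lm[[LANDMARK_LABELS[j]]] <- jit(c(Ra_es * cos(lm_angles[j]),
                                         Ra_es * sin(lm_angles[j]), -a))
  }
  lms <- landmark_set(ed_lm, es_lm, apex = c(0, 0, -L))

  stack <- contour_stack(subject_id = sprintf("phantom-%s-seed%d", spec$shape, spec$seed),
                         slices = slices, slice_thickness_mm = dz, slice_gap_mm = 0,
                         landmarks = lms, heart_rate_bpm = 60)
  truth <- phantom_truth(spec)
  structure(list(stack = stack, truth = truth, spec = spec), class = "lv_phantom")
}

# Analytic ground truth: closed form along the axis for the cylinder,
# midpoint quadrature at 100x slice resolution for the ellipsoid; the
# smoothed angular profile is integrated numerically in both cases.
phantom_truth <- function(spec, oversample = 100L) {
  R <- spec$base_radius_mm; L <- spec$length_mm; w <- spec$wall_mm
  a <- spec$avpd_mm
  pr <- profile_integrals(spec)
  if (spec$shape == "cylinder") {
    r <- R - w
    int_R2 <- R^2 * (L - a)                      # integral of epi radius^2 over the radial zone
    edv <- pi * r^2 * L
    A_epi_es <- pi * R^2 - 0.5 * R^2 * (pr$I_sept + pr$I_lat)
    esv <- (L - a) * A_epi_es - pi * (R^2 - r^2) * L
    long_ml <- pi * R^2 * a
  } else {
    m <- spec$n_slices * oversample
    ds <- L / m
    s <- (seq_len(m) - 0.5) * ds
    re2 <- epi_radius(spec, s)^2
    ri <- endo_radius(spec, s)
    ri2 <- ifelse(is.na(ri), 0, ri^2)
    edv <- pi * sum(ri2) * ds
    zone <- s > a
    int_R2 <- sum(re2[zone]) * ds
    endo_factor <- 1 - 0.5 * (pr$I_sept + pr$I_lat) / pi
    esv <- pi * endo_factor * sum(ri2[zone]) * ds
    long_ml <- pi * sum(re2[!zone]) * ds
  }
  sept_ml <- 0.5 * pr$I_sept * int_R2
  lat_ml <- 0.5 * pr$I_lat * int_R2
  structure(list(edv_ml = edv / 1000, esv_ml = esv / 1000,
                 sv_ml = (edv - esv) / 1000,
                 long_ml = long_ml / 1000,
                 lateral_ml = lat_ml / 1000,
                 septal_ml = sept_ml / 1000),
            class = "phantom_truth")
}

#' @export
print.lv_phantom <- function(x, ...) {
  t <- x$truth
  cat(sprintf("<lv_phantom> %s: R %.0f mm, L %.0f mm, wall %.0f mm, %d slices\n",
              x$spec$shape, x$spec$base_radius_mm, x$spec$length_mm,
              x$spec$wall_mm, x$spec$n_slices))
  cat(sprintf("  AVPD %.1f mm, lateral %.1f mm, septal %+.1f mm (span %.0f deg)\n",
              x$spec$avpd_mm, x$spec$lateral_mm, x$spec$septal_mm,
              x$spec$septal_span_deg))
  cat(sprintf("  truth: EDV %.1f  ESV %.1f  SV %.1f ml; long %.1f, lat %.1f, sept %+.1f ml\n",
              t$edv_ml, t$esv_ml, t$sv_ml, t$long_ml, t$lateral_ml, t$septal_ml))
  invisible(x)
}
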