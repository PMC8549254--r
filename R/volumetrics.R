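# Global LV quantities by short-axis slice summation.
#
# Each delineated slice contributes area x (thickness + gap); there is no
# partial-basal-slice weighting — basal inclusion is delegated to which
# slices carry contours, as in clinical delineation practice.  Units are
# centralized here: areas mm^2, volumes ml (1 ml = 1000 mm^3).

MUSCLE_DENSITY_G_PER_ML <- 1.05

mm3_to_ml <- function(x) x / 1000
mm2_to_cm2 <- function(x) x / 100

#' Cavity volume at one phase by slice summation
#'
#' Sums endocardial contour area times slice spacing over the slices that
#' carry an endocardial contour at the requested phase (trabeculations and
#' papillary muscles are included in the cavity by delineation convention).
#'
#' @param stack a [contour_stack].
#' @param phase `"ED"` or `"ES"`.
#' @return Volume in ml.
#' @export
cavity_volume <- function(stack, phase = c("ED", "ES")) {
  phase <- match.arg(phase)
  surface_volume(stack, "endocardial", phase,
                 err = sprintf("no endocardial contours at %s", phase))
}

surface_volume <- function(stack, surface, phase, err = NULL) {
  areas <- vapply(stack$slices, function(s) {
    ct <- get_contour(s, surface, phase)
    if (is.null(ct)) 0 else polygon_area(ct)
  }, numeric(1))
  if (all(areas == 0) && !is.null(err)) stop(err)
  mm3_to_ml(sum(areas) * slice_spacing(stack))
}

#' Left-ventricular mass
#'
#' Myocardial (epicardial minus endocardial) volume at end diastole times
#' the muscle density 1.05 g/ml.
#'
#' @param stack a [contour_stack] with ED epicardial and endocardial
#'   contours.
#' @return Mass in g.
#' @export
lv_mass <- function(stack) {
  MUSCLE_DENSITY_G_PER_ML * myocardial_volume(stack, "ED")
}

# Myocardial shell volume (ml) at a phase, over slices carrying both
# surfaces; errors if any slice has endocardium outside epicardium.
myocardial_volume <- function(stack, phase) {
  has_both <- vapply(stack$slices, function(s) {
    !is.null(get_contour(s, "epicardial", phase)) &&
      !is.null(get_contour(s, "endocardial", phase))
  }, logical(1))
  if (!any(has_both))
    stop(sprintf("no slice has both epicardial and endocardial contours at %s", phase))
  per_slice <- vapply(stack$slices, function(s) {
    epi <- get_contour(s, "epicardial", phase)
    endo <- get_contour(s, "endocardial", phase)
    if (is.null(epi) || is.null(endo)) return(0)
    d <- polygon_area(epi) - polygon_area(endo)
    if (d < -1e-9)
      stop(sprintf("negative myocardial area on slice %d at %s", s$index, phase))
    max(d, 0)
  }, numeric(1))
  mm3_to_ml(sum(per_slice) * slice_spacing(stack))
}

#' Global LV function by slice summation
#'
#' End-diastolic and end-systolic volumes, stroke volume (SV = EDV - ESV),
#' ejection fraction (EF = SV/EDV), LV mass, cardiac output when the heart
#' rate is known, and the per-slice ED epicardial short-axis areas.
#'
#' @param stack a [contour_stack] with ED and ES endocardial contours.
#' @return An object of class `lv_volumetrics`: list with `edv_ml`,
#'   `esv_ml`, `sv_ml`, `ef` (fraction 0-1), `mass_g`, `co_lmin` (NA without
#'   heart rate), `sa_area_ed_cm2` (per-slice vector) and `flags`.
#' @export
global_function <- function(stack) {
  edv <- cavity_volume(stack, "ED")
  esv <- cavity_volume(stack, "ES")
  sv <- edv - esv
  flags <- character(0)
  if (esv > edv) flags <- c(flags, "paradoxical: ESV exceeds EDV")
  ef <- if (edv > 0) sv / edv else NA_real_
  mass <- tryCatch(lv_mass(stack), error = function(e) NA_real_)
  co <- if (!is.null(stack$heart_rate_bpm)) sv * stack$heart_rate_bpm / 1000 else NA_real_
  sa <- vapply(stack$slices, function(s) {
    ct <- get_contour(s, "epicardial", "ED")
    if (is.null(ct)) NA_real_ else mm2_to_cm2(polygon_area(ct))
  }, numeric(1))
  structure(list(edv_ml = edv, esv_ml = esv, sv_ml = sv, ef = ef,
                 mass_g = mass, co_lmin = co, sa_area_ed_cm2 = sa,
                 flags = flags),
            class = "lv_volumetrics")
}

#' @export
print.lv_volumetrics <- function(x, ...) {
  cat("Left-ventricular volumetrics (slice summation)\n")
  cat(sprintf("  EDV %.1f ml   ESV %.1f ml   SV %.1f ml   EF %.1f%%\n",
              x$edv_ml, x$esv_ml, x$sv_ml, 100 * x$ef))
  cat(sprintf("  LV mass %.1f g   CO %s\n", x$mass_g,
              if (is.na(x$co_lmin)) "n/a (no heart rate)" else sprintf("%.1f l/min", x$co_lmin)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
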