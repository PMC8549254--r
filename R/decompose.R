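# Decomposition of LV stroke volume into longitudinal, lateral and septal
# contributions.
#
# Longitudinal: the atrioventricular plane sweeps an epicardial disc as it
# descends from ED to ES; that swept volume is AVPD times the mean of the
# two largest ED epicardial short-axis areas inside the swept band.
# Radial: on each slice apical to the ES AV-plane position, the region
# enclosed between the ED and ES epicardial arcs (split at the RV insertion
# points) is a signed swept area — positive when the ES border has moved
# toward the LV centroid, negative toward the RV — summed separately over
# the septal and free-wall arcs and multiplied by the slice spacing.
# Percentages are taken against the slice-summation stroke volume; the
# shortfall is reported as a residual, never redistributed.

#' Atrioventricular plane displacement (AVPD)
#'
#' Displacement of each of the six AV-plane landmarks from ED to ES,
#' projected onto the ED long axis (positive toward the apex), and their
#' mean.
#'
#' @param stack a [contour_stack] with a complete landmark set.
#' @return An object of class `avpd_result`: list with `per_landmark_mm`
#'   (named length-6 vector), `mean_mm`, and `axis` (the long axis used).
#' @export
compute_avpd <- function(stack) {
  lm <- stack$landmarks
  if (is.null(lm)) stop("contour stack has no landmark set")
  axis <- long_axis(stack)
  disp <- vapply(LANDMARK_LABELS, function(lab) {
    ed <- lm$ED[[lab]]; es <- lm$ES[[lab]]
    if (is.null(ed) || is.null(es)) stop(sprintf("missing landmark: %s", lab))
    sum((es - ed) * axis$direction)
  }, numeric(1))
  structure(list(per_landmark_mm = disp, mean_mm = mean(disp), axis = axis),
            class = "avpd_result")
}

#' @export
print.avpd_result <- function(x, ...) {
  cat(sprintf("AVPD %.2f mm (mean of six landmarks, positive apexward)\n", x$mean_mm))
  print(round(x$per_landmark_mm, 2))
  invisible(x)
}

#' Basal epicardial short-axis area swept by the AV plane
#'
#' A slice is "in band" when its plane position along the long axis lies in
#' the closed interval between the mean ED and mean ES AV-plane positions.
#' Returns the mean of the two largest ED epicardial areas among in-band
#' slices; with exactly one in-band slice, that slice's area; with none,
#' the most basal delineated slice's area (flagged).
#'
#' @param stack a [contour_stack].
#' @param avpd optional [compute_avpd] result (recomputed if missing).
#' @return Area in cm^2 with attributes `slices_used` (indices) and
#'   `fallback` (TRUE when no slice lay in the band).
#' @export
basal_epicardial_area <- function(stack, avpd = NULL) {
  if (is.null(avpd)) avpd <- compute_avpd(stack)
  axis <- avpd$axis
  s_ed <- av_plane_position(stack, "ED", axis)
  s_es <- av_plane_position(stack, "ES", axis)
  band <- sort(c(s_ed, s_es))
  pos <- slice_positions(stack, axis)
  has_epi <- vapply(stack$slices, function(s) !is.null(get_contour(s, "epicardial", "ED")),
                    logical(1))
  if (!any(has_epi)) stop("no epicardial ED contours in the stack")
  areas <- rep(NA_real_, length(stack$slices))
  areas[has_epi] <- vapply(stack$slices[has_epi],
                           function(s) polygon_area(get_contour(s, "epicardial", "ED")),
                           numeric(1))
  in_band <- which(has_epi & pos >= band[1] & pos <= band[2])
  fallback <- FALSE
  if (length(in_band) >= 2L) {
    top2 <- in_band[order(areas[in_band], decreasing = TRUE)][1:2]
    a <- mean(areas[top2]); used <- top2
  } else if (length(in_band) == 1L) {
    a <- areas[in_band]; used <- in_band
  } else {
    used <- which(has_epi)[1L]   # most basal delineated slice
    a <- areas[used]
    fallback <- TRUE
  }
  structure(mm2_to_cm2(a), slices_used = used, fallback = fallback)
}

#' Longitudinal contribution to stroke volume
#'
#' AVPD times the basal epicardial short-axis area, in ml, and as a
#' percentage of the slice-summation stroke volume.
#'
#' @param stack a [contour_stack].
#' @param sv_ml optional total stroke volume (computed from the stack when
#'   missing); with SV <= 0 the percentage is NA but the ml value is still
#'   returned.
#' @return List with `ml`, `pct`, `avpd_mm`, `basal_area_cm2`.
#' @export
sv_longitudinal <- function(stack, sv_ml = NULL) {
  avpd <- compute_avpd(stack)
  area <- basal_epicardial_area(stack, avpd)
  ml <- avpd$mean_mm * as.numeric(area) * 100 / 1000   # mm * cm^2 -> ml
  if (is.null(sv_ml)) sv_ml <- global_function(stack)$sv_ml
  pct <- if (is.finite(sv_ml) && sv_ml > 0) 100 * ml / sv_ml else NA_real_
  list(ml = ml, pct = pct, avpd_mm = avpd$mean_mm,
       basal_area_cm2 = as.numeric(area),
       basal_area_fallback = attr(area, "fallback"))
}

#' Signed septal and lateral swept areas on one slice
#'
#' Splits the ED and ES epicardial contours at their RV insertion points and
#' measures the signed area of the region enclosed by each pair of
#' corresponding arcs (ED arc, straight connectors between corresponding
#' insertion points, reversed ES arc).  Positive when the ES arc lies
#' displaced toward the ED epicardial centroid (motion toward the LV),
#' negative toward the RV.  A self-intersecting swept region is evaluated as
#' a signed-area sum (partial cancellation) and flagged.
#'
#' @param ed,es [lv_slice]s of the same slice at ED and ES (both must carry
#'   an epicardial contour and both insertion points).
#' @param axis long-axis list from [long_axis] (fixes the sign convention).
#' @return List with `septal_mm2`, `lateral_mm2` and `flags`.
#' @export
radial_slice_areas <- function(ed, es, axis) {
  d <- axis$direction
  epi_ed <- get_contour(ed, "epicardial", "ED")
  epi_es <- get_contour(es, "epicardial", "ES")
  ins_ed <- ed$insertions$ED
  ins_es <- es$insertions$ES
  if (is.null(epi_ed) || is.null(epi_es) || is.null(ins_ed) || is.null(ins_es))
    stop(sprintf("slice %d lacks an epicardial contour or insertion points at ED or ES",
                 ed$index))
  sp_ed <- split_at_insertions(epi_ed, ins_ed$anterior, ins_ed$inferior,
                               septal_hint = ed$septal_hint)
  sp_es <- split_at_insertions(epi_es, ins_es$anterior, ins_es$inferior,
                               septal_hint = es$septal_hint)
  flags <- character(0)
  swept <- function(arc_ed, arc_es, which) {
    # ED arc in counterclockwise order, ES arc reversed: for a contour
    # oriented counterclockwise about the apexward axis this traverses the
    # enclosed region positively exactly when the ES arc lies inside the ED
    # arc (toward the LV centroid).
    poly <- rbind(arc_ed, arc_es[rev(seq_len(nrow(arc_es))), , drop = FALSE])
    a <- signed_area(poly, d)
    if (arcs_cross(arc_ed, arc_es, d))
      flags <<- c(flags,
                  sprintf("slice %d: %s swept region self-intersects (signed-area sum used)",
                          ed$index, which))
    a
  }
  sept <- swept(sp_ed$septal, sp_es$septal, "septal")
  lat <- swept(sp_ed$free_wall, sp_es$free_wall, "free-wall")
  list(septal_mm2 = sept, lateral_mm2 = lat, flags = unique(flags))
}

# Slices eligible for the radial computation: epicardial contours and
# insertion points at both phases AND plane position apical to the ES
# AV-plane position (avoids double counting the longitudinally vacated
# band).  Returns integer indices into stack$slices.
radial_eligible_slices <- function(stack, axis = NULL) {
  if (is.null(axis)) axis <- long_axis(stack)
  pos <- slice_positions(stack, axis)
  s_es <- av_plane_position(stack, "ES", axis)
  ok <- vapply(stack$slices, function(s) {
    !is.null(get_contour(s, "epicardial", "ED")) &&
      !is.null(get_contour(s, "epicardial", "ES")) &&
      !is.null(s$insertions$ED$anterior) && !is.null(s$insertions$ED$inferior) &&
      !is.null(s$insertions$ES$anterior) && !is.null(s$insertions$ES$inferior)
  }, logical(1))
  which(ok & pos > s_es + 1e-9)
}

#' Septal and lateral contributions to stroke volume
#'
#' Sums the signed per-slice swept areas over the radial-eligible slices
#' (slices with epicardial contours and insertion points at both phases,
#' apical to the ES AV-plane position) times the slice spacing.
#'
#' @param stack a [contour_stack].
#' @param sv_ml optional total stroke volume for the percentages.
#' @return List with `septal_ml`, `septal_pct`, `lateral_ml`, `lateral_pct`,
#'   `slices_used`, `flags`.
#' @export
sv_radial <- function(stack, sv_ml = NULL) {
  axis <- long_axis(stack)
  elig <- radial_eligible_slices(stack, axis)
  if (length(elig) == 0L)
    stop("no slice is eligible for the radial computation")
  flags <- character(0)
  sept <- 0; lat <- 0
  for (i in elig) {
    r <- radial_slice_areas(stack$slices[[i]], stack$slices[[i]], axis)
    sept <- sept + r$septal_mm2
    lat <- lat + r$lateral_mm2
    flags <- c(flags, r$flags)
  }
  sp <- slice_spacing(stack)
  sept_ml <- mm3_to_ml(sept * sp)
  lat_ml <- mm3_to_ml(lat * sp)
  if (is.null(sv_ml)) sv_ml <- global_function(stack)$sv_ml
  pct <- function(ml) if (is.finite(sv_ml) && sv_ml > 0) 100 * ml / sv_ml else NA_real_
  list(septal_ml = sept_ml, septal_pct = pct(sept_ml),
       lateral_ml = lat_ml, lateral_pct = pct(lat_ml),
       slices_used = elig, flags = unique(flags))
}

#' Decompose the stroke volume of one subject
#'
#' The central fit: assembles the slice-summation volumetrics, the AVPD, and
#' the longitudinal, lateral and signed septal contributions to stroke
#' volume, each in ml and as a percentage of total SV, plus the residual
#' percentage 100 - (SV_long% + SV_lat% + SV_sept%).
#'
#' @param stack a [contour_stack] with endocardial and epicardial contours
#'   at both phases, insertion points, and the landmark set.
#' @return An object of class `sv_decomposition`.
#' @export
sv_decompose <- function(stack) {
  vol <- global_function(stack)
  flags <- vol$flags
  if (!is.finite(vol$sv_ml) || vol$sv_ml <= 0)
    flags <- c(flags, "SV <= 0: percentage fields undefined")
  lo <- sv_longitudinal(stack, vol$sv_ml)
  if (isTRUE(lo$basal_area_fallback))
    flags <- c(flags, "no slice in the AVPD band: most basal delineated slice used")
  ra <- sv_radial(stack, vol$sv_ml)
  flags <- c(flags, ra$flags)
  resid <- 100 - (lo$pct + ra$lateral_pct + ra$septal_pct)
  structure(list(subject_id = stack$subject_id,
                 volumetrics = vol,
                 avpd_mm = lo$avpd_mm,
                 basal_area_cm2 = lo$basal_area_cm2,
                 sv_long_ml = lo$ml, sv_long_pct = lo$pct,
                 sv_lat_ml = ra$lateral_ml, sv_lat_pct = ra$lateral_pct,
                 sv_sept_ml = ra$septal_ml, sv_sept_pct = ra$septal_pct,
                 residual_pct = resid,
                 radial_slices = ra$slices_used,
                 flags = unique(flags)),
            class = "sv_decomposition")
}

#' @export
print.sv_decomposition <- function(x, ...) {
  v <- x$volumetrics
  cat(sprintf("Stroke-volume decomposition — subject %s\n", x$subject_id))
  cat(sprintf("  EDV %.1f ml  ESV %.1f ml  SV %.1f ml  EF %.1f%%\n",
              v$edv_ml, v$esv_ml, v$sv_ml, 100 * v$ef))
  cat(sprintf("  AVPD %.1f mm  basal SA area %.1f cm^2\n", x$avpd_mm, x$basal_area_cm2))
  fmt <- function(ml, pct) sprintf("%7.1f ml  %s", ml,
                                   if (is.na(pct)) "   n/a" else sprintf("%6.1f%%", pct))
  cat("  longitudinal ", fmt(x$sv_long_ml, x$sv_long_pct), "\n")
  cat("  lateral      ", fmt(x$sv_lat_ml, x$sv_lat_pct), "\n")
  cat("  septal       ", fmt(x$sv_sept_ml, x$sv_sept_pct), "\n")
  if (!is.na(x$residual_pct)) cat(sprintf("  residual %21.1f%%\n", x$residual_pct))
  if (length(x$flags)) {
    # condense repeated per-slice flags into one line each
    body <- sub("^slice [0-9]+: ", "", x$flags)
    per_slice <- grepl("^slice [0-9]+: ", x$flags)
    shown <- c(unique(x$flags[!per_slice]),
               vapply(unique(body[per_slice]), function(b)
                 sprintf("%s [%d slice(s)]", b, sum(body == b & per_slice)),
                 character(1)))
    cat("  flags:", paste(shown, collapse = "; "), "\n")
  }
  invisible(x)
}

#' @export
summary.sv_decomposition <- function(object, ...) {
  v <- object$volumetrics
  out <- data.frame(
    subject_id = object$subject_id,
    edv_ml = v$edv_ml, esv_ml = v$esv_ml, sv_ml = v$sv_ml,
    ef_pct = 100 * v$ef, mass_g = v$mass_g, co_lmin = v$co_lmin,
    avpd_mm = object$avpd_mm, basal_area_cm2 = object$basal_area_cm2,
    sv_long_ml = object$sv_long_ml, sv_long_pct = object$sv_long_pct,
    sv_lat_ml = object$sv_lat_ml, sv_lat_pct = object$sv_lat_pct,
    sv_sept_ml = object$sv_sept_ml, sv_sept_pct = object$sv_sept_pct,
    residual_pct = object$residual_pct,
    stringsAsFactors = FALSE)
  class(out) <- c("summary.sv_decomposition", "data.frame")
  out
}

#' @export
coef.sv_decomposition <- function(object, ...) {
  c(sv_long_pct = object$sv_long_pct,
    sv_lat_pct = object$sv_lat_pct,
    sv_sept_pct = object$sv_sept_pct)
}

#' @export
residuals.sv_decomposition <- function(object, ...) {
  c(residual_pct = object$residual_pct)
}

#' @export
plot.sv_decomposition <- function(x, ...) {
  vals <- coef(x)
  graphics::barplot(vals, names.arg = c("longitudinal", "lateral", "septal"),
                    ylab = "% of stroke volume",
                    main = sprintf("Regional contributions — %s", x$subject_id), ...)
  graphics::abline(h = 0)
  invisible(x)
}
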