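# Containers for one subject's segmented cine-CMR geometry: a short-axis
# stack of epicardial/endocardial contours at ED and ES, per-slice RV
# insertion points, and the six long-axis atrioventricular-plane landmarks.

LANDMARK_LABELS <- c("inferoseptal", "anterolateral",   # 4-chamber
                     "anteroseptal", "inferolateral",   # 3-chamber
                     "anterior", "inferior")            # 2-chamber

#' Construct the atrioventricular-plane landmark set
#'
#' Six standardized landmarks per phase — inferoseptal and anterolateral
#' (4-chamber view), anteroseptal and inferolateral (3-chamber), anterior
#' and inferior (2-chamber) — plus an end-diastolic apex reference point.
#'
#' @param ED,ES named lists of six length-3 points (mm); names must be
#'   `r paste(LANDMARK_LABELS, collapse = ", ")`.
#' @param apex length-3 apex reference point at ED (mm).
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(ED, ES, apex) {
  chk <- function(lst, phase) {
    missing <- setdiff(LANDMARK_LABELS, names(lst))
    if (length(missing))
      stop(sprintf("missing %s landmark(s): %s", phase, paste(missing, collapse = ", ")))
    lapply(lst[LANDMARK_LABELS], function(p) {
      p <- as.numeric(p)
      if (length(p) != 3L || !all(is.finite(p))) stop("landmarks must be finite length-3 points")
      p
    })
  }
  structure(list(ED = chk(ED, "ED"), ES = chk(ES, "ES"), apex = as.numeric(apex)),
            class = "landmark_set")
}

#' Construct one short-axis slice
#'
#' @param index slice index; 0 is the most basal slice, increasing apexward.
#' @param origin length-3 point on the slice plane (mm).
#' @param normal length-3 slice-plane normal (normalized internally).
#' @param epicardial,endocardial named lists with optional `ED`/`ES`
#'   [planar_contour] entries (endocardial may be absent).
#' @param insertions named list with optional `ED`/`ES` entries, each a list
#'   with `anterior` and `inferior` length-3 points.
#' @param septal_hint optional length-3 point on the septal side used to
#'   override the shorter-arc septum rule.
#' @return An object of class `lv_slice`.
#' @export
lv_slice <- function(index, origin, normal, epicardial = list(),
                     endocardial = list(), insertions = list(),
                     septal_hint = NULL) {
  structure(list(index = as.integer(index),
                 origin = as.numeric(origin),
                 normal = unitize(as.numeric(normal)),
                 epicardial = epicardial,
                 endocardial = endocardial,
                 insertions = insertions,
                 septal_hint = if (is.null(septal_hint)) NULL else as.numeric(septal_hint)),
            class = "lv_slice")
}

#' Construct a contour stack
#'
#' The complete segmented geometry of one subject: an ordered short-axis
#' slice list (basal to apical), slice thickness and gap, and the long-axis
#' landmark set.  Contour orientation and slice normals are normalized so
#' that contours run counterclockwise seen from the apex and normals point
#' apexward.
#'
#' @param subject_id character id.
#' @param slices list of [lv_slice], ordered basal to apical.
#' @param slice_thickness_mm,slice_gap_mm acquisition geometry (mm);
#'   slice spacing is their sum and must be positive.
#' @param landmarks a [landmark_set].
#' @param heart_rate_bpm optional heart rate (beats/min) for cardiac output.
#' @param normalize normalize orientations (default TRUE).
#' @return An object of class `contour_stack`.
#' @export
contour_stack <- function(subject_id, slices, slice_thickness_mm,
                          slice_gap_mm = 0, landmarks = NULL,
                          heart_rate_bpm = NULL, normalize = TRUE) {
  spacing <- slice_thickness_mm + slice_gap_mm
  if (!is.finite(spacing) || spacing <= 0)
    stop("slice spacing (thickness + gap) must be positive")
  x <- structure(list(subject_id = as.character(subject_id),
                      slices = slices,
                      slice_thickness_mm = slice_thickness_mm,
                      slice_gap_mm = slice_gap_mm,
                      landmarks = landmarks,
                      heart_rate_bpm = heart_rate_bpm),
                 class = "contour_stack")
  if (!is.null(landmarks)) {
    ax <- long_axis(x)
    pos <- vapply(slices, function(s) axial_position(s$origin, ax), numeric(1))
    if (length(pos) > 1L && any(diff(pos) <= 0))
      stop("slice ordering must be monotone along the long axis (basal to apical)")
    if (normalize) x <- normalize_stack(x, ax)
  }
  x
}

#' @export
print.contour_stack <- function(x, ...) {
  cat(sprintf("<contour_stack> subject %s: %d slices, spacing %.1f mm (%.1f + %.1f gap)\n",
              x$subject_id, length(x$slices),
              x$slice_thickness_mm + x$slice_gap_mm,
              x$slice_thickness_mm, x$slice_gap_mm))
  n_endo <- sum(vapply(x$slices, function(s) !is.null(s$endocardial$ED), logical(1)))
  cat(sprintf("  ED endocardial contours on %d slices; landmarks %s\n",
              n_endo, if (is.null(x$landmarks)) "absent" else "present"))
  invisible(x)
}

slice_spacing <- function(stack) stack$slice_thickness_mm + stack$slice_gap_mm

get_contour <- function(slice, surface, phase) {
  lst <- if (surface == "epicardial") slice$epicardial else slice$endocardial
  lst[[phase]]
}

# Orient every contour counterclockwise as seen from the apex (positive
# signed area about the apexward axis direction) and point slice normals
# apexward.  Returns the stack with a count of flipped contours in
# attr(, "flipped").
normalize_stack <- function(stack, axis = NULL) {
  if (is.null(axis)) axis <- long_axis(stack)
  d <- axis$direction
  flipped <- 0L
  stack$slices <- lapply(stack$slices, function(s) {
    if (sum(s$normal * d) < 0) s$normal <- -s$normal
    for (surf in c("epicardial", "endocardial")) {
      for (ph in c("ED", "ES")) {
        ct <- s[[surf]][[ph]]
        if (!is.null(ct)) {
          if (signed_area(ct$vertices, d) < 0) {
            ct$vertices <- ct$vertices[rev(seq_len(nrow(ct$vertices))), , drop = FALSE]
            s[[surf]][[ph]] <- ct
            flipped <<- flipped + 1L
          }
        }
      }
    }
    s
  })
  attr(stack, "flipped") <- flipped
  stack
}

# Axial position (mm, positive apexward from the ED landmark centroid) of
# every slice plane.
slice_positions <- function(stack, axis = NULL) {
  if (is.null(axis)) axis <- long_axis(stack)
  vapply(stack$slices, function(s) axial_position(s$origin, axis), numeric(1))
}

# Mean axial position of the six AV-plane landmarks at a phase.
av_plane_position <- function(stack, phase, axis = NULL) {
  if (is.null(axis)) axis <- long_axis(stack)
  mean(vapply(stack$landmarks[[phase]], function(p) axial_position(p, axis), numeric(1)))
}
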