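# Planar contour primitives and axial geometry.
#
# All geometry lives in physical patient space (mm), right-handed axes.
# Short-axis contours are stored counterclockwise as seen from the apex
# looking toward the base, i.e. with positive signed area with respect to
# the apex-pointing long-axis direction.  Slice index 0 is the most basal
# slice and indices increase toward the apex.

PLANARITY_TOL_MM <- 0.5

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(a) sqrt(sum(a * a))

unitize <- function(a) {
  n <- vnorm(a)
  if (n < .Machine$double.eps^0.5) stop("cannot normalize a near-zero vector")
  a / n
}

#' Construct a planar contour
#'
#' A closed simple polygon lying in one short-axis slice plane.  The first
#' vertex is implicitly joined to the last; vertices are stored
#' counterclockwise as seen from the apex once a stack is normalized.
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates in mm (n >= 3).
#' @param surface `"epicardial"` or `"endocardial"`.
#' @param phase `"ED"` or `"ES"`.
#' @param validate check polygon simplicity and planarity (O(n^2); skip for
#'   trusted generated geometry).
#' @return An object of class `planar_contour`.
#' @export
planar_contour <- function(vertices, surface = c("epicardial", "endocardial"),
                           phase = c("ED", "ES"), validate = TRUE) {
  surface <- match.arg(surface)
  phase <- match.arg(phase)
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("contour vertices must be an n x 3 matrix")
  if (nrow(vertices) < 3L) stop("a contour needs at least 3 vertices")
  if (!all(is.finite(vertices))) stop("contour vertices must be finite")
  x <- structure(list(vertices = vertices, surface = surface, phase = phase),
                 class = "planar_contour")
  if (validate) {
    pl <- contour_plane(x)
    d <- abs((vertices - matrix(pl$origin, nrow(vertices), 3L, byrow = TRUE)) %*% pl$normal)
    if (max(d) > PLANARITY_TOL_MM)
      stop(sprintf("contour vertices deviate %.2f mm from their best plane (tolerance %.1f mm)",
                   max(d), PLANARITY_TOL_MM))
    if (!is_simple_polygon(project_to_plane(vertices, pl)))
      stop("contour is not a simple polygon (self-intersection)")
  }
  x
}

# Best-fit plane through the vertices: centroid + unit normal from the
# polygon vector area (exact for planar input, robust to small jitter);
# falls back to the least-squares plane for degenerate (zero-vector-area)
# polygons such as symmetric bowties.
contour_plane <- function(contour) {
  V <- if (inherits(contour, "planar_contour")) contour$vertices else contour
  va <- polygon_vector_area(V)
  n <- if (vnorm(va) > 1e-9) unitize(va) else {
    Vc <- sweep(V, 2, colMeans(V))
    svd(Vc, nu = 0)$v[, 3]
  }
  list(origin = colMeans(V), normal = n)
}

# Half the sum of successive cross products; for a planar polygon its norm
# is the enclosed area and its direction the right-hand-rule normal.
polygon_vector_area <- function(V) {
  n <- nrow(V)
  j <- c(2:n, 1L)
  0.5 * c(sum(V[, 2] * V[j, 3] - V[, 3] * V[j, 2]),
          sum(V[, 3] * V[j, 1] - V[, 1] * V[j, 3]),
          sum(V[, 1] * V[j, 2] - V[, 2] * V[j, 1]))
}

# Orthonormal in-plane basis (e1, e2) with e1 x e2 = normal, so that the
# 2-D shoelace sign matches the signed area about `normal`.
plane_basis <- function(normal) {
  normal <- unitize(normal)
  seed <- if (abs(normal[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitize(seed - sum(seed * normal) * normal)
  e2 <- vcross(normal, e1)
  list(e1 = e1, e2 = e2, normal = normal)
}

project_to_plane <- function(V, plane) {
  b <- plane_basis(plane$normal)
  Vc <- V - matrix(plane$origin, nrow(V), 3L, byrow = TRUE)
  cbind(Vc %*% b$e1, Vc %*% b$e2)
}

# 2-D shoelace signed area (positive = counterclockwise in the basis).
shoelace2d <- function(P) {
  n <- nrow(P)
  j <- c(2:n, 1L)
  0.5 * sum(P[, 1] * P[j, 2] - P[j, 1] * P[, 2])
}

#' Enclosed area of a planar contour
#'
#' Unsigned enclosed area in mm^2, independent of vertex ordering direction,
#' computed in the contour's slice plane.
#'
#' @param contour a [planar_contour] or an n x 3 vertex matrix.
#' @param check verify polygon simplicity first (error on self-intersection).
#' @param slice optional slice label used in error messages.
#' @return Area in mm^2.
#' @export
polygon_area <- function(contour, check = FALSE, slice = NULL) {
  V <- if (inherits(contour, "planar_contour")) contour$vertices else as.matrix(contour)
  if (nrow(V) < 3L) stop("polygon needs at least 3 vertices")
  if (check) {
    pl <- contour_plane(V)
    if (!is_simple_polygon(project_to_plane(V, pl)))
      stop(sprintf("self-intersecting polygon%s",
                   if (is.null(slice)) "" else sprintf(" on slice %s", slice)))
  }
  vnorm(polygon_vector_area(V))
}

# Signed area with respect to a reference normal; positive when the contour
# runs counterclockwise about `normal` (right-hand rule).
signed_area <- function(V, normal) {
  if (inherits(V, "planar_contour")) V <- V$vertices
  sum(polygon_vector_area(V) * unitize(normal))
}

# Simplicity test for a closed 2-D polygon: no two non-adjacent edges
# intersect.  Vectorized orientation tests over all edge pairs.
is_simple_polygon <- function(P) {
  n <- nrow(P)
  if (n < 3L) return(FALSE)
  if (anyDuplicated(P)) return(FALSE)
  jn <- c(2:n, 1L)
  ax <- P[, 1]; ay <- P[, 2]
  bx <- P[jn, 1]; by <- P[jn, 2]
  pr <- which(outer(seq_len(n), seq_len(n), function(i, j)
    j > i + 1L & !(i == 1L & j == n)), arr.ind = TRUE)
  if (nrow(pr) == 0L) return(TRUE)
  i <- pr[, 1]; j <- pr[, 2]
  o <- function(px, py, qx, qy, rx, ry) sign((qx - px) * (ry - py) - (qy - py) * (rx - px))
  d1 <- o(ax[i], ay[i], bx[i], by[i], ax[j], ay[j])
  d2 <- o(ax[i], ay[i], bx[i], by[i], bx[j], by[j])
  d3 <- o(ax[j], ay[j], bx[j], by[j], ax[i], ay[i])
  d4 <- o(ax[j], ay[j], bx[j], by[j], bx[i], by[i])
  proper <- (d1 * d2 < 0) & (d3 * d4 < 0)
  if (any(proper)) return(FALSE)
  # collinear touching: a zero orientation with the point inside the other
  # edge's bounding box counts as an intersection
  on_seg <- function(px, py, qx, qy, rx, ry, dd)
    dd == 0 & rx <= pmax(px, qx) & rx >= pmin(px, qx) &
      ry <= pmax(py, qy) & ry >= pmin(py, qy)
  touch <- on_seg(ax[i], ay[i], bx[i], by[i], ax[j], ay[j], d1) |
    on_seg(ax[i], ay[i], bx[i], by[i], bx[j], by[j], d2) |
    on_seg(ax[j], ay[j], bx[j], by[j], ax[i], ay[i], d3) |
    on_seg(ax[j], ay[j], bx[j], by[j], bx[i], by[i], d4)
  !any(touch)
}

# TRUE when two open polylines cross properly (transversally) in the plane
# normal to `normal`.  Coincident or touching segments do not count: a
# swept region between an ED and an ES arc is only non-simple (bowtie,
# partial sign cancellation) when the arcs actually cross.
arcs_cross <- function(A, B, normal) {
  pl <- list(origin = colMeans(A), normal = normal)
  A2 <- project_to_plane(A, pl)
  B2 <- project_to_plane(B, pl)
  na <- nrow(A2) - 1L; nb <- nrow(B2) - 1L
  if (na < 1L || nb < 1L) return(FALSE)
  idx <- expand.grid(i = seq_len(na), j = seq_len(nb))
  i <- idx$i; j <- idx$j
  o <- function(px, py, qx, qy, rx, ry) sign((qx - px) * (ry - py) - (qy - py) * (rx - px))
  p1x <- A2[i, 1]; p1y <- A2[i, 2]; p2x <- A2[i + 1L, 1]; p2y <- A2[i + 1L, 2]
  q1x <- B2[j, 1]; q1y <- B2[j, 2]; q2x <- B2[j + 1L, 1]; q2y <- B2[j + 1L, 2]
  d1 <- o(p1x, p1y, p2x, p2y, q1x, q1y)
  d2 <- o(p1x, p1y, p2x, p2y, q2x, q2y)
  d3 <- o(q1x, q1y, q2x, q2y, p1x, p1y)
  d4 <- o(q1x, q1y, q2x, q2y, p2x, p2y)
  any(d1 * d2 < 0 & d3 * d4 < 0)
}

#' Left-ventricular long axis of a contour stack
#'
#' Unit direction from the centroid of the six end-diastolic
#' atrioventricular-plane landmarks toward the end-diastolic apex reference,
#' plus that centroid as the base reference point.  Positive positions along
#' the axis increase toward the apex.
#'
#' @param stack a [contour_stack].
#' @return List with `direction` (unit length-3 vector) and `base` (length-3
#'   point, mm).
#' @export
long_axis <- function(stack) {
  lm <- stack$landmarks
  if (is.null(lm)) stop("contour stack has no landmark set")
  ed <- do.call(rbind, lm$ED)
  base <- colMeans(ed)
  axis <- lm$apex - base
  if (vnorm(axis) < 1e-6)
    stop("degenerate long axis: landmark centroid coincides with the apex reference")
  list(direction = unitize(axis), base = base)
}

# Signed position of a point along the long axis (mm, positive apexward).
axial_position <- function(p, axis) sum((p - axis$base) * axis$direction)

#' Split a contour at the right-ventricular insertion points
#'
#' Snaps the anterior and inferior RV insertion points to their nearest
#' contour vertices and partitions the closed contour into the septal arc
#' and the free-wall arc.  By default the septal arc is the shorter of the
#' two arcs (the septum spans well under half the circumference); an
#' optional `septal_hint` point overrides this by selecting the arc whose
#' midpoint lies nearer the hint.  For exactly antipodal insertions the tie
#' is broken with `rv_side`, a point on the right-ventricular side: the
#' septal arc is the one whose midpoint is nearer to it.
#'
#' @param contour a [planar_contour] or vertex matrix (counterclockwise).
#' @param anterior,inferior length-3 insertion points (mm).
#' @param septal_hint optional length-3 point on the septal side.
#' @param rv_side optional length-3 point used only to break an exact tie.
#' @return List with `septal` and `free_wall` open polylines (matrices), the
#'   snapped vertex indices, and the arc index sequences.  Arc vertex order
#'   follows the contour's counterclockwise order; the two arcs share their
#'   two endpoint vertices.
#' @export
split_at_insertions <- function(contour, anterior, inferior,
                                septal_hint = NULL, rv_side = NULL) {
  V <- if (inherits(contour, "planar_contour")) contour$vertices else as.matrix(contour)
  n <- nrow(V)
  nearest <- function(p) which.min(colSums((t(V) - p)^2))
  ia <- nearest(anterior)
  ii <- nearest(inferior)
  if (ia == ii)
    stop("both insertion points snap to the same contour vertex")
  cyc <- function(from, to) if (from <= to) from:to else c(from:n, 1L:to)
  arc1 <- cyc(ia, ii)   # counterclockwise from anterior to inferior
  arc2 <- cyc(ii, ia)   # counterclockwise from inferior to anterior
  arclen <- function(idx) {
    W <- V[idx, , drop = FALSE]
    sum(sqrt(rowSums((W[-1L, , drop = FALSE] - W[-nrow(W), , drop = FALSE])^2)))
  }
  l1 <- arclen(arc1); l2 <- arclen(arc2)
  midpt <- function(idx) colMeans(V[idx, , drop = FALSE])
  pick <- if (!is.null(septal_hint)) {
    if (sum((midpt(arc1) - septal_hint)^2) <= sum((midpt(arc2) - septal_hint)^2)) 1L else 2L
  } else if (abs(l1 - l2) <= 1e-9 * (l1 + l2)) {
    if (is.null(rv_side))
      stop("insertion points are antipodal and no rv_side tie-break point was given")
    if (sum((midpt(arc1) - rv_side)^2) <= sum((midpt(arc2) - rv_side)^2)) 1L else 2L
  } else if (l1 < l2) 1L else 2L
  sep_idx <- if (pick == 1L) arc1 else arc2
  fw_idx <- if (pick == 1L) arc2 else arc1
  list(septal = V[sep_idx, , drop = FALSE],
       free_wall = V[fw_idx, , drop = FALSE],
       anterior_index = ia, inferior_index = ii,
       septal_indices = sep_idx, free_wall_indices = fw_idx)
}
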