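# Contour primitives: areas, the long axis, and the insertion-point split.

test_that("polygon_area matches closed forms and is orientation-independent", {
  sq <- planar_contour(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)))
  expect_equal(polygon_area(sq), 1)
  expect_equal(polygon_area(sq$vertices[4:1, ]), 1)  # reversed ordering

  circ <- circle_contour(25, n = 720)
  expect_rel_equal(polygon_area(circ), pi * 625, 1e-4)
})

test_that("polygon_area agrees with a fan-triangulation oracle on a random 12-gon", {
  set.seed(42)
  # star-shaped 12-gon: fan triangulation from the origin is valid
  th <- sort(stats::runif(12, 0, 2 * pi))
  r <- stats::runif(12, 5, 20)
  V <- cbind(r * cos(th), r * sin(th), 0)
  fan <- sum(vapply(seq_len(12), function(i) {
    j <- if (i == 12) 1L else i + 1L
    0.5 * (V[i, 1] * V[j, 2] - V[j, 1] * V[i, 2])
  }, numeric(1)))
  expect_equal(polygon_area(V), abs(fan), tolerance = 1e-12)
})

test_that("polygon_area is invariant under vertex rotation and rigid transforms", {
  set.seed(7)
  th <- sort(stats::runif(15, 0, 2 * pi))
  V <- cbind(10 * cos(th), 10 * sin(th), 2)
  a0 <- polygon_area(V)
  for (k in c(3, 8, 12)) {
    expect_equal(polygon_area(V[c(k:15, 1:(k - 1)), ]), a0, tolerance = 1e-9)
  }
  ang <- 0.7
  Rz <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
  expect_equal(polygon_area(V %*% t(Rz) + matrix(c(5, -3, 11), 15, 3, byrow = TRUE)),
               a0, tolerance = 1e-9 * a0)
})

test_that("self-intersecting polygons are rejected when checked", {
  bow <- rbind(c(0, 0, 0), c(2, 2, 0), c(2, 0, 0), c(0, 2, 0))
  expect_error(polygon_area(bow, check = TRUE, slice = 3), "slice 3")
  expect_error(planar_contour(bow), "simple")
})

test_that("long_axis points from the landmark centroid to the apex", {
  lms <- landmark_set(ring_landmarks(30, 0),
                      ring_landmarks(30, -10),
                      apex = c(0, 0, -100))
  st <- structure(list(landmarks = lms), class = "contour_stack")
  ax <- long_axis(st)
  expect_equal(ax$direction, c(0, 0, -1), tolerance = 1e-12)
  expect_equal(ax$base, c(0, 0, 0), tolerance = 1e-12)

  # tilted axis recovered by construction
  tilt <- pi / 6
  Ry <- rbind(c(cos(tilt), 0, sin(tilt)), c(0, 1, 0), c(-sin(tilt), 0, cos(tilt)))
  rot <- function(p) as.numeric(Ry %*% p)
  lms2 <- landmark_set(lapply(ring_landmarks(30, 0), rot),
                       lapply(ring_landmarks(30, -10), rot),
                       apex = rot(c(0, 0, -100)))
  ax2 <- long_axis(structure(list(landmarks = lms2), class = "contour_stack"))
  expect_equal(ax2$direction, as.numeric(Ry %*% c(0, 0, -1)), tolerance = 1e-9)

  # translation invariance
  sh <- c(13, -4, 22)
  lms3 <- landmark_set(lapply(ring_landmarks(30, 0), function(p) p + sh),
                       lapply(ring_landmarks(30, -10), function(p) p + sh),
                       apex = c(0, 0, -100) + sh)
  ax3 <- long_axis(structure(list(landmarks = lms3), class = "contour_stack"))
  expect_equal(ax3$direction, ax$direction, tolerance = 1e-12)

  lms4 <- landmark_set(ring_landmarks(30, 0), ring_landmarks(30, -10),
                       apex = c(0, 0, 0))
  expect_error(long_axis(structure(list(landmarks = lms4), class = "contour_stack")),
               "degenerate")
})

test_that("jittered landmarks recover the axis direction within 1 degree", {
  set.seed(11)
  for (rep in 1:20) {
    jit <- function(p) p + pmin(pmax(stats::rnorm(3, 0, 0.5), -1.5), 1.5)
    lms <- landmark_set(lapply(ring_landmarks(30, 0), jit),
                        lapply(ring_landmarks(30, -10), jit),
                        apex = c(0, 0, -100))
    ax <- long_axis(structure(list(landmarks = lms), class = "contour_stack"))
    ang <- acos(min(1, sum(ax$direction * c(0, 0, -1)))) * 180 / pi
    expect_lt(ang, 1)
  }
})

test_that("split_at_insertions takes the shorter arc as septum", {
  circ <- circle_contour(30, n = 120)
  at <- function(deg) c(30 * cos(deg * pi / 180), 30 * sin(deg * pi / 180), 0)
  # insertions at 10 and 2 o'clock: minor arc through 12 o'clock is septal
  sp <- split_at_insertions(circ, at(120), at(60))
  mid <- colMeans(sp$septal)
  expect_gt(mid[2], 0)          # midpoint near 12 o'clock (positive y)
  expect_lt(nrow(sp$septal), nrow(sp$free_wall))

  # concatenation reproduces the full vertex set; endpoints shared once
  all_idx <- sort(c(sp$septal_indices, sp$free_wall_indices))
  expect_equal(sort(unique(all_idx)), 1:120)
  expect_equal(sum(duplicated(all_idx)), 2L)

  # both insertions snapping to one vertex is an error
  expect_error(split_at_insertions(circ, at(60), at(61)), "same contour vertex")
})

test_that("antipodal insertions need the rv_side tie-break and hints override", {
  circ <- circle_contour(30, n = 120)
  at <- function(deg) c(30 * cos(deg * pi / 180), 30 * sin(deg * pi / 180), 0)
  expect_error(split_at_insertions(circ, at(0), at(180)), "antipodal")
  sp <- split_at_insertions(circ, at(0), at(180), rv_side = c(0, 80, 0))
  expect_gt(colMeans(sp$septal)[2], 0)   # arc whose midpoint faces the RV side
  sp2 <- split_at_insertions(circ, at(0), at(180), rv_side = c(0, -80, 0))
  expect_lt(colMeans(sp2$septal)[2], 0)

  # septal hint overrides the shorter-arc rule
  sp3 <- split_at_insertions(circ, at(120), at(60), septal_hint = c(0, -80, 0))
  expect_lt(colMeans(sp3$septal)[2], 0)
  expect_gt(nrow(sp3$septal), nrow(sp3$free_wall))
})

test_that("a 120-degree septum occupies the expected perimeter fraction", {
  n <- 360
  circ <- circle_contour(30, n = n)
  at <- function(deg) c(30 * cos(deg * pi / 180), 30 * sin(deg * pi / 180), 0)
  sp <- split_at_insertions(circ, at(60), at(-60))
  arclen <- function(W) sum(sqrt(rowSums(diff(W)^2)))
  per <- arclen(rbind(circ$vertices, circ$vertices[1, ]))
  expect_equal(arclen(sp$septal) / per, 120 / 360, tolerance = 1.5 / n)
})
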