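# Polygon primitives in degrees of visual angle. Rings are n x 2 matrices
# of vertices (not repeated at the end); regions are interpreted with
# even-odd parity so oppositely wound inner rings act as holes.

.close_ring <- function(ring) {
  ring <- as.matrix(ring)
  if (nrow(ring) >= 2 &&
      isTRUE(all.equal(ring[1, ], ring[nrow(ring), ], check.attributes = FALSE)))
    ring <- ring[-nrow(ring), , drop = FALSE]
  ring
}

.ring_signed_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  0.5 * sum(x * yn - xn * y)
}

# segment-segment intersection (proper or touching), excluding shared
# endpoints of adjacent segments which the caller filters out
.segs_intersect <- function(p1, p2, p3, p4) {
  o <- function(a, b, c)
    sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  d1 <- o(p3, p4, p1); d2 <- o(p3, p4, p2)
  d3 <- o(p1, p2, p3); d4 <- o(p1, p2, p4)
  if (d1 != d2 && d3 != d4) return(TRUE)
  on_seg <- function(a, b, c)
    o(a, b, c) == 0 &&
      min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  on_seg(p3, p4, p1) || on_seg(p3, p4, p2) ||
    on_seg(p1, p2, p3) || on_seg(p1, p2, p4)
}

.ring_is_simple <- function(ring) {
  n <- nrow(ring)
  if (n < 3) return(FALSE)
  idx <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      # skip adjacent segments (share a vertex)
      if (b == a + 1 || (a == 1 && b == n)) next
      if (.segs_intersect(ring[idx[a, 1], ], ring[idx[a, 2], ],
                          ring[idx[b, 1], ], ring[idx[b, 2], ]))
        return(FALSE)
    }
  }
  TRUE
}

# even-odd crossing parity for points (px, py) against a list of rings;
# returns logical vector, TRUE = inside
.points_in_rings <- function(px, py, rings) {
  crossings <- integer(length(px))
  for (ring in rings) {
    x1 <- ring[, 1]; y1 <- ring[, 2]
    x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
    for (e in seq_along(x1)) {
      straddles <- (y1[e] > py) != (y2[e] > py)
      if (!any(straddles)) next
      xint <- x1[e] + (py - y1[e]) * (x2[e] - x1[e]) / (y2[e] - y1[e])
      crossings <- crossings + as.integer(straddles & px < xint)
    }
  }
  crossings %% 2L == 1L
}

# min distance from the origin to each segment of a ring given as a
# transformed coordinate matrix
.min_dist_origin_segments <- function(ring) {
  x1 <- ring[, 1]; y1 <- ring[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx^2 + dy^2
  t <- ifelse(len2 > 0, pmin(1, pmax(0, -(x1 * dx + y1 * dy) / len2)), 0)
  min(sqrt((x1 + t * dx)^2 + (y1 + t * dy)^2))
}

# affine map sending a coverage region (disc or ellipse) to the unit disc
# at the origin; returns transformed rings
.rings_to_region_frame <- function(rings, center, semi_radial,
                                   semi_tangential, orientation) {
  co <- cos(-orientation); si <- sin(-orientation)
  lapply(rings, function(r) {
    xs <- r[, 1] - center[1]; ys <- r[, 2] - center[2]
    cbind((xs * co - ys * si) / semi_radial,
          (xs * si + ys * co) / semi_tangential)
  })
}

# does the coverage region intersect the even-odd polygon region
# (positive area or boundary contact)?
.region_intersects <- function(rings, center, semi_radial, semi_tangential,
                               orientation, tol = 1e-9) {
  if (length(rings) == 0) return(FALSE)
  tr <- .rings_to_region_frame(rings, center, semi_radial,
                               semi_tangential, orientation)
  # region center inside the polygon
  if (.points_in_rings(0, 0, tr)) return(TRUE)
  # polygon boundary within the (unit-disc) region
  min(vapply(tr, .min_dist_origin_segments, 0)) <= 1 + tol
}

# distance from a point to the even-odd polygon region (0 if inside)
.dist_point_region <- function(px, py, rings) {
  if (length(rings) == 0) return(Inf)
  if (.points_in_rings(px, py, rings)) return(0)
  min(vapply(rings, function(r)
    .min_dist_origin_segments(cbind(r[, 1] - px, r[, 2] - py)), 0))
}
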