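# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive: they must not share code paths with the package.

the_grid <- mp_grid()

# --- set-metric oracle: logical bitmasks over 56 locations ---------------
bf_mask <- function(ids) {
  m <- logical(56)
  m[ids + 1L] <- TRUE
  m
}
bf_conc3 <- function(A, B, C) {
  a <- bf_mask(A); b <- bf_mask(B); c <- bf_mask(C)
  u <- sum(a | b | c)
  if (u == 0) 100 else 100 * sum(a & b & c) / u
}
bf_conc2 <- function(A, B) {
  a <- bf_mask(A); b <- bf_mask(B)
  u <- sum(a | b)
  if (u == 0) 100 else 100 * sum(a & b) / u
}
bf_comp <- function(A, B) {
  a <- bf_mask(A); b <- bf_mask(B)
  u <- sum(a | b)
  if (u == 0) 0 else 100 * sum(a & !b) / u
}

# --- connected-component oracle: boolean reachability closure ------------
bf_components <- function(flagged, adjacency) {
  # flagged: 0-based ids; adjacency: 0-based pair matrix
  n <- length(flagged)
  if (n == 0) return(list())
  R <- diag(TRUE, n)
  for (k in seq_len(nrow(adjacency))) {
    i <- match(adjacency[k, 1], flagged)
    j <- match(adjacency[k, 2], flagged)
    if (!is.na(i) && !is.na(j)) R[i, j] <- R[j, i] <- TRUE
  }
  repeat {
    R2 <- (R %*% R) > 0
    if (identical(R2, R)) break
    R <- R2
  }
  comps <- unique(apply(R, 1, function(row) sort(flagged[row]), simplify = FALSE))
  comps
}
bf_field_loss <- function(flagged, adjacency, min_cluster = 3) {
  comps <- bf_components(flagged, adjacency)
  sort(unlist(comps[vapply(comps, length, 0L) >= min_cluster]))
}

# --- lesion-mapping oracle: dense sampling of polygon edges --------------
# A coverage region intersects the polygon iff (a) a densely sampled
# boundary point of the polygon lies in the region, or (b) a polygon
# vertex lies in the region, or (c) the region center lies inside the
# polygon (winding-number test, independent of the package's parity code).
bf_winding_inside <- function(px, py, rings) {
  total <- 0
  for (r in rings) {
    xs <- r[, 1] - px; ys <- r[, 2] - py
    xn <- c(xs[-1], xs[1]); yn <- c(ys[-1], ys[1])
    ang <- atan2(xs * yn - ys * xn, xs * xn + ys * yn)
    total <- total + round(sum(ang) / (2 * pi))
  }
  total %% 2 != 0
}
bf_sample_edges <- function(rings, pitch) {
  pts <- NULL
  for (r in rings) {
    xn <- c(r[-1, 1], r[1, 1]); yn <- c(r[-1, 2], r[1, 2])
    for (e in seq_len(nrow(r))) {
      len <- sqrt((xn[e] - r[e, 1])^2 + (yn[e] - r[e, 2])^2)
      t <- seq(0, 1, length.out = max(2, ceiling(len / pitch) + 1))
      pts <- rbind(pts, cbind(r[e, 1] + t * (xn[e] - r[e, 1]),
                              r[e, 2] + t * (yn[e] - r[e, 2])))
    }
  }
  pts
}
bf_in_region <- function(pts, loc_row) {
  xs <- pts[, 1] - loc_row$x; ys <- pts[, 2] - loc_row$y
  co <- cos(-loc_row$orientation); si <- sin(-loc_row$orientation)
  u <- (xs * co - ys * si) / loc_row$semi_radial
  v <- (xs * si + ys * co) / loc_row$semi_tangential
  u^2 + v^2 <= 1
}
bf_map_lesion <- function(poly, grid, vertical_halfwidth = 10, pitch = 0.01) {
  loc <- grid$locations
  edge_pts <- bf_sample_edges(poly$rings, pitch)
  hit <- vapply(seq_len(nrow(loc)), function(i) {
    row <- loc[i, ]
    if (any(bf_in_region(edge_pts, row))) return(TRUE)
    bf_winding_inside(row$x, row$y, poly$rings)
  }, TRUE)
  ids <- loc$id[hit & abs(loc$y) <= vertical_halfwidth + 1e-9 &
                  abs(loc$x) <= 10 + 1e-9]
  sort(ids)
}

# --- fixture builders ----------------------------------------------------
# exactly representable normative model (dyadic expectations) so that
# deviation arithmetic is exact on the quantized dB scale
exact_model <- function(expected = rep(16, 56), q = c(-4, -6, -8)) {
  structure(list(
    intercept = expected, slope = rep(0, 56), resid_sd = rep(1, 56),
    td_q = matrix(rep(q, each = 56), 56, 3,
                  dimnames = list(NULL, c("p5", "p2", "p1"))),
    pd_q = matrix(rep(q, each = 56), 56, 3,
                  dimnames = list(NULL, c("p5", "p2", "p1"))),
    age_range = c(40, 90), gh_prob = 0.85, n = 0L,
    gh_estimator = "85th percentile of TD"), class = "mp_normative")
}

circle_ring <- function(radius, center = c(0, 0), n = 64) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}

random_star_poly <- function(modality = "OCT", max_r = 6) {
  n <- 36
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- runif(1, 1, max_r) * exp(0.3 * (cos(th * sample(2:4, 1)) * rnorm(1) +
                                         sin(th * sample(2:4, 1)) * rnorm(1)))
  r <- pmin(r, 8)
  c0 <- runif(2, -3, 3)
  p <- lesion_polygon(cbind(c0[1] + r * cos(th), c0[2] + r * sin(th)),
                      modality)
  attr(p, "center") <- c0
  p
}

# quantized random field on the 2-dB staircase lattice
random_quantized_values <- function() {
  v <- sample(seq(0, 20, by = 2), 56, replace = TRUE)
  v
}
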