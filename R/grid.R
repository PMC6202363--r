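#' Default 56-location stimulus grid layout
#'
#' Coordinates (degrees of visual angle, fovea-centered, right-eye
#' convention: positive x temporal) of the packaged default layout. The
#' inner zone is a Cartesian offset lattice at 1.4 deg spacing (odd
#' multiples of 0.7 deg) restricted to eccentricities up to 4.2 deg and
#' reduced to the 28 lowest-eccentricity points; the tie at 4.08 deg is
#' broken axis-symmetrically in favour of the horizontally extended
#' quadruple. The outer zone is the analogous lattice at 2.8 deg spacing
#' (odd multiples of 1.4 deg) between 4.2 and 9.8 deg, which contains
#' exactly 28 points.
#'
#' @return A data.frame with columns `index` (0-based id), `x_deg`, `y_deg`.
#' @seealso [mp_grid()], [read_grid_layout()]
#' @export
#' @examples
#' layout <- default_grid_layout()
#' nrow(layout)  # 56
default_grid_layout <- function() {
  inner_ax <- seq(0.7, 4.9, by = 1.4)
  inner <- expand.grid(x = c(-rev(inner_ax), inner_ax),
                       y = c(-rev(inner_ax), inner_ax))
  inner$ecc <- sqrt(inner$x^2 + inner$y^2)
  inner <- inner[inner$ecc <= 4.2, ]
  inner <- inner[order(inner$ecc, -abs(inner$x), inner$y, inner$x), ][1:28, ]

  outer_ax <- seq(1.4, 9.8, by = 2.8)
  outer <- expand.grid(x = c(-rev(outer_ax), outer_ax),
                       y = c(-rev(outer_ax), outer_ax))
  outer$ecc <- sqrt(outer$x^2 + outer$y^2)
  outer <- outer[outer$ecc > 4.2 & outer$ecc <= 9.8, ]

  pts <- rbind(inner, outer)
  pts <- pts[order(pts$ecc, atan2(pts$y, pts$x)), ]
  data.frame(index = seq_len(nrow(pts)) - 1L, x_deg = pts$x, y_deg = pts$y,
             row.names = NULL)
}

#' Read a stimulus grid layout file
#'
#' @param path CSV file with header `index,x_deg,y_deg` and 56 rows of
#'   decimal degrees.
#' @return A layout data.frame suitable for [mp_grid()].
#' @export
read_grid_layout <- function(path) {
  lay <- utils::read.csv(path)
  need <- c("index", "x_deg", "y_deg")
  if (!all(need %in% names(lay)))
    stop("grid layout file must have columns: ", paste(need, collapse = ", "))
  lay[need]
}

#' Coverage region of a stimulus location
#'
#' Each location is credited with a circular or elliptical region: the
#' lesion is counted present at the location if it is visible within half
#' the inter-stimulus separation, i.e. a disc of radius 0.7 deg at
#' eccentricities below 5 deg and 1.4 deg between 5 and 10 deg. At the
#' transition between the two grid resolutions (eccentricities in
#' [4.2, 5] deg) the region is an ellipse with radial semi-axis 1.4 deg
#' and tangential semi-axis 0.7 deg, oriented along the fovea-location ray.
#'
#' @param x,y Location center in degrees (fovea-centered).
#' @return List with `center`, `shape` ("disc" or "ellipse"),
#'   `semi_radial`, `semi_tangential` (degrees) and `orientation`
#'   (radians, direction of the radial semi-axis).
#' @export
#' @examples
#' coverage_region(0.7, 0.7)$semi_radial   # 0.7
#' coverage_region(7, 0)$semi_radial       # 1.4
coverage_region <- function(x, y) {
  ecc <- sqrt(x^2 + y^2)
  if (ecc > 10)
    stop("location eccentricity ", format(ecc), " exceeds the 10 degree test domain")
  if (ecc >= 4.2 && ecc <= 5) {
    list(center = c(x, y), shape = "ellipse",
         semi_radial = 1.4, semi_tangential = 0.7,
         orientation = atan2(y, x))
  } else if (ecc < 5) {
    list(center = c(x, y), shape = "disc",
         semi_radial = 0.7, semi_tangential = 0.7, orientation = 0)
  } else {
    list(center = c(x, y), shape = "disc",
         semi_radial = 1.4, semi_tangential = 1.4, orientation = 0)
  }
}

#' Contiguity graph of a stimulus grid
#'
#' Two locations are contiguous when their distance does not exceed
#' `factor` times the nominal inter-stimulus spacing of the less eccentric
#' member (1.4 deg inner zone, 2.8 deg outer zone). The default factor 1.5
#' reproduces 8-connectivity (orthogonal plus diagonal neighbours) on the
#' regular sub-lattices while excluding skip-one pairs.
#'
#' @param locations Data.frame with columns `x`, `y`, `ecc`, `zone`.
#' @param factor Scale factor (> 1) applied to the nominal spacing.
#' @return Two-column integer matrix of 0-based location id pairs (i < j).
#' @export
build_adjacency <- function(locations, factor = 1.5) {
  if (!is.numeric(factor) || factor <= 1)
    stop("adjacency scale factor must be > 1")
  n <- nrow(locations)
  d <- as.matrix(stats::dist(locations[, c("x", "y")]))
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  i <- pairs[, 1]; j <- pairs[, 2]
  less_ecc_inner <- ifelse(locations$ecc[i] <= locations$ecc[j],
                           locations$zone[i], locations$zone[j]) == "inner"
  nominal <- ifelse(less_ecc_inner, 1.4, 2.8)
  keep <- d[pairs] <= factor * nominal
  cbind(i = i[keep] - 1L, j = j[keep] - 1L)
}

.validate_layout <- function(lay) {
  if (nrow(lay) != 56)
    stop("invalid grid layout: location count must be exactly 56 (got ",
         nrow(lay), ")")
  x <- lay$x_deg; y <- lay$y_deg
  ecc <- sqrt(x^2 + y^2)
  if (any(ecc > 9.8 + 1e-9))
    stop("invalid grid layout: eccentricity must not exceed 9.8 degrees")
  n_inner <- sum(ecc <= 4.2)
  if (n_inner != 28)
    stop("invalid grid layout: zone split must be 28 inner / 28 outer (got ",
         n_inner, " inner)")
  # 4-fold reflection symmetry about both axes
  key <- function(a, b) paste(round(a, 6), round(b, 6))
  have <- key(x, y)
  for (sgn in list(c(-1, 1), c(1, -1), c(-1, -1))) {
    if (!all(key(sgn[1] * x, sgn[2] * y) %in% have))
      stop("invalid grid layout: grid must be symmetric under reflection ",
           "about both axes")
  }
  # nearest-neighbour spacing within zones
  d <- as.matrix(stats::dist(cbind(x, y)))
  diag(d) <- Inf
  inner <- ecc <= 4.2
  if (any(d[inner, inner] < 1.4 - 1e-9))
    stop("invalid grid layout: inner-zone nearest-neighbour spacing below 1.4 degrees")
  if (any(d[!inner, !inner] < 2.8 - 1e-6))
    stop("invalid grid layout: outer-zone nearest-neighbour spacing below 2.8 degrees")
  invisible(lay)
}

#' Build a microperimetry stimulus grid
#'
#' Constructs the 56-location stimulus grid used throughout the pipeline:
#' location coordinates and eccentricities, inner/outer zone membership
#' (boundary 4.2 deg assigned inner), per-location coverage regions
#' ([coverage_region()]) and the contiguity graph ([build_adjacency()]).
#' The layout must satisfy the structural invariants of the instrument
#' grid: exactly 56 locations, 28 per zone, reflection symmetry about both
#' axes, and zone-wise minimum spacing; violations are rejected with the
#' violated invariant named.
#'
#' @param layout Optional layout data.frame (`index`, `x_deg`, `y_deg`;
#'   56 rows). Defaults to [default_grid_layout()].
#' @param adjacency_factor Scale factor for [build_adjacency()].
#' @return An object of class `mp_grid`: list with `locations` (data.frame
#'   `id`, `x`, `y`, `ecc`, `zone`, `shape`, `semi_radial`,
#'   `semi_tangential`, `orientation`, `radius_nominal`), `adjacency`
#'   (0-based id pair matrix) and `adjacency_factor`.
#' @export
#' @examples
#' g <- mp_grid()
#' table(g$locations$zone)
mp_grid <- function(layout = NULL, adjacency_factor = 1.5) {
  if (is.null(layout)) layout <- default_grid_layout()
  .validate_layout(layout)
  x <- layout$x_deg; y <- layout$y_deg
  ecc <- sqrt(x^2 + y^2)
  zone <- ifelse(ecc <= 4.2, "inner", "outer")
  cov <- lapply(seq_along(x), function(i) coverage_region(x[i], y[i]))
  loc <- data.frame(
    id = seq_along(x) - 1L, x = x, y = y, ecc = ecc, zone = zone,
    shape = vapply(cov, `[[`, "", "shape"),
    semi_radial = vapply(cov, `[[`, 0, "semi_radial"),
    semi_tangential = vapply(cov, `[[`, 0, "semi_tangential"),
    orientation = vapply(cov, `[[`, 0, "orientation"),
    radius_nominal = ifelse(zone == "inner", 0.7, 1.4)
  )
  structure(list(locations = loc,
                 adjacency = build_adjacency(loc, adjacency_factor),
                 adjacency_factor = adjacency_factor),
            class = "mp_grid")
}

#' @export
print.mp_grid <- function(x, ...) {
  loc <- x$locations
  cat("Microperimetry stimulus grid:", nrow(loc), "locations (",
      sum(loc$zone == "inner"), "inner /", sum(loc$zone == "outer"),
      "outer )\n")
  cat("  eccentricity range:", round(min(loc$ecc), 2), "-",
      round(max(loc$ecc), 2), "deg;",
      sum(loc$shape == "ellipse"), "transition locations with elliptical coverage\n")
  cat("  contiguity edges:", nrow(x$adjacency),
      "(factor", x$adjacency_factor, ")\n")
  invisible(x)
}

#' @export
plot.mp_grid <- function(x, show_coverage = TRUE, ...) {
  loc <- x$locations
  plot(loc$x, loc$y, asp = 1, pch = 3,
       col = ifelse(loc$zone == "inner", "black", "grey40"),
       xlab = "x (deg)", ylab = "y (deg)",
       main = "Stimulus grid and coverage regions", ...)
  if (show_coverage) {
    th <- seq(0, 2 * pi, length.out = 73)
    for (i in seq_len(nrow(loc))) {
      a <- loc$semi_radial[i]; b <- loc$semi_tangential[i]
      o <- loc$orientation[i]
      ex <- a * cos(th) * cos(o) - b * sin(th) * sin(o) + loc$x[i]
      ey <- a * cos(th) * sin(o) + b * sin(th) * cos(o) + loc$y[i]
      graphics::polygon(ex, ey, border = grDevices::gray(0.7))
    }
  }
  invisible(x)
}

# Largest-empty-disc radius over a sampled quadrant (grid is 4-fold
# symmetric, so sampling x,y >= 0 suffices for the maximum). The tested
# extent is the union of per-location sampling catchments (half the cell
# diagonal); the gap at a point is its distance to the union of the
# nominal coverage discs (0.7 / 1.4 deg by zone).
.uncovered_radius <- function(loc, pitch, quadrant = TRUE) {
  catch <- ifelse(loc$zone == "inner", 1.4, 2.8) * sqrt(2) / 2
  rad <- loc$radius_nominal
  lim <- max(abs(c(loc$x, loc$y))) + max(catch)
  lo <- if (quadrant) 0 else -lim
  gx <- seq(lo, lim, by = pitch)
  dx2 <- outer(gx, loc$x, "-")^2
  best <- 0
  for (yy in seq(lo, lim, by = pitch)) {
    dy2 <- (yy - loc$y)^2
    d <- sqrt(dx2 + rep(dy2, each = length(gx)))
    in_extent <- gapmin <- NULL
    for (k in seq_len(ncol(d))) {
      in_k <- d[, k] <= catch[k]
      gap_k <- d[, k] - rad[k]
      if (k == 1) { in_extent <- in_k; gapmin <- gap_k }
      else { in_extent <- in_extent | in_k; gapmin <- pmin(gapmin, gap_k) }
    }
    if (any(in_extent)) best <- max(best, gapmin[in_extent], 0)
  }
  best
}

#' Maximum uncovered inter-stimulus diameter
#'
#' Diameter of the largest disc that fits in the tested extent of the grid
#' without touching any location's nominal coverage disc (0.7 deg inner
#' zone, 1.4 deg outer zone) -- the largest focal defect the sampling
#' scheme could miss entirely. The tested extent is the union of the
#' per-location sampling catchments (radius equal to half the cell
#' diagonal of the zone's nominal spacing); within it, the gap at a
#' sampled point is its distance to the union of coverage discs,
#' `min_i(dist_i - radius_i)` clamped at zero, and the result is twice the
#' maximum over a dense sampling.
#'
#' @param grid An [mp_grid()].
#' @param pitch Sampling pitch in degrees (default 0.01).
#' @return Diameter in degrees (unrounded).
#' @export
#' @examples
#' \donttest{
#' round(max_uncovered_diameter(mp_grid()), 1)  # 1.2
#' }
max_uncovered_diameter <- function(grid, pitch = 0.01) {
  stopifnot(inherits(grid, "mp_grid"))
  2 * .uncovered_radius(grid$locations, pitch)
}
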