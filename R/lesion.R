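#' Construct a lesion boundary polygon
#'
#' Represents a delineated lesion boundary (ICGA or SD-OCT) as one or more
#' simple closed rings in degrees of visual angle, fovea-centered. Rings
#' are interpreted with even-odd parity: a ring wound opposite to, and
#' contained in, another ring is a hole. Vertices must lie within
#' +-15 deg on both axes and every ring must be simple
#' (non-self-intersecting); violations are rejected with the offending
#' ring identified.
#'
#' @param rings A single n x 2 matrix or a list of such matrices
#'   (columns x, y in degrees; a repeated closing vertex is dropped).
#'   An empty list gives an empty polygon.
#' @param modality One of `"ICGA"`, `"OCT"`.
#' @return Object of class `lesion_polygon`.
#' @export
#' @examples
#' sq <- cbind(c(-1, 1, 1, -1), c(-1, -1, 1, 1))
#' p <- lesion_polygon(sq, "ICGA")
#' polygon_area_deg2(p)  # 4
lesion_polygon <- function(rings, modality = c("ICGA", "OCT")) {
  modality <- match.arg(modality)
  if (is.matrix(rings) || is.data.frame(rings)) rings <- list(as.matrix(rings))
  rings <- lapply(rings, .close_ring)
  for (k in seq_along(rings)) {
    r <- rings[[k]]
    if (!is.numeric(r) || ncol(r) != 2 || nrow(r) < 3)
      stop("ring ", k, " is invalid: need at least 3 two-column numeric vertices")
    if (any(!is.finite(r)))
      stop("ring ", k, " is invalid: non-finite vertex coordinates")
    if (any(abs(r) > 15))
      stop("ring ", k, " is invalid: vertices must lie within +-15 degrees")
    if (!.ring_is_simple(r))
      stop("ring ", k, " is invalid: ring is self-intersecting (not simple)")
  }
  structure(list(rings = rings, modality = modality),
            class = "lesion_polygon")
}

#' @export
print.lesion_polygon <- function(x, ...) {
  cat("Lesion polygon [", x$modality, "]: ", length(x$rings), " ring(s), area ",
      round(polygon_area_deg2(x), 2), " deg^2 (",
      round(polygon_area_mm2(x), 2), " mm^2 at 0.288 mm/deg)\n", sep = "")
  invisible(x)
}

#' Polygon area in square degrees
#'
#' Shoelace area summed over rings with their winding sign, absolute value
#' returned, so holes wound opposite to their outer ring subtract.
#'
#' @param polygon A [lesion_polygon()].
#' @return Area in deg^2.
#' @export
polygon_area_deg2 <- function(polygon) {
  stopifnot(inherits(polygon, "lesion_polygon"))
  if (length(polygon$rings) == 0) return(0)
  abs(sum(vapply(polygon$rings, .ring_signed_area, 0)))
}

#' Polygon area in square millimetres
#'
#' Converts the shoelace area to retinal mm^2 with a fixed linear scale
#' (default 0.288 mm per degree, schematic emmetropic eye). Per-eye axial
#' length modelling is deliberately out of scope; the scale is exposed as
#' a parameter instead.
#'
#' @inheritParams polygon_area_deg2
#' @param mm_per_degree Linear scale (> 0).
#' @return Area in mm^2.
#' @export
#' @examples
#' sq <- lesion_polygon(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)), "ICGA")
#' polygon_area_mm2(sq)  # 0.082944
polygon_area_mm2 <- function(polygon, mm_per_degree = 0.288) {
  if (!is.numeric(mm_per_degree) || mm_per_degree <= 0)
    stop("mm_per_degree must be positive")
  polygon_area_deg2(polygon) * mm_per_degree^2
}

#' Restrict an abnormality set to the analysed extent
#'
#' The common analysis area is constrained to 10 deg horizontally (the
#' grid's extent) and to either 5 or 10 deg vertically, depending on the
#' vertical extent of the SD-OCT volume scan. Idempotent.
#'
#' @param members Integer vector of 0-based location ids.
#' @param grid An [mp_grid()].
#' @param vertical_halfwidth 5 or 10 (degrees).
#' @param horizontal_halfwidth Fixed at 10 degrees.
#' @return Filtered sorted id vector.
#' @export
clip_to_extent <- function(members, grid, vertical_halfwidth = 10,
                           horizontal_halfwidth = 10) {
  if (!vertical_halfwidth %in% c(5, 10))
    stop("vertical_halfwidth must be 5 or 10 degrees")
  loc <- grid$locations
  keep <- loc$id %in% members &
    abs(loc$x) <= horizontal_halfwidth + 1e-9 &
    abs(loc$y) <= vertical_halfwidth + 1e-9
  sort(loc$id[keep])
}

#' Project a lesion polygon onto the stimulus grid
#'
#' A location is counted abnormal when the lesion is visible within half
#' the inter-stimulus separation of the grid, implemented as geometric
#' intersection (positive area or boundary contact) between the lesion
#' polygon and the location's coverage region ([coverage_region()]); the
#' alternative, stricter predicate requiring the lesion to cover the
#' location center is available via `rule = "contains_center"`. The result
#' is clipped to the analysed extent ([clip_to_extent()]).
#'
#' @param polygon A [lesion_polygon()].
#' @param grid An [mp_grid()].
#' @param vertical_halfwidth Vertical extent constraint (5 or 10 deg).
#' @param rule Presence predicate: `"intersect"` (default) or
#'   `"contains_center"`.
#' @param tol Intersection tolerance in region-frame units.
#' @return Sorted integer vector of 0-based location ids.
#' @export
#' @examples
#' g <- mp_grid()
#' disc <- lesion_polygon(
#'   cbind(2 * cos(seq(0, 2 * pi, length.out = 65)[-65]),
#'         2 * sin(seq(0, 2 * pi, length.out = 65)[-65])), "OCT")
#' length(map_lesion(disc, g))
map_lesion <- function(polygon, grid, vertical_halfwidth = 10,
                       rule = c("intersect", "contains_center"),
                       tol = 1e-9) {
  stopifnot(inherits(polygon, "lesion_polygon"), inherits(grid, "mp_grid"))
  rule <- match.arg(rule)
  rings <- polygon$rings
  if (length(rings) == 0) return(integer(0))
  loc <- grid$locations
  hit <- logical(nrow(loc))
  for (i in seq_len(nrow(loc))) {
    if (rule == "intersect") {
      hit[i] <- .region_intersects(rings, c(loc$x[i], loc$y[i]),
                                   loc$semi_radial[i], loc$semi_tangential[i],
                                   loc$orientation[i], tol = tol)
    } else {
      hit[i] <- .dist_point_region(loc$x[i], loc$y[i], rings) <= tol
    }
  }
  clip_to_extent(loc$id[hit], grid, vertical_halfwidth)
}
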