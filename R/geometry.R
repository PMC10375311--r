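# Planar geometry primitives on geographic lon/lat coordinates.
#
# Geometries are stored as "multipolygon lists": a geometry is a list of
# polygons; a polygon is a list of rings; a ring is an n x 2 numeric matrix of
# (lon, lat) vertices. Rings may be closed (first vertex repeated last) or
# open; all primitives tolerate both. Containment uses the even-odd (ray
# casting) rule, so any ring after the first in a polygon acts as a hole
# automatically. All computation is planar in raw degrees: at the spatial
# scales of ZCTA/county analysis, containment is topological and needs no
# projection.

# Drop a repeated closing vertex so each ring edge is counted once.
ring_open <- function(ring) {
  n <- nrow(ring)
  if (n >= 2 && all(ring[1, ] == ring[n, ])) ring[-n, , drop = FALSE] else ring
}

# Shoelace signed area of one ring (degrees^2).
ring_signed_area <- function(ring) {
  r <- ring_open(ring)
  n <- nrow(r)
  if (n < 3) return(0)
  x <- r[, 1]; y <- r[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Planar area of spatial units
#'
#' Computes the shoelace-formula area of each unit's geometry in squared
#' degrees. For a multipolygon the parts contribute additively; rings beyond
#' the first within one polygon are holes and subtract. Intended for
#' validation and synthetic-scenario checks, not for population-weighted
#' analysis (no projection is applied).
#'
#' @param units A spatial-unit tibble from [read_boundaries()] or
#'   [gen_units()].
#' @return Numeric vector of areas (degrees squared), one per unit.
#' @export
unit_area <- function(units) {
  vapply(units$geometry, function(geom) {
    sum(vapply(geom, function(poly) {
      areas <- vapply(poly, function(r) abs(ring_signed_area(r)), numeric(1))
      if (length(areas) == 0) 0 else areas[1] - sum(areas[-1])
    }, numeric(1)))
  }, numeric(1))
}

# Bounding box (xmin, ymin, xmax, ymax) of a multipolygon list.
geom_bbox <- function(geom) {
  xs <- unlist(lapply(geom, function(p) lapply(p, function(r) r[, 1])))
  ys <- unlist(lapply(geom, function(p) lapply(p, function(r) r[, 2])))
  c(min(xs), min(ys), max(xs), max(ys))
}

geom_centroid <- function(geom) {
  # Area-weighted centroid of the outer rings; adequate for label placement
  # and kernel evaluation, not a surveying-grade centroid.
  cx <- 0; cy <- 0; atot <- 0
  for (poly in geom) {
    r <- ring_open(poly[[1]])
    n <- nrow(r)
    if (n < 3) next
    x <- r[, 1]; y <- r[, 2]
    xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
    cross <- x * yn - xn * y
    a <- sum(cross) / 2
    if (abs(a) < .Machine$double.eps) next
    cx <- cx + sum((x + xn) * cross) / 6
    cy <- cy + sum((y + yn) * cross) / 6
    atot <- atot + a
  }
  if (atot == 0) {
    bb <- geom_bbox(geom)
    return(c((bb[1] + bb[3]) / 2, (bb[2] + bb[4]) / 2))
  }
  c(cx / atot, cy / atot)
}

# Exact-ish point-on-segment test (tolerance absorbs double rounding only).
point_on_segment <- function(px, py, x1, y1, x2, y2, eps = 1e-12) {
  cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
  scale <- max(abs(c(x1, y1, x2, y2, px, py, 1)))
  if (abs(cross) > eps * scale) return(FALSE)
  px >= min(x1, x2) - eps && px <= max(x1, x2) + eps &&
    py >= min(y1, y2) - eps && py <= max(y1, y2) + eps
}

# Even-odd ray-casting containment, vectorized over points. Returns TRUE for
# interior points and (by convention) for points exactly on a ring boundary;
# boundary ownership between adjacent units is resolved by the caller's
# deterministic unit ordering. The half-open rule on each edge's vertical
# extent avoids double counting at vertices, and toggling across all rings
# makes holes (rings after the first) subtract automatically.
points_in_geom <- function(px, py, geom, eps = 1e-12) {
  n <- length(px)
  inside <- rep(FALSE, n)
  on_edge <- rep(FALSE, n)
  for (poly in geom) {
    for (ring in poly) {
      r <- ring_open(ring)
      m <- nrow(r)
      if (m < 3) next
      j <- m
      for (i in seq_len(m)) {
        x1 <- r[j, 1]; y1 <- r[j, 2]
        x2 <- r[i, 1]; y2 <- r[i, 2]
        scale <- max(abs(c(x1, y1, x2, y2, 1)))
        cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
        on_edge <- on_edge |
          (abs(cross) <= eps * scale &
             px >= min(x1, x2) - eps & px <= max(x1, x2) + eps &
             py >= min(y1, y2) - eps & py <= max(y1, y2) + eps)
        crossing <- (y1 > py) != (y2 > py)
        idx <- which(crossing)
        if (length(idx) > 0) {
          xint <- x1 + (py[idx] - y1) / (y2 - y1) * (x2 - x1)
          hit <- idx[px[idx] < xint]
          inside[hit] <- !inside[hit]
        }
        j <- i
      }
    }
  }
  inside | on_edge
}

# Scalar convenience wrapper.
point_in_geom <- function(px, py, geom) {
  points_in_geom(px, py, geom)[1]
}
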