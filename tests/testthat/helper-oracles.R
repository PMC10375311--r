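# Independent oracles and fixture builders. These are deliberately written
# as plain, slow reference implementations, separate from the package's
# code paths, so agreement is evidence rather than tautology.

# Brute-force even-odd ray casting for a single point against one closed
# ring given as a data.frame of x/y vertices (first vertex not repeated).
oracle_point_in_ring <- function(px, py, xs, ys) {
  n <- length(xs)
  crossings <- 0
  for (i in seq_len(n)) {
    j <- if (i == 1) n else i - 1
    yi <- ys[i]; yj <- ys[j]
    if ((yi > py) != (yj > py)) {
      x_at <- xs[j] + (py - yj) / (yi - yj) * (xs[i] - xs[j])
      if (px < x_at) crossings <- crossings + 1
    }
  }
  crossings %% 2 == 1
}

# Counts points per axis-aligned grid cell by direct ray casting against
# each cell's ring.
oracle_grid_counts <- function(px, py, rows, cols, cell, ox, oy) {
  counts <- matrix(0L, rows, cols)
  for (p in seq_along(px)) {
    for (i in seq_len(rows)) {
      for (j in seq_len(cols)) {
        x0 <- ox + (j - 1) * cell
        y0 <- oy + (i - 1) * cell
        if (oracle_point_in_ring(px[p], py[p],
                                 c(x0, x0 + cell, x0 + cell, x0),
                                 c(y0, y0, y0 + cell, y0 + cell))) {
          counts[i, j] <- counts[i, j] + 1L
        }
      }
    }
  }
  counts
}

# Shoelace area of a ring given as vertex vectors (no repeated closure).
oracle_shoelace <- function(xs, ys) {
  n <- length(xs)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    s <- s + xs[i] * ys[j] - xs[j] * ys[i]
  }
  abs(s) / 2
}

# Sort-based summary with quartiles linearly interpolated between order
# statistics at positions 0.25/0.75 of (n - 1) (zero-based).
oracle_summary <- function(x) {
  s <- sort(x)
  n <- length(s)
  interp <- function(p) {
    h <- p * (n - 1)
    lo <- floor(h) + 1
    hi <- ceiling(h) + 1
    s[lo] + (h - floor(h)) * (s[hi] - s[lo])
  }
  list(mean = sum(s) / n, q1 = interp(0.25), median = interp(0.5),
       q3 = interp(0.75))
}

translate_geom_for_test <- function(geom, dx, dy) {
  lapply(geom, function(poly) lapply(poly, function(r) {
    cbind(r[, 1] + dx, r[, 2] + dy)
  }))
}

# A square spatial unit built by hand (not via gen_units).
make_square_unit <- function(unit_id, x0, y0, side = 1, level = "zcta",
                             region_id = "R1") {
  ring <- rbind(c(x0, y0), c(x0 + side, y0), c(x0 + side, y0 + side),
                c(x0, y0 + side), c(x0, y0))
  tibble::tibble(unit_id = unit_id, level = level, region_id = region_id,
                 geometry = list(list(list(ring))))
}

make_square_grid <- function(rows, cols, cell = 1, ox = 0, oy = 0,
                             region_id = "R1") {
  do.call(rbind, lapply(seq_len(rows), function(i) {
    do.call(rbind, lapply(seq_len(cols), function(j) {
      make_square_unit(sprintf("r%dc%d", i, j), ox + (j - 1) * cell,
                       oy + (i - 1) * cell, side = cell,
                       region_id = region_id)
    }))
  }))
}

make_facilities <- function(lon, lat, kind = "pharmacy",
                            ids = sprintf("f%d", seq_along(lon))) {
  tibble::tibble(facility_id = ids, kind = rep_len(kind, length(lon)),
                 lon = lon, lat = lat)
}

make_need <- function(unit_id, incidence, suppressed = FALSE) {
  tibble::tibble(unit_id = unit_id,
                 incidence_per_100k = incidence,
                 suppressed = rep_len(suppressed, length(unit_id)))
}

# Minimal hand-written GeoJSON for IO tests (independent of write_boundaries).
geojson_square_feature <- function(unit_id, x0, y0, side = 1,
                                   level = "zcta", region_id = "R1",
                                   drop_property = NULL) {
  props <- list(unit_id = unit_id, level = level, region_id = region_id)
  if (!is.null(drop_property)) props[[drop_property]] <- NULL
  prop_json <- paste(sprintf('"%s": "%s"', names(props), unlist(props)),
                     collapse = ", ")
  coords <- sprintf("[[%s]]", paste(
    sprintf("[%g, %g]",
            c(x0, x0 + side, x0 + side, x0, x0),
            c(y0, y0, y0 + side, y0 + side, y0)),
    collapse = ", "))
  sprintf('{"type": "Feature", "properties": {%s}, "geometry": {"type": "Polygon", "coordinates": %s}}',
          prop_json, coords)
}

geojson_collection <- function(features) {
  sprintf('{"type": "FeatureCollection", "features": [%s]}',
          paste(features, collapse = ",\n"))
}
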