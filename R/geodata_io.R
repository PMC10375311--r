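# Ingest and validation: boundary GeoJSON, facility tables, need tables, and
# the offline gazetteer used in place of a live geocoding service.

FACILITY_KINDS <- c("prep_prescriber", "pharmacy")
UNIT_LEVELS <- c("zcta", "county")

#' Read spatial-unit boundaries from GeoJSON
#'
#' Parses an RFC 7946 GeoJSON FeatureCollection of Polygon/MultiPolygon
#' features into a spatial-unit tibble. Each feature must carry `unit_id`,
#' `level` (`"zcta"` or `"county"`) and `region_id` properties; coordinates
#' are geographic lon/lat (WGS84, lon-lat order).
#'
#' @param path Path to a GeoJSON file.
#' @return A tibble with columns `unit_id`, `level`, `region_id` and a
#'   `geometry` list-column (each element a list of polygons, each polygon a
#'   list of rings, each ring an n x 2 lon/lat matrix).
#' @export
#' @examples
#' gj <- tempfile(fileext = ".geojson")
#' units <- gen_units(scenario_config(grid_rows = 2, grid_cols = 2))
#' write_boundaries(units, gj)
#' read_boundaries(gj)
read_boundaries <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    abort("boundary file is not a GeoJSON FeatureCollection",
          class = "pfnr_io_error")
  }
  feats <- gj$features
  if (length(feats) == 0) {
    abort("boundary FeatureCollection contains no features",
          class = "pfnr_io_error")
  }
  rows <- purrr::imap(feats, function(f, i) {
    props <- f$properties
    for (key in c("unit_id", "level", "region_id")) {
      if (is.null(props[[key]])) {
        abort(sprintf("feature %d is missing required property '%s'", i, key),
              class = "pfnr_io_error")
      }
    }
    level <- as.character(props$level)
    if (!level %in% UNIT_LEVELS) {
      abort(sprintf("feature %d ('%s'): level must be one of %s, got '%s'",
                    i, props$unit_id, paste(UNIT_LEVELS, collapse = "/"),
                    level),
            class = "pfnr_io_error")
    }
    geom <- parse_geojson_geometry(f$geometry, i)
    list(unit_id = as.character(props$unit_id), level = level,
         region_id = as.character(props$region_id), geometry = geom)
  })
  units <- tibble(
    unit_id = vapply(rows, `[[`, character(1), "unit_id"),
    level = vapply(rows, `[[`, character(1), "level"),
    region_id = vapply(rows, `[[`, character(1), "region_id"),
    geometry = lapply(rows, `[[`, "geometry")
  )
  validate_units(units)
  units
}

parse_geojson_geometry <- function(g, feature_index) {
  if (is.null(g) || is.null(g$type)) {
    abort(sprintf("feature %d has no geometry", feature_index),
          class = "pfnr_io_error")
  }
  to_ring <- function(coords) {
    m <- do.call(rbind, lapply(coords, function(pt) {
      c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))
    }))
    if (!all(is.finite(m))) {
      abort(sprintf("feature %d has non-finite coordinates", feature_index),
            class = "pfnr_io_error")
    }
    m
  }
  polys <- switch(
    g$type,
    Polygon = list(lapply(g$coordinates, to_ring)),
    MultiPolygon = lapply(g$coordinates, function(p) lapply(p, to_ring)),
    abort(sprintf("feature %d: unsupported geometry type '%s'",
                  feature_index, g$type), class = "pfnr_io_error")
  )
  n_vert <- sum(unlist(lapply(polys, function(p) lapply(p, nrow))))
  if (n_vert < 3) {
    abort(sprintf("feature %d has an empty or degenerate geometry",
                  feature_index), class = "pfnr_io_error")
  }
  polys
}

validate_units <- function(units) {
  dup <- units$unit_id[duplicated(units$unit_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate unit_id(s): %s",
                  paste(unique(dup), collapse = ", ")),
          class = "pfnr_io_error")
  }
  mixed <- tapply(units$level, units$region_id,
                  function(l) length(unique(l)) > 1)
  if (any(mixed)) {
    abort(sprintf("region(s) %s mix zcta and county units",
                  paste(names(mixed)[mixed], collapse = ", ")),
          class = "pfnr_io_error")
  }
  invisible(units)
}

#' Write spatial units to GeoJSON
#'
#' Inverse of [read_boundaries()]; rings are closed on output as RFC 7946
#' requires.
#'
#' @param units Spatial-unit tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_boundaries <- function(units, path) {
  close_ring <- function(r) {
    if (!all(r[1, ] == r[nrow(r), ])) r <- rbind(r, r[1, ])
    lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
  }
  feats <- lapply(seq_len(nrow(units)), function(i) {
    geom <- units$geometry[[i]]
    coords <- lapply(geom, function(poly) lapply(poly, close_ring))
    gtype <- if (length(geom) == 1) "Polygon" else "MultiPolygon"
    if (gtype == "Polygon") coords <- coords[[1]]
    list(type = "Feature",
         properties = list(unit_id = units$unit_id[i],
                           level = units$level[i],
                           region_id = units$region_id[i]),
         geometry = list(type = gtype, coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Build an offline gazetteer
#'
#' A gazetteer is a deterministic lookup from an address key to lon/lat
#' coordinates, standing in for a live geocoding service so that runs are
#' reproducible and offline. Unknown keys are explicit misses, never silent
#' defaults.
#'
#' @param keys Character vector of address keys.
#' @param lon,lat Numeric coordinate vectors, same length as `keys`.
#' @return An object of class `pfnr_gazetteer`.
#' @export
gazetteer <- function(keys, lon, lat) {
  stopifnot(length(keys) == length(lon), length(keys) == length(lat))
  if (anyDuplicated(keys)) {
    abort("gazetteer keys must be unique", class = "pfnr_io_error")
  }
  structure(list(keys = as.character(keys), lon = as.numeric(lon),
                 lat = as.numeric(lat)),
            class = "pfnr_gazetteer")
}

#' Resolve address keys through a gazetteer
#'
#' @param gaz A [gazetteer()].
#' @param keys Character vector of address keys.
#' @return A tibble with `key`, `lon`, `lat`, `hit` (logical); misses have
#'   `NA` coordinates and `hit = FALSE`.
#' @export
gazetteer_lookup <- function(gaz, keys) {
  stopifnot(inherits(gaz, "pfnr_gazetteer"))
  idx <- match(keys, gaz$keys)
  tibble(key = as.character(keys),
         lon = gaz$lon[idx], lat = gaz$lat[idx],
         hit = !is.na(idx))
}

#' Read a facility table
#'
#' Reads a delimited facility table (default CSV with header) of PrEP
#' prescribing locations and pharmacies. Rows either carry lon/lat
#' coordinates directly or an `address_key` resolved through an offline
#' [gazetteer()]. Gazetteer misses are dropped from the returned records and
#' tallied in the `misses` attribute (and a warning), mirroring how geocoding
#' failures reduce downstream counts.
#'
#' @param path Path to the delimited file.
#' @param gaz Optional [gazetteer()] for `address_key` resolution.
#' @param sep Field delimiter, default `","`.
#' @param columns Named character vector mapping the canonical names
#'   `facility_id`, `kind`, `lon`, `lat`, `address_key` to header names in
#'   the file; defaults to identical names.
#' @return A tibble with columns `facility_id`, `kind`, `lon`, `lat`, and
#'   attributes `misses` (character vector of unresolved keys) and `n_input`
#'   (input row count).
#' @export
read_facilities <- function(path, gaz = NULL, sep = ",",
                            columns = c(facility_id = "facility_id",
                                        kind = "kind", lon = "lon",
                                        lat = "lat",
                                        address_key = "address_key")) {
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  colClasses = "character")
  need_cols <- columns[c("facility_id", "kind")]
  missing_cols <- setdiff(need_cols, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("facility table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "pfnr_io_error")
  }
  get_col <- function(canon) {
    nm <- columns[[canon]]
    if (!is.null(nm) && nm %in% names(raw)) raw[[nm]] else
      rep(NA_character_, nrow(raw))
  }
  fid <- get_col("facility_id")
  kind <- get_col("kind")
  lon <- suppressWarnings(as.numeric(get_col("lon")))
  lat <- suppressWarnings(as.numeric(get_col("lat")))
  akey <- get_col("address_key")
  akey[!is.na(akey) & akey == ""] <- NA_character_

  bad_kind <- !kind %in% FACILITY_KINDS
  if (any(bad_kind)) {
    abort(sprintf("unknown facility kind '%s' (row %d); expected %s",
                  kind[which(bad_kind)[1]], which(bad_kind)[1],
                  paste(FACILITY_KINDS, collapse = " or ")),
          class = "pfnr_io_error")
  }
  has_coord <- !is.na(lon) & !is.na(lat)
  has_key <- !is.na(akey)
  orphan <- !has_coord & !has_key
  if (any(orphan)) {
    abort(sprintf("facility '%s' (row %d) has neither coordinates nor an address_key",
                  fid[which(orphan)[1]], which(orphan)[1]),
          class = "pfnr_io_error")
  }

  misses <- character(0)
  to_resolve <- has_key & !has_coord
  if (any(to_resolve)) {
    if (is.null(gaz)) {
      abort("facility table contains address keys but no gazetteer was supplied",
            class = "pfnr_io_error")
    }
    res <- gazetteer_lookup(gaz, akey[to_resolve])
    lon[to_resolve] <- res$lon
    lat[to_resolve] <- res$lat
    misses <- res$key[!res$hit]
  }
  keep <- !is.na(lon) & !is.na(lat)
  if (length(misses) > 0) {
    warn(sprintf("%d facility address key(s) not found in gazetteer; excluded: %s",
                 length(misses), paste(head(misses, 5), collapse = ", ")))
  }
  out_rows <- which(keep)
  bad_range <- lon[out_rows] < -180 | lon[out_rows] > 180 |
    lat[out_rows] < -90 | lat[out_rows] > 90
  if (any(bad_range)) {
    abort(sprintf("facility '%s' has coordinates outside lon [-180,180] / lat [-90,90]",
                  fid[out_rows][which(bad_range)[1]]),
          class = "pfnr_io_error")
  }
  out <- tibble(facility_id = fid[keep], kind = kind[keep],
                lon = lon[keep], lat = lat[keep])
  attr(out, "misses") <- misses
  attr(out, "n_input") <- nrow(raw)
  out
}

#' Write a facility table
#'
#' Inverse of [read_facilities()] for resolved records; round-trips exactly.
#'
#' @param facilities Facility tibble with `facility_id`, `kind`, `lon`, `lat`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_facilities <- function(facilities, path) {
  df <- data.frame(facility_id = facilities$facility_id,
                   kind = facilities$kind,
                   lon = format(facilities$lon, digits = 17, trim = TRUE,
                                scientific = FALSE),
                   lat = format(facilities$lat, digits = 17, trim = TRUE,
                                scientific = FALSE),
                   address_key = "")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a need table of 5-year HIV incidence
#'
#' Reads a delimited table keyed by `unit_id` with 5-year HIV incidence per
#' 100 000 persons. Suppressed small-area values (not released by the data
#' provider) are encoded by a designated token and carried as explicitly
#' suppressed records — never coerced to zero, since zero measured incidence
#' and unreleased incidence are different epidemiological statements.
#'
#' @param path Path to the delimited file.
#' @param suppressed_token Token marking a suppressed value, default `"NA"`.
#' @param sep Field delimiter, default `","`.
#' @param columns Named mapping for `unit_id` and `incidence_per_100k`.
#' @return A tibble with `unit_id`, `incidence_per_100k` (`NA` when
#'   suppressed), and logical `suppressed`.
#' @export
read_need_table <- function(path, suppressed_token = "NA", sep = ",",
                            columns = c(unit_id = "unit_id",
                                        incidence_per_100k = "incidence_per_100k")) {
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  colClasses = "character", na.strings = NULL)
  missing_cols <- setdiff(unname(columns), names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("need table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "pfnr_io_error")
  }
  uid <- raw[[columns[["unit_id"]]]]
  val_raw <- raw[[columns[["incidence_per_100k"]]]]
  dup <- uid[duplicated(uid)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate unit_id(s) in need table: %s",
                  paste(unique(dup), collapse = ", ")),
          class = "pfnr_io_error")
  }
  suppressed <- val_raw == suppressed_token
  val <- rep(NA_real_, length(val_raw))
  val[!suppressed] <- suppressWarnings(as.numeric(val_raw[!suppressed]))
  unparsed <- !suppressed & is.na(val)
  if (any(unparsed)) {
    abort(sprintf("unit '%s': incidence value '%s' is neither numeric nor the suppression token '%s'",
                  uid[which(unparsed)[1]], val_raw[which(unparsed)[1]],
                  suppressed_token),
          class = "pfnr_io_error")
  }
  neg <- !suppressed & val < 0
  if (any(neg)) {
    abort(sprintf("unit '%s' has negative incidence %s",
                  uid[which(neg)[1]], val_raw[which(neg)[1]]),
          class = "pfnr_io_error")
  }
  tibble(unit_id = uid, incidence_per_100k = val, suppressed = suppressed)
}

#' Write a need table
#'
#' @param need Need tibble from [read_need_table()] or [gen_incidence()].
#' @param path Output path.
#' @param suppressed_token Token written for suppressed records.
#' @return `path`, invisibly.
#' @export
write_need_table <- function(need, path, suppressed_token = "NA") {
  val <- ifelse(need$suppressed, suppressed_token,
                format(need$incidence_per_100k, digits = 17, trim = TRUE,
                       scientific = FALSE))
  df <- data.frame(unit_id = need$unit_id, incidence_per_100k = val)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
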