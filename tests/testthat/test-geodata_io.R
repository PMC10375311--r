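test_that("boundary GeoJSON parses into one unit per feature", {
  gj <- tempfile(fileext = ".geojson")
  writeLines(geojson_collection(c(
    geojson_square_feature("u1", 0, 0), geojson_square_feature("u2", 1, 0),
    geojson_square_feature("u3", 0, 1), geojson_square_feature("u4", 1, 1)
  )), gj)
  units <- read_boundaries(gj)
  expect_equal(nrow(units), 4)
  expect_setequal(units$unit_id, c("u1", "u2", "u3", "u4"))
  expect_true(all(units$level == "zcta"))
  expect_equal(unit_area(units), rep(1, 4))
})

test_that("boundary validation names the offending feature and rejects bad inputs", {
  gj <- tempfile(fileext = ".geojson")
  writeLines(geojson_collection(c(
    geojson_square_feature("u1", 0, 0),
    geojson_square_feature("u2", 1, 0, drop_property = "unit_id")
  )), gj)
  expect_error(read_boundaries(gj), "feature 2.*unit_id",
               class = "pfnr_io_error")

  writeLines(geojson_collection(c(
    geojson_square_feature("u1", 0, 0, level = "zcta"),
    geojson_square_feature("u2", 1, 0, level = "county")
  )), gj)
  expect_error(read_boundaries(gj), "mix", class = "pfnr_io_error")

  writeLines(geojson_collection(c(
    geojson_square_feature("u1", 0, 0), geojson_square_feature("u1", 1, 0)
  )), gj)
  expect_error(read_boundaries(gj), "duplicate", class = "pfnr_io_error")

  writeLines('{"type": "GeometryCollection"}', gj)
  expect_error(read_boundaries(gj), "FeatureCollection",
               class = "pfnr_io_error")
})

test_that("multipolygon area equals the shoelace sum of its parts", {
  # two disjoint squares: a 1x1 at the origin and a 2x2 at (3,0)
  gj <- tempfile(fileext = ".geojson")
  writeLines('{"type": "FeatureCollection", "features": [
    {"type": "Feature",
     "properties": {"unit_id": "mp1", "level": "zcta", "region_id": "R1"},
     "geometry": {"type": "MultiPolygon", "coordinates": [
       [[[0,0],[1,0],[1,1],[0,1],[0,0]]],
       [[[3,0],[5,0],[5,2],[3,2],[3,0]]]
     ]}}]}', gj)
  units <- read_boundaries(gj)
  expect_equal(nrow(units), 1)
  expected <- oracle_shoelace(c(0, 1, 1, 0), c(0, 0, 1, 1)) +
    oracle_shoelace(c(3, 5, 5, 3), c(0, 0, 2, 2))
  expect_equal(unit_area(units), expected)
})

test_that("facility tables parse coordinates, resolve address keys, and validate", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("facility_id,kind,lon,lat,address_key",
               "f1,pharmacy,-84.39,33.75,",
               "f2,prep_prescriber,,,ADDR7"), csv)
  gaz <- gazetteer("ADDR7", -84.4, 33.8)
  fac <- read_facilities(csv, gaz = gaz)
  expect_equal(nrow(fac), 2)
  expect_equal(fac$lon, c(-84.39, -84.4))
  expect_equal(fac$lat, c(33.75, 33.8))
  expect_equal(fac$kind, c("pharmacy", "prep_prescriber"))

  writeLines(c("facility_id,kind,lon,lat,address_key",
               "f1,clinic,-84.39,33.75,"), csv)
  expect_error(read_facilities(csv), "clinic", class = "pfnr_io_error")

  writeLines(c("facility_id,kind,lon,lat,address_key",
               "f1,pharmacy,,,"), csv)
  expect_error(read_facilities(csv), "neither", class = "pfnr_io_error")

  writeLines(c("facility_id,kind,lon,lat,address_key",
               "f1,pharmacy,-200,33.75,"), csv)
  expect_error(read_facilities(csv), "outside", class = "pfnr_io_error")
})

test_that("gazetteer misses are tallied, excluded and conserved", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("facility_id,kind,lon,lat,address_key",
               "f1,pharmacy,-84.39,33.75,",
               "f2,pharmacy,,,KNOWN",
               "f3,pharmacy,,,LOST1",
               "f4,prep_prescriber,,,LOST2"), csv)
  gaz <- gazetteer("KNOWN", -84.4, 33.8)
  expect_warning(fac <- read_facilities(csv, gaz = gaz), "2 facility")
  expect_equal(nrow(fac), 2)
  expect_setequal(attr(fac, "misses"), c("LOST1", "LOST2"))
  # miss count + resolved count = input row count
  expect_equal(length(attr(fac, "misses")) + nrow(fac),
               attr(fac, "n_input"))
  # unknown keys are explicit misses, never silent defaults
  lk <- gazetteer_lookup(gaz, c("KNOWN", "LOST1"))
  expect_equal(lk$hit, c(TRUE, FALSE))
  expect_true(is.na(lk$lon[2]))
})

test_that("need tables keep suppression distinct from zero and validate", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("unit_id,incidence_per_100k",
               "u1,312.5", "u2,NA", "u3,0"), csv)
  need <- read_need_table(csv)
  expect_equal(need$incidence_per_100k, c(312.5, NA, 0))
  expect_equal(need$suppressed, c(FALSE, TRUE, FALSE))
  # suppressed is not zero and zero is not suppressed
  expect_false(need$suppressed[3])
  expect_true(is.na(need$incidence_per_100k[2]))

  writeLines(c("unit_id,incidence_per_100k", "u3,-4"), csv)
  expect_error(read_need_table(csv), "negative", class = "pfnr_io_error")
  writeLines(c("unit_id,incidence_per_100k", "u1,5", "u1,6"), csv)
  expect_error(read_need_table(csv), "duplicate", class = "pfnr_io_error")
  writeLines(c("unit_id,incidence_per_100k", "u1,supp", "u2,7"), csv)
  need <- read_need_table(csv, suppressed_token = "supp")
  expect_equal(need$suppressed, c(TRUE, FALSE))
  writeLines(c("unit_id,incidence_per_100k", "u1,abc"), csv)
  expect_error(read_need_table(csv), "neither numeric",
               class = "pfnr_io_error")
})

test_that("facility, need and boundary files round-trip exactly", {
  fac <- make_facilities(c(-84.39123456, -83.2), c(33.75987654, 34.1),
                         kind = c("pharmacy", "prep_prescriber"))
  p <- tempfile(fileext = ".csv")
  write_facilities(fac, p)
  back <- read_facilities(p)
  expect_equal(as.data.frame(back), as.data.frame(fac), ignore_attr = TRUE)

  need <- make_need(c("u1", "u2", "u3"), c(312.5, NA, 0),
                    suppressed = c(FALSE, TRUE, FALSE))
  pn <- tempfile(fileext = ".csv")
  write_need_table(need, pn)
  expect_equal(read_need_table(pn), need)

  units <- make_square_grid(2, 2)
  pg <- tempfile(fileext = ".geojson")
  write_boundaries(units, pg)
  back_units <- read_boundaries(pg)
  expect_equal(back_units$unit_id, units$unit_id)
  expect_equal(unit_area(back_units), unit_area(units))
})
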