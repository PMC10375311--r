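# Synthetic scenario generation. The study's inputs (Board-of-Pharmacy
# purchases, a PrEP Locator snapshot, AIDSVu incidence extracts) are licensed
# and not redistributable, so every pipeline stage is exercised against
# generated scenarios with known ground truth: a rectangular grid of spatial
# units, a lognormal (right-skewed, strictly positive) incidence surface with
# optional small-area suppression, a sparse prescriber point process that can
# cluster around urban centers, and a dense near-homogeneous pharmacy process.

#' Synthetic scenario configuration
#'
#' Defaults emulate a metropolitan ZCTA analysis: a 10 x 10 grid of
#' 0.1-degree units, ~8 pharmacies per unit (dense, evenly spread), sparse
#' prescribers concentrated around a single downtown cluster, and a
#' right-skewed incidence surface with median near 150 cases per 100 000
#' persons over 5 years. With `prescriber_clusters = list()` the prescriber
#' process is homogeneous at `prescriber_intensity` per unit; with clusters,
#' the per-unit intensity is `prescriber_intensity` times a Gaussian-kernel
#' mixture `sum_j w_j exp(-d_j^2 / (2 bw_j^2))` evaluated at the unit
#' centroid, `d_j` the planar degree distance to center `j`.
#'
#' @param grid_rows,grid_cols Grid dimensions (units = rows x cols).
#' @param cell_size_deg Side length of each square unit, degrees.
#' @param origin_lon,origin_lat Southwest corner of the grid.
#' @param level Unit level, `"zcta"` or `"county"`.
#' @param region_id Region (state) identifier for all units.
#' @param prescriber_intensity Expected prescribers per unit (scale factor
#'   when clusters are present).
#' @param prescriber_clusters List of cluster centers, each a list/vector
#'   with `lon`, `lat`, `weight`, `bandwidth` (degrees).
#' @param pharmacy_intensity Expected pharmacies per unit (homogeneous).
#' @param incidence_log_mean,incidence_log_sd Lognormal parameters of
#'   per-unit 5-year incidence per 100 000.
#' @param suppression_prob Probability a unit's incidence is suppressed.
#' @param seed Integer seed; all generators draw from named substreams
#'   derived from it, so adding a generator never perturbs existing draws.
#' @return A list of class `pfnr_scenario_config`.
#' @export
scenario_config <- function(grid_rows = 10, grid_cols = 10,
                            cell_size_deg = 0.1,
                            origin_lon = -84.9, origin_lat = 33.3,
                            level = "zcta", region_id = "SYN",
                            prescriber_intensity = 3,
                            prescriber_clusters = list(
                              list(lon = -84.4, lat = 33.8, weight = 1,
                                   bandwidth = 0.15)),
                            pharmacy_intensity = 8,
                            incidence_log_mean = log(150),
                            incidence_log_sd = 0.7,
                            suppression_prob = 0,
                            seed = 1L) {
  stopifnot(grid_rows >= 1, grid_cols >= 1, cell_size_deg > 0,
            prescriber_intensity >= 0, pharmacy_intensity >= 0,
            incidence_log_sd >= 0,
            suppression_prob >= 0, suppression_prob <= 1)
  structure(list(
    grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
    cell_size_deg = cell_size_deg,
    origin_lon = origin_lon, origin_lat = origin_lat,
    level = match.arg(level, UNIT_LEVELS), region_id = region_id,
    prescriber_intensity = prescriber_intensity,
    prescriber_clusters = prescriber_clusters,
    pharmacy_intensity = pharmacy_intensity,
    incidence_log_mean = incidence_log_mean,
    incidence_log_sd = incidence_log_sd,
    suppression_prob = suppression_prob,
    seed = as.integer(seed)
  ), class = "pfnr_scenario_config")
}

# Named substream: a small string hash folded into the base seed so each
# generator has an independent, reproducible stream below 2^31.
substream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647)
}

#' Generate the grid of spatial units
#'
#' Deterministic (no randomness): `grid_rows x grid_cols` axis-aligned
#' square units tiling the domain, ids `"r{i}c{j}"` with row 1 at the
#' southern edge.
#'
#' @param config A [scenario_config()].
#' @return A spatial-unit tibble as from [read_boundaries()].
#' @export
gen_units <- function(config) {
  stopifnot(inherits(config, "pfnr_scenario_config"))
  cs <- config$cell_size_deg
  rows <- list()
  for (i in seq_len(config$grid_rows)) {
    for (j in seq_len(config$grid_cols)) {
      x0 <- config$origin_lon + (j - 1) * cs
      y0 <- config$origin_lat + (i - 1) * cs
      ring <- rbind(c(x0, y0), c(x0 + cs, y0), c(x0 + cs, y0 + cs),
                    c(x0, y0 + cs), c(x0, y0))
      rows[[length(rows) + 1]] <- list(
        unit_id = sprintf("r%dc%d", i, j),
        geometry = list(list(ring))
      )
    }
  }
  tibble(
    unit_id = vapply(rows, `[[`, character(1), "unit_id"),
    level = config$level,
    region_id = config$region_id,
    geometry = lapply(rows, `[[`, "geometry")
  )
}

#' Generate the per-unit incidence surface
#'
#' Independent lognormal draws per unit, independently suppressed with
#' probability `suppression_prob`. Fully determined by the config seed.
#'
#' @param units Units tibble from [gen_units()].
#' @param config A [scenario_config()].
#' @return A need tibble as from [read_need_table()].
#' @export
gen_incidence <- function(units, config) {
  stopifnot(inherits(config, "pfnr_scenario_config"))
  n <- nrow(units)
  withr_seed(substream_seed(config$seed, "incidence"), {
    inc <- rlnorm(n, meanlog = config$incidence_log_mean,
                  sdlog = config$incidence_log_sd)
    supp <- runif(n) < config$suppression_prob
  })
  inc[supp] <- NA_real_
  tibble(unit_id = units$unit_id, incidence_per_100k = inc,
         suppressed = supp)
}

# Evaluate a local RNG scope: save/restore .Random.seed so generation never
# disturbs the caller's stream.
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(code))
}

# Prescriber intensity per unit: homogeneous, or kernel mixture at centroids.
prescriber_intensity_per_unit <- function(units, config) {
  base <- config$prescriber_intensity
  cl <- config$prescriber_clusters
  if (length(cl) == 0) return(rep(base, nrow(units)))
  cents <- t(vapply(units$geometry, geom_centroid, numeric(2)))
  lam <- vapply(seq_len(nrow(units)), function(i) {
    sum(vapply(cl, function(cc) {
      d2 <- (cents[i, 1] - cc$lon)^2 + (cents[i, 2] - cc$lat)^2
      cc$weight * exp(-d2 / (2 * cc$bandwidth^2))
    }, numeric(1)))
  }, numeric(1))
  base * lam
}

#' Generate facility point sets
#'
#' Per-unit Poisson counts — homogeneous for pharmacies, kernel-mixture
#' intensity for prescribers — with points placed uniformly inside the
#' generating unit. Seeded and reproducible; the generating unit of every
#' point is recorded so assignment round-trips can be checked exactly.
#'
#' @param units Units tibble from [gen_units()].
#' @param config A [scenario_config()].
#' @return A facility tibble (`facility_id`, `kind`, `lon`, `lat`) with a
#'   `gen_unit` attribute giving the per-facility generating `unit_id` and a
#'   `true_intensity` attribute (tibble of per-unit expected counts).
#' @export
gen_facilities <- function(units, config) {
  stopifnot(inherits(config, "pfnr_scenario_config"))
  lam_prep <- prescriber_intensity_per_unit(units, config)
  lam_pharm <- rep(config$pharmacy_intensity, nrow(units))

  sample_class <- function(lams, kind, prefix, stream) {
    withr_seed(substream_seed(config$seed, stream), {
      ks <- rpois(length(lams), lams)
      lon <- numeric(sum(ks)); lat <- numeric(sum(ks))
      pos <- 0
      for (i in which(ks > 0)) {
        k <- ks[i]
        geom <- units$geometry[[i]]
        bb <- geom_bbox(geom)
        # batch rejection sampling within the bbox; accepts on the first
        # round for the generator's rectangular grid units
        filled <- 0
        while (filled < k) {
          cx <- runif(k - filled, bb[1], bb[3])
          cy <- runif(k - filled, bb[2], bb[4])
          ok <- points_in_geom(cx, cy, geom)
          n_ok <- sum(ok)
          if (n_ok > 0) {
            lon[pos + filled + seq_len(n_ok)] <- cx[ok]
            lat[pos + filled + seq_len(n_ok)] <- cy[ok]
            filled <- filled + n_ok
          }
        }
        pos <- pos + k
      }
      gen_unit <- rep(units$unit_id, ks)
      tibble(
        facility_id = paste0(prefix, "_", gen_unit, "_",
                             sequence(ks[ks > 0])),
        kind = kind, lon = lon, lat = lat, gen_unit = gen_unit
      )
    })
  }

  pharm <- sample_class(lam_pharm, "pharmacy", "ph", "pharmacy")
  prep <- sample_class(lam_prep, "prep_prescriber", "pr", "prescriber")
  all_fac <- dplyr::bind_rows(pharm, prep)
  if (nrow(all_fac) == 0) {
    all_fac <- tibble(facility_id = character(0), kind = character(0),
                      lon = numeric(0), lat = numeric(0),
                      gen_unit = character(0))
  }
  gen_unit <- all_fac$gen_unit
  all_fac$gen_unit <- NULL
  attr(all_fac, "gen_unit") <- gen_unit
  attr(all_fac, "true_intensity") <- tibble(
    unit_id = units$unit_id,
    prescriber_intensity = lam_prep,
    pharmacy_intensity = lam_pharm
  )
  all_fac
}

#' Generate and persist a complete scenario
#'
#' Writes the three standard pipeline inputs — boundary GeoJSON, facility
#' CSV, need CSV — plus a ground-truth JSON (true per-unit intensities and,
#' for homogeneous placement, the expected fold increase) for test
#' harnesses.
#'
#' @param config A [scenario_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the four file paths plus the in-memory
#'   `units`, `need`, `facilities` objects.
#' @export
write_scenario <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  units <- gen_units(config)
  need <- gen_incidence(units, config)
  fac <- gen_facilities(units, config)
  paths <- list(
    boundaries = file.path(dir, "boundaries.geojson"),
    facilities = file.path(dir, "facilities.csv"),
    need = file.path(dir, "need.csv"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  write_boundaries(units, paths$boundaries)
  write_facilities(fac, paths$facilities)
  write_need_table(need, paths$need)

  homog <- length(config$prescriber_clusters) == 0
  truth <- list(
    seed = config$seed,
    n_units = nrow(units),
    pharmacy_intensity = config$pharmacy_intensity,
    prescriber_intensity = config$prescriber_intensity,
    homogeneous_prescribers = homog,
    expected_fold_increase = if (homog && config$prescriber_intensity > 0) {
      config$pharmacy_intensity / config$prescriber_intensity
    } else NULL,
    true_intensity = attr(fac, "true_intensity")
  )
  jsonlite::write_json(truth, paths$ground_truth, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(c(paths, list(units = units, need = need, facilities = fac)))
}
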