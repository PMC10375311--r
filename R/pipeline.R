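# End-to-end orchestration: ingest -> assign -> PFNR -> report/maps.

#' Build a run configuration
#'
#' Everything that affects the numbers — suppression token, map binning,
#' decimation — lives in the configuration so a run is fully auditable from
#' its config plus its inputs. `run_config()` validates paths eagerly.
#'
#' @param boundaries,facilities,need Input file paths (GeoJSON, CSV, CSV).
#' @param out_dir Output directory (created if needed).
#' @param suppressed_token Need-table suppression token, default `"NA"`.
#' @param gazetteer Optional [gazetteer()] for address-keyed facilities.
#' @param map A [map_spec()].
#' @param aggregate_mode Also compute region-level aggregate PFNRs
#'   (total facilities over summed released incidence).
#' @return A list of class `pfnr_run_config`.
#' @export
run_config <- function(boundaries, facilities, need, out_dir,
                       suppressed_token = "NA", gazetteer = NULL,
                       map = map_spec(), aggregate_mode = FALSE) {
  for (p in c(boundaries, facilities, need)) {
    if (!file.exists(p)) {
      abort(sprintf("input path does not exist: %s", p),
            class = "pfnr_config_error")
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  structure(list(boundaries = boundaries, facilities = facilities,
                 need = need, out_dir = out_dir,
                 suppressed_token = suppressed_token,
                 gazetteer = gazetteer, map = map,
                 aggregate_mode = aggregate_mode),
            class = "pfnr_run_config")
}

#' Run the full PFNR analysis
#'
#' Reads and validates all inputs, assigns facilities to units, computes
#' per-unit metrics and per-region reports plus the pooled all-regions
#' report, and writes `report.csv`, one choropleth SVG per region
#' (`map_<region>.svg`), and `run.log` into the output directory. Outputs
#' are deterministic for fixed inputs. Stage failures propagate with the
#' stage name prepended.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `metrics`, `counts`, `reports` (per
#'   region), `pooled`, `report` (the written data frame), `unassigned`,
#'   and `paths`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "pfnr_run_config"))
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    inform(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            class = "pfnr_stage_error", parent = e)
    })
  }

  say("config: suppressed_token=%s aggregate_mode=%s decimation_k=%d",
      config$suppressed_token, config$aggregate_mode,
      config$map$decimation_k)

  units <- stage("read_boundaries", read_boundaries(config$boundaries))
  say("read %d spatial units (%d region(s)) from %s", nrow(units),
      length(unique(units$region_id)), config$boundaries)
  facilities <- stage("read_facilities",
                      read_facilities(config$facilities,
                                      gaz = config$gazetteer))
  say("read %d facilities from %s (%d input row(s), %d gazetteer miss(es))",
      nrow(facilities), config$facilities, attr(facilities, "n_input"),
      length(attr(facilities, "misses")))
  need <- stage("read_need_table",
                read_need_table(config$need,
                                suppressed_token = config$suppressed_token))
  say("read %d need records from %s (%d suppressed)", nrow(need),
      config$need, sum(need$suppressed))

  asg <- stage("assign_facilities", assign_facilities(facilities, units))
  say("unassigned facilities: %d prescriber(s), %d pharmacy(ies)",
      asg$unassigned[["prep_prescriber"]], asg$unassigned[["pharmacy"]])

  metrics <- stage("unit_metrics", unit_metrics(asg$counts, need))
  say("excluded units (suppressed or zero need): %d of %d",
      sum(!is.na(metrics$excluded_reason)), nrow(metrics))

  regions <- sort(unique(units$region_id))
  reports <- lapply(regions, function(r) {
    m <- metrics[metrics$unit_id %in% units$unit_id[units$region_id == r], ]
    region_report(m, r)
  })
  names(reports) <- regions
  pooled <- pooled_report(metrics)
  for (rep in c(reports, list(pooled))) {
    if (is.na(rep$fold_increase)) {
      warn(sprintf("region '%s': fold increase undefined (no current prescriber access or no defined PFNRs)",
                   rep$region_id))
    }
  }

  paths <- list(report = file.path(config$out_dir, "report.csv"),
                log = file.path(config$out_dir, "run.log"))
  report_df <- stage("write_report",
                     write_report(c(reports, list(pooled)), paths$report))
  if (config$aggregate_mode) {
    agg <- do.call(rbind, lapply(regions, function(r) {
      m <- metrics[metrics$unit_id %in% units$unit_id[units$region_id == r], ]
      data.frame(region_id = r,
                 aggregate_pfnr_prescribers = aggregate_pfnr(m, "prep_prescriber"),
                 aggregate_pfnr_pharmacies = aggregate_pfnr(m, "pharmacy"))
    }))
    paths$aggregate <- file.path(config$out_dir, "aggregate.csv")
    write.csv(agg, paths$aggregate, row.names = FALSE, quote = FALSE)
    say("wrote aggregate-mode PFNRs to %s", paths$aggregate)
  }
  orphan_need <- setdiff(need$unit_id, units$unit_id)
  if (length(orphan_need) > 0) {
    warn(sprintf("%d need record(s) reference units absent from boundaries: %s",
                 length(orphan_need),
                 paste(head(orphan_need, 5), collapse = ", ")))
  }
  for (r in regions) {
    p <- file.path(config$out_dir, sprintf("map_%s.svg", r))
    sel <- units$region_id == r
    need_r <- need[need$unit_id %in% units$unit_id[sel], ]
    stage("render_map",
          render_map(units[sel, ], need_r, facilities, config$map, p))
    paths[[paste0("map_", r)]] <- p
    say("wrote map for region %s to %s", r, p)
  }
  say("wrote report to %s", paths$report)
  writeLines(log_lines, paths$log)
  invisible(list(metrics = metrics, counts = asg$counts,
                 unassigned = asg$unassigned, reports = reports,
                 pooled = pooled, report = report_df, paths = paths))
}

#' Generate a synthetic scenario and analyze it
#'
#' Persists the generated inputs (boundary GeoJSON, facility and need CSVs,
#' ground-truth JSON) under `<out_dir>/inputs`, then runs [run_analysis()]
#' on them, so the generated files are themselves re-loadable pipeline
#' inputs.
#'
#' @param scenario A [scenario_config()].
#' @param out_dir Output directory.
#' @param map A [map_spec()].
#' @param aggregate_mode Passed to [run_config()].
#' @return Invisibly, the [run_analysis()] result with an extra `inputs`
#'   element (scenario file paths and generated objects).
#' @export
run_synthetic <- function(scenario, out_dir, map = map_spec(),
                          aggregate_mode = FALSE) {
  stopifnot(inherits(scenario, "pfnr_scenario_config"))
  in_dir <- file.path(out_dir, "inputs")
  gen <- write_scenario(scenario, in_dir)
  config <- run_config(gen$boundaries, gen$facilities, gen$need, out_dir,
                       map = map, aggregate_mode = aggregate_mode)
  res <- run_analysis(config)
  res$inputs <- gen
  invisible(res)
}

#' Load a run configuration from a YAML file
#'
#' Schema: `boundaries`, `facilities`, `need`, `out_dir` (paths, resolved
#' relative to the YAML file's directory), optional `suppressed_token`,
#' `aggregate_mode`, `gazetteer` (path to a CSV with `key,lon,lat` columns),
#' and a `map` block (`bin_edges`, `quantile_bins`, `decimation_k`).
#'
#' @param path Path to the YAML config.
#' @param out_dir Optional override for the configured output directory.
#' @return A [run_config()].
#' @export
load_run_config <- function(path, out_dir = NULL) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p) || grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  }
  gaz <- NULL
  if (!is.null(cfg$gazetteer)) {
    g <- read.csv(resolve(cfg$gazetteer), stringsAsFactors = FALSE)
    gaz <- gazetteer(g$key, g$lon, g$lat)
  }
  map <- map_spec(
    bin_edges = cfg$map$bin_edges %||% c(0, 100, 200, 300, 400),
    quantile_bins = cfg$map$quantile_bins %||% FALSE,
    decimation_k = cfg$map$decimation_k %||% 1
  )
  run_config(
    boundaries = resolve(cfg$boundaries),
    facilities = resolve(cfg$facilities),
    need = resolve(cfg$need),
    out_dir = out_dir %||% resolve(cfg$out_dir) %||% ".",
    suppressed_token = cfg$suppressed_token %||% "NA",
    gazetteer = gaz, map = map,
    aggregate_mode = isTRUE(cfg$aggregate_mode)
  )
}
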