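# Choropleth rendering and report-table output.

#' Map rendering specification
#'
#' Controls the incidence choropleth and the facility overlays. The default
#' bins step by 100 cases per 100 000 persons and cap at "400+", the scale
#' used for metropolitan ZCTA risk maps; pass `quantile_bins = TRUE` to bin
#' at the quartiles of the released incidence values instead. The pharmacy
#' layer can be decimated for legibility in dense areas: with decimation
#' factor `k`, each plotted pharmacy marker represents up to `k` pharmacies
#' of one unit (`ceiling(n/k)` markers per unit). Decimation is display-only
#' and never alters counts or PFNRs.
#'
#' @param bin_edges Strictly increasing lower bin edges (the last bin is
#'   open-ended). Ignored when `quantile_bins = TRUE`.
#' @param quantile_bins Use quartile-based bin edges computed from the data.
#' @param palette Fill colors, one per bin (recycled/ramped as needed).
#' @param decimation_k Pharmacy marker decimation factor, `>= 1`.
#' @return A list of class `pfnr_map_spec`.
#' @export
map_spec <- function(bin_edges = c(0, 100, 200, 300, 400),
                     quantile_bins = FALSE,
                     palette = c("#ffffb2", "#fecc5c", "#fd8d3c",
                                 "#f03b20", "#bd0026"),
                     decimation_k = 1) {
  if (!quantile_bins) {
    stopifnot(length(bin_edges) >= 1, !is.unsorted(bin_edges, strictly = TRUE))
  }
  stopifnot(decimation_k >= 1)
  structure(list(bin_edges = bin_edges, quantile_bins = quantile_bins,
                 palette = palette,
                 decimation_k = as.integer(decimation_k)),
            class = "pfnr_map_spec")
}

bin_colors <- function(spec, n_bins) {
  grDevices::colorRampPalette(spec$palette)(n_bins)
}

svg_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

num <- function(x) formatC(x, format = "fg", digits = 6)

#' Render an incidence choropleth with facility overlays
#'
#' Writes a self-contained SVG: spatial units filled by incidence bin,
#' suppressed or unreported units in a distinct hatched "no data" fill
#' (suppression is never drawn as zero incidence), prescribing locations as
#' circles, pharmacies as squares (optionally decimated), and a legend with
#' the bin edges and, when `decimation_k > 1`, the decimation convention.
#'
#' @param units Spatial-unit tibble.
#' @param need Need tibble; units in `need` absent from `units` are skipped
#'   with a warning.
#' @param facilities Facility tibble (may have zero rows).
#' @param spec A [map_spec()].
#' @param out Output SVG path.
#' @param width Image width in pixels (height follows the aspect ratio).
#' @return `out`, invisibly.
#' @export
render_map <- function(units, need, facilities, spec = map_spec(),
                       out, width = 800) {
  stopifnot(inherits(spec, "pfnr_map_spec"))
  orphan <- setdiff(need$unit_id, units$unit_id)
  if (length(orphan) > 0) {
    warn(sprintf("%d need record(s) reference units absent from boundaries; skipped: %s",
                 length(orphan), paste(head(orphan, 5), collapse = ", ")))
  }
  idx <- match(units$unit_id, need$unit_id)
  inc <- need$incidence_per_100k[idx]
  supp <- need$suppressed[idx]
  supp[is.na(idx)] <- TRUE  # no record -> rendered as no-data

  edges <- if (spec$quantile_bins) {
    vals <- inc[!supp & !is.na(inc)]
    if (length(vals) == 0) c(0) else
      unique(unname(quantile(vals, probs = c(0, 0.25, 0.5, 0.75), type = 7)))
  } else spec$bin_edges
  n_bins <- length(edges)
  cols <- bin_colors(spec, n_bins)
  bin_of <- function(v) findInterval(v, edges, rightmost.closed = FALSE)

  bbs <- lapply(units$geometry, geom_bbox)
  xmin <- min(vapply(bbs, `[`, numeric(1), 1))
  ymin <- min(vapply(bbs, `[`, numeric(1), 2))
  xmax <- max(vapply(bbs, `[`, numeric(1), 3))
  ymax <- max(vapply(bbs, `[`, numeric(1), 4))
  pad <- 0.02 * max(xmax - xmin, ymax - ymin, .Machine$double.eps)
  xmin <- xmin - pad; xmax <- xmax + pad
  ymin <- ymin - pad; ymax <- ymax + pad
  legend_w <- 190
  map_w <- width - legend_w
  scale <- map_w / (xmax - xmin)
  height <- max(240, ceiling((ymax - ymin) * scale))
  tx <- function(lon) (lon - xmin) * scale
  ty <- function(lat) height - (lat - ymin) * scale  # y grows downward in SVG

  lines <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            width, height, width, height),
    '<defs>',
    '<pattern id="nodata" width="6" height="6" patternUnits="userSpaceOnUse" patternTransform="rotate(45)">',
    '<rect width="6" height="6" fill="#e8e8e8"/>',
    '<line x1="0" y1="0" x2="0" y2="6" stroke="#9a9a9a" stroke-width="2"/>',
    '</pattern>',
    '</defs>',
    sprintf('<rect width="%d" height="%d" fill="#ffffff"/>', width, height),
    '<g id="choropleth">'
  )
  for (i in seq_len(nrow(units))) {
    d <- paste(vapply(units$geometry[[i]], function(poly) {
      paste(vapply(poly, function(r) {
        ro <- ring_open(r)
        pts <- paste(sprintf("%s %s", num(tx(ro[, 1])), num(ty(ro[, 2]))),
                     collapse = " L ")
        paste0("M ", pts, " Z")
      }, character(1)), collapse = " ")
    }, character(1)), collapse = " ")
    if (supp[i] || is.na(inc[i])) {
      fill <- 'url(#nodata)'; cls <- "unit no-data"
    } else {
      fill <- cols[max(1L, bin_of(inc[i]))]; cls <- "unit"
    }
    lines <- c(lines, sprintf(
      '<path class="%s" data-unit="%s" d="%s" fill="%s" fill-rule="evenodd" stroke="#555555" stroke-width="0.8"/>',
      cls, svg_escape(units$unit_id[i]), d, fill))
  }
  lines <- c(lines, '</g>')

  prep <- facilities[facilities$kind == "prep_prescriber", , drop = FALSE]
  pharm <- facilities[facilities$kind == "pharmacy", , drop = FALSE]
  pharm <- decimate_pharmacies(pharm, units, spec$decimation_k)

  lines <- c(lines, '<g id="pharmacies">')
  if (nrow(pharm) > 0) {
    lines <- c(lines, sprintf(
      '<rect class="facility pharmacy" x="%s" y="%s" width="5" height="5" fill="#2166ac" stroke="#ffffff" stroke-width="0.6"/>',
      num(tx(pharm$lon) - 2.5), num(ty(pharm$lat) - 2.5)))
  }
  lines <- c(lines, '</g>', '<g id="prescribers">')
  if (nrow(prep) > 0) {
    lines <- c(lines, sprintf(
      '<circle class="facility prescriber" cx="%s" cy="%s" r="3.2" fill="#d73027" stroke="#ffffff" stroke-width="0.6"/>',
      num(tx(prep$lon)), num(ty(prep$lat))))
  }
  lines <- c(lines, '</g>')

  # legend: one swatch per bin, a no-data swatch, facility keys
  lx <- map_w + 18
  ly <- 24
  lines <- c(lines, '<g id="legend">',
             sprintf('<text x="%d" y="%d" font-size="13" font-family="sans-serif" font-weight="bold">5-year HIV incidence / 100k</text>',
                     lx, ly))
  for (b in seq_len(n_bins)) {
    y <- ly + 10 + 20 * (b - 1)
    label <- if (b < n_bins) {
      sprintf("%s-%s", format(edges[b]), format(edges[b + 1]))
    } else sprintf("%s+", format(edges[b]))
    lines <- c(lines,
               sprintf('<rect x="%d" y="%d" width="14" height="14" fill="%s" stroke="#555555"/>', lx, y, cols[b]),
               sprintf('<text x="%d" y="%d" font-size="12" font-family="sans-serif">%s</text>',
                       lx + 20, y + 11, svg_escape(label)))
  }
  y <- ly + 10 + 20 * n_bins
  lines <- c(lines,
             sprintf('<rect x="%d" y="%d" width="14" height="14" fill="url(#nodata)" stroke="#555555"/>', lx, y),
             sprintf('<text x="%d" y="%d" font-size="12" font-family="sans-serif">no data (suppressed)</text>',
                     lx + 20, y + 11))
  y <- y + 28
  lines <- c(lines,
             sprintf('<circle cx="%d" cy="%d" r="3.2" fill="#d73027"/>', lx + 7, y + 7),
             sprintf('<text x="%d" y="%d" font-size="12" font-family="sans-serif">PrEP-prescribing location</text>',
                     lx + 20, y + 11),
             sprintf('<rect x="%d" y="%d" width="5" height="5" fill="#2166ac"/>', lx + 5, y + 24),
             sprintf('<text x="%d" y="%d" font-size="12" font-family="sans-serif">pharmacy%s</text>',
                     lx + 20, y + 31,
                     if (spec$decimation_k > 1) {
                       sprintf(" (1 marker = %d pharmacies)", spec$decimation_k)
                     } else ""))
  lines <- c(lines, '</g>', '</svg>')
  writeLines(lines, out)
  invisible(out)
}

# Keep ceiling(n/k) markers per containing unit, deterministically (sorted by
# facility_id, every k-th starting at the first). Facilities outside all
# units are kept undecimated; they are rare and decimation is cosmetic.
decimate_pharmacies <- function(pharm, units, k) {
  if (k <= 1 || nrow(pharm) == 0) return(pharm)
  asg <- assign_facilities(pharm, units, check_overlap = FALSE)$assignment
  pharm$.unit <- asg$unit_id[match(pharm$facility_id, asg$facility_id)]
  keep <- unlist(lapply(split(seq_len(nrow(pharm)), pharm$.unit), function(ix) {
    ix <- ix[order(pharm$facility_id[ix], method = "radix")]
    ix[seq(1, length(ix), by = k)]
  }))
  keep <- c(keep, which(is.na(pharm$.unit)))
  out <- pharm[sort(keep), , drop = FALSE]
  out$.unit <- NULL
  out
}

#' Write the regional PFNR report table
#'
#' Emits a CSV shaped like a per-state summary table: one row per region and
#' facility class (regions in the order given, a pooled row last when
#' supplied), with the full-precision mean, a display-rounded mean
#' companion, median and quartiles, the fold increase (full precision plus a
#' one-decimal display column), desert counts, and exclusion accounting.
#'
#' @param reports List of [region_report()] objects (include the
#'   [pooled_report()] as the final element for an all-regions row).
#' @param out Output CSV path.
#' @return The report data frame, invisibly.
#' @export
write_report <- function(reports, out) {
  stopifnot(length(reports) >= 1)
  rows <- list()
  for (rep in reports) {
    stopifnot(inherits(rep, "pfnr_region_report"))
    for (class in FACILITY_KINDS) {
      s <- if (class == "prep_prescriber") rep$prescribers else rep$pharmacies
      fold_reason <- if (!is.na(rep$fold_increase)) "" else if
      (!s$defined) "no_defined_pfnr" else if
      (rep$prescribers$defined && rep$prescribers$mean == 0)
        "no_current_access" else "undefined"
      rows[[length(rows) + 1]] <- data.frame(
        region_id = rep$region_id,
        class = class,
        mean = s$mean,
        mean_display = ifelse(is.na(s$mean), "NA",
                              formatC(signif(s$mean, 3), format = "fg")),
        median = s$median, q1 = s$q1, q3 = s$q3,
        fold_increase = rep$fold_increase,
        fold_display = ifelse(is.na(rep$fold_increase), "NA",
                              sprintf("%.1f", rep$fold_increase)),
        fold_reason = fold_reason,
        n_deserts = unname(rep$deserts[class]),
        n_units = rep$n_units,
        n_units_used = rep$n_units_used,
        n_units_excluded = rep$n_units_excluded,
        stringsAsFactors = FALSE
      )
    }
  }
  df <- do.call(rbind, rows)
  write.csv(df, out, row.names = FALSE, quote = FALSE)
  invisible(df)
}
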