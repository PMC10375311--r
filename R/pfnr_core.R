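# PFNR computation: per-unit ratios, regional distribution summaries, and
# the pharmacy-expansion fold increase.

#' Per-unit PrEP facility-to-need ratio
#'
#' The PFNR of a unit is its facility count divided by its 5-year HIV
#' incidence per 100 000 persons. The ratio is undefined when incidence is
#' suppressed (not released) or zero — a ratio "to need" carries no
#' information when measured need is absent — and such units are excluded
#' from summaries, never imputed. Vectorized over all arguments.
#'
#' @param count Non-negative facility count(s).
#' @param incidence_per_100k Incidence value(s); ignored where `suppressed`.
#' @param suppressed Logical; `TRUE` marks suppressed incidence.
#' @return A list with `pfnr` (numeric, `NA` where undefined) and
#'   `excluded_reason` (character: `NA`, `"suppressed_need"` or
#'   `"zero_need"`).
#' @export
#' @examples
#' compute_unit_pfnr(12, 300)         # 0.04
#' compute_unit_pfnr(5, NA, TRUE)     # undefined, suppressed_need
compute_unit_pfnr <- function(count, incidence_per_100k, suppressed = FALSE) {
  n <- max(length(count), length(incidence_per_100k), length(suppressed))
  count <- rep_len(count, n)
  incidence_per_100k <- rep_len(incidence_per_100k, n)
  suppressed <- rep_len(suppressed, n)
  if (any(count < 0)) {
    abort("facility count must be non-negative", class = "pfnr_value_error")
  }
  if (any(!suppressed & !is.na(incidence_per_100k) & incidence_per_100k < 0)) {
    abort("incidence must be non-negative", class = "pfnr_value_error")
  }
  reason <- rep(NA_character_, n)
  reason[suppressed] <- "suppressed_need"
  zero <- !suppressed & !is.na(incidence_per_100k) & incidence_per_100k == 0
  reason[zero] <- "zero_need"
  pfnr <- rep(NA_real_, n)
  ok <- is.na(reason) & !is.na(incidence_per_100k)
  pfnr[ok] <- count[ok] / incidence_per_100k[ok]
  list(pfnr = pfnr, excluded_reason = reason)
}

#' Per-unit metrics table
#'
#' Joins facility counts with the need table and computes both PFNRs per
#' unit. Units absent from the need table are treated as suppressed (no
#' released estimate).
#'
#' @param counts Counts tibble from [assign_facilities()].
#' @param need Need tibble from [read_need_table()] / [gen_incidence()].
#' @return A tibble with `unit_id`, `n_prescribers`, `n_pharmacies`,
#'   `incidence_per_100k`, `suppressed`, `pfnr_prescribers`,
#'   `pfnr_pharmacies`, `excluded_reason`.
#' @export
unit_metrics <- function(counts, need) {
  idx <- match(counts$unit_id, need$unit_id)
  incidence <- need$incidence_per_100k[idx]
  suppressed <- need$suppressed[idx]
  suppressed[is.na(idx)] <- TRUE
  prep <- compute_unit_pfnr(counts$n_prescribers, incidence, suppressed)
  pharm <- compute_unit_pfnr(counts$n_pharmacies, incidence, suppressed)
  tibble(
    unit_id = counts$unit_id,
    n_prescribers = counts$n_prescribers,
    n_pharmacies = counts$n_pharmacies,
    incidence_per_100k = incidence,
    suppressed = suppressed,
    pfnr_prescribers = prep$pfnr,
    pfnr_pharmacies = pharm$pfnr,
    excluded_reason = prep$excluded_reason
  )
}

#' Summarize the PFNR distribution of one facility class
#'
#' Mean, median and quartiles over the defined unit PFNRs only; excluded
#' units (suppressed or zero need) are counted, not imputed. Quartiles use
#' linear interpolation between order statistics at positions 0.25 and 0.75
#' of (n - 1) — the convention is pinned because quantile definitions differ
#' across software.
#'
#' @param metrics Metrics tibble from [unit_metrics()].
#' @param class `"prep_prescriber"` or `"pharmacy"`.
#' @return A list with `mean`, `median`, `q1`, `q3`, `n_used`, and `defined`
#'   (`FALSE`, with `NA` statistics, when no unit has a defined PFNR).
#' @export
summarize_region <- function(metrics,
                             class = c("prep_prescriber", "pharmacy")) {
  class <- match.arg(class)
  x <- if (class == "prep_prescriber") metrics$pfnr_prescribers else
    metrics$pfnr_pharmacies
  x <- x[!is.na(x)]
  if (length(x) == 0) {
    return(list(mean = NA_real_, median = NA_real_, q1 = NA_real_,
                q3 = NA_real_, n_used = 0L, defined = FALSE))
  }
  q <- unname(quantile(x, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE))
  list(mean = mean(x), median = q[2], q1 = q[1], q3 = q[3],
       n_used = length(x), defined = TRUE)
}

#' Fold increase in availability from pharmacy expansion
#'
#' Ratio of the mean pharmacy PFNR to the mean prescriber PFNR, both at full
#' precision. Higher values indicate a greater potential effect of expanding
#' PrEP provision to pharmacies. Undefined (reported as "no current access")
#' when the mean prescriber PFNR is zero.
#'
#' @param mean_pharm Mean pharmacy PFNR (must be positive).
#' @param mean_prep Mean prescriber PFNR (non-negative).
#' @return The fold increase, or `NA` when `mean_prep` is zero.
#' @export
fold_increase <- function(mean_pharm, mean_prep) {
  if (is.na(mean_pharm) || mean_pharm <= 0) {
    abort("mean pharmacy PFNR must be positive to compute a fold increase",
          class = "pfnr_value_error")
  }
  if (is.na(mean_prep) || mean_prep < 0) {
    abort("mean prescriber PFNR must be a non-negative number",
          class = "pfnr_value_error")
  }
  if (mean_prep == 0) return(NA_real_)
  mean_pharm / mean_prep
}

#' Regional PFNR report
#'
#' Bundles the per-class PFNR summaries, the fold increase, desert counts
#' and exclusion accounting for one region.
#'
#' @param metrics Metrics tibble from [unit_metrics()] restricted to one
#'   region's units.
#' @param region_id Region label for the report row.
#' @return A list of class `pfnr_region_report`.
#' @export
region_report <- function(metrics, region_id) {
  s_prep <- summarize_region(metrics, "prep_prescriber")
  s_pharm <- summarize_region(metrics, "pharmacy")
  fold <- if (s_pharm$defined && s_prep$defined && s_pharm$mean > 0) {
    fold_increase(s_pharm$mean, s_prep$mean)
  } else NA_real_
  structure(list(
    region_id = region_id,
    prescribers = s_prep,
    pharmacies = s_pharm,
    fold_increase = fold,
    deserts = c(
      prep_prescriber = sum(metrics$n_prescribers == 0),
      pharmacy = sum(metrics$n_pharmacies == 0)
    ),
    n_units = nrow(metrics),
    n_units_used = s_prep$n_used,
    n_units_excluded = nrow(metrics) - s_prep$n_used
  ), class = "pfnr_region_report")
}

#' @export
print.pfnr_region_report <- function(x, ...) {
  fmt <- function(s) sprintf("%.4g (%.4g [%.4g-%.4g], n=%d)",
                             s$mean, s$median, s$q1, s$q3, s$n_used)
  cat(sprintf("Region %s: %d units (%d used, %d excluded)\n",
              x$region_id, x$n_units, x$n_units_used, x$n_units_excluded))
  cat("  prescriber PFNR:", if (x$prescribers$defined) fmt(x$prescribers)
      else "undefined", "\n")
  cat("  pharmacy PFNR:  ", if (x$pharmacies$defined) fmt(x$pharmacies)
      else "undefined", "\n")
  cat("  fold increase:  ", if (is.na(x$fold_increase)) "undefined"
      else sprintf("%.1f", x$fold_increase), "\n")
  cat(sprintf("  deserts: %d without a prescriber, %d without a pharmacy\n",
              x$deserts[["prep_prescriber"]], x$deserts[["pharmacy"]]))
  invisible(x)
}

#' Pooled report over all regions
#'
#' Applies the identical summary algorithm to the union of all regions'
#' defined unit PFNRs — a pooled distribution, not a mean of region means.
#'
#' @param metrics Metrics tibble covering all regions' units.
#' @param region_id Label for the pooled row, default `"all_regions"`.
#' @return A `pfnr_region_report` for the pooled distribution.
#' @export
pooled_report <- function(metrics, region_id = "all_regions") {
  region_report(metrics, region_id)
}

#' Aggregate-mode regional PFNR
#'
#' An alternative, region-level formulation: total facilities of a class in
#' the region divided by the sum of released unit incidences. Kept behind
#' its own function rather than mixed into the distributional summaries;
#' suppressed units contribute neither numerator exclusions nor denominator.
#'
#' @param metrics Metrics tibble for one region.
#' @param class `"prep_prescriber"` or `"pharmacy"`.
#' @return A single ratio, or `NA` when total released incidence is zero.
#' @export
aggregate_pfnr <- function(metrics,
                           class = c("prep_prescriber", "pharmacy")) {
  class <- match.arg(class)
  counts <- if (class == "prep_prescriber") metrics$n_prescribers else
    metrics$n_pharmacies
  ok <- !metrics$suppressed & !is.na(metrics$incidence_per_100k)
  total_risk <- sum(metrics$incidence_per_100k[ok])
  if (total_risk == 0) return(NA_real_)
  sum(counts[ok]) / total_risk
}
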