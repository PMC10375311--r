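test_that("per-unit PFNR is count over incidence with explicit exclusions", {
  expect_equal(compute_unit_pfnr(12, 300)$pfnr, 0.04)
  expect_equal(compute_unit_pfnr(0, 150)$pfnr, 0)
  supp <- compute_unit_pfnr(5, NA, suppressed = TRUE)
  expect_true(is.na(supp$pfnr))
  expect_equal(supp$excluded_reason, "suppressed_need")
  zero <- compute_unit_pfnr(5, 0)
  expect_true(is.na(zero$pfnr))
  expect_equal(zero$excluded_reason, "zero_need")
  expect_error(compute_unit_pfnr(-1, 100), class = "pfnr_value_error")
  # vectorized: defined iff incidence present and positive
  v <- compute_unit_pfnr(c(2, 3, 4), c(100, 0, NA),
                         suppressed = c(FALSE, FALSE, TRUE))
  expect_equal(v$pfnr, c(0.02, NA, NA))
  expect_equal(v$excluded_reason, c(NA, "zero_need", "suppressed_need"))
})

test_that("regional summaries use defined PFNRs only, with pinned quartiles", {
  m1 <- unit_metrics(
    tibble::tibble(unit_id = "u1", n_prescribers = 1L, n_pharmacies = 2L),
    make_need("u1", 10))
  s1 <- summarize_region(m1, "prep_prescriber")
  expect_equal(c(s1$mean, s1$median, s1$q1, s1$q3), rep(0.1, 4))

  counts <- tibble::tibble(unit_id = sprintf("u%d", 1:5),
                           n_prescribers = c(0L, 0L, 0L, 2L, 6L),
                           n_pharmacies = 0L)
  m2 <- unit_metrics(counts, make_need(counts$unit_id, c(10, 10, 10, 500, 500)))
  s2 <- summarize_region(m2, "prep_prescriber")
  expect_equal(s2$median, 0)     # majority-zero order statistics
  expect_equal(s2$n_used, 5L)

  # no defined PFNRs -> explicit undefined flag, never zeros
  m3 <- unit_metrics(
    tibble::tibble(unit_id = "u1", n_prescribers = 1L, n_pharmacies = 1L),
    make_need("u1", NA, suppressed = TRUE))
  s3 <- summarize_region(m3, "pharmacy")
  expect_false(s3$defined)
  expect_true(is.na(s3$mean))
  expect_equal(s3$n_used, 0L)
})

test_that("summary statistics match a sort-and-interpolate oracle to 12 significant digits", {
  set.seed(2024)
  vals <- rlnorm(200, log(0.05), 1.2)
  counts <- tibble::tibble(unit_id = sprintf("u%03d", 1:200),
                           n_prescribers = 0L, n_pharmacies = 1L)
  m <- unit_metrics(counts, make_need(counts$unit_id, 1 / vals))
  s <- summarize_region(m, "pharmacy")
  o <- oracle_summary(vals)
  expect_equal(s$mean, o$mean, tolerance = 1e-12)
  expect_equal(s$median, o$median, tolerance = 1e-12)
  expect_equal(s$q1, o$q1, tolerance = 1e-12)
  expect_equal(s$q3, o$q3, tolerance = 1e-12)
})

test_that("fold increase is the ratio of full-precision means", {
  expect_equal(fold_increase(0.7, 0.008), 87.5)
  expect_equal(fold_increase(0.3, 0.3), 1)
  expect_true(is.na(fold_increase(0.5, 0)))  # no current access
  expect_error(fold_increase(0, 0.1), class = "pfnr_value_error")
  expect_error(fold_increase(-1, 0.1), class = "pfnr_value_error")
})

test_that("pooled report equals the identical algorithm on the union of units", {
  counts_a <- tibble::tibble(unit_id = sprintf("a%d", 1:6),
                             n_prescribers = c(0L, 1L, 0L, 2L, 0L, 1L),
                             n_pharmacies = c(3L, 8L, 0L, 12L, 5L, 9L))
  counts_b <- tibble::tibble(unit_id = sprintf("b%d", 1:4),
                             n_prescribers = c(0L, 0L, 3L, 1L),
                             n_pharmacies = c(6L, 0L, 20L, 11L))
  need_a <- make_need(counts_a$unit_id, c(120, 340, 80, 510, 95, 230))
  need_b <- make_need(counts_b$unit_id, c(45, 300, 610, 150))
  m_a <- unit_metrics(counts_a, need_a)
  m_b <- unit_metrics(counts_b, need_b)
  m_all <- rbind(m_a, m_b)

  # single region: pooled equals the region's own report
  expect_equal(unclass(pooled_report(m_a))[-1],
               unclass(region_report(m_a, "A"))[-1])

  pooled <- pooled_report(m_all)
  rep_a <- region_report(m_a, "A")
  rep_b <- region_report(m_b, "B")
  expect_equal(pooled$n_units_used,
               rep_a$n_units_used + rep_b$n_units_used)
  # pooled mean is the count-weighted combination of region means
  for (cls in c("prescribers", "pharmacies")) {
    expected <- (rep_a[[cls]]$mean * rep_a[[cls]]$n_used +
                   rep_b[[cls]]$mean * rep_b[[cls]]$n_used) /
      (rep_a[[cls]]$n_used + rep_b[[cls]]$n_used)
    expect_equal(pooled[[cls]]$mean, expected, tolerance = 1e-12)
  }
})

test_that("PFNRs scale inversely with incidence while the fold is invariant", {
  counts <- tibble::tibble(unit_id = sprintf("u%d", 1:8),
                           n_prescribers = c(0L, 1L, 0L, 2L, 1L, 0L, 4L, 1L),
                           n_pharmacies = c(5L, 9L, 2L, 30L, 11L, 7L, 40L, 13L))
  inc <- c(110, 75, 300, 420, 260, 55, 600, 180)
  for (c_scale in c(10, 0.25)) {
    r1 <- region_report(unit_metrics(counts, make_need(counts$unit_id, inc)), "R")
    r2 <- region_report(unit_metrics(counts,
                                     make_need(counts$unit_id, inc * c_scale)), "R")
    for (cls in c("prescribers", "pharmacies")) {
      for (stat in c("mean", "median", "q1", "q3")) {
        expect_equal(r2[[cls]][[stat]], r1[[cls]][[stat]] / c_scale,
                     tolerance = 1e-12)
      }
    }
    expect_equal(r2$fold_increase, r1$fold_increase, tolerance = 1e-12)
  }
})

test_that("adding pharmacies never decreases pharmacy PFNR or fold; fewer facilities means lower PFNR", {
  counts <- tibble::tibble(unit_id = sprintf("u%d", 1:5),
                           n_prescribers = c(1L, 0L, 2L, 1L, 0L),
                           n_pharmacies = c(4L, 6L, 1L, 9L, 3L))
  need <- make_need(counts$unit_id, c(150, 90, 310, 220, 70))
  base <- region_report(unit_metrics(counts, need), "R")
  for (i in 1:5) {
    bumped <- counts
    bumped$n_pharmacies[i] <- bumped$n_pharmacies[i] + 1L
    rep_b <- region_report(unit_metrics(bumped, need), "R")
    expect_gte(rep_b$pharmacies$mean, base$pharmacies$mean)
    expect_gte(rep_b$fold_increase, base$fold_increase)
  }
  # pointwise direction: holding incidence fixed, fewer facilities => lower PFNR
  expect_lt(compute_unit_pfnr(3, 250)$pfnr, compute_unit_pfnr(4, 250)$pfnr)
})

test_that("exclusion accounting is exhaustive and aggregate mode sums the region", {
  counts <- tibble::tibble(unit_id = sprintf("u%d", 1:4),
                           n_prescribers = c(1L, 2L, 0L, 3L),
                           n_pharmacies = c(2L, 4L, 1L, 6L))
  need <- make_need(counts$unit_id, c(100, NA, 0, 300),
                    suppressed = c(FALSE, TRUE, FALSE, FALSE))
  m <- unit_metrics(counts, need)
  rep <- region_report(m, "R")
  expect_equal(rep$n_units_used + rep$n_units_excluded, rep$n_units)
  expect_equal(rep$n_units_excluded, 2L)
  # aggregate mode: totals over released incidence only
  expect_equal(aggregate_pfnr(m, "prep_prescriber"), (1 + 0 + 3) / (100 + 0 + 300))
  expect_equal(aggregate_pfnr(m, "pharmacy"), (2 + 1 + 6) / 400)
})
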