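test_that("AUC handles rectangles and the dose/CL identity", {
  t <- c(0, 1, 2, 2 + 1e-9, 3)
  c0 <- c(10, 10, 10, 0, 0)
  expect_equal(pk_auc(t, c0), 20, tolerance = 1e-6)
  expect_error(pk_auc(c(0, 1, 1), c(1, 1, 1)), "increasing")
  # constant-clearance profile: dose / AUC_inf recovers the clearance. The
  # horizon must outlast the slow intracellular-adipose washout phase
  # (CLPD 0.1 L/h) before the log-linear tail is extrapolated.
  p <- ref_profile("cefazolin", 500, 2, t_end = 48)
  auc <- pk_auc(p$time, p$plasma_total, extrapolate = TRUE)
  expect_lt(abs(500 / auc / p$clr - 1), 0.005)
})

test_that("the printed footnote identities hold", {
  expect_equal(auc_from_clearance(1000, 7.18), 139.27, tolerance = 1e-4)
  expect_equal(clearance_from_auc(750, 77), 9.74, tolerance = 1e-3)
  expect_equal(clearance_from_auc(1500, 137), 10.9, tolerance = 1e-2)
  expect_identical(clearance_from_auc(0, 100), 0)
  expect_error(clearance_from_auc(100, 0), "AUC")
})

test_that("time above threshold matches the monoexponential closed form", {
  t <- seq(0, 12, by = 0.002)
  conc <- 100 * exp(-0.693 * t)
  # threshold 12.5 = three half-lives -> 3.0 h
  expect_equal(as.numeric(time_above_threshold(t, conc, 12.5)), 3.0,
               tolerance = 1e-3)
  low <- time_above_threshold(t, conc, 500)
  expect_identical(as.numeric(low), 0)
  expect_false(attr(low, "reached"))
  expect_gte(as.numeric(time_above_threshold(t, conc, 2)),
             as.numeric(time_above_threshold(t, conc, 8)))
  # from_time truncation only counts the residual interval
  expect_equal(as.numeric(time_above_threshold(t, conc, 12.5,
                                               from_time = 1)), 2.0,
               tolerance = 1e-3)
})

test_that("trial counting, determinism and percentile ordering hold", {
  tr <- cached("trial_small", {
    run_trials(lean_spec(n = 2, seed = 5), "cefazolin",
               dosing_regimen(500, 2), n_trials = 3, seed = 5, t_end = 8)
  })
  expect_identical(tr$n_subjects, 6L)
  expect_identical(ncol(tr$outputs$plasma_total), 6L)
  tr2 <- run_trials(lean_spec(n = 2, seed = 5), "cefazolin",
                    dosing_regimen(500, 2), n_trials = 3, seed = 5,
                    t_end = 8)
  expect_identical(tr$summary, tr2$summary)
  expect_identical(tr$endpoints, tr2$endpoints)
  s <- tr$summary$plasma_total
  expect_true(all(s$p5 <= s$mean + 1e-12))
  expect_true(all(s$mean <= s$p95 + 1e-12))
})

test_that("zero-variability populations collapse the percentile band", {
  tr <- run_trials(lean_spec(n = 3, seed = 2, variability = FALSE),
                   "cefazolin", dosing_regimen(500, 2), n_trials = 1,
                   seed = 2, t_end = 6)
  s <- tr$summary$plasma_total
  expect_equal(s$p5, s$mean, tolerance = 1e-12)
  expect_equal(s$p95, s$mean, tolerance = 1e-12)
})

test_that("free time-above-MIC equals total time above MIC/fu", {
  tr <- cached("trial_small", stop("cache miss"))
  tm <- tr$tmic
  p <- tr$outputs
  for (i in c(1, 4)) {
    direct <- time_above_threshold(tr$time, p$plasma_unbound[, i], 8)
    via_total <- time_above_threshold(tr$time, p$plasma_total[, i],
                                      8 / 0.225)
    expect_equal(as.numeric(direct), as.numeric(via_total),
                 tolerance = 1e-9)
  }
  # monotone in MIC for every subject and output
  wide <- reshape(tm, idvar = c("subject", "output"),
                  timevar = "threshold", direction = "wide")
  expect_true(all(wide$value_h.2 >= wide$value_h.4 - 1e-12))
  expect_true(all(wide$value_h.4 >= wide$value_h.8 - 1e-12))
})

test_that("time above MIC is nondecreasing in dose", {
  s <- ref_subject()
  cfz <- load_compound("cefazolin")
  p1 <- suppressWarnings(simulate_subject(s, cfz, dosing_regimen(500, 2)))
  p2 <- suppressWarnings(simulate_subject(s, cfz, dosing_regimen(1000, 2)))
  for (thr in c(2, 4, 8))
    expect_gte(as.numeric(time_above_threshold(p2$time, p2$plasma_total,
                                               thr)),
               as.numeric(time_above_threshold(p1$time, p1$plasma_total,
                                               thr)))
})

test_that("coverage fractions match a brute-force recount", {
  tr <- cached("trial_small", stop("cache miss"))
  expect_identical(coverage_at_time(tr, "plasma_total", 0, 1), 1)
  expect_identical(coverage_at_time(tr, "plasma_total", 1e6, 1), 0)
  thr <- 10; t0 <- 1.5
  vals <- apply(tr$outputs$plasma_total, 2, function(y)
    stats::approx(tr$time, y, xout = t0)$y)
  expect_identical(coverage_at_time(tr, "plasma_total", thr, t0),
                   sum(vals >= thr) / length(vals))
  expect_error(coverage_at_time(tr, "nope", 1, 1), "unknown output")
})

test_that("incision offsets truncate the covered window consistently", {
  tr <- cached("trial_small", stop("cache miss"))
  tab <- incision_offset_analysis(tr, offsets_min = c(0, 15, 30, 60),
                                  thresholds = c(2, 8))
  m <- tab[tab$statistic == "mean" & tab$output == "plasma_total", ]
  for (thr in c(2, 8)) {
    mm <- m[m$threshold == thr, ]
    mm <- mm[order(mm$offset_min), ]
    # offset 0 equals the unshifted endpoint
    expect_equal(mm$residual_h[1],
                 as.numeric(time_above_threshold(
                   tr$time, tr$summary$plasma_total$mean, thr)),
                 tolerance = 1e-9)
    expect_true(all(diff(mm$residual_h) <= 1e-12))
    # unique post-peak crossing: offset + residual is constant once the
    # offset is past the upward crossing during the infusion
    post <- mm$offset_min >= 15
    covered <- mm$offset_min[post] / 60 + mm$residual_h[post]
    if (all(mm$reached[post]))
      expect_lt(max(covered) - min(covered), 1e-6)
  }
})
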