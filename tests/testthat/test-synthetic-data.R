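test_that("noiseless synthetic studies reproduce the model exactly", {
  pop <- lean_spec(n = 2, seed = 11, variability = FALSE)
  reg <- dosing_regimen(1000, 2)
  spec <- synthetic_study_spec("cefazolin", pop, reg,
                               sampling_times_min = c(10, 30, 60, 120, 240),
                               residual_cv = 0, seed = 11)
  ds <- generate_virtual_study(spec)
  tr <- run_trials(pop, "cefazolin", reg, n_trials = 1, seed = 11)
  expected <- stats::approx(tr$time, tr$summary$plasma_total$mean,
                            xout = ds$observations$time_min / 60)$y
  expect_equal(ds$observations$mean, expected, tolerance = 1e-12)
  # determinism under a fixed seed
  ds2 <- generate_virtual_study(spec)
  expect_identical(ds$observations, ds2$observations)
})

test_that("the residual error reproduces its nominal CV", {
  pop <- lean_spec(n = 150, seed = 21, variability = FALSE)
  spec <- synthetic_study_spec("cefazolin", pop, dosing_regimen(1000, 2),
                               sampling_times_min = c(30, 120),
                               residual_cv = 0.2, seed = 21)
  ds <- generate_virtual_study(spec, t_end = 6)
  cv <- ds$observations$sd / ds$observations$mean
  expect_true(all(cv > 0.17 & cv < 0.23))
})

test_that("a noiseless synthetic round trip yields unit two-fold ratios", {
  pop <- lean_spec(n = 3, seed = 31, variability = FALSE)
  reg <- dosing_regimen(750, 2)
  spec <- synthetic_study_spec("cefazolin", pop, reg,
                               sampling_times_min = c(15, 45, 90, 180, 360),
                               residual_cv = 0, seed = 31)
  ds <- generate_virtual_study(spec)
  obs <- synthetic_to_observed(ds)
  tr <- run_trials(pop, "cefazolin", reg, n_trials = 1, seed = 31)
  rep <- evaluate_study(tr, obs)
  expect_identical(nrow(rep), 5L)
  expect_true(all(rep$ratio == 1.00))
  expect_true(all(rep$pass))
})

test_that("clearance recovery is self-consistent and dose-invariant", {
  pop <- lean_spec(n = 4, seed = 41, variability = FALSE)
  # dense over the distribution phase, then out past the slow adipose
  # washout phase
  dense <- c(seq(2, 60, by = 2), seq(70, 600, by = 10),
             seq(630, 2100, by = 30))
  spec <- synthetic_study_spec("cefazolin", pop, dosing_regimen(1000, 2),
                               sampling_times_min = dense,
                               residual_cv = 0, seed = 41)
  ds <- generate_virtual_study(spec, t_end = 36)
  rec <- parameter_recovery(ds)
  expect_lt(abs(rec / ds$true_cl - 1), 0.005)
  # doubling the dose leaves recovered clearance unchanged (linearity)
  spec2 <- synthetic_study_spec("cefazolin", pop, dosing_regimen(2000, 2),
                                sampling_times_min = dense,
                                residual_cv = 0, seed = 41)
  rec2 <- parameter_recovery(generate_virtual_study(spec2, t_end = 36))
  expect_equal(rec2, rec, tolerance = 1e-6)
  # sparse designs are refused
  sparse <- synthetic_study_spec("cefazolin", pop, dosing_regimen(1000, 2),
                                 sampling_times_min = c(30, 120),
                                 residual_cv = 0, seed = 41)
  expect_error(parameter_recovery(generate_virtual_study(sparse)),
               "insufficient")
})

test_that("clearance recovery stays within 15% at 20% residual noise", {
  pop <- lean_spec(n = 20, seed = 51)
  times <- c(10, 20, 40, 80, 160, 320, 480, 640)
  spec <- synthetic_study_spec("cefazolin", pop, dosing_regimen(1000, 2),
                               sampling_times_min = times,
                               residual_cv = 0.2, seed = 51)
  ds <- generate_virtual_study(spec)
  rec <- parameter_recovery(ds)
  expect_lt(abs(rec / ds$true_cl - 1), 0.15)
})

test_that("synthetic replicates almost always pass the two-fold AUC check", {
  times <- c(10, 20, 40, 80, 160, 320, 480, 640)
  passes <- vapply(1:200, function(s) {
    pop <- lean_spec(n = 6, seed = 1000 + s)
    spec <- synthetic_study_spec("cefazolin", pop, dosing_regimen(500, 2),
                                 sampling_times_min = times,
                                 residual_cv = 0.2, seed = 1000 + s)
    ds <- generate_virtual_study(spec)
    twofold_ratio(parameter_recovery(ds), ds$true_cl)$pass
  }, logical(1))
  expect_gte(mean(passes), 0.95)
})

test_that("spec validation guards sampling and noise", {
  pop <- lean_spec(n = 2)
  reg <- dosing_regimen(500, 2)
  expect_error(synthetic_study_spec("cefazolin", pop, reg,
                                    sampling_times_min = c(-5, 10)),
               "sampling")
  expect_error(synthetic_study_spec("cefazolin", pop, reg,
                                    sampling_times_min = 30,
                                    residual_cv = -0.1), "residual_cv")
  spec <- synthetic_study_spec("cefazolin", pop, reg,
                               sampling_times_min = c(30, 2000))
  expect_error(generate_virtual_study(spec, t_end = 12), "horizon")
})
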