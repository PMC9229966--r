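test_that("adipose exchange rates follow the two-pool equations", {
  g <- adipose_water_partition(1 / 0.141)  # v_isf = 1 L, v_iw ~ 0.2766 L
  # full equilibrium: plasma = ISF and unbound ISF = unbound IW
  r <- adipose_rates(c_isf = 10, c_iw = 10, c_plasma = 10, geometry = g,
                     q_adip = 5, clpd = 2, fu_isf = 0.5, fu_iw = 0.5)
  expect_equal(unname(r), c(0, 0))
  # direct substitution, unit volumes
  g1 <- list(v_isf = 1, v_iw = 1, v_adipose = 1 / 0.141)
  r2 <- adipose_rates(10, 0, c_plasma = 0, geometry = g1, q_adip = 0,
                      clpd = 1, fu_isf = 1, fu_iw = 1)
  expect_equal(unname(r2), c(-10, 10))
  # amount conservation of the CLPD exchange for arbitrary states
  set.seed(1)
  for (i in 1:20) {
    ci <- runif(1, 0, 50); cw <- runif(1, 0, 50)
    ra <- adipose_rates(ci, cw, c_plasma = ci, geometry = g, q_adip = 0,
                        clpd = runif(1, 0, 5), fu_isf = runif(1, 0.1, 1),
                        fu_iw = runif(1, 0.1, 1))
    expect_equal(g$v_isf * ra[[1]] + g$v_iw * ra[[2]], 0,
                 tolerance = 1e-10)
  }
})

test_that("the system matrix conserves amounts and flows", {
  s <- ref_subject()
  cfz <- load_compound("cefazolin")
  sys <- build_system(s, cfz)
  # every column of M sums to zero: amounts only move between states
  expect_lt(max(abs(colSums(sys$M))), 1e-9)
  # systemic tissue flows account for the whole cardiac output
  expect_equal(sum(s$tissue_flows), s$cardiac_output, tolerance = 1e-9)
  # missing Kp entries are refused
  kps <- predict_kp_set(cfz)
  expect_error(build_system(s, cfz,
                            kps = kps[names(kps) != "muscle"]), "missing")
})

test_that("the integrator reproduces the one-compartment closed form", {
  v <- 10; cl <- 2; dose <- 1000; t_inf <- 2 / 60
  M <- matrix(-cl / v, 1, 1)
  rate <- dose / t_inf
  times1 <- seq(0, t_inf, length.out = 11)
  out1 <- integrate_linear_system(M, u = rate, y0 = 0, times = times1)
  k <- cl / v
  a_end <- rate / k * (1 - exp(-k * t_inf))
  expect_equal(out1[11], a_end, tolerance = 1e-6)
  times2 <- seq(t_inf, 12, length.out = 200)
  out2 <- integrate_linear_system(M, u = 0, y0 = a_end, times = times2)
  analytic <- a_end * exp(-k * (times2 - t_inf))
  expect_lt(max(abs(out2[, 1] / analytic - 1)), 0.001)
})

test_that("simulation keeps mass balance and output invariants", {
  p <- ref_profile("cefazolin", 500, 2)
  expect_lt(p$mass_balance_error, 1e-3)
  expect_true(all(diff(p$time) > 0))
  expect_true(all(p$plasma_total >= 0))
  expect_equal(p$plasma_unbound, 0.225 * p$plasma_total, tolerance = 1e-12)
  # zero dose is a fixed point
  p0 <- simulate_subject(ref_subject(), load_compound("cefazolin"),
                         dosing_regimen(0), t_end = 2)
  expect_true(all(p0$plasma_total == 0) && all(p0$adipose_total == 0))
})

test_that("AUC and Cmax are exactly dose-linear", {
  s <- ref_subject(weight = 97.8, class = "obese")
  cfx <- load_compound("cefuroxime")
  p1 <- suppressWarnings(simulate_subject(s, cfx, dosing_regimen(750, 1)))
  p2 <- suppressWarnings(simulate_subject(s, cfx, dosing_regimen(1500, 1)))
  auc1 <- pk_auc(p1$time, p1$plasma_total, extrapolate = TRUE)
  auc2 <- pk_auc(p2$time, p2$plasma_total, extrapolate = TRUE)
  expect_equal(auc2 / auc1, 2, tolerance = 1e-6)
  expect_equal(max(p2$plasma_total) / max(p1$plasma_total), 2,
               tolerance = 1e-6)
  expect_equal(max(p2$adipose_total) / max(p1$adipose_total), 2,
               tolerance = 1e-6)
})

test_that("infinite permeability collapses to the perfusion-limited model", {
  s <- ref_subject()
  cfz <- load_compound("cefazolin")
  fast <- cfz; fast$adipose_clpd <- 1e6
  reg <- dosing_regimen(1000, 2)
  p_fast <- suppressWarnings(simulate_subject(s, fast, reg))
  p_ws <- suppressWarnings(simulate_subject(s, fast, reg,
                                            adipose_model = "perfusion"))
  auc_fast <- pk_auc(p_fast$time, p_fast$adipose_total)
  auc_ws <- pk_auc(p_ws$time, p_ws$adipose_total)
  expect_lt(abs(auc_fast / auc_ws - 1), 0.02)
})

test_that("adipose ISF peak lags the plasma peak", {
  p <- ref_profile("cefazolin", 500, 2)
  post <- p$time >= 10 / 60   # after circulatory mixing
  t_plasma <- p$time[post][which.max(p$plasma_unbound[post])]
  t_isf <- p$time[post][which.max(p$adipose_isf_unbound[post])]
  expect_gte(t_isf, t_plasma)
})

test_that("halving solver tolerances leaves the AUC unchanged", {
  s <- ref_subject()
  cfz <- load_compound("cefazolin")
  reg <- dosing_regimen(500, 2)
  p1 <- suppressWarnings(simulate_subject(s, cfz, reg))
  p2 <- suppressWarnings(simulate_subject(s, cfz, reg,
                                          rtol = 5e-9, atol = 5e-11))
  expect_lt(abs(pk_auc(p1$time, p1$plasma_total) /
                  pk_auc(p2$time, p2$plasma_total) - 1), 1e-4)
})

test_that("total adipose concentration combines the sub-pools by volume", {
  g <- adipose_water_partition(1)
  expect_equal(total_adipose_concentration(10, 10, g), 1.8)
  expect_equal(total_adipose_concentration(0, 0, g), 0)
  expect_equal(total_adipose_concentration(50, 0, g), 7.05)
})

test_that("dosing regimen guards the bolus convention", {
  expect_error(dosing_regimen(500, 0.5), "0.75 min")
  expect_silent(dosing_regimen(2000, 0.75))
  expect_error(dosing_regimen(-1), "dose")
})
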