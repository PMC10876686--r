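# Forward models: Parker AIF, Tofts/ETM convolution, Brix closed form,
# SPGR signal equation.

test_that("Parker AIF limiting cases and validation", {
  times <- seq(0, 300, by = 3.735)
  zero <- parker_params(0, 0, 0.17, 0.365, 0.056, 0.132, 0, 0.17, 38, 0.48)
  expect_equal(parker_aif(zero, times), rep(0, length(times)))

  # pure washout decays toward zero at long times
  wo <- parker_params(0, 0, 0.17, 0.365, 0.056, 0.132,
                      alpha_w = 1, beta_w = 0.5, s_sig = 38, tau_sig = 0.1)
  tail_val <- parker_aif(wo, 6000)
  expect_lt(tail_val, 1e-5)
  expect_gt(parker_aif(wo, 60), tail_val)

  expect_error(parker_params(NaN, 0.3, 0.17, 0.37, 0.06, 0.13, 1, 0.17, 38, 0.48),
               "finite")
  expect_error(parker_params(0.8, 0.3, 0.17, 0.37, -0.1, 0.13, 1, 0.17, 38, 0.48),
               "widths")
  expect_error(parker_aif(parker_reference_params(), c(3, 1, 2)), "sorted")
})

test_that("canonical Parker curve matches the dense-grid regression values", {
  # frozen from direct evaluation on a 1 ms grid
  tt <- seq(0, 600, by = 0.001)
  cb <- parker_aif(parker_reference_params(), tt)
  expect_equal(max(cb), 6.073208, tolerance = 1e-6)
  expect_equal(tt[which.max(cb)], 10.3540, tolerance = 1e-6)

  t1 <- seq(0, 360, by = 1)
  cb1 <- parker_aif(parker_reference_params(), t1)
  expect_equal(max(cb1), 6.042158, tolerance = 1e-6)
  expect_equal(cb1[61], 0.887187, tolerance = 1e-6)
  expect_equal(cb1[301], 0.452164, tolerance = 1e-6)
  expect_true(all(cb1 >= 0))
})

test_that("Tofts convolution matches fine-grid quadrature on the 3.735 s grid", {
  times <- seq(0, by = 3.735, length.out = 60)
  pk <- parker_reference_params()
  ca <- parker_aif(pk, times, t0 = 15)
  # the model's arterial input is the sampled curve; the oracle integrates
  # the same piecewise-linear input on a 10 ms grid
  aif_fun <- stats::approxfun(times, ca, rule = 2)

  for (p in list(c(0.05, 0.2, 0), c(0.2, 0.3, 0), c(0.2, 0.3, 0.05),
                 c(1.0, 0.6, 0.1))) {
    got <- tissue_conc_tofts(p[1], p[2], p[3], ca, times)
    want <- oracle_tofts_conv(p[1], p[2], p[3], aif_fun, times, dt_fine = 0.01)
    nz <- want > 1e-4
    expect_lt(max(abs(got[nz] - want[nz]) / want[nz]), 0.005)
  }
})

test_that("Tofts forward model degenerate cases", {
  times <- seq(0, by = 3.735, length.out = 40)
  ca <- parker_aif(parker_reference_params(), times, t0 = 10)
  expect_equal(tissue_conc_tofts(0, 0.3, 0, ca, times), rep(0, 40))
  expect_equal(tissue_conc_tofts(0, 0.3, 0.05, ca, times), 0.05 * ca)
  # ETM with vp = 0 identical to TM sample-for-sample
  expect_equal(tissue_conc_tofts(0.2, 0.4, 0, ca, times),
               tissue_conc_tofts(0.2, 0.4, vp = 0, ca, times),
               tolerance = 1e-12)
  expect_error(tissue_conc_tofts(0.2, -0.1, 0, ca, times), "positive")
  expect_error(tissue_conc_tofts(0.2, 0.4, 1.2, ca, times), "vp")
})

test_that("Brix closed form matches ODE integration", {
  times <- seq(0, 220, by = 3.735)
  cases <- list(c(1, 0.5, 0.05, 10), c(1.2, 0.8, 0.05, 6),
                c(0.5, 2, 0.3, 20), c(2, 0.3, 0.29, 6))
  for (p in cases) {
    got <- brix_enhancement(p[1], p[2], p[3], p[4], times)
    want <- oracle_brix_ode(p[1], p[2], p[3], p[4], times)
    expect_lt(max(abs(got - want) / abs(want)), 0.005)
  }
})

test_that("Brix curve shape: unity baseline, rise, washout, continuity at tau", {
  times <- seq(-10, 400, by = 0.5)
  s <- brix_enhancement(1, 0.5, 0.05, 10, times)
  expect_true(all(s[times <= 0] == 1))
  expect_equal(s[times == 0], 1)
  # rises during infusion
  infusion <- s[times >= 0 & times <= 10]
  expect_true(all(diff(infusion) > 0))
  # decays at long times
  expect_lt(s[length(s)], max(s))
  # continuous at tau: closely spaced samples straddling tau agree
  eps <- 1e-7
  expect_equal(brix_enhancement(1, 0.5, 0.05, 10, 10 - eps),
               brix_enhancement(1, 0.5, 0.05, 10, 10 + eps), tolerance = 1e-6)
  # zero amplitude is flat
  expect_equal(brix_enhancement(0, 0.5, 0.05, 10, times),
               rep(1, length(times)))
  expect_error(brix_enhancement(1, 0.5, 0.05, -1, times), "tau")
})

test_that("Brix degenerate kep = kel uses the analytic limit", {
  times <- seq(0, 300, by = 3.735)
  s_eq <- brix_enhancement(1, 0.4, 0.4, 10, times)
  s_near <- brix_enhancement(1, 0.4 + 1e-7, 0.4, 10, times)
  expect_lt(max(abs(s_eq - s_near)), 1e-5)
  want <- oracle_brix_ode(1, 0.4, 0.4, 10, times)
  expect_lt(max(abs(s_eq - want) / abs(want)), 0.005)
})

test_that("SPGR forward signal behaves physically", {
  acq <- acq_params()
  times <- seq(0, by = acq$dt, length.out = 20)
  s_flat <- spgr_signal(rep(0, 20), t10 = 1.0, acq)
  expect_equal(s_flat, rep(s_flat[1], 20))
  # monotone response to concentration
  conc <- seq(0, 3, length.out = 20)
  s <- spgr_signal(conc, t10 = 1.0, acq)
  expect_true(all(diff(s) > 0))
  expect_error(spgr_signal(conc, t10 = -1, acq), "t10")
  expect_error(spgr_signal(conc - 1, t10 = 1, acq), "non-negative")
})
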