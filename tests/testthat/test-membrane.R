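test_that("gating rates match the standard expressions and their limits", {
  # analytic limits at the removable singularities
  expect_equal(gating_rates(10)[["alpha_n"]], 0.1, tolerance = 1e-12)
  expect_equal(gating_rates(25)[["alpha_m"]], 1.0, tolerance = 1e-12)
  # direct evaluation away from singularities
  expect_equal(gating_rates(0)[["beta_h"]], 1 / (exp(3) + 1),
               tolerance = 1e-12)
  expect_equal(gating_rates(0)[["beta_m"]], 4, tolerance = 1e-12)
  # continuity across the singularities
  for (v0 in c(10, 25)) {
    r_lo <- gating_rates(v0 - 1e-6)
    r_hi <- gating_rates(v0 + 1e-6)
    r_at <- gating_rates(v0)
    for (nm in names(r_at)) {
      expect_equal(r_lo[[nm]], r_at[[nm]], tolerance = 1e-4)
      expect_equal(r_hi[[nm]], r_at[[nm]], tolerance = 1e-4)
    }
  }
  # all rates nonnegative over a wide potential range
  for (v in seq(-100, 200, by = 7)) {
    expect_true(all(gating_rates(v) >= 0))
  }
  expect_error(gating_rates(Inf), "finite")
  expect_error(gating_rates(NA_real_), "finite")
})

test_that("steady-state gating satisfies x_inf = alpha/(alpha + beta)", {
  for (v in c(-30, 0, 25, 60, 110)) {
    r <- gating_rates(v)
    ss <- steady_state_gating(v)
    expect_equal(ss[["m"]],
                 r[["alpha_m"]] / (r[["alpha_m"]] + r[["beta_m"]]))
    expect_true(all(ss >= 0 & ss <= 1))
  }
})

test_that("membrane derivative reproduces the current balance", {
  p <- membrane_params(E_Na = 5, E_K = 5, E_l = 5)
  expect_equal(membrane_derivative(5, p, I0 = 0, g_Na = 10, g_K = 10), 0)
  # pure capacitive charging: uA/uF = mV/ms
  p0 <- membrane_params(gbar_Na = 0, gbar_K = 0, g_l = 0)
  expect_equal(membrane_derivative(0, p0, I0 = 10, g_Na = 0, g_K = 0), 10)
  # the resting state of the full model is a fixed point to numerical
  # precision of the steady-state search
  p <- membrane_params()
  v_rest <- 0
  ss <- steady_state_gating(v_rest)
  dv <- membrane_derivative(v_rest, p, I0 = 0,
                            g_Na = p$gbar_Na * ss[["m"]]^3 * ss[["h"]],
                            g_K = p$gbar_K * ss[["n"]]^4)
  expect_lt(abs(dv), 0.05)
})

test_that("deterministic model rests, fires, and respects the threshold", {
  p <- membrane_params()
  # I0 = 0: settles to rest and stays
  out0 <- simulate_deterministic(p, I0 = 0, duration = 300)
  expect_length(out0$spike_times, 0)
  expect_lt(max(abs(tail(out0$V, 1000))), 1)
  # subthreshold bias: no sustained firing after the onset transient
  out2 <- simulate_deterministic(p, I0 = 2, duration = 1000)
  expect_equal(sum(out2$spike_times > 500), 0)
  # suprathreshold bias: sustained periodic firing
  out10 <- simulate_deterministic(p, I0 = 10, duration = 1000)
  expect_gt(sum(out10$spike_times > 500), 30)
  isi <- diff(out10$spike_times[out10$spike_times > 500])
  expect_lt(sd(isi) / mean(isi), 0.05)
})

test_that("threshold bisection brackets the classical value", {
  p <- membrane_params()
  th <- find_threshold_current(p, tolerance = 0.05)
  expect_equal(th, 6.3, tolerance = 0.05 / 6.3)
  # by definition of threshold
  expect_gt(sum(simulate_deterministic(p, th + 1)$spike_times > 500), 2)
  expect_equal(sum(simulate_deterministic(p, th - 1)$spike_times > 500), 0)
  # invariant to halving dt
  th2 <- find_threshold_current(p, tolerance = 0.05, dt = 0.00125)
  expect_lt(abs(th - th2), 0.1)
  expect_error(find_threshold_current(p, tolerance = 0.05,
                                      lower = 7, upper = 10),
               "bracket")
})
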