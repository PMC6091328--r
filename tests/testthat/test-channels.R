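test_that("patch construction rounds counts and derives 20 pS channels", {
  patch <- build_patch(2.2)
  expect_identical(patch$N_Na, 132L)
  expect_identical(patch$N_K, 40L)  # 39.6 rounds up
  big <- build_patch(15.7)
  expect_identical(big$N_Na, 942L)
  expect_identical(big$N_K, 283L)
  expect_equal(patch$gamma_Na, 20)  # 120 mS/cm2 over 60 channels/um2
  expect_equal(patch$gamma_K, 20)
  # all-open conductance equals the deterministic maximum
  expect_equal(patch$g_na_unit * patch$N_Na, 120)
  expect_error(build_patch(0.001), "rounds to zero")
})

test_that("stationary initialization conserves totals and hits limits", {
  patch <- build_patch(2.2)
  set.seed(5)
  st <- init_channel_state(patch, V = 0)
  expect_identical(sum(st$na_counts), patch$N_Na)
  expect_identical(sum(st$k_counts), patch$N_K)
  expect_true(all(st$na_counts >= 0), all(st$k_counts >= 0))
  # strong depolarization: m_inf -> 1, h_inf -> 0, so Na mass sits in m3h0
  st_hi <- init_channel_state(patch, V = 500)
  expect_identical(st_hi$na_counts[["m3h0"]], patch$N_Na)
  expect_identical(st_hi$k_counts[["n4"]], patch$N_K)
  # large ensemble at rest: open K fraction close to n_inf(0)^4
  huge <- build_patch(1000)
  set.seed(6)
  st_big <- init_channel_state(huge, V = 0)
  n_inf <- steady_state_gating(0)[["n"]]
  p_open <- n_inf^4
  se <- sqrt(p_open * (1 - p_open) / huge$N_K)
  expect_lt(abs(st_big$k_counts[["n4"]] / huge$N_K - p_open), 4 * se)
})

test_that("channel stepping conserves totals for every seed", {
  patch <- build_patch(2.2)
  for (seed in 1:5) {
    set.seed(seed)
    st <- init_channel_state(patch, V = 0)
    for (U in c(-40, 0, 30, 100)) {
      st <- step_channels(st, U, dt = 0.01, n_steps = 200)
      expect_identical(sum(st$na_counts), patch$N_Na)
      expect_identical(sum(st$k_counts), patch$N_K)
      expect_true(all(st$na_counts >= 0) && all(st$k_counts >= 0))
    }
  }
})

test_that("clamped ensembles relax to the deterministic steady state", {
  # time-averaged open fractions at a clamp match m_inf^3 h_inf and n_inf^4
  patch <- build_patch(200)  # 12000 Na, 3600 K channels
  ss <- steady_state_gating(30)
  p_na <- ss[["m"]]^3 * ss[["h"]]
  p_k <- ss[["n"]]^4
  set.seed(11)
  st <- init_channel_state(patch, V = 30)
  fr <- nodestim:::.clamped_open_fraction_cpp(
    unname(st$na_counts), unname(st$k_counts), 30, 0.01, 20000)
  # generous 3-sigma-ish bands accounting for temporal autocorrelation
  expect_equal(unname(fr[["na_open"]]), p_na, tolerance = 0.08)
  expect_equal(unname(fr[["k_open"]]), p_k, tolerance = 0.04)
})

test_that("open-fraction fluctuations scale as 1/sqrt(N)", {
  # sample the K open fraction across time at a clamp for several ensemble
  # sizes; log-variance against log-N must have slope -1
  sizes <- c(132, 660, 942, 4000)
  v <- vapply(sizes, function(N) {
    patch <- build_patch(N / 18)  # area chosen so N_K = N
    set.seed(17)
    st <- init_channel_state(patch, V = 20)
    xs <- numeric(300)
    for (i in seq_along(xs)) {
      st <- step_channels(st, 20, dt = 0.01, n_steps = 60)
      xs[i] <- st$k_counts[["n4"]] / patch$N_K
    }
    var(xs)
  }, numeric(1))
  slope <- coef(lm(log(v) ~ log(sizes)))[[2]]
  expect_equal(slope, -1, tolerance = 0.25)
})

test_that("conductances count only fully open channels", {
  patch <- build_patch(2.2)
  st <- init_channel_state(patch, V = 0)
  st$na_counts[] <- 0L
  st$k_counts[] <- 0L
  st$na_counts[["m0h1"]] <- patch$N_Na
  st$k_counts[["n0"]] <- patch$N_K
  expect_equal(unname(stochastic_conductances(st, patch)), c(0, 0))
  st$na_counts[] <- 0L
  st$na_counts[["m3h1"]] <- patch$N_Na
  expect_equal(stochastic_conductances(st, patch)[["g_Na"]], 120)
})

test_that("channel trajectories are bit-reproducible under a fixed seed", {
  patch <- build_patch(11)
  run <- function() {
    set.seed(99)
    st <- init_channel_state(patch, V = 0)
    st <- step_channels(st, 10, dt = 0.01, n_steps = 500)
    st
  }
  a <- run()
  b <- run()
  expect_identical(a, b)
})
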