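test_that("inactivation identities and the worked example hold", {
  # direct substitution: pathologic 56.5, healthy 42.1, stimulated 49.3
  expect_equal(inactivation(56.5, 49.3, 42.1)$ia, 50)
  # 0% when stimulation changes nothing; 100% when firing is physiologic
  set.seed(1)
  for (i in 1:20) {
    h <- runif(1, 30, 50)
    x <- h + runif(1, 5, 30)
    expect_equal(inactivation(x, x, h)$ia, 0)
    expect_equal(inactivation(x, h, h)$ia, 100)
  }
  expect_error(inactivation(40, 35, 45), "exceed")
})

test_that("inactivation is affine in the stimulated rate", {
  set.seed(2)
  for (i in 1:10) {
    h <- runif(1, 30, 50)
    pu <- h + runif(1, 5, 30)
    ps <- runif(1, h - 5, pu + 5)
    delta <- runif(1, 0.1, 5)
    ia1 <- inactivation(pu, ps, h)$ia
    ia2 <- inactivation(pu, ps - delta, h)$ia
    expect_equal(ia2 - ia1, 100 * delta / (pu - h), tolerance = 1e-9)
  }
})

test_that("inactivation can exceed 100% or go negative, uncertainty sane", {
  expect_gt(inactivation(56.5, 40, 42.1)$ia, 100)
  expect_lt(inactivation(56.5, 60, 42.1)$ia, 0)
  r <- inactivation(rate_summary(56.5, 0.5), rate_summary(49.3, 0.5),
                    rate_summary(42.1, 0.5))
  expect_gt(r$ia_uncertainty, 0)
  # exact-rate inputs carry zero uncertainty
  expect_equal(inactivation(56.5, 49.3, 42.1)$ia_uncertainty, 0)
})

test_that("mean firing rate summarizes counts and matches a Poisson oracle", {
  mk <- function(counts, dur = 1) {
    trains <- lapply(counts, function(n)
      structure(list(spike_times = seq_len(n), run_seed = NA, trace = NULL),
                class = "spike_train"))
    structure(list(spike_trains = trains, rates = counts / dur,
                   mean_rate = mean(counts / dur),
                   sem_rate = sd(counts / dur) / sqrt(length(counts)),
                   n_runs = length(counts), duration_s = dur,
                   condition = list(label = "fixture")),
              class = "ns_ensemble")
  }
  one <- mean_firing_rate(mk(5))
  expect_equal(one$rate, 5)
  two <- mean_firing_rate(mk(c(4, 6)))
  expect_equal(two$rate, 5)
  expect_equal(two$sem, 1)
  pois <- mean_firing_rate(make_poisson_ensemble(50, 1, 100, seed = 8))
  expect_lt(abs(pois$rate - 50), 3 * sqrt(50 / 100))
})

test_that("quadratic fits interpolate three points and report correlation", {
  x <- c(1.73, 5, 10)
  fit <- fit_quadratic(x, 0.35 * x^2)
  expect_equal(fit$c2, 0.35, tolerance = 1e-9)
  expect_equal(fit$c0, 0, tolerance = 1e-9)
  expect_equal(fit$c1, 0, tolerance = 1e-9)
  expect_equal(fit$correlation, 1, tolerance = 1e-9)
  # exact interpolation of arbitrary 3 points
  set.seed(3)
  y <- rnorm(3, 20, 10)
  fit2 <- fit_quadratic(x, y)
  expect_equal(fit2$fitted, y, tolerance = 1e-9)
  expect_error(fit_quadratic(c(1, 2), c(1, 2)), "3 points")
})

test_that("superadditivity is the arithmetic excess with shared baselines", {
  pu <- rate_summary(56.5, 0.5)
  hu <- rate_summary(42.1, 0.5)
  ia_c <- inactivation(pu, rate_summary(52, 0.5), hu)
  ia_g <- inactivation(pu, rate_summary(49, 0.5), hu)
  ia_b <- inactivation(pu, rate_summary(43, 0.5), hu)
  sup <- superadditivity(ia_b, ia_c, ia_g)
  expect_equal(sup$difference, ia_b$ia - ia_c$ia - ia_g$ia)
  expect_gt(sup$uncertainty, 0)
  # mismatched baselines are refused
  other <- inactivation(rate_summary(60, 0.5), rate_summary(50, 0.5), hu)
  expect_error(superadditivity(ia_b, other, ia_g), "baseline")
})
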