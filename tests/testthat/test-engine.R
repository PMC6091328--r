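test_that("spike detection counts upward crossings with lockout", {
  expect_length(detect_spikes(rep(0, 1000), 0.01), 0)
  # a single synthetic action potential crossing 50 mV once
  ap <- c(rep(0, 100), seq(0, 100, length.out = 50),
          seq(100, -10, length.out = 200), rep(0, 100))
  expect_length(detect_spikes(ap, 0.01), 1)
  # subthreshold excursions are ignored
  sine49 <- 49 * sin(seq(0, 20 * pi, length.out = 4000))
  expect_length(detect_spikes(sine49, 0.01, threshold = 50), 0)
  # lockout suppresses immediate re-crossings
  jitter <- c(rep(0, 50), 60, 40, 60, 40, 60, rep(0, 50))
  expect_length(detect_spikes(jitter, 0.01, threshold = 50, lockout = 1), 1)
})

test_that("runs are reproducible and spike times well-formed", {
  cfg <- quick_config(duration = 400)
  patch <- build_patch(2.2)
  a <- simulate_run(hh, patch, 10, stimulus_spec("none"), cfg, run_seed = 7)
  b <- simulate_run(hh, patch, 10, stimulus_spec("none"), cfg, run_seed = 7)
  expect_identical(a$spike_times, b$spike_times)
  expect_gt(length(a$spike_times), 0)
  expect_true(all(diff(a$spike_times) >= cfg$lockout))
  expect_true(all(a$spike_times > cfg$burn_in))
  c2 <- simulate_run(hh, patch, 10, stimulus_spec("none"), cfg,
                     run_seed = 8)
  expect_false(identical(a$spike_times, c2$spike_times))
})

test_that("channel noise sustains subthreshold firing; ensembles average it", {
  cfg <- quick_config(n_runs = 6, duration = 500, seed = 3)
  ens <- run_ensemble(hh, build_patch(2.2), 2, stimulus_spec("none"), cfg)
  # subthreshold drive alone is silent in the deterministic limit, yet the
  # small noisy patch fires tens of spikes per second
  expect_gt(ens$mean_rate, 20)
  expect_equal(length(ens$spike_trains), 6)
  expect_equal(ens$mean_rate, mean(ens$rates))
  # reproducibility of the whole ensemble
  ens2 <- run_ensemble(hh, build_patch(2.2), 2, stimulus_spec("none"), cfg)
  expect_identical(ens$rates, ens2$rates)
})

test_that("rates increase with bias current and decrease with patch area", {
  cfg <- quick_config(n_runs = 8, duration = 500, seed = 12)
  none <- stimulus_spec("none")
  r_small_lo <- run_ensemble(hh, build_patch(2.2), 2, none, cfg)
  r_small_hi <- run_ensemble(hh, build_patch(2.2), 10, none, cfg)
  r_big_lo <- run_ensemble(hh, build_patch(15.7), 2, none, cfg)
  # drive monotonicity with clearly separated 3-SEM intervals
  expect_gt(r_small_hi$mean_rate - 3 * r_small_hi$sem_rate,
            r_small_lo$mean_rate + 3 * r_small_lo$sem_rate)
  # noise monotonicity: bigger patch, less channel noise, fewer spikes
  expect_gt(r_small_lo$mean_rate - 3 * r_small_lo$sem_rate,
            r_big_lo$mean_rate + 3 * r_big_lo$sem_rate)
})

test_that("large patches approach the deterministic oracle", {
  # channel counts ~100x the largest physiological patch: subthreshold bias
  # is silent, suprathreshold rate matches the deterministic model within 5%
  cfg <- quick_config(n_runs = 2, duration = 1000, seed = 5)
  huge <- build_patch(1570)
  silent <- run_ensemble(hh, huge, 2, stimulus_spec("none"), cfg)
  expect_equal(silent$mean_rate, 0)
  firing <- run_ensemble(hh, huge, 10, stimulus_spec("none"), cfg)
  det <- simulate_deterministic(hh, 10, duration = 1050)
  det_rate <- sum(det$spike_times > 50)
  expect_equal(firing$mean_rate, det_rate, tolerance = 0.05)
})

test_that("spike trains export to the two-column text format", {
  cfg <- quick_config(n_runs = 3, duration = 300, seed = 2)
  ens <- run_ensemble(hh, build_patch(2.2), 10, stimulus_spec("none"), cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spike_trains(ens, path)
  tab <- read.delim(path)
  expect_named(tab, c("run_id", "spike_time_ms"))
  expect_equal(nrow(tab), sum(lengths(lapply(ens$spike_trains,
                                             `[[`, "spike_times"))))
})
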