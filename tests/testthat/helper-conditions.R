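# Shared fixtures: short, small ensembles for unit tests and a memo cache so
# expensive baselines are simulated at most once per test session.

hh <- membrane_params()

quick_config <- function(n_runs = 4, duration = 300, seed = 1, ...) {
  sim_config(n_runs = n_runs, duration = duration, master_seed = seed, ...)
}

.session_cache <- new.env(parent = emptyenv())

cached_condition <- function(area, I0, stim, config) {
  simulate_condition(area, I0, stim, config, hh, .session_cache)
}

# Acceptance-scale profile: the desk-scale protocol (>= 30 one-second runs
# at dt = 10 us).
accept_config <- function(n_runs = 30, seed = 20260926) {
  sim_config(n_runs = n_runs, duration = 1000, master_seed = seed)
}
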