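#' The full experimental condition grid
#'
#' The faithful grid crosses patch areas {2.2, 11.0, 15.7} um2 with bias
#' current densities {2, 6, 7, 10} uA/cm2 and stimuli: none; GWN with
#' sigma in {1.73, 5, 10} mV; CW with amplitude in {1.73, 5, 10} mV and
#' frequency in {25, 35, 50} kHz; and all CW x GWN combinations.  CW
#' amplitudes equal the GWN standard deviations so the two stimulus types
#' are compared at matched fluctuation amplitude.
#'
#' @param patch_areas patch areas (um2)
#' @param bias_currents bias current densities (uA/cm2); 2 is the healthy
#'   (physiologic) condition, the rest pathologic
#' @param amplitudes CW amplitudes / GWN standard deviations (mV)
#' @param frequencies CW frequencies (kHz)
#' @return list of class `experiment_grid`
#' @export
experiment_grid <- function(patch_areas = c(2.2, 11.0, 15.7),
                            bias_currents = c(2, 6, 7, 10),
                            amplitudes = c(1.73, 5, 10),
                            frequencies = c(25, 35, 50)) {
  structure(list(patch_areas = patch_areas, bias_currents = bias_currents,
                 amplitudes = amplitudes, frequencies = frequencies),
            class = "experiment_grid")
}

#' Memoizing simulation of one condition
#'
#' Runs (or retrieves from `cache`) the ensemble for one (area, I0,
#' stimulus) condition.  Baselines are thereby simulated once per session
#' and reused by every inactivation evaluation; recomputation with the same
#' seeds yields identical results.
#'
#' @param area patch area (um2)
#' @param I0 bias current density (uA/cm2)
#' @param stim_spec a [stimulus_spec()]
#' @param config a [sim_config()]
#' @param params a [membrane_params()]
#' @param cache an environment used as memo table (e.g. `new.env()`);
#'   NULL disables caching
#' @return an `ns_ensemble`
#' @export
simulate_condition <- function(area, I0, stim_spec, config,
                               params = membrane_params(), cache = NULL) {
  key <- paste(area, I0, stimulus_label(stim_spec), config$n_runs,
               config$duration, config$dt, config$burn_in,
               config$master_seed, sep = "|")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  ens <- run_ensemble(params, build_patch(area, params = params), I0,
                      stim_spec, config)
  if (!is.null(cache)) cache[[key]] <- ens
  ens
}

#' Spontaneous-rate table over the area x bias-current grid
#'
#' Mean spontaneous firing rates (no exogenous stimulus) for every patch
#' area and bias current density, with standard errors and the percent
#' increase of each pathologic rate over the healthy (lowest-I0) rate of
#' the same patch.
#'
#' @param grid an [experiment_grid()]
#' @param config a [sim_config()]
#' @param params a [membrane_params()]
#' @param cache optional memo environment shared with other runs
#' @return data.frame with columns `area`, `I0`, `rate`, `sem`,
#'   `pct_increase`
#' @export
run_table1 <- function(grid = experiment_grid(), config = sim_config(),
                       params = membrane_params(), cache = NULL) {
  none <- stimulus_spec("none")
  rows <- expand.grid(I0 = grid$bias_currents, area = grid$patch_areas)
  res <- lapply(seq_len(nrow(rows)), function(i) {
    ens <- simulate_condition(rows$area[i], rows$I0[i], none, config,
                              params, cache)
    data.frame(area = rows$area[i], I0 = rows$I0[i],
               rate = ens$mean_rate, sem = ens$sem_rate)
  })
  out <- do.call(rbind, res)
  base_I0 <- min(grid$bias_currents)
  out$pct_increase <- NA_real_
  for (a in unique(out$area)) {
    base <- out$rate[out$area == a & out$I0 == base_I0]
    sel <- out$area == a & out$I0 != base_I0
    out$pct_increase[sel] <- 100 * (out$rate[sel] - base) / base
  }
  out
}

ia_for_condition <- function(area, I0, stim_spec, config, params, cache,
                             healthy_I0 = 2) {
  none <- stimulus_spec("none")
  path_unstim <- simulate_condition(area, I0, none, config, params, cache)
  healthy <- simulate_condition(area, healthy_I0, none, config, params,
                                cache)
  path_stim <- simulate_condition(area, I0, stim_spec, config, params,
                                  cache)
  inactivation(path_unstim, path_stim, healthy)
}

#' Inactivation tables behind the figure grid
#'
#' Computes the inactivation statistic over the conditions shown in the
#' paper-style figure panels:
#' \describe{
#'   \item{gwn_by_area}{GWN at each sigma, for every area and pathologic
#'     I0 (IA versus patch area).}
#'   \item{cw_amplitude}{CW at 25 kHz for each amplitude, largest patch,
#'     every pathologic I0.}
#'   \item{cw_frequency}{CW at 10 mV for each frequency, largest patch.}
#'   \item{amplitude_response}{IA versus amplitude for CW (25 kHz) and GWN
#'     at matched amplitudes, largest patch, I0 = 6, with the quadratic
#'     fits attached as attributes `fit_cw` and `fit_gwn`.}
#'   \item{combined}{combined CW+GWN (best amplitudes) versus the sum of
#'     the individual IAs, for every area and pathologic I0.}
#' }
#' Unstimulated pathologic and healthy baselines are simulated once and
#' cached; every IA carries its first-order uncertainty.
#'
#' @param grid an [experiment_grid()]
#' @param config a [sim_config()]
#' @param params a [membrane_params()]
#' @param cache memo environment; created internally if NULL
#' @param tables which tables to compute (subset of the names above)
#' @return named list of data.frames
#' @export
run_figure_grid <- function(grid = experiment_grid(),
                            config = sim_config(),
                            params = membrane_params(), cache = NULL,
                            tables = c("gwn_by_area", "cw_amplitude",
                                       "cw_frequency",
                                       "amplitude_response", "combined")) {
  tables <- match.arg(tables, several.ok = TRUE)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  path_I0 <- setdiff(grid$bias_currents, min(grid$bias_currents))
  best_area <- max(grid$patch_areas)
  best_f <- min(grid$frequencies)
  out <- list()

  if ("gwn_by_area" %in% tables) {
    g <- expand.grid(sigma = grid$amplitudes, area = grid$patch_areas,
                     I0 = path_I0)
    g <- g[order(g$sigma, g$area, g$I0), ]
    res <- lapply(seq_len(nrow(g)), function(i) {
      ia <- ia_for_condition(g$area[i], g$I0[i],
                             stimulus_spec("gwn", sigma_N = g$sigma[i]),
                             config, params, cache)
      data.frame(sigma = g$sigma[i], area = g$area[i], I0 = g$I0[i],
                 ia = ia$ia, ia_unc = ia$ia_uncertainty)
    })
    out$gwn_by_area <- do.call(rbind, res)
  }

  if ("cw_amplitude" %in% tables) {
    g <- expand.grid(A = grid$amplitudes, I0 = path_I0)
    res <- lapply(seq_len(nrow(g)), function(i) {
      ia <- ia_for_condition(best_area, g$I0[i],
                             stimulus_spec("cw", A = g$A[i], f = best_f),
                             config, params, cache)
      data.frame(area = best_area, f = best_f, A = g$A[i], I0 = g$I0[i],
                 ia = ia$ia, ia_unc = ia$ia_uncertainty)
    })
    out$cw_amplitude <- do.call(rbind, res)
  }

  if ("cw_frequency" %in% tables) {
    A_max <- max(grid$amplitudes)
    g <- expand.grid(f = grid$frequencies, I0 = path_I0)
    res <- lapply(seq_len(nrow(g)), function(i) {
      ia <- ia_for_condition(best_area, g$I0[i],
                             stimulus_spec("cw", A = A_max, f = g$f[i]),
                             config, params, cache)
      data.frame(area = best_area, A = A_max, f = g$f[i], I0 = g$I0[i],
                 ia = ia$ia, ia_unc = ia$ia_uncertainty)
    })
    out$cw_frequency <- do.call(rbind, res)
  }

  if ("amplitude_response" %in% tables) {
    I0_best <- min(path_I0)
    res <- lapply(grid$amplitudes, function(a) {
      ia_cw <- ia_for_condition(best_area, I0_best,
                                stimulus_spec("cw", A = a, f = best_f),
                                config, params, cache)
      ia_gwn <- ia_for_condition(best_area, I0_best,
                                 stimulus_spec("gwn", sigma_N = a),
                                 config, params, cache)
      data.frame(area = best_area, I0 = I0_best, amplitude = a,
                 ia_cw = ia_cw$ia, ia_cw_unc = ia_cw$ia_uncertainty,
                 ia_gwn = ia_gwn$ia, ia_gwn_unc = ia_gwn$ia_uncertainty)
    })
    tab <- do.call(rbind, res)
    if (nrow(tab) >= 3) {
      attr(tab, "fit_cw") <- fit_quadratic(tab$amplitude, tab$ia_cw)
      attr(tab, "fit_gwn") <- fit_quadratic(tab$amplitude, tab$ia_gwn)
    }
    out$amplitude_response <- tab
  }

  if ("combined" %in% tables) {
    A_max <- max(grid$amplitudes)
    g <- expand.grid(area = grid$patch_areas, I0 = path_I0)
    res <- lapply(seq_len(nrow(g)), function(i) {
      cw <- stimulus_spec("cw", A = A_max, f = best_f)
      gwn <- stimulus_spec("gwn", sigma_N = A_max)
      both <- stimulus_spec("combined", A = A_max, f = best_f,
                            sigma_N = A_max)
      ia_cw <- ia_for_condition(g$area[i], g$I0[i], cw, config, params,
                                cache)
      ia_gwn <- ia_for_condition(g$area[i], g$I0[i], gwn, config, params,
                                 cache)
      ia_both <- ia_for_condition(g$area[i], g$I0[i], both, config, params,
                                  cache)
      sup <- superadditivity(ia_both, ia_cw, ia_gwn)
      data.frame(area = g$area[i], I0 = g$I0[i],
                 ia_combined = ia_both$ia, ia_cw = ia_cw$ia,
                 ia_gwn = ia_gwn$ia, ia_sum = ia_cw$ia + ia_gwn$ia,
                 excess = sup$difference, excess_unc = sup$uncertainty)
    })
    out$combined <- do.call(rbind, res)
  }
  out
}
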