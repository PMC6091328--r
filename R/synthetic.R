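#' Synthetic Poisson spike-train ensembles
#'
#' Generates homogeneous Poisson spike trains with a controlled rate,
#' packaged in the same ensemble structure as the biophysical simulator, so
#' the metrics layer can be exercised and validated independently of the
#' membrane model.  Poisson dispersion is a deliberate simplification of
#' the simulator's slightly refractory spike statistics: these fixtures
#' test the rate and inactivation algebra, not the biophysics.
#'
#' @param rate target firing rate (spikes/s), >= 0
#' @param duration train length (s)
#' @param n_runs ensemble size
#' @param seed integer seed
#' @return an `ns_ensemble` (see [run_ensemble()])
#' @examples
#' ens <- make_poisson_ensemble(50, duration = 1, n_runs = 20, seed = 1)
#' mean_firing_rate(ens)
#' @export
make_poisson_ensemble <- function(rate, duration = 1, n_runs = 100,
                                  seed = 1) {
  stopifnot(rate >= 0, duration > 0, n_runs >= 1)
  set.seed(as.integer(seed))
  trains <- lapply(seq_len(n_runs), function(i) {
    n <- rpois(1, rate * duration)
    structure(list(spike_times = sort(runif(n, 0, duration * 1000)),
                   run_seed = NA_integer_, trace = NULL),
              class = "spike_train")
  })
  counts <- vapply(trains, function(tr) length(tr$spike_times), numeric(1))
  rates <- counts / duration
  structure(list(
    spike_trains = trains, rates = rates,
    mean_rate = mean(rates),
    sem_rate = if (n_runs > 1) sd(rates) / sqrt(n_runs) else NA_real_,
    n_runs = n_runs, duration_s = duration,
    condition = list(area = NA, I0 = NA, stimulus = "synthetic",
                     label = sprintf("poisson_%g", rate)),
    master_seed = as.integer(seed)),
    class = "ns_ensemble")
}

#' Synthetic inactivation scenario with a known ground truth
#'
#' Inverts the inactivation formula: given healthy and pathologic baseline
#' rates and a target IA, the stimulated rate is set to
#' `pathologic - target_ia/100 * (pathologic - healthy)`, and Poisson
#' ensembles are drawn around all three rates.  Feeding the three ensembles
#' to [inactivation()] should recover `target_ia` up to sampling error
#' (parameter-recovery testing of the metrics stage).
#'
#' @param healthy,pathologic baseline rates (spikes/s); `pathologic` must
#'   exceed `healthy`
#' @param target_ia target inactivation (percent); may be negative or
#'   exceed 100
#' @param duration train length (s)
#' @param n_runs ensemble size per condition
#' @param seed integer seed
#' @return list with ensembles `healthy`, `pathologic`, `stimulated` and
#'   the implied `stimulated_rate`
#' @export
make_ia_scenario <- function(healthy, pathologic, target_ia, duration = 1,
                             n_runs = 100, seed = 1) {
  if (!(pathologic > healthy))
    stop("pathologic rate must exceed the healthy rate")
  stim_rate <- pathologic - target_ia / 100 * (pathologic - healthy)
  if (stim_rate < 0)
    stop("target inactivation implies a negative stimulated rate")
  list(
    healthy = make_poisson_ensemble(healthy, duration, n_runs,
                                    mix_seed(seed, 1)),
    pathologic = make_poisson_ensemble(pathologic, duration, n_runs,
                                       mix_seed(seed, 2)),
    stimulated = make_poisson_ensemble(stim_rate, duration, n_runs,
                                       mix_seed(seed, 3)),
    stimulated_rate = stim_rate)
}
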