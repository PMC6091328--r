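#' Membrane-patch specification with integer channel populations
#'
#' Converts a patch area and fixed channel densities into integer channel
#' counts (nearest integer) and per-channel conductances.  The single-channel
#' conductances are derived so that the all-open conductance per unit area
#' equals the deterministic maxima: `gamma = gbar / rho`, which for the
#' default densities (60 Na and 18 K channels per um2) gives 20 pS for both
#' channel types.  Auditory-fiber Ranvier nodes span roughly 2.2 to
#' 15.7 um2, i.e. 132 to 942 Na channels.
#'
#' @param area patch area (um2), > 0
#' @param rho_Na,rho_K channel densities (channels/um2)
#' @param params a [membrane_params()] object supplying the maximal
#'   conductances
#' @return an object of class `patch_spec` with fields `area`, `rho_Na`,
#'   `rho_K`, `N_Na`, `N_K`, `gamma_Na`, `gamma_K` (pS), and the per-open-
#'   channel conductance densities `g_na_unit`, `g_k_unit` (mS/cm2)
#' @examples
#' build_patch(2.2)   # 132 Na, 40 K channels
#' @export
build_patch <- function(area, rho_Na = 60, rho_K = 18,
                        params = membrane_params()) {
  stopifnot(is.numeric(area), length(area) == 1, area > 0,
            rho_Na > 0, rho_K > 0, inherits(params, "membrane_params"))
  N_Na <- as.integer(round(area * rho_Na))
  N_K <- as.integer(round(area * rho_K))
  if (N_Na < 1 || N_K < 1)
    stop("patch too small: a channel count rounds to zero")
  # gbar [mS/cm2] / rho [1/um2] -> pS: 1 mS*um2/cm2 = 1e-11 S = 10 pS
  gamma_Na <- params$gbar_Na / rho_Na * 10
  gamma_K <- params$gbar_K / rho_K * 10
  # conductance density contributed by one open channel:
  # gamma [pS] = 1e-9 mS spread over area um2 = area * 1e-8 cm2
  structure(list(area = area, rho_Na = rho_Na, rho_K = rho_K,
                 N_Na = N_Na, N_K = N_K,
                 gamma_Na = gamma_Na, gamma_K = gamma_K,
                 g_na_unit = gamma_Na * 0.1 / area,
                 g_k_unit = gamma_K * 0.1 / area),
            class = "patch_spec")
}

#' @export
print.patch_spec <- function(x, ...) {
  cat(sprintf("membrane patch: %g um2; %d Na + %d K channels (%g / %g pS)\n",
              x$area, x$N_Na, x$N_K, x$gamma_Na, x$gamma_K))
  invisible(x)
}

na_state_names <- c("m0h0", "m1h0", "m2h0", "m3h0",
                    "m0h1", "m1h1", "m2h1", "m3h1")
k_state_names <- paste0("n", 0:4)

#' Stationary channel-state initialization
#'
#' Draws the occupancy of the 8 Na and 5 K Markov states from the stationary
#' multinomial at a clamped potential `V`, built from the per-particle
#' steady-state probabilities `m_inf`, `h_inf`, `n_inf`.  Independent gating
#' particles make the stationary state occupancy a product-binomial law.
#'
#' @param patch a [build_patch()] object
#' @param V clamped membrane potential (mV)
#' @return an object of class `channel_state`: list of integer vectors
#'   `na_counts` (named m0h0..m3h1) and `k_counts` (n0..n4)
#' @export
init_channel_state <- function(patch, V = 0) {
  stopifnot(inherits(patch, "patch_spec"))
  ss <- steady_state_gating(V)
  m <- ss[["m"]]; h <- ss[["h"]]; n <- ss[["n"]]
  p_na <- as.vector(outer(stats::dbinom(0:3, 3, m), c(1 - h, h)))
  p_k <- stats::dbinom(0:4, 4, n)
  na <- as.integer(rmultinom(1, patch$N_Na, p_na))
  kk <- as.integer(rmultinom(1, patch$N_K, p_k))
  names(na) <- na_state_names
  names(kk) <- k_state_names
  structure(list(na_counts = na, k_counts = kk), class = "channel_state")
}

#' Advance the channel ensemble by Markov steps at a clamped potential
#'
#' For each occupied Markov state, the number of channels leaving within
#' `dt` is drawn from a binomial law with the embedded-jump probability
#' `1 - exp(-Lambda dt)` (`Lambda` = total outgoing rate, with multiplicity
#' factors such as `3 alpha_m` out of `m0`), and the leavers are allocated
#' among the outgoing edges multinomially in proportion to their rates.
#' For `rate * dt << 1` this reduces to independent `Binom(N, rate * dt)`
#' draws per edge, and unlike raw `rate * dt` probabilities it remains a
#' valid law at strongly hyperpolarized potentials where the m-deactivation
#' rate exceeds `1/dt`.  Totals are conserved exactly and no count can go
#' negative; at most one jump per channel is taken per step.
#'
#' @param state a `channel_state`
#' @param U effective membrane potential (mV) at which rates are evaluated
#' @param dt time step (ms)
#' @param n_steps number of consecutive steps to take
#' @return the advanced `channel_state`
#' @export
step_channels <- function(state, U, dt, n_steps = 1) {
  stopifnot(inherits(state, "channel_state"), dt > 0, n_steps >= 1)
  out <- .step_channels_cpp(unname(state$na_counts), unname(state$k_counts),
                            U, dt, as.integer(n_steps))
  na <- out$na_counts; kk <- out$k_counts
  names(na) <- na_state_names
  names(kk) <- k_state_names
  structure(list(na_counts = na, k_counts = kk), class = "channel_state")
}

#' Conductance densities of a channel-ensemble state
#'
#' Only channels in the fully open states conduct: `m3h1` for Na and `n4`
#' for K.  The conductance per unit area is the open count times the
#' single-channel conductance divided by the patch area.
#'
#' @param state a `channel_state`
#' @param patch the matching [build_patch()] object
#' @return named numeric vector `g_Na`, `g_K` (mS/cm2)
#' @export
stochastic_conductances <- function(state, patch) {
  stopifnot(inherits(state, "channel_state"), inherits(patch, "patch_spec"))
  c(g_Na = patch$g_na_unit * state$na_counts[["m3h1"]],
    g_K = patch$g_k_unit * state$k_counts[["n4"]])
}
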