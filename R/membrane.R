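#' Membrane parameters of the Hodgkin-Huxley Ranvier-node model
#'
#' Electrical constants of the space-clamped membrane equation
#' \deqn{C_m dV/dt = -g_l(V - E_l) - g_K(V - E_K) - g_{Na}(V - E_{Na}) + I_0}
#' in the original HH voltage convention: rest at 0 mV, depolarization
#' positive.  The defaults are the standard squid-axon set at 6.3 degrees C,
#' for which the deterministic firing threshold is the classical
#' 6.3 uA/cm2; the model's kinetics are only valid at this base temperature,
#' so `temperature` is fixed.
#'
#' @param C_m membrane capacitance per unit area (uF/cm2)
#' @param gbar_Na,gbar_K maximal Na/K conductances per unit area (mS/cm2)
#' @param g_l leak conductance per unit area (mS/cm2)
#' @param E_Na,E_K,E_l reversal potentials (mV, HH convention)
#' @return an object of class `membrane_params`
#' @examples
#' p <- membrane_params()
#' p$gbar_Na
#' @export
membrane_params <- function(C_m = 1, gbar_Na = 120, gbar_K = 36, g_l = 0.3,
                            E_Na = 115, E_K = -12, E_l = 10.613) {
  stopifnot(C_m > 0, gbar_Na >= 0, gbar_K >= 0, g_l >= 0)
  structure(list(C_m = C_m, gbar_Na = gbar_Na, gbar_K = gbar_K, g_l = g_l,
                 E_Na = E_Na, E_K = E_K, E_l = E_l, temperature = 6.3),
            class = "membrane_params")
}

#' @export
print.membrane_params <- function(x, ...) {
  cat("HH membrane parameters (rest = 0 mV convention, 6.3 C)\n")
  cat(sprintf("  C_m = %g uF/cm2; gbar_Na = %g, gbar_K = %g, g_l = %g mS/cm2\n",
              x$C_m, x$gbar_Na, x$gbar_K, x$g_l))
  cat(sprintf("  E_Na = %g, E_K = %g, E_l = %g mV\n", x$E_Na, x$E_K, x$E_l))
  invisible(x)
}

#' Hodgkin-Huxley gating transition rates
#'
#' Evaluates the six standard 1952 voltage-dependent transition rates at a
#' membrane potential `V`.  The removable singularities of `alpha_m` (at
#' V = 25 mV) and `alpha_n` (at V = 10 mV) are replaced by their analytic
#' limits, so the functions are continuous everywhere.
#'
#' @param V membrane potential (mV, HH convention); must be finite
#' @return named numeric vector with elements `alpha_m`, `beta_m`,
#'   `alpha_h`, `beta_h`, `alpha_n`, `beta_n` (1/ms)
#' @examples
#' gating_rates(10)["alpha_n"]  # analytic limit 0.1/ms
#' @export
gating_rates <- function(V) {
  if (!is.numeric(V) || length(V) != 1 || !is.finite(V))
    stop("V must be a single finite number")
  .hh_rates_cpp(V)
}

#' Steady-state gating variables at a clamped potential
#'
#' `x_inf = alpha_x / (alpha_x + beta_x)` for x in m, h, n.
#'
#' @inheritParams gating_rates
#' @return named numeric vector `m`, `h`, `n`
#' @export
steady_state_gating <- function(V) {
  r <- gating_rates(V)
  c(m = unname(r["alpha_m"] / (r["alpha_m"] + r["beta_m"])),
    h = unname(r["alpha_h"] / (r["alpha_h"] + r["beta_h"])),
    n = unname(r["alpha_n"] / (r["alpha_n"] + r["beta_n"])))
}

#' Right-hand side of the membrane equation
#'
#' Returns dV/dt (mV/ms) for given instantaneous conductances.  An exogenous
#' stimulus sample `s` enters as a potential perturbation: the driving
#' forces are evaluated at the effective potential `U = V + s` (series
#' voltage source; no capacitive displacement current is injected).
#'
#' @param V membrane potential (mV)
#' @param params a [membrane_params()] object
#' @param I0 bias current density (uA/cm2)
#' @param g_Na,g_K instantaneous Na/K conductances per unit area (mS/cm2)
#' @param s stimulus potential sample (mV), default 0
#' @return dV/dt in mV/ms
#' @export
membrane_derivative <- function(V, params, I0, g_Na, g_K, s = 0) {
  stopifnot(inherits(params, "membrane_params"), g_Na >= 0, g_K >= 0)
  if (!all(is.finite(c(V, I0, g_Na, g_K, s))))
    stop("non-finite input to membrane_derivative")
  U <- V + s
  (-params$g_l * (U - params$E_l) - g_K * (U - params$E_K) -
     g_Na * (U - params$E_Na) + I0) / params$C_m
}

#' Deterministic (infinite-channel) HH simulation
#'
#' Forward-Euler integration of the deterministic HH equations.  Serves as
#' the infinite-channel oracle: the stochastic patch converges to this
#' model's behaviour as the channel count grows.
#'
#' @param params a [membrane_params()] object
#' @param I0 bias current density (uA/cm2)
#' @param duration run length (ms)
#' @param dt time step (ms); must be <= 0.01 for accuracy
#' @param V0 initial potential (mV); gating variables start at their
#'   steady-state values for `V0`
#' @return list with `t` (ms), `V` (mV), and `spike_times` detected with the
#'   default +50 mV crossing rule
#' @examples
#' out <- simulate_deterministic(membrane_params(), I0 = 10, duration = 200)
#' length(out$spike_times) > 1
#' @export
simulate_deterministic <- function(params, I0, duration = 1000, dt = 0.01,
                                   V0 = 0) {
  stopifnot(inherits(params, "membrane_params"), dt > 0, duration > 0)
  if (dt > 0.01) stop("dt must be <= 0.01 ms for the forward-Euler scheme")
  x0 <- steady_state_gating(V0)
  n_steps <- round(duration / dt)
  V <- .sim_deterministic_cpp(n_steps, dt, I0,
                              params$C_m, params$g_l, params$E_l,
                              params$gbar_K, params$E_K,
                              params$gbar_Na, params$E_Na,
                              V0, x0[["m"]], x0[["h"]], x0[["n"]])
  list(t = seq_len(n_steps) * dt, V = V,
       spike_times = detect_spikes(V, dt))
}

#' Deterministic firing-threshold current density
#'
#' Bisects the bias current density between a silent and a firing value for
#' the deterministic model.  The firing criterion is at least two spikes in
#' the final 500 ms of a 1000 ms run, which excludes the single onset spike
#' that subthreshold current steps can elicit.  For the standard parameter
#' set at 6.3 degrees C the threshold is the classical 6.3 uA/cm2.
#'
#' @param params a [membrane_params()] object
#' @param tolerance bisection half-width (uA/cm2)
#' @param lower,upper bracketing current densities (uA/cm2); `lower` must be
#'   silent and `upper` firing
#' @param dt integration step (ms); the default is finer than the ensemble
#'   step because the forward-Euler error shifts the repetitive-firing
#'   boundary, which is converged to well below the default tolerance at
#'   2.5 us but sits visibly lower at 10 us
#' @return threshold current density (uA/cm2)
#' @examples
#' \donttest{
#' find_threshold_current(membrane_params(), tolerance = 0.05)
#' }
#' @export
find_threshold_current <- function(params, tolerance = 0.05, lower = 2,
                                   upper = 10, dt = 0.0025) {
  stopifnot(tolerance > 0, lower < upper)
  fires <- function(I0) {
    out <- simulate_deterministic(params, I0, duration = 1000, dt = dt)
    sum(out$spike_times > 500) >= 2
  }
  f_lo <- fires(lower)
  f_hi <- fires(upper)
  if (f_lo || !f_hi)
    stop("bracket invalid: lower endpoint must be silent, upper firing")
  while (upper - lower > 2 * tolerance) {
    mid <- (lower + upper) / 2
    if (fires(mid)) upper <- mid else lower <- mid
  }
  (lower + upper) / 2
}
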