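#' Firing-rate summary of an ensemble
#'
#' Mean and standard error of the per-run firing rates (spike counts
#' normalized to the counted window).
#'
#' @param ensemble an `ns_ensemble` from [run_ensemble()] or
#'   [make_poisson_ensemble()]
#' @return object of class `rate_summary`: `rate`, `sem` (spikes/s),
#'   `n_runs`, `label`
#' @export
mean_firing_rate <- function(ensemble) {
  stopifnot(inherits(ensemble, "ns_ensemble"))
  structure(list(rate = ensemble$mean_rate, sem = ensemble$sem_rate,
                 n_runs = ensemble$n_runs,
                 label = ensemble$condition$label),
            class = "rate_summary")
}

#' Construct a firing-rate summary directly
#'
#' @param rate mean rate (spikes/s)
#' @param sem standard error (spikes/s)
#' @param n_runs ensemble size
#' @param label condition label
#' @return a `rate_summary`
#' @export
rate_summary <- function(rate, sem = 0, n_runs = NA_integer_,
                         label = NULL) {
  stopifnot(rate >= 0, is.na(sem) || sem >= 0)
  structure(list(rate = rate, sem = sem, n_runs = n_runs, label = label),
            class = "rate_summary")
}

as_rate_summary <- function(x) {
  if (inherits(x, "rate_summary")) return(x)
  if (inherits(x, "ns_ensemble")) return(mean_firing_rate(x))
  if (is.numeric(x) && length(x) == 1) return(rate_summary(x))
  stop("expected a rate_summary, ns_ensemble, or single rate")
}

#' @export
print.rate_summary <- function(x, ...) {
  cat(sprintf("%s: %.1f spikes/s (SEM %s, n = %s)\n",
              x$label %||% "rate", x$rate,
              format(x$sem, digits = 3), format(x$n_runs)))
  invisible(x)
}

#' Inactivation: percent firing reduction toward the physiologic rate
#'
#' The suppression statistic
#' \deqn{IA = 100 \frac{r_{path} - r_{stim}}{r_{path} - r_{healthy}}}
#' where `r_path` is the unstimulated rate of the pathologic
#' (hyperexcited) node, `r_stim` its rate under exogenous stimulation, and
#' `r_healthy` the unstimulated rate of a healthy node (subthreshold bias
#' current).  IA is 0% when stimulation changes nothing, 100% when firing is
#' restored to the physiologic level; it can be negative (excitatory
#' stimulation) or exceed 100% (suppression below the physiologic rate).
#' Uncertainty is propagated to first order from the three standard errors.
#'
#' @param path_unstim,path_stim,healthy_unstim `rate_summary` objects (or
#'   ensembles / bare rates, which are coerced)
#' @return object of class `inactivation_result`: `ia` (percent),
#'   `ia_uncertainty` (percent, first-order), and the three rate summaries
#' @examples
#' inactivation(56.5, 49.3, 42.1)$ia  # 50%
#' @export
inactivation <- function(path_unstim, path_stim, healthy_unstim) {
  pu <- as_rate_summary(path_unstim)
  ps <- as_rate_summary(path_stim)
  hu <- as_rate_summary(healthy_unstim)
  D <- pu$rate - hu$rate
  if (!(D > 0))
    stop("pathologic unstimulated rate must exceed the healthy rate")
  ia <- 100 * (pu$rate - ps$rate) / D
  # delta method: dIA/d pu = 100 (ps - hu)/D^2 ; dIA/d ps = -100/D ;
  # dIA/d hu = 100 (pu - ps)/D^2
  sems <- c(pu$sem, ps$sem, hu$sem)
  sems[is.na(sems)] <- 0
  grad <- c(100 * (ps$rate - hu$rate) / D^2,
            -100 / D,
            100 * (pu$rate - ps$rate) / D^2)
  unc <- sqrt(sum((grad * sems)^2))
  structure(list(ia = ia, ia_uncertainty = unc,
                 rate_pathologic_unstim = pu, rate_pathologic_stim = ps,
                 rate_healthy_unstim = hu),
            class = "inactivation_result")
}

#' @export
print.inactivation_result <- function(x, ...) {
  cat(sprintf("inactivation IA = %.1f%% (+/- %.1f)\n",
              x$ia, x$ia_uncertainty))
  invisible(x)
}

#' Least-squares quadratic fit of inactivation versus stimulus amplitude
#'
#' Fits `ia = c0 + c1 x + c2 x^2` by ordinary least squares and reports the
#' correlation between fitted and observed values as the goodness measure
#' (the correlation coefficient R, not R squared).  With exactly three
#' points the parabola interpolates them.
#'
#' @param amplitudes stimulus amplitudes or noise standard deviations (mV)
#' @param ia_values inactivation values (percent)
#' @return object of class `quadratic_fit`: `c0`, `c1`, `c2`,
#'   `correlation`, `fitted`
#' @examples
#' fit_quadratic(c(1.73, 5, 10), 0.35 * c(1.73, 5, 10)^2)$c2
#' @export
fit_quadratic <- function(amplitudes, ia_values) {
  stopifnot(length(amplitudes) == length(ia_values))
  if (length(amplitudes) < 3)
    stop("a quadratic fit needs at least 3 points")
  fit <- lm(ia_values ~ amplitudes + I(amplitudes^2))
  cc <- unname(coef(fit))
  fv <- unname(fitted(fit))
  corr <- if (sd(fv) > 0 && sd(ia_values) > 0) cor(fv, ia_values) else NA_real_
  structure(list(c0 = cc[1], c1 = cc[2], c2 = cc[3],
                 correlation = corr, fitted = fv),
            class = "quadratic_fit")
}

#' @export
print.quadratic_fit <- function(x, ...) {
  cat(sprintf("IA(x) = %.3g + %.3g x + %.3g x^2   (R = %.5f)\n",
              x$c0, x$c1, x$c2, x$correlation))
  invisible(x)
}

#' Superadditivity of combined stimulation
#'
#' Signed difference `IA(CW+GWN) - (IA(CW) + IA(GWN))`, all three computed
#' against the same pathologic and healthy baselines; positive values mean
#' the combined stimulus suppresses more than the sum of its parts.
#' Uncertainty is propagated from the five underlying rates (the shared
#' baselines induce correlations, which the delta method here accounts
#' for exactly to first order).
#'
#' @param combined_ia,cw_ia,gwn_ia `inactivation_result` objects sharing
#'   baselines
#' @return list with `difference` (percentage points), `uncertainty`, and
#'   the three IA values
#' @export
superadditivity <- function(combined_ia, cw_ia, gwn_ia) {
  ias <- list(combined_ia, cw_ia, gwn_ia)
  stopifnot(all(vapply(ias, inherits, logical(1), "inactivation_result")))
  pu <- vapply(ias, function(x) x$rate_pathologic_unstim$rate, numeric(1))
  hu <- vapply(ias, function(x) x$rate_healthy_unstim$rate, numeric(1))
  if (max(pu) - min(pu) > 1e-9 || max(hu) - min(hu) > 1e-9)
    stop("inactivation results do not share baselines")
  diff <- combined_ia$ia - cw_ia$ia - gwn_ia$ia
  # diff = 100 (s1 + s2 - sc - pu) / (pu - hu); delta method over
  # (pu, hu, sc, s1, s2)
  D <- pu[1] - hu[1]
  num <- cw_ia$rate_pathologic_stim$rate + gwn_ia$rate_pathologic_stim$rate -
    combined_ia$rate_pathologic_stim$rate - pu[1]
  sem_of <- function(s) if (is.na(s$sem)) 0 else s$sem
  g_pu <- 100 * (-D - num) / D^2
  g_hu <- 100 * num / D^2
  g_sc <- -100 / D
  g_s1 <- 100 / D
  g_s2 <- 100 / D
  unc <- sqrt((g_pu * sem_of(combined_ia$rate_pathologic_unstim))^2 +
              (g_hu * sem_of(combined_ia$rate_healthy_unstim))^2 +
              (g_sc * sem_of(combined_ia$rate_pathologic_stim))^2 +
              (g_s1 * sem_of(cw_ia$rate_pathologic_stim))^2 +
              (g_s2 * sem_of(gwn_ia$rate_pathologic_stim))^2)
  list(difference = diff, uncertainty = unc,
       ia_combined = combined_ia$ia, ia_cw = cw_ia$ia, ia_gwn = gwn_ia$ia)
}
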