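#' Exogenous stimulus specification
#'
#' Describes the voltage perturbation applied to the node: a continuous-wave
#' (CW) sine of amplitude `A` (mV) and frequency `f` (kHz), zero-mean
#' Gaussian white noise (GWN) of standard deviation `sigma_N` (mV), their
#' sum, or no stimulus.  The noise standard deviation is defined per sample
#' at the simulation step, so CW amplitude and GWN sigma are directly
#' comparable measures of fluctuation amplitude.
#'
#' @param kind one of `"none"`, `"cw"`, `"gwn"`, `"combined"`
#' @param A CW amplitude (mV), >= 0
#' @param f CW frequency (kHz), > 0 when `kind` involves a CW
#' @param sigma_N GWN standard deviation (mV), >= 0
#' @param phase CW initial phase (rad)
#' @return an object of class `stimulus_spec`
#' @examples
#' stimulus_spec("combined", A = 10, f = 25, sigma_N = 10)
#' @export
stimulus_spec <- function(kind = c("none", "cw", "gwn", "combined"),
                          A = 0, f = 25, sigma_N = 0, phase = 0) {
  kind <- match.arg(kind)
  stopifnot(A >= 0, sigma_N >= 0)
  if (kind %in% c("cw", "combined") && !(f > 0))
    stop("CW frequency must be positive")
  structure(list(kind = kind, A = A, f = f, sigma_N = sigma_N, phase = phase),
            class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  lab <- switch(x$kind,
    none = "no stimulus",
    cw = sprintf("CW %g mV @ %g kHz", x$A, x$f),
    gwn = sprintf("GWN sigma %g mV", x$sigma_N),
    combined = sprintf("CW %g mV @ %g kHz + GWN sigma %g mV",
                       x$A, x$f, x$sigma_N))
  cat(lab, "\n")
  invisible(x)
}

stimulus_label <- function(spec) {
  switch(spec$kind,
    none = "none",
    cw = sprintf("cw_A%g_f%g", spec$A, spec$f),
    gwn = sprintf("gwn_s%g", spec$sigma_N),
    combined = sprintf("cw_A%g_f%g+gwn_s%g", spec$A, spec$f, spec$sigma_N))
}

#' Continuous-wave stimulus samples
#'
#' `s[k] = A sin(2 pi f (k-1) dt + phase)` for k = 1..n_steps; deterministic
#' and independent of the RNG.  Frequencies above the Nyquist limit
#' `1/(2 dt)` are rejected; at exactly the Nyquist frequency the sine is
#' sampled twice per period (a degenerate discretization, e.g. 50 kHz at
#' dt = 10 us), which is permitted with a warning since zero-phase sampling
#' there yields an identically small waveform.
#'
#' @param spec a [stimulus_spec()] whose kind involves a CW
#' @param n_steps number of samples
#' @param dt time step (ms)
#' @return numeric vector of stimulus samples (mV)
#' @export
make_cw <- function(spec, n_steps, dt) {
  stopifnot(inherits(spec, "stimulus_spec"),
            spec$kind %in% c("cw", "combined"))
  nyquist <- 1 / (2 * dt)  # kHz, since f is cycles/ms
  if (spec$f > nyquist)
    stop(sprintf("CW frequency %g kHz exceeds the Nyquist limit %g kHz",
                 spec$f, nyquist))
  if (spec$f == nyquist)
    warning(sprintf(
      "CW at the Nyquist frequency (%g kHz at dt = %g ms): 2 samples/period",
      spec$f, dt))
  k <- seq_len(n_steps) - 1
  spec$A * sin(2 * pi * spec$f * k * dt + spec$phase)
}

#' Gaussian-white-noise stimulus samples
#'
#' I.i.d. zero-mean Gaussian samples with per-sample standard deviation
#' `sigma_N`; the spectrum is flat up to the Nyquist frequency by
#' construction.  Draws from R's global RNG, so `set.seed()` makes the
#' realization reproducible.
#'
#' @param spec a [stimulus_spec()] whose kind involves GWN
#' @param n_steps number of samples
#' @return numeric vector of stimulus samples (mV)
#' @export
make_gwn <- function(spec, n_steps) {
  stopifnot(inherits(spec, "stimulus_spec"),
            spec$kind %in% c("gwn", "combined"))
  if (spec$sigma_N == 0) return(numeric(n_steps))
  rnorm(n_steps, mean = 0, sd = spec$sigma_N)
}

#' Assemble the stimulus sample sequence
#'
#' Dispatches on the spec's kind: zeros, CW, GWN, or their elementwise sum.
#'
#' @inheritParams make_cw
#' @return numeric vector of length `n_steps` (mV)
#' @export
make_stimulus <- function(spec, n_steps, dt) {
  stopifnot(inherits(spec, "stimulus_spec"), n_steps >= 1, dt > 0)
  switch(spec$kind,
    none = numeric(n_steps),
    cw = make_cw(spec, n_steps, dt),
    gwn = make_gwn(spec, n_steps),
    combined = make_cw(spec, n_steps, dt) + make_gwn(spec, n_steps))
}
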