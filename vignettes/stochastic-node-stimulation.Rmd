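---
title: "Methods: stochastic Hodgkin-Huxley simulation of auditory-fiber stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stochastic Hodgkin-Huxley simulation of auditory-fiber stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model and its assumptions

`nodestim` simulates a single Ranvier node of an auditory nerve fiber as a
space-clamped Hodgkin–Huxley membrane patch. The membrane equation

$$C_m \frac{dV}{dt} = -g_l (V - E_l) - g_K (V - E_K) - g_{Na}(V - E_{Na}) + I_0$$

uses the standard squid-axon constants at 6.3 °C in the original voltage
convention (rest at 0 mV, depolarization positive): $C_m = 1\ \mu F/cm^2$,
$\bar g_{Na} = 120$, $\bar g_K = 36$, $g_l = 0.3\ mS/cm^2$,
$E_{Na} = 115$, $E_K = -12$, $E_l = 10.613\ mV$. This parameter set is
pinned by the classical deterministic firing threshold of
$6.3\ \mu A/cm^2$, which the package's bisection search reproduces. The
kinetics are valid only at the 6.3 °C base temperature (the temperature
correction factor is exactly 1 there), so no temperature scaling is
exposed; mammalian-temperature node models (SENN, MRG) are out of scope.

The bias current density $I_0$ stands for the depolarizing drive from the
inner hair cells. Healthy fibers are modelled with the subthreshold
$I_0 = 2\ \mu A/cm^2$; the hyperexcited (tinnitus) state with 6, 7, or
$10\ \mu A/cm^2$. Because real Ranvier nodes are small (2.2–15.7 µm² at
60 Na and 18 K channels/µm², i.e. 132–942 Na channels of 20 pS each),
random channel gating produces conductance fluctuations of relative
magnitude $1/\sqrt{N}$ that sustain firing even below the deterministic
threshold. Both ingredients together set the spontaneous rate.

## Channel-noise algorithm

Gating is tracked as occupancy counts of the Markov states of each channel
type: 8 Na states ($m_0h_0 \dots m_3h_1$, open state $m_3h_1$) and 5 K
states ($n_0 \dots n_4$, open state $n_4$), with the standard 1952 rate
functions (removable singularities of $\alpha_m$ at 25 mV and $\alpha_n$
at 10 mV replaced by their analytic limits). Per 10 µs step, each occupied
state with outgoing rates $\lambda_i$ (including multiplicity factors such
as $3\alpha_m$) loses $\mathrm{Binom}(N, 1 - e^{-\Lambda\,dt})$ channels,
$\Lambda = \sum_i \lambda_i$, allocated among the edges multinomially in
proportion to $\lambda_i$. Three properties motivated this embedded-jump
law over raw $\lambda_i\,dt$ probabilities:

* it is a valid probability law for any rate, which matters because
  high-amplitude noise stimulation routinely drives the effective
  potential below $-26$ mV where $3\beta_m > 1/dt$;
* it reduces to the familiar independent $\mathrm{Binom}(N, \lambda\,dt)$
  edge draws whenever $\lambda\,dt \ll 1$ (the entire physiological
  range);
* totals are conserved exactly and counts can never go negative, by
  construction.

Its only approximation is one jump per channel per step; at 10 µs against
millisecond-scale gating this matters only during the brief hyperpolarized
noise excursions, where it slightly slows an already near-instant
relaxation. Clamped-ensemble tests confirm convergence of mean open
fractions to $m_\infty^3 h_\infty$ and $n_\infty^4$ and the $1/N$ variance
scaling. Binomial draws use a geometric waiting-time sampler on R's
uniform stream (falling back to `rbinom` at large $np$), so trajectories
are bit-reproducible under `set.seed()` and the inner loop stays fast
enough for 300-run ensembles.

Channel counts are the nearest integers to density × area (a ≤ 0.5-channel
rounding error, far below channel-noise scale). Ensembles are initialized
from the stationary product-binomial occupancy at the resting potential,
and a 50 ms burn-in is discarded before spike counting; spike-time
histograms are flat after burn-in, and doubling it does not move the
rates.

## Stimulation and its coupling

Stimuli are potential perturbations $s(t)$: a CW sine $A \sin(2\pi f t +
\varphi)$ (amplitudes 1.73/5/10 mV, frequencies 25/35/50 kHz, default
phase 0), zero-mean Gaussian white noise with per-sample standard
deviation $\sigma_N$ (1.73/5/10 mV, i.e. variances 3/25/100 mV²), or
their sum. The per-sample noise convention makes $\sigma_N$ directly
comparable to the CW amplitude as a measure of fluctuation size; its
consequence is that the noise power depends on the sampling step, so
dt is frozen at 10 µs for all reported runs. At 50 kHz the sine is
sampled exactly twice per period (the Nyquist limit of the 10 µs grid);
the package emits this degenerate case with a warning, since with zero
phase the sampled waveform nearly vanishes and the stimulus is
correspondingly ineffective.

The coupling contract is that the channels and conductances sense the
perturbed potential $U = V + s$ — in both the gating-rate arguments and
the ionic driving forces — while the integrated state variable remains $V$
and no capacitive displacement current from $ds/dt$ is injected
(a 25 kHz, 10 mV sine would otherwise add a $\sim$1.6 mA/cm² current,
three orders above threshold, and dominate everything). This was a
genuinely open design point, so the engine exposes it as
`sim_config(coupling =)` with variants `"gates"` (rates only) and
`"currents"` (driving forces only). Under `"currents"` both stimulus
types are mildly excitatory — that variant cannot reproduce any
suppression at all — while `"gates"` preserves noise suppression but
roughly halves CW efficacy; the default `"both"` is the only contract
consistent with the full pattern of suppression across stimulus types and
is used everywhere in the package's reported results.

## Spike detection

A spike is an upward crossing of +50 mV followed by a refractory lockout.
Action potentials of this model peak at 90–115 mV and neither the ≤ 10 mV
stimuli nor subthreshold channel noise can reach +50 mV without a
regenerative event, so the threshold is uncritical (rates change by < 1%
between thresholds of 50 and 70 mV). The lockout, however, must respect
the slow 6.3 °C kinetics: the action potential dwells about 1.3 ms above
+50 mV, and with a 1 ms lockout channel noise during repolarization
re-crosses the threshold and inflates counts by ~15% (producing
inter-spike intervals near 1 ms, which the model cannot generate). The
default lockout is therefore 5 ms — beyond the dwell time, comfortably
below the ~7 ms minimal genuine inter-spike interval at saturation;
counts are identical for any lockout between 2 and 5 ms.

## Ensembles, seeds, and the inactivation statistic

A condition (patch area, bias current, stimulus) is simulated as
`n_runs` independent 1 s runs; 300 runs is the faithful protocol
(about the number of afferent fibers contacted by one cochlear-implant
electrode). Per-run seeds derive from a master seed by an integer hash;
the stimulus realization and the channel RNG use separate derived
substreams, so conditions differing only in stimulus share channel-noise
seeds — a variance-reduction convenience for paired comparisons. Every
spike time is fully determined by (master seed, config, condition).

The inactivation statistic
$IA = 100\,(r_{path} - r_{stim})/(r_{path} - r_{healthy})$ is computed on
ensemble-mean rates (equivalent to spike counts for equal run counts, and
robust to unequal ones), with first-order (delta-method) uncertainty from
the three ensemble standard errors. It errors out when the pathologic
baseline does not exceed the healthy one. Negative and >100% values are
reported as-is. Quadratic fits of IA versus amplitude use ordinary least
squares, reporting the correlation between fitted and observed values
(the R convention, not R²). Superadditivity of combined stimulation is
the signed excess $IA_{CW+GWN} - (IA_{CW} + IA_{GWN})$, with the shared
baselines handled exactly in the first-order error propagation.

## Numerical choices and degenerate inputs

* Forward Euler at dt = 10 µs for all stochastic runs; runs abort with a
  diagnostic if $|V| > 500$ mV (a step-size pathology, never observed at
  the frozen dt).
* The deterministic threshold search uses a finer dt = 2.5 µs: the
  repetitive-firing boundary sits near 6.22 µA/cm² at 10 µs and is
  converged (~6.255) below 2.5 µs, and the search costs seconds either
  way. The firing criterion is ≥ 2 spikes in the last 500 ms of a 1 s
  run, which excludes the single onset spike of subthreshold steps.
* Patches whose channel counts round to zero are rejected; CW frequencies
  above Nyquist are errors, at Nyquist a warning.
* `fit_quadratic` with exactly three points interpolates them to machine
  precision (the paper-style amplitude sweeps have exactly three).

## What the synthetic generator does and does not test

`make_poisson_ensemble()` and `make_ia_scenario()` produce homogeneous
Poisson spike trains packaged identically to simulator output, with the
stimulated rate derived by inverting the IA formula. They validate the
entire metrics layer (rate summaries, IA identities, parameter recovery
within propagated errors) independently of the biophysics. They are
deliberately *not* a model of the simulator's statistics: real spike
trains here are mildly sub-Poisson (refractory), so passing
parameter-recovery tests on Poisson fixtures says nothing about membrane
dynamics — that is what the deterministic oracle, clamped-ensemble, and
scaling tests are for.

## Problem sizes used in the shipped checks

Unit tests run seconds-long ensembles (a few runs of 200–500 ms) plus
deterministic and clamped-ensemble oracles. The acceptance-style checks
and `scripts/acceptance.R` run the full 300 × 1 s protocol per condition;
the script's whole 16-condition sweep takes roughly 10–15 minutes on one
CPU. The quadratic amplitude-response coefficients are by far the
noisiest reported quantities (their Monte Carlo standard error is ~0.1
even at 300 runs, against fitted values of 0.3–0.6), which is why the
full-scale protocol rather than a reduced one is used for them.

## Known limitations

* Quantities dominated by stochastic gating are sensitive to the
  channel-tracking scheme at the few-percent-to-ten-percent level:
  different published stochastic-HH algorithms are known to disagree by
  comparable margins for spontaneous rates in noise-dominated regimes.
  In this implementation that sensitivity shows up as spontaneous rates
  a few percent above typical reference values at the smallest patches
  and subthreshold drive, and most visibly in the suppression achieved by
  the strongest (10 mV) noise stimulus — and hence in the curvature of
  the noise amplitude-response (quadratic coefficient ~0.8 here), which
  inherits that point's value amplified by the fit geometry. These are
  properties of the scheme under extreme hyperpolarized excursions, not
  of the integration step, detection rule, or burn-in, all of which were
  varied without material effect.
* Exact event-driven (Gillespie) stepping, Langevin approximations,
  colored noise, pulse-train waveforms, cable geometry, and
  mammalian-temperature kinetics are not implemented.
* The 50 kHz CW at the Nyquist limit of the 10 µs grid is a degenerate
  discretization kept deliberately (it mirrors the solver the reported
  results assume); conclusions about 50 kHz efficacy are partly a
  property of that discretization.
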