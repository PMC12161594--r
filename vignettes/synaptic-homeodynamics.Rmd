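---
title: "Synaptic homeodynamics across the sleep-wake cycle: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synaptic homeodynamics across the sleep-wake cycle: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Does sleep weaken synapses and wake strengthen them (the synaptic
homeostasis view, SHY), or the reverse (wake inhibition / sleep
excitation, WISE)? `sleepsyn` frames this as a modelling question: given
a calcium-based synaptic learning rule and the statistics of cortical
firing in NREM sleep (synchronized Up/Down alternation) versus
wakefulness (tonic, desynchronized firing), in which direction does
synaptic efficacy drift in each state?  This vignette documents the
models, the parameters that matter, and the numerical and design choices
behind the package.

## The plasticity model

Synaptic efficacy is a bistable variable $\rho \in [0,1]$ obeying

$$\tau_s\,\dot\rho \;=\; -\rho(1-\rho)(\rho^\ast-\rho)
\;+\; \gamma_p (1-\rho)\,\Theta[c-\theta_p]
\;-\; \gamma_d \rho\,\Theta[c-\theta_d] \;+\; \text{noise},$$

where $c$ is the postsynaptic Ca$^{2+}$ concentration and
$\Theta[x] = 1$ for $x \ge 0$.  The cubic term creates two stable states
(0 and 1) separated by the unstable point $\rho^\ast$ (default 0.5, the
referenced model's convention).  Ca$^{2+}$ is the sum of two sources:

* $C_\mathrm{pre}$, NMDAR-mediated, driven by presynaptic firing through
  second-order receptor gating (no Mg$^{2+}$ block), decaying with
  $\tau_\mathrm{pre}$;
* $C_\mathrm{post}$, VGCC-mediated, driven by the postsynaptic membrane
  potential through $m_{Ca\infty}^2(V)$, decaying with
  $\tau_\mathrm{post}$.

The scaling factors $\beta_\mathrm{NMDA}$, $\beta_\mathrm{VGCC}$ are not
free: `calibrate_scaling()` fixes them so that a single presynaptic
transient peaks at 0.7 uM and a single postsynaptic one at 1.4 uM under
the 1 Hz pairing protocol, matching the experimental amplitude ratio.
Both sources are linear in their scaling factor, so the calibration is
exact.  Because the amplitudes are pinned, the absolute magnitudes of the
unit conductances and of `alpha_ca` in `plasticity_constants()` are
immaterial; only the threshold positions relative to 0.7/1.4 uM matter.

### Noise term and the coefficient z

The efficacy noise is additive and gated: it acts only while $c$ exceeds
at least one threshold.  The implemented per-step form is

$$\Delta\rho_\text{noise} = \sigma\, z\,
\sqrt{\Theta[c-\theta_d]+\Theta[c-\theta_p]}\;
\sqrt{\Delta t/\tau_s}\;\eta,\qquad \eta\sim\mathcal N(0,1),$$

with $z = 3.5$.  The analytic change formula below uses the *same*
convention, so the two routes agree by construction; the
analytic-versus-Monte-Carlo property test is the contract that pins the
noise implementation down.  With this scaling the stationary SD of
$\rho$ during stimulation, $\sigma z \sqrt{(\alpha_p+\alpha_d) /
(2(\Gamma_p+\Gamma_d))}$, is independent of $\tau_s$.

### Analytic synaptic change

During a stimulation protocol, let $\alpha_x$ be the fraction of time $c$
spends above $\theta_x$ and $\Gamma_x = \gamma_x \alpha_x$.  Averaged
over threshold crossings, $\rho$ performs a noisy linear relaxation with
rate $(\Gamma_p+\Gamma_d)/\tau_s$ toward
$\Gamma_p/(\Gamma_p+\Gamma_d)$; the protocol endpoint is Gaussian with
known mean and variance.  After the protocol the cubic drift settles
every synapse to 0 or 1 according to the side of $\rho^\ast$, so the
mean final efficacy is the Gaussian's upper-tail probability at
$\rho^\ast$, and the reported *change* is that mean divided by
$\rho_0 = 0.5$.  Sub-threshold protocols return exactly 1.  The cubic
term is neglected *during* the protocol (it is orders of magnitude
slower than the threshold-gated terms for accepted parameter sets); the
Monte-Carlo comparison bounds the error of this approximation.

## Learning-rule search

`search_rules()` samples rule parameters uniformly, calibrates the
scaling, rebalances $\gamma_d$ so that potentiation and depression rates
cancel at a 100 ms pre-post lag (spike pairs too far apart to interact
leave no net change — this also forces the change curve to 1 at large
lags), computes the analytic change over lags $-160..160$ ms in 10 ms
steps, and accepts candidates whose sum of squared errors against a
piecewise-Gaussian target (amplitude `a_lr`, width `tau_lr`, sign
pattern per family) is strictly below the threshold (0.25 by default,
0.6 for the network-model variant).  On top of the SSE the search
requires the curve lobes at $\pm 20$ ms to carry the family's sign
pattern, so every accepted set satisfies the curve taxonomy by
construction.  Accepted sets are returned in ascending SSE order.

The sampling boxes (`default_rule_ranges()`) are package defaults chosen
once: thresholds live in two bands anchored to the calibrated amplitudes
(a high band 0.8–1.6 uM reachable mainly by coincident transients and a
low band 0.5–1.0 uM reachable by single transients, assigned by the
family's threshold ordering, mirroring the printed network-search
boxes); Ca$^{2+}$ decay constants 5–60 ms span the STDP window;
$\gamma$'s 20–400 and $\tau_s$ 30–180 s put the 60 s protocol in the
partially-relaxed regime; $\sigma$ 0.2–1.0 with $z=3.5$ gives graded
(neither frozen nor saturated) change curves.  Acceptance rates are
roughly 0.2% (STDP), 0.8% (Hebbian), 0.6% (Anti-Hebbian) and 0.08%
(Anti-STDP) of sampled candidates; the default pairing protocol is 1 Hz
for 60 s as in the search procedure (one figure caption says 60 Hz,
which conflicts with the printed search protocol; the rate is an
argument).

## Synthetic firing patterns

The generator is the package's definition of the study conditions, not a
fixture.  Interval lengths are lognormal in $\log_{10}$(ms), with the SD
of each distribution tied to its mean through fixed linear regressions
estimated from in vivo rat recordings (`sd_from_mean()`), e.g. wake ISI
SD $= 0.03\,m + 0.65$.  Outside the observed range these regressions
extrapolate to negative SDs; sampling floors the SD at 0.01.

* **Wake-like** trains cumulate lognormal ISIs.
* **Sleep-like** trains alternate Up and Down intervals drawn from their
  duration lognormals and fill each Up interval with lognormal-ISI
  spikes.  All neurons of one pattern share a single Up/Down skeleton
  (population-wide slow-wave synchrony — the premise of the sleep
  score) with independent within-Up spiking.

The default Fig-1-style configuration uses mean Up duration
$10^{2.7}$ ms, within-Up mean ISI $10^{1.5}$ ms, and adjusts the mean
Down duration to hit a target mean rate.  The printed "UPM = 1.5,
ISIM = 2.7" annotation would give Up states shorter than one ISI; the
package adopts the swapped, physiological reading (the companion
annotation "DOWNM = 3.12, UPM = 2.7" is consistent with it).  Rate
matching (`match_rate()`) bisects on the chosen knob against a
deterministic empirical rate estimate (`evaluate_spec_rate()`: five
fixed-seed trains, duration scaled to cover enough Up/Down episodes);
the 2% tolerance is meaningful under that estimator, while independent
realizations of slow Up/Down alternation fluctuate more.

Spike trains become membrane-potential waveforms by piecewise-linear
interpolation through anchors: baseline $\to$ peak (+30 mV) over 1 ms,
peak $\to$ after-hyperpolarization (−75 mV) over 2 ms, return to
baseline by 8 ms; anchor offsets compress proportionally when spikes are
closer than the anchor window so peaks stay exactly at the timestamps.
The baseline is the Down-state potential (−70 mV) in wake and Down
states, and the Up-state potential (−55 mV by default, a 15 mV
separation; 5 and 10 mV are supported) inside Up intervals.  These
anchor values are package defaults standing in for an unavailable
constants table; they matter only through the widths of the VGCC and
NMDAR activation transients.

## Fixed-pattern experiments

`run_state_comparison()` drives every rule set over a topology
(`fan_in_10`, `fan_in_96`, or `random_p12`) with one generated pattern
per state: initial efficacies 0.5, six simulated minutes, the last two
minutes averaged; the across-synapse CV is computed per time step and
averaged over the window.  Each state runs under its own copy of the
seed stream, so identical state specifications yield identical reports
and the sleep−wake contrast is a paired comparison under common random
numbers.  `sweep_rates()` repeats this over a rate grid in two designs:
`matched` (equal mean rates, the Fig-1/2 design) and `up_rate` (wake
rate equal to the within-Up sleep rate, i.e. both states share the mean
ISI; wake then fires roughly three times faster overall).

Mechanistically, WISE under Hebbian/STDP at matched rates comes from the
synchronized Up states: the ten presynaptic partners and the
postsynaptic neuron all burst together, so NMDAR and VGCC transients
summate past the potentiation threshold far more often than in
desynchronized wake firing at the same mean rate, while the balanced
depression dominates isolated wake transients.  The Anti rules invert
the threshold bands and hence the verdict.  In the `up_rate` design the
within-Up advantage is removed by construction; the contrast then
reflects total exposure, and flips from WISE at low rates to a small
SHY-direction difference once the wake rate is high enough for
sustained Ca$^{2+}$ summation (the high-rate regime equilibrates both
states toward the same attractor, so the flipped difference is small —
a known fragility of this reproduction, sensitive to the pattern
realization).

## Hodgkin-Huxley network

The averaged-neuron model has nine intrinsic currents (leak, Na, K, A,
KS, Ca, KCa, NaP, AR), three synaptic receptor currents (AMPA, NMDA,
GABA) whose gating is driven by the neuron's own potential in the
single-neuron ("averaged", mean-field) configuration, and a cell-body
Ca$^{2+}$ pool.  Units: mV, ms, mS/cm$^2$ intrinsic conductances
(converted to nA by area $\times$ 10), uS synaptic conductances.
Reversal potentials, kinetics and the Ca$^{2+}$ conversion factor follow
the classic cortical slow-oscillation lineage of the model family
(`hh_constants()`); they stand in for an unavailable constants table and
are configurable.

The search (`search_swo()`) samples conductances log-uniformly over the
printed decade intervals ("exponential distribution bounded to an
interval" is read as log-uniform, the standard choice for
decade-spanning bounds), integrates 6 s with RK4 from the printed
initial values and classifies the 1–6 s window by the printed six-way
rules (`classify_pattern()`).  Defaults: dt = 0.05 ms (the upper end of
the reference step range; integration instabilities at this step
classify as EXCLUDED, as blow-ups did in the source procedure), voltage
functions tabulated on a 0.05 mV grid, and a quiescence fast-forward
that freezes trajectories pinned within 0.01 mV for 500 ms (their
remaining trace is constant).  About 1% of sampled sets land in the SWO
family.  Eight searched sets are shipped as
`inst/extdata/hh_swo_sets_synthetic.csv` — synthetic representatives
produced by this package's own reduced search, standing in for the
original (unavailable) representative table.

Bifurcation analysis multiplies one conductance (or the presynaptic
activation coefficients jointly) along log-uniform grids with the
printed endpoints and step counts; single-neuron sweeps are accepted
when an adjacent AWAKE-to-SWO transition hyperpolarizes the SWO side by
more than 5 mV.  Network stages (80 neurons, E:I 4:1, two synapses per
neuron, no I-to-I connections, conductances divided by the mean synapse
count) are summarized per step by the sleep score (CV of population
spike counts in 50 ms bins), the percentages of SWO- and AWAKE-family
neurons, and the mean rate; wake-like steps need score < 1.0 and > 30%
AWAKE neurons, sleep-like steps score >= 1.3 and > 30% SWO neurons, and
`select_matched_pair()` requires the rates to agree within 2 Hz.
Network initial conditions are randomly assigned (V uniform in −80..−50
mV, gates uniform in 0..1 — ranges are package defaults, as the source
states no ranges).  Plasticity couples each excitatory synapse's
efficacy to its AMPAR conductance as $g = g_0(0.5+\rho)$; in the
network the NMDAR Ca$^{2+}$ driving force uses the instantaneous
postsynaptic potential, the scaling uses $\beta_\mathrm{NMDA}=1$ with
$\beta_\mathrm{VGCC}$ from $2\,MC_\mathrm{pre}=MC_\mathrm{post}$, and
thresholds are renormalized by $MC_\mathrm{pre}/0.7$ (amplitudes
measured as means of per-second window maxima — a robust stand-in for
per-transient peaks when transients overlap).

## Sleep-wake oscillator

Two phosphorylation fractions of a CaMKII-like kinase drive spontaneous
state alternation: $r$ (self-activating, Ca$^{2+}$-activated) and $a$
(activated by $r$, Ca$^{2+}$-inhibited), each relaxing toward a sigmoid
of its inputs, with exact-discretization Ornstein-Uhlenbeck input noise
(stationary SD $\varepsilon$, time scale $1/\theta$).  The selected
variable (default $a$) multiplies the bifurcation conductance by
`max_rate` $\times\,a(t)$, sweeping the network across its wake/sleep
bifurcation as phosphorylation accumulates during wake.  The
presynaptic-mechanism Ca$^{2+}$ proxy is implemented, as printed,
without its own relaxation (an instantaneous algebraic function of the
presynaptic potential).  Kinase states live per neuron and update every
`stride` integration steps with Ca$^{2+}$ averaged over the stride (the
kinase time scales are four orders of magnitude slower than the
membrane).  `kinase_params()` ships two documented presets — oscillatory
(relaxation oscillation, period a few minutes at the default
$\tau_r = 5$ s, $\tau_a = 15$ s) and bistable (alternation only under
noise); `max_rate = 2` spans multiplier 0–2, which covers the
bifurcation interval of the shipped representative sets.  Sleep/wake
periods are classified by thresholding sleep scores computed in sliding
5 s windows (500 ms step, 10-point moving average) against a
`null_threshold()` quantile (default ensemble 10^4 instead of 10^6;
the quantile's order-statistic CI is attached).  Process S follows its
exact exponential updates, and `select_dynamics_models()` keeps runs
with total sleep/wake balance in [0.7, 1.3) ranked by the Pearson
correlation between the configured variable and Process S.

## Statistics

`bayes_diff_means()` implements the Bayesian two-group comparison as a
conjugate Gibbs sampler: independent normal likelihoods, vague normal
priors on the means (SD $10^3$) and inverse-gamma (10^{-3}, 10^{-3})
priors on the variances ("non-informative" is realized this way because
no specific priors are named; with the group sizes used, the posterior
is insensitive to these hyperparameters, which remain arguments), 5000
kept draws after 2000 burn-in.  A difference is called when the 95%
credible interval excludes zero; WISE/SHY verdict strings are derived
from the interval's sign only.  Student and Welch t tests wrap
`stats::t.test()`.  No multiple-comparison correction is applied,
matching the source analyses.

## Problem sizes and numerical choices

Analyses in the test suite and acceptance script are scaled-down runs of
the identical procedures: 100 accepted sets per rule family (from a few
hundred thousand candidates) instead of 1000 from over a million;
10^4-sample slow-wave searches; 10^4-replicate null ensembles; fan-in-10
comparisons over 6 simulated minutes at dt = 0.05 ms; rule searches at
dt = 0.1 ms.  The linear Ca$^{2+}$ filters are integrated with the exact
exponential integrator (closed-form, cheaper and more accurate than RK4
for tabulated drives); nonlinear receptor gating and the
Hodgkin-Huxley equations use RK4; the efficacy SDE uses Euler-Maruyama
(the standard strong-order-1 scheme for additive noise), with the
deterministic part verified to be step-insensitive (halving dt moves
endpoints by < 10^{-3}).  Ca$^{2+}$ is clipped at zero from below
(concentrations are non-negative; the exponential integrator can
undershoot on steep drive edges).  Efficacy noise may transiently push
$\rho$ outside [0, 1]; the cubic drift restores it, and no clipping is
applied so the stationary statistics stay unbiased.

## What the synthetic data do and do not show

The generators emulate the interval statistics (lognormal durations and
ISIs, their mean-SD coupling) and the population synchrony structure of
cortical recordings.  They do not emulate mixed ISI distributions within
Up states (a single lognormal is used), cell-to-cell rate
heterogeneity, travelling-wave structure of slow oscillations, or any
neuromodulatory influence on the learning rules.  Passing tests
therefore show that the *models* behave as derived under the stated
firing statistics — not that cortical synapses do.  The WISE/SHY
verdicts are statements about median behaviour of accepted rule
ensembles under matched-rate synthetic drive; single synapses settle
stochastically to either attractor.

## Known limitations

* The high-rate side of the Up-state-rate-matched sweep produces only a
  small negative (SHY-direction) median difference; both states
  equilibrate toward the same efficacy attractor once Ca$^{2+}$
  summation saturates, so the sign is sensitive to the pattern
  realization at realistic ensemble sizes.
* Full-scale searches (10^6 candidates, 10^6-replicate null ensembles)
  and long (18–36 min) low-rate runs are supported by the same code but
  not exercised by the shipped tests.
* The network rule search and the sleep-wake cycle runs are validated
  structurally and at reduced scale; finding network parameter sets
  with both an accepted wake-like and sleep-like step is rare enough
  that end-to-end network WISE/SHY statistics need a larger search than
  the shipped examples.
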