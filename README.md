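# sleepsyn

Does NREM sleep weaken cortical synapses and wakefulness strengthen them
(synaptic homeostasis, **SHY**), or the reverse (**WISE** — wake
inhibition, sleep excitation)? `sleepsyn` is a simulation framework for
asking that question of a model rather than a mouse. It combines:

* a **two-threshold calcium-based plasticity rule**: bistable efficacy
  `rho` driven by `tau_s drho/dt = -rho(1-rho)(rho*-rho) +
  gamma_p (1-rho) H(c-theta_p) - gamma_d rho H(c-theta_d) + noise`,
  where the postsynaptic calcium `c` sums an NMDAR source (presynaptic
  spikes, decay `tau_pre`) and a VGCC source (postsynaptic potential,
  decay `tau_post`), with source amplitudes calibrated to 0.7 and
  1.4 uM;
* an **analytic STDP curve** and a random parameter search that
  classifies rules into Hebbian, STDP, Anti-Hebbian and Anti-STDP
  families by fitting piecewise-Gaussian targets;
* **lognormal spike-train generators** for sleep-like (shared Up/Down
  skeleton, within-Up bursting) and wake-like (tonic) firing, with
  mean-SD regressions from in vivo recordings and rate matching;
* fixed-pattern **efficacy experiments** (fan-in and random topologies,
  6-minute runs, last-2-minute averages) comparing the two states;
* a **Hodgkin-Huxley averaged-neuron network** (9 intrinsic + 3
  synaptic currents) with a slow-wave-oscillation parameter search,
  two-stage bifurcation analysis, a population-synchrony "sleep score",
  and efficacy-to-AMPAR coupling;
* a **two-state kinase (CaMKII-like) sleep-wake oscillator** with
  Ornstein-Uhlenbeck input noise and Process S;
* **comparison statistics**: Bayesian difference of group means (Gibbs
  MCMC, 95% credible intervals) and t tests, with WISE/SHY verdicts
  derived from the interval sign.

## Worked example

Search for STDP rules, build matched 1 Hz sleep/wake patterns, and
compare mean synaptic efficacy between the states:

```r
library(sleepsyn)

rules <- search_rules("STDP", n_target = 20, budget = 4e4, seed = 42)
nrow(rules)                      # 20 accepted sets, ascending SSE
head(rules$sse, 3)               # 0.129 0.135 0.142

ss <- match_rate(pattern_spec("sleep", 360, isim = 1.5, upm = 2.7,
                              downm = 3.5), 1, "downm")
ws <- match_rate(pattern_spec("wake", 360, isim = 2.4), 1, "isim")
attr(ss, "achieved_rate")        # 0.9901  (Hz)
attr(ws, "achieved_rate")        # 1.0089

cfg <- experiment_config(rules, ss, ws)
rep <- run_state_comparison(cfg, build_topology("fan_in_10"), seed = 3)
aggregate(mean ~ state, rep, mean)
#>   state      mean
#> 1 sleep 0.649
#> 2 wake  0.503

comparison_table(rep, method = "bayes_mcmc", seed = 1)
#>   rule_label  n  diff ci_low ci_high excludes_zero verdict
#> 1       STDP 20 0.146  0.086   0.204          TRUE    WISE
```

At equal mean rates (1 Hz), sleep-like synchronized bursting drives the
mean efficacy of the STDP rules above their wake-like values: the
credible interval of the sleep-minus-wake difference excludes zero from
above, which the package reports as WISE. Running the same comparison
with `search_rules("AntiSTDP", ...)` flips the verdict to SHY.

The slow-wave network side works the same way from a shell:

```sh
Rscript inst/cli/sleepsyn.R search-swo --n 1000 --seed 4 --out swo.csv
# 9 / 1000 sets classified SWO-family -> swo.csv
```

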