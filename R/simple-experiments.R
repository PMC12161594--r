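#' Build a pre/post connection topology
#'
#' Topologies of the fixed-firing-pattern experiments: `fan_in_10` /
#' `fan_in_96` connect that many presynaptic neurons to one postsynaptic
#' neuron; `random_p12` wires each ordered pair of `n` neurons with
#' probability 0.12 (no self-edges).
#'
#' @param kind Topology kind.
#' @param n Number of neurons for `random_p12` (default 10).
#' @param seed Optional integer seed (random kind only).
#' @return A `topology` object: list with `kind`, `n_neurons` and an edge
#'   data frame (`pre`, `post`, 1-based neuron indices).
#' @export
build_topology <- function(kind = c("fan_in_10", "fan_in_96", "random_p12"),
                           n = 10, seed = NULL) {
  kind <- match.arg(kind)
  edges <- switch(kind,
    fan_in_10 = data.frame(pre = 1:10, post = 11L),
    fan_in_96 = data.frame(pre = 1:96, post = 97L),
    random_p12 = with_seed(seed, {
      pairs <- expand.grid(pre = seq_len(n), post = seq_len(n))
      pairs <- pairs[pairs$pre != pairs$post, ]
      pairs[stats::runif(nrow(pairs)) < 0.12, c("pre", "post")]
    })
  )
  n_neurons <- switch(kind, fan_in_10 = 11L, fan_in_96 = 97L,
                      random_p12 = as.integer(n))
  structure(list(kind = kind, n_neurons = n_neurons,
                 edges = as.data.frame(edges)),
            class = "topology")
}

#' Configuration of a fixed-firing-pattern efficacy experiment
#'
#' @param rules Data frame of calibrated, balanced rule parameter sets
#'   (from [search_rules()]).
#' @param sleep_spec,wake_spec [pattern_spec()]s for the two states
#'   (typically rate-matched with [match_rate()]).
#' @param duration_s Simulation duration (s); default 360 (6 min).
#' @param window_s Averaging window at the end of the run (s); default 120.
#' @param rho0 Initial efficacy.
#' @param dt Integration step (ms).
#' @param rate_tolerance Maximal relative mean-rate mismatch between the
#'   two specs (checked when both carry an `achieved_rate`).
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(rules, sleep_spec, wake_spec,
                              duration_s = 360, window_s = 120, rho0 = 0.5,
                              dt = 0.05, rate_tolerance = 0.05) {
  stopifnot(is.data.frame(rules), nrow(rules) >= 1,
            duration_s >= window_s, rho0 >= 0, rho0 <= 1)
  structure(list(rules = rules, sleep_spec = sleep_spec,
                 wake_spec = wake_spec, duration_s = duration_s,
                 window_s = window_s, rho0 = rho0, dt = dt,
                 rate_tolerance = rate_tolerance),
            class = "experiment_config")
}

# Unscaled Ca2+ influx drive traces for a set of voltage traces.
# Returns list(pre = matrix steps x n_neurons, post = list of vectors).
drive_from_voltage <- function(v, consts, dt, what = c("pre", "post")) {
  what <- match.arg(what)
  if (what == "pre") {
    s <- cpp_nmda_gate(v, dt, consts$a_s_nmda, consts$a_x_nmda,
                       consts$tau_s_nmda, consts$tau_x_nmda)
    consts$alpha_ca * consts$g_nmda * s * (consts$v_ca - consts$v_rest)
  } else {
    m <- vgcc_activation(v)
    consts$alpha_ca * consts$area * consts$g_ca * m * m * (consts$v_ca - v)
  }
}

# Run all rule sets over one state's generated pattern on a topology.
run_state <- function(rules, spec, topology, duration_s, window_s, rho0, dt,
                      consts, wf) {
  sp <- spec
  sp$duration_s <- duration_s
  pats <- generate_pattern(sp, topology$n_neurons)
  traces <- lapply(pats, spikes_to_voltage, wf = wf, dt = dt)
  nsteps <- length(traces[[1]])
  window_start <- as.integer(round((duration_s - window_s) * 1000 / dt))

  rules_list <- list(beta_n = rules$beta_nmda, beta_v = rules$beta_vgcc,
                     tau_pre = rules$tau_pre, tau_post = rules$tau_post,
                     theta_p = rules$theta_p, theta_d = rules$theta_d,
                     gamma_p = rules$gamma_p, gamma_d = rules$gamma_d,
                     sigma = rules$sigma, tau_s = rules$tau_s,
                     rho_star = rules$rho_star)
  z <- rules$z[1]

  posts <- unique(topology$edges$post)
  acc_mean <- matrix(0, nrow(rules), 0)
  acc_cv <- matrix(0, nrow(rules), 0)
  for (q in posts) {
    pre_ids <- topology$edges$pre[topology$edges$post == q]
    drive_pre <- matrix(0, nsteps, length(pre_ids))
    for (j in seq_along(pre_ids))
      drive_pre[, j] <- drive_from_voltage(traces[[pre_ids[j]]], consts, dt,
                                           "pre")
    drive_post <- drive_from_voltage(traces[[q]], consts, dt, "post")
    res <- cpp_efficacy_batch(drive_pre, drive_post, rules_list, z, dt,
                              rho0, window_start)
    acc_mean <- cbind(acc_mean, res$syn_mean)
    acc_cv <- cbind(acc_cv, res$cv)
  }
  list(mean = rowMeans(acc_mean),
       cv = rowMeans(acc_cv, na.rm = TRUE),
       realized_rate = mean(vapply(pats, function(p) p$mean_rate, 0)))
}

#' Compare synaptic efficacy between sleep-like and wake-like patterns
#'
#' Generates one multi-neuron firing pattern per state, converts it to
#' voltage waveforms, drives every rule set's synapses over the topology
#' and reports the time-averaged mean efficacy and the across-synapse CV
#' over the final window, per rule set and state.
#'
#' @param cfg An [experiment_config()].
#' @param topology A [build_topology()] result.
#' @param seed Optional integer seed (patterns and efficacy noise).
#' @param consts,wf Model constants and waveform parameters.
#' @return Data frame (class `efficacy_report`) with one row per rule set
#'   and state: `rule_id`, `rule_label`, `state`, `mean`, `cv`,
#'   `realized_rate`.
#' @export
run_state_comparison <- function(cfg, topology, seed = NULL,
                                 consts = plasticity_constants(),
                                 wf = waveform_params()) {
  stopifnot(inherits(cfg, "experiment_config"), inherits(topology, "topology"))
  rs <- attr(cfg$sleep_spec, "achieved_rate")
  rw <- attr(cfg$wake_spec, "achieved_rate")
  if (!is.null(rs) && !is.null(rw) &&
      abs(rs - rw) / max(rs, rw) > cfg$rate_tolerance)
    stop(sprintf("state rates not matched: sleep %.3g Hz vs wake %.3g Hz",
                 rs, rw), call. = FALSE)
  # each state runs under its own copy of the seed stream: identical
  # specs then give identical results, and the sleep-wake contrast is a
  # paired comparison under common random numbers
  out <- lapply(c("sleep", "wake"), function(state) {
    spec <- if (state == "sleep") cfg$sleep_spec else cfg$wake_spec
    st <- with_seed(seed,
                    run_state(cfg$rules, spec, topology, cfg$duration_s,
                              cfg$window_s, cfg$rho0, cfg$dt, consts, wf))
    data.frame(rule_id = seq_len(nrow(cfg$rules)),
               rule_label = cfg$rules$rule_label, state = state,
               mean = st$mean, cv = st$cv,
               realized_rate = st$realized_rate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("efficacy_report", "data.frame")
  out
}

#' Sweep firing rates and compare states at each rate
#'
#' For each target rate the state specs are rate-adjusted and
#' [run_state_comparison()] is run.  Two designs are supported:
#' `"matched"` (both states at the same mean rate; sleep adjusted via
#' `knob`, wake via its mean ISI) and `"up_rate"` (the wake mean rate
#' equals the within-Up mean rate of sleep: both states share the mean
#' ISI, so wake fires faster overall).  Per-rate failures are recorded as
#' missing rows rather than aborting the sweep.
#'
#' @param cfg An [experiment_config()]; its specs provide the baseline
#'   sleep parameters.
#' @param rates Numeric vector of target mean rates (Hz).  Under
#'   `"up_rate"` these are wake rates.
#' @param knob Sleep-rate knob for the matched design (`"downm"` or
#'   `"isim"`).
#' @param design `"matched"` or `"up_rate"`.
#' @param seed Optional integer seed.
#' @param n_draws Independent pattern realizations per rate; the per-rate
#'   comparison is repeated for each draw and the summary averages over
#'   draws (reduces the Monte-Carlo noise of scaled-down sweeps).
#' @inheritParams run_state_comparison
#' @return Long data frame: `rate`, `draw`, `rule_id`, `rule_label`,
#'   `state`, `mean`, `cv`, plus a `median_diff` attribute table
#'   (per-rate median of sleep minus wake mean efficacy, averaged over
#'   draws).
#' @export
sweep_rates <- function(cfg, rates, knob = c("downm", "isim"),
                        design = c("matched", "up_rate"), seed = NULL,
                        n_draws = 1L,
                        topology = build_topology("fan_in_10"),
                        consts = plasticity_constants(),
                        wf = waveform_params()) {
  knob <- match.arg(knob)
  design <- match.arg(design)
  rows <- list()
  fails <- list()
  for (i in seq_along(rates)) {
    r <- rates[i]
    res <- tryCatch({
      if (design == "matched") {
        ss <- match_rate(cfg$sleep_spec, r, knob)
        ws <- match_rate(cfg$wake_spec, r, "isim")
      } else {
        ws <- match_rate(cfg$wake_spec, r, "isim")
        ss <- cfg$sleep_spec
        ss$isim <- ws$isim
        attr(ss, "achieved_rate") <- NULL
        attr(ws, "achieved_rate") <- NULL
      }
      cfg_r <- cfg
      cfg_r$sleep_spec <- ss
      cfg_r$wake_spec <- ws
      draws <- lapply(seq_len(n_draws), function(k) {
        rep <- run_state_comparison(
          cfg_r, topology,
          seed = if (is.null(seed)) NULL else seed + i + 1000L * (k - 1L),
          consts = consts, wf = wf)
        rep$rate <- r
        rep$draw <- k
        rep
      })
      do.call(rbind, draws)
    }, error = function(e) e)
    if (inherits(res, "error")) fails[[as.character(r)]] <- conditionMessage(res)
    else rows[[length(rows) + 1L]] <- res
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(rate = numeric(0), draw = integer(0), rule_id = integer(0),
               rule_label = character(0), state = character(0),
               mean = numeric(0), cv = numeric(0))
  if (nrow(out)) {
    md <- do.call(rbind, lapply(split(out, out$rate), function(d) {
      per_draw <- vapply(split(d, d$draw), function(dd)
        stats::median(dd$mean[dd$state == "sleep"]) -
          stats::median(dd$mean[dd$state == "wake"]), 0)
      data.frame(rate = d$rate[1], median_diff = mean(per_draw))
    }))
    rownames(md) <- NULL
    attr(out, "median_diff") <- md
  }
  attr(out, "failures") <- fails
  out
}
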