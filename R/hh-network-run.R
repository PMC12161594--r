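#' Build the 80-neuron cortical network
#'
#' Excitatory:inhibitory ratio 4:1.  Each neuron receives a number of
#' excitatory synapses drawn from a lognormal distribution (default mean
#' 2, SD 0.01 — effectively two), and each excitatory neuron likewise
#' receives inhibitory synapses; inhibitory-to-inhibitory connections are
#' not wired.  Synaptic conductances are divided by the average number of
#' excitatory or inhibitory synapses per neuron.
#'
#' @param n_neurons Network size (default 80).
#' @param ei_ratio Excitatory fraction (default 0.8).
#' @param syn_mean,syn_sd Mean and SD of the per-neuron synapse-count
#'   lognormal (counts are rounded and floored at 1).
#' @param seed Optional integer seed.
#' @return An `hh_network` list: `is_exc`, edge vectors `pre`, `post`,
#'   `exc`, and the divisors `mean_n_exc`, `mean_n_inh`.
#' @export
build_hh_network <- function(n_neurons = 80, ei_ratio = 0.8, syn_mean = 2,
                             syn_sd = 0.01, seed = NULL) {
  with_seed(seed, {
    n_exc <- round(n_neurons * ei_ratio)
    is_exc <- c(rep(TRUE, n_exc), rep(FALSE, n_neurons - n_exc))
    exc_ids <- which(is_exc)
    inh_ids <- which(!is_exc)
    draw_n <- function(k) {
      mu <- log(syn_mean^2 / sqrt(syn_mean^2 + syn_sd^2))
      sg <- sqrt(log(1 + syn_sd^2 / syn_mean^2))
      pmax(1L, as.integer(round(stats::rlnorm(k, mu, sg))))
    }
    pre <- integer(0); post <- integer(0); exc <- logical(0)
    ne_counts <- draw_n(n_neurons)
    for (q in seq_len(n_neurons)) {
      src <- sample(setdiff(exc_ids, q), ne_counts[q],
                    replace = ne_counts[q] > length(setdiff(exc_ids, q)))
      pre <- c(pre, src); post <- c(post, rep(q, length(src)))
      exc <- c(exc, rep(TRUE, length(src)))
    }
    ni_counts <- draw_n(n_exc)
    for (j in seq_along(exc_ids)) {
      q <- exc_ids[j]
      src <- sample(inh_ids, ni_counts[j], replace = ni_counts[j] >
                      length(inh_ids))
      pre <- c(pre, src); post <- c(post, rep(q, length(src)))
      exc <- c(exc, rep(FALSE, length(src)))
    }
    structure(list(is_exc = is_exc, pre = as.integer(pre - 1L),
                   post = as.integer(post - 1L), exc = exc,
                   mean_n_exc = mean(ne_counts),
                   mean_n_inh = mean(ni_counts)),
              class = "hh_network")
  })
}

#' Random initial network state
#'
#' V, hNa, nK, hA and mKS are drawn uniformly within physiological ranges
#' (V in -80..-50 mV, gates in 0..1); the remaining variables start at the
#' single-neuron search values.
#'
#' @param n_neurons Network size.
#' @param seed Optional integer seed.
#' @return Matrix `n_neurons x 10` of initial states.
#' @export
hh_network_init <- function(n_neurons = 80, seed = NULL) {
  with_seed(seed, {
    m <- matrix(0, n_neurons, 10)
    colnames(m) <- names(hh_initial_single())
    m[, 1] <- stats::runif(n_neurons, -80, -50)
    m[, 2] <- stats::runif(n_neurons)
    m[, 3] <- stats::runif(n_neurons)
    m[, 4] <- stats::runif(n_neurons)
    m[, 5] <- stats::runif(n_neurons)
    m[, 6] <- 1
    m[, 7:10] <- 0.01
    m
  })
}

no_plasticity <- function() list(enabled = FALSE)
no_kinase <- function() list(mode = 0L)
no_stim <- function() list(targets = integer(0), rate_hz = 0,
                           amp_na = 0, width_ms = 0)

plasticity_options <- function(rule, rho0 = 0.5, couple_ampa = TRUE,
                               consts = plasticity_constants(),
                               record_rho_edges = FALSE) {
  list(enabled = TRUE, beta_n = rule$beta_nmda, beta_v = rule$beta_vgcc,
       tau_pre = rule$tau_pre, tau_post = rule$tau_post,
       theta_p = rule$theta_p, theta_d = rule$theta_d,
       gamma_p = rule$gamma_p, gamma_d = rule$gamma_d,
       sigma = rule$sigma, tau_s = rule$tau_s, rho_star = rule$rho_star,
       z = rule$z, rho0 = rho0, a_s_nmda = consts$a_s_nmda,
       a_x_nmda = consts$a_x_nmda, tau_s_nmda = consts$tau_s_nmda,
       tau_x_nmda = consts$tau_x_nmda, g_nmda = consts$g_nmda,
       g_ca = consts$g_ca, couple_ampa = couple_ampa,
       record_rho_edges = record_rho_edges)
}

#' Simulate the Hodgkin-Huxley network
#'
#' One compiled run over one or more phases (each with its own multiplier
#' on the bifurcation axis and optional stimulation), optionally with
#' per-synapse plasticity coupled to the AMPAR conductance and per-neuron
#' kinase (sleep-wake) dynamics modulating a conductance.
#'
#' @param params One row of [sample_hh_params()].
#' @param network A [build_hh_network()] object.
#' @param axis Bifurcation axis name, or `"none"`.
#' @param phases Data frame with columns `duration_s`, `multiplier` and
#'   optionally `stim` (logical).
#' @param dt Step (ms).
#' @param record_dt Recording step (ms).
#' @param init Initial state matrix, see [hh_network_init()].
#' @param plasticity `NULL` or [plasticity_options()].
#' @param kinase `NULL` or [kinase_options()].
#' @param stim `NULL` or a list with `targets` (1-based neuron indices),
#'   `rate_hz`, `amp_na`, `width_ms`.
#' @param consts HH constants.
#' @param seed Optional integer seed (initial state and noise).
#' @return List with `time` (ms), `v` (matrix), per-neuron `spikes`,
#'   plasticity traces (`rho_mean`, `rho_sd`, `cpre_mean`, `cpost_mean`,
#'   `rho_final`, optionally `rho_edges`), kinase traces (`r`, `a`,
#'   `xi`) and `ok`.
#' @export
hh_network_run <- function(params, network, axis = "none",
                           phases = data.frame(duration_s = 2.5,
                                               multiplier = 1),
                           dt = 0.025, record_dt = 1, init = NULL,
                           plasticity = NULL, kinase = NULL, stim = NULL,
                           consts = hh_constants(), seed = NULL) {
  with_seed(seed, {
    nn <- length(network$is_exc)
    if (is.null(init)) init <- hh_network_init(nn)
    if (is.null(plasticity)) plasticity <- no_plasticity()
    if (is.null(kinase)) kinase <- no_kinase()
    if (is.null(stim)) stim <- no_stim() else
      stim$targets <- as.integer(stim$targets - 1L)
    axis_id <- if (axis == "none") 0L else bifurcation_axes[[axis]]
    if (!"stim" %in% names(phases)) phases$stim <- FALSE
    pv <- hh_param_vector(params)
    out <- cpp_hh_network(pv, consts, unclass(network),
                          phases$duration_s * 1000, phases$multiplier,
                          phases$stim, dt, record_dt, plasticity, kinase,
                          stim, axis_id, list(state = init))
    out$record_dt <- record_dt
    out$duration_ms <- sum(phases$duration_s) * 1000
    out
  })
}

# classify every neuron of a network run over an analysis window and
# summarize the step (used by the network bifurcation stages)
classify_network_step <- function(run, t0_ms = NULL, t1_ms = NULL) {
  if (is.null(t0_ms)) t0_ms <- 0
  if (is.null(t1_ms)) t1_ms <- run$duration_ms
  nn <- ncol(run$v)
  idx <- which(run$time >= t0_ms & run$time <= t1_ms)
  labels <- character(nn)
  rates <- numeric(nn)
  for (i in seq_len(nn)) {
    st <- run$spikes[[i]]
    st <- st[st >= t0_ms & st < t1_ms]
    rates[i] <- length(st) / ((t1_ms - t0_ms) / 1000)
    if (!run$ok) { labels[i] <- "EXCLUDED"; next }
    vwin <- run$v[idx, i]
    labels[i] <- classify_pattern(spike_rate = rates[i], vmin = min(vwin),
                                  vmax = max(vwin),
                                  peak_hz = peak_frequency(vwin,
                                                           run$record_dt))
  }
  score <- sleep_score(lapply(seq_len(nn), function(i) {
    st <- run$spikes[[i]]; st[st >= t0_ms & st < t1_ms]
  }), duration_ms = t1_ms, t0_ms = t0_ms)
  data.frame(
    sleep_score = score,
    pct_sleep = 100 * mean(labels %in% c("SWO", "SWO_high")),
    pct_wake = 100 * mean(labels %in% c("AWAKE", "AWAKE_high")),
    mean_rate = mean(rates), ok = run$ok
  )
}

#' Network bifurcation sweep
#'
#' Simulates the network at each multiplier step of the stage grid and
#' summarizes each step by its sleep score, the percentages of
#' sleep-classified (SWO family) and wake-classified (AWAKE family)
#' neurons, and the mean firing rate.
#'
#' @param params One row of [sample_hh_params()].
#' @param network A [build_hh_network()].
#' @param axis Bifurcation axis.
#' @param stage `"network1"` (2.5 s per step) or `"network2"` (5 s).
#' @param multipliers Optional explicit grid.
#' @param dt Step (ms).
#' @param seed Optional integer seed (shared initial state across steps).
#' @param consts HH constants.
#' @return Data frame per step with the summary columns.
#' @export
network_bifurcation_sweep <- function(params, network, axis = "gnmda",
                                      stage = c("network1", "network2"),
                                      multipliers = NULL, dt = 0.025,
                                      seed = NULL,
                                      consts = hh_constants()) {
  stage <- match.arg(stage)
  if (is.null(multipliers)) multipliers <- bifurcation_grid(stage, axis)
  duration_s <- if (stage == "network1") 2.5 else 5
  nn <- length(network$is_exc)
  init <- hh_network_init(nn, seed = seed)
  rows <- lapply(multipliers, function(m) {
    run <- hh_network_run(params, network, axis,
                          data.frame(duration_s = duration_s,
                                     multiplier = m),
                          dt = dt, init = init, consts = consts)
    cbind(data.frame(multiplier = m), classify_network_step(run))
  })
  do.call(rbind, rows)
}

#' Accepted wake-like / sleep-like steps of a network sweep
#'
#' Wake-like network steps have sleep score < 1.0 and > 30% of neurons
#' classified in the AWAKE family; sleep-like steps have sleep score
#' >= 1.3 and > 30% in the SWO family.
#'
#' @param sweep A [network_bifurcation_sweep()] table.
#' @return The table with logical columns `wake_ok` and `sleep_ok` added.
#' @export
network_step_acceptance <- function(sweep) {
  sweep$wake_ok <- !is.na(sweep$sleep_score) & sweep$sleep_score < 1.0 &
    sweep$pct_wake > 30 & sweep$ok
  sweep$sleep_ok <- !is.na(sweep$sleep_score) & sweep$sleep_score >= 1.3 &
    sweep$pct_sleep > 30 & sweep$ok
  sweep
}

#' Select a rate-matched wake/sleep multiplier pair
#'
#' From an acceptance-annotated sweep, returns the accepted wake-like and
#' sleep-like steps whose mean firing rates differ by less than
#' `max_rate_diff` Hz (2.0 by default); among candidates the pair with
#' the smallest rate difference is chosen.
#'
#' @param sweep Output of [network_step_acceptance()].
#' @param max_rate_diff Maximal |rate difference| (Hz).
#' @return List with `wake_multiplier`, `sleep_multiplier`, `rate_diff`,
#'   `found`; when no pair qualifies, `found = FALSE` (the parameter set
#'   is excluded).
#' @export
select_matched_pair <- function(sweep, max_rate_diff = 2.0) {
  if (!all(c("wake_ok", "sleep_ok") %in% names(sweep)))
    sweep <- network_step_acceptance(sweep)
  w <- sweep[sweep$wake_ok, , drop = FALSE]
  s <- sweep[sweep$sleep_ok, , drop = FALSE]
  if (!nrow(w) || !nrow(s))
    return(list(found = FALSE, wake_multiplier = NA_real_,
                sleep_multiplier = NA_real_, rate_diff = NA_real_))
  grid <- expand.grid(iw = seq_len(nrow(w)), is = seq_len(nrow(s)))
  grid$diff <- abs(w$mean_rate[grid$iw] - s$mean_rate[grid$is])
  grid <- grid[grid$diff < max_rate_diff, , drop = FALSE]
  if (!nrow(grid))
    return(list(found = FALSE, wake_multiplier = NA_real_,
                sleep_multiplier = NA_real_, rate_diff = NA_real_))
  best <- grid[which.min(grid$diff), ]
  list(found = TRUE, wake_multiplier = w$multiplier[best$iw],
       sleep_multiplier = s$multiplier[best$is], rate_diff = best$diff)
}

#' Calibrate plasticity scaling against a network wake trace
#'
#' Network variant of the scaling calibration: `beta_nmda` is fixed at 1
#' and `beta_vgcc` is set so that the mean VGCC-sourced transient
#' amplitude is twice the NMDAR-sourced one (`2 MC_pre = MC_post`), from
#' a preliminary wake-like simulation without learning rules.  The rule's
#' thresholds are then normalized by `MC_pre / 0.7` so that the
#' simple-model threshold bands keep their meaning.  Amplitudes are
#' measured as the mean of per-1-s-window maxima of the synapse-averaged
#' Ca2+ traces.
#'
#' @param rule A [plasticity_rule()].
#' @param params,network,axis,wake_multiplier Network configuration and
#'   the wake-like step of the matched pair.
#' @param duration_s Preliminary simulation length (s).
#' @param dt Step (ms).
#' @param seed Optional integer seed.
#' @param consts HH constants.
#' @param pconsts Plasticity constants.
#' @return The rule with updated `beta_nmda`, `beta_vgcc`, `theta_p`,
#'   `theta_d` (attribute `mc_pre` records the measured amplitude).
#' @export
calibrate_scaling_hh <- function(rule, params, network, axis,
                                 wake_multiplier, duration_s = 10,
                                 dt = 0.025, seed = NULL,
                                 consts = hh_constants(),
                                 pconsts = plasticity_constants()) {
  probe <- rule
  probe$beta_nmda <- 1
  probe$beta_vgcc <- 1
  run <- hh_network_run(params, network, axis,
                        data.frame(duration_s = duration_s,
                                   multiplier = wake_multiplier),
                        dt = dt,
                        plasticity = plasticity_options(probe,
                                                        couple_ampa = FALSE,
                                                        consts = pconsts),
                        consts = consts, seed = seed)
  mc <- function(x) {
    win <- floor((seq_along(x) - 1) * run$record_dt / 1000)
    mean(tapply(x, win, max))
  }
  mc_pre <- mc(run$cpre_mean)
  mc_post <- mc(run$cpost_mean)
  if (!is.finite(mc_pre) || mc_pre <= 0 || !is.finite(mc_post) ||
      mc_post <= 0)
    stop("degenerate network calibration: zero Ca2+ amplitude",
         call. = FALSE)
  rule$beta_nmda <- 1
  rule$beta_vgcc <- 2 * mc_pre / mc_post
  rule$theta_p <- rule$theta_p * mc_pre / 0.7
  rule$theta_d <- rule$theta_d * mc_pre / 0.7
  attr(rule, "mc_pre") <- mc_pre
  rule
}

#' Learning-rule search against network voltage traces
#'
#' Network-model variant of [search_rules()]: a wake-like membrane
#' potential trace of a representative neuron (the one with the smallest
#' CV of 1-s firing rates) is duplicated with a short delay at each lag;
#' the NMDAR Ca2+ driving force uses the postsynaptic potential.
#' Threshold occupancies are measured over the 1-4 s window and extended
#' to 60 s by stationarity; candidates are accepted when the SSE against
#' the piecewise-Gaussian target is below `sse_threshold` (default 0.6).
#'
#' @param v_wake Voltage trace (mV) of the representative neuron, at
#'   least 4 s at step `dt`.
#' @param rule_label `"STDP"` or `"AntiSTDP"` (Hebbian variants allowed).
#' @param n_target,budget,seed Search controls.
#' @param mc_pre Mean NMDAR-sourced Ca2+ amplitude of the wake state
#'   (normalizes the candidate thresholds); when `NULL`, measured from
#'   the candidate's own unscaled trace.
#' @param dt Trace step (ms).
#' @param lags Lag grid (ms).
#' @param a_lr,tau_lr,sse_threshold Target parameters (threshold 0.6).
#' @param chunk Candidates per batch.
#' @param pconsts Plasticity constants.
#' @return Data frame of accepted sets (normalized thresholds), ascending
#'   SSE.
#' @export
search_rules_hh <- function(v_wake, rule_label = "STDP", n_target = 10,
                            budget = 2e4, seed = NULL, dt = 0.1,
                            lags = seq(-160, 160, by = 10), a_lr = 0.5,
                            tau_lr = 30, sse_threshold = 0.6, chunk = 2000,
                            pconsts = plasticity_constants()) {
  stopifnot(length(v_wake) * dt >= 4000)
  v_wake <- v_wake[seq_len(floor(4000 / dt))]
  with_seed(seed, {
    # unscaled drives from the wake trace; NMDAR force uses Vpost
    s <- cpp_nmda_gate(v_wake, dt, pconsts$a_s_nmda, pconsts$a_x_nmda,
                       pconsts$tau_s_nmda, pconsts$tau_x_nmda)
    drive_pre <- pconsts$alpha_ca * pconsts$g_nmda * s *
      (pconsts$v_ca - v_wake)
    m <- vgcc_activation(v_wake)
    drive_post <- pconsts$alpha_ca * pconsts$area * pconsts$g_ca * m * m *
      (pconsts$v_ca - v_wake)
    np <- length(v_wake)
    win <- seq(floor(1000 / dt) + 1L, np)
    w1s <- floor((win - win[1]) * dt / 1000)
    lag_steps <- as.integer(round(lags / dt))
    # shifted index vectors are lag-specific, not candidate-specific
    idx_by_lag <- lapply(lag_steps, function(sh) {
      idx <- win - (sh %% np)
      ((idx - 1L) %% np) + 1L
    })
    target <- rule_target(rule_label, lags, a_lr, tau_lr)
    i20p <- which(lags == 20); i20n <- which(lags == -20)
    want_pd <- rule_label %in% c("Hebbian", "STDP")
    ranges <- default_rule_ranges(rule_label, hh = TRUE)

    accepted <- list(); n_acc <- 0L; n_eval <- 0L
    while (n_acc < n_target && n_eval < budget) {
      nc <- min(chunk, budget - n_eval)
      cand <- sample_rule_params(nc, ranges, rule_label)
      n_eval <- n_eval + nc
      keep <- if (want_pd) cand$theta_p > cand$theta_d else
        cand$theta_p < cand$theta_d
      cand <- cand[keep, , drop = FALSE]
      if (!nrow(cand)) next
      res <- lapply(seq_len(nrow(cand)), function(j) {
        cp <- cpp_linear_filter(drive_pre, cand$tau_pre[j], dt)
        cq <- cpp_linear_filter(drive_post, cand$tau_post[j], dt)
        mc_pre_j <- mean(tapply(cp[win], w1s, max))
        mc_post_j <- mean(tapply(cq[win], w1s, max))
        if (!is.finite(mc_pre_j) || mc_pre_j <= 0 || mc_post_j <= 0)
          return(NULL)
        beta_v <- 2 * mc_pre_j / mc_post_j
        thp <- cand$theta_p[j] * mc_pre_j / 0.7
        thd <- cand$theta_d[j] * mc_pre_j / 0.7
        ap <- ad <- numeric(length(lags))
        cpw <- cp[win]
        for (l in seq_along(lags)) {
          cc <- cpw + beta_v * cq[idx_by_lag[[l]]]
          ap[l] <- mean(cc >= thp)
          ad[l] <- mean(cc >= thd)
        }
        ib <- which.min(abs(lags - 100))
        if (ap[ib] <= 0 || ad[ib] <= 0) return(NULL)
        gd <- cand$gamma_p[j] * ap[ib] / ad[ib]
        list(beta_v = beta_v, thp = thp, thd = thd, gd = gd, ap = ap,
             ad = ad, mc_pre = mc_pre_j)
      })
      for (j in seq_along(res)) {
        rj <- res[[j]]
        if (is.null(rj)) next
        row <- cand[j, ]
        row$beta_nmda <- 1
        row$beta_vgcc <- rj$beta_v
        row$theta_p <- rj$thp
        row$theta_d <- rj$thd
        row$gamma_d <- rj$gd
        rr <- rule_from_row(row)
        change <- analytic_change(rj$ap, rj$ad, rr, 60, 0.5)
        sse <- sum((change - 1 - target)^2)
        if (sse < sse_threshold &&
            curve_taxonomy_ok(change[i20p], change[i20n], rule_label)) {
          row$sse <- sse
          accepted[[length(accepted) + 1L]] <- row
          n_acc <- n_acc + 1L
        }
      }
    }
    out <- if (length(accepted)) do.call(rbind, accepted) else {
      warning("search budget exhausted with no accepted parameter sets")
      cbind(sample_rule_params(0), data.frame(sse = numeric(0)))
    }
    if (nrow(out)) out <- out[order(out$sse), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "n_evaluated") <- n_eval
    out
  })
}

#' Pick the representative neuron of a wake-like network run
#'
#' The neuron with the minimum CV of firing rates over non-overlapping
#' 1-s windows (the most stationary trace).
#'
#' @param run An [hh_network_run()] result.
#' @return Neuron index (1-based).
#' @export
representative_neuron <- function(run) {
  nn <- ncol(run$v)
  cvs <- vapply(seq_len(nn), function(i) {
    st <- run$spikes[[i]]
    if (length(st) < 2) return(Inf)
    counts <- tabulate(floor(st / 1000) + 1L,
                       nbins = floor(run$duration_ms / 1000))
    if (mean(counts) == 0) return(Inf)
    stats::sd(counts) / mean(counts)
  }, 0)
  which.min(cvs)
}

#' Plastic network run at a matched wake or sleep step
#'
#' Runs the network with per-synapse efficacy dynamics coupled to the
#' AMPAR conductance (`gAMPA = gAMPA_original x (0.5 + rho)`), and
#' reports the mean and across-synapse CV of efficacy averaged over
#' 10-60 s (time steps before 10 s are discarded as transient).
#'
#' @param params,network,axis Network configuration.
#' @param rule Calibrated rule from [calibrate_scaling_hh()].
#' @param multiplier The state's multiplier step.
#' @param duration_s Run length (s), default 60.
#' @param discard_s Transient discarded from the averages (s).
#' @param dt Step (ms).
#' @param seed Optional integer seed.
#' @param consts,pconsts Constants.
#' @return List with `mean`, `cv`, `mean_rate`, the recorded traces and
#'   `ok`.
#' @export
run_plastic_network <- function(params, network, axis, rule, multiplier,
                                duration_s = 60, discard_s = 10,
                                dt = 0.025, seed = NULL,
                                consts = hh_constants(),
                                pconsts = plasticity_constants()) {
  run <- hh_network_run(params, network, axis,
                        data.frame(duration_s = duration_s,
                                   multiplier = multiplier),
                        dt = dt,
                        plasticity = plasticity_options(rule,
                                                        consts = pconsts),
                        consts = consts, seed = seed)
  keep <- run$time >= discard_s * 1000
  mean_eff <- mean(run$rho_mean[keep])
  cvs <- ifelse(run$rho_mean[keep] > 0,
                run$rho_sd[keep] / run$rho_mean[keep], NA)
  nsp <- sum(vapply(run$spikes, function(s)
    sum(s >= discard_s * 1000), 0))
  list(mean = mean_eff, cv = mean(cvs, na.rm = TRUE),
       mean_rate = nsp / (duration_s - discard_s) /
         length(network$is_exc),
       run = run, ok = run$ok)
}

#' Stimulation experiment during wakefulness
#'
#' Excitatory neurons are split into three groups (defaults 20/20/24);
#' groups 1 and 2 receive simultaneous current-pulse stimulation at the
#' end of a wake-like phase, after which the network switches to a
#' sleep-like phase.  Reports the mean-efficacy trajectory per group and
#' each group's ratio of mean efficacy after versus before the sleep
#' phase.
#'
#' @param params,network,axis Network configuration (intracellular VGCC
#'   axis in the reference design, wake multiplier `10^-0.4`, sleep
#'   `10^-0.1`).
#' @param rule Calibrated rule (STDP in the reference design).
#' @param wake_multiplier,sleep_multiplier Phase multipliers.
#' @param wake_s,stim_s,sleep_s Phase durations (s); stimulation runs
#'   15 s at 20 Hz by default.
#' @param stim_rate_hz,stim_amp_na,stim_width_ms Pulse-train parameters.
#' @param group_sizes Sizes of the three excitatory groups.
#' @param dt Step (ms).
#' @param seed Optional integer seed.
#' @param consts,pconsts Constants.
#' @return List with `groups` (membership), `trajectory` (data frame of
#'   per-group mean efficacy over time), `ratio_after_before` per group
#'   and `ok`.
#' @export
stimulation_experiment <- function(params, network, axis = "gca", rule,
                                   wake_multiplier = 10^-0.4,
                                   sleep_multiplier = 10^-0.1,
                                   wake_s = 10, stim_s = 15, sleep_s = 20,
                                   stim_rate_hz = 20, stim_amp_na = 1.5,
                                   stim_width_ms = 3,
                                   group_sizes = c(20, 20, 24),
                                   dt = 0.025, seed = NULL,
                                   consts = hh_constants(),
                                   pconsts = plasticity_constants()) {
  exc_ids <- which(network$is_exc)
  stopifnot(sum(group_sizes) == length(exc_ids))
  g1 <- exc_ids[seq_len(group_sizes[1])]
  g2 <- exc_ids[group_sizes[1] + seq_len(group_sizes[2])]
  g3 <- exc_ids[group_sizes[1] + group_sizes[2] + seq_len(group_sizes[3])]
  phases <- data.frame(
    duration_s = c(wake_s, stim_s, sleep_s),
    multiplier = c(wake_multiplier, wake_multiplier, sleep_multiplier),
    stim = c(FALSE, TRUE, FALSE))
  run <- hh_network_run(params, network, axis, phases, dt = dt,
                        plasticity = plasticity_options(
                          rule, consts = pconsts,
                          record_rho_edges = TRUE),
                        stim = list(targets = c(g1, g2),
                                    rate_hz = stim_rate_hz,
                                    amp_na = stim_amp_na,
                                    width_ms = stim_width_ms),
                        consts = consts, seed = seed)
  edge_post <- network$post + 1L
  exc_edges <- which(network$exc)
  grp_of_edge <- rep(NA_integer_, length(network$post))
  grp_of_edge[edge_post %in% g1] <- 1L
  grp_of_edge[edge_post %in% g2] <- 2L
  grp_of_edge[edge_post %in% g3] <- 3L
  traj <- data.frame(time = run$time)
  for (g in 1:3) {
    sel <- exc_edges[grp_of_edge[exc_edges] == g]
    traj[[paste0("group", g)]] <- rowMeans(run$rho_edges[, sel,
                                                         drop = FALSE])
  }
  t_sleep0 <- (wake_s + stim_s) * 1000
  before <- run$time >= t_sleep0 - 5000 & run$time < t_sleep0
  after <- run$time >= run$duration_ms - 5000
  ratio <- vapply(1:3, function(g) {
    x <- traj[[paste0("group", g)]]
    mean(x[after]) / mean(x[before])
  }, 0)
  list(groups = list(group1 = g1, group2 = g2, group3 = g3),
       trajectory = traj, ratio_after_before = ratio, ok = run$ok,
       run = run)
}
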