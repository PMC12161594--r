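#' Parameters of the two-state kinase (sleep-wake) oscillator
#'
#' Two phosphorylation fractions of a CaMKII-like kinase: `r` (first
#' state) relaxes with time constant `tau_r` toward
#' `R_inf(w r + alpha Ca - b a + I + xi)` and `a` (second state) with
#' `tau_a` toward `A_inf(r - beta Ca - d)`, where `R_inf(x) =
#' 1/(1+exp(-c x))`, `A_inf(x) = 1/(1+exp(-e x))` and `xi` is
#' Ornstein-Uhlenbeck noise (time scale `1/theta`, stationary SD
#' `epsilon`).  The second state (or optionally `r`) multiplies a target
#' conductance by `max_rate x a(t)`, which drives the network across its
#' wake/sleep bifurcation.
#'
#' Two presets are provided: `"oscillatory"` (slow negative feedback
#' produces spontaneous relaxation oscillations) and `"bistable"`
#' (wake-like and sleep-like states are both stable; only noise switches
#' between them).
#'
#' @param regime Preset name.
#' @param ... Named overrides of individual parameters.
#' @return A `kinase_params` list.
#' @export
kinase_params <- function(regime = c("oscillatory", "bistable"), ...) {
  regime <- match.arg(regime)
  p <- list(
    tau_r = 5e3,      # ms
    tau_a = 15e3,     # ms
    w = 6,            # auto-activation of r
    alpha = 0.4,      # Ca activation of r (per uM)
    b = 5,            # inhibition of r by a
    beta = 0.1,       # Ca inhibition of a (per uM)
    i0 = -1.0,        # constant input
    c = 2, d = 0.55, e = 8,
    theta = 5e-5,     # OU rate (1/ms)
    epsilon = 0.3,    # OU stationary SD
    max_rate = 2,     # conductance coupling gain
    couple = "a"      # coupling variable
  )
  if (regime == "bistable") {
    p$tau_a <- 25e3
    p$b <- 3.2
    p$w <- 8
    p$i0 <- -3.1
    p$d <- 0.5
  }
  dots <- list(...)
  if (length(dots)) {
    stopifnot(all(names(dots) %in% names(p)))
    p[names(dots)] <- dots
  }
  structure(p, class = "kinase_params", regime = regime)
}

#' One update of the kinase state
#'
#' Exponential relaxation of `r` and `a` toward their sigmoid targets and
#' an exact Ornstein-Uhlenbeck update of the input noise `xi`.
#'
#' @param state List/vector with `r`, `a`, `xi`.
#' @param ca Coupling Ca2+ (uM) held over the step.
#' @param p A [kinase_params()].
#' @param dt Step (ms), > 0.
#' @return Updated state list.
#' @export
step_kinase <- function(state, ca, p, dt) {
  stopifnot(dt > 0)
  oue <- exp(-p$theta * dt)
  xi <- state$xi * oue +
    if (p$theta > 0) p$epsilon * sqrt(1 - oue^2) * stats::rnorm(1) else 0
  rinf <- 1 / (1 + exp(-p$c * (p$w * state$r + p$alpha * ca -
                                 p$b * state$a + p$i0 + xi)))
  ainf <- 1 / (1 + exp(-p$e * (state$r - p$beta * ca - p$d)))
  r <- state$r + (rinf - state$r) * (1 - exp(-dt / p$tau_r))
  a <- state$a + (ainf - state$a) * (1 - exp(-dt / p$tau_a))
  list(r = r, a = a, xi = xi)
}

#' Simulate the standalone kinase oscillator
#'
#' Integrates the two-state kinase under a fixed (or time-varying) Ca2+
#' input, without a network.
#'
#' @param p A [kinase_params()].
#' @param duration_s Simulated time (s).
#' @param dt Step (ms).
#' @param ca Coupling Ca2+ (scalar or vector over steps, uM).
#' @param r0,a0,xi0 Initial values.
#' @param seed Optional integer seed.
#' @return Data frame with `time_s`, `r`, `a`, `xi`.
#' @export
simulate_kinase <- function(p, duration_s, dt = 100, ca = 0, r0 = 0.1,
                            a0 = 0.1, xi0 = 0, seed = NULL) {
  with_seed(seed, {
    n <- floor(duration_s * 1000 / dt)
    ca <- rep_len(ca, n)
    r <- a <- xi <- numeric(n + 1)
    r[1] <- r0; a[1] <- a0; xi[1] <- xi0
    oue <- exp(-p$theta * dt)
    ousd <- if (p$theta > 0) p$epsilon * sqrt(1 - oue^2) else 0
    er <- 1 - exp(-dt / p$tau_r)
    ea <- 1 - exp(-dt / p$tau_a)
    noise <- if (ousd > 0) stats::rnorm(n, 0, ousd) else numeric(n)
    for (i in seq_len(n)) {
      xi[i + 1] <- xi[i] * oue + noise[i]
      rinf <- 1 / (1 + exp(-p$c * (p$w * r[i] + p$alpha * ca[i] -
                                     p$b * a[i] + p$i0 + xi[i + 1])))
      ainf <- 1 / (1 + exp(-p$e * (r[i] - p$beta * ca[i] - p$d)))
      r[i + 1] <- r[i] + (rinf - r[i]) * er
      a[i + 1] <- a[i] + (ainf - a[i]) * ea
    }
    data.frame(time_s = (0:n) * dt / 1000, r = r, a = a, xi = xi)
  })
}

#' Multiplicative conductance coupling of the kinase
#'
#' `g = g_original x max_rate x {a or r}`.
#'
#' @param state Kinase state (list with `r`, `a`).
#' @param g_original Original conductance, >= 0.
#' @param p A [kinase_params()] (fields `max_rate`, `couple`).
#' @return Effective conductance.
#' @export
couple_conductance <- function(state, g_original, p) {
  stopifnot(g_original >= 0)
  v <- if (identical(p$couple, "a")) state$a else state$r
  g_original * p$max_rate * v
}

#' Instantaneous presynaptic Ca2+ proxy
#'
#' VGCC-mediated presynaptic Ca2+, written as printed without its own
#' relaxation dynamics: `-alpha_ca A I_Ca_pre beta_vgcc` with
#' `I_Ca_pre = g_Ca mCa_inf(V_pre)^2 (V_pre - V_Ca)`.  Non-negative for
#' potentials below the Ca2+ reversal.
#'
#' @param v_pre Presynaptic membrane potential (mV).
#' @param g_ca VGCC conductance.
#' @param beta_vgcc Scaling factor.
#' @param consts HH constants (`alpha_ca`, `area`, `v_ca`).
#' @return Ca2+ proxy (uM-scale).
#' @export
presyn_calcium <- function(v_pre, g_ca = 1, beta_vgcc = 1,
                           consts = hh_constants()) {
  stopifnot(all(is.finite(v_pre)))
  m <- vgcc_activation(v_pre)
  i_ca <- g_ca * m^2 * (v_pre - consts$v_ca)
  -consts$alpha_ca * (consts$area * 10) * i_ca * beta_vgcc
}

#' Process S (sleep need) over a sleep/wake label sequence
#'
#' Exponential saturation toward the upper asymptote during wake and
#' decay toward the lower asymptote during sleep:
#' `S_{t+1} = UA - (UA - S_t) exp(-dt/tau_i)` (wake),
#' `S_{t+1} = LA + (S_t - LA) exp(-dt/tau_d)` (sleep).
#'
#' @param states Character/logical vector per step (`"sleep"`/`"wake"` or
#'   TRUE for sleep).
#' @param dt Step duration (same unit as the time constants).
#' @param ua,la Upper/lower asymptotes (ua > la).
#' @param tau_i,tau_d Rise (wake) and decay (sleep) time constants.
#' @param s0 Initial level, within [la, ua].
#' @return Numeric vector of S (length `length(states) + 1`).
#' @export
process_s <- function(states, dt, ua = 1, la = 0, tau_i = 60, tau_d = 30,
                      s0 = la) {
  if (ua <= la) stop("`ua` must exceed `la`", call. = FALSE)
  stopifnot(s0 >= la, s0 <= ua)
  sleep <- if (is.logical(states)) states else states == "sleep"
  s <- numeric(length(states) + 1)
  s[1] <- s0
  ei <- exp(-dt / tau_i)
  ed <- exp(-dt / tau_d)
  for (i in seq_along(states)) {
    s[i + 1] <- if (sleep[i]) la + (s[i] - la) * ed else
      ua - (ua - s[i]) * ei
  }
  s
}

#' Classify sleep-like and wake-like periods from population spiking
#'
#' Sleep scores are computed in sliding windows (5 s, advancing by
#' 500 ms), smoothed by a moving average over 10 consecutive values, and
#' thresholded: smoothed score above the threshold marks a sleep-like
#' period.
#'
#' @param spike_times List of per-neuron spike times (ms).
#' @param duration_ms Total duration (ms).
#' @param threshold Sleep-score threshold (from [null_threshold()]).
#' @param window_ms Window length (ms).
#' @param step_ms Window step (ms).
#' @param smooth Moving-average span (windows).
#' @return Data frame with `t_ms` (window centers), `score`,
#'   `score_smooth`, `state` (`"sleep"`/`"wake"`).
#' @export
classify_periods <- function(spike_times, duration_ms, threshold,
                             window_ms = 5000, step_ms = 500,
                             smooth = 10) {
  starts <- seq(0, duration_ms - window_ms, by = step_ms)
  if (length(starts) < smooth)
    stop("run shorter than the smoothing span", call. = FALSE)
  score <- vapply(starts, function(t0)
    sleep_score(spike_times, duration_ms = t0 + window_ms, t0_ms = t0), 0)
  sm <- stats::filter(score, rep(1 / smooth, smooth), sides = 1)
  sm[seq_len(smooth - 1)] <- score[seq_len(smooth - 1)]
  sm <- as.numeric(sm)
  data.frame(t_ms = starts + window_ms / 2, score = score,
             score_smooth = sm,
             state = ifelse(!is.na(sm) & sm > threshold, "sleep", "wake"),
             stringsAsFactors = FALSE)
}

#' Select sleep-wake dynamics models by balance and Process-S correlation
#'
#' Candidate runs must spend comparable time asleep and awake
#' (`0.7 <= sleep/wake < 1.3`, half-open); qualifying runs are ranked by
#' the Pearson correlation between the configured kinase variable and
#' Process S (largest first).  Runs whose kinase trace is constant have
#' undefined correlation and are excluded with a diagnostic.
#'
#' @param runs List of candidate runs; each needs `periods` (from
#'   [classify_periods()]), the kinase traces `r` and `a` sampled at the
#'   period grid, and `s` (Process S on the same grid).
#' @param optimize_var `"r"` or `"a"`: the variable correlated with
#'   Process S.
#' @return Data frame of accepted runs (`run`, `balance`, `correlation`),
#'   ranked; attribute `diagnostics` lists exclusions.
#' @export
select_dynamics_models <- function(runs, optimize_var = "r") {
  diag <- list()
  rows <- list()
  for (i in seq_along(runs)) {
    x <- runs[[i]]
    st <- x$periods$state
    t_sleep <- sum(st == "sleep")
    t_wake <- sum(st == "wake")
    if (t_wake == 0) { diag[[i]] <- "no wake time"; next }
    bal <- t_sleep / t_wake
    if (!(bal >= 0.7 && bal < 1.3)) {
      diag[[i]] <- sprintf("balance %.2f outside [0.7, 1.3)", bal)
      next
    }
    v <- x[[optimize_var]]
    if (stats::sd(v) == 0 || stats::sd(x$s) == 0) {
      diag[[i]] <- "constant trace: correlation undefined"
      next
    }
    rows[[length(rows) + 1L]] <-
      data.frame(run = i, balance = bal,
                 correlation = stats::cor(v, x$s))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(run = integer(0), balance = numeric(0),
               correlation = numeric(0))
  out <- out[order(-out$correlation), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "diagnostics") <- diag
  out
}

#' Kinase options for the network integrator
#'
#' @param p A [kinase_params()].
#' @param mode Coupling mechanism: `"post"` (NMDAR conductance),
#'   `"intracellular"` (VGCC conductance) or `"presyn"` (presynaptic
#'   activation coefficients).
#' @param r0,a0,xi0 Initial values.
#' @param stride Kinase update interval in integration steps.
#' @return Option list for [hh_network_run()].
#' @export
kinase_options <- function(p, mode = c("post", "intracellular", "presyn"),
                           r0 = 0.1, a0 = 0.1, xi0 = 0, stride = 400L) {
  mode <- match.arg(mode)
  list(mode = match(mode, c("post", "intracellular", "presyn")),
       tau_r = p$tau_r, tau_a = p$tau_a, w = p$w, alpha = p$alpha,
       b = p$b, beta = p$beta, i0 = p$i0, c = p$c, d = p$d, e = p$e,
       theta = p$theta, epsilon = p$epsilon, max_rate = p$max_rate,
       stride = as.integer(stride), r0 = r0, a0 = a0, xi0 = xi0,
       couple_a = identical(p$couple, "a"))
}

#' Full sleep-wake cycle with plasticity and kinase dynamics
#'
#' Network run with the kinase oscillator modulating the bifurcation
#' conductance and per-synapse plasticity coupled to AMPAR, followed by
#' continuous sleep-score classification, Process S, and per-period
#' efficacy statistics.
#'
#' @param params,network Network configuration.
#' @param rule Calibrated plasticity rule.
#' @param kin [kinase_params()].
#' @param mode Kinase coupling mechanism (see [kinase_options()]).
#' @param duration_s Run length (s); 300-500 in the reference design.
#' @param threshold Sleep-score threshold (from [null_threshold()]).
#' @param dt Step (ms).
#' @param seed Optional integer seed.
#' @param r0,a0,xi0 Kinase initial values (wake-like start by default).
#' @param consts,pconsts Constants.
#' @return List: the run, `periods`, `s` (Process S per period step),
#'   per-period efficacy means (`mean_sleep`, `mean_wake`, `cv_sleep`,
#'   `cv_wake`) and the correlation inputs (`r`, `a` at the period grid).
#' @export
run_full_cycle <- function(params, network, rule, kin,
                           mode = "post", duration_s = 300,
                           threshold = 1.0, dt = 0.025, seed = NULL,
                           r0 = 0.1, a0 = 0.1, xi0 = 0,
                           consts = hh_constants(),
                           pconsts = plasticity_constants()) {
  run <- hh_network_run(params, network, axis = switch(
    mode, post = "gnmda", intracellular = "gca", presyn = "presyn"),
    phases = data.frame(duration_s = duration_s, multiplier = 1),
    dt = dt,
    plasticity = plasticity_options(rule, consts = pconsts),
    kinase = kinase_options(kin, mode, r0 = r0, a0 = a0, xi0 = xi0),
    consts = consts, seed = seed)
  periods <- classify_periods(run$spikes, run$duration_ms, threshold)
  s <- process_s(periods$state, dt = 0.5, ua = 1, la = 0,
                 tau_i = 60, tau_d = 30, s0 = 0.2)[-1]
  grid_idx <- vapply(periods$t_ms, function(t)
    which.min(abs(run$time - t)), 0L)
  sleep_steps <- which(periods$state == "sleep")
  wake_steps <- which(periods$state == "wake")
  eff_at <- function(ix) run$rho_mean[grid_idx[ix]]
  cv_at <- function(ix) {
    m <- run$rho_mean[grid_idx[ix]]
    ifelse(m > 0, run$rho_sd[grid_idx[ix]] / m, NA)
  }
  list(run = run, periods = periods, s = s,
       r = run$r[grid_idx], a = run$a[grid_idx],
       mean_sleep = mean(eff_at(sleep_steps)),
       mean_wake = mean(eff_at(wake_steps)),
       cv_sleep = mean(cv_at(sleep_steps), na.rm = TRUE),
       cv_wake = mean(cv_at(wake_steps), na.rm = TRUE),
       ok = run$ok)
}
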