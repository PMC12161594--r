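#' Sample Hodgkin-Huxley channel-parameter sets
#'
#' Conductances are drawn log-uniformly over the bounded intervals of the
#' random search: intrinsic channels (gL, gNa, gK, gA, gKS, gCa, gKCa,
#' gNaP, gAR) over 1e-2..1e2 mS/cm2, synaptic receptors (gAMPA, gNMDA,
#' gGABA) over 1e-3..1e1 uS, and the intracellular Ca2+ time constant over
#' 1e1..1e3 ms.
#'
#' @param n Number of parameter sets.
#' @param seed Optional integer seed.
#' @param consts HH constants (supply the fixed activation coefficients).
#' @return Data frame, one row per set.
#' @export
sample_hh_params <- function(n, seed = NULL, consts = hh_constants()) {
  with_seed(seed, {
    lu <- function(lo, hi) 10^stats::runif(n, log10(lo), log10(hi))
    data.frame(
      gl = lu(1e-2, 1e2), gna = lu(1e-2, 1e2), gk = lu(1e-2, 1e2),
      ga = lu(1e-2, 1e2), gks = lu(1e-2, 1e2), gca = lu(1e-2, 1e2),
      gkca = lu(1e-2, 1e2), gnap = lu(1e-2, 1e2), gar = lu(1e-2, 1e2),
      gampa = lu(1e-3, 1e1), gnmda = lu(1e-3, 1e1), ggaba = lu(1e-3, 1e1),
      tau_ca = lu(1e1, 1e3),
      a_ampa = consts$a_ampa, a_x_nmda = consts$a_x_nmda,
      a_gaba = consts$a_gaba, a_s_nmda = consts$a_s_nmda
    )
  })
}

hh_param_vector <- function(row) {
  v <- as.numeric(row[c("gl", "gna", "gk", "ga", "gks", "gca", "gkca",
                        "gnap", "gar", "gampa", "gnmda", "ggaba", "tau_ca",
                        "a_ampa", "a_x_nmda", "a_gaba", "a_s_nmda")])
  names(v) <- c("gl", "gna", "gk", "ga", "gks", "gca", "gkca", "gnap",
                "gar", "gampa", "gnmda", "ggaba", "tau_ca", "a_ampa",
                "a_x_nmda", "a_gaba", "a_s_nmda")
  v
}

#' Initial state of the single averaged neuron
#'
#' The printed initial values of the parameter search: V = -45 mV,
#' hNa = 0.045, nK = 0.54, hA = 0.045, mKS = 0.34, Ca = 1 uM, and 0.01 for
#' the four synaptic gating variables.
#'
#' @return Named numeric vector of the 10 state variables.
#' @export
hh_initial_single <- function() {
  c(v = -45, hna = 0.045, nk = 0.54, ha = 0.045, mks = 0.34, ca = 1,
    sampa = 0.01, snmda = 0.01, xnmda = 0.01, sgaba = 0.01)
}

#' Simulate the single averaged neuron
#'
#' RK4 integration of the 10-variable averaged-neuron model (intrinsic
#' currents, self-driven synaptic receptors, cell-body Ca2+).  Returns the
#' downsampled voltage trace plus the spike statistics of the analysis
#' window.  Integration aborts (flagging the run) if the potential
#' diverges.
#'
#' @param params One row of [sample_hh_params()] (or a named list/vector).
#' @param duration_s Simulated time (s).
#' @param dt Step (ms).
#' @param record_dt Voltage recording step (ms).
#' @param analysis_start_s Start of the analysis window (s).
#' @param init Initial state, see [hh_initial_single()].
#' @param consts HH constants.
#' @param fastforward Stop integrating once the trajectory is pinned at a
#'   fixed point (the remaining trace is constant).
#' @return List with `v` (trace, mV), `record_dt`, `spike_rate` (1/s, from
#'   half the -20 mV crossings), `spike_times`, `vmin`, `vmax`, `ok`,
#'   `final_state`.
#' @export
hh_simulate <- function(params, duration_s = 6, dt = 0.025, record_dt = 1,
                        analysis_start_s = 1, init = hh_initial_single(),
                        consts = hh_constants(), fastforward = TRUE) {
  pv <- hh_param_vector(params)
  out <- cpp_hh_single(pv, consts, duration_s * 1000, dt, init, record_dt,
                       analysis_start_s * 1000, fastforward)
  out$spike_rate <- (out$n_cross / 2) / (duration_s - analysis_start_s)
  out
}

#' Spike detection on a voltage trace
#'
#' The spike count is half the number of -20 mV crossings; spike times are
#' the upward crossings.
#'
#' @param v Voltage trace (mV) at uniform `dt`.
#' @param dt Sampling step (ms).
#' @return List with `count` and `times` (ms).
#' @export
detect_spikes <- function(v, dt) {
  up <- which(v[-length(v)] < -20 & v[-1] >= -20)
  down <- which(v[-length(v)] >= -20 & v[-1] < -20)
  list(count = (length(up) + length(down)) / 2, times = up * dt)
}

#' Peak frequency of a voltage trace
#'
#' Frequency of the largest magnitude-spectrum bin of the mean-subtracted
#' trace, excluding the zero bin.  A constant trace has peak frequency 0.
#'
#' @param v Voltage trace.
#' @param dt Sampling step (ms).
#' @return Peak frequency (Hz).
#' @export
peak_frequency <- function(v, dt) {
  x <- v - mean(v)
  if (all(abs(x) < 1e-12)) return(0)
  n <- length(x)
  sp <- abs(stats::fft(x))[2:floor(n / 2)]
  freq <- (seq_along(sp)) / (n * dt / 1000)
  freq[which.max(sp)]
}

#' Classify a firing pattern
#'
#' The six-way classification of the single-neuron search, applied in
#' order: traces exceeding +/-200 mV (or failed integrations) are
#' `EXCLUDED`; `Resting` (rate < 0.6 /s, peak frequency <= 0.5 Hz, and the
#' trace stays on one side of -30 mV); `SWO` (peak >= 0.5 Hz and
#' 2 x peak <= rate < 30); `SWO_high` (peak >= 0.5, rate >= 2 x peak,
#' rate >= 30); `AWAKE` (peak >= 0.5, rate <= 2 x peak, rate < 30);
#' `AWAKE_high` (peak >= 0.5, 30 < rate <= 2 x peak, rate < 100);
#' everything else `EXCLUDED`.
#'
#' @param v Voltage trace of the analysis window (mV) or `NULL` when the
#'   summary statistics are given directly.
#' @param dt Sampling step (ms).
#' @param spike_rate Spikes per second (half the -20 mV crossings); when
#'   omitted, computed from the trace.
#' @param vmin,vmax Trace extrema; when omitted, computed from the trace.
#' @param peak_hz Peak frequency; when omitted, computed from the trace.
#' @param ok Integration success flag.
#' @return Classification label (character scalar).
#' @export
classify_pattern <- function(v = NULL, dt = 1, spike_rate = NULL,
                             vmin = NULL, vmax = NULL, peak_hz = NULL,
                             ok = TRUE) {
  if (!ok) return("EXCLUDED")
  if (is.null(spike_rate)) {
    stopifnot(!is.null(v))
    spike_rate <- detect_spikes(v, dt)$count / (length(v) * dt / 1000)
  }
  if (is.null(vmin)) vmin <- min(v)
  if (is.null(vmax)) vmax <- max(v)
  if (is.null(peak_hz)) peak_hz <- peak_frequency(v, dt)
  if (vmax > 200 || vmin < -200) return("EXCLUDED")
  if (spike_rate < 0.6 && peak_hz <= 0.5 && (vmax < -30 || vmin > -30))
    return("Resting")
  if (peak_hz >= 0.5 && 2 * peak_hz <= spike_rate && spike_rate < 30)
    return("SWO")
  if (peak_hz >= 0.5 && spike_rate >= 2 * peak_hz && spike_rate >= 30)
    return("SWO_high")
  if (peak_hz >= 0.5 && spike_rate <= 2 * peak_hz && spike_rate < 30)
    return("AWAKE")
  if (peak_hz >= 0.5 && spike_rate > 30 && spike_rate <= 2 * peak_hz &&
      spike_rate < 100)
    return("AWAKE_high")
  "EXCLUDED"
}

#' Population synchrony (sleep score)
#'
#' Coefficient of variation of the total spike count per non-overlapping
#' 50-ms window across all neurons (population SD / mean).  High values
#' indicate synchronized, slow-wave-like firing.
#'
#' @param spike_times List of per-neuron spike-time vectors (ms), or one
#'   numeric vector.
#' @param duration_ms Duration covered (ms); must span at least one window.
#' @param window_ms Window length (ms).
#' @param t0_ms Start of the scored interval (ms).
#' @return The sleep score (`NA` when no spikes fall in the interval).
#' @export
sleep_score <- function(spike_times, duration_ms, window_ms = 50,
                        t0_ms = 0) {
  if (is.list(spike_times)) spike_times <- unlist(spike_times)
  stopifnot(duration_ms - t0_ms >= window_ms)
  nwin <- floor((duration_ms - t0_ms) / window_ms)
  st <- spike_times[spike_times >= t0_ms &
                      spike_times < t0_ms + nwin * window_ms]
  if (length(st) == 0) return(NA_real_)
  counts <- tabulate(floor((st - t0_ms) / window_ms) + 1L, nbins = nwin)
  m <- mean(counts)
  sd_pop <- sqrt(mean((counts - m)^2))
  sd_pop / m
}

#' Sleep-score threshold from a desynchronized null ensemble
#'
#' Generates `reps` sets of desynchronized wake-like spike trains
#' (lognormal ISIs; per-neuron mean rates drawn uniformly from
#' `rate_range`), scores each set, and returns the `1 - p` quantile: the
#' sleep-score value above which a network is called sleep-like at level
#' `p`.  A Monte-Carlo confidence interval for the quantile (order
#' statistics, 95%) is attached.
#'
#' @param n_neurons Neurons per set.
#' @param duration_s Duration of each set (s).
#' @param rate_range Range of per-neuron mean rates (Hz).
#' @param reps Ensemble size (>= 100).
#' @param p Tail probability.
#' @param seed Optional integer seed.
#' @param window_ms Scoring window (ms).
#' @return The threshold score, with attributes `ci` and `scores`.
#' @export
null_threshold <- function(n_neurons = 80, duration_s = 5,
                           rate_range = c(0.5, 15), reps = 10000,
                           p = 0.01, seed = NULL, window_ms = 50) {
  stopifnot(reps >= 100)
  with_seed(seed, {
    dur <- duration_s * 1000
    nwin <- floor(dur / window_ms)
    scores <- numeric(reps)
    for (r in seq_len(reps)) {
      rate <- stats::runif(n_neurons, rate_range[1], rate_range[2])
      isim <- vapply(rate, isim_for_rate, 0, kind = "isi_wake")
      counts <- numeric(nwin)
      for (j in seq_len(n_neurons)) {
        s <- max(sd_from_mean("isi_wake", isim[j]), 0.01)
        n_guess <- max(8, ceiling(dur / (1000 / rate[j]) * 2))
        tt <- cumsum(rlog10norm(n_guess, isim[j], s))
        while (tt[length(tt)] <= dur)
          tt <- c(tt, tt[length(tt)] + cumsum(rlog10norm(n_guess, isim[j], s)))
        tt <- tt[tt < nwin * window_ms]
        if (length(tt))
          counts <- counts + tabulate(floor(tt / window_ms) + 1L,
                                      nbins = nwin)
      }
      m <- mean(counts)
      scores[r] <- if (m > 0) sqrt(mean((counts - m)^2)) / m else NA_real_
    }
    scores <- scores[is.finite(scores)]
    thr <- unname(stats::quantile(scores, 1 - p, type = 7))
    k <- (1 - p) * length(scores)
    lo <- stats::qbinom(0.025, length(scores), 1 - p)
    hi <- stats::qbinom(0.975, length(scores), 1 - p)
    srt <- sort(scores)
    attr(thr, "ci") <- c(srt[max(lo, 1)], srt[min(hi, length(srt))])
    attr(thr, "n") <- length(scores)
    thr
  })
}

# mean ISI (ms) of the lognormal with the kind's mean-SD regression equals
# 1000/rate; solved for the log10 mean
isim_for_rate <- function(rate, kind = "isi_wake") {
  f <- function(m) {
    s <- max(sd_from_mean(kind, m), 0.01)
    m * log(10) + (s * log(10))^2 / 2 - log(1000 / rate)
  }
  stats::uniroot(f, c(-1, 5))$root
}

#' Random search for slow-wave-oscillation parameter sets
#'
#' Samples channel-parameter sets ([sample_hh_params()]), simulates each
#' single averaged neuron for `duration_s` seconds from the printed
#' initial values, classifies the voltage pattern of the 1-6 s analysis
#' window and returns all sets with their labels; SWO and SWO_high sets
#' are the search hits.
#'
#' @param n_samples Number of sampled sets.
#' @param seed Optional integer seed.
#' @param duration_s,dt,analysis_start_s Simulation settings.
#' @param consts HH constants.
#' @param verbose Print progress.
#' @return Data frame of parameters plus `label`, `spike_rate`,
#'   `peak_hz`, `vmin`, `vmax`.
#' @export
search_swo <- function(n_samples, seed = NULL, duration_s = 6, dt = 0.05,
                       analysis_start_s = 1, consts = hh_constants(),
                       verbose = FALSE) {
  params <- sample_hh_params(n_samples, seed, consts)
  lab <- character(n_samples)
  rate <- pk <- vmn <- vmx <- numeric(n_samples)
  for (i in seq_len(n_samples)) {
    sim <- hh_simulate(params[i, ], duration_s, dt,
                       analysis_start_s = analysis_start_s,
                       consts = consts)
    nrec <- length(sim$v)
    i0 <- floor(analysis_start_s * 1000 / sim$record_dt) + 1L
    vwin <- sim$v[i0:nrec]
    pk[i] <- if (sim$ok) peak_frequency(vwin, sim$record_dt) else 0
    rate[i] <- sim$spike_rate
    vmn[i] <- sim$vmin
    vmx[i] <- sim$vmax
    lab[i] <- classify_pattern(spike_rate = sim$spike_rate, vmin = sim$vmin,
                               vmax = sim$vmax, peak_hz = pk[i],
                               ok = sim$ok)
    if (verbose && i %% 500 == 0)
      message(sprintf("%d / %d (%d SWO)", i, n_samples,
                      sum(lab %in% c("SWO", "SWO_high"))))
  }
  params$label <- lab
  params$spike_rate <- rate
  params$peak_hz <- pk
  params$vmin <- vmn
  params$vmax <- vmx
  params
}

bifurcation_axes <- c(gl = 1L, gna = 2L, gk = 3L, ga = 4L, gks = 5L,
                      gca = 6L, gkca = 7L, gnap = 8L, gar = 9L,
                      gampa = 10L, gnmda = 11L, ggaba = 12L,
                      presyn = 13L, tau_ca = 14L)

#' Multiplier grid of a bifurcation stage
#'
#' Log-uniform multiplier grids with the stage-specific endpoints and step
#' counts: single-neuron sweeps use 1e-2..1e2 in 100 steps (1e-2..1e1 in
#' 100 steps on the presynaptic axis); the first network stage 1e-2..1e2
#' in 17 steps (1e-2..1e1 in 16); the second network stage 1e-2..10^1.5 in
#' 36 steps (1e-2..10^0.8 in 29).
#'
#' @param stage `"single"`, `"network1"` or `"network2"`.
#' @param axis Axis name (see `names(sleepsyn:::bifurcation_axes)`).
#' @return Numeric vector of multipliers.
#' @export
bifurcation_grid <- function(stage = c("single", "network1", "network2"),
                             axis = "gnmda") {
  stage <- match.arg(stage)
  presyn <- axis == "presyn"
  spec <- switch(stage,
    single   = if (presyn) c(-2, 1, 100) else c(-2, 2, 100),
    network1 = if (presyn) c(-2, 1, 16) else c(-2, 2, 17),
    network2 = if (presyn) c(-2, 0.8, 29) else c(-2, 1.5, 36)
  )
  10^seq(spec[1], spec[2], length.out = spec[3])
}

#' Single-neuron bifurcation sweep
#'
#' Sweeps one parameter axis over the multiplier grid, classifying the
#' firing pattern at each step, and reports whether the sweep contains an
#' AWAKE-to-SWO bifurcation whose SWO side is at least 5 mV more
#' hyperpolarized than the AWAKE side (the single-neuron acceptance rule).
#'
#' @param params One row of [sample_hh_params()].
#' @param axis Axis name.
#' @param multipliers Multiplier grid; defaults to the stage grid.
#' @param duration_s,dt,analysis_start_s Simulation settings.
#' @param consts HH constants.
#' @return Data frame per step (`multiplier`, `label`, `spike_rate`,
#'   `peak_hz`, `vmin`, `vmax`) with attribute `accepted` (logical).
#' @export
bifurcation_sweep <- function(params, axis = "gnmda", multipliers = NULL,
                              duration_s = 6, dt = 0.025,
                              analysis_start_s = 1,
                              consts = hh_constants()) {
  stopifnot(axis %in% names(bifurcation_axes))
  if (is.null(multipliers)) multipliers <- bifurcation_grid("single", axis)
  rows <- vector("list", length(multipliers))
  for (i in seq_along(multipliers)) {
    p <- params
    m <- multipliers[i]
    if (axis == "presyn") {
      p$a_ampa <- p$a_ampa * m
      p$a_x_nmda <- p$a_x_nmda * m
      p$a_gaba <- p$a_gaba * m
    } else {
      p[[axis]] <- p[[axis]] * m
    }
    sim <- hh_simulate(p, duration_s, dt, analysis_start_s = analysis_start_s,
                       consts = consts)
    i0 <- floor(analysis_start_s * 1000 / sim$record_dt) + 1L
    pk <- if (sim$ok) peak_frequency(sim$v[i0:length(sim$v)],
                                     sim$record_dt) else 0
    rows[[i]] <- data.frame(
      multiplier = m, spike_rate = sim$spike_rate, peak_hz = pk,
      vmin = sim$vmin, vmax = sim$vmax,
      label = classify_pattern(spike_rate = sim$spike_rate,
                               vmin = sim$vmin, vmax = sim$vmax,
                               peak_hz = pk, ok = sim$ok),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "accepted") <- single_bifurcation_accepted(out)
  out
}

#' Single-neuron bifurcation acceptance rule
#'
#' A sweep is accepted when two adjacent multiplier steps switch between
#' an AWAKE-family and an SWO-family label and the SWO side satisfies
#' `min V(SWO) + 5 mV < min V(AWAKE)`.
#'
#' @param sweep A [bifurcation_sweep()] table (columns `label`, `vmin`).
#' @return Logical.
#' @export
single_bifurcation_accepted <- function(sweep) {
  lab <- sweep$label
  swo <- lab %in% c("SWO", "SWO_high")
  awk <- lab %in% c("AWAKE", "AWAKE_high")
  for (i in seq_len(nrow(sweep) - 1)) {
    pair <- NULL
    if (awk[i] && swo[i + 1]) pair <- c(i + 1, i)
    if (swo[i] && awk[i + 1]) pair <- c(i, i + 1)
    if (!is.null(pair) &&
        sweep$vmin[pair[1]] + 5 < sweep$vmin[pair[2]])
      return(TRUE)
  }
  FALSE
}
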