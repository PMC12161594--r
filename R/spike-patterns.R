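#' Regression from lognormal mean to lognormal SD (log10 scale)
#'
#' The interval distributions of the synthetic firing patterns are
#' lognormal in base-10 logarithm, and the SD of each distribution is tied
#' to its mean through linear regressions estimated from in vivo cortical
#' recordings:
#' Up-state duration `0.35 m - 0.7`; Down-state duration `0.25 m - 0.35`;
#' ISI within sleep Up states `-0.2 m + 0.95`; wake ISI `0.03 m + 0.65`
#' (`m` = log10 of the mean, durations in ms).
#'
#' @param kind One of `"up"`, `"down"`, `"isi_sleep_up"`, `"isi_wake"`.
#' @param log10_mean log10 of the mean interval (ms); finite.
#' @return log10 SD of the interval distribution.
#' @export
sd_from_mean <- function(kind, log10_mean) {
  if (!all(is.finite(log10_mean)))
    stop("`log10_mean` must be finite", call. = FALSE)
  kind <- match.arg(kind, c("up", "down", "isi_sleep_up", "isi_wake"))
  switch(kind,
    up           = 0.35 * log10_mean - 0.7,
    down         = 0.25 * log10_mean - 0.35,
    isi_sleep_up = -0.2 * log10_mean + 0.95,
    isi_wake     = 0.03 * log10_mean + 0.65
  )
}

#' Mean Down-state duration from mean Up-state duration
#'
#' `DOWNM = -0.7 UPM + 4.0` (log10 ms), the in vivo regression linking the
#' two slow-oscillation interval means.  Used only in configurations that
#' do not state DOWNM explicitly.
#'
#' @param upm log10 mean Up-state duration (ms).
#' @return log10 mean Down-state duration (ms).
#' @export
downm_from_upm <- function(upm) {
  stopifnot(is.finite(upm))
  -0.7 * upm + 4.0
}

#' Specification of a synthetic firing pattern
#'
#' @param state `"sleep"` (Up/Down alternation) or `"wake"` (tonic).
#' @param duration_s Pattern duration in seconds, > 0.
#' @param isim log10 mean ISI (ms): wake ISI for wake patterns, within-Up
#'   ISI for sleep patterns.
#' @param upm,downm log10 mean Up-/Down-state durations (ms); sleep only.
#' @param isi_kind Which mean-SD regression governs the ISI distribution;
#'   defaults to the state-appropriate one.  Setting `"isi_wake"` on a
#'   sleep spec with zero Down time makes the generator degenerate exactly
#'   into the wake generator (control experiments).
#' @return An object of class `pattern_spec`.
#' @export
pattern_spec <- function(state = c("sleep", "wake"), duration_s, isim,
                         upm = NULL, downm = NULL, isi_kind = NULL) {
  state <- match.arg(state)
  stopifnot(is.numeric(duration_s), duration_s > 0, is.finite(isim))
  if (state == "sleep") {
    if (is.null(upm)) stop("sleep spec needs `upm`", call. = FALSE)
    if (is.null(downm)) downm <- downm_from_upm(upm)
    # downm = -Inf encodes zero Down time (degenerate tonic control)
    stopifnot(is.finite(upm), !is.na(downm), downm < Inf)
  }
  if (is.null(isi_kind))
    isi_kind <- if (state == "sleep") "isi_sleep_up" else "isi_wake"
  structure(list(state = state, duration_s = duration_s, isim = isim,
                 upm = upm, downm = downm, isi_kind = isi_kind),
            class = "pattern_spec")
}

# draw n values from the log10-lognormal with mean m, sd s (log10 of ms).
# The mean-SD regressions extrapolate to negative SDs outside the observed
# range; sampling floors the SD at a hair above zero there.
rlog10norm <- function(n, m, s) 10^stats::rnorm(n, m, max(s, 0.01))

# cumulated lognormal-ISI timestamps within (0, len]; shared by the wake
# generator and the within-Up sleep generator so the two consume the RNG
# identically
draw_isi_train <- function(len, isim, s) {
  mean_isi <- exp(isim * log(10) + (max(s, 0.01) * log(10))^2 / 2)
  n_guess <- max(16, ceiling(len / mean_isi * 1.5))
  tt <- cumsum(rlog10norm(n_guess, isim, s))
  while (tt[length(tt)] <= len)
    tt <- c(tt, tt[length(tt)] + cumsum(rlog10norm(n_guess, isim, s)))
  tt[tt <= len]
}

#' Sample a wake-like (tonic) spike train
#'
#' ISIs are drawn from the wake lognormal (SD from [sd_from_mean()]) and
#' cumulated until the duration is exceeded.
#'
#' @param spec A [pattern_spec()] with `state = "wake"`.
#' @param seed Optional integer seed.
#' @return A `spike_pattern`: list with `spikes` (sorted timestamps, ms),
#'   `up_intervals` (empty matrix for wake), `mean_rate` (Hz) and
#'   `duration_ms`.
#' @export
sample_wake_train <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "pattern_spec"), spec$state == "wake")
  with_seed(seed, {
    dur <- spec$duration_s * 1000
    s <- sd_from_mean(spec$isi_kind, spec$isim)
    times <- draw_isi_train(dur, spec$isim, s)
    if (length(times) == 0)
      warning("mean ISI exceeds duration: empty train")
    new_spike_pattern(times, matrix(numeric(0), ncol = 2), dur)
  })
}

#' Sample a sleep-like (Up/Down alternating) spike train
#'
#' Alternating Up/Down interval skeleton drawn from the duration
#' lognormals; within each Up interval, spikes are drawn from the within-Up
#' ISI lognormal.  Down intervals are silent.  For multi-neuron patterns
#' use [generate_pattern()], which shares one skeleton across neurons
#' (population-wide slow-wave synchrony).
#'
#' @param spec A [pattern_spec()] with `state = "sleep"`.
#' @param seed Optional integer seed.
#' @param skeleton Optional precomputed Up-interval matrix (two columns,
#'   ms) to reuse across neurons.
#' @return A `spike_pattern` (see [sample_wake_train()]); `up_intervals`
#'   holds the (start, end) times in ms.
#' @export
sample_sleep_train <- function(spec, seed = NULL, skeleton = NULL) {
  stopifnot(inherits(spec, "pattern_spec"), spec$state == "sleep")
  with_seed(seed, {
    dur <- spec$duration_s * 1000
    if (is.null(skeleton)) skeleton <- sample_updown_skeleton(spec)
    s_isi <- sd_from_mean(spec$isi_kind, spec$isim)
    spikes <- vector("list", nrow(skeleton))
    for (i in seq_len(nrow(skeleton))) {
      len <- skeleton[i, 2] - skeleton[i, 1]
      spikes[[i]] <- skeleton[i, 1] + draw_isi_train(len, spec$isim, s_isi)
    }
    new_spike_pattern(unlist(spikes), skeleton, dur)
  })
}

# Alternating Down/Up skeleton over the spec duration (starts in a Down
# state).  Returns a matrix of Up (start, end) pairs in ms.
sample_updown_skeleton <- function(spec) {
  dur <- spec$duration_s * 1000
  if (10^spec$downm <= 0) {
    # zero Down time: one Up interval covers the whole train
    return(matrix(c(0, dur), ncol = 2))
  }
  s_up <- sd_from_mean("up", spec$upm)
  s_down <- sd_from_mean("down", spec$downm)
  ups <- matrix(numeric(0), ncol = 2)
  t <- 0
  while (t < dur) {
    t <- t + rlog10norm(1, spec$downm, s_down)
    if (t >= dur) break
    up_len <- rlog10norm(1, spec$upm, s_up)
    ups <- rbind(ups, c(t, min(t + up_len, dur)))
    t <- t + up_len
  }
  ups
}

new_spike_pattern <- function(times, up_intervals, duration_ms) {
  times <- sort(times)
  structure(list(spikes = times, up_intervals = up_intervals,
                 mean_rate = length(times) / (duration_ms / 1000),
                 duration_ms = duration_ms),
            class = "spike_pattern")
}

#' @export
print.spike_pattern <- function(x, ...) {
  cat(sprintf("<spike_pattern> %d spikes over %.1f s (%.3f Hz), %d Up intervals\n",
              length(x$spikes), x$duration_ms / 1000, x$mean_rate,
              nrow(x$up_intervals)))
  invisible(x)
}

#' Generate a multi-neuron firing pattern
#'
#' Wake patterns are independent tonic trains; sleep patterns share one
#' Up/Down skeleton across neurons with independent within-Up spiking.
#'
#' @param spec A [pattern_spec()].
#' @param n_neurons Number of neurons.
#' @param seed Optional integer seed.
#' @return List of `spike_pattern`s (one per neuron); for sleep they share
#'   `up_intervals`.
#' @export
generate_pattern <- function(spec, n_neurons, seed = NULL) {
  with_seed(seed, {
    if (spec$state == "wake") {
      lapply(seq_len(n_neurons), function(i) sample_wake_train(spec))
    } else {
      skel <- sample_updown_skeleton(spec)
      lapply(seq_len(n_neurons), function(i)
        sample_sleep_train(spec, skeleton = skel))
    }
  })
}

#' Adjust a pattern spec to hit a target mean firing rate
#'
#' Monotone bisection on the chosen knob (`downm`: longer Down states lower
#' the rate; `isim`: longer ISIs lower the rate) until the empirical
#' long-run mean rate of a generated evaluation train matches the target.
#' The evaluation train is regenerated from a fixed internal seed at every
#' bisection step, so the returned spec reproduces the target rate exactly
#' under that seed; across independent seeds the match holds in
#' expectation.
#'
#' @param spec A [pattern_spec()].
#' @param target_rate Target mean rate (Hz), > 0.
#' @param knob `"downm"` or `"isim"`.
#' @param tolerance Relative tolerance on the rate (default 2%).
#' @param eval_duration_s Duration of each evaluation train (s); defaults
#'   to `max(600, 1500 / target_rate)` so that slow Up/Down alternation is
#'   sampled over enough episodes.
#' @param n_eval Number of evaluation trains averaged per bisection step.
#' @param eval_seed Internal base seed for the evaluation trains.
#' @param bounds Knob search interval (log10 ms).
#' @return The adjusted `pattern_spec` (with attribute `achieved_rate`).
#' @export
match_rate <- function(spec, target_rate, knob = c("downm", "isim"),
                       tolerance = 0.02, eval_duration_s = NULL,
                       n_eval = 5L, eval_seed = 20260101L, bounds = NULL) {
  knob <- match.arg(knob)
  stopifnot(target_rate > 0)
  if (knob == "downm" && spec$state != "sleep")
    stop("`downm` knob applies to sleep specs only", call. = FALSE)
  if (is.null(bounds))
    bounds <- if (knob == "downm") c(0.5, 6.5) else c(0.3, 3.6)
  if (is.null(eval_duration_s))
    eval_duration_s <- max(600, 1500 / target_rate)

  eval_rate <- function(value) {
    sp <- spec
    sp[[knob]] <- value
    evaluate_spec_rate(sp, eval_duration_s, n_eval, eval_seed)
  }
  # rate is decreasing in both knobs
  r_lo <- eval_rate(bounds[1])
  r_hi <- eval_rate(bounds[2])
  if (target_rate > r_lo || target_rate < r_hi)
    stop(sprintf(
      "target rate %.3g Hz outside achievable bracket [%.3g, %.3g] Hz",
      target_rate, r_hi, r_lo), call. = FALSE)
  lo <- bounds[1]; hi <- bounds[2]
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    r <- eval_rate(mid)
    if (abs(r - target_rate) / target_rate < tolerance * 0.5) break
    if (r > target_rate) lo <- mid else hi <- mid
  }
  out <- spec
  out[[knob]] <- mid
  attr(out, "achieved_rate") <- r
  out
}

#' Long-run mean firing rate of a pattern spec
#'
#' Deterministic empirical rate estimate: the mean rate of `n_eval`
#' independently generated trains under fixed seeds.  [match_rate()]
#' bisects on this quantity.
#'
#' @param spec A [pattern_spec()].
#' @param duration_s Duration of each evaluation train (s).
#' @param n_eval Number of trains averaged.
#' @param eval_seed Base seed.
#' @return Mean firing rate (Hz).
#' @export
evaluate_spec_rate <- function(spec, duration_s = 600, n_eval = 5L,
                               eval_seed = 20260101L) {
  sp <- spec
  sp$duration_s <- duration_s
  rates <- vapply(seq_len(n_eval), function(k) {
    pat <- if (sp$state == "sleep")
      sample_sleep_train(sp, seed = eval_seed + k)
    else sample_wake_train(sp, seed = eval_seed + k)
    pat$mean_rate
  }, 0)
  mean(rates)
}

#' Convert a spike pattern to a membrane-potential waveform
#'
#' Piecewise-linear interpolation through anchor points: each spike
#' timestamp is a peak, followed by an after-hyperpolarization anchor and a
#' return to the local baseline.  Sleep traces sit at the Up-state
#' potential inside Up intervals and at the Down-state baseline outside;
#' wake traces sit at the baseline throughout.  When consecutive spikes are
#' closer than the anchor window, the anchor offsets are compressed
#' proportionally so peaks stay exactly at the timestamps.
#'
#' @param pattern A `spike_pattern`.
#' @param wf Waveform parameters, see [waveform_params()].
#' @param dt Sampling step (ms), > 0.
#' @return Numeric voltage trace (mV) of length `duration_ms/dt + 1`, with
#'   attribute `dt`.
#' @export
spikes_to_voltage <- function(pattern, wf = waveform_params(), dt = 0.05) {
  if (!is.numeric(dt) || dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  dur <- pattern$duration_ms
  n <- floor(dur / dt) + 1
  tgrid <- seq(0, by = dt, length.out = n)

  sleep <- nrow(pattern$up_intervals) > 0
  flat <- if (sleep) as.vector(t(pattern$up_intervals)) else numeric(0)
  base_at <- function(tt) {
    if (!sleep) return(rep(wf$v_down, length(tt)))
    inside <- findInterval(tt, flat) %% 2L == 1L
    wf$v_down + (wf$v_up - wf$v_down) * inside
  }

  # baseline anchors: state levels, with short ramps at Up boundaries
  at <- c(0); av <- c(base_at(0))
  if (sleep) {
    for (i in seq_len(nrow(pattern$up_intervals))) {
      a <- pattern$up_intervals[i, 1]; b <- pattern$up_intervals[i, 2]
      r <- min(wf$up_ramp_ms, (b - a) / 2)
      at <- c(at, a, a + r, b - r, b)
      av <- c(av, wf$v_down, wf$v_up, wf$v_up, wf$v_down)
    }
  }
  at <- c(at, dur); av <- c(av, base_at(dur))

  sp <- pattern$spikes
  if (length(sp)) {
    gap_prev <- c(Inf, diff(sp))
    gap_next <- c(diff(sp), Inf)
    s_pre <- pmin(1, gap_prev / (wf$recover_ms + wf$rise_ms))
    s_post <- pmin(1, gap_next / (wf$recover_ms + wf$rise_ms))
    base_sp <- base_at(sp)
    at <- c(at, sp - wf$rise_ms * s_pre, sp,
            sp + wf$ahp_ms * s_post, sp + wf$recover_ms * s_post)
    av <- c(av, base_sp, rep(wf$v_peak, length(sp)), rep(wf$v_ahp, length(sp)),
            base_sp)
  }
  o <- order(at)
  at <- at[o]; av <- av[o]
  keep <- !duplicated(at)
  # spike anchors must win over coincident baseline anchors
  v <- stats::approx(at[keep], av[keep], xout = tgrid, rule = 2)$y
  if (length(sp)) {
    idx <- round(sp / dt) + 1
    idx <- idx[idx >= 1 & idx <= n]
    v[idx] <- wf$v_peak
  }
  attr(v, "dt") <- dt
  v
}
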