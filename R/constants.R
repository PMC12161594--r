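#' Fixed constants of the simple plasticity model
#'
#' Model constants shared by every learning-rule instance: the NMDAR gating
#' kinetics (second-order, no Mg2+ block, faster turnover than the classic
#' cortical-network values so that single transients resolve on the STDP
#' time scale), the VGCC driving-force convention and the Ca2+ current
#' conversion factor. The absolute scale of `g_nmda`, `g_ca` and `alpha_ca`
#' is immaterial for the learning rules because the scaling factors
#' `beta_nmda`/`beta_vgcc` are always calibrated so that the mean transient
#' amplitudes equal 0.7 uM (NMDAR source) and 1.4 uM (VGCC source).
#'
#' @param ... named overrides for individual constants.
#' @return Named list of constants: `alpha_ca` (uM nA^-1 ms^-1), `g_nmda`,
#'   `g_ca` (unit conductances), `v_rest`, `v_ca` (mV), `area`
#'   (dimensionless bookkeeping factor), NMDAR gating constants
#'   (`a_s_nmda`, `a_x_nmda` in ms^-1; `tau_s_nmda`, `tau_x_nmda` in ms)
#'   and the noise coefficient `z`.
#' @export
plasticity_constants <- function(...) {
  consts <- list(
    alpha_ca  = 0.005,  # uM per nA ms
    g_nmda    = 1.0,
    g_ca      = 1.0,
    v_rest    = -70,    # mV, NMDAR Ca driving-force reference (simple model)
    v_ca      = 120,    # mV
    area      = 0.02,
    a_s_nmda  = 0.5,    # ms^-1
    a_x_nmda  = 3.48,   # ms^-1
    tau_s_nmda = 20,    # ms
    tau_x_nmda = 1,     # ms
    z         = 3.5     # noise coefficient
  )
  dots <- list(...)
  if (length(dots)) {
    stopifnot(all(nzchar(names(dots))), all(names(dots) %in% names(consts)))
    consts[names(dots)] <- dots
  }
  consts
}

#' Waveform parameters for converting spike trains to membrane potential
#'
#' Spike timestamps become piecewise-linear voltage waveforms anchored at
#' the spike peak, the after-hyperpolarization and the return to the local
#' baseline.  In sleep-like traces the baseline alternates between the Up-
#' and Down-state potentials (default separation 15 mV; 5 and 10 mV are the
#' supported robustness settings).
#'
#' @param up_down_diff Up-minus-Down potential difference in mV.
#' @param v_peak Spike peak potential (mV).
#' @param v_ahp After-hyperpolarization potential (mV).
#' @param v_down Down-state / wake baseline potential (mV).
#' @param rise_ms Time from baseline anchor to peak (ms).
#' @param ahp_ms Time from peak to the AHP anchor (ms).
#' @param recover_ms Time from peak back to baseline (ms).
#' @param up_ramp_ms Ramp duration at Up-state onset/offset (ms).
#' @return Named list with the above plus `v_up = v_down + up_down_diff`.
#' @export
waveform_params <- function(up_down_diff = 15, v_peak = 30, v_ahp = -75,
                            v_down = -70, rise_ms = 1, ahp_ms = 2,
                            recover_ms = 8, up_ramp_ms = 10) {
  stopifnot(up_down_diff >= 0, v_peak > v_down + up_down_diff,
            rise_ms > 0, recover_ms > ahp_ms, ahp_ms > 0)
  list(v_peak = v_peak, v_ahp = v_ahp, v_down = v_down,
       v_up = v_down + up_down_diff, up_down_diff = up_down_diff,
       rise_ms = rise_ms, ahp_ms = ahp_ms, recover_ms = recover_ms,
       up_ramp_ms = up_ramp_ms)
}

#' Fixed constants of the Hodgkin-Huxley-based network model
#'
#' Reversal potentials, capacitance, Ca2+ handling and synaptic kinetics of
#' the averaged cortical neuron.  Intrinsic currents (mS/cm2 conductances)
#' are converted to nA by the factor `area * 10`.
#'
#' @param ... named overrides.
#' @return Named list of constants.
#' @export
hh_constants <- function(...) {
  consts <- list(
    c_m    = 0.2,      # nF (1 uF/cm2 at the bookkeeping area)
    area   = 0.02,
    v_l    = -60.95,   # mV
    v_na   = 55,
    v_k    = -100,
    v_ca   = 120,
    v_ampa = 0,
    v_nmda = 0,
    v_gaba = -70,
    kd     = 30,       # uM, KCa half-activation
    tau_ha = 15,       # ms
    phi    = 1,
    alpha_ca = 0.005,  # uM per nA ms
    tau_ca_syn = 15,   # ms, synaptic Ca2+ compartment
    tau_ampa  = 2,     # ms
    tau_s_nmda = 100,  # ms
    tau_x_nmda = 2,    # ms
    tau_gaba  = 10,    # ms
    a_ampa    = 3.48,  # ms^-1
    a_s_nmda  = 0.5,
    a_x_nmda  = 3.48,
    a_gaba    = 1
  )
  dots <- list(...)
  if (length(dots)) {
    stopifnot(all(nzchar(names(dots))), all(names(dots) %in% names(consts)))
    consts[names(dots)] <- dots
  }
  consts
}

# Restore the RNG state on exit and run `expr` under `seed` (no-op when
# seed is NULL).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
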