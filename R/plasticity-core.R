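#' Saturating NMDAR activation function of membrane potential
#'
#' `f(V) = 1 / (1 + exp(-(V - 20)/2))`, the presynaptic drive of the
#' second-order NMDAR gating kinetics.  Strictly increasing with midpoint
#' at +20 mV (spike peaks activate it, subthreshold potentials do not).
#'
#' @param v Membrane potential (mV); finite numeric vector.
#' @return Activation fraction in (0, 1).
#' @export
saturating_gate <- function(v) {
  if (!is.numeric(v) || any(!is.finite(v)))
    stop("`v` must be finite numeric", call. = FALSE)
  1 / (1 + exp(-(v - 20) / 2))
}

#' Steady-state VGCC activation
#'
#' `mCa_inf(V) = 1 / (1 + exp(-(V + 20)/9))`; the VGCC Ca2+ current uses
#' its square.
#'
#' @inheritParams saturating_gate
#' @return Activation fraction in (0, 1).
#' @export
vgcc_activation <- function(v) {
  if (!is.numeric(v) || any(!is.finite(v)))
    stop("`v` must be finite numeric", call. = FALSE)
  1 / (1 + exp(-(v + 20) / 9))
}

#' One integrator step of the calcium state
#'
#' Advances the NMDAR gating pair (x, s), the NMDAR-sourced `c_pre` and the
#' VGCC-sourced `c_post` by one RK4 step.  In the simple model the NMDAR
#' Ca2+ driving force is the fixed resting potential; set
#' `use_vpost = TRUE` for the network variant where the instantaneous
#' postsynaptic potential is used instead.
#'
#' @param state Named list or vector with `c_pre`, `c_post`, `s_nmda`,
#'   `x_nmda` (all >= 0).
#' @param v_pre,v_post Pre-/postsynaptic membrane potential (mV) held over
#'   the step.
#' @param rule A [plasticity_rule()] (provides `beta_nmda`, `beta_vgcc`,
#'   `tau_pre`, `tau_post`).
#' @param consts Model constants, see [plasticity_constants()].
#' @param dt Step size (ms), > 0.
#' @param use_vpost Use `v_post` as the NMDAR Ca2+ driving-force reference.
#' @return Updated state list.
#' @export
step_calcium <- function(state, v_pre, v_post, rule,
                         consts = plasticity_constants(), dt = 0.1,
                         use_vpost = FALSE) {
  if (!is.numeric(dt) || dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  stopifnot(all(c("c_pre", "c_post", "s_nmda", "x_nmda") %in% names(state)))
  vref <- if (use_vpost) v_post else consts$v_rest
  fr <- saturating_gate(v_pre)
  deriv <- function(y) {
    c(
      x = consts$a_x_nmda * fr - y[["x"]] / consts$tau_x_nmda,
      s = consts$a_s_nmda * y[["x"]] * (1 - y[["s"]]) -
        y[["s"]] / consts$tau_s_nmda,
      cp = consts$alpha_ca * consts$g_nmda * y[["s"]] *
        (consts$v_ca - vref) * rule$beta_nmda - y[["cp"]] / rule$tau_pre,
      cq = consts$alpha_ca * consts$area * consts$g_ca *
        vgcc_activation(v_post)^2 * (consts$v_ca - v_post) * rule$beta_vgcc -
        y[["cq"]] / rule$tau_post
    )
  }
  y <- c(x = state$x_nmda, s = state$s_nmda, cp = state$c_pre,
         cq = state$c_post)
  k1 <- deriv(y)
  k2 <- deriv(y + dt / 2 * k1)
  k3 <- deriv(y + dt / 2 * k2)
  k4 <- deriv(y + dt * k3)
  y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  list(c_pre = max(y[["cp"]], 0), c_post = max(y[["cq"]], 0),
       s_nmda = y[["s"]], x_nmda = y[["x"]])
}

#' Calcium traces from a pre/post voltage-trace pair
#'
#' Integrates the NMDAR gating kinetics and both Ca2+ sources over full
#' voltage traces (compiled; RK4 for the gating, exact exponential
#' integration for the linear Ca2+ filters).
#'
#' @param v_pre,v_post Voltage traces (mV) on a shared time base.
#' @param rule A [plasticity_rule()].
#' @param consts Model constants.
#' @param dt Step size (ms).
#' @param use_vpost See [step_calcium()].
#' @return List with `c_pre`, `c_post`, `c` (their sum) and `s_nmda`.
#' @export
simulate_calcium <- function(v_pre, v_post, rule,
                             consts = plasticity_constants(), dt = 0.1,
                             use_vpost = FALSE) {
  if (length(v_pre) != length(v_post))
    stop("pre/post traces must share a time base", call. = FALSE)
  out <- cpp_calcium_pair(v_pre, v_post, consts, rule$beta_nmda,
                          rule$beta_vgcc, rule$tau_pre, rule$tau_post, dt,
                          use_vpost)
  out$c <- out$c_pre + out$c_post
  out
}

#' One Euler-Maruyama step of the efficacy variable
#'
#' The bistable efficacy rho follows
#' `tau_s drho = [-rho(1-rho)(rho*-rho) + gamma_p (1-rho) H(c-theta_p)
#'  - gamma_d rho H(c-theta_d)] dt + noise`, with additive Gaussian noise
#' active only while the Ca2+ concentration exceeds at least one threshold:
#' `drho_noise = sigma z sqrt(H_d + H_p) sqrt(dt/tau_s) eta`.  Noise may
#' transiently push rho outside [0, 1]; the cubic drift restores it.
#'
#' @param rho Current efficacy.
#' @param c_total Total postsynaptic Ca2+ (uM).
#' @param rule A [plasticity_rule()].
#' @param dt Step size (ms), > 0.
#' @return Updated rho (scalar).
#' @export
step_efficacy <- function(rho, c_total, rule, dt = 0.1) {
  if (!is.numeric(dt) || dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  hp <- c_total >= rule$theta_p
  hd <- c_total >= rule$theta_d
  drift <- -rho * (1 - rho) * (rule$rho_star - rho) +
    rule$gamma_p * (1 - rho) * hp - rule$gamma_d * rho * hd
  rho <- rho + drift * dt / rule$tau_s
  nact <- hp + hd
  if (nact > 0)
    rho <- rho + rule$sigma * rule$z * sqrt(nact) * sqrt(dt / rule$tau_s) *
      stats::rnorm(1)
  rho
}

#' Simulate one synapse over a pre/post voltage-trace pair
#'
#' Full pipeline: calcium dynamics from the traces, then the efficacy SDE
#' over the resulting Ca2+ concentration.  Deterministic given `seed`.
#'
#' @param v_pre,v_post Voltage traces (mV), equal length, fixed `dt`.
#' @param rule A [plasticity_rule()].
#' @param rho0 Initial efficacy in [0, 1].
#' @param dt Step size (ms).
#' @param consts Model constants.
#' @param seed Optional integer seed.
#' @param stride Record every `stride`-th step of the rho trajectory.
#' @param use_vpost See [step_calcium()].
#' @return List with `time` (ms), `rho` (trajectory), `c` (Ca2+ trace) and
#'   the final efficacy `rho_final`.
#' @export
simulate_synapse <- function(v_pre, v_post, rule, rho0 = 0.5, dt = 0.05,
                             consts = plasticity_constants(), seed = NULL,
                             stride = 1L, use_vpost = FALSE) {
  if (length(v_pre) != length(v_post))
    stop("pre/post traces must share a time base", call. = FALSE)
  stopifnot(rho0 >= 0, rho0 <= 1)
  ca <- simulate_calcium(v_pre, v_post, rule, consts, dt, use_vpost)
  rho <- with_seed(seed, cpp_rho_trace(
    ca$c, dt, rule$theta_p, rule$theta_d, rule$gamma_p, rule$gamma_d,
    rule$sigma, rule$tau_s, rule$rho_star, rule$z, rho0, as.integer(stride)
  ))
  list(time = seq(0, by = dt * stride, length.out = length(rho)),
       rho = rho, c = ca$c, rho_final = rho[length(rho)])
}
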