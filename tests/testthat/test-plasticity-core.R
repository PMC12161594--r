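test_that("voltage gates match their closed forms and are monotone", {
  expect_equal(saturating_gate(20), 0.5)
  expect_equal(saturating_gate(0), 1 / (1 + exp(10)))
  expect_equal(vgcc_activation(-20), 0.5)
  expect_equal(vgcc_activation(-38), 1 / (1 + exp(2)))
  v <- seq(-120, 80, by = 0.5)
  expect_true(all(diff(saturating_gate(v)) > 0))
  expect_true(all(diff(vgcc_activation(v)) > 0))
  expect_true(all(saturating_gate(v) > 0 & saturating_gate(v) < 1))
  expect_gt(saturating_gate(1e3), 1 - 1e-10)
  expect_lt(saturating_gate(-1e3), 1e-10)
  expect_error(saturating_gate(NA_real_), "finite")
  expect_error(vgcc_activation(Inf), "finite")
})

test_that("calcium decays exponentially without drive and is linear in gNMDA", {
  rule <- ref_rule_raw("STDP")
  consts <- plasticity_constants()
  # resting presynaptic potential: gate ~ 0, c_pre decays with tau_pre
  n <- 2000
  dt <- 0.1
  v_rest <- rep(consts$v_rest, n)
  st <- list(c_pre = 1, c_post = 0, s_nmda = 0, x_nmda = 0)
  for (i in 1:100)
    st <- step_calcium(st, consts$v_rest, consts$v_rest, rule, consts, dt)
  expect_equal(st$c_pre, exp(-100 * dt / rule$tau_pre), tolerance = 1e-6)

  # doubling gNMDA doubles the NMDAR drive at fixed gating
  c1 <- plasticity_constants()
  c2 <- plasticity_constants(g_nmda = 2 * c1$g_nmda)
  v <- spike_trace(50, 200)
  ca1 <- simulate_calcium(v, rep(c1$v_rest, length(v)), rule, c1, 0.1)
  ca2 <- simulate_calcium(v, rep(c1$v_rest, length(v)), rule, c2, 0.1)
  expect_equal(ca2$c_pre, 2 * ca1$c_pre, tolerance = 1e-12)
  # and the VGCC source is untouched
  expect_equal(ca2$c_post, ca1$c_post)
})

test_that("one presynaptic transient matches a fine-step reference", {
  rule <- ref_rule("STDP")
  consts <- plasticity_constants()
  v <- spike_trace(100, 400, dt = 0.1)
  v10 <- spike_trace(100, 400, dt = 0.01)
  vq <- rep(consts$v_rest, length(v))
  vq10 <- rep(consts$v_rest, length(v10))
  ca <- simulate_calcium(v, vq, rule, consts, 0.1)
  ca10 <- simulate_calcium(v10, vq10, rule, consts, 0.01)
  idx10 <- seq(1, length(v10), by = 10)
  err <- max(abs(ca$c_pre - ca10$c_pre[idx10])) / max(ca10$c_pre)
  expect_lt(err, 1e-3)
})

test_that("calcium integration agrees with an independent ODE solver", {
  skip_if_not_installed("deSolve")
  rule <- ref_rule_raw("STDP")
  consts <- plasticity_constants()
  dt <- 0.1
  v <- spike_trace(60, 300, dt = dt)
  vfun <- stats::approxfun(seq(0, by = dt, length.out = length(v)), v,
                           rule = 2)
  rhs <- function(t, y, parms) {
    f <- 1 / (1 + exp(-(vfun(t) - 20) / 2))
    dx <- consts$a_x_nmda * f - y[1] / consts$tau_x_nmda
    ds <- consts$a_s_nmda * y[1] * (1 - y[2]) - y[2] / consts$tau_s_nmda
    dc <- consts$alpha_ca * consts$g_nmda * y[2] *
      (consts$v_ca - consts$v_rest) * rule$beta_nmda - y[3] / rule$tau_pre
    list(c(dx, ds, dc))
  }
  sol <- deSolve::lsoda(c(0, 0, 0), seq(0, 300, by = dt), rhs, NULL,
                        rtol = 1e-8, atol = 1e-10)
  ca <- simulate_calcium(v, rep(consts$v_rest, length(v)), rule, consts,
                         dt)
  expect_lt(max(abs(sol[, 4] - ca$c_pre)) / max(ca$c_pre), 1e-3)
})

test_that("efficacy drift has the bistable fixed-point structure", {
  rule <- ref_rule_raw("STDP")
  rule$sigma <- 0
  # below both thresholds, rho < rho*: cubic pushes down
  r1 <- step_efficacy(0.2, 0, rule, dt = 1)
  expect_lt(r1, 0.2)
  r2 <- step_efficacy(0.8, 0, rule, dt = 1)
  expect_gt(r2, 0.8)
  # held above both thresholds with dominant amplitudes: attractor at
  # gamma_p / (gamma_p + gamma_d)
  rule$gamma_p <- 200; rule$gamma_d <- 100
  rho <- 0.1
  for (i in 1:20000) rho <- step_efficacy(rho, 10, rule, dt = 10)
  expect_equal(rho, 200 / 300, tolerance = 0.01)
})

test_that("without noise the efficacy stays in [0, 1] for any calcium input", {
  rule <- ref_rule_raw("STDP")
  rule$sigma <- 0
  set.seed(11)
  for (k in 1:20) {
    c_seq <- sample(c(0, 0.8, 1.6, 3), 400, replace = TRUE)
    rho <- runif(1)
    for (i in seq_along(c_seq))
      rho <- step_efficacy(rho, c_seq[i], rule, dt = 5)
    expect_true(rho >= 0 && rho <= 1)
  }
})

test_that("noise is gated off strictly below both thresholds", {
  rule <- ref_rule_raw("STDP")
  c_below <- min(rule$theta_p, rule$theta_d) - 1e-9
  set.seed(2)
  r1 <- replicate(50, step_efficacy(0.4, c_below, rule, dt = 0.1))
  expect_equal(stats::var(r1), 0)
  c_above <- min(rule$theta_p, rule$theta_d) + 1e-9
  r2 <- replicate(50, step_efficacy(0.4, c_above, rule, dt = 0.1))
  expect_gt(stats::var(r2), 0)
})

test_that("halving the step changes the deterministic trajectory negligibly", {
  rule <- ref_rule("STDP")
  rule$sigma <- 0
  wf <- waveform_params()
  pre <- spike_trace(seq(100, 1900, by = 200), 2000, dt = 0.05)
  post <- spike_trace(seq(120, 1920, by = 200), 2000, dt = 0.05)
  s1 <- simulate_synapse(pre, post, rule, dt = 0.05, seed = 1)
  pre2 <- spike_trace(seq(100, 1900, by = 200), 2000, dt = 0.025)
  post2 <- spike_trace(seq(120, 1920, by = 200), 2000, dt = 0.025)
  s2 <- simulate_synapse(pre2, post2, rule, dt = 0.025, seed = 1)
  expect_lt(abs(s1$rho_final - s2$rho_final), 1e-3)
})

test_that("simulate_synapse is seed-deterministic and checks inputs", {
  rule <- ref_rule("STDP")
  pre <- spike_trace(c(100, 300), 500)
  post <- spike_trace(c(120, 320), 500)
  a <- simulate_synapse(pre, post, rule, seed = 7, dt = 0.1)
  b <- simulate_synapse(pre, post, rule, seed = 7, dt = 0.1)
  expect_identical(a$rho, b$rho)
  expect_error(simulate_synapse(pre[-1], post, rule), "time base")
})

test_that("sub-threshold stimulation leaves rho at the unstable point", {
  rule <- ref_rule("STDP")
  rule$sigma <- 0
  # raise thresholds so the protocol never crosses them
  rule$theta_p <- 50
  rule$theta_d <- 40
  pre <- spike_trace(c(100, 300), 600, dt = 0.1)
  post <- spike_trace(c(120, 320), 600, dt = 0.1)
  s <- simulate_synapse(pre, post, rule, rho0 = rule$rho_star, dt = 0.1)
  expect_equal(s$rho_final, rule$rho_star)
})

test_that("repeated pairing at a short positive lag potentiates under STDP", {
  rule <- ref_rule("STDP")
  # individual runs settle to either attractor; the mean over repeats of
  # the pairing protocol (pre 20 ms before post, 1 Hz for 60 s) rises
  mc <- mc_stdp_change(rule, lags = 20, nrep = 200, seed = 5)
  expect_gt(mc$change_mc, 1 + 3 * mc$se)
  # and a single simulated trajectory stays within the unit interval
  pre_t <- seq(500, by = 1000, length.out = 10)
  pre <- spike_trace(pre_t, 10.5e3, dt = 0.1)
  post <- spike_trace(pre_t + 20, 10.5e3, dt = 0.1)
  s <- simulate_synapse(pre, post, rule, rho0 = 0.5, dt = 0.1, seed = 5)
  expect_true(all(s$rho > -0.2 & s$rho < 1.2))
})
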