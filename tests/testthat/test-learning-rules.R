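test_that("occupancy fractions are exact on constructed traces", {
  dt <- 0.1
  n <- 10000 # 1 s
  expect_equal(occupancy_fractions(rep(2, n), 1, c(0, 1), dt), 1)
  expect_equal(occupancy_fractions(rep(0.5, n), 1, c(0, 1), dt), 0)
  sq <- rep(c(2, 0), each = n / 2)
  expect_equal(occupancy_fractions(sq, 1, c(0, 1), dt), 0.5)
  expect_error(occupancy_fractions(rep(1, n), 1, c(0.5, 0.5), dt),
               "window")
})

test_that("calibration hits the target amplitudes and scales inversely with gNMDA", {
  rule <- calibrate_scaling(ref_rule_raw("STDP"))
  # re-simulate the pairing protocol with the returned betas
  consts <- plasticity_constants()
  pre_t <- seq(500, by = 1000, length.out = 3)
  pre <- spike_trace(pre_t, 3000, dt = 0.1)
  post <- spike_trace(pre_t, 3000, dt = 0.1)
  ca <- simulate_calcium(pre, post, rule, consts, 0.1)
  win <- seq(20001, 30000)
  expect_equal(max(ca$c_pre[win]), 0.7, tolerance = 0.01)
  expect_equal(max(ca$c_post[win]), 1.4, tolerance = 0.01)
  expect_true(rule$beta_nmda > 0 && rule$beta_vgcc > 0)

  rule2 <- calibrate_scaling(ref_rule_raw("STDP"),
                             consts = plasticity_constants(g_nmda = 2))
  expect_equal(rule2$beta_nmda, rule$beta_nmda / 2, tolerance = 1e-9)
})

test_that("balancing equalizes the rates at the 100 ms lag and is idempotent", {
  rule <- calibrate_scaling(ref_rule_raw("STDP"))
  bal <- balance_depression_amplitude(rule)
  ap <- attr(bal, "alpha_p")
  ad <- attr(bal, "alpha_d")
  expect_lt(abs(bal$gamma_p * ap - bal$gamma_d * ad), 1e-9)
  bal2 <- balance_depression_amplitude(bal)
  expect_equal(bal2$gamma_d, bal$gamma_d, tolerance = 1e-9)
  # degenerate: thresholds unreachable
  rule$theta_p <- 100
  rule$theta_d <- 90
  expect_error(balance_depression_amplitude(rule), "degenerate")
})

test_that("analytic change has the stated limits", {
  rule <- ref_rule_raw("STDP")
  expect_equal(analytic_change(0, 0, rule), 1)
  # no depression, long protocol, no noise: rho -> 1, ratio -> 2
  r2 <- rule
  r2$sigma <- 0
  r2$gamma_d <- 0
  expect_equal(analytic_change(0.05, 0, r2, duration_s = 1e6, rho0 = 0.5),
               2)
  # balanced occupancies pin the mean at rho*: no change
  r3 <- rule
  r3$gamma_d <- r3$gamma_p
  expect_equal(analytic_change(0.02, 0.02, r3, duration_s = 60), 1)
})

test_that("balanced rules produce curves with unit tails", {
  rule <- ref_rule("STDP")
  cv <- stdp_curve(rule)
  expect_true(all(diff(cv$lag) > 0))
  expect_true(all(cv$change > 0))
  tails <- abs(cv$change[abs(cv$lag) >= 140] - 1)
  expect_true(all(tails < 0.05))
  # STDP polarity at the +/-20 ms lobes
  expect_gt(cv$change[cv$lag == 20], 1)
  expect_lt(cv$change[cv$lag == -20], 1)
})

test_that("rule_fit matches its definition and acceptance is strict", {
  lags <- seq(-160, 160, by = 10)
  target <- rule_target("STDP", lags, a_lr = 0.5, tau_lr = 30)
  expect_equal(rule_fit(target + 1, target), 0)
  flat <- rep(1, length(lags))
  expect_equal(rule_fit(flat, target), sum(target^2))
  # boundary: sse equal to the threshold is rejected (strict <)
  expect_false(sum(target^2) < sum(target^2))
  expect_error(rule_fit(flat[-1], target), "lag grid")
})

test_that("rule targets encode the four sign patterns", {
  lags <- c(-20, 20)
  expect_equal(sign(rule_target("Hebbian", lags)), c(1, 1))
  expect_equal(sign(rule_target("STDP", lags)), c(-1, 1))
  expect_equal(sign(rule_target("AntiHebbian", lags)), c(-1, -1))
  expect_equal(sign(rule_target("AntiSTDP", lags)), c(1, -1))
  # |a| = |b| and Gaussian decay
  t160 <- rule_target("STDP", c(-160, 0, 160), a_lr = 0.5, tau_lr = 30)
  expect_equal(abs(t160[1]), abs(t160[3]))
  expect_equal(t160[2], 0.5)
})

test_that("a small search returns valid, ordered, taxonomy-true sets", {
  res <- search_rules("STDP", n_target = 5, budget = 2e4, seed = 101)
  expect_gt(nrow(res), 0)
  expect_true(all(res$theta_p > res$theta_d))
  expect_true(all(res$sse < 0.25))
  expect_true(!is.unsorted(res$sse))
  for (i in seq_len(min(3, nrow(res)))) {
    cv <- stdp_curve(as_plasticity_rule(res[i, ]))
    expect_gt(cv$change[cv$lag == 20], 1)
    expect_lt(cv$change[cv$lag == -20], 1)
  }
  # anti rules obey the mirrored threshold ordering
  res2 <- search_rules("AntiSTDP", n_target = 2, budget = 3e4, seed = 5)
  if (nrow(res2)) expect_true(all(res2$theta_p < res2$theta_d))
})

test_that("Monte-Carlo simulation matches the analytic change within error", {
  rule <- ref_rule("STDP")
  mc <- mc_stdp_change(rule, lags = c(-40, -20, 0, 20, 40), nrep = 150,
                       seed = 12)
  dev <- abs(mc$change_mc - mc$change)
  expect_true(all(dev < pmax(3 * mc$se, 1e-9)))
})
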