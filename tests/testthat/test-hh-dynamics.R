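test_that("neutral plasticity leaves the network dynamics unchanged", {
  # with rho pinned at 0.5 the AMPAR coupling factor (0.5 + rho) is 1,
  # so the spiking must match a run without plasticity
  sw <- local_swo_set()
  net <- build_hh_network(n_neurons = 10, seed = 3)
  rule <- ref_rule("STDP")
  rule$sigma <- 0
  rule$theta_p <- 1e6   # never crossed: no drift, no noise
  rule$theta_d <- 1e6
  phases <- data.frame(duration_s = 1, multiplier = 1)
  base <- hh_network_run(sw, net, phases = phases, dt = 0.025, seed = 5)
  plast <- hh_network_run(sw, net, phases = phases, dt = 0.025, seed = 5,
                          plasticity = plasticity_options(rule))
  expect_equal(plast$v, base$v, tolerance = 1e-12)
  expect_true(all(abs(plast$rho_final - 0.5) < 1e-12))
})

test_that("plastic network runs report windowed efficacy statistics", {
  sw <- local_swo_set()
  net <- build_hh_network(n_neurons = 10, seed = 3)
  rule <- calibrate_scaling_hh(ref_rule_raw("STDP"), sw, net, "gnmda", 1,
                               duration_s = 3, dt = 0.025, seed = 2)
  expect_equal(rule$beta_nmda, 1)
  expect_gt(rule$beta_vgcc, 0)
  expect_gt(attr(rule, "mc_pre"), 0)
  # thresholds were renormalized by MC_pre / 0.7
  expect_equal(rule$theta_p / ref_rule_raw("STDP")$theta_p,
               attr(rule, "mc_pre") / 0.7)
  res <- run_plastic_network(sw, net, "gnmda", rule, multiplier = 1,
                             duration_s = 6, discard_s = 2, dt = 0.025,
                             seed = 9)
  expect_true(res$ok)
  expect_true(res$mean >= 0 && res$mean <= 1)
  expect_true(is.finite(res$cv))
})

test_that("network rule search honours the printed boxes and threshold", {
  # wake-like voltage trace of a tonic neuron
  ws <- pattern_spec("wake", 5, isim = 2.0)
  v <- spikes_to_voltage(sample_wake_train(ws, seed = 3),
                         waveform_params(), dt = 0.1)
  res <- search_rules_hh(v, "STDP", n_target = 2, budget = 4000,
                         seed = 21, dt = 0.1)
  expect_gt(nrow(res), 0)
  expect_true(all(res$sse < 0.6))
  # thresholds are the sampled boxes scaled by MC_pre / 0.7: the ratio
  # theta_p / theta_d must stay within the box-ratio envelope
  ratio <- res$theta_p / res$theta_d
  expect_true(all(ratio > 0.8 / 1.0 & ratio < 1.6 / 0.5))
  expect_true(all(res$beta_nmda == 1))
})

test_that("stimulation experiments keep the printed group structure", {
  sw <- local_swo_set()
  net <- build_hh_network(n_neurons = 80, seed = 4)
  rule <- ref_rule("STDP")
  res <- stimulation_experiment(sw, net, axis = "gca", rule,
                                wake_s = 1, stim_s = 1, sleep_s = 1.5,
                                dt = 0.05, seed = 6)
  expect_length(res$groups$group1, 20)
  expect_length(res$groups$group2, 20)
  expect_length(res$groups$group3, 24)
  expect_true(all(vapply(res$groups, function(g)
    all(net$is_exc[g]), TRUE)))
  expect_length(res$ratio_after_before, 3)
  expect_true(all(c("group1", "group2", "group3") %in%
                    names(res$trajectory)))
  # group sizes must partition the excitatory population
  expect_error(stimulation_experiment(sw, net, axis = "gca", rule,
                                      group_sizes = c(10, 10, 10),
                                      wake_s = 0.5, stim_s = 0.5,
                                      sleep_s = 0.5),
               "group_sizes")
})

test_that("a reduced full cycle produces periods, Process S and kinase traces", {
  sw <- local_swo_set()
  net <- build_hh_network(n_neurons = 20, seed = 8)
  rule <- ref_rule("STDP")
  kin <- kinase_params("oscillatory")
  out <- run_full_cycle(sw, net, rule, kin, mode = "post",
                        duration_s = 20, threshold = 1.0, dt = 0.05,
                        seed = 12)
  expect_true(out$ok)
  expect_true(all(out$periods$state %in% c("sleep", "wake")))
  expect_true(all(out$s >= 0 & out$s <= 1))
  expect_length(out$r, nrow(out$periods))
  expect_true(all(out$r >= 0 & out$r <= 1))
  expect_true(all(out$a >= 0 & out$a <= 1))
})
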