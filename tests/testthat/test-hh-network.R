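test_that("steady-state gates match the printed sigmoids", {
  # hAR half-activates at -75 mV; a few other closed forms
  p <- sample_hh_params(1, seed = 1)
  p[1, c("gna", "gk", "ga", "gks", "gca", "gkca", "gnap", "gampa",
         "gnmda", "ggaba")] <- 0
  p$gar <- 1; p$gl <- 0
  consts <- hh_constants()
  # I_AR at V = -75: g * 0.5 * (V - VK)
  init <- hh_initial_single()
  init["v"] <- -75
  sim <- hh_simulate(p[1, ], duration_s = 0.001, dt = 0.001,
                     init = init, record_dt = 0.001,
                     fastforward = FALSE)
  # dV = -area10 * 0.5 * (-75 - (-100)) / c_m = -0.2*12.5/0.2 per ms
  dv <- (sim$v[2] - sim$v[1]) / 0.001
  expect_equal(dv, -0.2 * 0.5 * 25 / 0.2, tolerance = 1e-2)
})

test_that("a leak-only neuron rests at the leak reversal", {
  p <- sample_hh_params(1, seed = 2)
  p[1, c("gna", "gk", "ga", "gks", "gca", "gkca", "gnap", "gar",
         "gampa", "gnmda", "ggaba")] <- 0
  p$gl <- 0.1
  sim <- hh_simulate(p[1, ], duration_s = 1, dt = 0.01,
                     fastforward = FALSE)
  expect_true(sim$ok)
  expect_equal(unname(sim$final_state[1]), hh_constants()$v_l,
               tolerance = 1e-3)
})

test_that("RK4 trajectory matches a fine-step reference", {
  # subthreshold variant of a searched set (fast Na removed): pointwise
  # comparison stays meaningful over a full second
  sw <- local_swo_set()
  sw$gna <- 0
  s1 <- hh_simulate(sw, duration_s = 1, dt = 0.025, record_dt = 1,
                    analysis_start_s = 0, fastforward = FALSE)
  s2 <- hh_simulate(sw, duration_s = 1, dt = 0.0025, record_dt = 1,
                    analysis_start_s = 0, fastforward = FALSE)
  expect_lt(max(abs(s1$v - s2$v)), 0.5)
  # with spikes, the spike count of the window agrees at both steps
  sp1 <- hh_simulate(local_swo_set(), duration_s = 2, dt = 0.025,
                     analysis_start_s = 1, fastforward = FALSE)
  sp2 <- hh_simulate(local_swo_set(), duration_s = 2, dt = 0.0125,
                     analysis_start_s = 1, fastforward = FALSE)
  expect_lt(abs(sp1$spike_rate - sp2$spike_rate),
            0.2 * max(sp1$spike_rate, 1))
})

test_that("spike detection counts threshold crossings", {
  dt <- 1
  expect_equal(detect_spikes(rep(-65, 1000), dt)$count, 0)
  # one clean action potential: 2 crossings -> 1 spike
  v <- rep(-65, 100); v[50:52] <- c(10, 30, -30)
  d <- detect_spikes(v, dt)
  expect_equal(d$count, 1)
  # sine around -20 mV with k periods -> k spikes
  k <- 7
  t <- seq(0, k, length.out = 7000)
  vs <- -20 + 30 * sin(2 * pi * t)
  expect_equal(detect_spikes(vs, dt)$count, k, tolerance = 0.51)
})

test_that("pattern classification follows the printed decision rules", {
  # silent trace
  expect_equal(classify_pattern(rep(-65, 5000), dt = 1), "Resting")
  # synthetic 1 Hz burst train, 10 spikes per burst: SWO
  v <- rep(-70, 5000)
  for (b in seq(0, 4000, by = 1000))
    for (s in seq(0, 90, by = 10)) v[b + s + 1:3] <- c(20, 30, -40)
  expect_equal(classify_pattern(v, dt = 1), "SWO")
  # boundary: rate exactly 30 with peak >= 0.5 goes to SWO_high
  expect_equal(classify_pattern(spike_rate = 30, vmin = -80, vmax = 30,
                                peak_hz = 1), "SWO_high")
  expect_equal(classify_pattern(spike_rate = 29.9, vmin = -80, vmax = 30,
                                peak_hz = 1), "SWO")
  # tonic fast spiking: AWAKE family
  expect_equal(classify_pattern(spike_rate = 16, vmin = -80, vmax = 30,
                                peak_hz = 16), "AWAKE")
  expect_equal(classify_pattern(spike_rate = 40, vmin = -80, vmax = 30,
                                peak_hz = 40), "AWAKE_high")
  # amplitude guard and failed integrations
  expect_equal(classify_pattern(spike_rate = 10, vmin = -300, vmax = 0,
                                peak_hz = 1), "EXCLUDED")
  expect_equal(classify_pattern(spike_rate = 10, vmin = -80, vmax = 30,
                                peak_hz = 1, ok = FALSE), "EXCLUDED")
  # slow sparse firing below the Resting rate bound is Resting
  expect_equal(classify_pattern(spike_rate = 0.4, vmin = -80, vmax = -40,
                                peak_hz = 0.4), "Resting")
  # the printed Resting/SWO gap (rate above 0.6 /s but peak below
  # 0.5 Hz) falls through to EXCLUDED
  expect_equal(classify_pattern(spike_rate = 0.8, vmin = -80, vmax = 30,
                                peak_hz = 0.45), "EXCLUDED")
})

test_that("sleep score matches its closed forms and orders synchrony", {
  # uniform counts: score 0
  st <- seq(25, 9975, by = 50)
  expect_equal(sleep_score(st, 10000), 0)
  # all spikes in one of N windows: sqrt(N - 1)
  n_win <- 20
  st2 <- rep(10, 40)
  expect_equal(sleep_score(st2, n_win * 50), sqrt(n_win - 1))
  # no spikes: missing
  expect_true(is.na(sleep_score(numeric(0), 1000)))
  # synchronized bursts score higher than desynchronized trains
  set.seed(4)
  desync <- lapply(1:20, function(i) sort(runif(40, 0, 5000)))
  sync <- lapply(1:20, function(i)
    unlist(lapply(seq(0, 4500, by = 500), function(b) b + runif(4, 0, 60))))
  expect_gt(sleep_score(sync, 5000), sleep_score(desync, 5000))
})

test_that("null threshold behaves like a quantile", {
  thr <- null_threshold(n_neurons = 20, duration_s = 2.5, reps = 300,
                        seed = 5)
  expect_gt(thr, 0)
  expect_true(all(attr(thr, "ci") > 0))
  # determinism
  thr2 <- null_threshold(n_neurons = 20, duration_s = 2.5, reps = 300,
                         seed = 5)
  expect_equal(as.numeric(thr), as.numeric(thr2))
  # p = 0.5 returns the ensemble median
  thr_med <- null_threshold(n_neurons = 20, duration_s = 2.5, reps = 300,
                            p = 0.5, seed = 5)
  expect_lt(thr_med, thr)
  # longer windows average out fluctuations: threshold non-increasing
  thr_long <- null_threshold(n_neurons = 20, duration_s = 10, reps = 300,
                             seed = 5)
  expect_lte(thr_long, thr)
  expect_error(null_threshold(reps = 50), "reps")
})

test_that("sampled parameter sets respect the printed bounds", {
  p <- sample_hh_params(500, seed = 9)
  intr <- c("gl", "gna", "gk", "ga", "gks", "gca", "gkca", "gnap", "gar")
  for (g in intr)
    expect_true(all(p[[g]] >= 1e-2 & p[[g]] <= 1e2))
  for (g in c("gampa", "gnmda", "ggaba"))
    expect_true(all(p[[g]] >= 1e-3 & p[[g]] <= 1e1))
  expect_true(all(p$tau_ca >= 1e1 & p$tau_ca <= 1e3))
})

test_that("a reduced search classifies and finds slow-wave sets", {
  sw <- search_swo(120, seed = 8)
  expect_true(all(sw$label %in% c("Resting", "SWO", "SWO_high", "AWAKE",
                                  "AWAKE_high", "EXCLUDED")))
  expect_gt(sum(sw$label == "Resting"), 0)
})

test_that("bifurcation grids have the printed endpoints and step counts", {
  g1 <- bifurcation_grid("single", "gnmda")
  expect_length(g1, 100)
  expect_equal(range(g1), c(1e-2, 1e2))
  g1p <- bifurcation_grid("single", "presyn")
  expect_length(g1p, 100)
  expect_equal(range(g1p), c(1e-2, 1e1))
  expect_length(bifurcation_grid("network1", "gnmda"), 17)
  expect_length(bifurcation_grid("network1", "presyn"), 16)
  g2 <- bifurcation_grid("network2", "gnmda")
  expect_length(g2, 36)
  expect_equal(max(g2), 10^1.5)
  g2p <- bifurcation_grid("network2", "presyn")
  expect_length(g2p, 29)
  expect_equal(max(g2p), 10^0.8)
  # log-uniform spacing
  expect_equal(stats::sd(diff(log10(g1))), 0, tolerance = 1e-12)
})

test_that("the single-neuron acceptance rule needs a hyperpolarized SWO side", {
  sweep <- data.frame(
    multiplier = 1:4,
    label = c("AWAKE", "AWAKE", "SWO", "SWO"),
    vmin = c(-60, -60, -70, -70))
  expect_true(single_bifurcation_accepted(sweep))
  # SWO side not hyperpolarized enough: rejected
  sweep$vmin <- c(-60, -60, -63, -63)
  expect_false(single_bifurcation_accepted(sweep))
  # no adjacent transition: rejected
  sweep2 <- data.frame(multiplier = 1:3,
                       label = c("AWAKE", "EXCLUDED", "SWO"),
                       vmin = c(-60, -100, -75))
  expect_false(single_bifurcation_accepted(sweep2))
})

test_that("network acceptance rules and pair matching are enforced", {
  sweep <- data.frame(
    multiplier = c(0.1, 0.3, 1, 3),
    sleep_score = c(0.5, 0.9, 1.35, 1.6),
    pct_sleep = c(5, 10, 50, 70),
    pct_wake = c(70, 40, 5, 0),
    mean_rate = c(6.1, 5.0, 4.6, 1.0),
    ok = TRUE)
  acc <- network_step_acceptance(sweep)
  expect_equal(acc$wake_ok, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(acc$sleep_ok, c(FALSE, FALSE, TRUE, TRUE))
  pair <- select_matched_pair(acc)
  expect_true(pair$found)
  expect_lt(pair$rate_diff, 2)
  expect_equal(pair$wake_multiplier, 0.3)
  expect_equal(pair$sleep_multiplier, 1)
  # boundary: exactly 2 Hz apart is rejected
  sweep$mean_rate <- c(8, 7, 5, 1)
  pair2 <- select_matched_pair(network_step_acceptance(sweep))
  expect_false(pair2$found)
})

test_that("neurons decouple when synaptic conductances vanish", {
  sw <- local_swo_set()
  p <- sw
  p[c("gampa", "gnmda", "ggaba")] <- 0
  net <- build_hh_network(n_neurons = 3, ei_ratio = 2 / 3, seed = 2)
  init <- hh_network_init(3, seed = 5)
  run <- hh_network_run(p, net, phases = data.frame(duration_s = 0.5,
                                                    multiplier = 1),
                        dt = 0.025, record_dt = 1, init = init)
  for (i in 1:3) {
    ini <- hh_initial_single()
    ini[] <- init[i, ]
    single <- hh_simulate(p, duration_s = 0.5, dt = 0.025, record_dt = 1,
                          init = ini, analysis_start_s = 0,
                          fastforward = FALSE)
    expect_lt(max(abs(run$v[, i] - single$v[seq_len(nrow(run$v))])), 1e-6)
  }
})

test_that("gating variables stay in range during a network run", {
  sw <- local_swo_set()
  net <- build_hh_network(n_neurons = 10, seed = 3)
  run <- hh_network_run(sw, net, phases = data.frame(duration_s = 1,
                                                     multiplier = 1),
                        dt = 0.025, seed = 4)
  expect_true(run$ok)
  expect_true(all(is.finite(run$v)))
})
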