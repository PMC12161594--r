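test_that("kinase relaxes to the sigmoid fixed point", {
  # with no auto-activation, inhibition, input or noise: R_inf(0) = 0.5
  p <- kinase_params("oscillatory", w = 0, b = 0, i0 = 0, alpha = 0,
                     theta = 0, epsilon = 0)
  st <- list(r = 0.9, a = 0.5, xi = 0)
  for (i in 1:400) st <- step_kinase(st, 0, p, dt = 1000)
  expect_equal(st$r, 0.5, tolerance = 1e-6)
  # stronger inhibition by a lowers the r fixed point monotonically
  fp <- vapply(c(0, 2, 4), function(b) {
    pb <- kinase_params("oscillatory", b = b, theta = 0, epsilon = 0,
                        w = 0, i0 = 0, alpha = 0)
    s <- list(r = 0.5, a = 1, xi = 0)
    for (i in 1:400) s <- step_kinase(s, 0, pb, dt = 1000)
    s$r
  }, 0)
  expect_true(all(diff(fp) < 0))
})

test_that("OU noise recovers its stationary SD and time scale", {
  p <- kinase_params("oscillatory")
  k <- simulate_kinase(p, duration_s = 40000, dt = 100, ca = 0, seed = 2)
  xi <- k$xi[-seq_len(100)]
  n_eff <- length(xi) * p$theta * 100  # ~ independent samples
  se <- p$epsilon / sqrt(2 * n_eff)
  expect_lt(abs(stats::sd(xi) - p$epsilon), 3 * se + 0.01)
  # autocorrelation time ~ 1/theta: correlation at one e-folding ~ 1/e
  lag <- round(1 / (p$theta * 100))
  ac <- stats::cor(xi[-seq_len(lag)], xi[seq_len(length(xi) - lag)])
  expect_lt(abs(ac - exp(-1)), 0.1)
})

test_that("conductance coupling is multiplicative in the chosen variable", {
  p <- kinase_params("oscillatory", max_rate = 2)
  st <- list(r = 0.3, a = 0)
  expect_equal(couple_conductance(st, 5, p), 0)  # couples to a by default
  st$a <- 0.25
  expect_equal(couple_conductance(st, 5, p), 5 * 2 * 0.25)
  expect_equal(couple_conductance(st, 10, p), 2 * couple_conductance(st, 5, p))
  p$couple <- "r"
  expect_equal(couple_conductance(st, 5, p), 5 * 2 * 0.3)
})

test_that("the presynaptic calcium proxy has the right sign and scaling", {
  consts <- hh_constants()
  expect_equal(presyn_calcium(consts$v_ca), 0)
  v <- seq(-80, 0, by = 10)
  expect_true(all(presyn_calcium(v) >= 0))
  expect_equal(presyn_calcium(-40, beta_vgcc = 2),
               2 * presyn_calcium(-40, beta_vgcc = 1))
})

test_that("Process S follows its exact exponential updates", {
  # one wake step from S0
  s <- process_s("wake", dt = 7, ua = 1, la = 0, tau_i = 60, tau_d = 30,
                 s0 = 0.3)
  expect_equal(s[2], 1 - (1 - 0.3) * exp(-7 / 60))
  # monotone saturation toward the asymptotes
  sw <- process_s(rep("wake", 400), dt = 10, s0 = 0.1)
  expect_true(all(diff(sw) >= 0) && sw[2] > sw[1])
  expect_equal(sw[length(sw)], 1, tolerance = 1e-3)
  ss <- process_s(rep("sleep", 400), dt = 10, s0 = 0.9)
  expect_true(all(diff(ss) <= 0) && ss[2] < ss[1])
  expect_equal(ss[length(ss)], 0, tolerance = 1e-3)
  expect_true(all(ss >= 0 & ss <= 1))
  expect_error(process_s("wake", 1, ua = 0, la = 1), "exceed")
})

test_that("period classification thresholds smoothed sleep scores", {
  # constructed population spiking: synchronized bursts then tonic
  sync <- lapply(1:10, function(i)
    unlist(lapply(seq(0, 29500, by = 500), function(b) b + runif(3, 0, 50))))
  per <- classify_periods(sync, 30000, threshold = 1.0,
                          window_ms = 5000, step_ms = 500, smooth = 10)
  expect_true(all(per$state == "sleep"))
  set.seed(1)
  desync <- lapply(1:10, function(i) sort(runif(180, 0, 30000)))
  per2 <- classify_periods(desync, 30000, threshold = 1.0,
                           window_ms = 5000, step_ms = 500, smooth = 10)
  expect_true(all(per2$state == "wake"))
  expect_error(classify_periods(desync, 6000, 1.0), "smoothing")
})

test_that("model selection enforces the half-open balance band", {
  mk <- function(nsleep, nwake, corr_noise = 0.01) {
    st <- c(rep("sleep", nsleep), rep("wake", nwake))
    s <- seq_along(st) / length(st)
    r <- s + rnorm(length(s), 0, corr_noise)
    list(periods = data.frame(state = st), r = r, a = r, s = s)
  }
  set.seed(3)
  runs <- list(mk(70, 100), mk(130, 100), mk(100, 100), mk(129, 100))
  sel <- select_dynamics_models(runs)
  # balance exactly 0.7 accepted, exactly 1.3 rejected
  expect_true(1 %in% sel$run)
  expect_false(2 %in% sel$run)
  expect_true(all(c(3, 4) %in% sel$run))
  # ranked by correlation, highest first
  expect_true(!is.unsorted(rev(sel$correlation)))
  # constant traces are excluded with a diagnostic
  runs2 <- list(mk(100, 100))
  runs2[[1]]$r <- rep(0.5, length(runs2[[1]]$r))
  sel2 <- select_dynamics_models(runs2)
  expect_equal(nrow(sel2), 0)
  expect_match(attr(sel2, "diagnostics")[[1]], "constant")
})

test_that("the bistable regime does not alternate without noise", {
  p <- kinase_params("bistable", theta = 0, epsilon = 0)
  lo <- simulate_kinase(p, 1000, dt = 200, ca = 0.5, r0 = 0.05, a0 = 0.05)
  hi <- simulate_kinase(p, 1000, dt = 200, ca = 0.5, r0 = 0.95, a0 = 0.9)
  expect_true(all(lo$r < 0.5))
  expect_true(all(hi$r[-1] > 0.5))
  # the oscillatory preset alternates even without noise
  po <- kinase_params("oscillatory", theta = 0, epsilon = 0)
  osc <- simulate_kinase(po, 1000, dt = 200, ca = 0.5, r0 = 0.1, a0 = 0.1)
  expect_gt(sum(abs(diff(osc$r > 0.5))), 2)
})

test_that("phosphorylation is higher at sleep onsets than at wake onsets", {
  # in the oscillatory regime a(t) drives the slow-wave state, so
  # a-upcrossings mark sleep onsets; r (the sleep-need-like first state)
  # must be high there and low at wake onsets
  p <- kinase_params("oscillatory", theta = 0, epsilon = 0)
  o <- simulate_kinase(p, 2000, dt = 200, ca = 0.5, r0 = 0.1, a0 = 0.1)
  up <- which(diff(o$a > 0.5) == 1)
  down <- which(diff(o$a > 0.5) == -1)
  expect_gt(length(up), 1)
  expect_gt(mean(o$r[up]), mean(o$r[down]))
})

test_that("kinase coupling drives the network across its bifurcation", {
  # the conductance modulation sweeps gNMDA between the wake-like and
  # sleep-like multipliers as a moves over its range
  p <- kinase_params("oscillatory", max_rate = 2)
  g <- vapply(seq(0, 1, by = 0.25), function(a)
    couple_conductance(list(r = 0, a = a), 1, p), 0)
  expect_equal(g, seq(0, 2, by = 0.5))
})
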