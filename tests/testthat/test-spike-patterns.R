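test_that("mean-SD regressions evaluate to their closed forms", {
  expect_equal(sd_from_mean("up", 2.0), 0.0)
  expect_equal(sd_from_mean("down", 3.0), 0.40)
  expect_equal(sd_from_mean("isi_wake", 2.0), 0.71)
  expect_equal(sd_from_mean("isi_sleep_up", 2.0), 0.55)
  expect_error(sd_from_mean("bogus", 2), "arg")
  expect_error(sd_from_mean("up", NA), "finite")
})

test_that("down-state mean follows the up-state regression", {
  expect_equal(downm_from_upm(2.0), 2.6)
  expect_equal(downm_from_upm(4.0), 1.2)
  u <- seq(1, 4, by = 0.25)
  expect_equal(diff(downm_from_upm(u)) / diff(u), rep(-0.7, length(u) - 1))
  # used as the default when a sleep spec omits downm
  sp <- pattern_spec("sleep", 10, isim = 1.5, upm = 2.0)
  expect_equal(sp$downm, 2.6)
})

test_that("wake trains recover their log10-ISI location", {
  spec <- pattern_spec("wake", duration_s = 4500, isim = 2.0)
  pat <- sample_wake_train(spec, seed = 1)
  isi <- diff(pat$spikes)
  n <- length(isi)
  expect_gt(n, 1e4)
  m <- mean(log10(isi))
  se <- stats::sd(log10(isi)) / sqrt(n)
  expect_lt(abs(m - 2.0), 3 * se)
  # determinism
  pat2 <- sample_wake_train(spec, seed = 1)
  expect_identical(pat$spikes, pat2$spikes)
  expect_error(pattern_spec("wake", 0, isim = 2), "duration_s")
})

test_that("sleep trains keep spikes inside shared Up intervals", {
  spec <- pattern_spec("sleep", duration_s = 600, isim = 1.5, upm = 2.7,
                       downm = 3.0)
  pat <- sample_sleep_train(spec, seed = 3)
  expect_gt(nrow(pat$up_intervals), 2)
  inside <- findInterval(pat$spikes,
                         as.vector(t(pat$up_intervals))) %% 2 == 1
  expect_true(all(inside))
  # shared skeleton in multi-neuron patterns
  pats <- generate_pattern(spec, 4, seed = 9)
  expect_identical(pats[[1]]$up_intervals, pats[[2]]$up_intervals)
  expect_false(identical(pats[[1]]$spikes, pats[[2]]$spikes))
  # determinism
  expect_identical(sample_sleep_train(spec, seed = 3)$spikes, pat$spikes)
})

test_that("long-run Up-time fraction matches the renewal expectation", {
  spec <- pattern_spec("sleep", duration_s = 5000, isim = 1.5, upm = 2.7,
                       downm = 3.0)
  s_up <- sd_from_mean("up", 2.7)
  s_down <- sd_from_mean("down", 3.0)
  e_up <- exp(2.7 * log(10) + (s_up * log(10))^2 / 2)
  e_down <- exp(3.0 * log(10) + (s_down * log(10))^2 / 2)
  expected <- e_up / (e_up + e_down)
  fr <- replicate(8, {
    pat <- sample_sleep_train(spec)
    sum(pat$up_intervals[, 2] - pat$up_intervals[, 1]) / pat$duration_ms
  })
  se <- stats::sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - expected), max(3 * se, 0.02))
})

test_that("rate matching converges, is monotone and idempotent", {
  spec <- pattern_spec("sleep", 360, isim = 1.5, upm = 2.7, downm = 3.5)
  m <- match_rate(spec, 1, "downm")
  r <- evaluate_spec_rate(m, duration_s = 1500)
  expect_lt(abs(r - 1), 0.02)
  # monotonicity: larger downm, lower rate
  lo <- m; lo$downm <- m$downm - 0.5
  hi <- m; hi$downm <- m$downm + 0.5
  expect_gt(evaluate_spec_rate(lo), evaluate_spec_rate(hi))
  # idempotence: re-matching moves the knob negligibly
  m2 <- match_rate(m, 1, "downm")
  expect_lt(abs(m2$downm - m$downm), 0.02)
  # matched wake/sleep pair agrees in rate
  w <- match_rate(pattern_spec("wake", 360, isim = 2.4), 1, "isim")
  expect_lt(abs(attr(w, "achieved_rate") - attr(m, "achieved_rate")),
            0.02 * 1)
  expect_error(match_rate(pattern_spec("wake", 10, isim = 2), 1e6,
                          "isim"), "bracket")
})

test_that("matched sleep trains fire faster within Up states than wake", {
  ss <- match_rate(pattern_spec("sleep", 600, isim = 1.5, upm = 2.7,
                                downm = 3.5), 1, "downm")
  ws <- match_rate(pattern_spec("wake", 600, isim = 2.4), 1, "isim")
  sp <- sample_sleep_train(ss, seed = 2)
  wp <- sample_wake_train(ws, seed = 2)
  up_time <- sum(sp$up_intervals[, 2] - sp$up_intervals[, 1])
  rate_in_up <- length(sp$spikes) / (up_time / 1000)
  expect_gt(rate_in_up, 2 * wp$mean_rate)
})

test_that("waveforms anchor peaks at the timestamps and keep state offsets", {
  wf <- waveform_params()
  dt <- 0.05
  pat <- sleepsyn:::new_spike_pattern(c(100, 104, 300),
                                      matrix(c(80, 320), ncol = 2), 500)
  v <- spikes_to_voltage(pat, wf, dt)
  idx <- round(c(100, 104, 300) / dt) + 1
  expect_true(all(v[idx] == wf$v_peak))
  expect_true(all(v <= wf$v_peak))
  # Up plateau vs Down baseline differ by 15 mV by default
  expect_equal(v[round(200 / dt)], wf$v_down + 15)
  expect_equal(v[round(450 / dt)], wf$v_down)
  # empty train: flat baseline
  flat <- spikes_to_voltage(
    sleepsyn:::new_spike_pattern(numeric(0), matrix(numeric(0), ncol = 2),
                                 100), wf, dt)
  expect_true(all(flat == wf$v_down))
  # alternative Up-Down separations are supported
  v10 <- spikes_to_voltage(pat, waveform_params(up_down_diff = 10), dt)
  expect_equal(v10[round(200 / dt)], wf$v_down + 10)
})

test_that("zero-Down sleep spec with wake ISIs degenerates to the wake train", {
  ws <- pattern_spec("wake", 60, isim = 2.2)
  ss <- pattern_spec("sleep", 60, isim = 2.2, upm = 2.7, downm = -Inf,
                     isi_kind = "isi_wake")
  a <- sample_wake_train(ws, seed = 4)
  b <- sample_sleep_train(ss, seed = 4)
  expect_equal(a$spikes, b$spikes)
  expect_equal(b$up_intervals, matrix(c(0, 60000), ncol = 2))
})
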