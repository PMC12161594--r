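test_that("topologies have the specified structure", {
  t10 <- build_topology("fan_in_10")
  expect_equal(nrow(t10$edges), 10)
  expect_true(all(t10$edges$post == 11))
  t96 <- build_topology("fan_in_96")
  expect_equal(nrow(t96$edges), 96)
  # random wiring: no self-edges, edge count near 10 * 9 * 0.12
  counts <- vapply(1:2000, function(s) {
    tp <- build_topology("random_p12", seed = s)
    expect_true(all(tp$edges$pre != tp$edges$post))
    nrow(tp$edges)
  }, 0)
  expected <- 10 * 9 * 0.12
  se <- sqrt(90 * 0.12 * 0.88 / 2000)
  expect_lt(abs(mean(counts) - expected), 3 * se)
  # determinism
  expect_identical(build_topology("random_p12", seed = 42)$edges,
                   build_topology("random_p12", seed = 42)$edges)
})

test_that("identical state inputs give identical reports", {
  rules <- utils::head(cached_rules("STDP"), 4)
  spec <- pattern_spec("wake", 30, isim = 2.4)
  cfg <- experiment_config(rules, spec, spec, duration_s = 30,
                           window_s = 10)
  rep <- run_state_comparison(cfg, build_topology("fan_in_10"), seed = 7)
  s <- rep[rep$state == "sleep", c("mean", "cv")]
  w <- rep[rep$state == "wake", c("mean", "cv")]
  expect_equal(s$mean, w$mean)
  expect_equal(s$cv, w$cv)
  # end-to-end seed determinism
  rep2 <- run_state_comparison(cfg, build_topology("fan_in_10"), seed = 7)
  expect_identical(rep, rep2)
})

test_that("unmatched state rates are rejected", {
  rules <- utils::head(cached_rules("STDP"), 2)
  ss <- pattern_spec("sleep", 30, isim = 1.5, upm = 2.7, downm = 4)
  ws <- pattern_spec("wake", 30, isim = 2.4)
  attr(ss, "achieved_rate") <- 1
  attr(ws, "achieved_rate") <- 2
  cfg <- experiment_config(rules, ss, ws)
  expect_error(run_state_comparison(cfg, build_topology("fan_in_10")),
               "not matched")
})

test_that("degenerate zero-Down sleep controls match wake statistically", {
  rules <- utils::head(cached_rules("STDP"), 8)
  ws <- pattern_spec("wake", 60, isim = 2.4)
  ss <- pattern_spec("sleep", 60, isim = 2.4, upm = 2.7, downm = -Inf,
                     isi_kind = "isi_wake")
  cfg <- experiment_config(rules, ss, ws, duration_s = 60, window_s = 30)
  rep <- run_state_comparison(cfg, build_topology("fan_in_10"), seed = 21)
  d <- rep$mean[rep$state == "sleep"] - rep$mean[rep$state == "wake"]
  # same generator modulo realization: paired t sees no systematic shift
  expect_gt(stats::t.test(d)$p.value, 0.01)
})

test_that("an empty rate grid yields an empty sweep table", {
  rules <- utils::head(cached_rules("STDP"), 2)
  cfg <- experiment_config(rules,
                           pattern_spec("sleep", 30, isim = 1.5,
                                        upm = 2.7, downm = 4),
                           pattern_spec("wake", 30, isim = 2.4))
  sw <- sweep_rates(cfg, numeric(0))
  expect_equal(nrow(sw), 0)
})

test_that("per-rate failures are recorded without aborting the sweep", {
  rules <- utils::head(cached_rules("STDP"), 2)
  cfg <- experiment_config(rules,
                           pattern_spec("sleep", 20, isim = 1.5,
                                        upm = 2.7, downm = 4),
                           pattern_spec("wake", 20, isim = 2.4),
                           duration_s = 20, window_s = 10)
  sw <- sweep_rates(cfg, c(1e6), seed = 1)  # unreachable rate
  expect_equal(nrow(sw), 0)
  expect_length(attr(sw, "failures"), 1)
})
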