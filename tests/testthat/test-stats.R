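test_that("identical groups straddle zero; separated groups do not", {
  set.seed(8)
  x <- rnorm(60, 0, 1)
  r <- bayes_diff_means(x, x + rnorm(60, 0, 1e-4), seed = 1)
  expect_false(r$excludes_zero)
  g1 <- rnorm(100, 1, 0.01)
  g2 <- rnorm(100, 0, 0.01)
  r2 <- bayes_diff_means(g1, g2, seed = 2)
  expect_true(r2$excludes_zero)
  expect_equal(r2$direction, 1L)
  expect_lt(r2$ci[1], r2$ci[2])
})

test_that("the posterior matches the conjugate-limit oracle", {
  set.seed(5)
  g1 <- rnorm(200, 0.3, 0.5)
  g2 <- rnorm(150, 0.1, 0.8)
  r <- bayes_diff_means(g1, g2, seed = 3)
  delta <- mean(g1) - mean(g2)
  se <- sqrt(stats::var(g1) / 200 + stats::var(g2) / 150)
  # posterior mean ~ sample difference; CI ~ normal-approximation CI
  expect_lt(abs(r$diff_mean - delta), 4 * se / sqrt(1000))
  expect_equal(unname(r$ci[1]), delta - 1.96 * se, tolerance = 0.05)
  expect_equal(unname(r$ci[2]), delta + 1.96 * se, tolerance = 0.05)
})

test_that("MCMC is reproducible and shrinks with sample size", {
  set.seed(9)
  g1 <- rnorm(40, 0.2); g2 <- rnorm(40)
  a <- bayes_diff_means(g1, g2, seed = 11)
  b <- bayes_diff_means(g1, g2, seed = 11)
  expect_identical(a$draws, b$draws)
  big1 <- rnorm(400, 0.2); big2 <- rnorm(400)
  wide <- diff(bayes_diff_means(g1, g2, seed = 1)$ci)
  narrow <- diff(bayes_diff_means(big1, big2, seed = 1)$ci)
  expect_lt(narrow, wide)
  expect_error(bayes_diff_means(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(bayes_diff_means(1, rnorm(5)))
})

test_that("t tests match closed forms and distinguish variants", {
  g1 <- c(5.1, 4.9, 5.3, 5.0, 5.2)
  g2 <- c(4.4, 4.7, 4.5, 4.6)
  r <- two_sample_t(g1, g2, "student")
  # hand-computed pooled-variance t
  sp2 <- (4 * stats::var(g1) + 3 * stats::var(g2)) / 7
  t_hand <- (mean(g1) - mean(g2)) / sqrt(sp2 * (1 / 5 + 1 / 4))
  expect_equal(r$statistic, t_hand)
  expect_equal(r$df, 7)
  # equal groups: t = 0, p = 1
  r0 <- two_sample_t(c(1, 2, 3), c(1, 2, 3), "student")
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # Welch dof differs from Student under unequal variances
  set.seed(2)
  a <- rnorm(10, 0, 0.1); b <- rnorm(30, 0, 3)
  expect_lt(two_sample_t(a, b, "welch")$df,
            two_sample_t(a, b, "student")$df)
  expect_error(two_sample_t(1, c(1, 2)), "two observations")
})

test_that("verdict strings derive from the interval, not the labels", {
  set.seed(3)
  rep <- data.frame(
    rule_id = rep(1:30, 2), rule_label = "STDP",
    state = rep(c("sleep", "wake"), each = 30),
    mean = c(rnorm(30, 0.7, 0.05), rnorm(30, 0.4, 0.05)),
    cv = 0.1)
  tab <- comparison_table(rep, method = "bayes_mcmc", seed = 4)
  expect_equal(tab$verdict, "WISE")
  rep$mean <- rev(rep$mean)
  tab2 <- comparison_table(rep, method = "bayes_mcmc", seed = 4)
  expect_equal(tab2$verdict, "SHY")
  rep$mean <- rnorm(60, 0.5, 0.05)
  tab3 <- comparison_table(rep, method = "student_t")
  expect_true(tab3$verdict %in% c("inconclusive", "WISE", "SHY"))
})
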