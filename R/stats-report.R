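#' Bayesian posterior of a difference in group means
#'
#' Independent normal models for the two groups with vague priors (normal
#' on each mean, inverse-gamma on each variance) sampled by a conjugate
#' Gibbs sampler; the reported quantity is the posterior of
#' `diff = mu_1 - mu_2` with its 95% credible interval.  A difference is
#' flagged when the interval excludes zero.
#'
#' @param group1,group2 Numeric vectors (n >= 2 each); in the sleep-wake
#'   comparisons group 1 is sleep.
#' @param draws Posterior draws kept (default 5000).
#' @param burn Burn-in iterations discarded (default 2000).
#' @param seed Optional integer seed.
#' @param prior_mean_sd Prior SD of the group means.
#' @param prior_a,prior_b Inverse-gamma shape/rate of the variances.
#' @return A `comparison_result` list: `diff_mean`, `ci` (2.5%, 97.5%),
#'   `excludes_zero`, `direction` (+1/-1/0), `n`, `method`, `draws`.
#' @export
bayes_diff_means <- function(group1, group2, draws = 5000, burn = 2000,
                             seed = NULL, prior_mean_sd = 1e3,
                             prior_a = 1e-3, prior_b = 1e-3) {
  stopifnot(length(group1) >= 2, length(group2) >= 2)
  if (stats::var(group1) == 0 || stats::var(group2) == 0)
    stop("degenerate model: a group has zero variance", call. = FALSE)
  with_seed(seed, {
    gibbs <- function(x) {
      n <- length(x)
      xbar <- mean(x)
      mu <- xbar
      s2 <- stats::var(x)
      tau0 <- prior_mean_sd^2
      out <- numeric(draws)
      for (i in seq_len(draws + burn)) {
        v_n <- 1 / (n / s2 + 1 / tau0)
        mu <- stats::rnorm(1, v_n * n * xbar / s2, sqrt(v_n))
        s2 <- 1 / stats::rgamma(1, prior_a + n / 2,
                                prior_b + sum((x - mu)^2) / 2)
        if (i > burn) out[i - burn] <- mu
      }
      out
    }
    d <- gibbs(group1) - gibbs(group2)
    ci <- unname(stats::quantile(d, c(0.025, 0.975)))
    structure(list(
      diff_mean = mean(d), ci = ci,
      excludes_zero = ci[1] > 0 || ci[2] < 0,
      direction = if (ci[1] > 0) 1L else if (ci[2] < 0) -1L else 0L,
      n = c(length(group1), length(group2)), method = "bayes_mcmc",
      draws = d), class = "comparison_result")
  })
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "<comparison_result> %s\n  diff = %.4g, 95%% CI [%.4g, %.4g]%s (n = %d / %d)\n",
    x$method, x$diff_mean, x$ci[1], x$ci[2],
    if (x$excludes_zero) " *" else "", x$n[1], x$n[2]))
  invisible(x)
}

#' Two-sample t test
#'
#' Student (pooled-variance) or Welch two-sided t test.
#'
#' @param group1,group2 Numeric vectors (n >= 2 each).
#' @param variant `"student"` or `"welch"`.
#' @return A `comparison_result` list with `statistic`, `p_value`, `df`.
#' @export
two_sample_t <- function(group1, group2, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(group1) < 2 || length(group2) < 2)
    stop("each group needs at least two observations", call. = FALSE)
  tt <- stats::t.test(group1, group2, var.equal = variant == "student")
  structure(list(
    statistic = unname(tt$statistic), p_value = tt$p.value,
    df = unname(tt$parameter), diff_mean = mean(group1) - mean(group2),
    ci = unname(tt$conf.int), excludes_zero = tt$p.value < 0.05,
    direction = sign(mean(group1) - mean(group2)),
    n = c(length(group1), length(group2)),
    method = paste0(variant, "_t")), class = "comparison_result")
}

#' State-comparison table with verdicts
#'
#' Applies [bayes_diff_means()] (or a t test) to the sleep and wake mean
#' efficacies of an efficacy report, per rule label, and derives the
#' verdict string from the interval: sleep above wake with the interval
#' excluding zero reads as WISE, the reverse as SHY, otherwise
#' inconclusive.
#'
#' @param report An `efficacy_report` (from [run_state_comparison()]).
#' @param method `"bayes_mcmc"`, `"student_t"` or `"welch_t"`.
#' @param seed Optional integer seed (MCMC only).
#' @return Data frame per rule label: difference, CI bounds, flag,
#'   verdict.
#' @export
comparison_table <- function(report, method = c("bayes_mcmc", "student_t",
                                                "welch_t"), seed = NULL) {
  method <- match.arg(method)
  rows <- lapply(split(report, report$rule_label), function(d) {
    g1 <- d$mean[d$state == "sleep"]
    g2 <- d$mean[d$state == "wake"]
    cr <- switch(method,
      bayes_mcmc = bayes_diff_means(g1, g2, seed = seed),
      student_t = two_sample_t(g1, g2, "student"),
      welch_t = two_sample_t(g1, g2, "welch"))
    verdict <- if (!cr$excludes_zero) "inconclusive" else
      if (cr$direction > 0) "WISE" else "SHY"
    data.frame(rule_label = d$rule_label[1], n = length(g1),
               diff = cr$diff_mean, ci_low = cr$ci[1], ci_high = cr$ci[2],
               excludes_zero = cr$excludes_zero, verdict = verdict,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
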