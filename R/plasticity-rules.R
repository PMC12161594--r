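#' Construct a synaptic learning-rule parameter set
#'
#' Bundles the eight free parameters of the two-threshold calcium-based
#' plasticity rule together with the calibrated Ca2+-source scaling factors
#' and the rule family label.
#'
#' @param theta_p Potentiation Ca2+ threshold (uM), > 0.
#' @param theta_d Depression Ca2+ threshold (uM), > 0.
#' @param gamma_p Potentiation amplitude (unitless), >= 0.
#' @param gamma_d Depression amplitude (unitless), >= 0.
#' @param tau_pre Decay time constant of NMDAR-sourced Ca2+ (ms), > 0.
#' @param tau_post Decay time constant of VGCC-sourced Ca2+ (ms), > 0.
#' @param sigma Noise amplitude (unitless), >= 0.
#' @param tau_s Efficacy time constant (ms), > 0.
#' @param rho_star Unstable fixed point of the cubic drift, in (0, 1).
#' @param z Noise coefficient; the value used throughout is 3.5.
#' @param beta_nmda,beta_vgcc Ca2+-source scaling factors (set by
#'   [calibrate_scaling()]).
#' @param rule_label One of `"Hebbian"`, `"STDP"`, `"AntiHebbian"`,
#'   `"AntiSTDP"`, or `NA` before classification.
#' @return An object of class `plasticity_rule` (a named list).
#' @export
plasticity_rule <- function(theta_p, theta_d, gamma_p, gamma_d,
                            tau_pre, tau_post, sigma, tau_s,
                            rho_star = 0.5, z = 3.5,
                            beta_nmda = 1, beta_vgcc = 1,
                            rule_label = NA_character_) {
  stopifnot(
    is.numeric(theta_p), theta_p > 0, is.numeric(theta_d), theta_d > 0,
    gamma_p >= 0, gamma_d >= 0, tau_pre > 0, tau_post > 0,
    sigma >= 0, tau_s > 0, rho_star > 0, rho_star < 1, z >= 0
  )
  if (!is.na(rule_label))
    rule_label <- match.arg(rule_label,
                            c("Hebbian", "STDP", "AntiHebbian", "AntiSTDP"))
  structure(
    list(theta_p = theta_p, theta_d = theta_d, gamma_p = gamma_p,
         gamma_d = gamma_d, tau_pre = tau_pre, tau_post = tau_post,
         sigma = sigma, tau_s = tau_s, rho_star = rho_star, z = z,
         beta_nmda = beta_nmda, beta_vgcc = beta_vgcc,
         rule_label = rule_label),
    class = "plasticity_rule"
  )
}

#' @export
print.plasticity_rule <- function(x, ...) {
  cat(sprintf(
    "<plasticity_rule> %s\n  theta_p=%.3f theta_d=%.3f gamma_p=%.1f gamma_d=%.1f\n  tau_pre=%.1f ms tau_post=%.1f ms sigma=%.3f tau_s=%.0f ms\n  beta_nmda=%.4g beta_vgcc=%.4g rho_star=%.2f z=%.1f\n",
    ifelse(is.na(x$rule_label), "(unclassified)", x$rule_label),
    x$theta_p, x$theta_d, x$gamma_p, x$gamma_d, x$tau_pre, x$tau_post,
    x$sigma, x$tau_s, x$beta_nmda, x$beta_vgcc, x$rho_star, x$z))
  invisible(x)
}

#' @export
as.data.frame.plasticity_rule <- function(x, ...) {
  as.data.frame(unclass(x), stringsAsFactors = FALSE)
}

rule_fields <- c("theta_p", "theta_d", "gamma_p", "gamma_d", "tau_pre",
                 "tau_post", "sigma", "tau_s", "rho_star", "z",
                 "beta_nmda", "beta_vgcc", "rule_label")

#' Sampling ranges for the learning-rule parameter search
#'
#' Uniform sampling boxes for the free rule parameters.  The Ca2+
#' thresholds live in two bands anchored to the calibrated transient
#' amplitudes (0.7 uM NMDAR, 1.4 uM VGCC): a high band [0.8, 1.6] uM for
#' the threshold that gates on coincident transients and a low band
#' [0.5, 1.0] uM for the one single transients can reach.  Hebbian/STDP
#' place the potentiation threshold in the high band (`theta_p > theta_d`),
#' the Anti rules mirror the bands; [search_rules()] additionally rejects
#' candidates violating the ordering.
#'
#' @param rule_label Rule family orienting the threshold bands.
#' @param hh Logical; the network-model search uses the same boxes.
#' @return Named list of `c(min, max)` ranges.
#' @export
default_rule_ranges <- function(rule_label = "STDP", hh = FALSE) {
  r <- list(
    theta_p  = c(0.8, 1.6),    # uM
    theta_d  = c(0.5, 1.0),    # uM
    gamma_p  = c(20, 400),
    gamma_d  = c(20, 400),
    sigma    = c(0.2, 1.0),
    tau_pre  = c(5, 60),       # ms
    tau_post = c(5, 60),       # ms
    tau_s    = c(3e4, 1.8e5)   # ms
  )
  if (!rule_label %in% c("STDP", "Hebbian")) {
    r$theta_p <- c(0.5, 1.0)
    r$theta_d <- c(0.8, 1.6)
  }
  r
}

sample_rule_params <- function(n, ranges = default_rule_ranges(),
                               rule_label = NA_character_) {
  draw <- function(rg) stats::runif(n, rg[1], rg[2])
  df <- data.frame(
    theta_p = draw(ranges$theta_p), theta_d = draw(ranges$theta_d),
    gamma_p = draw(ranges$gamma_p), gamma_d = draw(ranges$gamma_d),
    sigma = draw(ranges$sigma), tau_pre = draw(ranges$tau_pre),
    tau_post = draw(ranges$tau_post), tau_s = draw(ranges$tau_s),
    rho_star = 0.5, z = 3.5, beta_nmda = 1, beta_vgcc = 1,
    rule_label = rule_label, stringsAsFactors = FALSE
  )
  df
}

#' Write / read learning-rule parameter sets
#'
#' Flat CSV (one row per rule instance) or JSON; both round-trip all
#' fields, including the calibrated scaling factors.
#'
#' @param rules A data frame of rule parameters (as returned by
#'   [search_rules()]) or a single `plasticity_rule`.
#' @param path Output file; format chosen by extension (`.csv` or `.json`).
#' @return `read_rules()` returns a data frame; `write_rules()` its input,
#'   invisibly.
#' @export
write_rules <- function(rules, path) {
  if (inherits(rules, "plasticity_rule")) rules <- as.data.frame(rules)
  stopifnot(is.data.frame(rules))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(rules, path, digits = NA, auto_unbox = FALSE)
  } else {
    utils::write.csv(rules, path, row.names = FALSE)
  }
  invisible(rules)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  df
}

#' Coerce one row of a rules data frame into a `plasticity_rule`
#'
#' @param row A one-row data frame with the [plasticity_rule()] fields
#'   (as produced by [search_rules()] or [read_rules()]).
#' @return A `plasticity_rule`.
#' @export
as_plasticity_rule <- function(row) {
  plasticity_rule(
    theta_p = row$theta_p, theta_d = row$theta_d, gamma_p = row$gamma_p,
    gamma_d = row$gamma_d, tau_pre = row$tau_pre, tau_post = row$tau_post,
    sigma = row$sigma, tau_s = row$tau_s, rho_star = row$rho_star,
    z = row$z, beta_nmda = row$beta_nmda, beta_vgcc = row$beta_vgcc,
    rule_label = if (is.null(row$rule_label)) NA_character_ else row$rule_label
  )
}

rule_from_row <- as_plasticity_rule
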