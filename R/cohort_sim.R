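# Synthetic cohorts for calibration and power studies.  Defaults encode
# the reference cohort: 519 patients followed up to 670 days with ~6.9%
# all-cause mortality, NATV mean 660 cc (SD 266) correlated with BMI at
# rho ~ 0.66, AWV mean 23.6 cc (SD 8.1), median age ~61.

#' Simulate a cohort table
#'
#' Generates per-patient covariates and right-censored survival with an
#' optional planted hazard ratio for the NATV:AWV upper quartile.  Death
#' times are exponential with baseline rate chosen in closed form so the
#' expected null mortality matches `mortality` by the end of follow-up;
#' censoring is administrative at a per-patient uniform time between
#' `followup_range` days (staggered entry, maximum 670).
#'
#' @param n cohort size (default 519).
#' @param upper_quartile_hr hazard ratio planted on upper-quartile
#'   membership (1 = null).
#' @param mortality expected null death fraction by end of follow-up
#'   (default 0.069, i.e. 35/509 deaths at cohort scale).
#' @param followup_range administrative censoring window in days
#'   (default `c(300, 670)`).
#' @param seed integer seed; the table is reproducible given the seed.
#' @return a data.frame in the cohort schema of [run_cohort_analysis()].
#' @export
simulate_cohort <- function(n = 519, upper_quartile_hr = 1,
                            mortality = 0.069,
                            followup_range = c(300, 670), seed = 1L) {
  nc_assert(n >= 8 && upper_quartile_hr > 0 && mortality > 0 &&
              mortality < 1, "invalid simulation parameters")
  with_seed(seed, {
    age <- pmin(pmax(rnorm(n, 61, 14), 18), 95)
    sex <- ifelse(runif(n) < 0.55, "male", "female")
    bmi <- pmin(pmax(rnorm(n, 27, 4.5), 16), 45)
    # NATV regressed on BMI to give r ~ 0.66 at SD 266 around mean 660
    natv <- pmax(60, -390 + 38.9 * bmi + rnorm(n, 0, 200))
    awv <- pmax(5, rnorm(n, 23.6, 8.1))
    ratio <- natv / awv
    upper <- ratio >= quantile(ratio, 0.75, type = 7)

    cens <- runif(n, followup_range[1], followup_range[2])
    mean_cens <- mean(followup_range)
    lambda0 <- -log(1 - mortality) / mean_cens
    tdeath <- rexp(n, rate = lambda0 *
                     ifelse(upper, upper_quartile_hr, 1))
    died <- as.integer(tdeath <= cens)
    data.frame(
      patient_id = sprintf("P%04d", seq_len(n)),
      age = age, sex = sex, bmi = bmi,
      natv_cc = natv, awv_cc = awv, ratio = ratio,
      followup_days = pmin(tdeath, cens), died = died,
      stringsAsFactors = FALSE)
  })
}

#' Simulate observer pairs with a fixed bias
#'
#' Second-observer values differ from the first by
#' `d ~ Normal(bias, diff_sd)`, emulating interobserver remeasurement of
#' the same scans (reference scale: NATV mean difference 4.17 cc,
#' SD 13.35 cc, over measurements of SD ~266 cc, giving ICC near 0.999).
#'
#' @param true_values first-observer measurements (cc).
#' @param bias mean difference obs1 - obs2 (default 4.17 cc).
#' @param diff_sd SD of the difference (default 13.35 cc).
#' @param seed integer seed.
#' @return an [observer_pairs()].
#' @export
simulate_observer_pairs <- function(true_values, bias = 4.17,
                                    diff_sd = 13.35, seed = 1L) {
  nc_assert(length(true_values) >= 2 && all(is.finite(true_values)),
            "need >= 2 finite values")
  with_seed(seed, {
    d <- rnorm(length(true_values), bias, diff_sd)
    observer_pairs(seq_along(true_values), true_values, true_values - d)
  })
}

#' Simulate survival data with a known log hazard ratio
#'
#' Exponential event times with hazard `exp(beta * x)` for a binary
#' (probability 0.5) or standard-normal covariate, administratively
#' censored at the time `tau` that yields the requested expected event
#' fraction (solved from the exponential model, not tuned).
#'
#' @param n sample size.
#' @param beta true log hazard ratio per covariate unit.
#' @param event_frac expected fraction of subjects with an event.
#' @param covariate `"binary"` (default) or `"normal"`.
#' @param seed integer seed.
#' @return a data.frame with columns `time`, `event`, `x`.
#' @export
simulate_survival_data <- function(n, beta = 0.7, event_frac = 0.4,
                                   covariate = c("binary", "normal"),
                                   seed = 1L) {
  nc_assert(event_frac > 0 && event_frac < 1, "event_frac in (0, 1)")
  covariate <- match.arg(covariate)
  # solve E_x[1 - exp(-e^(beta x) tau)] = event_frac for tau
  expected <- if (covariate == "binary") {
    function(tau) 0.5 * (1 - exp(-tau)) +
      0.5 * (1 - exp(-exp(beta) * tau))
  } else {
    function(tau) stats::integrate(function(z)
      stats::dnorm(z) * (1 - exp(-exp(beta * z) * tau)),
      -8, 8)$value
  }
  tau <- uniroot(function(tau) expected(tau) - event_frac,
                 c(1e-8, 200))$root
  with_seed(seed, {
    x <- if (covariate == "binary") rbinom(n, 1, 0.5) else rnorm(n)
    t0 <- rexp(n, rate = exp(beta * x))
    data.frame(time = pmin(t0, tau), event = as.integer(t0 <= tau), x = x)
  })
}
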