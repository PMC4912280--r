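# Cohort statistics: interobserver agreement (ICC for absolute agreement,
# Bland-Altman limits), Spearman correlation, BMI categorization and
# nonparametric group comparison, quartile stratification, Kaplan-Meier /
# log-rank survival, univariate Cox regression, and ICC sample-size
# planning.  Survival machinery is delegated to the `survival` package;
# the agreement statistics are computed from first principles (no ICC
# implementation exists in the installed stack).

#' Observer pair set
#'
#' Per-subject measurements by two independent observers of the same
#' quantity (cc), the substrate of the agreement analysis.
#'
#' @param subject_id identifiers.
#' @param obs1,obs2 finite numeric measurements, one pair per subject.
#' @return a data.frame of class `observer_pairs`.
#' @export
observer_pairs <- function(subject_id, obs1, obs2) {
  nc_assert(length(obs1) == length(obs2) &&
              length(subject_id) == length(obs1),
            "subject_id, obs1, obs2 must have equal length")
  nc_assert(all(is.finite(obs1)) && all(is.finite(obs2)),
            "observer values must be finite")
  structure(data.frame(subject_id = subject_id, obs1 = obs1, obs2 = obs2,
                       stringsAsFactors = FALSE),
            class = c("observer_pairs", "data.frame"))
}

#' Intraclass correlation for absolute agreement, ICC(A,1)
#'
#' Two-way random effects, absolute agreement, single measures
#' (McGraw-Wong ICC(A,1)): from the two-way ANOVA mean squares with
#' k = 2 raters,
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`,
#' with the F-based 95% confidence interval.  A table with zero variance
#' everywhere (all values identical) is degenerate; by convention it
#' reports ICC = 1 with a warning.
#'
#' @param pairs an [observer_pairs()] with n >= 3 subjects.
#' @param conf_level confidence level (default 0.95).
#' @return a list with `icc`, `icc_ci` (length 2), `p` (F test of the
#'   subject effect), `n`, `k`.
#' @export
icc_absolute_agreement <- function(pairs, conf_level = 0.95) {
  x <- as.matrix(pairs[, c("obs1", "obs2")])
  n <- nrow(x); k <- 2L
  if (n < 3) nc_stop("ICC needs at least 3 subjects", "neckct_sample_error")
  gm <- mean(x)
  rowm <- rowMeans(x)
  colm <- colMeans(x)
  msr <- k * sum((rowm - gm)^2) / (n - 1)
  msc <- n * sum((colm - gm)^2) / (k - 1)
  sse <- sum((x - outer(rowm, rep(1, k)) -
                outer(rep(1, n), colm) + gm)^2)
  mse <- sse / ((n - 1) * (k - 1))

  if (msr == 0 && mse == 0 && msc == 0) {
    warning("all values identical across subjects and raters; ICC = 1 by convention")
    return(list(icc = 1, icc_ci = c(1, 1), p = NA_real_, n = n, k = k))
  }

  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  alpha <- 1 - conf_level

  if (mse == 0 && msc == 0) {         # perfect agreement, subject variance > 0
    return(list(icc = 1, icc_ci = c(1, 1), p = 0, n = n, k = k))
  }

  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fl <- qf(1 - alpha / 2, n - 1, v)
  fu <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  p <- pf(msr / mse, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  list(icc = icc, icc_ci = c(lower, upper), p = p, n = n, k = k)
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = obs1 - obs2`: bias (mean difference), its SD, the 95%
#' limits of agreement `bias +/- 1.96 sd(d)`, a one-sample t test of the
#' fixed bias against zero, and the percent discrepancy
#' `100 |bias| / grand mean`.  With zero-variance differences the t test
#' is undefined; by convention p = 1 when the bias is exactly 0 and p = 0
#' otherwise.
#'
#' @param pairs an [observer_pairs()] with n >= 2 subjects.
#' @return a list with `bias`, `bias_sd`, `loa` (length 2),
#'   `fixed_bias_p`, `pct_discrepancy`, `n`.
#' @export
bland_altman <- function(pairs) {
  d <- pairs$obs1 - pairs$obs2
  n <- length(d)
  if (n < 2) nc_stop("Bland-Altman needs at least 2 subjects",
                     "neckct_sample_error")
  bias <- mean(d)
  s <- sd(d)
  loa <- bias + c(-1, 1) * 1.96 * s
  p <- if (s > 0) {
    tstat <- bias / (s / sqrt(n))
    2 * pt(-abs(tstat), n - 1)
  } else if (bias == 0) 1 else 0
  gm <- mean(c(pairs$obs1, pairs$obs2))
  list(bias = bias, bias_sd = s, loa = loa, fixed_bias_p = p,
       pct_discrepancy = if (gm != 0) 100 * abs(bias) / gm else NA_real_,
       n = n)
}

#' Spearman rank correlation
#'
#' Rank correlation with midranks for ties and the large-sample t
#' approximation for the p-value.
#'
#' @param x,y equal-length numeric vectors, n >= 3.
#' @return a list with `rho`, `p`, `n`.
#' @export
spearman_rho <- function(x, y) {
  nc_assert(length(x) == length(y), "x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) nc_stop("Spearman needs at least 3 complete pairs",
                     "neckct_sample_error")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    nc_stop("zero rank variance: correlation undefined",
            "neckct_degenerate_error")
  rho <- cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tstat), n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' WHO BMI categorization
#'
#' Cutoffs 25 and 30 with right-open intervals: BMI < 25 is normal or
#' underweight, 25 <= BMI < 30 overweight, BMI >= 30 obese.
#'
#' @param bmi numeric vector of BMI values (kg/m^2, > 0).
#' @return factor with levels `normal_or_under`, `overweight`, `obese`.
#' @export
bmi_category <- function(bmi) {
  nc_assert(is.numeric(bmi) && all(is.finite(bmi)) && all(bmi > 0),
            "BMI values must be positive and finite")
  cut(bmi, breaks = c(0, 25, 30, Inf), right = FALSE,
      labels = c("normal_or_under", "overweight", "obese"))
}

#' Nonparametric group comparison
#'
#' Mann-Whitney U for two groups (exact p without ties and small samples,
#' otherwise the tie-corrected normal approximation without continuity
#' correction), Kruskal-Wallis for three or more.
#'
#' @param values numeric outcome.
#' @param groups factor/character of group membership (>= 2 non-empty
#'   groups).
#' @return a list with `method` (`"mann_whitney"` or `"kruskal_wallis"`),
#'   `statistic` (U of the first group, or the tie-corrected H), `p`, and
#'   for Mann-Whitney `exact` (logical).
#' @export
group_compare <- function(values, groups) {
  groups <- droplevels(factor(groups))
  nc_assert(length(values) == length(groups), "length mismatch")
  lev <- levels(groups)
  if (length(lev) < 2)
    nc_stop("group comparison needs at least 2 groups",
            "neckct_input_error")
  nc_assert(all(table(groups) >= 1), "each group needs >= 1 value")

  if (length(lev) == 2) {
    x <- values[groups == lev[1]]
    y <- values[groups == lev[2]]
    n1 <- length(x); n2 <- length(y)
    r <- rank(c(x, y))
    ties <- table(c(x, y))
    has_ties <- any(ties > 1)
    u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    if (!has_ties && n1 < 50 && n2 < 50) {
      p <- if (u > n1 * n2 / 2)
        stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE)
      else stats::pwilcox(u, n1, n2)
      return(list(method = "mann_whitney", statistic = u,
                  p = min(1, 2 * p), exact = TRUE))
    }
    nn <- n1 + n2
    tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
    sigma2 <- n1 * n2 / 12 * ((nn + 1) - tie_term)
    if (sigma2 <= 0)
      return(list(method = "mann_whitney", statistic = u, p = 1,
                  exact = FALSE))
    z <- (u - n1 * n2 / 2) / sqrt(sigma2)
    list(method = "mann_whitney", statistic = u, p = 2 * pnorm(-abs(z)),
         exact = FALSE)
  } else {
    kt <- kruskal.test(values, groups)
    list(method = "kruskal_wallis", statistic = unname(kt$statistic),
         p = kt$p.value, df = unname(kt$parameter))
  }
}

#' Upper-quartile stratification
#'
#' Splits values at the 75th percentile (linear-interpolation quantile,
#' R type 7); values at or above the threshold form the upper-quartile
#' group.  With all values equal every value ties the threshold and the
#' whole cohort lands in the upper group (flagged with a warning).
#'
#' @param ratios numeric vector, n >= 4.
#' @return a list with `labels` (factor `upper_quartile` /
#'   `lower_three`) and `threshold`.
#' @export
top_quartile_split <- function(ratios) {
  nc_assert(all(is.finite(ratios)), "ratios must be finite")
  if (length(ratios) < 4)
    nc_stop("quartile split needs at least 4 values",
            "neckct_sample_error")
  thr <- quantile(ratios, 0.75, type = 7, names = FALSE)
  if (all(ratios == ratios[1]))
    warning("all values equal: entire cohort is in the upper-quartile group")
  labels <- factor(ifelse(ratios >= thr, "upper_quartile", "lower_three"),
                   levels = c("lower_three", "upper_quartile"))
  list(labels = labels, threshold = thr)
}

#' Kaplan-Meier curves and log-rank test for two groups
#'
#' Product-limit survival estimates per group and the 1-df log-rank
#' chi-square (observed minus expected events over the shared event
#' times), via the `survival` package.
#'
#' @param times follow-up times (days, >= 0).
#' @param events event indicator (1/TRUE = death, 0/FALSE = censored at
#'   `times`).
#' @param groups factor with exactly 2 levels.
#' @return a list with `fit` (a `survfit` object), `chisq`, `df`, `p`,
#'   `obs`, `exp` (per-group observed/expected events), `n`.
#' @export
km_logrank <- function(times, events, groups) {
  nc_assert(all(times >= 0), "times must be >= 0")
  groups <- droplevels(factor(groups))
  nc_assert(nlevels(groups) == 2, "log-rank comparison needs 2 groups")
  events <- as.integer(events)
  if (sum(events) == 0)
    nc_stop("no events observed: log-rank test degenerate",
            "neckct_degenerate_error")
  df <- data.frame(times = times, events = events, groups = groups)
  fit <- survival::survfit(survival::Surv(times, events) ~ groups, data = df)
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ groups,
                            data = df)
  p <- stats::pchisq(sd_$chisq, length(sd_$n) - 1, lower.tail = FALSE)
  list(fit = fit, chisq = unname(sd_$chisq), df = length(sd_$n) - 1,
       p = p, obs = sd_$obs, exp = sd_$exp, n = sd_$n)
}

#' Univariate Cox regression (optionally age/sex adjusted)
#'
#' Maximizes the Cox partial likelihood with Breslow tie handling and
#' reports the hazard ratio per covariate unit with its Wald 95%
#' confidence interval and p-value.
#'
#' @param times,events follow-up and event indicator as in [km_logrank()].
#' @param covariate numeric or two-level factor exposure.
#' @param adjusters optional data.frame of adjustment covariates (e.g.
#'   columns `age`, `sex`).
#' @param conf_level confidence level (default 0.95).
#' @return an object of class `survival_fit`: list with `beta`, `se`,
#'   `hr`, `hr_ci`, `p`, `adjusted_for`, `ties`, `n`, `n_events`.
#' @export
cox_univariate <- function(times, events, covariate, adjusters = NULL,
                           conf_level = 0.95) {
  events <- as.integer(events)
  nc_assert(sum(events) >= 1, "Cox regression needs at least one event",
            "neckct_degenerate_error")
  cov_num <- if (is.factor(covariate) || is.character(covariate))
    as.numeric(factor(covariate)) - 1 else as.numeric(covariate)
  if (length(unique(cov_num)) < 2)
    nc_stop("constant covariate: hazard ratio undefined",
            "neckct_input_error")
  df <- data.frame(.time = times, .event = events, .x = cov_num)
  rhs <- ".x"
  adjusted_for <- character(0)
  if (!is.null(adjusters)) {
    adjusters <- as.data.frame(adjusters)
    for (nm in names(adjusters)) {
      v <- adjusters[[nm]]
      df[[nm]] <- if (is.character(v)) factor(v) else v
    }
    adjusted_for <- names(adjusters)
    rhs <- paste(c(".x", adjusted_for), collapse = " + ")
  }
  fml <- stats::as.formula(paste0("survival::Surv(.time, .event) ~ ", rhs))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "breslow"),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w)))
        nc_stop(paste0("Cox likelihood did not converge: ",
                       conditionMessage(w)),
                "neckct_convergence_error")
      invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit)[".x"])
  se <- sqrt(stats::vcov(fit)[".x", ".x"])
  if (!is.finite(beta) || !is.finite(se) || abs(beta) > 20)
    nc_stop("Cox likelihood monotone (perfect separation)",
            "neckct_convergence_error")
  z <- qnorm(1 - (1 - conf_level) / 2)
  structure(list(beta = beta, se = se, hr = exp(beta),
                 hr_ci = exp(beta + c(-1, 1) * z * se),
                 p = 2 * pnorm(-abs(beta / se)),
                 adjusted_for = adjusted_for, ties = "breslow",
                 n = nrow(df), n_events = sum(events)),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  adj <- if (length(x$adjusted_for))
    paste0(" (adjusted for ", paste(x$adjusted_for, collapse = ", "), ")")
  else " (crude)"
  cat(sprintf("<survival_fit>%s HR = %.3f, 95%% CI %.3f-%.3f, p = %.4g\n",
              adj, x$hr, x$hr_ci[1], x$hr_ci[2], x$p))
  invisible(x)
}

#' Sample size for estimating an ICC to a target CI width
#'
#' Smallest number of subjects whose expected two-sided 95% confidence
#' interval for the ICC has width at most `ci_width`, using the Bonett
#' (2002) large-sample approximation
#' `w(n) = 2 z (1 - icc) (1 + (k - 1) icc) sqrt(2 / (k (k - 1) (n - 1)))`.
#' The approximation is stated in the output metadata; other software
#' (e.g. exact F-interval planners) may return slightly different n for
#' the same inputs.
#'
#' @param target_icc anticipated ICC, strictly inside (0, 1).
#' @param ci_width desired full CI width (> 0).
#' @param ratings_per_subject raters per subject, k >= 2.
#' @param conf_level confidence level (default 0.95).
#' @return a list with `n`, `method`, and the echoed inputs.
#' @export
icc_sample_size <- function(target_icc, ci_width, ratings_per_subject = 2,
                            conf_level = 0.95) {
  nc_assert(target_icc > 0 && target_icc < 1,
            "target_icc must be strictly inside (0, 1)",
            "neckct_domain_error")
  nc_assert(ci_width > 0, "ci_width must be > 0", "neckct_domain_error")
  k <- ratings_per_subject
  nc_assert(k >= 2, "need at least 2 ratings per subject",
            "neckct_domain_error")
  z <- qnorm(1 - (1 - conf_level) / 2)
  num <- 8 * z^2 * (1 - target_icc)^2 * (1 + (k - 1) * target_icc)^2
  n <- ceiling(1 + num / (k * (k - 1) * ci_width^2))
  if (!is.finite(n))
    nc_stop("infeasible ICC sample-size request", "neckct_domain_error")
  list(n = as.integer(n), method = "bonett2002_expected_width",
       target_icc = target_icc, ci_width = ci_width, k = k,
       conf_level = conf_level)
}
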