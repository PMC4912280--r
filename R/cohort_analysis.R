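# Full cohort analysis: composes the agreement, correlation, group
# comparison, stratification and survival operations into one structured
# report mirroring a clinical results section.

COHORT_REQUIRED <- c("patient_id", "age", "sex", "bmi", "natv_cc",
                     "awv_cc", "followup_days", "died")

#' Run the complete cohort analysis
#'
#' Emits, as a structured report: the interobserver agreement block (if
#' observer pairs are supplied), NATV-BMI and AWV-BMI Spearman
#' correlations, NATV against NCSA levels when NCSA columns are present,
#' NATV across WHO BMI categories (Kruskal-Wallis with per-category
#' median/IQR), the NATV:AWV upper-quartile split, Kaplan-Meier/log-rank
#' mortality comparison of the upper quartile versus the lower three, and
#' crude plus age/sex-adjusted Cox regressions for the ratio and for BMI.
#' Alpha = 0.05 (two-sided) is recorded in the report but never used to
#' suppress output.
#'
#' @param cohort data.frame with columns `patient_id`, `age`, `sex`,
#'   `bmi`, `natv_cc`, `awv_cc`, `followup_days`, `died` (and optionally
#'   `ratio`, `ncsa_upper_mm2`, `ncsa_lower_mm2`).
#' @param pairs optional [observer_pairs()], or a named list of them
#'   (e.g. `list(natv = ..., awv = ...)`).
#' @return an object of class `cohort_analysis` (a nested list).
#' @export
run_cohort_analysis <- function(cohort, pairs = NULL) {
  missing_cols <- setdiff(COHORT_REQUIRED, names(cohort))
  if (length(missing_cols))
    nc_stop(paste0("cohort table missing column(s): ",
                   paste(missing_cols, collapse = ", ")),
            "neckct_schema_error")
  cohort <- as.data.frame(cohort)
  if (is.null(cohort$ratio))
    cohort$ratio <- mapply(natv_awv_ratio, cohort$natv_cc, cohort$awv_cc)
  cohort$bmi_category <- bmi_category(cohort$bmi)
  nc_assert(all(cohort$followup_days >= 0), "followup_days must be >= 0",
            "neckct_schema_error")

  med_iqr <- function(v) {
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    list(median = q[2], iqr = c(q[1], q[3]))
  }

  report <- list(
    n = nrow(cohort),
    alpha = 0.05,
    descriptives = list(
      sex = frequency_table(cohort$sex),
      bmi_category = frequency_table(cohort$bmi_category),
      natv = med_iqr(cohort$natv_cc),
      awv = med_iqr(cohort$awv_cc),
      ratio = med_iqr(cohort$ratio)
    )
  )

  if (!is.null(pairs)) {
    if (inherits(pairs, "observer_pairs")) pairs <- list(pairs)
    report$agreement <- lapply(pairs, function(p)
      c(icc_absolute_agreement(p), bland_altman(p)))
  }

  report$correlations <- list(
    natv_bmi = spearman_rho(cohort$natv_cc, cohort$bmi),
    awv_bmi = spearman_rho(cohort$awv_cc, cohort$bmi)
  )
  if (!is.null(cohort$ncsa_upper_mm2))
    report$correlations$natv_ncsa_upper <-
      spearman_rho(cohort$natv_cc, cohort$ncsa_upper_mm2)
  if (!is.null(cohort$ncsa_lower_mm2))
    report$correlations$natv_ncsa_lower <-
      spearman_rho(cohort$natv_cc, cohort$ncsa_lower_mm2)

  by_cat <- split(cohort$natv_cc, cohort$bmi_category)
  report$natv_by_bmi_category <- list(
    per_category = lapply(by_cat, med_iqr),
    test = group_compare(cohort$natv_cc, cohort$bmi_category)
  )
  report$awv_by_bmi_category <- list(
    per_category = lapply(split(cohort$awv_cc, cohort$bmi_category), med_iqr),
    test = group_compare(cohort$awv_cc, cohort$bmi_category)
  )

  qs <- top_quartile_split(cohort$ratio)
  report$quartile_split <- list(
    threshold = qs$threshold,
    n_upper = sum(qs$labels == "upper_quartile"),
    n_lower = sum(qs$labels == "lower_three")
  )

  km <- km_logrank(cohort$followup_days, cohort$died, qs$labels)
  report$survival <- list(
    logrank = list(chisq = km$chisq, df = km$df, p = km$p,
                   obs = as.numeric(km$obs), exp = as.numeric(km$exp),
                   n = as.numeric(km$n)),
    deaths_upper = sum(cohort$died[qs$labels == "upper_quartile"]),
    deaths_lower = sum(cohort$died[qs$labels == "lower_three"])
  )

  adj <- cohort[, c("age", "sex")]
  # a monotone partial likelihood (possible in small cohorts with few
  # deaths) is reported as a per-fit failure, not a report abort
  strip_fit <- function(expr) {
    tryCatch(
      unclass(expr)[c("beta", "se", "hr", "hr_ci", "p", "adjusted_for",
                      "ties", "n", "n_events")],
      neckct_convergence_error = function(e)
        list(error = conditionMessage(e)))
  }
  report$cox <- list(
    ratio_crude = strip_fit(
      cox_univariate(cohort$followup_days, cohort$died, cohort$ratio)),
    ratio_adjusted = strip_fit(
      cox_univariate(cohort$followup_days, cohort$died, cohort$ratio,
                     adjusters = adj)),
    quartile_crude = strip_fit(
      cox_univariate(cohort$followup_days, cohort$died,
                     qs$labels == "upper_quartile")),
    bmi_crude = strip_fit(
      cox_univariate(cohort$followup_days, cohort$died, cohort$bmi)),
    bmi_adjusted = strip_fit(
      cox_univariate(cohort$followup_days, cohort$died, cohort$bmi,
                     adjusters = adj))
  )

  structure(report, class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat("<cohort_analysis> n =", x$n, "\n")
  cat(sprintf("  median NATV %.0f cc, AWV %.1f cc, NATV:AWV %.1f\n",
              x$descriptives$natv$median, x$descriptives$awv$median,
              x$descriptives$ratio$median))
  if (!is.null(x$agreement))
    for (nm in seq_along(x$agreement)) {
      a <- x$agreement[[nm]]
      cat(sprintf("  agreement[%s]: ICC %.4f (%.4f-%.4f), bias %.2f cc\n",
                  names(x$agreement)[nm] %||% nm, a$icc, a$icc_ci[1],
                  a$icc_ci[2], a$bias))
    }
  cat(sprintf("  NATV~BMI Spearman rho %.3f (p %.3g)\n",
              x$correlations$natv_bmi$rho, x$correlations$natv_bmi$p))
  cat(sprintf("  upper quartile: %d of %d; deaths %d vs %d; log-rank p %.3g\n",
              x$quartile_split$n_upper, x$n, x$survival$deaths_upper,
              x$survival$deaths_lower, x$survival$logrank$p))
  cr <- x$cox$quartile_crude
  if (is.null(cr$error)) {
    cat(sprintf("  upper-quartile HR %.2f (95%% CI %.2f-%.2f, p %.3g)\n",
                cr$hr, cr$hr_ci[1], cr$hr_ci[2], cr$p))
  } else {
    cat("  upper-quartile Cox fit failed:", cr$error, "\n")
  }
  invisible(x)
}
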