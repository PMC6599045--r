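#' Per-instrument Wald ratio causal estimates
#'
#' The Wald (ratio) estimator of the causal effect of the exposure on the
#' outcome for a single instrument is the SNP-outcome effect divided by
#' the SNP-exposure effect, `theta = beta_outcome / beta_exposure`: each
#' SNP's effect on the outcome is weighted by its effect on the exposure.
#' The first-order standard error is `se_outcome / |beta_exposure|`; the
#' second-order standard error additionally propagates the uncertainty in
#' the exposure effect,
#' `sqrt(se_y^2 / bx^2 + by^2 * se_x^2 / bx^4)`.
#'
#' @param harmonized A harmonized instrument table from
#'   [harmonize_instruments()]. Rows with `action == "dropped_palindromic"`
#'   are excluded.
#' @param se_order `"first"` (default) or `"second"`.
#' @param level Confidence level for the odds-ratio interval. Default 0.95.
#' @return A tibble with one row per instrument: `rsid`, `theta`,
#'   `se_theta`, `or_point`, `ci_low`, `ci_high`, `pvalue`.
#' @export
wald_ratio <- function(harmonized, se_order = c("first", "second"),
                       level = 0.95) {
  se_order <- match.arg(se_order)
  h <- harmonized[harmonized$action != "dropped_palindromic", ]
  if (nrow(h) == 0) {
    abort("No usable instruments (all dropped or empty input).",
          class = "mrkit_input_error")
  }
  if (any(h$beta_exposure == 0)) {
    abort(sprintf("Zero exposure effect for %s: the Wald ratio is undefined for a null instrument.",
                  paste(h$rsid[h$beta_exposure == 0], collapse = ", ")),
          class = "mrkit_weak_instrument_error")
  }
  bx <- h$beta_exposure
  theta <- h$beta_outcome / bx
  se_theta <- switch(
    se_order,
    first = h$se_outcome / abs(bx),
    second = sqrt(h$se_outcome^2 / bx^2 +
                    h$beta_outcome^2 * h$se_exposure^2 / bx^4)
  )
  ci <- logor_to_or_ci(theta, se_theta, level = level)
  tibble::tibble(
    rsid = h$rsid,
    theta = theta,
    se_theta = se_theta,
    or_point = ci$or_point,
    ci_low = ci$ci_low,
    ci_high = ci$ci_high,
    pvalue = 2 * pnorm(-abs(theta / se_theta))
  )
}

#' Fixed-effects inverse-variance-weighted pooling of Wald estimates
#'
#' Combines per-instrument causal estimates under a common-effect model:
#' `theta_pooled = sum(w * theta) / sum(w)` with weights `w = 1 / se^2`
#' and `se_pooled = 1 / sqrt(sum(w))`. Heterogeneity across instruments is
#' summarized by Cochran's Q, `Q = sum(w * (theta - theta_pooled)^2)` on
#' `k - 1` degrees of freedom, and by `I^2 = max(0, (Q - df) / Q)`, the
#' fraction of between-instrument variability in excess of chance. A 95%
#' interval for I^2 is obtained by Q-profile inversion (see Details).
#'
#' @details The I^2 interval uses the Higgins-Thompson test-based method:
#' a normal interval for `log H` (where `H^2 = Q / df`) with the
#' standard-error formula switching between the large-Q and small-Q
#' variants, back-transformed through `I^2 = 1 - 1 / H^2` and truncated
#' to `[0, 1]`. With very few instruments this interval is extremely wide
#' (with k = 3 nearly-homogeneous instruments the upper bound sits around
#' 90%); it is reported for context, not inference. With a single
#' instrument Q is 0 and I^2 is reported as 0 with a degenerate `[0, 0]`
#' interval.
#'
#' When the heterogeneity test rejects (`q_pvalue < 0.05`) a warning is
#' emitted; no random-effects fallback is applied.
#'
#' @param estimates A tibble of Wald estimates from [wald_ratio()]
#'   (columns `theta`, `se_theta`, optionally `rsid`).
#' @param level Confidence level for the pooled interval. Default 0.95.
#' @return A one-row tibble: `theta_pooled`, `se_pooled`, `or_point`,
#'   `ci_low`, `ci_high`, `pvalue`, `k`, `q_stat`, `q_df`, `q_pvalue`,
#'   `i2`, `i2_ci_low`, `i2_ci_high`.
#' @export
ivw_fixed <- function(estimates, level = 0.95) {
  if (nrow(estimates) == 0) {
    abort("Cannot pool an empty set of estimates.", class = "mrkit_input_error")
  }
  if (any(estimates$se_theta <= 0)) {
    abort("All standard errors must be positive.", class = "mrkit_domain_error")
  }
  theta <- estimates$theta
  w <- 1 / estimates$se_theta^2
  k <- length(theta)
  theta_pooled <- sum(w * theta) / sum(w)
  se_pooled <- 1 / sqrt(sum(w))
  q_df <- k - 1L
  q_stat <- sum(w * (theta - theta_pooled)^2)
  q_pvalue <- if (k > 1) pchisq(q_stat, df = q_df, lower.tail = FALSE) else NA_real_
  i2 <- if (k > 1 && q_stat > 0) max(0, (q_stat - q_df) / q_stat) else 0
  i2_ci <- i2_ci_test_based(q_stat, k, level = level)
  if (k > 1 && !is.na(q_pvalue) && q_pvalue < 0.05) {
    warn(sprintf(
      "Instruments are heterogeneous (Q = %.2f on %d df, p = %.3g); the fixed-effects pooled estimate assumes a single common causal effect.",
      q_stat, q_df, q_pvalue))
  }
  ci <- logor_to_or_ci(theta_pooled, se_pooled, level = level)
  tibble::tibble(
    theta_pooled = theta_pooled,
    se_pooled = se_pooled,
    or_point = ci$or_point,
    ci_low = ci$ci_low,
    ci_high = ci$ci_high,
    pvalue = 2 * pnorm(-abs(theta_pooled / se_pooled)),
    k = k,
    q_stat = q_stat,
    q_df = q_df,
    q_pvalue = q_pvalue,
    i2 = i2,
    i2_ci_low = i2_ci[1],
    i2_ci_high = i2_ci[2]
  )
}

# Higgins-Thompson test-based interval for I^2: normal CI for log H with
# H^2 = Q/df, back-transformed via I^2 = 1 - 1/H^2. The log-H standard
# error uses the large-Q formula when Q > k and the small-Q variant
# otherwise (the latter requires k > 2; with k = 2 and small Q the
# interval is maximally uninformative and reported as [0, 1]).
i2_ci_test_based <- function(q_stat, k, level = 0.95) {
  if (k < 2) return(c(0, 0))
  df <- k - 1
  z <- z_quantile(level)
  log_h <- 0.5 * max(0, log(q_stat) - log(df))
  se_log_h <- if (q_stat > k) {
    0.5 * (log(q_stat) - log(df)) / (sqrt(2 * q_stat) - sqrt(2 * k - 3))
  } else if (k > 2) {
    sqrt(1 / (2 * (k - 2)) * (1 - 1 / (3 * (k - 2)^2)))
  } else {
    return(c(0, 1))
  }
  h_lo <- max(1, exp(log_h - z * se_log_h))
  h_hi <- exp(log_h + z * se_log_h)
  pmin(pmax(c(1 - 1 / h_lo^2, 1 - 1 / h_hi^2), 0), 1)
}

#' End-to-end two-sample Mendelian randomization analysis
#'
#' Harmonizes the exposure and outcome summary statistics, computes
#' per-instrument Wald ratios, and pools them by fixed-effects
#' inverse-variance weighting. The result carries everything needed for a
#' forest plot: per-SNP odds ratios with confidence bars plus the pooled
#' summary diamond.
#'
#' @param exposure,outcome Summary-statistics data frames (see
#'   [validate_sumstats()]).
#' @param snps Optional character vector restricting the analysis to a
#'   subset of instruments (e.g. a single-SNP sensitivity analysis).
#' @param se_order Standard-error order for the Wald ratios; see
#'   [wald_ratio()].
#' @param palindrome_eaf_window Passed to [harmonize_instruments()].
#' @param level Confidence level. Default 0.95.
#' @return An object of class `mr_result`: a list with elements
#'   `instruments` (harmonized table), `estimates` (per-SNP Wald tibble)
#'   and `pooled` (one-row IVW tibble). Supports [tidy()], [glance()],
#'   [autoplot()] and `print()`.
#' @export
#' @examples
#' ex <- il18_ibd_example()
#' fit <- mr_analysis(ex$exposure, ex$outcome)
#' fit
#' tidy(fit)
mr_analysis <- function(exposure, outcome, snps = NULL,
                        se_order = c("first", "second"),
                        palindrome_eaf_window = 0.08, level = 0.95) {
  se_order <- match.arg(se_order)
  if (!is.null(snps)) {
    exposure <- dplyr::filter(exposure, .data$rsid %in% snps)
    outcome <- dplyr::filter(outcome, .data$rsid %in% snps)
    if (nrow(exposure) == 0) {
      abort("No exposure instruments left after the `snps` filter.",
            class = "mrkit_input_error")
    }
  }
  instruments <- harmonize_instruments(exposure, outcome,
                                       palindrome_eaf_window)
  estimates <- wald_ratio(instruments, se_order = se_order, level = level)
  pooled <- ivw_fixed(estimates, level = level)
  structure(
    list(instruments = instruments, estimates = estimates, pooled = pooled,
         exposure_trait = exposure$trait[1] %||% NA_character_,
         outcome_trait = outcome$trait[1] %||% NA_character_,
         level = level),
    class = "mr_result"
  )
}

#' Leave-one-out sensitivity analysis
#'
#' Repeats the pooled IVW analysis `k` times, omitting one instrument at
#' a time. An omission that changes the sign of the pooled estimate is a
#' red flag that a single instrument drives the result.
#'
#' @inheritParams mr_analysis
#' @return A tibble with one row per omitted instrument: `omitted`
#'   followed by the [ivw_fixed()] columns and `sign_change`.
#' @export
leave_one_out <- function(exposure, outcome,
                          se_order = c("first", "second"),
                          palindrome_eaf_window = 0.08, level = 0.95) {
  se_order <- match.arg(se_order)
  instruments <- harmonize_instruments(exposure, outcome,
                                       palindrome_eaf_window)
  estimates <- wald_ratio(instruments, se_order = se_order, level = level)
  if (nrow(estimates) < 2) {
    abort("Leave-one-out needs at least two usable instruments.",
          class = "mrkit_input_error")
  }
  full <- ivw_fixed(estimates, level = level)
  rows <- purrr::map(seq_len(nrow(estimates)), function(i) {
    res <- ivw_fixed(estimates[-i, ], level = level)
    dplyr::bind_cols(tibble::tibble(omitted = estimates$rsid[i]), res)
  })
  out <- dplyr::bind_rows(rows)
  out$sign_change <- sign(out$theta_pooled) != sign(full$theta_pooled) &
    out$theta_pooled != 0
  out
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("Two-sample MR: %s -> %s\n",
              x$exposure_trait, x$outcome_trait))
  cat(sprintf("%d instrument(s); fixed-effects IVW\n", x$pooled$k))
  est <- x$estimates
  for (i in seq_len(nrow(est))) {
    cat(sprintf("  %-12s OR %.2f (%.2f-%.2f)  p = %.2g\n",
                est$rsid[i], est$or_point[i], est$ci_low[i],
                est$ci_high[i], est$pvalue[i]))
  }
  p <- x$pooled
  cat(sprintf("Pooled: OR %.2f (%.2f-%.2f)  p = %.2g\n",
              p$or_point, p$ci_low, p$ci_high, p$pvalue))
  if (p$k > 1) {
    cat(sprintf("Heterogeneity: Q = %.2f on %d df (p = %.2g), I2 = %.0f%% (95%% CI %.0f-%.0f%%)\n",
                p$q_stat, p$q_df, p$q_pvalue, 100 * p$i2,
                100 * p$i2_ci_low, 100 * p$i2_ci_high))
  }
  invisible(x)
}
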