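#' Analytic power of two-sample MR with a binary outcome
#'
#' Non-centrality approximation for the power of a two-sample MR study of
#' a binary outcome: with total outcome sample size `N`, case fraction
#' `K`, instrument-explained exposure variance `r2` and alternative odds
#' ratio `or_alt` per SD of the exposure (`b = log(or_alt)`),
#'
#' `power = pnorm(sqrt(N * r2 * K * (1 - K)) * |b| - z_{1 - alpha/2})`.
#'
#' Several variants of this calculation circulate; this is the
#' case-fraction (`N K (1 - K)`) effective-sample-size form used by the
#' standard online MR power calculators, and the same approximation the
#' synthetic-data generator uses for its outcome standard errors, so
#' analytic power and simulated rejection rates are mutually consistent.
#'
#' @param n_cases,n_controls Outcome GWAS case and control counts.
#' @param r2 Fraction of exposure variance explained by the instruments,
#'   in (0, 1); see [variance_explained()].
#' @param or_alt Alternative-hypothesis odds ratio per SD of exposure.
#' @param alpha Two-sided significance level. Default 0.05.
#' @return Power as a fraction in (0, 1). Vectorized over all arguments.
#' @export
#' @examples
#' # replication-stage configuration: 99% power to detect OR 1.2 per SD
#' mr_power_binary(25042, 34915, r2 = 0.038, or_alt = 1.2)
mr_power_binary <- function(n_cases, n_controls, r2, or_alt, alpha = 0.05) {
  if (any(n_cases <= 0) || any(n_controls <= 0)) {
    abort("`n_cases` and `n_controls` must be positive.",
          class = "mrkit_domain_error")
  }
  if (any(r2 <= 0 | r2 >= 1)) {
    abort("`r2` must lie strictly between 0 and 1.",
          class = "mrkit_domain_error")
  }
  if (any(or_alt <= 0)) {
    abort("`or_alt` must be positive.", class = "mrkit_domain_error")
  }
  if (any(alpha <= 0 | alpha >= 1)) {
    abort("`alpha` must lie strictly between 0 and 1.",
          class = "mrkit_domain_error")
  }
  n <- n_cases + n_controls
  k <- n_cases / n
  b <- log(or_alt)
  pnorm(sqrt(n * r2 * k * (1 - k)) * abs(b) - qnorm(1 - alpha / 2))
}

#' Smallest detectable odds ratio at a target power
#'
#' Inverts [mr_power_binary()]: the smallest odds ratio above 1 at which
#' the study reaches `target_power`.
#'
#' @inheritParams mr_power_binary
#' @param target_power Desired power, in (0, 1).
#' @return The minimum detectable odds ratio (> 1).
#' @export
#' @examples
#' min_detectable_or(25042, 34915, r2 = 0.038, target_power = 0.99)
min_detectable_or <- function(n_cases, n_controls, r2, alpha = 0.05,
                              target_power = 0.8) {
  if (target_power <= 0 || target_power >= 1) {
    abort("`target_power` must lie strictly between 0 and 1.",
          class = "mrkit_domain_error")
  }
  f <- function(b) {
    mr_power_binary(n_cases, n_controls, r2, exp(b), alpha) - target_power
  }
  if (f(0) >= 0) return(1)
  upper <- 1
  while (f(upper) < 0 && upper < 100) upper <- upper * 2
  if (f(upper) < 0) {
    abort("Target power is unreachable at any plausible odds ratio.",
          class = "mrkit_diagnostic_error")
  }
  exp(uniroot(f, c(0, upper), tol = 1e-12)$root)
}
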