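# Independent oracles kept deliberately naive.

# IVW as weighted least squares of theta on the constant 1 through the
# origin, via lm() machinery.
wls_ivw_oracle <- function(theta, se) {
  fit <- stats::lm(theta ~ 1, weights = 1 / se^2)
  est <- unname(coef(fit)[1])
  # fixed-effects SE, not the lm residual-scaled one
  se_pooled <- 1 / sqrt(sum(1 / se^2))
  list(theta = est, se = se_pooled)
}

# Wakefield ABF by quadrature: ratio of the marginal likelihood of the
# estimate under the normal effect prior to its likelihood under the null.
abf_quadrature_oracle <- function(beta_hat, se, prior_sd) {
  marginal <- integrate(function(b) {
    dnorm(beta_hat, mean = b, sd = se) * dnorm(b, mean = 0, sd = prior_sd)
  }, lower = -Inf, upper = Inf, rel.tol = 1e-12)$value
  log(marginal) - dnorm(beta_hat, mean = 0, sd = se, log = TRUE)
}

# Colocalization posteriors by direct enumeration of causal
# configurations: each trait's causal variant is one of the n SNPs or
# absent, priors applied per configuration pair.
coloc_enumeration_oracle <- function(region, p1 = 1e-4, p2 = 1e-4,
                                     p12 = 1e-5, prior_sd1 = 0.15,
                                     prior_sd2 = 0.15) {
  abf1 <- exp(wakefield_abf(region$beta1, region$se1, prior_sd1))
  abf2 <- exp(wakefield_abf(region$beta2, region$se2, prior_sd2))
  n <- nrow(region)
  h0 <- 1
  h1 <- sum(p1 * abf1)
  h2 <- sum(p2 * abf2)
  h3 <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) h3 <- h3 + p1 * p2 * abf1[i] * abf2[j]
    }
  }
  h4 <- sum(p12 * abf1 * abf2)
  post <- c(h0, h1, h2, h3, h4)
  post / sum(post)
}
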