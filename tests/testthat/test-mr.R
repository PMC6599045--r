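test_that("Wald ratio reproduces the published single-instrument estimate", {
  h <- harmonize_instruments(table1_exposure(), table1_outcome())
  w <- wald_ratio(h)
  il18 <- w[w$rsid == "rs71478720", ]
  # published: OR 1.21 (1.05-1.40); recomputation from the rounded table
  # lands within a display digit
  expect_equal(il18$or_point, 1.21, tolerance = 0.02 / 1.21)
  expect_equal(il18$ci_low, 1.045, tolerance = 0.01)
  expect_equal(il18$ci_high, 1.39, tolerance = 0.01)
  expect_equal(round(il18$pvalue, 3), 0.012)
})

test_that("unit instrument passes the outcome association through unchanged", {
  h <- tibble::tibble(rsid = "rs1", beta_exposure = 1, se_exposure = 0.1,
                      beta_outcome = 0.33, se_outcome = 0.08,
                      action = "none")
  w <- wald_ratio(h)
  expect_equal(w$theta, 0.33)
  expect_equal(w$se_theta, 0.08)

  h$beta_exposure <- 0
  expect_error(wald_ratio(h), class = "mrkit_weak_instrument_error")
})

test_that("second-order SE exceeds first-order and matches a parametric bootstrap", {
  h <- tibble::tibble(rsid = "rs1", beta_exposure = 0.267,
                      se_exposure = 0.0285, beta_outcome = 0.0488,
                      se_outcome = 0.0195, action = "none")
  se1 <- wald_ratio(h, se_order = "first")$se_theta
  se2 <- wald_ratio(h, se_order = "second")$se_theta
  expect_gt(se2, se1)
  # delta-method SE of a ratio, checked by simulation from the sampling
  # distribution of the two estimates
  set.seed(31)
  n <- 1e6
  bx <- rnorm(n, 0.267, 0.0285)
  by <- rnorm(n, 0.0488, 0.0195)
  expect_equal(se2, sd(by / bx), tolerance = 0.02)
})

test_that("fixed-effects IVW pools the published instruments correctly", {
  h <- harmonize_instruments(table1_exposure(), table1_outcome())
  pooled <- ivw_fixed(wald_ratio(h))
  expect_equal(pooled$or_point, 1.22, tolerance = 0.011)
  expect_equal(pooled$ci_low, 1.11, tolerance = 0.011)
  expect_equal(pooled$ci_high, 1.34, tolerance = 0.011)
  expect_equal(pooled$i2, 0)
  expect_equal(pooled$k, 3)
  # printed p-value 5.9e-5; rounded inputs shift it within the same
  # order of magnitude
  expect_gt(pooled$pvalue, 1e-5)
  expect_lt(pooled$pvalue, 1e-4)
})

test_that("IVW degenerate cases behave as the algebra dictates", {
  one <- tibble::tibble(rsid = "rs1", theta = 0.2, se_theta = 0.05)
  p1 <- ivw_fixed(one)
  expect_equal(p1$theta_pooled, 0.2)
  expect_equal(p1$se_pooled, 0.05)
  expect_equal(p1$q_stat, 0)
  expect_equal(p1$i2, 0)

  k <- 4
  same <- tibble::tibble(rsid = sprintf("rs%d", 1:k), theta = 0.2,
                         se_theta = 0.05)
  pk <- ivw_fixed(same)
  expect_equal(pk$theta_pooled, 0.2)
  expect_equal(pk$se_pooled, 0.05 / sqrt(k))
  expect_equal(pk$q_stat, 0)

  expect_error(ivw_fixed(one[0, ]), class = "mrkit_input_error")
})

test_that("IVW equals a weighted-least-squares oracle on random inputs", {
  set.seed(41)
  for (i in 1:50) {
    est <- random_wald_estimates(sample(2:10, 1))
    pooled <- suppressWarnings(ivw_fixed(est))
    oracle <- wls_ivw_oracle(est$theta, est$se_theta)
    expect_equal(pooled$theta_pooled, oracle$theta, tolerance = 1e-12)
    expect_equal(pooled$se_pooled, oracle$se, tolerance = 1e-12)
  }
})

test_that("IVW and heterogeneity agree with an independent meta-analysis fit", {
  skip_if_not_installed("metafor")
  set.seed(42)
  est <- random_wald_estimates(6)
  pooled <- suppressWarnings(ivw_fixed(est))
  ref <- suppressWarnings(
    metafor::rma(yi = est$theta, sei = est$se_theta, method = "FE"))
  expect_equal(pooled$theta_pooled, unname(c(ref$beta)), tolerance = 1e-10)
  expect_equal(pooled$se_pooled, unname(ref$se), tolerance = 1e-10)
  expect_equal(pooled$q_stat, unname(ref$QE), tolerance = 1e-10)
})

test_that("IVW is permutation-invariant and scale-equivariant", {
  set.seed(43)
  est <- random_wald_estimates(7)
  p <- suppressWarnings(ivw_fixed(est))
  perm <- suppressWarnings(ivw_fixed(est[sample(7), ]))
  expect_equal(p$theta_pooled, perm$theta_pooled)
  expect_equal(p$q_stat, perm$q_stat)

  # scaling every exposure beta by c divides theta by c exactly
  ex <- table1_exposure(); out <- table1_outcome()
  ex_scaled <- dplyr::mutate(ex, beta = beta * 2.5, se = se * 2.5)
  p1 <- mr_analysis(ex, out)$pooled
  p2 <- mr_analysis(ex_scaled, out)$pooled
  expect_equal(p2$theta_pooled, p1$theta_pooled / 2.5)

  # I2 invariant under common rescaling of (theta, se)
  est2 <- dplyr::mutate(est, theta = theta * 3, se_theta = se_theta * 3)
  p3 <- suppressWarnings(ivw_fixed(est2))
  expect_equal(p3$i2, p$i2)
  expect_equal(p3$q_stat, p$q_stat)
})

test_that("mr_analysis restricted to a SNP subset matches direct computation", {
  ex <- table1_exposure(); out <- table1_outcome()
  fit <- mr_analysis(ex, out, snps = "rs71478720")
  expect_equal(fit$pooled$k, 1)
  w <- wald_ratio(harmonize_instruments(ex, out))
  expect_equal(fit$pooled$theta_pooled, w$theta[w$rsid == "rs71478720"])
  expect_error(mr_analysis(ex, out, snps = "rs99999"),
               class = "mrkit_input_error")
})

test_that("leave-one-out reduces to complements and flags nothing stable", {
  ex <- table1_exposure(); out <- table1_outcome()
  loo <- leave_one_out(ex, out)
  expect_equal(nrow(loo), 3)
  expect_true(all(loo$or_point > 1))
  expect_false(any(loo$sign_change))

  # with k = 2 each row equals the other instrument's Wald estimate
  ex2 <- ex[1:2, ]; out2 <- out[1:2, ]
  loo2 <- leave_one_out(ex2, out2)
  w2 <- wald_ratio(harmonize_instruments(ex2, out2))
  expect_equal(loo2$theta_pooled[loo2$omitted == "rs385076"],
               w2$theta[w2$rsid == "rs17229943"])
  expect_equal(loo2$theta_pooled[loo2$omitted == "rs17229943"],
               w2$theta[w2$rsid == "rs385076"])

  expect_error(leave_one_out(ex[1, ], out[1, ]), class = "mrkit_input_error")
})

test_that("heterogeneous instruments trigger a warning, not a model switch", {
  est <- tibble::tibble(rsid = c("rs1", "rs2", "rs3"),
                        theta = c(-1, 0, 1), se_theta = 0.05)
  expect_warning(res <- ivw_fixed(est), regexp = "heterogeneous")
  expect_gt(res$i2, 0.9)
  expect_equal(res$se_pooled, 1 / sqrt(sum(1 / est$se_theta^2)))
})
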