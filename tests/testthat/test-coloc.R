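test_that("Wakefield log ABF matches its closed form and a quadrature oracle", {
  # null estimate: shrinkage term only, always negative
  r <- 0.15^2 / (0.15^2 + 0.05^2)
  expect_equal(wakefield_abf(0, 0.05, 0.15), 0.5 * log(1 - r))
  expect_lt(wakefield_abf(0, 0.05, 0.15), 0)
  # point-null prior: no evidence either way
  expect_equal(wakefield_abf(0.2, 0.05, 1e-12), 0, tolerance = 1e-6)
  # quadrature over the effect prior
  expect_equal(wakefield_abf(0.2, 0.05, 0.15),
               abf_quadrature_oracle(0.2, 0.05, 0.15), tolerance = 1e-6)
  expect_equal(wakefield_abf(-0.07, 0.03, 0.2),
               abf_quadrature_oracle(-0.07, 0.03, 0.2), tolerance = 1e-6)
  # monotone in |z|
  expect_gt(wakefield_abf(0.3, 0.05, 0.15), wakefield_abf(0.2, 0.05, 0.15))
  expect_error(wakefield_abf(0.1, 0, 0.15), class = "mrkit_domain_error")
})

test_that("colocalization posteriors behave structurally", {
  # global null: quiet in both traits
  null_region <- tibble::tibble(rsid = sprintf("rs%d", 1:20),
                                beta1 = 0, se1 = 0.02,
                                beta2 = 0, se2 = 0.02)
  res <- coloc_abf(null_region)
  expect_gt(res$summary$pp0, 0.99)
  expect_equal(sum(unlist(res$summary[paste0("pp", 0:4)])), 1,
               tolerance = 1e-10)

  # one SNP, strong in both traits: shared variant, pp3 structurally zero
  one <- tibble::tibble(rsid = "rs1", beta1 = 0.5, se1 = 0.02,
                        beta2 = 0.5, se2 = 0.02)
  r1 <- coloc_abf(one)$summary
  expect_equal(r1$pp3, 0)
  expect_gt(r1$pp4, r1$pp1)
  expect_gt(r1$pp4, r1$pp2)

  expect_error(coloc_abf(null_region[0, ]), class = "mrkit_input_error")
  expect_error(coloc_abf(null_region, p1 = 0), class = "mrkit_domain_error")
})

test_that("posteriors equal brute-force enumeration on small regions", {
  set.seed(61)
  for (i in 1:40) {
    n <- sample(1:6, 1)
    region <- tibble::tibble(
      rsid = sprintf("rs%d", 1:n),
      beta1 = runif(n, -0.3, 0.3), se1 = runif(n, 0.02, 0.1),
      beta2 = runif(n, -0.3, 0.3), se2 = runif(n, 0.02, 0.1))
    got <- coloc_abf(region)$summary
    want <- coloc_enumeration_oracle(region)
    expect_equal(unname(unlist(got[paste0("pp", 0:4)])), want,
                 tolerance = 1e-10)
  }
})

test_that("posteriors are order-invariant and pp4 is monotone in p12", {
  set.seed(62)
  region <- tibble::tibble(
    rsid = sprintf("rs%d", 1:10),
    beta1 = rnorm(10, 0, 0.2), se1 = runif(10, 0.01, 0.1),
    beta2 = rnorm(10, 0, 0.2), se2 = runif(10, 0.01, 0.1))
  a <- coloc_abf(region)$summary
  b <- coloc_abf(region[sample(10), ])$summary
  expect_equal(unlist(a[paste0("pp", 0:4)]), unlist(b[paste0("pp", 0:4)]),
               tolerance = 1e-12)

  pp4s <- vapply(c(1e-6, 1e-5, 1e-4),
                 function(p12) coloc_abf(region, p12 = p12)$summary$pp4,
                 numeric(1))
  expect_true(all(diff(pp4s) > 0))
})

test_that("LD-confounding check separates shared from distinct causal variants", {
  shared <- simulate_coloc_region(n_snps = 40, causal_config = "shared",
                                  effect1 = 0.2, effect2 = 0.2, seed = 71)
  inst <- shared$region$rsid[shared$truth$causal_index_trait1]
  expect_false(check_ld_confounding(shared$region, inst)$flagged)

  distinct <- simulate_coloc_region(n_snps = 40, causal_config = "distinct",
                                    ld_decay = 0.6, effect1 = 0.2,
                                    effect2 = 0.2, seed = 72)
  inst2 <- distinct$region$rsid[distinct$truth$causal_index_trait1]
  expect_true(check_ld_confounding(distinct$region, inst2)$flagged)

  # a single-SNP region can never show two distinct variants
  single <- tibble::tibble(rsid = "rs1", beta1 = 0.4, se1 = 0.02,
                           beta2 = 0.4, se2 = 0.02)
  expect_false(check_ld_confounding(single, "rs1")$flagged)
  expect_error(check_ld_confounding(single, "rs2"),
               class = "mrkit_input_error")
})
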