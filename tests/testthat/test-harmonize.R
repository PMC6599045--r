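snp_record <- function(rsid = "rs1", ea = "C", oa = "T", eaf = 0.3,
                       beta = 0.2, se = 0.05, trait = "x",
                       trait_type = "quantitative") {
  validate_sumstats(tibble::tibble(
    rsid = rsid, chrom = "1", effect_allele = ea, other_allele = oa,
    eaf = eaf, beta = beta, se = se,
    pvalue = 2 * pnorm(-abs(beta / se)), n = 1000, trait = trait,
    trait_type = trait_type))
}

test_that("aligned, swapped and strand-complement allele codes are resolved", {
  ex <- snp_record(beta = 0.243)
  same <- harmonize_instruments(ex, snp_record(beta = 0.049, trait = "y"))
  expect_equal(same$action, "none")
  expect_equal(same$beta_outcome, 0.049)

  swapped <- harmonize_instruments(
    ex, snp_record(ea = "T", oa = "C", eaf = 0.7, beta = -0.049, trait = "y"))
  expect_equal(swapped$action, "sign_flip")
  expect_equal(swapped$beta_outcome, 0.049)
  expect_equal(swapped$eaf_outcome, 0.3)

  # same locus reported on the opposite strand: C/T vs G/A
  strand <- harmonize_instruments(
    ex, snp_record(ea = "G", oa = "A", beta = 0.049, trait = "y"))
  expect_equal(strand$action, "strand_flip")
  expect_equal(strand$beta_outcome, 0.049)

  expect_error(
    harmonize_instruments(ex, snp_record(ea = "A", oa = "C", trait = "y")),
    class = "mrkit_harmonization_error")
})

test_that("ambiguous palindromic SNPs are dropped, resolvable ones aligned", {
  ex <- snp_record(ea = "A", oa = "T", eaf = 0.49)
  out <- snp_record(ea = "A", oa = "T", eaf = 0.49, beta = 0.05, trait = "y")
  h <- harmonize_instruments(ex, out, palindrome_eaf_window = 0.08)
  expect_equal(h$action, "dropped_palindromic")
  expect_error(wald_ratio(h), class = "mrkit_input_error")

  # frequencies on opposite sides of 0.5 imply opposite strand labels
  ex2 <- snp_record(ea = "A", oa = "T", eaf = 0.2)
  out2 <- snp_record(ea = "A", oa = "T", eaf = 0.8, beta = -0.05, trait = "y")
  h2 <- harmonize_instruments(ex2, out2)
  expect_equal(h2$action, "sign_flip")
  expect_equal(h2$beta_outcome, 0.05)

  # missing frequency cannot resolve the strand
  ex3 <- snp_record(ea = "A", oa = "T", eaf = NA_real_)
  h3 <- harmonize_instruments(ex3, out2)
  expect_equal(h3$action, "dropped_palindromic")
})

test_that("instruments are oriented to the exposure-increasing allele", {
  ex <- snp_record(ea = "C", oa = "T", eaf = 0.3, beta = -0.2)
  out <- snp_record(ea = "C", oa = "T", eaf = 0.3, beta = -0.05, trait = "y")
  h <- harmonize_instruments(ex, out)
  expect_equal(h$beta_exposure, 0.2)
  expect_equal(h$beta_outcome, 0.05)
  expect_equal(h$effect_allele, "T")
  expect_equal(h$eaf_exposure, 0.7)
})

test_that("harmonization is idempotent", {
  ex <- snp_record(ea = "T", oa = "C", eaf = 0.3, beta = -0.2)
  out <- snp_record(ea = "C", oa = "T", eaf = 0.6, beta = 0.05, trait = "y")
  h1 <- harmonize_instruments(ex, out)
  # feed the harmonized records back through as two studies
  ex2 <- snp_record(ea = h1$effect_allele, oa = h1$other_allele,
                    eaf = h1$eaf_exposure, beta = h1$beta_exposure,
                    se = h1$se_exposure)
  out2 <- snp_record(ea = h1$effect_allele, oa = h1$other_allele,
                     eaf = h1$eaf_outcome, beta = h1$beta_outcome,
                     se = h1$se_outcome, trait = "y")
  h2 <- harmonize_instruments(ex2, out2)
  expect_equal(h2$action, "none")
  expect_equal(h2$beta_exposure, h1$beta_exposure)
  expect_equal(h2$beta_outcome, h1$beta_outcome)
  expect_equal(h2$effect_allele, h1$effect_allele)
})

test_that("flipping outcome alleles and negating beta leaves Wald ratios unchanged", {
  set.seed(21)
  for (i in 1:20) {
    ea <- sample(c("A", "C", "G", "T"), 1)
    oa <- sample(setdiff(c("A", "C", "G", "T"),
                         c(ea, chartr("ACGT", "TGCA", ea))), 1)
    bx <- rnorm(1, 0.25, 0.1)
    by <- rnorm(1, 0, 0.1)
    f <- runif(1, 0.1, 0.9)
    ex <- snp_record(ea = ea, oa = oa, eaf = f, beta = bx)
    out <- snp_record(ea = ea, oa = oa, eaf = f, beta = by, trait = "y")
    out_flipped <- snp_record(ea = oa, oa = ea, eaf = 1 - f, beta = -by,
                              trait = "y")
    w1 <- wald_ratio(harmonize_instruments(ex, out))
    w2 <- wald_ratio(harmonize_instruments(ex, out_flipped))
    expect_equal(w1$theta, w2$theta)
    expect_equal(w1$se_theta, w2$se_theta)
  }
})

test_that("mismatched or disjoint studies are rejected", {
  ex <- snp_record(rsid = "rs1")
  out <- snp_record(rsid = "rs2", trait = "y")
  expect_error(harmonize_instruments(ex, out),
               class = "mrkit_empty_intersection_error")
})
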