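# Published IL18 instrument records, rebuilt in code (independent of the
# packaged TSV fixture so the reader can be tested against them).
table1_exposure <- function() {
  validate_sumstats(tibble::tibble(
    rsid = c("rs385076", "rs17229943", "rs71478720"),
    chrom = c("2", "5", "11"),
    effect_allele = "C",
    other_allele = c("T", "G", "G"),
    eaf = c(0.64, 0.05, 0.76),
    beta = c(0.243, 0.312, 0.267),
    se = abs(c(0.243, 0.312, 0.267)) /
      qnorm(c(1.7e-22, 1.6e-11, 3.1e-22) / 2, lower.tail = FALSE),
    pvalue = c(1.7e-22, 1.6e-11, 3.1e-22),
    n = 3636,
    trait = "IL18 level (SD)",
    trait_type = "quantitative"
  ))
}

table1_outcome <- function() {
  conv <- or_ci_to_logor(c(1.05, 1.07, 1.05),
                         c(1.02, 0.97, 1.01),
                         c(1.09, 1.18, 1.09))
  validate_sumstats(tibble::tibble(
    rsid = c("rs385076", "rs17229943", "rs71478720"),
    chrom = c("2", "5", "11"),
    effect_allele = "C",
    other_allele = c("T", "G", "G"),
    eaf = c(0.64, 0.05, 0.76),
    beta = conv$logor,
    se = conv$se,
    pvalue = c(0.005, 0.066, 0.012),
    n = 34652,
    trait = "IBD",
    trait_type = "binary"
  ))
}

random_wald_estimates <- function(k) {
  tibble::tibble(
    rsid = sprintf("rs%d", seq_len(k)),
    theta = rnorm(k, 0, 0.5),
    se_theta = runif(k, 0.02, 0.5)
  )
}
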