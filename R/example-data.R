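#' Packaged IL18-IBD instrument data
#'
#' The three published genome-wide-significant instruments for
#' circulating IL18 level (rs385076 at *NLRC4*, rs17229943 at *OCLN*,
#' rs71478720 intronic in *IL18*) with their effects on IL18 (SD units,
#' Finnish cytokine GWAS, N = 3,636) and on inflammatory bowel disease
#' (odds ratios with 95% CIs, IIBDGC GWAS of 12,882 cases and 21,770
#' controls). On load, outcome odds ratios are converted to log-odds with
#' standard errors reconstructed from the CIs, and exposure standard
#' errors are reconstructed from the published effect sizes and p-values.
#'
#' Because the source table reports values to two or three significant
#' figures, estimates recomputed from these records can differ from the
#' originally published ones in the last displayed digit.
#'
#' The non-effect alleles are not printed in the source table; the
#' packaged values are synthetic placeholders, identical across the two
#' files and chosen so that no instrument is palindromic. They never
#' enter any computed number.
#'
#' @return A list with elements `exposure` and `outcome` (validated
#'   summary-statistics tibbles, three rows each) and `meta` (a list with
#'   the outcome GWAS `n_cases` and `n_controls` and the exposure GWAS
#'   size `n_exposure`).
#' @export
#' @examples
#' ex <- il18_ibd_example()
#' mr_analysis(ex$exposure, ex$outcome)
il18_ibd_example <- function() {
  exposure <- read_sumstats(
    system.file("extdata", "il18_exposure_table1.tsv", package = "mrkit",
                mustWork = TRUE),
    trait_type = "quantitative", trait = "IL18 level (SD)"
  )
  outcome <- read_sumstats(
    system.file("extdata", "ibd_outcome_table1.tsv", package = "mrkit",
                mustWork = TRUE),
    trait_type = "binary", trait = "IBD"
  )
  list(exposure = exposure, outcome = outcome,
       meta = list(n_cases = 12882, n_controls = 21770, n_exposure = 3636))
}
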