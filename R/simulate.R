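# Run `expr` under a private RNG stream: the global .Random.seed is left
# exactly as it was, and a given seed always yields the same draws.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

random_allele_pair <- function(palindromic) {
  if (palindromic) {
    p <- sample(list(c("A", "T"), c("G", "C")), 1)[[1]]
  } else {
    p <- sample(list(c("A", "G"), c("A", "C"), c("C", "T"), c("G", "T")),
                1)[[1]]
  }
  sample(p) # random orientation
}

#' Simulate paired two-sample GWAS summary statistics with known truth
#'
#' Generates exposure and outcome per-SNP association tables of the form
#' consumed by [mr_analysis()], under a two-sample design with a known
#' causal effect: the exposure is a standardized quantitative trait
#' measured in one cohort, the outcome a binary trait from an independent
#' case-control GWAS. For each instrument with minor-allele frequency
#' `maf` and true per-SD effect `beta_x`:
#'
#' * the estimated exposure effect is drawn as
#'   `Normal(beta_x, se_x^2)` with `se_x = 1 / sqrt(2 maf (1 - maf) n_exposure)`;
#' * the estimated outcome log-odds is `Normal(theta * beta_x + pleiotropy, se_y^2)`
#'   with `se_y = 1 / sqrt(2 maf (1 - maf) N K (1 - K))`, `N` the total
#'   outcome sample and `K` the case fraction — the same effective-size
#'   approximation used by [mr_power_binary()], so simulated rejection
#'   rates and analytic power are mutually consistent.
#'
#' Per-SNP direct (pleiotropic) effects on the outcome are drawn as
#' `Normal(pleiotropy_mean, pleiotropy_sd^2)`; they violate the exclusion
#' restriction the single-instrument sensitivity analysis probes.
#'
#' Defaults mirror the IL18-IBD discovery design: three instruments with
#' the published effect sizes and frequencies, an exposure GWAS of 3,636
#' and an outcome GWAS of 12,882 cases and 21,770 controls.
#'
#' @param n_instruments Number of instruments. Default 3.
#' @param theta True causal log-odds of outcome per SD of exposure.
#'   Default 0.
#' @param exposure_betas True per-SD exposure effects; recycled or, if
#'   `NULL`, drawn uniformly from `[0.15, 0.35]`. Default: the three
#'   published IL18 instrument effects when `n_instruments == 3`,
#'   otherwise `NULL`.
#' @param mafs Minor-allele frequencies; recycled or, if `NULL`, drawn
#'   uniformly from `maf_range`. Default: the published IL18 instrument
#'   frequencies (folded to the minor allele) when `n_instruments == 3`.
#' @param maf_range Sampling interval for `mafs` when not supplied; must
#'   lie within (0, 0.5].
#' @param n_exposure Exposure GWAS sample size. Default 3636.
#' @param n_cases,n_controls Outcome GWAS sizes. Defaults 12882 / 21770.
#' @param pleiotropy_mean,pleiotropy_sd Mean and SD of per-SNP direct
#'   effects on the outcome log-odds. Defaults 0 (no pleiotropy).
#' @param palindromic_fraction Expected fraction of instruments assigned
#'   palindromic (A/T or G/C) allele pairs. Default 0.
#' @param seed Integer seed; identical seeds give identical output, and
#'   the caller's RNG state is untouched.
#' @return A list with elements `exposure` and `outcome` (validated
#'   summary-statistics tibbles) and `truth` (a list holding `theta`,
#'   the latent `exposure_betas`, `mafs`, per-SNP `pleiotropy`, and the
#'   instrument-strength `r2` implied by the latent effects).
#' @export
#' @examples
#' sim <- simulate_two_sample_study(theta = log(1.2), seed = 42)
#' mr_analysis(sim$exposure, sim$outcome)
simulate_two_sample_study <- function(n_instruments = 3,
                                      theta = 0,
                                      exposure_betas = if (n_instruments == 3)
                                        c(0.243, 0.312, 0.267) else NULL,
                                      mafs = if (n_instruments == 3)
                                        c(0.36, 0.05, 0.24) else NULL,
                                      maf_range = c(0.05, 0.5),
                                      n_exposure = 3636,
                                      n_cases = 12882,
                                      n_controls = 21770,
                                      pleiotropy_mean = 0,
                                      pleiotropy_sd = 0,
                                      palindromic_fraction = 0,
                                      seed = NULL) {
  if (n_instruments < 1) {
    abort("`n_instruments` must be at least 1.",
          class = "mrkit_configuration_error")
  }
  if (any(c(n_exposure, n_cases, n_controls) <= 0)) {
    abort("Sample sizes must be positive.",
          class = "mrkit_configuration_error")
  }
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    abort("`maf_range` must lie within (0, 0.5].",
          class = "mrkit_configuration_error")
  }
  if (palindromic_fraction < 0 || palindromic_fraction > 1) {
    abort("`palindromic_fraction` must lie in [0, 1].",
          class = "mrkit_configuration_error")
  }

  with_local_seed(seed, {
    k <- n_instruments
    mafs <- if (is.null(mafs)) stats::runif(k, maf_range[1], maf_range[2])
            else rep_len(mafs, k)
    bx <- if (is.null(exposure_betas)) stats::runif(k, 0.15, 0.35)
          else rep_len(exposure_betas, k)
    n_out <- n_cases + n_controls
    case_frac <- n_cases / n_out
    se_x <- 1 / sqrt(2 * mafs * (1 - mafs) * n_exposure)
    se_y <- 1 / sqrt(2 * mafs * (1 - mafs) * n_out * case_frac * (1 - case_frac))
    pleio <- rnorm(k, pleiotropy_mean, pleiotropy_sd)
    bx_hat <- rnorm(k, bx, se_x)
    by_hat <- rnorm(k, theta * bx + pleio, se_y)

    palindromic <- stats::runif(k) < palindromic_fraction
    alleles <- purrr::map(palindromic, random_allele_pair)
    rsid <- sprintf("rs%06d", seq_len(k))

    exposure <- validate_sumstats(tibble::tibble(
      rsid = rsid,
      chrom = as.character(rep_len(1:22, k)),
      effect_allele = purrr::map_chr(alleles, 1),
      other_allele = purrr::map_chr(alleles, 2),
      eaf = mafs,
      beta = bx_hat,
      se = se_x,
      pvalue = pmax(2 * pnorm(-abs(bx_hat / se_x)), .Machine$double.xmin),
      n = n_exposure,
      trait = "simulated exposure",
      trait_type = "quantitative"
    ))
    outcome <- validate_sumstats(tibble::tibble(
      rsid = rsid,
      chrom = exposure$chrom,
      effect_allele = exposure$effect_allele,
      other_allele = exposure$other_allele,
      eaf = mafs,
      beta = by_hat,
      se = se_y,
      pvalue = pmax(2 * pnorm(-abs(by_hat / se_y)), .Machine$double.xmin),
      n = n_out,
      trait = "simulated outcome",
      trait_type = "binary"
    ))
    list(
      exposure = exposure,
      outcome = outcome,
      truth = list(theta = theta, exposure_betas = bx, mafs = mafs,
                   pleiotropy = pleio,
                   r2 = sum(variance_explained(mafs, bx)),
                   n_exposure = n_exposure, n_cases = n_cases,
                   n_controls = n_controls)
    )
  })
}

#' Simulate summary statistics for a colocalization region
#'
#' Draws per-SNP z-scores for two traits over a region with
#' autoregressive linkage disequilibrium (`cor(z_i, z_j) = ld_decay^|i-j|`)
#' and a configurable causal architecture, then converts them to
#' beta/se pairs on the standardized scale (`se = 1/sqrt(n)`). Marginal
#' z-score means follow GWAS asymptotics: `E[z] = R Lambda sqrt(n) b`,
#' so non-causal SNPs in LD with a causal SNP pick up proportionally
#' attenuated signal — the mechanism behind LD-confounded instruments.
#'
#' @param n_snps Number of SNPs in the region.
#' @param ld_decay AR(1) correlation parameter in `[0, 1)`. Default 0.8.
#' @param causal_config `"shared"` (one SNP drives both traits),
#'   `"distinct"` (different causal SNPs for the two traits),
#'   `"trait1_only"`, or `"null"`.
#' @param effect1,effect2 Causal effects on the standardized scale for
#'   traits 1 and 2. Defaults 0.15.
#' @param n1,n2 Per-trait GWAS sample sizes. Defaults 10000.
#' @param causal_index,causal_index2 Positions of the causal SNP(s); by
#'   default the region centre, and (for `"distinct"`) a SNP several
#'   positions away.
#' @param seed Integer seed (private RNG stream).
#' @return A list with `region` (tibble `rsid`, `beta1`, `se1`, `beta2`,
#'   `se2`) and `truth` (causal configuration and indices).
#' @export
simulate_coloc_region <- function(n_snps = 50, ld_decay = 0.8,
                                  causal_config = c("shared", "distinct",
                                                    "trait1_only", "null"),
                                  effect1 = 0.15, effect2 = 0.15,
                                  n1 = 10000, n2 = 10000,
                                  causal_index = NULL, causal_index2 = NULL,
                                  seed = NULL) {
  causal_config <- match.arg(causal_config)
  if (n_snps < 1) {
    abort("`n_snps` must be at least 1.",
          class = "mrkit_configuration_error")
  }
  if (ld_decay < 0 || ld_decay >= 1) {
    abort("`ld_decay` must lie in [0, 1) for a positive-definite LD matrix.",
          class = "mrkit_configuration_error")
  }
  if (n_snps == 1 && causal_config == "distinct") {
    abort("A single-SNP region cannot host two distinct causal variants.",
          class = "mrkit_configuration_error")
  }

  with_local_seed(seed, {
    idx1 <- causal_index %||% ceiling(n_snps / 2)
    idx2 <- causal_index2 %||% max(1, idx1 - max(2, round(n_snps / 5)))
    if (causal_config == "distinct" && idx2 == idx1) idx2 <- idx1 - 1
    R <- ld_decay^abs(outer(seq_len(n_snps), seq_len(n_snps), "-"))
    L <- chol(R)

    mean_z <- function(idx, eff, n) {
      lam <- numeric(n_snps)
      if (!is.null(idx)) lam[idx] <- eff * sqrt(n)
      drop(R %*% lam)
    }
    mu1 <- switch(causal_config,
                  shared = mean_z(idx1, effect1, n1),
                  distinct = mean_z(idx1, effect1, n1),
                  trait1_only = mean_z(idx1, effect1, n1),
                  null = numeric(n_snps))
    mu2 <- switch(causal_config,
                  shared = mean_z(idx1, effect2, n2),
                  distinct = mean_z(idx2, effect2, n2),
                  trait1_only = numeric(n_snps),
                  null = numeric(n_snps))
    z1 <- mu1 + drop(crossprod(L, rnorm(n_snps)))
    z2 <- mu2 + drop(crossprod(L, rnorm(n_snps)))

    region <- tibble::tibble(
      rsid = sprintf("rs%06d", seq_len(n_snps)),
      beta1 = z1 / sqrt(n1), se1 = 1 / sqrt(n1),
      beta2 = z2 / sqrt(n2), se2 = 1 / sqrt(n2)
    )
    truth <- list(causal_config = causal_config,
                  causal_index_trait1 = if (causal_config == "null") NA_integer_ else idx1,
                  causal_index_trait2 = switch(causal_config,
                                               shared = idx1,
                                               distinct = idx2,
                                               NA_integer_),
                  ld_decay = ld_decay)
    list(region = region, truth = truth)
  })
}
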