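complement_allele <- function(a) {
  chartr("ACGT", "TGCA", a)
}

is_palindromic <- function(a1, a2) {
  a1 == complement_allele(a2)
}

#' Harmonize exposure and outcome summary statistics to a shared effect allele
#'
#' Two-sample MR requires the instrument-exposure and instrument-outcome
#' effects to refer to the same allele. For each SNP present in both
#' studies this aligns the outcome record to the exposure's effect allele:
#' outcome effects are sign-flipped when the studies report opposite
#' alleles, strand-complement allele codes (A<->T, C<->G) are resolved
#' before comparison, and palindromic SNPs (A/T or G/C) whose
#' effect-allele frequency falls within `palindrome_eaf_window` of 0.5 in
#' either study are retained but marked `dropped_palindromic`, since their
#' strand cannot be resolved. Finally every instrument is oriented so the
#' exposure effect is non-negative, i.e. to the exposure-increasing
#' allele.
#'
#' Palindromic SNPs outside the ambiguity window are aligned by frequency:
#' if the exposure and outcome effect-allele frequencies lie on opposite
#' sides of 0.5, the outcome record is taken to refer to the opposite
#' allele and is flipped.
#'
#' @param exposure,outcome Summary-statistics data frames (see
#'   [validate_sumstats()]) for the exposure and outcome GWAS.
#' @param palindrome_eaf_window Half-width of the frequency window around
#'   0.5 inside which palindromic SNPs are considered unresolvable.
#'   Default 0.08 (drop when eaf is in `[0.42, 0.58]`).
#' @return A tibble with one row per shared SNP: `rsid`, `effect_allele`,
#'   `other_allele` (post-harmonization orientation), `eaf_exposure`,
#'   `beta_exposure`, `se_exposure`, `eaf_outcome`, `beta_outcome`,
#'   `se_outcome`, `pvalue_exposure`, `pvalue_outcome`, and `action`
#'   (`"none"`, `"sign_flip"`, `"strand_flip"`, `"dropped_palindromic"`).
#'   Rows marked `dropped_palindromic` are excluded from estimation by
#'   downstream functions.
#' @export
harmonize_instruments <- function(exposure, outcome,
                                  palindrome_eaf_window = 0.08) {
  exposure <- validate_sumstats(exposure)
  outcome <- validate_sumstats(outcome)
  shared <- intersect(exposure$rsid, outcome$rsid)
  if (length(shared) == 0) {
    abort("No rsid is shared between the exposure and outcome studies.",
          class = "mrkit_empty_intersection_error")
  }
  ex <- exposure[match(shared, exposure$rsid), ]
  ou <- outcome[match(shared, outcome$rsid), ]

  e1 <- ex$effect_allele; e2 <- ex$other_allele
  o1 <- ou$effect_allele; o2 <- ou$other_allele
  n <- length(shared)
  action <- rep(NA_character_, n)
  flip <- rep(FALSE, n)

  pal <- is_palindromic(e1, e2)

  # non-palindromic: direct or strand-complement matching
  c1 <- complement_allele(o1); c2 <- complement_allele(o2)
  same <- !pal & o1 == e1 & o2 == e2
  swap <- !pal & o1 == e2 & o2 == e1
  strand_same <- !pal & !same & !swap & c1 == e1 & c2 == e2
  strand_swap <- !pal & !same & !swap & c1 == e2 & c2 == e1
  bad <- !pal & !same & !swap & !strand_same & !strand_swap
  if (any(bad)) {
    abort(sprintf("Alleles cannot be reconciled between studies for: %s.",
                  paste(shared[bad], collapse = ", ")),
          class = "mrkit_harmonization_error")
  }
  action[same] <- "none"
  action[swap] <- "sign_flip"
  action[strand_same | strand_swap] <- "strand_flip"
  flip[swap | strand_swap] <- TRUE

  # palindromic: strand unresolvable from alleles; use frequency if clear
  if (any(pal)) {
    ambiguous <- pal & (is.na(ex$eaf) | is.na(ou$eaf) |
                          abs(ex$eaf - 0.5) <= palindrome_eaf_window |
                          abs(ou$eaf - 0.5) <= palindrome_eaf_window)
    pal_flip <- pal & !ambiguous & (ex$eaf - 0.5) * (ou$eaf - 0.5) < 0
    action[ambiguous] <- "dropped_palindromic"
    action[pal & !ambiguous] <- ifelse(pal_flip[pal & !ambiguous],
                                       "sign_flip", "none")
    flip[pal_flip] <- TRUE
  }

  ou_beta <- ifelse(flip, -ou$beta, ou$beta)
  ou_eaf <- ifelse(flip, 1 - ou$eaf, ou$eaf)

  # orient to the exposure-increasing allele
  reorient <- ex$beta < 0 & action != "dropped_palindromic"
  ea <- ifelse(reorient, e2, e1)
  oa <- ifelse(reorient, e1, e2)
  ex_beta <- ifelse(reorient, -ex$beta, ex$beta)
  ex_eaf <- ifelse(reorient, 1 - ex$eaf, ex$eaf)
  ou_beta <- ifelse(reorient, -ou_beta, ou_beta)
  ou_eaf <- ifelse(reorient, 1 - ou_eaf, ou_eaf)

  tibble::tibble(
    rsid = shared,
    effect_allele = ea,
    other_allele = oa,
    eaf_exposure = ex_eaf,
    beta_exposure = ex_beta,
    se_exposure = ex$se,
    eaf_outcome = ou_eaf,
    beta_outcome = ou_beta,
    se_outcome = ou$se,
    pvalue_exposure = ex$pvalue,
    pvalue_outcome = ou$pvalue,
    action = action
  )
}
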