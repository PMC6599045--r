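#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise significance level, in (0, 1).
#' @param m Number of tests in the family, at least 1.
#' @return `alpha / m`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 3864)
bonferroni_threshold <- function(alpha, m) {
  if (any(m < 1)) {
    abort("`m` must be at least 1.", class = "mrkit_domain_error")
  }
  if (any(alpha <= 0 | alpha >= 1)) {
    abort("`alpha` must lie strictly between 0 and 1.",
          class = "mrkit_domain_error")
  }
  alpha / m
}

#' Phenome-wide MR scan of one instrument set across many outcomes
#'
#' Runs a fixed-effects IVW MR of the same exposure instruments against
#' every outcome in a catalogue and controls the family-wise error rate
#' by Bonferroni correction. The correction denominator defaults to the
#' number of outcomes in the catalogue — outcomes that cannot be analysed
#' (no instrument overlap) are skipped with a reason but still count in
#' `m`, the conservative convention.
#'
#' @param exposure Exposure summary statistics (see
#'   [validate_sumstats()]).
#' @param catalogue Long-format data frame of outcome summary statistics
#'   restricted to the instrument rsids, with the outcome label in the
#'   `trait` column; or a named list of per-outcome data frames.
#' @param alpha Family-wise significance level. Default 0.05.
#' @param m Correction denominator; defaults to the number of outcomes in
#'   the catalogue.
#' @param se_order,palindrome_eaf_window Passed to [mr_analysis()].
#' @return A tibble with one row per outcome, sorted by p-value
#'   (skipped outcomes last): `outcome`, `k`, `theta`, `se`, `or_point`,
#'   `ci_low`, `ci_high`, `pvalue`, `bonferroni_alpha`, `significant`,
#'   `skipped`, `skip_reason`.
#' @export
phewas_scan <- function(exposure, catalogue, alpha = 0.05, m = NULL,
                        se_order = c("first", "second"),
                        palindrome_eaf_window = 0.08) {
  se_order <- match.arg(se_order)
  if (is.data.frame(catalogue)) {
    if (!"trait" %in% names(catalogue)) {
      abort("A long-format catalogue needs a `trait` column labelling outcomes.",
            class = "mrkit_configuration_error")
    }
    catalogue <- split(catalogue, catalogue$trait)
  }
  if (length(catalogue) == 0) {
    abort("The outcome catalogue is empty.", class = "mrkit_input_error")
  }
  if (is.null(names(catalogue)) || anyDuplicated(names(catalogue))) {
    abort("Catalogue outcomes must carry unique labels.",
          class = "mrkit_configuration_error")
  }
  m <- m %||% length(catalogue)
  thr <- bonferroni_threshold(alpha, m)

  rows <- purrr::imap(catalogue, function(out_stats, label) {
    fit <- tryCatch(
      mr_analysis(exposure, out_stats, se_order = se_order,
                  palindrome_eaf_window = palindrome_eaf_window),
      mrkit_empty_intersection_error = function(e) e,
      mrkit_input_error = function(e) e
    )
    if (inherits(fit, "error")) {
      return(tibble::tibble(
        outcome = label, k = 0L, theta = NA_real_, se = NA_real_,
        or_point = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        pvalue = NA_real_, bonferroni_alpha = thr, significant = NA,
        skipped = TRUE, skip_reason = conditionMessage(fit)))
    }
    p <- fit$pooled
    tibble::tibble(
      outcome = label, k = p$k, theta = p$theta_pooled, se = p$se_pooled,
      or_point = p$or_point, ci_low = p$ci_low, ci_high = p$ci_high,
      pvalue = p$pvalue, bonferroni_alpha = thr,
      significant = p$pvalue < thr, skipped = FALSE,
      skip_reason = NA_character_)
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$skipped, .data$pvalue)
}
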