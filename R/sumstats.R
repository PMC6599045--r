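#' Convert an odds ratio with confidence interval to log-odds and standard error
#'
#' GWAS consortia often publish binary-trait associations as an odds ratio
#' with a 95% confidence interval rather than a log-odds coefficient with a
#' standard error. This inverts that presentation: the log-odds is
#' `log(or)` and the standard error is reconstructed from the width of the
#' interval on the log scale, `(log(ci_high) - log(ci_low)) / (2 * z)`,
#' where `z` is the exact standard-normal quantile at `(1 + level) / 2`
#' (1.959964 at 95%, not 1.96).
#'
#' Standard errors reconstructed from intervals printed to two decimal
#' places carry roughly 1% relative rounding error; downstream estimates
#' recomputed from published tables can therefore differ from the
#' originals in the last displayed digit.
#'
#' @param or_point Odds ratio point estimate (positive).
#' @param ci_low,ci_high Confidence interval bounds (positive,
#'   `ci_low <= or_point <= ci_high`).
#' @param level Confidence level of the interval, in (0, 1). Default 0.95.
#' @return A tibble with columns `logor` and `se`.
#' @seealso [logor_to_or_ci()] for the inverse transformation.
#' @export
#' @examples
#' or_ci_to_logor(1.05, 1.02, 1.09)
or_ci_to_logor <- function(or_point, ci_low, ci_high, level = 0.95) {
  if (any(level <= 0) || any(level >= 1)) {
    abort("`level` must be strictly between 0 and 1.", class = "mrkit_domain_error")
  }
  if (any(c(or_point, ci_low, ci_high) <= 0)) {
    abort("Odds ratios and interval bounds must be positive.",
          class = "mrkit_domain_error")
  }
  bad <- or_point < ci_low | or_point > ci_high | ci_low > ci_high
  if (any(bad)) {
    abort(sprintf("Inconsistent interval: `or_point` outside [ci_low, ci_high] at position %s.",
                  paste(which(bad), collapse = ", ")),
          class = "mrkit_inconsistency_error")
  }
  z <- z_quantile(level)
  tibble::tibble(
    logor = log(or_point),
    se = (log(ci_high) - log(ci_low)) / (2 * z)
  )
}

#' Convert log-odds and standard error to an odds ratio with confidence interval
#'
#' @param logor Effect on the log-odds scale.
#' @param se Standard error of `logor` (non-negative).
#' @param level Confidence level for the returned interval. Default 0.95.
#' @return A tibble with columns `or_point`, `ci_low`, `ci_high`.
#' @export
#' @examples
#' logor_to_or_ci(0.1943, 0.0480)
logor_to_or_ci <- function(logor, se, level = 0.95) {
  if (any(se < 0)) {
    abort("`se` must be non-negative.", class = "mrkit_domain_error")
  }
  z <- z_quantile(level)
  tibble::tibble(
    or_point = exp(logor),
    ci_low = exp(logor - z * se),
    ci_high = exp(logor + z * se)
  )
}

#' Variance in a standardized trait explained by a SNP
#'
#' For a trait measured in standard-deviation units, a biallelic SNP with
#' effect-allele frequency `eaf` and per-allele effect `beta` explains
#' `2 * eaf * (1 - eaf) * beta^2` of the trait variance. Summed over
#' independent instruments this gives the instrument-strength R^2 consumed
#' by [mr_power_binary()].
#'
#' @param eaf Effect-allele frequency in `[0, 1]`.
#' @param beta Per-allele effect in SD units of the trait.
#' @return Numeric fraction(s) of variance explained.
#' @export
#' @examples
#' variance_explained(0.64, 0.243)
variance_explained <- function(eaf, beta) {
  if (any(is.na(eaf))) {
    abort("Effect-allele frequency is required to compute variance explained.",
          class = "mrkit_frequency_required_error")
  }
  if (any(eaf < 0 | eaf > 1)) {
    abort("`eaf` must lie in [0, 1].", class = "mrkit_domain_error")
  }
  2 * eaf * (1 - eaf) * beta^2
}

sumstats_columns <- c("rsid", "chrom", "effect_allele", "other_allele",
                      "eaf", "beta", "se", "pvalue", "n", "trait", "trait_type")

#' Validate a summary-statistics data frame
#'
#' Checks the invariants of a per-SNP association table: positive standard
#' errors, distinct A/C/G/T alleles, frequencies in `[0, 1]`, p-values in
#' (0, 1]. Rows violating any invariant raise an error naming the rows and
#' fields.
#'
#' @param data A data frame with (at least) columns `rsid`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `pvalue`; optionally
#'   `chrom`, `eaf`, `n`, `trait`, `trait_type`.
#' @return `data`, invisibly coerced to a tibble with the canonical
#'   column set (missing optional columns filled with `NA`).
#' @export
validate_sumstats <- function(data) {
  data <- tibble::as_tibble(data)
  required <- c("rsid", "effect_allele", "other_allele", "beta", "se", "pvalue")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("Missing required column(s): %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "mrkit_configuration_error")
  }
  for (col in setdiff(sumstats_columns, names(data))) {
    data[[col]] <- if (col %in% c("eaf", "beta", "se", "pvalue", "n")) NA_real_ else NA_character_
  }
  data <- data[sumstats_columns]

  problems <- character()
  flag <- function(bad, what) {
    if (any(bad, na.rm = TRUE)) {
      problems <<- c(problems, sprintf("%s (row %s)", what,
                                       paste(which(bad), collapse = ", ")))
    }
  }
  flag(!is.finite(data$se) | data$se <= 0, "se must be > 0")
  flag(!data$effect_allele %in% c("A", "C", "G", "T"),
       "effect_allele must be one of A/C/G/T")
  flag(!data$other_allele %in% c("A", "C", "G", "T"),
       "other_allele must be one of A/C/G/T")
  flag(data$effect_allele == data$other_allele,
       "effect_allele must differ from other_allele")
  flag(!is.na(data$eaf) & (data$eaf < 0 | data$eaf > 1), "eaf must lie in [0, 1]")
  flag(!is.finite(data$pvalue) | data$pvalue <= 0 | data$pvalue > 1,
       "pvalue must lie in (0, 1]")
  flag(!is.finite(data$beta), "beta must be finite")
  if (length(problems) > 0) {
    abort(paste0("Summary-statistics validation failed:\n  ",
                 paste(problems, collapse = "\n  ")),
          class = "mrkit_validation_error")
  }
  data
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a header-labelled TSV or CSV (delimiter auto-detected from the
#' header line) and maps its columns onto the canonical per-SNP
#' association schema via a declarative column map. Binary-trait files
#' that publish odds ratios with confidence intervals are converted to
#' log-odds and standard error with [or_ci_to_logor()]; files that carry
#' `beta` and `pvalue` but no standard-error column have the standard
#' error reconstructed as `|beta| / qnorm(1 - pvalue / 2)`.
#'
#' @param path Path to the file.
#' @param column_map Named character vector mapping canonical field names
#'   (`rsid`, `chrom`, `effect_allele`, `other_allele`, `eaf`, `beta`,
#'   `se`, `pvalue`, `n`, or for odds-ratio files `or`, `ci_low`,
#'   `ci_high`) to column names in the file. Unmapped canonical names are
#'   taken verbatim when a column of that name exists.
#' @param trait_type `"quantitative"` or `"binary"`. Binary traits are
#'   stored on the log-odds scale.
#' @param trait Trait label attached to every row. Default: file name.
#' @param ci_level Confidence level of `ci_low`/`ci_high` columns when an
#'   odds-ratio map is used. Default 0.95.
#' @return A validated tibble of per-SNP associations (see
#'   [validate_sumstats()]).
#' @export
read_sumstats <- function(path, column_map = NULL,
                          trait_type = c("quantitative", "binary"),
                          trait = NULL, ci_level = 0.95) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) {
    abort(sprintf("Summary-statistics file not found: %s", path),
          class = "mrkit_io_error")
  }
  column_map <- as.list(column_map)
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)

  pick <- function(field) {
    src <- column_map[[field]] %||% field
    if (!src %in% names(raw)) return(NULL)
    raw[[src]]
  }
  if (length(column_map) > 0) {
    mapped <- unlist(column_map)
    absent <- mapped[!mapped %in% names(raw)]
    if (length(absent) > 0) {
      abort(sprintf("Column(s) named in `column_map` not present in %s: %s.",
                    path, paste(absent, collapse = ", ")),
            class = "mrkit_configuration_error")
    }
  }

  out <- tibble::tibble(
    rsid = as.character(pick("rsid") %||% abort(
      "No `rsid` column found; map it via `column_map`.",
      class = "mrkit_configuration_error")),
    chrom = as.character(pick("chrom") %||% NA_character_),
    effect_allele = toupper(as.character(pick("effect_allele") %||% NA_character_)),
    other_allele = toupper(as.character(pick("other_allele") %||% NA_character_)),
    eaf = as.numeric(pick("eaf") %||% NA_real_),
    pvalue = as.numeric(pick("pvalue") %||% NA_real_),
    n = as.numeric(pick("n") %||% NA_real_)
  )

  or_col <- pick("or")
  if (!is.null(or_col)) {
    lo <- pick("ci_low")
    hi <- pick("ci_high")
    if (is.null(lo) || is.null(hi)) {
      abort("Odds-ratio input needs `ci_low` and `ci_high` columns mapped alongside `or`.",
            class = "mrkit_configuration_error")
    }
    conv <- or_ci_to_logor(as.numeric(or_col), as.numeric(lo), as.numeric(hi),
                           level = ci_level)
    out$beta <- conv$logor
    out$se <- conv$se
  } else {
    out$beta <- as.numeric(pick("beta") %||% abort(
      "No `beta` (or `or`) column found; map it via `column_map`.",
      class = "mrkit_configuration_error"))
    se_col <- pick("se")
    if (is.null(se_col)) {
      if (all(is.na(out$pvalue))) {
        abort("Neither `se` nor `pvalue` available: cannot recover standard errors.",
              class = "mrkit_configuration_error")
      }
      out$se <- abs(out$beta) / qnorm(out$pvalue / 2, lower.tail = FALSE)
    } else {
      out$se <- as.numeric(se_col)
    }
  }
  if (all(is.na(out$pvalue))) {
    # floor at the smallest normal double so extreme z-scores stay in (0, 1]
    out$pvalue <- pmax(2 * pnorm(-abs(out$beta / out$se)),
                       .Machine$double.xmin)
  }
  out$trait <- trait %||% tools::file_path_sans_ext(basename(path))
  out$trait_type <- trait_type
  if (nrow(out) == 0) return(validate_sumstats(out[0, , drop = FALSE]))
  validate_sumstats(out)
}
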