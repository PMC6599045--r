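#' Run the primary MR analysis flow and assemble a report bundle
#'
#' Ties the pipeline stages together the way a drug-target MR study is
#' reported: the main fixed-effects IVW analysis of each outcome, an
#' optional restricted-instrument sensitivity analysis (e.g. only the
#' cis instrument, to probe pleiotropy), a leave-one-out table, analytic
#' power at a stated alternative, and forest-plot data. When `out_dir`
#' is given, per-instrument and pooled tables are written as TSV and the
#' whole bundle as JSON.
#'
#' @param exposure Exposure summary statistics: a data frame, or a file
#'   path read via [read_sumstats()].
#' @param outcomes A single outcome data frame (or path), or a named
#'   list of them.
#' @param sensitivity_snps Optional character vector of rsids for a
#'   restricted-instrument sensitivity analysis.
#' @param power_query Optional list with `n_cases`, `n_controls`, `r2`,
#'   `or_alt` (and optionally `alpha`) for an analytic power summary. If
#'   `r2` is omitted it is computed from the exposure records via
#'   [variance_explained()].
#' @param se_order,palindrome_eaf_window,level Passed to
#'   [mr_analysis()].
#' @param column_map,trait_type Used when `exposure`/`outcomes` are file
#'   paths; see [read_sumstats()].
#' @param out_dir Optional output directory for TSV/JSON reports.
#' @return A list of class `mr_report`: `main` (named list of
#'   `mr_result`s), `sensitivity` (named list of `mr_result`s or
#'   `NULL`), `leave_one_out` (named list of tibbles), `forest` (named
#'   list of forest tibbles), `power` (one-row tibble or `NULL`), and
#'   `files` (paths written, if any).
#' @export
run_primary_analysis <- function(exposure, outcomes,
                                 sensitivity_snps = NULL,
                                 power_query = NULL,
                                 se_order = c("first", "second"),
                                 palindrome_eaf_window = 0.08,
                                 level = 0.95,
                                 column_map = NULL,
                                 trait_type = "binary",
                                 out_dir = NULL) {
  se_order <- match.arg(se_order)
  load_stats <- function(x, type) {
    if (is.character(x)) read_sumstats(x, column_map = column_map,
                                       trait_type = type)
    else validate_sumstats(x)
  }
  exposure <- load_stats(exposure, "quantitative")
  if (is.data.frame(outcomes) || is.character(outcomes)) {
    outcomes <- list(outcome = outcomes)
  }
  if (is.null(names(outcomes)) || any(names(outcomes) == "")) {
    names(outcomes) <- paste0("outcome", seq_along(outcomes))
  }
  outcomes <- purrr::map(outcomes, load_stats, type = trait_type)

  main <- purrr::map(outcomes, function(out) {
    mr_analysis(exposure, out, se_order = se_order,
                palindrome_eaf_window = palindrome_eaf_window,
                level = level)
  })
  sensitivity <- if (!is.null(sensitivity_snps)) {
    purrr::map(outcomes, function(out) {
      mr_analysis(exposure, out, snps = sensitivity_snps,
                  se_order = se_order,
                  palindrome_eaf_window = palindrome_eaf_window,
                  level = level)
    })
  }
  loo <- purrr::map(main, function(fit) {
    if (fit$pooled$k >= 2) {
      leave_one_out_from(fit, level = level)
    }
  })
  forest <- purrr::map(main, function(fit) {
    make_forest_data(fit$estimates, fit$pooled)
  })
  power <- if (!is.null(power_query)) {
    q <- power_query
    r2 <- q$r2 %||% sum(variance_explained(exposure$eaf, exposure$beta))
    alpha <- q$alpha %||% 0.05
    p <- mr_power_binary(q$n_cases, q$n_controls, r2, q$or_alt, alpha)
    tibble::tibble(n_cases = q$n_cases, n_controls = q$n_controls,
                   r2 = r2, or_alt = q$or_alt, alpha = alpha,
                   power = p, power_percent = round(100 * p))
  }

  files <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (label in names(main)) {
      est_path <- file.path(out_dir, paste0(label, "_instruments.tsv"))
      pooled_path <- file.path(out_dir, paste0(label, "_pooled.tsv"))
      readr::write_tsv(main[[label]]$estimates, est_path)
      readr::write_tsv(main[[label]]$pooled, pooled_path)
      files <- c(files, est_path, pooled_path)
    }
    json_path <- file.path(out_dir, "report.json")
    jsonlite::write_json(
      list(
        main = purrr::map(main, function(f)
          list(estimates = f$estimates, pooled = f$pooled)),
        sensitivity = purrr::map(sensitivity %||% list(), function(f)
          list(estimates = f$estimates, pooled = f$pooled)),
        power = power
      ),
      json_path, auto_unbox = TRUE, digits = NA, na = "null")
    files <- c(files, json_path)
  }

  structure(
    list(main = main, sensitivity = sensitivity, leave_one_out = loo,
         forest = forest, power = power, files = files),
    class = "mr_report"
  )
}

# leave-one-out recomputed from an existing fit's per-SNP estimates
leave_one_out_from <- function(fit, level = 0.95) {
  estimates <- fit$estimates
  full <- fit$pooled
  rows <- purrr::map(seq_len(nrow(estimates)), function(i) {
    res <- ivw_fixed(estimates[-i, ], level = level)
    dplyr::bind_cols(tibble::tibble(omitted = estimates$rsid[i]), res)
  })
  out <- dplyr::bind_rows(rows)
  out$sign_change <- sign(out$theta_pooled) != sign(full$theta_pooled) &
    out$theta_pooled != 0
  out
}

#' @export
print.mr_report <- function(x, ...) {
  for (label in names(x$main)) {
    cat(sprintf("== %s ==\n", label))
    print(x$main[[label]])
    if (!is.null(x$sensitivity[[label]])) {
      cat(sprintf("-- sensitivity (instruments: %s) --\n",
                  paste(x$sensitivity[[label]]$estimates$rsid,
                        collapse = ", ")))
      print(x$sensitivity[[label]])
    }
  }
  if (!is.null(x$power)) {
    cat(sprintf("Power: %.0f%% to detect OR %.2f per SD (R2 = %.3f, alpha = %.2g)\n",
                x$power$power_percent, x$power$or_alt, x$power$r2,
                x$power$alpha))
  }
  invisible(x)
}
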