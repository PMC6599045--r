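#' Tidy a two-sample MR fit into per-instrument rows
#'
#' @param x An `mr_result` from [mr_analysis()].
#' @param ... Unused.
#' @return A tibble with one row per instrument and one summary row
#'   (`term == "IVW (fixed effects)"`), in forest-plot order.
#' @exportS3Method generics::tidy
tidy.mr_result <- function(x, ...) {
  make_forest_data(x$estimates, x$pooled) |>
    dplyr::rename(term = "label")
}

#' One-row summary of a two-sample MR fit
#'
#' @param x An `mr_result` from [mr_analysis()].
#' @param ... Unused.
#' @return The pooled one-row tibble from [ivw_fixed()].
#' @exportS3Method generics::glance
glance.mr_result <- function(x, ...) {
  x$pooled
}

#' Forest-plot-ready table from per-instrument and pooled estimates
#'
#' @param per_snp Per-instrument Wald tibble ([wald_ratio()]).
#' @param pooled One-row pooled tibble ([ivw_fixed()]).
#' @return A tibble with columns `label`, `or`, `ci_low`, `ci_high`,
#'   `pvalue`, `weight_share` (inverse-variance weight fraction, summing
#'   to 1 over instruments) and `is_summary`.
#' @export
make_forest_data <- function(per_snp, pooled) {
  if (nrow(per_snp) == 0) {
    abort("Need at least one per-instrument estimate.",
          class = "mrkit_input_error")
  }
  w <- 1 / per_snp$se_theta^2
  dplyr::bind_rows(
    tibble::tibble(
      label = per_snp$rsid,
      or = per_snp$or_point,
      ci_low = per_snp$ci_low,
      ci_high = per_snp$ci_high,
      pvalue = per_snp$pvalue,
      weight_share = w / sum(w),
      is_summary = FALSE
    ),
    tibble::tibble(
      label = "IVW (fixed effects)",
      or = pooled$or_point,
      ci_low = pooled$ci_low,
      ci_high = pooled$ci_high,
      pvalue = pooled$pvalue,
      weight_share = NA_real_,
      is_summary = TRUE
    )
  )
}

#' Forest plot of a two-sample MR fit
#'
#' Per-instrument odds ratios with confidence bars (box area proportional
#' to inverse-variance weight) and the pooled fixed-effects estimate as a
#' summary diamond row.
#'
#' @param object An `mr_result` from [mr_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mr_result <- function(object, ...) {
  dat <- make_forest_data(object$estimates, object$pooled)
  dat$label <- factor(dat$label, levels = rev(dat$label))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$or, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      height = 0.15) +
    ggplot2::geom_point(
      ggplot2::aes(size = .data$weight_share,
                   shape = .data$is_summary,
                   colour = .data$is_summary)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 15, `TRUE` = 18),
                                guide = "none") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::scale_size_area(max_size = 5, guide = "none", na.value = 5) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = sprintf("Odds ratio of %s per SD of %s (log scale)",
                  object$outcome_trait, object$exposure_trait),
      y = NULL) +
    ggplot2::theme_minimal()
}
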