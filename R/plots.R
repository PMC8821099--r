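# ggplot2 graphics for the main result types

#' @exportS3Method ggplot2::autoplot
autoplot.alps_cohort <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$arm, y = .data$alps, fill = .data$arm)) +
    ggplot2::geom_boxplot(width = 0.5, outlier.shape = NA, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.1, size = 1, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "DTI-ALPS index") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.alps_stats_report <- function(object, ...) {
  cmp <- object$comparison
  cmp$neglog_p <- -log10(pmax(cmp$p.value, 1e-300))
  ggplot2::ggplot(cmp, ggplot2::aes(x = stats::reorder(.data$variable, .data$neglog_p),
                                    y = .data$neglog_p, fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(object$alpha), linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(object$correction$alpha_adjusted), linetype = 3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(-log[10](p)),
                  fill = "significant",
                  caption = "dashed: uncorrected alpha; dotted: Bonferroni-adjusted") +
    ggplot2::theme_minimal()
}

#' Scatter plot of the ALPS index against a clinical variable
#'
#' @param cohort A cohort tibble with `alps` filled.
#' @param variable Clinical variable name (default `"pth"`).
#' @return A ggplot.
#' @export
plot_alps_scatter <- function(cohort, variable = "pth") {
  if (!variable %in% names(cohort)) abort_input(sprintf("No column `%s` in cohort.", variable))
  d <- cohort[!is.na(cohort[[variable]]), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[variable]], y = .data$alps)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE, color = "steelblue") +
    ggplot2::labs(x = variable, y = "DTI-ALPS index") +
    ggplot2::theme_minimal()
}
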