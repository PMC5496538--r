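#' Bar chart of proportions with exact binomial confidence intervals
#'
#' Draws the standard figure of the survey and monitoring analyses: per
#' group, the observed proportion as a bar with its Clopper-Pearson
#' interval as an (asymmetric) error bar.
#'
#' @param data A tibble with `estimate`, `lower`, `upper` columns, as
#'   produced by [add_binom_ci()] or found in report proportion blocks.
#' @param x Column mapped to the x axis (tidy-eval), e.g. `sex`.
#' @param fill Optional column mapped to fill.
#' @param facet Optional column to facet by, e.g. `population`.
#' @return A ggplot object.
#' @examples
#' survey <- simulate_survey(sim_config(n_units = 60, n_populations = 3))
#' props <- survey |>
#'   dplyr::group_by(population, sex) |>
#'   dplyr::summarise(k = sum(eggs > 0), n = dplyr::n(), .groups = "drop") |>
#'   add_binom_ci(k, n)
#' plot_proportions(props, sex, facet = population)
#' @export
plot_proportions <- function(data, x, fill = NULL, facet = NULL) {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = {{ x }}, y = .data$estimate,
                                          fill = {{ fill }})) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower,
                                        ymax = .data$upper),
                           width = 0.15) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(y = "proportion (95% exact binomial CI)") +
    ggplot2::theme_minimal()
  facet_quo <- rlang::enquo(facet)
  if (!rlang::quo_is_null(facet_quo)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(!!facet_quo))
  }
  p
}

#' Plot a permutation null distribution
#'
#' Histogram of the permutation null with the observed statistic marked.
#'
#' @param object An `"ovb_perm"` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.ovb_perm <- function(object, ...) {
  df <- if (!is.null(object$null_pmf)) {
    tibble::tibble(value = object$null_pmf$value,
                   weight = object$null_pmf$prob)
  } else {
    tibble::tibble(value = object$null_stats,
                   weight = 1 / length(object$null_stats))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value,
                                   weight = .data$weight)) +
    ggplot2::geom_histogram(bins = min(50, length(unique(df$value))),
                            fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed_stat,
                        colour = "firebrick", linewidth = 1) +
    ggplot2::labs(
      x = object$statistic, y = "null probability",
      subtitle = sprintf("observed = %.3g; two-tailed p = %.3g (%s)",
                         object$observed_stat, object$p_two_tailed,
                         if (object$exact) "exact" else
                           sprintf("B = %d", object$B))
    ) +
    ggplot2::theme_minimal()
}
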