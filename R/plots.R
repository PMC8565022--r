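# ggplot2 figures for elicited-value summaries.

#' Scatter of per-state SG vs RS means with a LOWESS smooth
#'
#' One point per health state (mean RS value against mean SG utility) with
#' the robust locally weighted regression line and the identity line for
#' reference; SG means sitting above the diagonal visualise the systematic
#' SG > RS pattern.
#'
#' @param table3 A summary table as from [build_table3()] or
#'   [read_table3_fixture()].
#' @param span LOWESS span passed to [lowess_fit()].
#' @return A ggplot object.
#' @examples
#' plot_method_correlation(read_table3_fixture())
#' @export
plot_method_correlation <- function(table3, span = 2 / 3) {
  wide <- table3 %>%
    select(all_of(c("state_id", "method", "mean"))) %>%
    tidyr::pivot_wider(names_from = "method", values_from = "mean")
  wide$smooth <- lowess_fit(wide$RS, wide$SG, span = span)
  ggplot2::ggplot(wide, ggplot2::aes(x = .data$RS, y = .data$SG)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_line(ggplot2::aes(y = .data$smooth), colour = "#2c7fb8") +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Mean RS value", y = "Mean SG utility",
                  title = "Rating scale vs standard gamble, by health state",
                  subtitle = "Line: robust LOWESS; dotted: identity") +
    ggplot2::theme_minimal()
}

#' Distribution of elicited values by state and method
#'
#' Boxplots of the raw elicited utilities per state, split by method; makes
#' the near-degenerate SG distributions (medians at 1) visible next to the
#' spread-out RS values.
#'
#' @param records A tibble of UC records.
#' @return A ggplot object.
#' @export
plot_state_distributions <- function(records) {
  validate_uc_records(records)
  df <- filter(records, .data$method %in% c("SG", "RS"))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$state_id),
                                   y = .data$value,
                                   fill = .data$method)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, linewidth = 0.3) +
    ggplot2::labs(x = "Health state", y = "Elicited utility",
                  fill = "Method") +
    ggplot2::theme_minimal()
}

#' Plot a ranking concordance as a slope chart
#'
#' @param object A [rank_concordance()] object.
#' @param ... Unused.
#' @return A ggplot object connecting each state's rank under the two
#'   orderings; crossing segments are the discordant states.
#' @method autoplot rank_concordance
#' @export
autoplot.rank_concordance <- function(object, ...) {
  td <- tidy(object)
  long <- tibble(
    state = c(td$state_a, td$state_b),
    side = rep(c("A", "B"), each = nrow(td)),
    order = rep(td$order, 2)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$side, y = .data$order,
                                     group = .data$state)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_text(ggplot2::aes(label = .data$state), size = 3) +
    ggplot2::scale_y_reverse(breaks = td$order) +
    ggplot2::labs(x = NULL, y = "Rank (worst state first)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
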