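# Study summary tables: per-state descriptives, method rankings, and the
# cross-study comparison with the North-American comparator values.

#' Bundled per-state summary statistics
#'
#' The published per-state summaries of the 47-respondent study: mean, SD
#' and five-number summary of the SG-elicited utilities and RS values for
#' each of the 18 states (values as printed, 3 decimals).
#'
#' @return A tibble with columns `state_id`, `method`, `mean`, `sd`, `max`,
#'   `min`, `median`, `q1`, `q3` (36 rows).
#' @export
read_table3_fixture <- function() {
  readr::read_csv(
    utilicit_example("table3_summary.csv"),
    col_types = readr::cols(
      state_id = readr::col_integer(),
      method = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
}

#' Bundled comparator utilities (North-American study)
#'
#' SG means and 95% CIs for the same health states elicited from a
#' North-American population in an earlier study; state 11 (post-operative
#' hemorrhages) was not valued there and is `NA`.
#'
#' @return A tibble with columns `state_id`, `mean`, `ci_low`, `ci_high`.
#' @export
read_dealmeida_fixture <- function() {
  readr::read_csv(
    utilicit_example("table5_dealmeida.csv"),
    col_types = readr::cols(
      state_id = readr::col_integer(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
}

#' Per-state, per-method summary table
#'
#' Builds the descriptive-statistics table of a repository: one row per
#' (state, method), SG block first, values rounded to 3 decimals to match
#' the reporting convention.
#'
#' @param records A tibble of UC records covering every state of the
#'   catalog for both SG and RS.
#' @param states Health-state catalog (used to check coverage); defaults to
#'   the bundled 18 states.
#' @param digits Rounding applied to the statistics (`NULL` for none).
#' @return A tibble shaped like [read_table3_fixture()].
#' @examples
#' sim <- simulate_study(n = 5, seed = 1)
#' build_table3(sim$records)
#' @export
build_table3 <- function(records, states = load_state_catalog(), digits = 3) {
  validate_uc_records(records)
  methods <- c("SG", "RS")
  for (m in methods) {
    covered <- unique(records$state_id[records$method == m])
    absent <- setdiff(states$state_id, covered)
    if (length(absent) > 0L) {
      abort_validation("No %s records for state(s): %s.", m,
                       paste(absent, collapse = ", "))
    }
  }
  out <- records %>%
    filter(.data$method %in% methods) %>%
    group_by(.data$state_id, .data$method) %>%
    dplyr::reframe(summarize_values(.data$value)) %>%
    mutate(method = factor(.data$method, levels = methods)) %>%
    arrange(.data$method, .data$state_id) %>%
    mutate(method = as.character(.data$method)) %>%
    select(all_of(c("state_id", "method", "mean", "sd", "max", "min",
                    "median", "q1", "q3")))
  if (!is.null(digits)) {
    out <- mutate(out, across(all_of(c("mean", "sd", "max", "min", "median",
                                       "q1", "q3")),
                              ~ round(.x, digits)))
  }
  out
}

#' Method-ranking comparison table
#'
#' Orders the states from worst to best separately by mean SG utility and
#' mean RS value and lays the two rankings side by side, flagging positions
#' where they disagree.
#'
#' @param table3 A summary table as from [build_table3()] or
#'   [read_table3_fixture()].
#' @param states Catalog supplying labels.
#' @return A tibble with columns `order`, `sg_state_id`, `sg_label`,
#'   `rs_state_id`, `rs_label`, `same_state`, plus the
#'   [rank_concordance()] object as attribute `"concordance"`.
#' @export
build_table4 <- function(table3, states = load_state_catalog()) {
  order_sg <- rank_states(filter(table3, .data$method == "SG"))
  order_rs <- rank_states(filter(table3, .data$method == "RS"))
  rc <- rank_concordance(order_sg, order_rs)
  labels <- stats::setNames(states$label, states$state_id)
  out <- tibble(
    order = seq_along(order_sg),
    sg_state_id = order_sg,
    sg_label = unname(labels[as.character(order_sg)]),
    rs_state_id = order_rs,
    rs_label = unname(labels[as.character(order_rs)]),
    same_state = order_sg == order_rs
  )
  attr(out, "concordance") <- rc
  out
}

#' Cross-study comparison table
#'
#' Puts the present study's SG means with normal-approximation 95%
#' confidence intervals next to the comparator study's published means and
#' CIs, rounded to 2 decimals. States missing from the comparator render as
#' `NA`.
#'
#' @param table3 A summary table (`SG` rows are used).
#' @param n Number of respondents behind the summary means (47 in the
#'   study).
#' @param comparator Comparator tibble as from [read_dealmeida_fixture()].
#' @param states Catalog supplying labels.
#' @param digits Rounding for the present-study columns.
#' @return A tibble with columns `state_id`, `label`, `comparator_mean`,
#'   `comparator_low`, `comparator_high`, `mean`, `low`, `high`.
#' @examples
#' build_table5(read_table3_fixture(), n = 47)
#' @export
build_table5 <- function(table3, n, comparator = read_dealmeida_fixture(),
                         states = load_state_catalog(), digits = 2) {
  sg <- filter(table3, .data$method == "SG")
  absent <- setdiff(states$state_id, sg$state_id)
  if (length(absent) > 0L) {
    abort_validation("Summary table lacks SG rows for state(s): %s.",
                     paste(absent, collapse = ", "))
  }
  ci <- mean_ci(sg$mean, sg$sd, n)
  present <- tibble(
    state_id = sg$state_id,
    mean = round(ci$mean, digits),
    low = round(ci$low, digits),
    high = round(ci$high, digits)
  )
  states %>%
    select(all_of(c("state_id", "label"))) %>%
    left_join(
      rename(comparator, comparator_mean = "mean", comparator_low = "ci_low",
             comparator_high = "ci_high"),
      by = "state_id"
    ) %>%
    left_join(present, by = "state_id")
}
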