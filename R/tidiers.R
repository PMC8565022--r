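# broom-style tidiers for the package's result objects.

#' Tidy a ranking concordance
#'
#' @param x A [rank_concordance()] object.
#' @param ... Unused.
#' @return One row per rank position: `order`, `state_a`, `state_b`,
#'   `same_state`.
#' @method tidy rank_concordance
#' @export
tidy.rank_concordance <- function(x, ...) {
  tibble(
    order = seq_along(x$order_a),
    state_a = x$order_a,
    state_b = x$order_b,
    same_state = x$order_a == x$order_b
  )
}

#' Glance at a ranking concordance
#'
#' @param x A [rank_concordance()] object.
#' @param ... Unused.
#' @return A one-row tibble: `n_states`, `n_same_position`,
#'   `common_prefix_len`, `common_suffix_len`.
#' @method glance rank_concordance
#' @export
glance.rank_concordance <- function(x, ...) {
  tibble(
    n_states = length(x$order_a),
    n_same_position = x$n_same_position,
    common_prefix_len = x$common_prefix_len,
    common_suffix_len = x$common_suffix_len
  )
}

#' Tidy a standard-gamble session
#'
#' @param x An `sg_session`.
#' @param ... Unused.
#' @return The titration history, one row per question: `step`, `p`,
#'   `answer`.
#' @method tidy sg_session
#' @export
tidy.sg_session <- function(x, ...) {
  tibble(step = seq_along(x$history$p), p = x$history$p,
         answer = x$history$answer)
}

#' Glance at a standard-gamble session
#'
#' @param x An `sg_session`.
#' @param ... Unused.
#' @return A one-row tibble: `state_id`, `status`, `n_steps`, `p_low`,
#'   `p_high`, `utility` (`NA` while active).
#' @method glance sg_session
#' @export
glance.sg_session <- function(x, ...) {
  tibble(
    state_id = x$state_id,
    status = x$status,
    n_steps = length(x$history$p),
    p_low = x$p_low,
    p_high = x$p_high,
    utility = if (x$status == "active") NA_real_ else sg_utility(x)
  )
}
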