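# Elicitation procedures: rating scale, standard-gamble titration state
# machine, and time trade-off.

#' Elicitation protocol parameters
#'
#' @param tolerance Bracket width (probability) at which standard-gamble
#'   titration stops. The default 0.01 matches the one-point granularity of
#'   the 0-100 rating scale.
#' @param max_steps Hard cap on titration questions per state.
#' @param rs_first Ask the rating-scale question before the gamble and seed
#'   the first proposed risk with `1 - UCrs` (the protocol used in the
#'   study; shortens titration).
#' @param seed Optional integer seed recorded for provenance.
#' @return An object of class `elicitation_config`.
#' @export
elicitation_config <- function(tolerance = 0.01, max_steps = 30L,
                               rs_first = TRUE, seed = NULL) {
  check_number(tolerance, "tolerance")
  if (tolerance <= 0 || tolerance >= 1) {
    abort_validation("`tolerance` must lie strictly between 0 and 1.")
  }
  check_number(max_steps, "max_steps", lower = 1)
  structure(
    list(tolerance = tolerance, max_steps = as.integer(max_steps),
         rs_first = isTRUE(rs_first), seed = seed),
    class = "elicitation_config"
  )
}

#' Rating-scale elicitation
#'
#' Converts a direct rating on the 0-100 scale (0 = death, 100 = perfect
#' health) to a utility value by normalising to \[0, 1\]. Rating-scale
#' values are not utilities in the decision-theoretic sense (no uncertainty
#' is involved) but serve as comparators and as the starting point for the
#' standard gamble.
#'
#' @param response Numeric rating(s) in \[0, 100\].
#' @return Utility value(s) in \[0, 1\].
#' @examples
#' rs_elicit(50)
#' rs_elicit(c(0, 76.3, 100))
#' @export
rs_elicit <- function(response) {
  if (!is.numeric(response) || any(!is.finite(response))) {
    abort_validation("`response` must be finite numeric rating(s).")
  }
  if (any(response < 0 | response > 100)) {
    abort_validation("Rating-scale responses must lie in [0, 100].")
  }
  response / 100
}

#' Start a standard-gamble titration session
#'
#' The standard gamble offers a choice between remaining in the sub-optimal
#' state for sure and a treatment that restores perfect health but carries a
#' probability `p` of immediate death. `p` is titrated by bisection until
#' the respondent is indifferent; the utility is `1 - p` at that point.
#' The first proposed risk is `1 - rs_utility`, clamped away from the
#' degenerate endpoints 0 and 1 (a zero-risk gamble carries no information),
#' with the bracket initialised to \[0, 1\].
#'
#' @param rs_utility The respondent's rating-scale utility for the same
#'   state, in \[0, 1\].
#' @param config An [elicitation_config()].
#' @param state_id Optional state identifier carried through to records.
#' @return An `sg_session` object (status `"active"`).
#' @examples
#' s <- sg_start(0.546)
#' s$p_current
#' @export
sg_start <- function(rs_utility, config = elicitation_config(),
                     state_id = NA_integer_) {
  check_number(rs_utility, "rs_utility", 0, 1)
  p0 <- min(max(1 - rs_utility, config$tolerance), 1 - config$tolerance)
  structure(
    list(
      state_id = state_id,
      p_current = p0,
      p_low = 0,
      p_high = 1,
      p_star = NA_real_,
      history = list(p = double(), answer = character()),
      status = "active",
      tolerance = config$tolerance,
      max_steps = config$max_steps
    ),
    class = "sg_session"
  )
}

#' Advance a standard-gamble session by one answer
#'
#' Records the respondent's answer to the currently proposed risk and
#' updates the bracket: accepting the gamble at risk `p` implies the
#' indifference risk is at least `p` (`p_low <- p`); rejecting implies it is
#' at most `p` (`p_high <- p`). The next proposal is the bracket midpoint.
#' The session converges on an explicit `"indifferent"` answer, when the
#' bracket closes to within `tolerance`, or at `max_steps`;
#' `"refuse_any_risk"` is only admissible as the answer to the first
#' proposal and marks the whole gamble as refused.
#'
#' @param session An active `sg_session`.
#' @param answer One of `"accept"`, `"reject"`, `"indifferent"`,
#'   `"refuse_any_risk"`.
#' @return The updated `sg_session`.
#' @export
sg_step <- function(session, answer) {
  stopifnot(inherits(session, "sg_session"))
  if (session$status != "active") {
    abort_state("Cannot step a session with status '%s'.", session$status)
  }
  answer <- arg_match0(answer,
                       c("accept", "reject", "indifferent", "refuse_any_risk"))
  step_i <- length(session$history$p) + 1L
  session$history$p <- c(session$history$p, session$p_current)
  session$history$answer <- c(session$history$answer, answer)
  if (answer == "refuse_any_risk") {
    if (step_i != 1L) {
      abort_state("A gamble can only be refused outright at the first proposal.")
    }
    session$status <- "refused"
    return(session)
  }
  if (answer == "indifferent") {
    session$p_star <- session$p_current
    session$status <- "converged"
    return(session)
  }
  if (answer == "accept") {
    session$p_low <- session$p_current
  } else {
    session$p_high <- session$p_current
  }
  if (session$p_high - session$p_low <= session$tolerance ||
      step_i >= session$max_steps) {
    session$p_star <- (session$p_low + session$p_high) / 2
    session$status <- "converged"
    return(session)
  }
  session$p_current <- (session$p_low + session$p_high) / 2
  session
}

#' Utility from a finished standard-gamble session
#'
#' A refused gamble means the respondent would not trade the state against
#' any risk of death, so its utility is 1. Otherwise the utility is
#' `1 - p*`, where `p*` is the risk at the explicit indifference answer or
#' the midpoint of the final bracket.
#'
#' @param session A `sg_session` with status `"refused"` or `"converged"`.
#' @return A utility in \[0, 1\].
#' @export
sg_utility <- function(session) {
  stopifnot(inherits(session, "sg_session"))
  if (session$status == "active") {
    abort_state("Session is still active; no utility available yet.")
  }
  if (session$status == "refused") return(1)
  1 - session$p_star
}

#' @export
print.sg_session <- function(x, ...) {
  cat(sprintf(
    "<sg_session> state %s | status: %s | bracket [%.4f, %.4f] | %d question(s)\n",
    format(x$state_id), x$status, x$p_low, x$p_high, length(x$history$p)))
  if (x$status != "active") {
    cat(sprintf("  elicited utility: %.4f\n", sg_utility(x)))
  }
  invisible(x)
}

#' Time-trade-off utility
#'
#' The respondent trades remaining lifespan in the sub-optimal state
#' (`t_full` years) against a shorter life (`t_traded` years) in perfect
#' health; at indifference the utility is `t_traded / t_full`.
#'
#' @param t_full Full remaining lifespan in the state, years > 0.
#' @param t_traded Equivalent lifespan in perfect health, `0 <= t_traded <=
#'   t_full`.
#' @return Utility `t_traded / t_full`.
#' @examples
#' tto_utility(10, 8)
#' @export
tto_utility <- function(t_full, t_traded) {
  if (!is.numeric(t_full) || !is.numeric(t_traded) ||
      any(!is.finite(t_full)) || any(!is.finite(t_traded))) {
    abort_validation("Times must be finite numbers.")
  }
  if (any(t_full <= 0)) abort_validation("`t_full` must be > 0.")
  if (any(t_traded < 0) || any(t_traded > t_full)) {
    abort_validation("`t_traded` must lie in [0, t_full].")
  }
  t_traded / t_full
}

#' Run a full two-question interview over a state catalog
#'
#' For every state in the catalog the provider is asked the rating-scale
#' question and then taken through a standard-gamble titration seeded with
#' its own rating (`p0 = 1 - UCrs`), yielding exactly two records (one RS,
#' one SG) per state.
#'
#' @param respondent An answer provider: a list with functions
#'   `rs(state)` returning a 0-100 rating and `sg(state, p, step)` returning
#'   one of `"accept"`, `"reject"`, `"indifferent"`, `"refuse_any_risk"`,
#'   plus an optional `respondent_id`. [synthetic_respondent()] builds one.
#' @param states A health-state catalog tibble ([load_state_catalog()]).
#' @param config An [elicitation_config()].
#' @return A tibble of UC records, `2 * nrow(states)` rows. If the provider
#'   errors mid-interview the records collected so far are returned with
#'   attribute `interview_error` carrying the condition message.
#' @examples
#' always_50 <- list(
#'   respondent_id = "demo",
#'   rs = function(state) 50,
#'   sg = function(state, p, step) if (p > 0.25) "reject" else "indifferent"
#' )
#' run_interview(always_50, load_state_catalog()[1:2, ])
#' @export
run_interview <- function(respondent, states, config = elicitation_config()) {
  stopifnot(is.list(respondent), is.function(respondent$rs),
            is.function(respondent$sg))
  rid <- respondent$respondent_id %||% "anonymous"
  out <- vector("list", nrow(states) * 2L)
  err <- NULL
  for (i in seq_len(nrow(states))) {
    state <- states[i, ]
    res <- tryCatch({
      rating <- respondent$rs(state)
      uc_rs <- rs_elicit(rating)
      session <- sg_start(uc_rs, config, state_id = state$state_id)
      while (session$status == "active") {
        ans <- respondent$sg(state, session$p_current,
                             length(session$history$p) + 1L)
        session <- sg_step(session, ans)
      }
      list(
        tibble(respondent_id = rid, state_id = state$state_id,
               method = "RS", value = uc_rs, n_steps = 0L,
               refused_gamble = FALSE),
        tibble(respondent_id = rid, state_id = state$state_id,
               method = "SG", value = sg_utility(session),
               n_steps = length(session$history$p),
               refused_gamble = session$status == "refused")
      )
    }, error = function(e) e)
    if (inherits(res, "error")) {
      err <- conditionMessage(res)
      break
    }
    out[[2L * i - 1L]] <- res[[1L]]
    out[[2L * i]] <- res[[2L]]
  }
  records <- bind_rows(out[!vapply(out, is.null, logical(1))])
  if (!is.null(err)) {
    warn(sprintf("Interview for '%s' aborted: %s (partial results returned).",
                 rid, err))
    attr(records, "interview_error") <- err
  }
  records
}
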