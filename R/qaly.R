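# Quality-adjusted life years from utility-weighted survival segments.

#' Quality-adjusted life years of a health profile
#'
#' A profile splits expected survival into ordered segments, each spent in
#' one health state: `duration` years weighted by that state's utility
#' coefficient. Undiscounted QALYs are the weighted sum
#' `sum(duration * utility)`. With a positive continuous discount rate `r`,
#' a segment running from calendar time `t0` for `T` years contributes
#' `utility * exp(-r * t0) * (1 - exp(-r * T)) / r` (segments are taken in
#' row order from time 0).
#'
#' @param segments A data frame with numeric columns `duration` (years,
#'   >= 0) and `utility` (in \[0, 1\]); extra columns (e.g. `state_id`) are
#'   ignored.
#' @param discount_rate Per-year continuous discount rate >= 0; the default
#'   0 gives the plain weighted sum.
#' @return QALYs (years), a single number.
#' @examples
#' compute_qalys(data.frame(duration = c(2, 3), utility = c(0.9, 0.5)))
#' @export
compute_qalys <- function(segments, discount_rate = 0) {
  if (!is.data.frame(segments) ||
      !all(c("duration", "utility") %in% names(segments))) {
    abort_validation("`segments` needs numeric columns `duration` and `utility`.")
  }
  d <- segments$duration
  u <- segments$utility
  if (any(!is.finite(d)) || any(d < 0)) {
    abort_validation("Segment durations must be finite and >= 0.")
  }
  if (any(!is.finite(u)) || any(u < 0) || any(u > 1)) {
    abort_validation("Segment utilities must lie in [0, 1].")
  }
  check_number(discount_rate, "discount_rate", lower = 0)
  if (nrow(segments) == 0L) return(0)
  if (discount_rate == 0) return(sum(d * u))
  t0 <- cumsum(c(0, d))[seq_along(d)]
  r <- discount_rate
  sum(u * exp(-r * t0) * (1 - exp(-r * d)) / r)
}

#' Incremental QALYs between two profiles
#'
#' `compute_qalys(profile_a) - compute_qalys(profile_b)` under a common
#' discount rate; positive when profile A accrues more quality-adjusted
#' survival.
#'
#' @param profile_a,profile_b Segment data frames as for [compute_qalys()].
#' @param discount_rate Per-year continuous discount rate >= 0.
#' @return Incremental QALYs (years).
#' @export
qaly_difference <- function(profile_a, profile_b, discount_rate = 0) {
  compute_qalys(profile_a, discount_rate) -
    compute_qalys(profile_b, discount_rate)
}
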