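# A-priori sample size for estimating a mean utility to a target margin of
# error.

#' Half-width of the confidence interval achievable at a given sample size
#'
#' `q * sd / sqrt(n)`, with `q` the two-sided t quantile on `n - 1` degrees
#' of freedom (default) or the normal quantile. Monotone decreasing in `n`.
#'
#' @param n Sample size (>= 2, vectorised).
#' @param sd Assumed standard deviation of the utility values.
#' @param confidence Confidence level in (0, 1).
#' @param method `"t"` (default) or `"z"`.
#' @return Margin(s) of error on the utility scale.
#' @examples
#' achieved_margin(38, sd = 0.15)
#' @export
achieved_margin <- function(n, sd, confidence = 0.95, method = c("t", "z")) {
  method <- match.arg(method)
  if (any(n < 2)) abort_validation("`n` must be >= 2.")
  check_number(sd, "sd")
  if (sd <= 0) abort_validation("`sd` must be > 0.")
  check_number(confidence, "confidence")
  if (confidence <= 0 || confidence >= 1) {
    abort_validation("`confidence` must lie strictly between 0 and 1.")
  }
  alpha <- 1 - confidence
  q <- if (method == "t") qt(1 - alpha / 2, df = n - 1) else qnorm(1 - alpha / 2)
  q * sd / sqrt(n)
}

#' Minimum sample size for a target margin of error
#'
#' Smallest `n >= 2` whose achieved confidence-interval half-width does not
#' exceed the target margin. The default iterative t-based criterion finds
#' the smallest `n` with `t(1 - alpha/2, n - 1) * sd / sqrt(n) <= margin`;
#' with margin 0.05, SD 0.15 and 95% confidence this gives 38 respondents.
#' The closed-form normal approximation `ceiling((z * sd / margin)^2)`
#' (method `"z"`) gives 35 for the same inputs — it ignores the estimation
#' of the SD and is offered for comparison.
#'
#' @param margin Target margin of error (> 0) on the utility scale.
#' @param sd Assumed standard deviation.
#' @param confidence Confidence level in (0, 1).
#' @param method `"t"` (iterative, default) or `"z"` (closed form).
#' @param n_max Search cap for the iterative criterion.
#' @return Integer sample size.
#' @examples
#' min_sample_size(margin = 0.05, sd = 0.15, confidence = 0.95)
#' @export
min_sample_size <- function(margin, sd, confidence = 0.95,
                            method = c("t", "z"), n_max = 1e6) {
  method <- match.arg(method)
  check_number(margin, "margin")
  if (margin <= 0) abort_validation("`margin` must be > 0.")
  if (method == "z") {
    z <- qnorm(1 - (1 - confidence) / 2)
    return(max(2L, as.integer(ceiling((z * sd / margin)^2))))
  }
  n <- 2L
  while (achieved_margin(n, sd, confidence) > margin) {
    n <- n + 1L
    if (n > n_max) {
      abort_validation("No n <= %g achieves margin %g.", n_max, margin)
    }
  }
  n
}
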