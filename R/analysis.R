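# Descriptive and comparative analysis of elicited utilities.

#' Descriptive summary of a set of utilities
#'
#' Mean, sample (n-1) standard deviation and the five-number quantile
#' summary of a utility vector, with quartiles by linear interpolation
#' between order statistics (`stats::quantile()` type 7).
#'
#' @param values Non-empty numeric vector of utilities.
#' @return A one-row tibble: `n`, `mean`, `sd`, `min`, `q1`, `median`, `q3`,
#'   `max`.
#' @examples
#' summarize_values(c(0, 0.25, 0.5, 0.75, 1))
#' @export
summarize_values <- function(values) {
  if (!is.numeric(values) || length(values) == 0L || any(!is.finite(values))) {
    abort_validation("`values` must be a non-empty finite numeric vector.")
  }
  q <- unname(quantile(values, c(0, 0.25, 0.5, 0.75, 1), type = 7))
  tibble(
    n = length(values),
    mean = mean(values),
    sd = if (length(values) > 1L) sd(values) else 0,
    min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5]
  )
}

#' Rank states by mean utility
#'
#' Orders states ascending by their mean elicited value (worst state
#' first); ties break by ascending state id.
#'
#' @param per_state_means A data frame with columns `state_id` and `mean`,
#'   or a named numeric vector (names = state ids).
#' @return Integer vector of state ids, worst to best.
#' @examples
#' rank_states(c(`1` = 0.9, `2` = 0.4, `3` = 0.4))
#' @export
rank_states <- function(per_state_means) {
  if (is.data.frame(per_state_means)) {
    ids <- as.integer(per_state_means$state_id)
    means <- per_state_means$mean
  } else {
    ids <- as.integer(names(per_state_means))
    means <- unname(per_state_means)
  }
  if (length(ids) == 0L) abort_validation("No states to rank.")
  if (anyNA(means) || any(!is.finite(means))) {
    abort_validation("Missing mean value for state(s): %s.",
                     paste(ids[!is.finite(means)], collapse = ", "))
  }
  if (anyDuplicated(ids)) abort_validation("Duplicate state ids.")
  ids[order(means, ids)]
}

#' Concordance of two state rankings
#'
#' Compares two orderings of the same states (e.g. ascending by SG mean vs
#' ascending by RS mean): the number of rank positions at which both name
#' the same state, and the lengths of the identical initial run (agreement
#' on the worst states) and final run (agreement on the best states).
#'
#' @param order_a,order_b Permutations of the same state-id set, worst to
#'   best.
#' @return A `rank_concordance` object; see [tidy()] and [glance()] methods.
#' @examples
#' rc <- rank_concordance(c(3, 1, 2), c(3, 2, 1))
#' glance(rc)
#' @export
rank_concordance <- function(order_a, order_b) {
  order_a <- as.integer(order_a)
  order_b <- as.integer(order_b)
  if (length(order_a) != length(order_b) ||
      !setequal(order_a, order_b) ||
      anyDuplicated(order_a) || anyDuplicated(order_b)) {
    abort_validation("`order_a` and `order_b` must be permutations of the same id set.")
  }
  same <- order_a == order_b
  k <- length(same)
  prefix <- if (all(same)) k else which(!same)[1] - 1L
  suffix <- if (all(same)) k else k - max(which(!same))
  structure(
    list(order_a = order_a, order_b = order_b,
         n_same_position = sum(same),
         common_prefix_len = as.integer(prefix),
         common_suffix_len = as.integer(suffix)),
    class = "rank_concordance"
  )
}

#' @export
print.rank_concordance <- function(x, ...) {
  cat(sprintf(
    "<rank_concordance> %d states | same position: %d | common worst-prefix: %d | common best-suffix: %d\n",
    length(x$order_a), x$n_same_position, x$common_prefix_len,
    x$common_suffix_len))
  invisible(x)
}

#' Normal-approximation confidence interval for a mean
#'
#' `mean +/- z * sd / sqrt(n)` with the two-sided normal quantile
#' (1.959964 at 95%). Reporting layers typically round to 2 decimals. A
#' t-quantile variant is available; it is about 3% wider at n = 47.
#'
#' @param mean,sd,n Sample mean, sample SD and size (vectorised; `n >= 2`).
#' @param level Confidence level in (0, 1).
#' @param method `"z"` (default) or `"t"`.
#' @return A tibble with columns `mean`, `low`, `high`.
#' @examples
#' mean_ci(0.902, 0.203, 47)
#' @export
mean_ci <- function(mean, sd, n, level = 0.95, method = c("z", "t")) {
  method <- match.arg(method)
  if (any(!is.finite(mean)) || any(!is.finite(sd)) || any(sd < 0)) {
    abort_validation("`mean` must be finite and `sd` finite and >= 0.")
  }
  if (any(n < 2)) abort_validation("`n` must be >= 2.")
  check_number(level, "level")
  if (level <= 0 || level >= 1) {
    abort_validation("`level` must lie strictly between 0 and 1.")
  }
  q <- if (method == "z") qnorm(1 - (1 - level) / 2)
       else qt(1 - (1 - level) / 2, df = n - 1)
  half <- q * sd / sqrt(n)
  tibble(mean = mean, low = mean - half, high = mean + half)
}

#' Spearman rank correlation
#'
#' Rank correlation with midranks for ties and a p-value from the
#' t-approximation on ranks (via [stats::cor.test()]).
#'
#' @param x,y Equal-length numeric vectors, length >= 3.
#' @return A one-row tibble: `rho`, `p_value`, `n`.
#' @examples
#' spearman_cor(1:10, (1:10)^2)
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) abort_validation("`x` and `y` differ in length.")
  if (length(x) < 3L) abort_validation("Need at least 3 paired observations.")
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = FALSE)
  )
  tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum comparison of two groups (via
#' [stats::wilcox.test()]): exact enumeration for small untied samples,
#' continuity-corrected normal approximation otherwise.
#'
#' @param a,b Non-empty numeric vectors.
#' @return A one-row tibble: `statistic` (rank-sum W for group `a`),
#'   `p_value`, `n_a`, `n_b`.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    abort_validation("Both groups must be non-empty.")
  }
  wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
  tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
         n_a = length(a), n_b = length(b))
}

#' Robust locally weighted scatterplot smoothing (LOWESS)
#'
#' Local linear fits with tricube neighbourhood weights over the `span`
#' fraction of nearest neighbours, refined by `robust_iters` bisquare
#' robustness iterations (Cleveland's algorithm via [stats::lowess()]).
#' Fitted values are returned in the order of the input `x`.
#'
#' @param x,y Numeric vectors, length >= 2.
#' @param span Smoothing span in (0, 1].
#' @param robust_iters Number of robustness iterations (0 disables).
#' @return Numeric vector of fitted values aligned with `x`.
#' @examples
#' x <- seq(0, 1, length.out = 20)
#' lowess_fit(x, 2 * x + 1)
#' @export
lowess_fit <- function(x, y, span = 2 / 3, robust_iters = 3L) {
  if (length(x) != length(y)) abort_validation("`x` and `y` differ in length.")
  if (length(x) < 2L) abort_validation("Need at least 2 points.")
  check_number(span, "span")
  if (span <= 0 || span > 1) abort_validation("`span` must lie in (0, 1].")
  fit <- lowess(x, y, f = span, iter = robust_iters)
  out <- numeric(length(x))
  out[order(x)] <- fit$y
  out
}
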