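# Deterministic answer providers used across the elicitation tests.

# Thresholding gamble answerer: indifference point at risk pi = 1 - latent,
# with an optional indifference band (probability half-width).
threshold_sg <- function(latent, band = 0) {
  function(state, p, step) {
    if (abs((1 - p) - latent) <= band) "indifferent"
    else if ((1 - p) > latent) "accept" else "reject"
  }
}

# A full answer provider with fixed latent utilities per state id.
threshold_respondent <- function(latents, band = 0, id = "T001",
                                 refuse_states = integer()) {
  list(
    respondent_id = id,
    rs = function(state) 100 * latents[[as.character(state$state_id)]],
    sg = function(state, p, step) {
      if (step == 1L && state$state_id %in% refuse_states) {
        return("refuse_any_risk")
      }
      threshold_sg(latents[[as.character(state$state_id)]], band)(state, p, step)
    }
  )
}

# Run one standard-gamble titration to completion against an answerer.
titrate <- function(latent, rs_utility = latent, band = 0,
                    config = elicitation_config()) {
  session <- sg_start(rs_utility, config)
  ans <- threshold_sg(latent, band)
  while (session$status == "active") {
    session <- sg_step(session, ans(NULL, session$p_current, NULL))
  }
  sg_utility(session)
}

# Brute-force descriptive summary used as the independent oracle for
# summarize_values(): explicit sort-and-interpolate quantiles.
oracle_summary <- function(v) {
  s <- sort(v)
  n <- length(s)
  interp_q <- function(prob) {
    h <- (n - 1) * prob + 1
    lo <- floor(h)
    hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }
  list(
    mean = sum(s) / n,
    sd = if (n > 1) sqrt(sum((s - sum(s) / n)^2) / (n - 1)) else 0,
    min = s[1], q1 = interp_q(0.25), median = interp_q(0.5),
    q3 = interp_q(0.75), max = s[n]
  )
}

# Independent Spearman rho: midranks then the explicit Pearson formula.
oracle_spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

make_valid_records <- function(n, seed = 1) {
  withr::with_seed(seed, {
    method <- sample(c("SG", "RS"), n, replace = TRUE)
    refused <- method == "SG" & runif(n) < 0.1
    value <- round(runif(n), 6)
    value[refused] <- 1
    tibble::tibble(
      respondent_id = sprintf("R%03d", sample(50, n, replace = TRUE)),
      state_id = sample(18L, n, replace = TRUE),
      method = method,
      value = value,
      n_steps = as.integer(ifelse(method == "RS", 0L,
                                  sample(0:8, n, replace = TRUE))),
      refused_gamble = refused
    )
  })
}
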