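# Synthetic respondents: a generative stand-in for the interviewed
# volunteers, with the statistical structure the downstream analysis
# assumes (bounded latent utilities, SG responses pushed toward 1,
# occasional outright gamble refusals).

#' Default demographic mix of the study population
#'
#' Category proportions (and the age distribution) matching the reference
#' study population: 70% female, predominantly university-educated,
#' mean age about 41 years. Profession and marital-status category sets are
#' not fully enumerated in the source tables; the defaults here are
#' configurable stand-ins.
#'
#' @param path JSON file of proportions; defaults to the bundled mix.
#' @return A named list of per-field proportion vectors plus an `age` block
#'   (`mean`, `sd`, `min`, `max`).
#' @export
default_demographics <- function(path = utilicit_example("table2_demographics.json")) {
  demo <- jsonlite::fromJSON(path)
  demo$n_reference <- NULL
  demo
}

#' Generative model for synthetic respondents
#'
#' Each respondent holds, for every state `s`, a latent rating-scale utility
#' drawn from a beta distribution with mean `mu[s]` and concentration
#' `kappa` (shape parameters `mu*kappa`, `(1-mu)*kappa`). The latent
#' standard-gamble utility is a deterministic distortion of it,
#' `1 - (1 - u)^(1/gamma)` with `gamma <= 1`, which pushes SG values toward
#' 1 — reproducing the strong right-skew of gamble responses relative to
#' ratings. On top of the distortion, a respondent may refuse the gamble
#' outright (utility exactly 1) with probability `refusal_prob` when the
#' latent SG utility exceeds `refusal_threshold`. Observed ratings add
#' Gaussian noise (`rs_noise_sd`, on the 0-100 scale); during titration the
#' respondent answers "indifferent" once the proposed risk is within
#' `indifference_band` of the latent indifference point.
#'
#' @param mu Named numeric vector of per-state latent RS means in (0, 1);
#'   names are state ids. Defaults to the bundled per-state RS means.
#' @param kappa Beta concentration (> 0); larger is less dispersed.
#' @param gamma SG distortion exponent in (0, 1]; 1 disables the distortion.
#' @param rs_noise_sd SD of rating noise on the 0-100 scale.
#' @param indifference_band Probability half-width within which a proposed
#'   risk is answered "indifferent".
#' @param refusal_prob Probability of refusing any gamble when the latent SG
#'   utility exceeds `refusal_threshold`.
#' @param refusal_threshold Latent SG utility above which refusal is
#'   possible.
#' @return An object of class `synthetic_model`.
#' @export
synthetic_model <- function(mu = NULL, kappa = 6, gamma = 0.35,
                            rs_noise_sd = 5, indifference_band = 0.01,
                            refusal_prob = 0.2, refusal_threshold = 0.9) {
  if (is.null(mu)) {
    t3 <- read_table3_fixture()
    rs <- t3[t3$method == "RS", ]
    mu <- stats::setNames(rs$mean, rs$state_id)
  }
  if (is.null(names(mu))) names(mu) <- seq_along(mu)
  if (any(mu <= 0 | mu >= 1)) {
    abort_validation("Latent means `mu` must lie strictly in (0, 1).")
  }
  check_number(kappa, "kappa")
  if (kappa <= 0) abort_validation("`kappa` must be > 0.")
  check_number(gamma, "gamma")
  if (gamma <= 0 || gamma > 1) {
    abort_validation("`gamma` must lie in (0, 1].")
  }
  check_number(rs_noise_sd, "rs_noise_sd", lower = 0)
  check_number(indifference_band, "indifference_band", lower = 0)
  check_number(refusal_prob, "refusal_prob", 0, 1)
  check_number(refusal_threshold, "refusal_threshold", 0, 1)
  structure(
    list(mu = mu, kappa = kappa, gamma = gamma, rs_noise_sd = rs_noise_sd,
         indifference_band = indifference_band, refusal_prob = refusal_prob,
         refusal_threshold = refusal_threshold),
    class = "synthetic_model"
  )
}

#' Map a latent rating-scale utility to its standard-gamble counterpart
#'
#' The distortion `1 - (1 - u)^(1/gamma)` with `gamma < 1` compresses
#' distance from 1, so SG utilities dominate RS utilities state by state.
#'
#' @param u Latent RS utility in \[0, 1\].
#' @param gamma Distortion exponent in (0, 1].
#' @return Latent SG utility in \[0, 1\]; `>= u` whenever `gamma <= 1`.
#' @export
sg_distort <- function(u, gamma) {
  1 - (1 - u)^(1 / gamma)
}

#' Generate a synthetic respondent population
#'
#' Draws respondent profiles matching target category proportions and age
#' distribution (ages from a normal distribution truncated by resampling to
#' the configured range, rounded to whole years). Reproducible under a
#' fixed seed.
#'
#' @param n Number of respondents (>= 1).
#' @param demographics Proportions list as from [default_demographics()].
#' @param seed Integer seed.
#' @return A tibble of respondent profiles ([validate_respondent_profiles()]).
#' @examples
#' generate_population(5, seed = 1)
#' @export
generate_population <- function(n, demographics = default_demographics(),
                                seed = 1L) {
  check_number(n, "n", lower = 1)
  n <- as.integer(n)
  cat_fields <- c("sex", "education", "family_situation", "profession",
                  "marital_status")
  for (fld in cat_fields) {
    p <- unlist(demographics[[fld]])
    if (abs(sum(p) - 1) > 1e-6) {
      abort_validation("Proportions for `%s` sum to %.4f, not 1.", fld, sum(p))
    }
  }
  with_seed(derive_seed(seed, "population"), {
    draw_cat <- function(fld) {
      p <- unlist(demographics[[fld]])
      sample(names(p), n, replace = TRUE, prob = p)
    }
    age_spec <- demographics$age
    age <- numeric(0)
    while (length(age) < n) {
      a <- rnorm(2L * n, age_spec$mean, age_spec$sd)
      age <- c(age, a[a >= age_spec$min & a <= age_spec$max])
    }
    tibble(
      respondent_id = sprintf("R%03d", seq_len(n)),
      age = round(age[seq_len(n)]),
      sex = draw_cat("sex"),
      education = draw_cat("education"),
      family_situation = draw_cat("family_situation"),
      profession = draw_cat("profession"),
      marital_status = draw_cat("marital_status"),
      is_patient = FALSE,
      country = "Switzerland"
    )
  })
}

#' Draw a respondent's latent utilities for every state
#'
#' Latent RS utilities are beta draws with mean `mu[s]` and concentration
#' `kappa`; latent SG utilities follow by the deterministic distortion
#' [sg_distort()]. Per-state refusal decisions are drawn here too. The
#' random stream is derived by stable hashing of `(seed, respondent_id)`, so
#' draws are independent of evaluation order.
#'
#' @param model A [synthetic_model()].
#' @param respondent_id Identifier entering the stream hash.
#' @param seed Base integer seed.
#' @return A tibble with columns `state_id`, `latent_rs`, `latent_sg`,
#'   `refuses`.
#' @export
draw_latent_utilities <- function(model, respondent_id = "R001", seed = 1L) {
  stopifnot(inherits(model, "synthetic_model"))
  with_seed(derive_seed(seed, "latent", respondent_id), {
    mu <- model$mu
    latent_rs <- rbeta(length(mu), shape1 = mu * model$kappa,
                       shape2 = (1 - mu) * model$kappa)
    latent_sg <- sg_distort(latent_rs, model$gamma)
    refuses <- runif(length(mu)) < model$refusal_prob &
      latent_sg > model$refusal_threshold
    tibble(
      state_id = as.integer(names(mu)),
      latent_rs = latent_rs,
      latent_sg = latent_sg,
      refuses = refuses
    )
  })
}

#' Simulate an observed rating-scale response
#'
#' The observed rating is the latent utility on the 0-100 scale plus
#' Gaussian noise, rounded to a whole point and clamped to \[0, 100\].
#'
#' @param latent_rs Latent utility in \[0, 1\] (vectorised).
#' @param rs_noise_sd Noise SD on the 0-100 scale.
#' @param seed Optional seed for a local stream; `NULL` uses the ambient
#'   stream.
#' @return Integer-valued rating(s) in \[0, 100\].
#' @export
simulate_rs_response <- function(latent_rs, rs_noise_sd = 5, seed = NULL) {
  with_seed(seed, {
    raw <- 100 * latent_rs + rnorm(length(latent_rs), 0, rs_noise_sd)
    pmin(pmax(round(raw), 0), 100)
  })
}

#' Simulate a standard-gamble decision
#'
#' The respondent compares the sure state (latent SG utility) with the
#' gamble's expected standing `1 - p`: within `delta` of the indifference
#' point the answer is `"indifferent"`, otherwise the gamble is accepted
#' exactly when `1 - p` exceeds the latent utility. Outright refusal is a
#' respondent-level decision handled by [synthetic_respondent()] at the
#' first proposal only.
#'
#' @param latent_sg Latent SG utility in \[0, 1\].
#' @param p Proposed risk of death in \[0, 1\].
#' @param delta Indifference half-width (probability).
#' @return One of `"accept"`, `"reject"`, `"indifferent"`.
#' @examples
#' simulate_sg_decision(0.75, p = 0.454)
#' @export
simulate_sg_decision <- function(latent_sg, p, delta = 0) {
  check_number(latent_sg, "latent_sg", 0, 1)
  check_number(p, "p", 0, 1)
  check_number(delta, "delta", lower = 0)
  if (abs((1 - p) - latent_sg) <= delta) return("indifferent")
  if ((1 - p) > latent_sg) "accept" else "reject"
}

#' Build an answer provider from the generative model
#'
#' Packages one simulated interviewee as the answer-provider interface
#' consumed by [run_interview()]: latent utilities and refusal decisions are
#' drawn once per respondent; the rating answer adds observation noise; the
#' gamble answers threshold on the latent SG utility with the model's
#' indifference band.
#'
#' @param model A [synthetic_model()].
#' @param respondent_id Identifier (also seeds the respondent's stream).
#' @param seed Base integer seed.
#' @return An answer provider (list with `respondent_id`, `rs`, `sg`,
#'   and the drawn `latents` tibble).
#' @export
synthetic_respondent <- function(model, respondent_id = "R001", seed = 1L) {
  latents <- draw_latent_utilities(model, respondent_id, seed)
  lookup <- function(state) {
    row <- latents[latents$state_id == state$state_id, ]
    if (nrow(row) != 1L) {
      abort_validation("Model has no latent utility for state %s.",
                       format(state$state_id))
    }
    row
  }
  list(
    respondent_id = respondent_id,
    latents = latents,
    rs = function(state) {
      row <- lookup(state)
      simulate_rs_response(row$latent_rs, model$rs_noise_sd,
                           seed = derive_seed(seed, "rs", respondent_id,
                                              state$state_id))
    },
    sg = function(state, p, step) {
      row <- lookup(state)
      if (step == 1L && row$refuses) return("refuse_any_risk")
      simulate_sg_decision(row$latent_sg, p, model$indifference_band)
    }
  )
}

#' Simulate a full elicitation study
#'
#' Generates `n` synthetic respondents and runs the two-question interview
#' over the whole catalog for each, yielding `n * nrow(states) * 2` UC
#' records — the synthetic analogue of a complete study repository.
#'
#' @param n Number of respondents.
#' @param model A [synthetic_model()].
#' @param states Health-state catalog; defaults to the bundled 18 states.
#' @param config An [elicitation_config()].
#' @param demographics Demographic mix for [generate_population()].
#' @param seed Integer seed controlling every random draw.
#' @return A list with `records` (UC tibble) and `profiles` (respondent
#'   tibble).
#' @examples
#' sim <- simulate_study(n = 2, seed = 7)
#' nrow(sim$records)
#' @export
simulate_study <- function(n = 47, model = synthetic_model(),
                           states = load_state_catalog(),
                           config = elicitation_config(),
                           demographics = default_demographics(),
                           seed = 1L) {
  profiles <- generate_population(n, demographics, seed)
  records <- purrr::map(profiles$respondent_id, function(rid) {
    run_interview(synthetic_respondent(model, rid, seed), states, config)
  })
  list(records = bind_rows(records), profiles = profiles)
}
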