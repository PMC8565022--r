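test_that("population generation is reproducible and hits target proportions", {
  p1 <- generate_population(47, seed = 42)
  p2 <- generate_population(47, seed = 42)
  expect_equal(p1, p2)
  expect_equal(nrow(p1), 47L)
  validate_respondent_profiles(p1)
  expect_true(all(p1$age >= 21 & p1$age <= 68))

  expect_equal(nrow(generate_population(1, seed = 1)), 1L)

  # law of large numbers: empirical mix approaches the configured one
  big <- generate_population(10000, seed = 7)
  expect_lt(abs(mean(big$sex == "female") - 0.7021277), 0.02)
  expect_lt(abs(mean(big$education == "university") - 0.7659574), 0.02)
  expect_lt(abs(mean(big$age) - 40.8), 1.5)

  demo <- default_demographics()
  demo$sex <- list(male = 0.6, female = 0.6)
  expect_error(generate_population(5, demo), class = "utilicit_error_validation")
})

test_that("latent utilities follow the beta/distortion model", {
  states <- load_state_catalog()
  model <- synthetic_model()
  lat <- draw_latent_utilities(model, "R001", seed = 1)
  expect_equal(lat$state_id, states$state_id)
  expect_true(all(lat$latent_rs >= 0 & lat$latent_rs <= 1))
  expect_true(all(lat$latent_sg >= 0 & lat$latent_sg <= 1))
  # gamma < 1 pushes the gamble utility above the rating utility
  expect_true(all(lat$latent_sg >= lat$latent_rs))
  expect_equal(draw_latent_utilities(model, "R001", seed = 1), lat)

  ident <- synthetic_model(gamma = 1, refusal_prob = 0)
  lat1 <- draw_latent_utilities(ident, "R002", seed = 5)
  expect_equal(lat1$latent_sg, lat1$latent_rs)

  expect_equal(sg_distort(0.25, 1), 0.25)
  expect_gte(sg_distort(0.25, 0.35), 0.25)
})

test_that("latent draws are anchored to the configured per-state means", {
  # 10^4 independent draws at the palliative-care anchor mean 0.072
  model <- synthetic_model(mu = stats::setNames(rep(0.072, 1e4), 1:1e4))
  lat <- draw_latent_utilities(model, "R001", seed = 11)
  expect_lt(abs(mean(lat$latent_rs) - 0.072), 0.01)
})

test_that("rating responses are noisy, rounded and clamped", {
  expect_equal(simulate_rs_response(0.55, rs_noise_sd = 0), 55)
  expect_equal(simulate_rs_response(1, rs_noise_sd = 40, seed = 2) <= 100, TRUE)
  many <- simulate_rs_response(rep(0.5, 1e4), rs_noise_sd = 5, seed = 3)
  expect_true(all(many >= 0 & many <= 100))
  expect_lt(abs(mean(many) - 50), 0.2)
})

test_that("simulated gamble decisions threshold on the latent utility", {
  expect_equal(simulate_sg_decision(0.8, p = 0), "accept")
  expect_equal(simulate_sg_decision(0.8, p = 1), "reject")
  expect_equal(simulate_sg_decision(0.75, p = 0.25, delta = 0), "indifferent")
  expect_equal(simulate_sg_decision(0.75, p = 0.26, delta = 0.02), "indifferent")
  # end-to-end: a deterministic simulated respondent is recovered by titration
  for (latent in c(0.1, 0.5, 0.75)) {
    session <- sg_start(latent)
    while (session$status == "active") {
      session <- sg_step(session, simulate_sg_decision(latent,
                                                       session$p_current))
    }
    expect_lte(abs(sg_utility(session) - latent), 0.01)
  }
})

test_that("simulated studies reproduce the SG-skew and state ordering", {
  model <- synthetic_model()  # gamma = 0.35 < 0.5
  sim <- simulate_study(n = 120, model = model, seed = 2024)
  expect_equal(nrow(sim$records), 120L * 18L * 2L)
  t3 <- build_table3(sim$records, digits = NULL)
  wide <- tidyr::pivot_wider(
    t3[c("state_id", "method", "median", "q3", "mean")],
    names_from = "method", values_from = c("median", "q3", "mean"))
  # strong right-skew: SG median at or above the RS upper quartile
  non_terminal <- wide$state_id <= 16
  expect_true(all(wide$median_SG[non_terminal] >= wide$q3_RS[non_terminal]))
  # SG dominates RS on every state mean
  expect_true(all(wide$mean_SG >= wide$mean_RS))
  # ordering preservation: mean simulated RS tracks the latent anchors
  anchors <- synthetic_model()$mu
  rho <- spearman_cor(anchors[as.character(wide$state_id)],
                      wide$mean_RS)$rho
  expect_gte(rho, 0.95)
  expect_equal(rank_states(tibble::tibble(state_id = wide$state_id,
                                          mean = wide$mean_RS))[1:2],
               c(18L, 17L))
})
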