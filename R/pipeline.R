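# End-to-end pipeline: simulate a study, analyse it, write every table.

#' Run the simulate-elicit-analyze pipeline
#'
#' Simulates a full elicitation study (`n_respondents` synthetic
#' interviewees, two questions per state), writes the elicited-value
#' repository and respondent profiles, and derives every summary product:
#' the per-state descriptive table, the SG/RS ranking comparison, the
#' cross-study CI comparison, per-state SG-RS correlations and age
#' correlations. All outputs are plain text (CSV/JSON) under `out_dir`,
#' together with a run manifest recording the seed and parameters; outputs
#' are deterministic given the seed.
#'
#' @param out_dir Output directory (created if missing). `NULL` skips
#'   writing and just returns the results.
#' @param n_respondents Number of simulated respondents (study default 47).
#' @param seed Integer seed for every random draw.
#' @param model A [synthetic_model()].
#' @param states Health-state catalog.
#' @param config An [elicitation_config()].
#' @param demographics Demographic mix.
#' @param verbose Print progress to stderr.
#' @return Invisibly, a list: `records`, `profiles`, `table3`, `table4`,
#'   `table5`, `correlations`, `concordance`, `manifest`.
#' @examples
#' res <- run_pipeline(out_dir = NULL, n_respondents = 2, seed = 1)
#' nrow(res$records)
#' @export
run_pipeline <- function(out_dir = NULL, n_respondents = 47, seed = 1L,
                         model = synthetic_model(),
                         states = load_state_catalog(),
                         config = elicitation_config(),
                         demographics = default_demographics(),
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  say("Simulating %d respondents over %d states (seed %d)",
      n_respondents, nrow(states), seed)
  sim <- simulate_study(n = n_respondents, model = model, states = states,
                        config = config, demographics = demographics,
                        seed = seed)
  say("Collected %d records; building tables", nrow(sim$records))
  table3 <- build_table3(sim$records, states)
  table4 <- build_table4(table3, states)
  rc <- attr(table4, "concordance")
  # the cross-study CI table needs at least two respondents behind each mean
  table5 <- if (n_respondents >= 2) {
    build_table5(table3, n = n_respondents, states = states)
  }

  sg_means <- filter(table3, .data$method == "SG")$mean
  rs_means <- filter(table3, .data$method == "RS")$mean
  method_cor <- spearman_cor(sg_means, rs_means)

  # Per-state Spearman correlation of elicited values with respondent age.
  wide <- sim$records %>%
    left_join(select(sim$profiles, all_of(c("respondent_id", "age"))),
              by = "respondent_id")
  age_cor <- if (n_respondents >= 3) {
    wide %>%
      group_by(.data$state_id, .data$method) %>%
      dplyr::reframe(spearman_cor(.data$age, .data$value))
  } else {
    tibble(state_id = integer(), method = character(), rho = double(),
           p_value = double(), n = integer())
  }
  correlations <- bind_rows(
    mutate(method_cor, state_id = NA_integer_, method = "SG~RS",
           .before = 1),
    mutate(age_cor, method = paste0(.data$method, "~age"))
  )

  manifest <- list(
    package_version = as.character(utils::packageVersion("utilicit")),
    seed = seed,
    n_respondents = n_respondents,
    n_states = nrow(states),
    n_records = nrow(sim$records),
    tolerance = config$tolerance,
    max_steps = config$max_steps,
    model = model[c("kappa", "gamma", "rs_noise_sd", "indifference_band",
                    "refusal_prob", "refusal_threshold")],
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_uc_repository(sim$records, file.path(out_dir, "records.csv"))
    write_respondent_profiles(sim$profiles,
                              file.path(out_dir, "profiles.json"))
    readr::write_csv(table3, file.path(out_dir, "table3.csv"),
                     progress = FALSE)
    readr::write_csv(select(table4, -dplyr::any_of("concordance")),
                     file.path(out_dir, "table4.csv"), progress = FALSE)
    if (!is.null(table5)) {
      readr::write_csv(table5, file.path(out_dir, "table5.csv"),
                       progress = FALSE)
    }
    readr::write_csv(correlations, file.path(out_dir, "correlations.csv"),
                     progress = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("Wrote outputs to %s", out_dir)
  }
  invisible(list(records = sim$records, profiles = sim$profiles,
                 table3 = table3, table4 = table4, table5 = table5,
                 correlations = correlations, concordance = rc,
                 manifest = manifest))
}
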