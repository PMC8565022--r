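# Health-state catalog, respondent profiles and the elicited-value repository.

#' Load a health-state catalog
#'
#' Reads a JSON catalog of health states to be valued. Each record carries a
#' numeric `state_id`, a human-readable `label`, one or more SNOMED CT
#' `code|term|` expressions (post-coordinated states carry several), and an
#' optional opaque `scenario_ref` identifying the clinical vignette shown to
#' respondents. The default is the bundled 18-state catalog of post
#' trans-oral-surgery states (first-month surgical recovery through
#' palliative care).
#'
#' @param path Path to a JSON catalog. Defaults to the bundled catalog.
#' @return A tibble with columns `state_id` (integer), `label` (character),
#'   `snomed_exprs` (list of character vectors) and `scenario_ref`
#'   (character).
#' @examples
#' states <- load_state_catalog()
#' nrow(states)
#' @export
load_state_catalog <- function(path = utilicit_example("table1_states.json")) {
  if (!file.exists(path)) {
    abort_validation("Catalog file does not exist: '%s'.", path)
  }
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
    error = function(e) {
      abort(sprintf("Failed to parse catalog '%s': %s", path,
                    conditionMessage(e)),
            class = "utilicit_error_parse")
    }
  )
  if (length(raw) == 0L) {
    return(tibble(state_id = integer(), label = character(),
                  snomed_exprs = list(), scenario_ref = character()))
  }
  states <- purrr::imap(raw, function(rec, i) {
    for (fld in c("state_id", "label", "snomed_exprs")) {
      if (is.null(rec[[fld]])) {
        abort(sprintf("Catalog record %d is missing field '%s'.", i, fld),
              class = "utilicit_error_parse")
      }
    }
    tibble(
      state_id = as.integer(rec$state_id),
      label = as.character(rec$label),
      snomed_exprs = list(as.character(unlist(rec$snomed_exprs))),
      scenario_ref = if (is.null(rec$scenario_ref)) NA_character_
                     else as.character(rec$scenario_ref)
    )
  })
  out <- bind_rows(states)
  validate_state_catalog(out)
  out
}

validate_state_catalog <- function(states) {
  dup <- states$state_id[duplicated(states$state_id)]
  if (length(dup) > 0L) {
    abort_validation("Duplicate state_id in catalog: %s.",
                     paste(unique(dup), collapse = ", "))
  }
  n_tokens <- lengths(states$snomed_exprs)
  if (any(n_tokens == 0L)) {
    abort_validation("State(s) %s have no SNOMED expression.",
                     paste(states$state_id[n_tokens == 0L], collapse = ", "))
  }
  ok <- purrr::map_lgl(states$snomed_exprs,
                       ~ all(validate_snomed_expression(.x)))
  if (!all(ok)) {
    abort_validation("State(s) %s carry malformed SNOMED expression(s).",
                     paste(states$state_id[!ok], collapse = ", "))
  }
  invisible(states)
}

#' Syntactic validation of a SNOMED CT expression
#'
#' Checks the `code|term|` compositional shape used for (possibly
#' post-coordinated) SNOMED CT expressions: one or more pairs of an all-digit
#' concept code and a non-empty term, each delimited by `|`. Validation is
#' purely syntactic; no terminology server is consulted.
#'
#' @param expr Character vector of expressions.
#' @return Logical vector, `TRUE` where the expression is well-formed.
#' @examples
#' validate_snomed_expression("103735009|Palliative care|")
#' validate_snomed_expression("25173007|Recurrent tumor|255470001|Local|")
#' validate_snomed_expression("abc|x|")
#' @export
validate_snomed_expression <- function(expr) {
  if (length(expr) == 0L) return(logical())
  !is.na(expr) & grepl("^([0-9]+\\|[^|]+\\|)+$", expr)
}

uc_repository_columns <- c("respondent_id", "state_id", "method", "value",
                           "n_steps", "refused_gamble")

#' Validate a table of elicited utility records
#'
#' A utility-coefficient (UC) record stores one elicited value: who answered
#' (`respondent_id`), which state (`state_id`), by which method (`"SG"`,
#' `"RS"` or `"TTO"`), the utility `value` in \[0, 1\], how many titration
#' questions were asked (`n_steps`, 0 for RS), and whether the respondent
#' refused any gamble (`refused_gamble`; a refusal is only possible under SG
#' and forces the value to 1).
#'
#' @param records A data frame with the repository columns.
#' @return The records, invisibly, as a validated tibble; errors with class
#'   `utilicit_error_validation` describe the first violated constraint.
#' @export
validate_uc_records <- function(records) {
  missing_cols <- setdiff(uc_repository_columns, names(records))
  if (length(missing_cols) > 0L) {
    abort_validation("Records are missing column(s): %s.",
                     paste(missing_cols, collapse = ", "))
  }
  records <- as_tibble(records)
  if (nrow(records) == 0L) return(invisible(records))
  if (!all(records$method %in% c("SG", "RS", "TTO"))) {
    abort_validation("`method` must be one of 'SG', 'RS', 'TTO'.")
  }
  bad <- !is.finite(records$value) | records$value < 0 | records$value > 1
  if (any(bad)) {
    abort_validation("%d record(s) have a utility value outside [0, 1].",
                     sum(bad))
  }
  if (any(records$n_steps < 0)) {
    abort_validation("`n_steps` must be >= 0.")
  }
  off <- records$refused_gamble &
    (records$method != "SG" | records$value != 1)
  if (any(off)) {
    abort_validation(
      "refused_gamble records must be SG elicitations with value 1 (%d violate this).",
      sum(off))
  }
  invisible(records)
}

#' Read and write a utility-coefficient repository
#'
#' The repository is a UTF-8 CSV with the fixed header
#' `respondent_id,state_id,method,value,n_steps,refused_gamble` and `.` as
#' decimal separator, so elicited values move between tools without loss.
#' `write_uc_repository()` validates before writing; a write followed by a
#' read returns the same records.
#'
#' @param path CSV file path.
#' @param records A data frame of valid UC records.
#' @return `read_uc_repository()` returns a tibble of records;
#'   `write_uc_repository()` returns `path` invisibly.
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' recs <- tibble::tibble(
#'   respondent_id = "R001", state_id = 18L, method = "SG",
#'   value = 0.2, n_steps = 6L, refused_gamble = FALSE
#' )
#' write_uc_repository(recs, tmp)
#' read_uc_repository(tmp)
#' @export
read_uc_repository <- function(path) {
  if (!file.exists(path)) {
    abort_validation("Repository file does not exist: '%s'.", path)
  }
  records <- readr::read_csv(
    path,
    col_types = readr::cols(
      respondent_id = readr::col_character(),
      state_id = readr::col_integer(),
      method = readr::col_character(),
      value = readr::col_double(),
      n_steps = readr::col_integer(),
      refused_gamble = readr::col_logical()
    ),
    progress = FALSE
  )
  validate_uc_records(records)
  records
}

#' @rdname read_uc_repository
#' @export
write_uc_repository <- function(records, path) {
  validate_uc_records(records)
  records <- as_tibble(records)[, uc_repository_columns]
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}

profile_levels <- list(
  sex = c("male", "female"),
  education = c("secondary school", "high school", "university"),
  family_situation = c("has_dependant_child",
                       "has_adult_non_self-sufficient_dependant",
                       "none_of_the_above")
)

#' Validate respondent profiles
#'
#' Profiles describe the interviewed individuals: `respondent_id`, `age`
#' (years), `sex`, `education`, `family_situation`, free-text `profession`
#' and `marital_status` categories, `is_patient` and `country`. The closed
#' categorical fields (`sex`, `education`, `family_situation`) are restricted
#' to their study enumerations; profession and marital-status category sets
#' are open.
#'
#' @param profiles A data frame of profiles.
#' @return The profiles, invisibly, as a validated tibble.
#' @export
validate_respondent_profiles <- function(profiles) {
  needed <- c("respondent_id", "age", "sex", "education", "family_situation",
              "profession", "marital_status", "is_patient", "country")
  missing_cols <- setdiff(needed, names(profiles))
  if (length(missing_cols) > 0L) {
    abort_validation("Profiles are missing column(s): %s.",
                     paste(missing_cols, collapse = ", "))
  }
  profiles <- as_tibble(profiles)
  if (nrow(profiles) == 0L) return(invisible(profiles))
  if (any(!is.finite(profiles$age) | profiles$age <= 0)) {
    abort_validation("`age` must be finite and > 0.")
  }
  for (fld in names(profile_levels)) {
    bad <- !profiles[[fld]] %in% profile_levels[[fld]]
    if (any(bad)) {
      abort_validation("`%s` contains value(s) outside {%s}.", fld,
                       paste(profile_levels[[fld]], collapse = ", "))
    }
  }
  invisible(profiles)
}

#' Read and write respondent profiles (JSON)
#'
#' @param profiles A data frame of valid respondent profiles.
#' @param path JSON file path.
#' @return `read_respondent_profiles()` returns a tibble;
#'   `write_respondent_profiles()` returns `path` invisibly.
#' @export
read_respondent_profiles <- function(path) {
  if (!file.exists(path)) {
    abort_validation("Profile file does not exist: '%s'.", path)
  }
  profiles <- as_tibble(jsonlite::fromJSON(path))
  if (nrow(profiles) > 0L) {
    profiles$age <- as.numeric(profiles$age)
    profiles$is_patient <- as.logical(profiles$is_patient)
  }
  validate_respondent_profiles(profiles)
  profiles
}

#' @rdname read_respondent_profiles
#' @export
write_respondent_profiles <- function(profiles, path) {
  validate_respondent_profiles(profiles)
  jsonlite::write_json(profiles, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
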