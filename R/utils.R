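# Internal helpers shared across modules.

abort_validation <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "utilicit_error_validation")
}

abort_state <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "utilicit_error_state")
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_validation("`%s` must be a single finite number.", name)
  }
  if (x < lower || x > upper) {
    abort_validation("`%s` must lie in [%s, %s] (got %s).",
                     name, format(lower), format(upper), format(x))
  }
  invisible(x)
}

# Deterministic 31-bit stream seed from a base seed plus arbitrary keys
# (respondent/state ids). Polynomial string hash folded modulo a Mersenne
# prime keeps derived seeds < 2^31 and independent of R's RNG state.
derive_seed <- function(seed, ...) {
  keys <- paste(c(seed, ...), collapse = "\r")
  m <- 2147483647
  h <- 0
  for (cp in utf8ToInt(keys)) h <- (h * 31 + cp) %% m
  as.integer(h %% (m - 1L) + 1L)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG state is untouched. A NULL seed uses (and advances) the global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
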