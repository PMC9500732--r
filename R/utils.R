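# Internal helpers shared across modules.

#' @importFrom rlang %||% abort warn inform
#' @importFrom dplyr %>%
NULL

# Deterministic 31-bit substream seed from a base seed and a character tag.
# Keeps per-sample read streams stable when replicate counts change.
derive_seed <- function(seed, tag) {
  h <- 0
  for (v in utf8ToInt(tag)) h <- (h * 131 + v) %% 1000003L
  as.integer((as.numeric(seed) * 2654435L + h * 97L) %% 2147483647L)
}

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

assert_positive_int <- function(x, name) {
  if (length(x) != 1 || is.na(x) || x < 1 || x != as.integer(x)) {
    abort(sprintf("configuration error: `%s` must be a positive integer", name),
          class = "riboage_config_error")
  }
}

assert_prob <- function(x, name) {
  if (length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("configuration error: `%s` must lie in [0, 1]", name),
          class = "riboage_config_error")
  }
}

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing column(s): %s", what,
                  paste(missing, collapse = ", ")))
  }
}

# 0-based half-open interval overlap length.
interval_overlap <- function(a_start, a_end, b_start, b_end) {
  pmax(0L, pmin(a_end, b_end) - pmax(a_start, b_start))
}
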