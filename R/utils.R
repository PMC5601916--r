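# Internal validation helpers. Kept tiny on purpose: most checks read as one
# line at the top of the exported function that needs them.

stop_if_not_scalar_number <- function(x, what, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", what))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0 (got %s).", what, format(x)))
  }
  invisible(x)
}

stop_if_not_proportion <- function(x, what) {
  stop_if_not_scalar_number(x, what)
  if (x < 0 || x > 1) {
    abort(sprintf("`%s` must lie in [0, 1] (got %s).", what, format(x)))
  }
  invisible(x)
}

stop_if_not_count <- function(x, what) {
  stop_if_not_scalar_number(x, what)
  if (x != as.integer(x) || x <= 0) {
    abort(sprintf("`%s` must be a positive integer (got %s).", what, format(x)))
  }
  invisible(as.integer(x))
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf(
      "`%s` is missing required column(s): %s.",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# All randomness in the package flows through here: a fixed offset per use
# site keeps independent stages reproducible and decoupled under one seed.
with_stage_seed <- function(seed, offset, code) {
  withr::with_seed(as.integer((as.numeric(seed) + offset) %% .Machine$integer.max), code)
}
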