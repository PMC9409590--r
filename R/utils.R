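# Internal helpers shared across modules.

# Round half away from zero; base round() uses banker's rounding, which
# disagrees with how diet tables are conventionally printed.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Squared Euclidean norm of each row.
row_sq_norm <- function(m) rowSums(m^2)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")),
          class = "tunadiet_schema_error")
  }
  invisible(df)
}
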