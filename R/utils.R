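# internal helpers shared across modules

# calendar day of a timezone-naive timestamp (stored as UTC POSIXct)
as_day <- function(timestamp) as.Date(timestamp, tz = "UTC")

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")),
          class = "dendrosap_schema_error")
  }
  invisible(df)
}

# running maximum that carries the last observed maximum across NA gaps;
# leading NAs stay NA
cummax_na <- function(x) {
  y <- x
  y[is.na(y)] <- -Inf
  r <- cummax(y)
  r[is.infinite(r)] <- NA_real_
  r
}

# parse "YYYY-MM-DD" or Date into Date
as_date_strict <- function(x, what = "date") {
  out <- tryCatch(as.Date(x), error = function(e) NA)
  if (any(is.na(out))) {
    abort(sprintf("could not parse %s: %s", what, paste(x, collapse = ", ")),
          class = "dendrosap_input_error")
  }
  out
}

# deterministic child seed derivation, kept below 2^31
child_seed <- function(seed, stream, index = 0L) {
  (as.integer(seed) %% 1000003L) * 1009L + stream * 101L + as.integer(index)
}

doy <- function(date) as.integer(strftime(date, "%j", tz = "UTC"))
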