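#' Tree water deficit from a stem-radius trace (zero-growth concept)
#'
#' The tree water deficit is the shortfall of the current stem radius below
#' the highest radius previously attained: `twd = running_max - radius`,
#' floored at zero.  Under the zero-growth concept, irreversible growth only
#' occurs while the cambium is fully hydrated (TWD = 0), so the running
#' maximum separates growth from reversible shrinkage in a single dendrometer
#' trace.  The running maximum carries across data gaps (a gap cannot erase
#' the historical maximum); missing samples stay missing.
#'
#' @param trace Data frame with columns `tree_id`, `timestamp` (strictly
#'   increasing within tree) and `radius_disp` (cumulative radial
#'   displacement, um).
#' @return Tibble with `running_max` and `twd` columns appended.
#' @examples
#' tr <- tibble::tibble(tree_id = "t1",
#'   timestamp = as.POSIXct("2022-06-01", tz = "UTC") + 600 * (0:4),
#'   radius_disp = c(100, 120, 90, 110, 130))
#' twd(tr)$twd  # 0 0 30 10 0
#' @export
twd <- function(trace) {
  assert_cols(trace, c("tree_id", "timestamp", "radius_disp"), "trace")
  as_tibble(trace) |>
    group_by(.data$tree_id) |>
    arrange(.data$timestamp, .by_group = TRUE) |>
    mutate(running_max = cummax_na(.data$radius_disp),
           twd = pmax(.data$running_max - .data$radius_disp, 0)) |>
    ungroup()
}

#' Daily minimum (and maximum) tree water deficit
#'
#' The daily minimum TWD is the drought signal of interest: it only rises
#' above zero once the deficit built up during the day can no longer be
#' removed overnight, i.e. once stem water reserves fail to recharge.  The
#' daily maximum is also returned because the per-tree normalisation scale is
#' taken from the largest daily maxima.
#'
#' @param twd_series Output of [twd()].
#' @return Tibble with `tree_id`, `date`, `twd_min`, `twd_max`, `n_obs`;
#'   fully missing days are dropped.
#' @export
daily_min_twd <- function(twd_series) {
  assert_cols(twd_series, c("tree_id", "timestamp", "twd"), "twd_series")
  as_tibble(twd_series) |>
    mutate(date = as_day(.data$timestamp)) |>
    group_by(.data$tree_id, .data$date) |>
    summarise(n_obs = sum(!is.na(.data$twd)),
              twd_min = if (any(!is.na(.data$twd)))
                min(.data$twd, na.rm = TRUE) else NA_real_,
              twd_max = if (any(!is.na(.data$twd)))
                max(.data$twd, na.rm = TRUE) else NA_real_,
              .groups = "drop") |>
    filter(.data$n_obs > 0L)
}

#' Normalise a series by the mean of its highest values
#'
#' Divides `x` by the mean of the `ceiling(top_fraction * N)` largest finite
#' values of `reference` (default: of `x` itself).  With the default 2.5%
#' top fraction this maps a per-tree series onto a 0 to ~1 relative scale
#' while being robust to single extreme values; the maximum can slightly
#' exceed 1.  Sap flow uses the series of daily sums as its own reference;
#' TWD divides the daily minima by the scale of the daily maxima.
#'
#' @param x Numeric vector to rescale.
#' @param top_fraction Fraction of the largest values averaged into the
#'   divisor (default 0.025).
#' @param reference Numeric vector from which the divisor is computed
#'   (default `x`).  Must hold at least `1 / top_fraction` finite values so
#'   the top set is non-empty and meaningful.
#' @return `x / divisor`, with the divisor attached as attribute `divisor`.
#' @export
relative_normalize <- function(x, top_fraction = 0.025, reference = x) {
  ref <- reference[is.finite(reference)]
  n <- length(ref)
  if (n < ceiling(1 / top_fraction)) {
    abort(sprintf("need at least %d finite reference values for a top-%.1f%% scale (got %d)",
                  ceiling(1 / top_fraction), 100 * top_fraction, n),
          class = "dendrosap_input_error")
  }
  m <- ceiling(top_fraction * n)
  divisor <- mean(sort(ref, decreasing = TRUE)[seq_len(m)])
  if (!is.finite(divisor) || divisor <= 0) {
    abort("cannot normalise: the top of the reference series is not positive (all-zero series?)",
          class = "dendrosap_input_error")
  }
  out <- x / divisor
  attr(out, "divisor") <- divisor
  out
}

#' Total radial increment over a window
#'
#' Growth over the window under the zero-growth concept: the rise of the
#' running maximum from the first observation inside the window to the last,
#' reported in mm.  A trace that only shrinks yields 0 (the running maximum
#' never rises).
#'
#' @param trace Data frame for a single tree with `timestamp` and
#'   `radius_disp` (um).
#' @param window Length-2 date range that the trace must cover.
#' @return Increment in mm (scalar).
#' @export
total_increment <- function(trace, window) {
  assert_cols(trace, c("timestamp", "radius_disp"), "trace")
  window <- as_date_strict(window, "increment window")
  d <- as_day(trace$timestamp)
  inside <- which(d >= window[1] & d <= window[2] & !is.na(trace$radius_disp))
  if (length(inside) == 0L) {
    abort("trace does not cover the increment window",
          class = "dendrosap_input_error")
  }
  covered <- range(d[inside])
  if (covered[1] > window[1] + 7 || covered[2] < window[2] - 7) {
    abort(sprintf("trace covers %s..%s but the window is %s..%s",
                  covered[1], covered[2], window[1], window[2]),
          class = "dendrosap_input_error")
  }
  x <- trace$radius_disp[inside][order(trace$timestamp[inside])]
  rm <- cummax_na(x)
  (tail(rm, 1L) - x[1L]) / 1000
}

#' Growth relative to the mean ring width of previous years
#'
#' @param increment Radial increment of the observed season, mm.
#' @param prior_mean Mean annual ring width of the reference decade, mm
#'   (must be positive).  Ring widths and dendrometer increments are not 1:1
#'   comparable (the latter includes bark tissue); the raw ratio is reported.
#' @return Percentage `100 * increment / prior_mean`.
#' @examples
#' growth_ratio(1.39, 2.51)  # ~55
#' @export
growth_ratio <- function(increment, prior_mean) {
  if (any(prior_mean <= 0, na.rm = TRUE)) {
    abort("prior_mean ring width must be positive",
          class = "dendrosap_input_error")
  }
  100 * increment / prior_mean
}

#' Basal-area increment and relative basal-area increment
#'
#' With stem radius `r = dbh/2` (converted to mm) and a radial increment
#' `i`, the season's areal gain is `bai = pi * (r^2 - (r - i)^2)` and the
#' relative gain `rbai = 100 * (r^2 - (r - i)^2) / r^2` expresses it as a
#' percentage of the stem's basal area, compensating for tree size.
#'
#' @param dbh Diameter at breast height, cm (> 0).
#' @param increment Radial increment, mm; must be non-negative and smaller
#'   than the stem radius.
#' @return Tibble with columns `bai` (mm^2) and `rbai` (%).
#' @export
rbai <- function(dbh, increment) {
  if (any(dbh <= 0, na.rm = TRUE)) {
    abort("dbh must be positive", class = "dendrosap_input_error")
  }
  if (any(increment < 0, na.rm = TRUE)) {
    abort("increment must be non-negative", class = "dendrosap_input_error")
  }
  r <- dbh / 2 * 10  # mm
  if (any(increment >= r, na.rm = TRUE)) {
    abort("increment must be smaller than the stem radius",
          class = "dendrosap_input_error")
  }
  area <- r^2 - (r - increment)^2
  tibble(bai = pi * area, rbai = 100 * area / r^2)
}
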