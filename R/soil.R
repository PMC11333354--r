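#' Clean raw soil-moisture sensor series
#'
#' Two reproducible rules stand in for "outliers and obvious errors":
#' physically impossible values (outside `range`, default 0--60 % volumetric)
#' are removed, and isolated spikes -- a single-step jump larger than
#' `spike_jump` percentage points that returns to within `spike_jump` of the
#' pre-jump level within `spike_return` samples -- are removed.  Gaps are
#' left as `NA`, never interpolated.
#'
#' @param sensors Long data frame with columns `site_id`, `sensor_id`,
#'   `depth`, `timestamp`, `vswc` (hourly, % volumetric).
#' @param range Plausible physical range of volumetric water content, %.
#' @param spike_jump Jump size (percentage points) that marks a spike.
#' @param spike_return Maximum number of samples after which the series must
#'   be back near the pre-jump level for the excursion to count as a spike.
#' @return The input tibble with spike/out-of-range values set to `NA`.  A
#'   warning names any sensor losing more than half of its samples.
#' @export
clean_vswc <- function(sensors, range = c(0, 60), spike_jump = 5,
                       spike_return = 2L) {
  assert_cols(sensors, c("sensor_id", "timestamp", "vswc"), "sensors")
  grouping <- intersect(c("site_id", "sensor_id", "depth"), names(sensors))
  df <- as_tibble(sensors) |>
    arrange(across(all_of(c(grouping, "timestamp"))))
  key <- interaction(df[grouping], drop = TRUE)
  for (idx in split(seq_len(nrow(df)), key)) {
    df$vswc[idx] <- clean_vswc_vec(df$vswc[idx], range, spike_jump,
                                   spike_return,
                                   label = as.character(df$sensor_id[idx[1]]))
  }
  df
}

clean_vswc_vec <- function(x, range, spike_jump, spike_return, label = "?") {
  n_in <- sum(!is.na(x))
  x[!is.na(x) & (x < range[1] | x > range[2])] <- NA_real_
  n <- length(x)
  if (n >= 3L) {
    drop <- logical(n)
    i <- 2L
    while (i < n) {
      prev <- x[i - 1L]
      if (!is.na(prev) && !is.na(x[i]) && abs(x[i] - prev) > spike_jump) {
        # look for a return to the pre-jump level within spike_return steps
        jmax <- min(n, i + spike_return)
        back <- which(!is.na(x[(i + 1L):jmax]) &
                        abs(x[(i + 1L):jmax] - prev) <= spike_jump)
        if (length(back) > 0L) {
          j <- i + back[1L]           # first sample that is back in band
          drop[i:(j - 1L)] <- TRUE
          i <- j
          next
        }
      }
      i <- i + 1L
    }
    x[drop] <- NA_real_
  }
  n_out <- sum(!is.na(x))
  if (n_in > 0L && n_out < n_in / 2) {
    warn(sprintf("sensor %s: more than half of its samples were removed during cleaning",
                 label), class = "dendrosap_cleaning_warning")
  }
  x
}

#' Average cleaned sensors to a site-level soil-moisture series
#'
#' Per timestamp (and depth) mean over the sensors that report a value, with
#' the number of contributing sensors recorded.  Timestamps at which no
#' sensor reports give `NA`.
#'
#' @param sensors Cleaned long sensor table (see [clean_vswc()]).
#' @return Tibble with `site_id`, `depth`, `timestamp`, `vswc_mean`,
#'   `n_sensors_used`.
#' @export
site_mean_vswc <- function(sensors) {
  assert_cols(sensors, c("site_id", "depth", "timestamp", "vswc"), "sensors")
  as_tibble(sensors) |>
    group_by(.data$site_id, .data$depth, .data$timestamp) |>
    summarise(n_sensors_used = sum(!is.na(.data$vswc)),
              vswc_mean = if (any(!is.na(.data$vswc)))
                mean(.data$vswc, na.rm = TRUE) else NA_real_,
              .groups = "drop") |>
    select("site_id", "depth", "timestamp", "vswc_mean", "n_sensors_used") |>
    arrange(.data$site_id, .data$depth, .data$timestamp)
}

#' Seasonal extrema of site soil moisture (field-capacity / wilting proxies)
#'
#' The maximum and minimum site-mean volumetric water content observed within
#' the calibration window are used as proxies for field capacity and the
#' permanent wilting point when rescaling to relative extractable water.
#' The whole observation season (nominally March--October) should be used.
#'
#' @param site_series Output of [site_mean_vswc()].
#' @param window Optional length-2 date range restricting the calibration
#'   window; default uses all data.  Windows shorter than 30 days raise a
#'   warning (extrema over a short window are unlikely to approximate field
#'   capacity and wilting point).
#' @return Tibble with `site_id`, `depth`, `vswc_min`, `vswc_max`,
#'   `window_start`, `window_end`.  A constant series (degenerate
#'   `vswc_min == vswc_max`) is an error.
#' @export
soil_calibration <- function(site_series, window = NULL) {
  assert_cols(site_series, c("site_id", "depth", "timestamp", "vswc_mean"),
              "site_series")
  df <- as_tibble(site_series)
  if (!is.null(window)) {
    window <- as_date_strict(window, "calibration window")
    if (diff(as.numeric(window)) < 30) {
      warn("calibration window shorter than 30 days: extrema are likely unrepresentative",
           class = "dendrosap_calibration_warning")
    }
    d <- as_day(df$timestamp)
    df <- df[d >= window[1] & d <= window[2], ]
  }
  out <- df |>
    filter(!is.na(.data$vswc_mean)) |>
    group_by(.data$site_id, .data$depth) |>
    summarise(vswc_min = min(.data$vswc_mean),
              vswc_max = max(.data$vswc_mean),
              window_start = min(as_day(.data$timestamp)),
              window_end = max(as_day(.data$timestamp)),
              .groups = "drop")
  if (any(out$vswc_max <= out$vswc_min)) {
    abort("degenerate soil calibration: vswc_max <= vswc_min (constant series?)",
          class = "dendrosap_calibration_error")
  }
  out
}

#' Relative extractable water
#'
#' `REW = (VSWC - VSWCmin) / (VSWCmax - VSWCmin)`, the fraction of the
#' plant-extractable soil water still present, 0 at the wilting-point proxy
#' and 1 at the field-capacity proxy.  Values falling outside the calibration
#' range (possible when the analysis window differs from the calibration
#' window) are clipped to \[0, 1\]; the number of clipped points is attached
#' as attribute `n_clipped`.
#'
#' @param vswc Volumetric soil water content, %.
#' @param vswc_min,vswc_max Calibration extrema, % (`vswc_min < vswc_max`).
#' @param clip Clip results to \[0, 1\] (default `TRUE`).
#' @return Numeric vector of REW fractions.
#' @examples
#' rew(14.35, 6.4, 22.3)  # 0.5
#' @export
rew <- function(vswc, vswc_min, vswc_max, clip = TRUE) {
  if (any(vswc_max <= vswc_min)) {
    abort("vswc_max must exceed vswc_min", class = "dendrosap_input_error")
  }
  r <- (vswc - vswc_min) / (vswc_max - vswc_min)
  n_clipped <- sum(r < 0 | r > 1, na.rm = TRUE)
  if (clip) r <- pmin(pmax(r, 0), 1)
  attr(r, "n_clipped") <- n_clipped
  r
}

#' Daily extrema of relative extractable water
#'
#' Converts the hourly site series to REW and reduces it to per-day maximum
#' and minimum.  The analysis downstream pairs tree water deficit against the
#' site's daily maximum REW.
#'
#' @param site_series Output of [site_mean_vswc()] (one site and depth).
#' @param calibration One row of [soil_calibration()] for the same site and
#'   depth.
#' @return Tibble with `site_id`, `depth`, `date`, `rew_max`, `rew_min`,
#'   `n_hours`; fully missing days are dropped.  The total number of clipped
#'   hourly points is attached as attribute `n_clipped`.
#' @export
daily_rew <- function(site_series, calibration) {
  assert_cols(site_series, c("site_id", "depth", "timestamp", "vswc_mean"),
              "site_series")
  assert_cols(calibration, c("site_id", "depth", "vswc_min", "vswc_max"),
              "calibration")
  df <- as_tibble(site_series) |>
    inner_join(as_tibble(calibration)[, c("site_id", "depth", "vswc_min",
                                          "vswc_max")],
               by = c("site_id", "depth"))
  if (nrow(df) == 0L) {
    abort("site_series and calibration share no site_id/depth",
          class = "dendrosap_input_error")
  }
  r <- rew(df$vswc_mean, df$vswc_min, df$vswc_max)
  df$rew <- as.numeric(r)
  out <- df |>
    mutate(date = as_day(.data$timestamp)) |>
    group_by(.data$site_id, .data$depth, .data$date) |>
    summarise(n_hours = sum(!is.na(.data$rew)),
              rew_max = if (any(!is.na(.data$rew)))
                max(.data$rew, na.rm = TRUE) else NA_real_,
              rew_min = if (any(!is.na(.data$rew)))
                min(.data$rew, na.rm = TRUE) else NA_real_,
              .groups = "drop") |>
    filter(.data$n_hours > 0L)
  attr(out, "n_clipped") <- attr(r, "n_clipped")
  out
}
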