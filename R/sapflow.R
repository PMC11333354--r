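#' Zero-flow baseline for a thermal-dissipation trace
#'
#' Granier-type sensors report the temperature excess `delta_t` of a
#' constantly heated probe over an unheated reference; the excess is largest
#' at zero flow.  The baseline takes each day's maximum `delta_t` (at the
#' time it occurs) as a zero-flow anchor and interpolates linearly between
#' consecutive anchors; before the first and after the last anchor it is held
#' constant.  Days with no valid sample contribute no anchor, so the
#' interpolation spans the gap.
#'
#' @param trace Data frame with `tree_id`, `timestamp` (10-min) and
#'   `delta_t` (degC).
#' @return The input tibble with a `delta_t_max` baseline column appended.
#' @export
build_baseline <- function(trace) {
  assert_cols(trace, c("tree_id", "timestamp", "delta_t"), "trace")
  as_tibble(trace) |>
    group_by(.data$tree_id) |>
    arrange(.data$timestamp, .by_group = TRUE) |>
    mutate(delta_t_max = baseline_vec(.data$timestamp, .data$delta_t)) |>
    ungroup()
}

baseline_vec <- function(timestamp, delta_t) {
  ok <- !is.na(delta_t)
  if (!any(ok)) return(rep(NA_real_, length(delta_t)))
  day <- as_day(timestamp)
  idx <- which(ok)
  split_idx <- split(idx, day[idx])
  anchors <- vapply(split_idx, function(i) i[which.max(delta_t[i])], integer(1))
  at <- as.numeric(timestamp[anchors])
  av <- delta_t[anchors]
  if (length(anchors) == 1L) return(rep(av, length(delta_t)))
  approx(at, av, xout = as.numeric(timestamp), rule = 2)$y
}

#' Granier flow index K
#'
#' `K = (delta_t_max - delta_t) / delta_t`, floored at zero (baseline noise
#' can make the instantaneous excess exceed the interpolated zero-flow
#' reference).  Non-positive `delta_t` marks an invalid sample and returns
#' `NA`.
#'
#' @param delta_t Measured temperature excess, degC.
#' @param delta_t_max Zero-flow baseline at the same instant, degC.
#' @return Dimensionless flow index, `NA` for invalid samples.
#' @export
granier_k <- function(delta_t, delta_t_max) {
  k <- pmax((delta_t_max - delta_t) / delta_t, 0)
  k[!is.na(delta_t) & delta_t <= 0] <- NA_real_
  k
}

#' Sap flux density from the flow index
#'
#' Empirical Granier calibration `u = coefficient * K^exponent` in
#' g cm^-2 s^-1; the canonical coefficients (0.0119, 1.231) are the package
#' defaults and configurable.
#'
#' @param k Dimensionless flow index (>= 0).
#' @param coefficient Calibration coefficient, g cm^-2 s^-1.
#' @param exponent Calibration exponent.
#' @return Flux density in g cm^-2 s^-1.
#' @export
flux_density <- function(k, coefficient = 0.0119, exponent = 1.231) {
  coefficient * k^exponent
}

#' Daily whole-tree sap flow
#'
#' Scales flux density by the tree's sapwood area (uniform flux over the
#' conducting area is assumed, matching plain area scaling) and sums the
#' 10-minute samples to daily totals in kg per day.  Days missing more than
#' `max_missing` of their 144 samples are flagged.
#'
#' @param trace Data frame with `tree_id`, `timestamp`, `delta_t`, and
#'   `delta_t_max` (see [build_baseline()]).
#' @param hydraulics Data frame with `tree_id` and `sapwood_area` (cm^2).
#' @param coefficient,exponent Granier calibration, see [flux_density()].
#' @param step_s Sampling interval in seconds (default 600).
#' @param max_missing Maximum tolerated fraction of missing samples per day.
#' @return Tibble with `tree_id`, `date`, `flow_kg`, `n_obs`, `flagged`.
#' @export
whole_tree_daily <- function(trace, hydraulics, coefficient = 0.0119,
                             exponent = 1.231, step_s = 600,
                             max_missing = 0.25) {
  assert_cols(trace, c("tree_id", "timestamp", "delta_t", "delta_t_max"),
              "trace")
  assert_cols(hydraulics, c("tree_id", "sapwood_area"), "hydraulics")
  n_expected <- 86400 / step_s
  as_tibble(trace) |>
    inner_join(as_tibble(hydraulics)[, c("tree_id", "sapwood_area")],
               by = "tree_id") |>
    mutate(k = granier_k(.data$delta_t, .data$delta_t_max),
           u = flux_density(.data$k, coefficient, exponent),
           date = as_day(.data$timestamp)) |>
    group_by(.data$tree_id, .data$date) |>
    summarise(n_obs = sum(!is.na(.data$u)),
              flow_kg = sum(.data$u * .data$sapwood_area * step_s,
                            na.rm = TRUE) / 1000,
              .groups = "drop") |>
    mutate(flow_kg = ifelse(.data$n_obs == 0L, NA_real_, .data$flow_kg),
           flagged = .data$n_obs < (1 - max_missing) * n_expected)
}

#' Synthesise a thermal-dissipation trace that reproduces target daily flows
#'
#' Inverts the Granier chain: a smooth diurnal flux profile (zero at night)
#' is scaled so its daily integral matches each target total, converted to
#' the flow index `K = (u / coefficient)^(1/exponent)` and to a temperature
#' excess `delta_t = delta_t_max / (1 + K)`.  Because flow is zero at night,
#' each day's maximum excess equals `delta_t_max`, so the forward pipeline's
#' interpolated baseline recovers the reference exactly and (with a constant
#' `delta_t_max`) the round trip reproduces the targets to numerical
#' precision.
#'
#' @param daily_flow Data frame with `date` and `flow_kg` (targets, kg/day),
#'   optionally `tree_id`.
#' @param sapwood_area Sapwood area of the tree, cm^2.
#' @param delta_t_max Zero-flow temperature excess, degC (scalar).
#' @param coefficient,exponent Granier calibration, see [flux_density()].
#' @param step_s Sampling interval in seconds (default 600).
#' @param min_delta_t Smallest representable excess, degC; targets that would
#'   require `delta_t` below this (too large a flow index) are an error.
#' @return Tibble with `tree_id`, `timestamp`, `delta_t` at `step_s`
#'   resolution covering every target day.
#' @export
simulate_inverse <- function(daily_flow, sapwood_area, delta_t_max = 10,
                             coefficient = 0.0119, exponent = 1.231,
                             step_s = 600, min_delta_t = 0.1) {
  assert_cols(daily_flow, c("date", "flow_kg"), "daily_flow")
  if (any(daily_flow$flow_kg < 0, na.rm = TRUE)) {
    abort("target daily flow must be non-negative",
          class = "dendrosap_input_error")
  }
  tree_id <- if ("tree_id" %in% names(daily_flow))
    daily_flow$tree_id[1L] else "tree"
  n_per_day <- as.integer(86400 / step_s)
  hour <- (seq_len(n_per_day) - 1L) * step_s / 3600
  # daylight bell, zero outside 06:00-21:00, unit integral over the day
  shape <- pmax(0, sin(pi * (hour - 6) / 15))^2
  shape <- shape / sum(shape * step_s)
  k_max <- delta_t_max / min_delta_t - 1
  u_max <- flux_density(k_max, coefficient, exponent)
  rows <- lapply(seq_len(nrow(daily_flow)), function(i) {
    d <- daily_flow$date[i]
    target_g <- daily_flow$flow_kg[i] * 1000
    u <- target_g * shape / sapwood_area  # g cm^-2 s^-1
    if (any(u > u_max)) {
      abort(sprintf("target flow on %s exceeds the representable flow index",
                    format(d)), class = "dendrosap_input_error")
    }
    k <- (u / coefficient)^(1 / exponent)
    tibble(tree_id = tree_id,
           timestamp = as.POSIXct(as.numeric(as.POSIXct(as.character(d),
                                                        tz = "UTC")) +
                                    (seq_len(n_per_day) - 1L) * step_s,
                                  tz = "UTC", origin = "1970-01-01"),
           delta_t = delta_t_max / (1 + k))
  })
  list_rbind(rows)
}
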