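#' Saturation vapor pressure of air (Magnus form)
#'
#' FAO-56 Magnus formulation, `es(T) = 6.108 * exp(17.27 * T / (T + 237.3))`,
#' returned in hectopascal.  Strictly increasing in temperature over the
#' supported range.
#'
#' @param air_temp Air temperature in degrees Celsius; must lie in
#'   \[-40, 60\].
#' @return Saturation vapor pressure in hPa, same length as `air_temp`.
#'   `NA` inputs give `NA`.
#' @examples
#' saturation_vapor_pressure(0)   # 6.108
#' saturation_vapor_pressure(20)  # ~23.39
#' @export
saturation_vapor_pressure <- function(air_temp) {
  bad <- which(!is.na(air_temp) & (air_temp < -40 | air_temp > 60))
  if (length(bad) > 0L) {
    abort(sprintf("air temperature outside [-40, 60] degC at position(s) %s",
                  paste(head(bad, 5L), collapse = ", ")),
          class = "dendrosap_input_error")
  }
  6.108 * exp(17.27 * air_temp / (air_temp + 237.3))
}

#' Vapor pressure deficit from temperature and relative humidity
#'
#' `vpd = es(T) * (1 - RH/100)` in hPa.  Air pressure is accepted by the
#' tabular interface ([add_vpd()]) but not used: over land at the elevations
#' this package targets, VPD is insensitive to the barometric term.
#'
#' @param air_temp Air temperature, degC.
#' @param rel_humidity Relative humidity in percent, within \[0, 100\].
#' @return VPD in hPa (non-negative; exactly 0 at saturation).
#' @examples
#' vpd(20, 100)  # 0
#' vpd(20, 50)   # ~11.69
#' @export
vpd <- function(air_temp, rel_humidity) {
  bad <- which(!is.na(rel_humidity) & (rel_humidity < 0 | rel_humidity > 100))
  if (length(bad) > 0L) {
    abort(sprintf("relative humidity outside [0, 100] %% at position(s) %s",
                  paste(head(bad, 5L), collapse = ", ")),
          class = "dendrosap_input_error")
  }
  saturation_vapor_pressure(air_temp) * (1 - rel_humidity / 100)
}

#' Add a VPD column to an hourly meteorological table
#'
#' @param met Data frame with columns `timestamp` (POSIXct, hourly),
#'   `air_temp` (degC) and `rel_humidity` (%).  A `pressure` column (hPa) may
#'   be present and is carried through unchanged.
#' @return `met` as a tibble with a `vpd` column (hPa) appended.  Errors name
#'   the first offending timestamp when a value is out of physical range.
#' @export
add_vpd <- function(met) {
  assert_cols(met, c("timestamp", "air_temp", "rel_humidity"), "met")
  bad_t <- which(!is.na(met$air_temp) & (met$air_temp < -40 | met$air_temp > 60))
  if (length(bad_t) > 0L) {
    abort(sprintf("air temperature out of range at timestamp %s",
                  format(met$timestamp[bad_t[1L]])),
          class = "dendrosap_input_error")
  }
  bad_h <- which(!is.na(met$rel_humidity) &
                   (met$rel_humidity < 0 | met$rel_humidity > 100))
  if (length(bad_h) > 0L) {
    abort(sprintf("relative humidity out of range at timestamp %s",
                  format(met$timestamp[bad_h[1L]])),
          class = "dendrosap_input_error")
  }
  as_tibble(met) |>
    mutate(vpd = vpd(.data$air_temp, .data$rel_humidity))
}

#' Daily maximum VPD and the high evaporative-demand mask
#'
#' Collapses an hourly VPD series to one row per calendar day with the daily
#' maximum and a logical `high_demand` flag (`vpd_max > threshold`; the
#' default 10 hPa is the 1 kPa filter used when relating sap flow to soil
#' drying).  Days where more than `max_missing` of the 24 hours are absent or
#' `NA` are kept but flagged `incomplete` with `vpd_max = NA`: a maximum over
#' a sparse day is biased low.
#'
#' @param met Data frame with `timestamp` and `vpd` columns (see
#'   [add_vpd()]).
#' @param threshold High-demand threshold in hPa (default 10 = 1 kPa).
#' @param max_missing Maximum tolerated fraction of missing hours per day
#'   (default 0.25).
#' @return Tibble with columns `date`, `vpd_max`, `high_demand`, `n_hours`,
#'   `incomplete`.  Empty input gives an empty tibble with a warning.
#' @export
daily_max_vpd <- function(met, threshold = 10, max_missing = 0.25) {
  assert_cols(met, c("timestamp", "vpd"), "met")
  if (nrow(met) == 0L) {
    warn("empty meteorological series; returning no daily records")
    return(tibble(date = as.Date(character()), vpd_max = double(),
                  high_demand = logical(), n_hours = integer(),
                  incomplete = logical()))
  }
  out <- as_tibble(met) |>
    mutate(date = as_day(.data$timestamp)) |>
    group_by(date = .data$date) |>
    summarise(n_hours = sum(!is.na(.data$vpd)),
              vpd_max = if (any(!is.na(.data$vpd)))
                max(.data$vpd, na.rm = TRUE) else NA_real_,
              .groups = "drop") |>
    mutate(incomplete = .data$n_hours < ceiling(24 * (1 - max_missing)),
           vpd_max = ifelse(.data$incomplete, NA_real_, .data$vpd_max),
           high_demand = .data$vpd_max > threshold)
  out[, c("date", "vpd_max", "high_demand", "n_hours", "incomplete")]
}
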