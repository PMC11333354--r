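#' Analysis configuration
#'
#' All tunable parameters of the site analysis with their defaults: the
#' analysis window (day-of-year 106-244, April 15 to August 31), the REW
#' calibration window (the whole March-October season), the fixed tangent
#' slope (-3), the high evaporative-demand VPD threshold (10 hPa = 1 kPa),
#' the REW range of the sap-flow decline fit (\[0, 0.5\]), the drought
#' percentile (0.10), the relative-TWD quantile for the maximum-TWD
#' statistic (0.9), the top fraction of the relative normalisation (0.025),
#' the soil depth analysed (20 cm) and the Granier calibration.
#'
#' @param window_doy Analysis window as day-of-year limits.
#' @param calibration_window REW calibration window (month-day strings,
#'   applied to the data's year), default March 1 to October 31.
#' @param tangent_slope Fixed tangent slope for the threshold construction.
#' @param vpd_threshold High-demand threshold, hPa.
#' @param decline_range REW range of the decline fit.
#' @param drought_percentile REW percentile defining maximum drought.
#' @param twd_quantile Relative-TWD cutoff for the maximum-TWD statistic.
#' @param top_fraction Top fraction of the relative normalisation.
#' @param depth Soil depth analysed, cm.
#' @param granier_coefficient,granier_exponent Granier calibration.
#' @param twd_norm_basis Reference series for the TWD normalisation scale:
#'   `"daily_max"` (default; the series of daily maxima) or `"raw"` (all
#'   10-minute TWD values).
#' @return Object of class `analysis_config` (a list).
#' @export
analysis_config <- function(window_doy = c(106L, 244L),
                            calibration_window = c("03-01", "10-31"),
                            tangent_slope = -3, vpd_threshold = 10,
                            decline_range = c(0, 0.5),
                            drought_percentile = 0.10, twd_quantile = 0.9,
                            top_fraction = 0.025, depth = 20,
                            granier_coefficient = 0.0119,
                            granier_exponent = 1.231,
                            twd_norm_basis = c("daily_max", "raw")) {
  cfg <- as.list(environment())
  cfg$twd_norm_basis <- match.arg(twd_norm_basis)
  structure(cfg, class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat(sprintf(paste0("Analysis configuration: DOY %d-%d, tangent slope %g, ",
                     "VPD > %g hPa, decline REW [%g, %g], depth %g cm\n"),
              x$window_doy[1], x$window_doy[2], x$tangent_slope,
              x$vpd_threshold, x$decline_range[1], x$decline_range[2],
              x$depth), ...)
  invisible(x)
}

#' Write a synthetic site dataset as plain CSV files
#'
#' @param ds A `site_dataset` (see [simulate_site()]).
#' @param dir Target directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_site_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "site_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt_ts <- function(x) format(x, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  readr::write_csv(dplyr::transmute(ds$radius, tree_id = .data$tree_id,
                                    timestamp = fmt_ts(.data$timestamp),
                                    radius_um = .data$radius_disp),
                   file.path(dir, "radius.csv"))
  readr::write_csv(dplyr::transmute(ds$thermal, tree_id = .data$tree_id,
                                    timestamp = fmt_ts(.data$timestamp),
                                    delta_t_C = .data$delta_t),
                   file.path(dir, "thermal.csv"))
  readr::write_csv(dplyr::transmute(ds$soil, site_id = .data$site_id,
                                    sensor_id = .data$sensor_id,
                                    depth_cm = .data$depth,
                                    timestamp = fmt_ts(.data$timestamp),
                                    vswc_pct = .data$vswc),
                   file.path(dir, "soil.csv"))
  readr::write_csv(dplyr::transmute(ds$meteo,
                                    timestamp = fmt_ts(.data$timestamp),
                                    air_temp_C = .data$air_temp,
                                    rel_humidity_pct = .data$rel_humidity,
                                    pressure_hPa = .data$pressure),
                   file.path(dir, "meteo.csv"))
  readr::write_csv(ds$rain, file.path(dir, "rain.csv"))
  readr::write_csv(dplyr::transmute(ds$metadata, tree_id = .data$tree_id,
                                    dbh_cm = .data$dbh,
                                    sapwood_area_cm2 = .data$sapwood_area,
                                    tr_prior_mean_mm = .data$tr_prior_mean),
                   file.path(dir, "metadata.csv"))
  jsonlite::write_json(ds$truth, file.path(dir, "truth.json"),
                       digits = NA)
  invisible(dir)
}

#' Read a site dataset directory
#'
#' Reads the CSV schemas written by [write_site_dataset()] /
#' [make_fixture_suite()] back into the in-memory `site_dataset` layout.
#'
#' @param dir Dataset directory.
#' @return List with `radius`, `thermal`, `soil`, `meteo`, `rain`,
#'   `metadata` tibbles (and `truth` when a `truth.json` is present).
#' @export
read_site_dataset <- function(dir) {
  need <- c("radius.csv", "thermal.csv", "soil.csv", "meteo.csv",
            "metadata.csv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing) > 0L) {
    abort(sprintf("dataset directory '%s' is missing: %s", dir,
                  paste(missing, collapse = ", ")),
          class = "dendrosap_schema_error")
  }
  ts <- function(x) as.POSIXct(x, tz = "UTC")
  rd <- function(f) readr::read_csv(file.path(dir, f), show_col_types = FALSE,
                                    progress = FALSE)
  radius <- rd("radius.csv")
  assert_cols(radius, c("tree_id", "timestamp", "radius_um"), "radius.csv")
  thermal <- rd("thermal.csv")
  assert_cols(thermal, c("tree_id", "timestamp", "delta_t_C"), "thermal.csv")
  soil <- rd("soil.csv")
  assert_cols(soil, c("site_id", "sensor_id", "depth_cm", "timestamp",
                      "vswc_pct"), "soil.csv")
  meteo <- rd("meteo.csv")
  assert_cols(meteo, c("timestamp", "air_temp_C", "rel_humidity_pct"),
              "meteo.csv")
  metadata <- rd("metadata.csv")
  assert_cols(metadata, c("tree_id", "dbh_cm", "sapwood_area_cm2",
                          "tr_prior_mean_mm"), "metadata.csv")
  out <- list(
    radius = transmute(radius, tree_id = .data$tree_id,
                       timestamp = ts(.data$timestamp),
                       radius_disp = .data$radius_um),
    thermal = transmute(thermal, tree_id = .data$tree_id,
                        timestamp = ts(.data$timestamp),
                        delta_t = .data$delta_t_C),
    soil = transmute(soil, site_id = .data$site_id,
                     sensor_id = .data$sensor_id, depth = .data$depth_cm,
                     timestamp = ts(.data$timestamp), vswc = .data$vswc_pct),
    meteo = tibble(timestamp = ts(meteo$timestamp),
                   air_temp = meteo$air_temp_C,
                   rel_humidity = meteo$rel_humidity_pct),
    metadata = transmute(metadata, tree_id = .data$tree_id,
                         dbh = .data$dbh_cm,
                         sapwood_area = .data$sapwood_area_cm2,
                         tr_prior_mean = .data$tr_prior_mean_mm))
  if (file.exists(file.path(dir, "rain.csv"))) {
    out$rain <- rd("rain.csv")
  }
  if (file.exists(file.path(dir, "truth.json"))) {
    out$truth <- as_tibble(jsonlite::read_json(file.path(dir, "truth.json"),
                                               simplifyVector = TRUE))
  }
  out
}

#' Validate a site dataset before analysis
#'
#' Schema check per table, clock-alignment check (regular sampling steps)
#' and coverage check of the analysis window.  Hard failures (missing files
#' or columns) abort; coverage problems are reported as warnings in the
#' returned report.
#'
#' @param data A dataset list (from [read_site_dataset()] or a
#'   [simulate_site()] result).
#' @param config An [analysis_config()].
#' @return Tibble report with columns `check`, `status` (`"ok"`/`"warning"`),
#'   `detail`.
#' @export
validate_site_dataset <- function(data, config = analysis_config()) {
  checks <- list()
  add <- function(check, status, detail = "") {
    checks[[length(checks) + 1L]] <<- tibble(check = check, status = status,
                                             detail = detail)
  }
  assert_cols(data$radius, c("tree_id", "timestamp", "radius_disp"), "radius")
  assert_cols(data$thermal, c("tree_id", "timestamp", "delta_t"), "thermal")
  assert_cols(data$soil, c("site_id", "sensor_id", "depth", "timestamp",
                           "vswc"), "soil")
  assert_cols(data$meteo, c("timestamp", "air_temp", "rel_humidity"), "meteo")
  assert_cols(data$metadata, c("tree_id", "dbh", "sapwood_area",
                               "tr_prior_mean"), "metadata")
  add("schema", "ok", "all tables carry the required columns")

  for (tb in c("radius", "thermal")) {
    steps <- data[[tb]] |>
      group_by(.data$tree_id) |>
      arrange(.data$timestamp, .by_group = TRUE) |>
      summarise(irregular = any(diff(as.numeric(.data$timestamp)) <= 0),
                .groups = "drop")
    if (any(steps$irregular)) {
      add(paste0(tb, " clock"), "warning",
          sprintf("non-increasing timestamps in: %s",
                  paste(steps$tree_id[steps$irregular], collapse = ", ")))
    } else {
      add(paste0(tb, " clock"), "ok", "timestamps strictly increasing")
    }
  }

  year <- format(min(data$meteo$timestamp), "%Y")
  win <- as.Date(paste0(year, "-01-01")) + config$window_doy - 1L
  for (tb in c("radius", "thermal", "soil", "meteo")) {
    d <- range(as_day(data[[tb]]$timestamp))
    if (d[1] > win[1] || d[2] < win[2]) {
      add(paste0(tb, " coverage"), "warning",
          sprintf("%s covers %s..%s but the analysis window is %s..%s",
                  tb, d[1], d[2], win[1], win[2]))
    } else {
      add(paste0(tb, " coverage"), "ok", "analysis window covered")
    }
  }
  trees_radius <- unique(data$radius$tree_id)
  no_meta <- setdiff(trees_radius, data$metadata$tree_id)
  if (length(no_meta) > 0L) {
    add("metadata", "warning",
        sprintf("trees without metadata: %s", paste(no_meta, collapse = ", ")))
  } else {
    add("metadata", "ok", "every tree has metadata")
  }
  list_rbind(checks)
}

#' Run the full site analysis
#'
#' Orchestrates the whole chain: VPD and the high-demand day mask; soil
#' cleaning, site averaging, REW calibration and daily REW; tree water
#' deficit, daily minima and relative normalisation; Granier baseline, flux
#' density, whole-tree daily sap flow and relative normalisation; the
#' exponential TWD-REW fit with the fixed-slope tangent threshold `k` (per
#' tree and for the site-mean series), the segmented-regression alternative,
#' the sap-flow decline fit (slope `m`), and the derived drought statistics.
#' Growth summaries (increment, growth ratio, BAI/rBAI) complete the
#' site report.
#'
#' @param data A dataset list: tibbles `radius`, `thermal`, `soil`, `meteo`,
#'   `metadata` (a [simulate_site()] result works directly).
#' @param config An [analysis_config()].
#' @param site_id Site label; defaults to the one in `data$soil`.
#' @return Object of class `site_analysis`: list with the intermediate daily
#'   tables, per-tree and site-level fits, flags, and `summary` /
#'   `tree_summary` / `growth` tibbles.
#' @export
run_site_analysis <- function(data, config = analysis_config(),
                              site_id = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  site_id <- site_id %||% as.character(data$soil$site_id[1])
  flags <- character()

  year <- format(min(data$meteo$timestamp, na.rm = TRUE), "%Y")
  window <- as.Date(paste0(year, "-01-01")) + config$window_doy - 1L
  cal_window <- as.Date(paste0(year, "-", config$calibration_window))

  # --- meteorology ---------------------------------------------------------
  met <- add_vpd(data$meteo)
  vpd_daily <- daily_max_vpd(met, threshold = config$vpd_threshold)

  # --- soil ----------------------------------------------------------------
  soil <- data$soil |> filter(.data$depth == config$depth)
  if (nrow(soil) == 0L) {
    abort(sprintf("no soil sensors at the configured depth (%g cm)",
                  config$depth), class = "dendrosap_input_error")
  }
  site_soil <- site_mean_vswc(clean_vswc(soil))
  calibration <- soil_calibration(site_soil, window = cal_window)
  rew_daily <- daily_rew(site_soil, calibration)
  n_clipped <- attr(rew_daily, "n_clipped")

  in_window <- function(d) d >= window[1] & d <= window[2]

  # --- tree water deficit --------------------------------------------------
  twd_all <- twd(data$radius)
  twd_daily <- daily_min_twd(twd_all)
  twd_daily <- twd_daily |>
    group_by(.data$tree_id) |>
    group_modify(function(df, key) {
      dfw <- df[in_window(df$date), ]
      ref <- if (config$twd_norm_basis == "daily_max") {
        dfw$twd_max
      } else {
        tw <- twd_all$twd[twd_all$tree_id == key$tree_id[1]]
        tw[in_window(as_day(twd_all$timestamp[twd_all$tree_id ==
                                                key$tree_id[1]]))]
      }
      scaled <- relative_normalize(df$twd_min, config$top_fraction,
                                   reference = ref)
      df$twd_min_rel <- as.numeric(scaled)
      df$twd_divisor <- attr(scaled, "divisor")
      df
    }) |>
    ungroup()

  # --- sap flow ------------------------------------------------------------
  sap_daily <- data$thermal |>
    build_baseline() |>
    whole_tree_daily(data$metadata,
                     coefficient = config$granier_coefficient,
                     exponent = config$granier_exponent) |>
    filter(!.data$flagged) |>
    group_by(.data$tree_id) |>
    group_modify(function(df, key) {
      scaled <- relative_normalize(df$flow_kg, config$top_fraction,
                                   reference = df$flow_kg[in_window(df$date)])
      df$flow_rel <- as.numeric(scaled)
      df$flow_divisor <- attr(scaled, "divisor")
      df
    }) |>
    ungroup()

  # --- site-mean daily series ---------------------------------------------
  site_twd <- twd_daily |>
    group_by(.data$date) |>
    summarise(twd_min_rel = mean(.data$twd_min_rel, na.rm = TRUE),
              n_trees = sum(is.finite(.data$twd_min_rel)), .groups = "drop")
  site_sap <- sap_daily |>
    group_by(.data$date) |>
    summarise(flow_rel = mean(.data$flow_rel, na.rm = TRUE),
              n_trees = sum(is.finite(.data$flow_rel)), .groups = "drop")

  fit_unit <- function(twd_df, sap_df, unit_id) {
    res <- list(unit_id = unit_id, exp_fit = NULL, k = NA_real_,
                piecewise = NULL, k_pw = NA_real_, decline = NULL,
                m = NA_real_, sap_at_k = NA_real_, sap_at_drought = NA_real_,
                sap_at_max_twd = NA_real_, flags = character())
    pairs <- withCallingHandlers(
      paired_daily_data(twd_df, rew_daily, window = window),
      warning = function(w) {
        if (inherits(w, "dendrosap_few_days_warning"))
          invokeRestart("muffleWarning")
      })
    res$pairs <- pairs
    res$exp_fit <- tryCatch(fit_twd_exponential(pairs),
                            error = function(e) {
                              res$flags <<- c(res$flags, conditionMessage(e))
                              NULL
                            },
                            warning = function(w) NULL)
    if (is.null(res$exp_fit)) {
      res$exp_fit <- tryCatch(
        suppressWarnings(fit_twd_exponential(pairs)),
        error = function(e) NULL)
    }
    if (!is.null(res$exp_fit)) {
      k <- tryCatch(tangent_threshold(res$exp_fit,
                                      slope = config$tangent_slope),
                    error = function(e) {
                      res$flags <<- c(res$flags, "no tangent point")
                      NA_real_
                    },
                    warning = function(w) {
                      suppressWarnings(tangent_threshold(
                        res$exp_fit, slope = config$tangent_slope))
                    })
      res$k <- as.numeric(k)
      res$piecewise <- tryCatch(piecewise_threshold(pairs),
                                error = function(e) NULL)
      if (!is.null(res$piecewise)) res$k_pw <- res$piecewise$k_pw
    } else {
      res$flags <- c(res$flags, "degenerate TWD-REW fit")
    }
    res$decline <- tryCatch(
      fit_sapflow_decline(sap_df[in_window(sap_df$date), ], rew_daily,
                          vpd_daily, rew_range = config$decline_range),
      error = function(e) {
        res$flags <<- c(res$flags, "decline fit refused")
        NULL
      })
    if (!is.null(res$decline)) {
      res$m <- res$decline$m
      if (is.finite(res$k)) {
        res$sap_at_k <- sapflow_at_threshold(res$decline, res$k)
      }
    }
    sapw <- sap_df[in_window(sap_df$date), ]
    res$sap_at_drought <- tryCatch(
      as.numeric(suppressWarnings(sapflow_at_max_drought(
        sapw, rew_daily, percentile = config$drought_percentile))),
      error = function(e) NA_real_)
    twdw <- twd_df[in_window(twd_df$date), ]
    res$sap_at_max_twd <- as.numeric(suppressWarnings(
      sapflow_at_max_twd(sapw, twdw, threshold = config$twd_quantile)))
    res
  }

  site_fit <- fit_unit(site_twd, site_sap, site_id)
  tree_ids <- sort(unique(twd_daily$tree_id))
  tree_fits <- lapply(tree_ids, function(id) {
    fit_unit(twd_daily[twd_daily$tree_id == id, ],
             sap_daily[sap_daily$tree_id == id, ], id)
  })
  names(tree_fits) <- tree_ids

  # --- growth summaries ----------------------------------------------------
  growth <- list_rbind(lapply(tree_ids, function(id) {
    tr <- data$radius[data$radius$tree_id == id, ]
    inc <- tryCatch(total_increment(tr, window), error = function(e) NA_real_)
    md <- data$metadata[data$metadata$tree_id == id, ]
    if (nrow(md) == 0L || !is.finite(inc)) {
      return(tibble(tree_id = id, increment = inc, tr_prior_mean = NA_real_,
                    growth_ratio = NA_real_, dbh = NA_real_,
                    bai = NA_real_, rbai = NA_real_))
    }
    ba <- rbai(md$dbh[1], inc)
    tibble(tree_id = id, increment = inc, tr_prior_mean = md$tr_prior_mean[1],
           growth_ratio = growth_ratio(inc, md$tr_prior_mean[1]),
           dbh = md$dbh[1], bai = ba$bai, rbai = ba$rbai)
  }))

  tree_summary <- list_rbind(lapply(tree_fits, function(r) {
    tibble(unit_id = r$unit_id,
           k = r$k, r2_twd = if (!is.null(r$exp_fit)) r$exp_fit$r2 else NA_real_,
           k_pw = r$k_pw,
           m = r$m, r2_sapflow = if (!is.null(r$decline)) r$decline$r2 else NA_real_,
           sapflow_at_k = r$sap_at_k,
           sapflow_at_max_drought = r$sap_at_drought,
           sapflow_at_max_twd = r$sap_at_max_twd,
           flags = paste(r$flags, collapse = "; "))
  }))

  summary_tbl <- tibble(
    site_id = site_id,
    n_trees = length(tree_ids),
    k = site_fit$k,
    k_pct = 100 * site_fit$k,
    r2_twd = if (!is.null(site_fit$exp_fit)) site_fit$exp_fit$r2 else NA_real_,
    k_pw = site_fit$k_pw,
    m = site_fit$m,
    r2_sapflow = if (!is.null(site_fit$decline)) site_fit$decline$r2 else NA_real_,
    sapflow_at_k = site_fit$sap_at_k,
    sapflow_at_max_drought = site_fit$sap_at_drought,
    sapflow_at_max_twd = site_fit$sap_at_max_twd,
    mean_k_trees = mean(tree_summary$k, na.rm = TRUE),
    mean_m_trees = mean(tree_summary$m, na.rm = TRUE),
    flags = paste(site_fit$flags, collapse = "; "))

  structure(list(site_id = site_id, config = config, window = window,
                 vpd_daily = vpd_daily, calibration = calibration,
                 rew_daily = rew_daily, n_rew_clipped = n_clipped,
                 twd_daily = twd_daily, sap_daily = sap_daily,
                 site_twd = site_twd, site_sap = site_sap,
                 site_fit = site_fit, tree_fits = tree_fits,
                 growth = growth, tree_summary = tree_summary,
                 summary = summary_tbl),
            class = "site_analysis")
}

#' @export
print.site_analysis <- function(x, ...) {
  cat(sprintf("Site analysis '%s' (%s to %s)\n", x$site_id,
              x$window[1], x$window[2]))
  s <- x$summary
  if (is.finite(s$k)) {
    cat(sprintf("  threshold k = %.3f REW (%.1f %%), R2 of TWD-REW fit = %.2f\n",
                s$k, s$k_pct, s$r2_twd))
  } else {
    cat(sprintf("  threshold k: not determined (%s)\n",
                if (nzchar(s$flags)) s$flags else "no fit"))
  }
  if (is.finite(s$m)) {
    cat(sprintf("  sap-flow decline m = %.2f %%/%% (R2 = %.2f); sap flow at k = %.1f %%\n",
                s$m, s$r2_sapflow, s$sapflow_at_k))
  } else {
    cat("  sap-flow decline: fit refused (too few qualifying days)\n")
  }
  cat(sprintf("  sap flow at max drought = %.1f %%, at max TWD = %.1f %%\n",
              s$sapflow_at_max_drought, s$sapflow_at_max_twd))
  invisible(x)
}
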