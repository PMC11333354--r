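#' Configuration of a synthetic monitoring site
#'
#' Bundles every knob of the forward simulator that produces a complete
#' synthetic site dataset (rain, soil-moisture sensors, hourly meteorology,
#' 10-minute stem-radius and thermal-dissipation traces, tree metadata) with
#' known ground truth.  The two truth parameters are `k_true`, the REW
#' threshold at which stem water deficits persist overnight, and `m_true`,
#' the percent decline of relative daily sap flow per percent REW below 0.5.
#'
#' The latent stem water deficit is an exponential in REW whose steepness is
#' solved internally from `k_true` so that the fixed-slope(-3) tangent
#' construction applied to the latent relative curve intersects the x-axis
#' exactly at `k_true`: the generator is built as the inverse of the
#' inference it feeds.
#'
#' @param site_id Site label.
#' @param n_trees Number of trees (default 5).
#' @param season Length-2 date range generated (default 2022-04-08 to
#'   2022-09-08, a ~150-day growing season around the April-August analysis
#'   window).
#' @param k_true True REW threshold, in (0, 0.5).
#' @param m_true True sap-flow decline slope, %/% (positive).
#' @param rain_rate Poisson rain-event rate per day outside the drought
#'   spell.
#' @param rain_mean_mm Mean depth of a rain event (exponential), mm.
#' @param drought_window Length-2 date range of the summer drought spell.
#' @param drought_rain_factor Multiplier on `rain_rate` inside the spell.
#' @param vswc_min,vswc_max Wilting-point / field-capacity proxies, % VSWC.
#' @param rain_to_vswc Percentage points of VSWC added per mm of rain.
#' @param et_max Maximum daily soil-water draw-down, % VSWC per day.
#' @param et_vpd_ref VPD (hPa) at which atmospheric demand saturates.
#' @param et_rew_ref REW below which supply limits draw-down.
#' @param et_floor Lower bound of the supply factor (residual evaporation
#'   and deep uptake keep drying the profile near the wilting point).
#' @param vpd_amp Seasonal amplitude of daily maximum VPD, hPa.
#' @param vpd_day_sd Day-to-day log-scale VPD variability.
#' @param rain_vpd_factor VPD damping on rain days.
#' @param n_sensors Soil sensors per site (default 5).
#' @param depth Sensor depth, cm (default 20).
#' @param sensor_offset_sd Between-sensor constant offset sd, % VSWC.
#' @param sensor_ar,sensor_noise_sd AR(1) coefficient and innovation sd of
#'   hourly sensor noise.
#' @param growth_max Peak irreversible growth rate, um/day.
#' @param growth_gate_um Latent-deficit gate (um) below which the stem is
#'   considered fully hydrated and irreversible growth can proceed
#'   (zero-growth concept).
#' @param diurnal_um_per_hpa Reversible diurnal shrinkage per hPa of daily
#'   maximum VPD, um.
#' @param radius_noise_sd Dendrometer noise sd, um.
#' @param deficit_scale_um Target amplitude of the latent deficit at REW=0,
#'   um.
#' @param tree_amp_jitter Log-scale between-tree jitter of the latent
#'   deficit amplitude (the onset `k_true` and steepness are shared by all
#'   trees; amplitude differences are largely absorbed by the per-tree
#'   normalisation).
#' @param flow_max_kg Whole-tree daily sap flow under wet, high-demand
#'   conditions, kg/day.
#' @param sap_vpd_ref Daily maximum VPD (hPa) at which sap flow saturates.
#' @param sap_floor Lower bound of the relative sap-flow response.
#' @param sap_noise_sd Log-scale day-to-day sap-flow noise.
#' @param delta_t_max Zero-flow temperature excess of the synthetic probes,
#'   degC.
#' @param dt_noise_sd Thermal-trace noise sd, degC.
#' @param dbh_mean,dbh_sd Tree diameter distribution, cm.
#' @param sapwood_area_mean,sapwood_area_sd Sapwood area distribution, cm^2.
#' @param tr_prior_mean_mm,tr_prior_sd_mm Prior-decade mean ring width, mm.
#' @param noiseless Zero all stochastic noise terms (sensor, dendrometer,
#'   VPD day factor, sap flow, thermal, between-tree jitter); rain timing
#'   stays stochastic under `seed`.
#' @param seed Integer seed; identical configurations (including the seed)
#'   yield identical datasets.
#' @return Object of class `site_config` (a list).
#' @export
site_config <- function(site_id = "SYN", n_trees = 5L,
                        season = c("2022-04-08", "2022-09-08"),
                        k_true = 0.25, m_true = 1.5,
                        rain_rate = 0.35, rain_mean_mm = 5,
                        drought_window = c("2022-06-25", "2022-08-25"),
                        drought_rain_factor = 0.15,
                        vswc_min = 6, vswc_max = 22,
                        rain_to_vswc = 0.45, et_max = 0.8,
                        et_vpd_ref = 15, et_rew_ref = 0.5, et_floor = 0.35,
                        vpd_amp = 24, vpd_day_sd = 0.25,
                        rain_vpd_factor = 0.35,
                        n_sensors = 5L, depth = 20,
                        sensor_offset_sd = 1.0, sensor_ar = 0.8,
                        sensor_noise_sd = 0.3,
                        growth_max = 28, growth_gate_um = 10,
                        diurnal_um_per_hpa = 1.5,
                        radius_noise_sd = 1.5, deficit_scale_um = 350,
                        tree_amp_jitter = 0.15,
                        flow_max_kg = 40, sap_vpd_ref = 12, sap_floor = 0.02,
                        sap_noise_sd = 0.03, delta_t_max = 10,
                        dt_noise_sd = 0.02,
                        dbh_mean = 45, dbh_sd = 5,
                        sapwood_area_mean = 1000, sapwood_area_sd = 120,
                        tr_prior_mean_mm = 3, tr_prior_sd_mm = 0.4,
                        noiseless = FALSE, seed = 1L) {
  if (!(k_true > 0 && k_true < 0.5)) {
    abort("k_true must lie in (0, 0.5)", class = "dendrosap_input_error")
  }
  if (m_true <= 0) {
    abort("m_true must be positive", class = "dendrosap_input_error")
  }
  if (vswc_min >= vswc_max) {
    abort("vswc_min must be below vswc_max", class = "dendrosap_input_error")
  }
  cfg <- as.list(environment())
  cfg$season <- as_date_strict(season, "season")
  cfg$drought_window <- as_date_strict(drought_window, "drought window")
  if (noiseless) {
    cfg$vpd_day_sd <- 0
    cfg$sensor_offset_sd <- 0
    cfg$sensor_noise_sd <- 0
    cfg$radius_noise_sd <- 0
    cfg$sap_noise_sd <- 0
    cfg$dt_noise_sd <- 0
    cfg$tree_amp_jitter <- 0
  }
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "site_config")
}

#' @export
print.site_config <- function(x, ...) {
  cat(sprintf("Synthetic site '%s': %d trees, %s to %s\n", x$site_id,
              x$n_trees, x$season[1], x$season[2]))
  cat(sprintf("  truth: k = %.3f REW, m = %.2f %%/%%; VSWC range %.1f-%.1f %%; seed %d%s\n",
              x$k_true, x$m_true, x$vswc_min, x$vswc_max, x$seed,
              if (x$noiseless) " (noiseless)" else ""))
  invisible(x)
}

# expected extra contribution of the diurnal cycle to the daily-maximum TWD
# on the driest days (um), net of the small deficit present when the running
# maximum was last set (the growth gate) -- used when mapping k_true to the
# latent steepness
expected_diurnal_amp <- function(cfg) {
  cfg$diurnal_um_per_hpa * cfg$vpd_amp * 0.95 - 0.5 * cfg$growth_gate_um
}

# Solve the latent steepness b < 0 such that the tangent with slope -3 to the
# latent relative deficit curve a~ * exp(b * rew) crosses zero at k_true.
# The relative amplitude a~ = A / (A * exp(b * rew0) + amp0) anticipates the
# top-2.5% normalisation: the driest days sit near rew0 and carry the diurnal
# amplitude amp0 on top of the latent deficit.  onset_shift compensates the
# small downward pull that the running-max offset (deficits are measured
# relative to the last fully hydrated day, not to zero) exerts on the fitted
# curve; it was calibrated once on noiseless forward runs.
solve_latent_steepness <- function(k_true, A, amp0, rew0 = 0.01, slope = -3,
                                   onset_shift = 0.012) {
  k_true <- k_true + onset_shift
  khat <- function(b) {
    a_rel <- A / (A * exp(b * rew0) + amp0)
    if (a_rel * b > slope) return(Inf)  # curve never attains the slope
    x_star <- log(slope / (a_rel * b)) / b
    x_star - a_rel * exp(b * x_star) / slope
  }
  f <- function(b) khat(b) - k_true
  lo <- -80; hi <- -3.2
  while (!is.finite(f(hi)) && hi < -0.5) hi <- hi * 0.98
  if (!is.finite(f(hi)) || f(lo) * f(hi) > 0) {
    abort(sprintf("k_true = %.3f is outside the range representable by the latent deficit model",
                  k_true), class = "dendrosap_input_error")
  }
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Simulate the site environment (rain, soil moisture, meteorology)
#'
#' Daily rain events are Poisson with exponential depths (rate reduced
#' during the configured summer drought spell); site soil water follows a
#' daily bucket `VSWC[t+1] = VSWC[t] + alpha * rain[t] - ET[t]` clipped to
#' the configured extrema, with draw-down limited by atmospheric demand and
#' by supply; hourly sensor series add per-sensor offsets and AR(1) noise;
#' hourly temperature and humidity are constructed so that the VPD computed
#' from them follows a diurnal cycle (zero at night) peaking at the day's
#' target maximum.
#'
#' @param cfg A [site_config()].
#' @return List with tibbles `rain` (`date`, `rain_mm`), `soil` (long sensor
#'   table), `meteo` (hourly), and `daily` (internal per-day truth: site
#'   VSWC, true REW, target maximum VPD).
#' @export
simulate_environment <- function(cfg) {
  stopifnot(inherits(cfg, "site_config"))
  set.seed(child_seed(cfg$seed, 1L))
  dates <- seq(cfg$season[1], cfg$season[2], by = "day")
  n <- length(dates)
  dd <- doy(dates)

  in_drought <- dates >= cfg$drought_window[1] & dates <= cfg$drought_window[2]
  lambda <- cfg$rain_rate * ifelse(in_drought, cfg$drought_rain_factor, 1)
  events <- rpois(n, lambda)
  rain_mm <- vapply(events, function(e)
    if (e == 0L) 0 else sum(rexp(e, 1 / cfg$rain_mean_mm)), numeric(1))

  season_env <- pmax(0.15, 0.35 + 0.65 * sin(pi * (dd - 80) / 200))
  day_factor <- exp(rnorm(n, 0, cfg$vpd_day_sd)) *
    ifelse(rain_mm > 1, cfg$rain_vpd_factor, 1)
  vpd_max <- pmax(0.5, cfg$vpd_amp * season_env * day_factor)

  vswc <- numeric(n)
  vswc[1] <- cfg$vswc_max
  range_pct <- cfg$vswc_max - cfg$vswc_min
  for (t in seq_len(n - 1L)) {
    rew_t <- (vswc[t] - cfg$vswc_min) / range_pct
    et <- cfg$et_max * min(1, vpd_max[t] / cfg$et_vpd_ref) *
      min(1, max(rew_t / cfg$et_rew_ref, cfg$et_floor))
    vswc[t + 1L] <- min(cfg$vswc_max,
                        max(cfg$vswc_min,
                            vswc[t] + cfg$rain_to_vswc * rain_mm[t] - et))
  }
  rew_true <- (vswc - cfg$vswc_min) / range_pct

  daily <- tibble(date = dates, doy = dd, rain_mm = rain_mm,
                  vpd_max = vpd_max, vswc_site = vswc, rew_true = rew_true)

  # hourly soil sensors: site value held constant within the day
  hours <- seq(as.POSIXct(paste(cfg$season[1], "00:00:00"), tz = "UTC"),
               as.POSIXct(paste(cfg$season[2], "23:00:00"), tz = "UTC"),
               by = "hour")
  day_idx <- match(as_day(hours), dates)
  site_hourly <- vswc[day_idx]
  soil <- list_rbind(lapply(seq_len(cfg$n_sensors), function(s) {
    offset <- rnorm(1, 0, cfg$sensor_offset_sd)
    eps <- rnorm(length(hours), 0, cfg$sensor_noise_sd)
    ar <- numeric(length(hours))
    if (length(hours) > 0L) {
      ar[1] <- eps[1]
      for (t in seq_along(hours)[-1]) {
        ar[t] <- cfg$sensor_ar * ar[t - 1L] + eps[t]
      }
    }
    tibble(site_id = cfg$site_id,
           sensor_id = sprintf("%s_s%02d", cfg$site_id, s),
           depth = cfg$depth, timestamp = hours,
           vswc = pmin(59, pmax(0.5, site_hourly + offset + ar)))
  }))

  # hourly meteorology consistent with the target daily maximum VPD
  hod <- as.numeric(format(hours, "%H", tz = "UTC"))
  vpd_shape <- pmax(0, sin(pi * (hod - 7) / 12))^1.5  # zero at night, peak 13:00
  vpd_target <- vpd_max[day_idx] * vpd_shape
  t_max <- pmax(16, 8 + 0.75 * vpd_max[day_idx])
  air_temp <- t_max - 9 * (1 - pmax(0, sin(pi * (hod - 8) / 12)))
  es <- saturation_vapor_pressure(air_temp)
  rel_humidity <- pmin(100, pmax(3, 100 * (1 - vpd_target / es)))
  meteo <- tibble(timestamp = hours, air_temp = air_temp,
                  rel_humidity = rel_humidity, pressure = 950)

  list(rain = tibble(date = dates, rain_mm = rain_mm),
       soil = soil, meteo = meteo, daily = daily)
}

#' Simulate one tree (stem-radius and thermal-dissipation traces)
#'
#' The latent daily stem water deficit is `A * exp(b * REW)` (um) with the
#' steepness solved from `k_true` (see [site_config()]); irreversible growth
#' proceeds only while REW is above `k_true` (zero-growth gating); the
#' 10-minute radius trace adds a VPD-scaled reversible diurnal cycle and
#' dendrometer noise.  Relative daily sap flow saturates with evaporative
#' demand and declines linearly below REW 0.5 at `m_true` %/%; the
#' temperature-difference trace is produced by inverting the Granier chain
#' ([simulate_inverse()]).
#'
#' @param cfg A [site_config()].
#' @param env Output of [simulate_environment()] for the same config.
#' @param index Tree index (1-based), used for the tree's substream seed.
#' @return List with tibbles `radius`, `thermal`, `metadata` and the
#'   single-row `truth` record.
#' @export
simulate_tree <- function(cfg, env, index = 1L) {
  stopifnot(inherits(cfg, "site_config"))
  set.seed(child_seed(cfg$seed, 2L, index))
  tree_id <- sprintf("%s_t%02d", cfg$site_id, index)
  daily <- env$daily
  n <- nrow(daily)

  amp0 <- expected_diurnal_amp(cfg)
  b_site <- solve_latent_steepness(cfg$k_true, cfg$deficit_scale_um, amp0)
  b_i <- b_site
  a_rel <- (-3 / b_i) * exp(-b_i * (cfg$k_true + 0.012) - 1)
  w0 <- exp(b_i * 0.01)
  if (a_rel * w0 >= 1) {
    abort("latent amplitude not solvable for this steepness",
          class = "dendrosap_input_error")
  }
  # trees share the latent steepness (and hence the onset k_true); they
  # differ in deficit amplitude, which the per-tree normalisation absorbs
  A_i <- a_rel * amp0 / (1 - a_rel * w0) *
    exp(rnorm(1, 0, cfg$tree_amp_jitter))

  deficit <- A_i * exp(b_i * daily$rew_true)            # um, per day
  # zero-growth gating: cells divide only while the stem is near full
  # hydration, i.e. while the latent deficit is below a small gate
  grows <- deficit <= cfg$growth_gate_um
  genv <- pmax(0, sin(pi * (daily$doy - 95) / 170))
  growth <- cfg$growth_max * genv * grows

  # 10-minute grid
  n_per_day <- 144L
  step_s <- 600
  ts0 <- as.POSIXct(paste(daily$date[1], "00:00:00"), tz = "UTC")
  stamps <- ts0 + (seq_len(n * n_per_day) - 1L) * step_s
  day_i <- rep(seq_len(n), each = n_per_day)
  frac <- rep((seq_len(n_per_day) - 1L) / n_per_day, n)
  hour <- frac * 24
  cum_growth <- c(0, cumsum(growth))[day_i] + growth[day_i] * frac
  shrink_shape <- pmax(0, sin(pi * (hour - 7) / 13))^1.2  # midday shrinkage
  amp_d <- cfg$diurnal_um_per_hpa * daily$vpd_max
  radius <- 100 + cum_growth - amp_d[day_i] * shrink_shape -
    deficit[day_i] + rnorm(length(stamps), 0, cfg$radius_noise_sd)
  radius_tr <- tibble(tree_id = tree_id, timestamp = stamps,
                      radius_disp = radius)

  # relative daily sap flow and its thermal-dissipation trace
  r_soil <- ifelse(daily$rew_true >= 0.5, 1,
                   pmax(cfg$sap_floor,
                        1 - (cfg$m_true / 100) * (50 - 100 * daily$rew_true)))
  s_rel <- pmin(1, daily$vpd_max / cfg$sap_vpd_ref) * r_soil
  flow_kg <- cfg$flow_max_kg * s_rel * exp(rnorm(n, 0, cfg$sap_noise_sd))
  sapwood_area <- max(200, rnorm(1, cfg$sapwood_area_mean,
                                 cfg$sapwood_area_sd))
  thermal <- simulate_inverse(tibble(tree_id = tree_id, date = daily$date,
                                     flow_kg = flow_kg),
                              sapwood_area = sapwood_area,
                              delta_t_max = cfg$delta_t_max)
  if (cfg$dt_noise_sd > 0) {
    thermal$delta_t <- pmax(0.05, thermal$delta_t +
                              rnorm(nrow(thermal), 0, cfg$dt_noise_sd))
  }

  dbh <- max(15, rnorm(1, cfg$dbh_mean, cfg$dbh_sd))
  metadata <- tibble(tree_id = tree_id, dbh = dbh,
                     sapwood_area = sapwood_area,
                     tr_prior_mean = max(0.5, rnorm(1, cfg$tr_prior_mean_mm,
                                                    cfg$tr_prior_sd_mm)))
  truth <- tibble(site_id = cfg$site_id, tree_id = tree_id,
                  k_true = cfg$k_true, m_true = cfg$m_true,
                  a_true = A_i, b_true = b_i, seed = cfg$seed)
  list(radius = radius_tr, thermal = thermal, metadata = metadata,
       truth = truth)
}

#' Simulate a complete synthetic site dataset
#'
#' @param cfg A [site_config()].
#' @return Object of class `site_dataset`: list with `config`, `rain`,
#'   `soil`, `meteo`, `radius`, `thermal`, `metadata`, `truth` and the
#'   internal `env_daily` truth table.
#' @export
simulate_site <- function(cfg) {
  stopifnot(inherits(cfg, "site_config"))
  env <- simulate_environment(cfg)
  trees <- lapply(seq_len(cfg$n_trees), function(i)
    simulate_tree(cfg, env, i))
  structure(list(config = cfg,
                 rain = env$rain, soil = env$soil, meteo = env$meteo,
                 radius = list_rbind(lapply(trees, `[[`, "radius")),
                 thermal = list_rbind(lapply(trees, `[[`, "thermal")),
                 metadata = list_rbind(lapply(trees, `[[`, "metadata")),
                 truth = list_rbind(lapply(trees, `[[`, "truth")),
                 env_daily = env$daily),
            class = "site_dataset")
}

#' @export
print.site_dataset <- function(x, ...) {
  cat(sprintf("Synthetic site dataset '%s': %d trees, %d days, %d soil sensors\n",
              x$config$site_id, x$config$n_trees,
              nrow(x$env_daily), x$config$n_sensors))
  invisible(x)
}

#' Default scenario suite
#'
#' Four site scenarios spanning the conditions the package targets: a dry
#' continental site, an intermediate site, a dense stand on a wet
#' fine-textured soil, and an oceanic site; their true thresholds bracket
#' 0.217-0.296 REW and the decline slopes 1.1-2.0 %/%.
#'
#' @param seed Base seed; each scenario derives its own substream.
#' @param n_trees,noiseless Passed through to [site_config()].
#' @return Named list of four [site_config()] objects.
#' @export
default_site_configs <- function(seed = 1L, n_trees = 5L, noiseless = FALSE) {
  list(
    continental_dry = site_config(
      site_id = "CD", k_true = 0.296, m_true = 1.3,
      vswc_min = 6.4, vswc_max = 22.3, rain_rate = 0.30, vpd_amp = 26,
      n_trees = n_trees, noiseless = noiseless,
      seed = child_seed(seed, 11L)),
    intermediate = site_config(
      site_id = "IN", k_true = 0.217, m_true = 1.1,
      vswc_min = 6.2, vswc_max = 21.2, rain_rate = 0.35, vpd_amp = 24,
      n_trees = n_trees, noiseless = noiseless,
      seed = child_seed(seed, 12L)),
    dense_wet_soil = site_config(
      site_id = "DW", k_true = 0.273, m_true = 1.6,
      vswc_min = 14.9, vswc_max = 34.5, rain_rate = 0.38, vpd_amp = 22,
      et_max = 1.0,
      n_trees = n_trees, noiseless = noiseless,
      seed = child_seed(seed, 13L)),
    oceanic = site_config(
      site_id = "OC", k_true = 0.275, m_true = 2.0,
      vswc_min = 5.8, vswc_max = 27.2, rain_rate = 0.42, vpd_amp = 22,
      drought_rain_factor = 0.10, et_max = 1.05,
      n_trees = n_trees, noiseless = noiseless,
      seed = child_seed(seed, 14L))
  )
}

#' A wet-season control scenario with essentially no drought
#'
#' Frequent rain keeps REW high all season, so stem water deficits never
#' persist: the pipeline should report "no tangent point" rather than a
#' numeric threshold, and the sap-flow decline fit should be refused for
#' lack of qualifying dry days.
#'
#' @param seed Seed passed to [site_config()].
#' @param ... Overrides forwarded to [site_config()].
#' @return A [site_config()].
#' @export
wet_site_config <- function(seed = 1L, ...) {
  site_config(site_id = "WET", k_true = 0.05, m_true = 1.5,
              rain_rate = 0.9, rain_mean_mm = 8, drought_rain_factor = 1,
              seed = seed, ...)
}

#' Write a suite of synthetic scenario datasets to disk
#'
#' Writes one sub-directory per scenario with plain-CSV files (`radius.csv`,
#' `thermal.csv`, `soil.csv`, `meteo.csv`, `rain.csv`, `metadata.csv`) in
#' the schemas the ingestion functions read, plus the ground truth as
#' `truth.json`.
#'
#' @param dir Target directory.
#' @param configs List of [site_config()]s (default [default_site_configs()]).
#' @param force Overwrite a non-empty target directory (default `FALSE`:
#'   refuse).
#' @return Invisibly, the vector of scenario directories written.
#' @export
make_fixture_suite <- function(dir, configs = default_site_configs(),
                               force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !force) {
    abort(sprintf("target directory '%s' is not empty (use force = TRUE)", dir),
          class = "dendrosap_input_error")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- vapply(configs, function(cfg) {
    ds <- simulate_site(cfg)
    sub <- file.path(dir, cfg$site_id)
    dir.create(sub, showWarnings = FALSE)
    write_site_dataset(ds, sub)
    sub
  }, character(1))
  invisible(written)
}
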