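#' Pair daily tree water deficit with daily soil water availability
#'
#' Joins the per-day minimum relative TWD with the site's daily maximum REW
#' on shared, non-missing dates, optionally restricted to an analysis
#' window.
#'
#' @param twd_daily Data frame with `date` and `twd_min_rel` (see
#'   [daily_min_twd()] after normalisation).
#' @param rew_daily Data frame with `date` and `rew_max` (see
#'   [daily_rew()]).
#' @param window Optional length-2 date range.
#' @return Tibble with `date`, `rew`, `twd` (one row per shared day).  Fewer
#'   than 30 shared days raise a warning.
#' @export
paired_daily_data <- function(twd_daily, rew_daily, window = NULL) {
  assert_cols(twd_daily, c("date", "twd_min_rel"), "twd_daily")
  assert_cols(rew_daily, c("date", "rew_max"), "rew_daily")
  out <- inner_join(as_tibble(twd_daily)[, c("date", "twd_min_rel")],
                    as_tibble(rew_daily)[, c("date", "rew_max")],
                    by = "date") |>
    filter(is.finite(.data$twd_min_rel), is.finite(.data$rew_max)) |>
    transmute(date = .data$date, rew = .data$rew_max,
              twd = .data$twd_min_rel)
  if (!is.null(window)) {
    window <- as_date_strict(window, "analysis window")
    out <- filter(out, .data$date >= window[1], .data$date <= window[2])
  }
  if (nrow(out) < 30L) {
    warn(sprintf("only %d shared days between TWD and REW series", nrow(out)),
         class = "dendrosap_few_days_warning")
  }
  out
}

#' Exponential model of tree water deficit against soil water
#'
#' Fits `twd = a * exp(b * rew)` by nonlinear least squares.  Starting
#' values come from a log-linear regression of `log(twd + epsilon)` on `rew`
#' with the wettest tercile of days excluded (where TWD is near zero and the
#' log transform is dominated by `epsilon`); up to `max_restarts` jittered
#' restarts are attempted on non-convergence.  The coefficient of
#' determination is computed on the original scale and the model is tested
#' against the mean-only model with an F test.
#'
#' @param pairs Data frame with `rew` and `twd` columns (see
#'   [paired_daily_data()]); relative TWD should lie in \[0, ~1\].
#' @param min_pairs Minimum number of pairs required (default 30).
#' @param epsilon Offset used in the log-linear initialisation.
#' @param max_restarts Jittered restarts on non-convergence.
#' @return Object of class `twd_exp_fit`: a list with elements `a`, `b`,
#'   `r2`, `p_value`, `n`, `data` and the underlying `nls` fit.  Degenerate
#'   input (fewer than 3 positive TWD values, or zero variance) is an error
#'   of class `dendrosap_degenerate_error`.
#' @export
fit_twd_exponential <- function(pairs, min_pairs = 30L, epsilon = 1e-3,
                                max_restarts = 5L) {
  assert_cols(pairs, c("rew", "twd"), "pairs")
  pairs <- as_tibble(pairs) |>
    filter(is.finite(.data$rew), is.finite(.data$twd))
  n <- nrow(pairs)
  if (n < min_pairs) {
    warn(sprintf("exponential fit on only %d pairs (recommended >= %d)",
                 n, min_pairs), class = "dendrosap_few_days_warning")
  }
  if (n < 5L || sum(pairs$twd > 0) < 3L || var(pairs$twd) == 0) {
    abort("degenerate TWD-REW data: too few positive deficits to fit",
          class = "dendrosap_degenerate_error")
  }
  dry <- pairs[pairs$rew <= quantile(pairs$rew, 2 / 3), ]
  init <- coef(lm(log(twd + epsilon) ~ rew, data = dry))
  b0 <- unname(init[2]); a0 <- exp(unname(init[1]))
  if (!is.finite(b0) || b0 >= 0) b0 <- -5
  if (!is.finite(a0) || a0 <= 0) a0 <- max(pairs$twd)
  fit <- NULL
  for (i in 0:max_restarts) {
    jitter <- if (i == 0) c(1, 1) else exp(rnorm(2, 0, 0.3))
    fit <- tryCatch(
      minpack.lm::nlsLM(twd ~ a * exp(b * rew), data = pairs,
                        start = list(a = a0 * jitter[1], b = b0 * jitter[2]),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    abort(sprintf("exponential fit did not converge after %d restarts (start a=%.3g, b=%.3g)",
                  max_restarts, a0, b0),
          class = "dendrosap_fit_error")
  }
  co <- coef(fit)
  sse <- sum(resid(fit)^2)
  sst <- sum((pairs$twd - mean(pairs$twd))^2)
  r2 <- 1 - sse / sst
  f <- ((sst - sse) / 1) / (sse / (n - 2))
  p <- pf(f, 1, n - 2, lower.tail = FALSE)
  structure(list(a = unname(co["a"]), b = unname(co["b"]), r2 = r2,
                 p_value = p, n = n, data = pairs, fit = fit),
            class = "twd_exp_fit")
}

#' @export
print.twd_exp_fit <- function(x, ...) {
  cat(sprintf("Exponential TWD-REW fit: twd = %.4g * exp(%.4g * rew)\n",
              x$a, x$b))
  cat(sprintf("  n = %d days, R2 = %.3f, p = %.3g\n", x$n, x$r2, x$p_value))
  invisible(x)
}

#' Soil-water threshold from a fixed-slope tangent
#'
#' Constructs the tangent with fixed slope `slope` (default -3) to the
#' fitted curve `a * exp(b * rew)` and returns its x-intercept, the REW
#' threshold `k` below which a tree water deficit persists.  The tangent
#' point is `x* = log(slope / (a b)) / b` (where the curve attains the given
#' slope) and the intercept follows in closed form
#' `k = x* - a exp(b x*) / slope`.
#'
#' @param a,b Coefficients of the exponential fit (`a > 0`, `b < 0`), or a
#'   `twd_exp_fit` object as `a` with `b` missing.
#' @param slope Fixed tangent slope (negative; default -3).
#' @return Threshold `k` (REW fraction) with the tangent point attached as
#'   attribute `x_tangent`.  If the curve never attains the requested slope
#'   on `x >= 0` (`a * b > slope`) an error of class
#'   `dendrosap_no_tangent_error` is raised; a `k` outside \[0, 1\] is
#'   flagged with a warning.
#' @examples
#' tangent_threshold(0.3, -10)  # 0.1: slope matched exactly at the origin
#' @export
tangent_threshold <- function(a, b, slope = -3) {
  if (inherits(a, "twd_exp_fit")) {
    fit <- a
    a <- fit$a
    b <- fit$b
  }
  if (!is.finite(a) || !is.finite(b) || a <= 0 || b >= 0 || slope >= 0) {
    abort("tangent threshold needs a > 0, b < 0 and a negative slope",
          class = "dendrosap_no_tangent_error")
  }
  if (a * b > slope) {
    abort(sprintf("no tangent point: curve slope at the origin (%.3g) is shallower than %.3g",
                  a * b, slope),
          class = "dendrosap_no_tangent_error")
  }
  x_star <- log(slope / (a * b)) / b
  k <- x_star - a * exp(b * x_star) / slope
  if (k < 0 || k > 1) {
    warn(sprintf("threshold k = %.3f lies outside [0, 1]", k),
         class = "dendrosap_threshold_warning")
  }
  attr(k, "x_tangent") <- x_star
  k
}

#' Segmented-regression alternative for the soil-water threshold
#'
#' Fits a continuous two-segment linear model to the TWD-REW pairs with the
#' breakpoint chosen by grid search over the observed REW values (between
#' the `grid_quantiles`), minimising total SSE.  The threshold `k_pw` is the
#' x-intercept of the steep (left, low-REW) segment.  If the segmented model
#' does not improve significantly on a single line (F test on the 2 extra
#' degrees of freedom at `alpha`), the data carry no breakpoint and the fit
#' is flagged.
#'
#' @param pairs Data frame with `rew` and `twd` columns.
#' @param grid_quantiles Quantile range of observed REW values searched for
#'   the breakpoint.
#' @param alpha Significance level of the segmented-vs-line F test.
#' @return Object of class `piecewise_fit`: list with `k_pw`, `breakpoint`,
#'   `slope_left`, `slope_right`, `r2`, `p_value`, `no_breakpoint`, `n`.
#'   With `no_breakpoint = TRUE`, `k_pw` is `NA`.  A steep segment with
#'   non-negative slope is an error of class `dendrosap_no_breakpoint_error`.
#' @export
piecewise_threshold <- function(pairs, grid_quantiles = c(0.1, 0.9),
                                alpha = 0.05) {
  assert_cols(pairs, c("rew", "twd"), "pairs")
  pairs <- as_tibble(pairs) |>
    filter(is.finite(.data$rew), is.finite(.data$twd))
  x <- pairs$rew
  y <- pairs$twd
  n <- length(x)
  if (n < 10L) {
    abort("too few pairs for a segmented regression",
          class = "dendrosap_input_error")
  }
  qs <- quantile(x, grid_quantiles)
  grid <- sort(unique(x[x > qs[1] & x < qs[2]]))
  if (length(grid) < 3L) {
    abort("not enough distinct REW values to search for a breakpoint",
          class = "dendrosap_input_error")
  }
  sse <- vapply(grid, function(cc) {
    sum(resid(lm(y ~ x + pmax(x - cc, 0)))^2)
  }, numeric(1))
  best <- which.min(sse)
  cc <- grid[best]
  seg <- lm(y ~ x + pmax(x - cc, 0))
  sse1 <- sum(resid(seg)^2)
  line <- lm(y ~ x)
  sse0 <- sum(resid(line)^2)
  # the breakpoint and the slope change are 2 extra parameters
  f <- ((sse0 - sse1) / 2) / (sse1 / (n - 4))
  p <- pf(f, 2, n - 4, lower.tail = FALSE)
  no_bp <- !is.finite(f) || f <= 0 || p >= alpha
  slope_left <- unname(coef(seg)[2])
  slope_right <- slope_left + unname(coef(seg)[3])
  k_pw <- NA_real_
  if (!no_bp) {
    if (slope_left >= 0) {
      abort("steep (left) segment has non-negative slope: no declining TWD regime",
            class = "dendrosap_no_breakpoint_error")
    }
    k_pw <- -unname(coef(seg)[1]) / slope_left
  }
  structure(list(k_pw = k_pw, breakpoint = cc, slope_left = slope_left,
                 slope_right = slope_right,
                 r2 = 1 - sse1 / sum((y - mean(y))^2),
                 p_value = p, no_breakpoint = no_bp, n = n),
            class = "piecewise_fit")
}

#' @export
print.piecewise_fit <- function(x, ...) {
  if (x$no_breakpoint) {
    cat("Segmented TWD-REW fit: no breakpoint (single line is adequate)\n")
  } else {
    cat(sprintf("Segmented TWD-REW fit: breakpoint at REW = %.3f, k_pw = %.3f\n",
                x$breakpoint, x$k_pw))
  }
  invisible(x)
}

#' Linear decline of daily sap flow with soil drying
#'
#' On days of high evaporative demand (daily maximum VPD above 1 kPa) and
#' REW within `rew_range` (default 0 to 0.5), relative daily sap flow
#' declines approximately linearly with REW.  Ordinary least squares of
#' `100 * flow_rel` on `100 * rew_max` gives the decline slope `m`: percent
#' sap flow lost per percent REW lost (the regression slope itself, positive
#' for a decline towards dry soil).
#'
#' @param sapflow_daily Data frame with `date` and `flow_rel` (relative
#'   daily sap flow).
#' @param rew_daily Data frame with `date` and `rew_max`.
#' @param vpd_daily Optional data frame with `date` and `high_demand`
#'   (see [daily_max_vpd()]); when supplied, only high-demand days enter the
#'   fit.
#' @param rew_range Closed REW interval fitted (default `c(0, 0.5)`).
#' @param min_days Fits on fewer qualifying days are refused (default 10).
#' @return Object of class `sapflow_decline`: list with `m`, `intercept`,
#'   `r2`, `p_value`, `n_days`, `rew_range`, `data` and the underlying `lm`.
#' @export
fit_sapflow_decline <- function(sapflow_daily, rew_daily, vpd_daily = NULL,
                                rew_range = c(0, 0.5), min_days = 10L) {
  assert_cols(sapflow_daily, c("date", "flow_rel"), "sapflow_daily")
  assert_cols(rew_daily, c("date", "rew_max"), "rew_daily")
  df <- inner_join(as_tibble(sapflow_daily)[, c("date", "flow_rel")],
                   as_tibble(rew_daily)[, c("date", "rew_max")],
                   by = "date")
  if (!is.null(vpd_daily)) {
    assert_cols(vpd_daily, c("date", "high_demand"), "vpd_daily")
    df <- inner_join(df, as_tibble(vpd_daily)[, c("date", "high_demand")],
                     by = "date") |>
      filter(.data$high_demand %in% TRUE)
  }
  df <- df |>
    filter(is.finite(.data$flow_rel), is.finite(.data$rew_max),
           .data$rew_max >= rew_range[1], .data$rew_max <= rew_range[2]) |>
    mutate(flow_pct = 100 * .data$flow_rel, rew_pct = 100 * .data$rew_max)
  if (nrow(df) < min_days) {
    abort(sprintf("decline fit refused: only %d qualifying days (need >= %d)",
                  nrow(df), min_days),
          class = "dendrosap_too_few_days_error")
  }
  fit <- lm(flow_pct ~ rew_pct, data = df)
  sm <- suppressWarnings(summary(fit))
  structure(list(m = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r2 = sm$r.squared,
                 p_value = unname(pf(sm$fstatistic[1], sm$fstatistic[2],
                                     sm$fstatistic[3], lower.tail = FALSE)),
                 n_days = nrow(df), rew_range = rew_range,
                 data = as_tibble(df), fit = fit),
            class = "sapflow_decline")
}

#' @export
print.sapflow_decline <- function(x, ...) {
  cat(sprintf("Sap-flow decline for REW in [%.2f, %.2f]: m = %.3f %%/%% (intercept %.1f %%)\n",
              x$rew_range[1], x$rew_range[2], x$m, x$intercept))
  cat(sprintf("  n = %d high-demand days, R2 = %.3f, p = %.3g\n",
              x$n_days, x$r2, x$p_value))
  invisible(x)
}

#' Relative sap flow predicted at the soil-water threshold
#'
#' Evaluates the fitted decline line at REW = `k`:
#' `intercept + m * 100k` (the intercept is the extrapolated flow at REW 0,
#' the driest end), clipped at zero.
#'
#' @param fit A `sapflow_decline` object.
#' @param k Soil-water threshold as a REW fraction.
#' @return Relative sap flow in percent.
#' @export
sapflow_at_threshold <- function(fit, k) {
  stopifnot(inherits(fit, "sapflow_decline"))
  pmax(fit$intercept + fit$m * 100 * k, 0)
}

#' Mean relative sap flow under maximum soil drought
#'
#' Average relative sap flow over the driest `percentile` fraction of days
#' (default: the 10% of paired days with the lowest daily maximum REW).
#' Days are ranked by REW, so heavy ties at the quantile -- e.g. a drought
#' that pins REW at zero for weeks -- still select exactly the driest
#' fraction.
#'
#' @param sapflow_daily Data frame with `date` and `flow_rel`.
#' @param rew_daily Data frame with `date` and `rew_max`.
#' @param percentile Drought quantile (default 0.10).
#' @param min_days Minimum paired days before the statistic is meaningful.
#' @return Mean relative sap flow in percent, with the number of drought
#'   days attached as attribute `n_days`.
#' @export
sapflow_at_max_drought <- function(sapflow_daily, rew_daily,
                                   percentile = 0.10, min_days = 20L) {
  df <- inner_join(as_tibble(sapflow_daily)[, c("date", "flow_rel")],
                   as_tibble(rew_daily)[, c("date", "rew_max")],
                   by = "date") |>
    filter(is.finite(.data$flow_rel), is.finite(.data$rew_max))
  if (nrow(df) < min_days) {
    warn(sprintf("only %d paired days for the drought statistic", nrow(df)),
         class = "dendrosap_few_days_warning")
  }
  if (nrow(df) == 0L) {
    abort("no paired days for the drought statistic",
          class = "dendrosap_input_error")
  }
  n_sel <- max(1L, floor(percentile * nrow(df)))
  sel <- order(df$rew_max)[seq_len(n_sel)]
  out <- mean(100 * df$flow_rel[sel])
  attr(out, "n_days") <- n_sel
  out
}

#' Mean relative sap flow under maximum tree water deficit
#'
#' Average relative sap flow over days whose relative daily minimum TWD
#' exceeds `threshold` (default 0.9).  Returns `NA` with a warning when no
#' day qualifies.
#'
#' @param sapflow_daily Data frame with `date` and `flow_rel`.
#' @param twd_daily Data frame with `date` and `twd_min_rel`.
#' @param threshold Relative TWD above which a day counts (default 0.9).
#' @return Mean relative sap flow in percent (attribute `n_days`), or `NA`.
#' @export
sapflow_at_max_twd <- function(sapflow_daily, twd_daily, threshold = 0.9) {
  df <- inner_join(as_tibble(sapflow_daily)[, c("date", "flow_rel")],
                   as_tibble(twd_daily)[, c("date", "twd_min_rel")],
                   by = "date") |>
    filter(is.finite(.data$flow_rel), is.finite(.data$twd_min_rel))
  sel <- df$twd_min_rel > threshold
  if (!any(sel)) {
    warn(sprintf("no day with relative TWD > %.2f; returning NA", threshold),
         class = "dendrosap_missing_warning")
    out <- NA_real_
    attr(out, "n_days") <- 0L
    return(out)
  }
  out <- mean(100 * df$flow_rel[sel])
  attr(out, "n_days") <- sum(sel)
  out
}
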