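#' Plot an exponential TWD-REW fit with its tangent threshold
#'
#' Scatter of daily minimum relative TWD against daily maximum REW, the
#' fitted exponential, and (when the tangent exists) the fixed-slope tangent
#' with a vertical line at its x-intercept, the threshold `k`.
#'
#' @param object A `twd_exp_fit`.
#' @param slope Tangent slope used for the threshold overlay (default -3).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.twd_exp_fit <- function(object, slope = -3, ...) {
  grid <- tibble(rew = seq(0, max(object$data$rew), length.out = 200))
  grid$twd <- object$a * exp(object$b * grid$rew)
  p <- ggplot(object$data, aes(x = .data$rew, y = .data$twd)) +
    geom_point(alpha = 0.5, colour = "steelblue4") +
    geom_line(data = grid, colour = "black") +
    labs(x = "daily maximum REW (fraction)",
         y = "relative daily minimum TWD",
         title = sprintf("TWD = %.3g exp(%.3g REW), R2 = %.2f",
                         object$a, object$b, object$r2))
  k <- tryCatch(tangent_threshold(object, slope = slope),
                error = function(e) NULL)
  if (!is.null(k)) {
    x_star <- attr(k, "x_tangent")
    tang <- tibble(rew = c(as.numeric(k), max(0.6, x_star * 1.5)))
    tang$twd <- slope * (tang$rew - as.numeric(k))
    p <- p +
      geom_line(data = tang, linetype = "dotted") +
      geom_vline(xintercept = as.numeric(k), linetype = "dashed") +
      annotate("text", x = as.numeric(k), y = max(object$data$twd),
               label = sprintf("k = %.3f", as.numeric(k)), hjust = -0.1)
  }
  p
}

#' Plot a sap-flow decline fit
#'
#' Relative daily sap flow against daily maximum REW on the fitted
#' high-demand days, with the fitted decline line over the fit range.
#'
#' @param object A `sapflow_decline`.
#' @param k Optional threshold (REW fraction) marked with a vertical line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sapflow_decline <- function(object, k = NULL, ...) {
  line <- tibble(rew_pct = 100 * object$rew_range)
  line$flow_pct <- object$intercept - object$m * line$rew_pct
  p <- ggplot(object$data, aes(x = .data$rew_pct, y = .data$flow_pct)) +
    geom_point(alpha = 0.5, colour = "darkorange3") +
    geom_line(data = line) +
    labs(x = "daily maximum REW (%)", y = "relative daily sap flow (%)",
         title = sprintf("decline m = %.2f %%/%%, R2 = %.2f",
                         object$m, object$r2))
  if (!is.null(k)) {
    p <- p + geom_vline(xintercept = 100 * k, linetype = "dashed")
  }
  p
}

#' Overview plot of a site analysis
#'
#' Two panels: the TWD-REW relation with the tangent threshold, and the
#' sap-flow decline, both for the site-mean series.
#'
#' @param object A `site_analysis`.
#' @param ... Unused.
#' @return A ggplot object (the TWD panel) when the decline fit is missing,
#'   otherwise a combined patchwork-free list is avoided by returning the
#'   TWD panel with the decline available via [autoplot.sapflow_decline()].
#' @export
autoplot.site_analysis <- function(object, ...) {
  if (!is.null(object$site_fit$exp_fit)) {
    autoplot.twd_exp_fit(object$site_fit$exp_fit,
                         slope = object$config$tangent_slope) +
      labs(subtitle = sprintf("site %s", object$site_id))
  } else if (!is.null(object$site_fit$decline)) {
    autoplot.sapflow_decline(object$site_fit$decline, k = object$site_fit$k)
  } else {
    ggplot(object$site_twd, aes(x = .data$date, y = .data$twd_min_rel)) +
      geom_line() +
      labs(x = NULL, y = "relative daily minimum TWD",
           subtitle = sprintf("site %s (no fit available)", object$site_id))
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
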