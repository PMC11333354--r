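#' Tidy an exponential TWD-REW fit
#'
#' @param x A `twd_exp_fit` (see [fit_twd_exponential()]).
#' @param ... Unused.
#' @return One row per coefficient with estimate and standard error.
#' @export
tidy.twd_exp_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble(term = rownames(sm), estimate = sm[, "Estimate"],
         std.error = sm[, "Std. Error"], statistic = sm[, "t value"],
         p.value = sm[, "Pr(>|t|)"])
}

#' @rdname tidy.twd_exp_fit
#' @export
glance.twd_exp_fit <- function(x, ...) {
  tibble(a = x$a, b = x$b, r.squared = x$r2, p.value = x$p_value, nobs = x$n)
}

#' Tidy a sap-flow decline fit
#'
#' @param x A `sapflow_decline` (see [fit_sapflow_decline()]).
#' @param ... Unused.
#' @return One row per coefficient of the underlying linear model.
#' @export
tidy.sapflow_decline <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble(term = rownames(sm), estimate = sm[, "Estimate"],
         std.error = sm[, "Std. Error"], statistic = sm[, "t value"],
         p.value = sm[, "Pr(>|t|)"])
}

#' @rdname tidy.sapflow_decline
#' @export
glance.sapflow_decline <- function(x, ...) {
  tibble(m = x$m, intercept = x$intercept, r.squared = x$r2,
         p.value = x$p_value, nobs = x$n_days)
}

#' Tidy a segmented threshold fit
#'
#' @param x A `piecewise_fit` (see [piecewise_threshold()]).
#' @param ... Unused.
#' @return One-row tibble with the breakpoint, segment slopes and `k_pw`.
#' @export
tidy.piecewise_fit <- function(x, ...) {
  tibble(breakpoint = x$breakpoint, slope_left = x$slope_left,
         slope_right = x$slope_right, k_pw = x$k_pw,
         no_breakpoint = x$no_breakpoint, r.squared = x$r2,
         p.value = x$p_value, nobs = x$n)
}

#' Tidy a PCA of tree or site variables
#'
#' @param x A `site_pca` (see [fit_pca()]).
#' @param ... Unused.
#' @return Long tibble with `variable`, `axis`, `loading`, `eig_fraction`.
#' @export
tidy.site_pca <- function(x, ...) {
  x$loadings |>
    tidyr::pivot_longer(-"variable", names_to = "axis",
                        values_to = "loading") |>
    mutate(eig_fraction = x$eig_fraction[as.integer(sub("axis", "",
                                                        .data$axis))])
}

#' Tidy Tukey HSD comparisons
#'
#' @param x A `tukey_letters` (see [tukey_hsd_letters()]).
#' @param ... Unused.
#' @return The pairwise comparison tibble.
#' @export
tidy.tukey_letters <- function(x, ...) x$comparisons

#' Tidy a full site analysis
#'
#' @param x A `site_analysis` (see [run_site_analysis()]).
#' @param ... Unused.
#' @return The per-tree summary tibble.
#' @export
tidy.site_analysis <- function(x, ...) x$tree_summary

#' @rdname tidy.site_analysis
#' @export
glance.site_analysis <- function(x, ...) x$summary
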