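make_pairs <- function(rew, twd) tibble::tibble(date = as.Date("2022-05-01") +
                                                  seq_along(rew), rew = rew,
                                                twd = twd)

test_that("paired_daily_data intersects dates and drops missing days", {
  twd_d <- tibble::tibble(date = as.Date("2022-06-01") + 0:49,
                          twd_min_rel = runif(50))
  rew_d <- tibble::tibble(date = as.Date("2022-06-10") + 0:49,
                          rew_max = runif(50))
  p <- suppressWarnings(paired_daily_data(twd_d, rew_d))
  expect_equal(nrow(p), 41L)  # 2022-06-10 .. 2022-07-20 inclusive
  twd_d$twd_min_rel[25] <- NA  # a day inside the overlap
  expect_equal(nrow(suppressWarnings(paired_daily_data(twd_d, rew_d))), 40L)
  disjoint <- suppressWarnings(paired_daily_data(
    twd_d, dplyr::mutate(rew_d, date = date + 1000)))
  expect_equal(nrow(disjoint), 0L)
  expect_warning(paired_daily_data(twd_d[1:10, ], rew_d[1:10, ]),
                 class = "dendrosap_few_days_warning")
})

test_that("the exponential fit recovers noiseless and noisy parameters", {
  set.seed(11)
  rew <- runif(120, 0, 1)
  exact <- fit_twd_exponential(make_pairs(rew, 0.5 * exp(-8 * rew)))
  expect_equal(exact$a, 0.5, tolerance = 1e-6)
  expect_equal(exact$b, -8, tolerance = 1e-6)
  expect_equal(exact$r2, 1, tolerance = 1e-9)

  noisy <- fit_twd_exponential(make_pairs(
    rew, pmax(0, exp(-10 * rew) + rnorm(120, 0, 0.02))))
  expect_lt(abs(noisy$b - (-10)) / 10, 0.10)
  expect_lt(noisy$p_value, 0.001)

  expect_error(fit_twd_exponential(make_pairs(rew, c(1, rep(0, 119)))),
               class = "dendrosap_degenerate_error")
})

test_that("tangent threshold matches its closed form on known cases", {
  k1 <- tangent_threshold(0.3, -10)
  expect_equal(as.numeric(k1), 0.1)
  expect_equal(attr(k1, "x_tangent"), 0)

  k2 <- tangent_threshold(1, -10)
  expect_equal(as.numeric(k2), log(10 / 3) / 10 + 0.1, tolerance = 1e-12)
  expect_equal(round(as.numeric(k2), 5), 0.22040)

  # shallower tangents intersect further out
  expect_gt(tangent_threshold(1, -10, slope = -2),
            tangent_threshold(1, -10, slope = -4))

  expect_error(tangent_threshold(0.2, -10), # a*b = -2 shallower than -3
               class = "dendrosap_no_tangent_error")
  expect_error(tangent_threshold(-1, -10),
               class = "dendrosap_no_tangent_error")
  expect_warning(tangent_threshold(200, -4),
                 class = "dendrosap_threshold_warning")
})

test_that("tangent threshold agrees with the numeric construction oracle", {
  set.seed(21)
  n_checked <- 0L
  while (n_checked < 200L) {
    a <- runif(1, 0.2, 3)
    b <- runif(1, -15, -3.5)
    if (a * -b < 3) next
    k_closed <- as.numeric(tangent_threshold(a, b))
    expect_equal(k_closed, tangent_oracle(a, b), tolerance = 1e-8)
    n_checked <- n_checked + 1L
  }
})

test_that("the segmented regression finds hinge breakpoints", {
  set.seed(5)
  x <- runif(120, 0, 1)
  hinge <- pmax(0, 0.05 - 0.25 * (x - 0.2))
  pw <- piecewise_threshold(make_pairs(x, hinge))
  expect_false(pw$no_breakpoint)
  expect_equal(pw$k_pw, 0.4, tolerance = 0.02)
  expect_lt(pw$slope_left, 0)

  noisy <- piecewise_threshold(make_pairs(
    x, pmax(0, hinge + rnorm(120, 0, 0.02))))
  expect_equal(noisy$k_pw, 0.4, tolerance = 0.05)

  linear <- piecewise_threshold(make_pairs(x, 0.5 - 0.3 * x +
                                             rnorm(120, 0, 0.01)))
  expect_true(linear$no_breakpoint)
  expect_true(is.na(linear$k_pw))

  # permutation invariance
  idx <- sample(120)
  pw2 <- piecewise_threshold(make_pairs(x[idx], hinge[idx]))
  expect_equal(pw2$k_pw, pw$k_pw)
})

decline_inputs <- function(n = 60, m_true = 2, noise = 0, seed = 1) {
  set.seed(seed)
  rew <- runif(n, 0, 0.5)
  flow <- pmax(0, 1 - (m_true / 100) * (50 - 100 * rew) +
                 rnorm(n, 0, noise) / 100)
  dates <- as.Date("2022-06-01") + seq_len(n)
  list(sap = tibble::tibble(date = dates, flow_rel = flow),
       rew = tibble::tibble(date = dates, rew_max = rew),
       vpd = tibble::tibble(date = dates, high_demand = TRUE))
}

test_that("the decline fit recovers the generating slope", {
  d <- decline_inputs(noise = 0, m_true = 1)
  # flow_rel = rew exactly when m 1 and intercept 0.5 at rew 0.5
  fit <- fit_sapflow_decline(d$sap, d$rew, d$vpd)
  expect_equal(fit$m, 1, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-9)

  d2 <- decline_inputs(noise = 5, m_true = 2)
  fit2 <- fit_sapflow_decline(d2$sap, d2$rew, d2$vpd)
  expect_lt(abs(fit2$m - 2), 0.3)
})

test_that("the decline fit refuses underpowered or fully masked data", {
  d <- decline_inputs(n = 8)
  expect_error(fit_sapflow_decline(d$sap, d$rew, d$vpd),
               class = "dendrosap_too_few_days_error")
  d2 <- decline_inputs(n = 60)
  d2$vpd$high_demand <- FALSE
  expect_error(fit_sapflow_decline(d2$sap, d2$rew, d2$vpd),
               class = "dendrosap_too_few_days_error")
})

test_that("sap flow at the threshold evaluates the decline line", {
  d <- decline_inputs(noise = 0, m_true = 2)
  fit <- fit_sapflow_decline(d$sap, d$rew, d$vpd)
  expect_equal(sapflow_at_threshold(fit, 0.25), fit$intercept + 2 * 25,
               tolerance = 1e-6)
  expect_equal(sapflow_at_threshold(fit, 0), fit$intercept)
  fit0 <- fit
  fit0$m <- 0
  expect_equal(sapflow_at_threshold(fit0, 0.4), fit$intercept)
})

test_that("drought and maximum-TWD statistics select the right days", {
  dates <- as.Date("2022-05-01") + 1:100
  sap <- tibble::tibble(date = dates,
                        flow_rel = c(rep(0.1, 10), rep(1, 90)))
  rew_d <- tibble::tibble(date = dates, rew_max = (1:100) / 100)
  out <- sapflow_at_max_drought(sap, rew_d)
  expect_equal(as.numeric(out), 10)
  expect_equal(attr(out, "n_days"), 10L)

  const <- tibble::tibble(date = dates, flow_rel = 0.2)
  expect_equal(as.numeric(sapflow_at_max_drought(const, rew_d)), 20)

  twd_d <- tibble::tibble(date = dates,
                          twd_min_rel = c(rep(0.95, 1), rep(0.2, 99)))
  one_day <- tibble::tibble(date = dates, flow_rel = c(0.036, runif(99)))
  expect_equal(as.numeric(sapflow_at_max_twd(one_day, twd_d)), 3.6)
  twd_low <- dplyr::mutate(twd_d, twd_min_rel = 0.5)
  expect_warning(res <- sapflow_at_max_twd(one_day, twd_low),
                 class = "dendrosap_missing_warning")
  expect_true(is.na(res))
  all_qual <- dplyr::mutate(twd_d, twd_min_rel = 0.95)
  expect_equal(as.numeric(sapflow_at_max_twd(const, all_qual)), 20)
})
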