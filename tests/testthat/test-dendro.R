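trace_tbl <- function(x, tree_id = "t1", start = "2022-06-01") {
  tibble::tibble(tree_id = tree_id,
                 timestamp = as.POSIXct(start, tz = "UTC") +
                   600 * (seq_along(x) - 1L),
                 radius_disp = x)
}

test_that("twd is the shortfall below the running maximum", {
  expect_equal(twd(trace_tbl(c(100, 120, 90, 110, 130)))$twd,
               c(0, 0, 30, 10, 0))
  expect_equal(twd(trace_tbl(1:10))$twd, rep(0, 10))
  expect_equal(twd(trace_tbl(rep(5, 10)))$twd, rep(0, 10))
})

test_that("twd agrees with the brute-force oracle and is translation invariant", {
  set.seed(42)
  for (i in 1:25) {
    x <- cumsum(rnorm(sample(20:200, 1)))
    tr <- trace_tbl(x)
    expect_equal(twd(tr)$twd, twd_oracle(x))
    tr_shift <- tr
    tr_shift$radius_disp <- x + 1234.5
    expect_equal(twd(tr_shift)$twd, twd(tr)$twd)
  }
})

test_that("running maximum carries across gaps; missing stays missing", {
  x <- c(100, 150, NA, NA, 120, 160)
  out <- twd(trace_tbl(x))
  expect_equal(out$twd, c(0, 0, NA, NA, 30, 0))
  expect_equal(out$running_max, c(100, 150, 150, 150, 150, 160))
})

test_that("daily minimum TWD appears once overnight recovery fails", {
  # day 1: full recovery each night; day 2: deficit persists at 20 um
  n <- 144L
  diurnal <- 40 * pmax(0, sin(pi * ((seq_len(n) - 1) / 6 - 8) / 10))
  x <- c(1000 - diurnal, 1000 - 20 - diurnal)
  d <- daily_min_twd(twd(trace_tbl(x)))
  expect_equal(d$twd_min, c(0, 20))
  expect_equal(d$twd_max, c(40, 60))
})

test_that("relative normalisation divides by the mean of the top values", {
  x40 <- c(1:39, 100)
  out <- relative_normalize(x40)
  expect_equal(attr(out, "divisor"), 100)  # ceil(0.025 * 40) = 1
  expect_equal(max(out), 1)

  x80 <- c(runif(78, 0, 5), 10, 8)
  out80 <- relative_normalize(x80)
  expect_equal(attr(out80, "divisor"), 9)  # mean of the top 2
  expect_equal(max(out80), 10 / 9)

  expect_equal(as.numeric(relative_normalize(rep(3, 50))), rep(1, 50))

  # scale equivariance
  set.seed(3)
  y <- runif(60)
  expect_equal(as.numeric(relative_normalize(7 * y)),
               as.numeric(relative_normalize(y)))

  expect_error(relative_normalize(rep(0, 50)), class = "dendrosap_input_error")
  expect_error(relative_normalize(1:10), class = "dendrosap_input_error")
})

test_that("total increment is the rise of the running maximum, in mm", {
  n_days <- 10L
  x <- seq(0, 1390, length.out = n_days * 144L)
  w <- c("2022-06-01", "2022-06-10")
  expect_equal(total_increment(trace_tbl(x), w), 1.39)
  expect_equal(total_increment(trace_tbl(rep(100, n_days * 144L)), w), 0)
  expect_equal(total_increment(trace_tbl(seq(500, 100,
                                             length.out = n_days * 144L)), w),
               0)
  expect_error(total_increment(trace_tbl(x), c("2023-01-01", "2023-03-01")),
               class = "dendrosap_input_error")
})

test_that("growth ratio matches simple arithmetic", {
  expect_equal(round(growth_ratio(1.39, 2.51)), 55)
  expect_equal(round(growth_ratio(2.87, 3.78)), 76)
  expect_equal(growth_ratio(3.3, 3.3), 100)
  expect_error(growth_ratio(1, 0), class = "dendrosap_input_error")
})

test_that("basal-area increment compensates for tree size", {
  expect_equal(rbai(40, 0)$rbai, 0)
  expect_equal(round(rbai(38.9, 2.87)$rbai, 2), 2.93)
  # rbai vanishes for very large trees at fixed increment
  expect_lt(rbai(400, 2.87)$rbai, rbai(40, 2.87)$rbai)
  # bai consistency: area difference of the two circles
  r <- 38.9 / 2 * 10
  expect_equal(rbai(38.9, 2.87)$bai, pi * (r^2 - (r - 2.87)^2))
  expect_error(rbai(1, 6), class = "dendrosap_input_error")
})
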