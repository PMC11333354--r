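test_that("sensor cleaning removes impossible values and isolated spikes", {
  clean20 <- clean_vswc(sensor_tbl(rep(20, 10)))
  expect_equal(clean20$vswc, rep(20, 10))

  with95 <- clean_vswc(sensor_tbl(c(20, 20, 95, 20, 20)))
  expect_equal(is.na(with95$vswc), c(FALSE, FALSE, TRUE, FALSE, FALSE))

  spike <- clean_vswc(sensor_tbl(c(20, 20, 28, 20, 20)))
  expect_equal(is.na(spike$vswc), c(FALSE, FALSE, TRUE, FALSE, FALSE))

  # a persistent level shift is not a spike
  shift <- clean_vswc(sensor_tbl(c(20, 20, 28, 28, 28, 28)))
  expect_equal(sum(is.na(shift$vswc)), 0L)

  expect_warning(clean_vswc(sensor_tbl(c(70, 75, 80, 20))),
                 class = "dendrosap_cleaning_warning")
})

test_that("site averaging uses the available sensors", {
  s <- dplyr::bind_rows(sensor_tbl(c(10, 10), "a"), sensor_tbl(c(20, NA), "b"))
  m <- site_mean_vswc(s)
  expect_equal(m$vswc_mean, c(15, 10))
  expect_equal(m$n_sensors_used, c(2L, 1L))

  # permutation invariance and per-timestamp bounds
  set.seed(7)
  s3 <- dplyr::bind_rows(lapply(1:5, function(i)
    sensor_tbl(runif(48, 10, 30), paste0("s", i))))
  m1 <- site_mean_vswc(s3)
  m2 <- site_mean_vswc(dplyr::slice_sample(s3, prop = 1))
  expect_equal(m1, m2)
  rng <- s3 |> dplyr::group_by(timestamp) |>
    dplyr::summarise(lo = min(vswc), hi = max(vswc))
  expect_true(all(m1$vswc_mean >= rng$lo & m1$vswc_mean <= rng$hi))
})

test_that("calibration takes window extrema and rejects degenerate series", {
  s <- site_mean_vswc(sensor_tbl(c(22.3, 15, 6.4, 10)))
  cal <- soil_calibration(s)
  expect_equal(cal$vswc_min, 6.4)
  expect_equal(cal$vswc_max, 22.3)
  expect_error(soil_calibration(site_mean_vswc(sensor_tbl(rep(20, 10)))),
               class = "dendrosap_calibration_error")
  expect_warning(soil_calibration(s, window = c("2022-06-01", "2022-06-05")),
                 class = "dendrosap_calibration_warning")
})

test_that("rew rescales between the calibration extrema", {
  expect_equal(as.numeric(rew(6.4, 6.4, 22.3)), 0)
  expect_equal(as.numeric(rew(22.3, 6.4, 22.3)), 1)
  expect_equal(as.numeric(rew(14.35, 6.4, 22.3)), 0.5)
  expect_error(rew(10, 15, 15), class = "dendrosap_input_error")

  # affine invariance and round trip
  r <- seq(0, 1, by = 0.1)
  v <- 6.4 + r * (22.3 - 6.4)
  expect_equal(as.numeric(rew(v, 6.4, 22.3)), r)
  expect_equal(as.numeric(rew(v + 5, 6.4 + 5, 22.3 + 5)), r)

  out <- rew(c(4, 25), 6.4, 22.3)
  expect_equal(as.numeric(out), c(0, 1))
  expect_equal(attr(out, "n_clipped"), 2L)
})

test_that("daily REW reduces hourly values to per-day extrema", {
  v <- c(rep(14.35, 24), seq(6.4, 22.3, length.out = 24))
  s <- site_mean_vswc(sensor_tbl(v))
  cal <- soil_calibration(s)
  d <- daily_rew(s, cal)
  expect_equal(d$rew_max, c(0.5, 1))
  expect_equal(d$rew_min, c(0.5, 0))
})
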