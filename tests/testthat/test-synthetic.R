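# short, small configurations keep the unit tests fast; the full-scale
# parameter-recovery experiment lives in the acceptance suite
small_cfg <- function(...) {
  args <- list(season = c("2022-05-01", "2022-07-31"),
               drought_window = c("2022-06-10", "2022-07-25"),
               n_trees = 2L, n_sensors = 3L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(site_config, args)
}

test_that("identical configurations yield identical datasets", {
  a <- simulate_site(small_cfg(seed = 42))
  b <- simulate_site(small_cfg(seed = 42))
  expect_identical(a$radius, b$radius)
  expect_identical(a$thermal, b$thermal)
  expect_identical(a$soil, b$soil)
  expect_identical(a$truth, b$truth)
  c <- simulate_site(small_cfg(seed = 43))
  expect_false(identical(a$radius$radius_disp, c$radius$radius_disp))
})

test_that("adding a tree does not perturb the environment or earlier trees", {
  two <- simulate_site(small_cfg(seed = 7, n_trees = 2L))
  three <- simulate_site(small_cfg(seed = 7, n_trees = 3L))
  expect_identical(two$soil, three$soil)
  expect_identical(two$meteo, three$meteo)
  first_two <- unique(two$radius$tree_id)
  expect_identical(two$radius,
                   three$radius[three$radius$tree_id %in% first_two, ])
})

test_that("soil water stays inside the configured extrema", {
  env <- simulate_environment(small_cfg(seed = 3))
  cfg <- small_cfg(seed = 3)
  expect_true(all(env$daily$vswc_site >= cfg$vswc_min - 1e-9))
  expect_true(all(env$daily$vswc_site <= cfg$vswc_max + 1e-9))
  # without rain the bucket only empties
  dry <- simulate_environment(small_cfg(seed = 3, rain_rate = 0))
  expect_true(all(diff(dry$daily$vswc_site) <= 1e-9))
  expect_true(all(dry$rain$rain_mm == 0))
})

test_that("the generated meteorology reproduces the target daily maximum VPD", {
  cfg <- small_cfg(seed = 5, noiseless = TRUE)
  env <- simulate_environment(cfg)
  observed <- daily_max_vpd(add_vpd(env$meteo), threshold = 10)
  expect_equal(observed$vpd_max, env$daily$vpd_max, tolerance = 1e-6)
})

test_that("the truth record is persisted and consistent", {
  ds <- simulate_site(small_cfg(seed = 9))
  expect_equal(nrow(ds$truth), 2L)
  expect_equal(unique(ds$truth$k_true), ds$config$k_true)
  expect_equal(unique(ds$truth$m_true), ds$config$m_true)
  expect_true(all(ds$truth$b_true < 0))
  expect_true(all(ds$truth$a_true > 0))
})

test_that("invalid configurations are rejected", {
  expect_error(site_config(k_true = 0.7), class = "dendrosap_input_error")
  expect_error(site_config(m_true = -1), class = "dendrosap_input_error")
  expect_error(site_config(vswc_min = 30, vswc_max = 20),
               class = "dendrosap_input_error")
})

test_that("fixture suites round-trip through disk", {
  dir <- file.path(tempdir(), "dendrosap-fixtures")
  unlink(dir, recursive = TRUE)
  cfgs <- list(small_cfg(seed = 1, site_id = "X1"),
               small_cfg(seed = 2, site_id = "X2"))
  make_fixture_suite(dir, cfgs)
  expect_true(all(file.exists(file.path(dir, c("X1", "X2"), "radius.csv"))))
  expect_error(make_fixture_suite(dir, cfgs),
               class = "dendrosap_input_error")

  ds <- simulate_site(cfgs[[1]])
  back <- read_site_dataset(file.path(dir, "X1"))
  expect_equal(back$radius$radius_disp, ds$radius$radius_disp,
               tolerance = 1e-9)
  expect_equal(back$soil$vswc, ds$soil$vswc, tolerance = 1e-9)
  expect_equal(back$truth$k_true, rep(cfgs[[1]]$k_true, 2))
  report <- validate_site_dataset(back)
  expect_true(all(report$status %in% c("ok", "warning")))
  unlink(dir, recursive = TRUE)
})
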