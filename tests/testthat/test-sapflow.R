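thermal_tbl <- function(dt, tree_id = "t1", start = "2022-06-01") {
  tibble::tibble(tree_id = tree_id,
                 timestamp = as.POSIXct(start, tz = "UTC") +
                   600 * (seq_along(dt) - 1L),
                 delta_t = dt)
}

test_that("baseline anchors at daily maxima and interpolates between them", {
  const <- build_baseline(thermal_tbl(rep(10, 288)))
  expect_equal(const$delta_t_max, rep(10, 288))

  # two days whose maxima (10 and 12) sit at midnight each
  dt <- c(10, rep(8, 143), 12, rep(8, 143))
  bl <- build_baseline(thermal_tbl(dt))$delta_t_max
  expect_equal(bl[1], 10)
  expect_equal(bl[145], 12)
  # strictly monotone ramp between the two anchors, held after the last
  expect_true(all(diff(bl[1:145]) > 0))
  expect_equal(bl[146:288], rep(12, 143))

  single <- build_baseline(thermal_tbl(c(9, 11, 10)))
  expect_equal(single$delta_t_max, rep(11, 3))
})

test_that("the flow index and flux density follow the Granier calibration", {
  expect_equal(granier_k(10, 10), 0)
  expect_equal(granier_k(5, 10), 1)
  expect_equal(granier_k(8, 10), 0.25)
  expect_true(is.na(granier_k(0, 10)))
  expect_true(is.na(granier_k(-1, 10)))
  expect_equal(granier_k(12, 10), 0)  # noise above baseline floors at 0

  expect_equal(flux_density(0), 0)
  expect_equal(flux_density(1), 0.0119)
  k <- seq(0.1, 2, by = 0.1)
  expect_true(all(diff(flux_density(k)) > 0))
})

test_that("whole-tree daily flow scales with sapwood area and time", {
  # constant flux density of 0.001 g cm-2 s-1 over a full day, 1000 cm2
  k_const <- (0.001 / 0.0119)^(1 / 1.231)
  dt <- rep(10 / (1 + k_const), 144)
  dt[1] <- 10  # zero-flow anchor so the baseline is 10
  tr <- build_baseline(thermal_tbl(dt))
  hyd <- tibble::tibble(tree_id = "t1", sapwood_area = 1000)
  out <- whole_tree_daily(tr, hyd)
  # one sample is the anchor (zero flow), so 143/144 of the ideal 86.4 kg
  expect_equal(out$flow_kg, 0.001 * 1000 * 600 * 143 / 1000)
  out2 <- whole_tree_daily(tr, dplyr::mutate(hyd, sapwood_area = 2000))
  expect_equal(out2$flow_kg, 2 * out$flow_kg)

  zero <- whole_tree_daily(build_baseline(thermal_tbl(rep(10, 144))), hyd)
  expect_equal(zero$flow_kg, 0)
})

test_that("days with too many missing samples are flagged", {
  dt <- rep(8, 144); dt[1] <- 10
  dt[2:50] <- NA  # > 25% missing
  out <- whole_tree_daily(build_baseline(thermal_tbl(dt)),
                          tibble::tibble(tree_id = "t1", sapwood_area = 1000))
  expect_true(out$flagged)
})

test_that("the Granier chain round-trips through simulate_inverse", {
  target <- tibble::tibble(date = as.Date("2022-06-01") + 0:9,
                           flow_kg = c(0, 5, 20, 40, 12.5, 33.3, 0.1, 60,
                                       18, 25))
  tr <- simulate_inverse(target, sapwood_area = 1000)
  recovered <- tr |>
    build_baseline() |>
    whole_tree_daily(tibble::tibble(tree_id = "tree", sapwood_area = 1000))
  expect_equal(recovered$flow_kg, target$flow_kg, tolerance = 1e-10)
  # zero target means the trace sits at the zero-flow reference
  expect_true(all(tr$delta_t[as.Date(tr$timestamp, tz = "UTC") ==
                               target$date[1]] == 10))
  expect_error(simulate_inverse(tibble::tibble(date = Sys.Date(),
                                               flow_kg = 1e9),
                                sapwood_area = 1000),
               class = "dendrosap_input_error")
})

test_that("daily totals are invariant to whole-day time shifts", {
  target <- tibble::tibble(date = as.Date("2022-06-01") + 0:4,
                           flow_kg = c(3, 9, 27, 1, 14))
  tr <- simulate_inverse(target, sapwood_area = 800)
  hyd <- tibble::tibble(tree_id = "tree", sapwood_area = 800)
  base <- (tr |> build_baseline() |> whole_tree_daily(hyd))$flow_kg
  tr2 <- tr
  tr2$timestamp <- tr2$timestamp + 2 * 86400
  shifted <- (tr2 |> build_baseline() |> whole_tree_daily(hyd))$flow_kg
  expect_equal(shifted, base)
})
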