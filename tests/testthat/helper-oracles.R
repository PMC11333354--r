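# Independent oracles used across tests.  They deliberately avoid the code
# paths they check.

# brute-force tree water deficit: max over all previous values minus current,
# floored at zero -- O(n^2)
twd_oracle <- function(x) {
  vapply(seq_along(x), function(i) max(0, max(x[1:i]) - x[i]), numeric(1))
}

# numeric tangent construction for y = a * exp(b * x): bracket the point
# where the curve's slope equals s on a dense grid, refine by root finding,
# then extend the tangent line to the x axis
tangent_oracle <- function(a, b, s = -3, x_hi = 5) {
  slope_diff <- function(x) a * b * exp(b * x) - s
  grid <- seq(0, x_hi, length.out = 2000)
  v <- slope_diff(grid)
  i <- which(v[-1] * v[-length(v)] <= 0)[1]
  if (is.na(i)) stop("no tangent point on the grid")
  x_star <- uniroot(slope_diff, c(grid[i], grid[i + 1]), tol = 1e-14)$root
  x_star - a * exp(b * x_star) / s
}

# 10-minute timestamps covering n full days
ts_days <- function(n, start = "2022-06-01") {
  as.POSIXct(start, tz = "UTC") + 600 * (seq_len(n * 144L) - 1L)
}

# hourly timestamps covering n full days
ts_hours <- function(n, start = "2022-06-01") {
  as.POSIXct(start, tz = "UTC") + 3600 * (seq_len(n * 24L) - 1L)
}

# small helper: a soil sensor table from a vswc vector
sensor_tbl <- function(vswc, sensor_id = "s1", site_id = "S", depth = 20,
                       start = "2022-06-01") {
  tibble::tibble(site_id = site_id, sensor_id = sensor_id, depth = depth,
                 timestamp = as.POSIXct(start, tz = "UTC") +
                   3600 * (seq_along(vswc) - 1L),
                 vswc = vswc)
}
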