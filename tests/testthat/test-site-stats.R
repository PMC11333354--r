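test_that("pooled weighted mean weights sites by tree count", {
  s <- tibble::tibble(m = c(43.5, 43.9, 48.9, 53.5), n = c(9, 9, 4, 2))
  expect_equal(round(pooled_weighted_mean(s, m, n), 1), 45.4)
  eq <- tibble::tibble(m = c(10, 20, 30), n = c(4, 4, 4))
  expect_equal(pooled_weighted_mean(eq, m, n), 20)
  one <- tibble::tibble(m = 7.5, n = 3)
  expect_equal(pooled_weighted_mean(one, m, n), 7.5)
  # all-equal means return that mean regardless of the weights
  same <- tibble::tibble(m = rep(4.2, 3), n = c(1, 10, 100))
  expect_equal(pooled_weighted_mean(same, m, n), 4.2)
  zero <- tibble::tibble(m = 1, n = 0)
  expect_error(pooled_weighted_mean(zero, m, n),
               class = "dendrosap_input_error")
})

test_that("Tukey HSD letters separate the groups that differ", {
  set.seed(2)
  identical_groups <- tibble::tibble(
    value = rep(c(1, 2, 3, 4, 5), 2),
    site = rep(c("A", "B"), each = 5))
  tk <- tukey_hsd_letters(identical_groups, value, site)
  expect_equal(tk$comparisons$p_adj, 1)
  expect_equal(tk$letters$letters, c("a", "a"))

  separated <- tibble::tibble(
    value = c(rnorm(10, 0, 1), rnorm(10, 10, 1)),
    site = rep(c("A", "B"), each = 10))
  tk2 <- tukey_hsd_letters(separated, value, site)
  expect_lt(tk2$comparisons$p_adj, 0.001)
  expect_equal(tk2$letters$letters, c("a", "b"))

  three <- tibble::tibble(
    value = c(rnorm(10, 0, 1), rnorm(10, 0.2, 1), rnorm(10, 15, 1)),
    site = rep(c("A", "B", "C"), each = 10))
  tk3 <- tukey_hsd_letters(three, value, site)
  expect_equal(tk3$letters$letters, c("a", "a", "b"))

  # p-values do not depend on group order
  tk3r <- tukey_hsd_letters(three[sample(30), ], value, site)
  expect_equal(sort(tk3$comparisons$p_adj), sort(tk3r$comparisons$p_adj))
})

test_that("groups with a single observation are excluded with a warning", {
  df <- tibble::tibble(value = c(1, 2, 3, 4, 9),
                       site = c("A", "A", "B", "B", "C"))
  expect_warning(tk <- tukey_hsd_letters(df, value, site),
                 class = "dendrosap_group_warning")
  expect_false("C" %in% tk$letters$group)
})

test_that("the PCA decomposes the correlation structure", {
  set.seed(8)
  x <- rnorm(50)
  two <- tibble::tibble(a = x, b = 3 * x + 2)
  p <- fit_pca(two)
  expect_equal(p$eig_fraction[1], 1)
  expect_equal(abs(p$loadings$axis1), rep(1 / sqrt(2), 2))

  # unit-norm loadings, sign convention, affine invariance
  df <- tibble::tibble(a = rnorm(200), b = rnorm(200), c = rnorm(200))
  df$d <- df$a + 0.5 * df$b + rnorm(200, 0, 0.3)
  p2 <- fit_pca(df)
  norms <- sapply(p2$loadings[, -1], function(v) sqrt(sum(v^2)))
  expect_equal(unname(norms), rep(1, 3))
  for (j in 2:4) {
    v <- p2$loadings[[j]]
    expect_gt(v[which.max(abs(v))], 0)
  }
  scaled <- dplyr::mutate(df, a = 10 * a + 100, c = -c)
  p3 <- fit_pca(dplyr::mutate(scaled, c = -c))  # undo sign to compare exactly
  expect_equal(p3$loadings$axis1, p2$loadings$axis1, tolerance = 1e-9)

  # near-uncorrelated variables spread variance evenly
  expect_lt(max(fit_pca(df[, c("a", "b", "c")])$eig_fraction), 0.45)

  expect_error(fit_pca(dplyr::mutate(df, e = 1)),
               class = "dendrosap_input_error")
})
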