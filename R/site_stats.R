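#' Tree-count-weighted pooled mean across sites
#'
#' Pools per-site summary means into a cross-site figure, weighting each
#' site by the number of trees behind its mean: `sum(mean_i * n_i) / sum(n_i)`.
#'
#' @param summaries Data frame of per-site summaries.
#' @param mean Column holding the per-site means (tidy-eval).
#' @param n Column holding the per-site tree counts (tidy-eval).
#' @return The pooled mean (scalar).
#' @examples
#' s <- tibble::tibble(m = c(43.5, 43.9, 48.9, 53.5), n = c(9, 9, 4, 2))
#' pooled_weighted_mean(s, m, n)  # ~45.4
#' @export
pooled_weighted_mean <- function(summaries, mean, n) {
  m <- dplyr::pull(summaries, {{ mean }})
  w <- dplyr::pull(summaries, {{ n }})
  keep <- is.finite(m) & is.finite(w)
  m <- m[keep]; w <- w[keep]
  if (sum(w) <= 0) {
    abort("total tree count is zero", class = "dendrosap_input_error")
  }
  sum(m * w) / sum(w)
}

#' Tukey HSD comparisons with compact letter display
#'
#' Pairwise studentized-range (Tukey HSD) tests of the per-site means of a
#' tree-level variable, with a compact letter display in which groups
#' sharing a letter do not differ at `alpha`.  Groups with fewer than two
#' observations cannot contribute a within-group variance and are excluded
#' with a warning.
#'
#' @param df Data frame of tree-level values.
#' @param value Value column (tidy-eval).
#' @param group Grouping column (tidy-eval), e.g. the site.
#' @param alpha Significance level for the letter display (default 0.05).
#' @return Object of class `tukey_letters`: list with `comparisons` (tibble:
#'   `group1`, `group2`, `diff`, `lwr`, `upr`, `p_adj`) and `letters`
#'   (tibble: `group`, `n`, `mean`, `letters`).
#' @export
tukey_hsd_letters <- function(df, value, group, alpha = 0.05) {
  dat <- tibble(value = dplyr::pull(df, {{ value }}),
                group = as.character(dplyr::pull(df, {{ group }}))) |>
    filter(is.finite(.data$value), !is.na(.data$group))
  counts <- dat |> count(.data$group)
  small <- counts$group[counts$n < 2L]
  if (length(small) > 0L) {
    warn(sprintf("excluding group(s) with n < 2: %s",
                 paste(small, collapse = ", ")),
         class = "dendrosap_group_warning")
    dat <- filter(dat, !.data$group %in% small)
  }
  groups <- sort(unique(dat$group))
  if (length(groups) < 2L) {
    abort("need at least two groups with n >= 2",
          class = "dendrosap_input_error")
  }
  dat$group <- factor(dat$group, levels = groups)
  tk <- TukeyHSD(aov(value ~ group, data = dat))$group
  nm <- strsplit(rownames(tk), "-", fixed = TRUE)
  comparisons <- tibble(group1 = vapply(nm, `[`, "", 1L),
                        group2 = vapply(nm, `[`, "", 2L),
                        diff = tk[, "diff"], lwr = tk[, "lwr"],
                        upr = tk[, "upr"], p_adj = tk[, "p adj"])
  sig <- comparisons[comparisons$p_adj < alpha, c("group1", "group2")]
  letters_map <- cld_insert_absorb(groups, sig)
  means <- dat |>
    group_by(.data$group) |>
    summarise(n = dplyr::n(), mean = mean(.data$value), .groups = "drop") |>
    mutate(group = as.character(.data$group))
  out <- structure(list(comparisons = comparisons,
                        letters = left_join(means,
                                            letters_map, by = "group"),
                        alpha = alpha),
                   class = "tukey_letters")
  out
}

# insert-and-absorb compact letter display: start from one column holding all
# groups; each significant pair splits every column containing both; columns
# that are subsets of another are absorbed; letters are assigned per column
cld_insert_absorb <- function(groups, sig_pairs) {
  cols <- list(groups)
  if (nrow(sig_pairs) > 0L) {
    for (i in seq_len(nrow(sig_pairs))) {
      g1 <- sig_pairs$group1[i]; g2 <- sig_pairs$group2[i]
      new_cols <- list()
      for (col in cols) {
        if (g1 %in% col && g2 %in% col) {
          new_cols <- c(new_cols, list(setdiff(col, g2), setdiff(col, g1)))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      # absorb columns contained in another
      keep <- rep(TRUE, length(new_cols))
      for (a in seq_along(new_cols)) {
        for (b in seq_along(new_cols)) {
          if (a != b && keep[a] &&
              all(new_cols[[a]] %in% new_cols[[b]]) &&
              (length(new_cols[[a]]) < length(new_cols[[b]]) || a > b)) {
            keep[a] <- FALSE
          }
        }
      }
      cols <- new_cols[keep]
    }
  }
  # letter columns in the order of their first member, so the first group
  # always carries "a"
  cols <- cols[order(vapply(cols, function(col) min(match(col, groups)),
                            numeric(1)))]
  lab <- letters[seq_along(cols)]
  tibble(group = groups,
         letters = vapply(groups, function(g) {
           paste0(lab[vapply(cols, function(col) g %in% col, logical(1))],
                  collapse = "")
         }, "", USE.NAMES = FALSE))
}

#' @export
print.tukey_letters <- function(x, ...) {
  cat(sprintf("Tukey HSD comparisons (alpha = %.2f)\n", x$alpha))
  print(x$letters)
  invisible(x)
}

#' Standardised principal component analysis of tree or site variables
#'
#' All variables are standardised (zero mean, unit standard deviation), so
#' the decomposition is of the correlation matrix.  Loadings are unit-norm
#' eigenvectors; eigenvalue fractions give the variance captured per axis.
#' Because eigenvector signs are arbitrary, each axis is oriented so its
#' largest-magnitude loading is positive.
#'
#' @param df Data frame of units (trees or sites) by variables; only numeric
#'   columns enter, all must be complete and non-constant.
#' @param n_axes Number of axes to report (default 3, capped at the number
#'   of variables).
#' @return Object of class `site_pca`: list with `loadings` (tibble with
#'   `variable` and one column per axis), `eig_fraction`, `n_units`.
#' @export
fit_pca <- function(df, n_axes = 3L) {
  num <- df[vapply(df, is.numeric, logical(1))]
  if (ncol(num) < 2L || nrow(num) < 3L) {
    abort("PCA needs at least 3 units and 2 numeric variables",
          class = "dendrosap_input_error")
  }
  if (anyNA(num)) {
    abort("PCA input must be complete (no missing values)",
          class = "dendrosap_input_error")
  }
  sds <- vapply(num, sd, numeric(1))
  if (any(sds == 0)) {
    abort(sprintf("constant column(s): %s",
                  paste(names(num)[sds == 0], collapse = ", ")),
          class = "dendrosap_input_error")
  }
  pr <- prcomp(as.matrix(num), center = TRUE, scale. = TRUE)
  n_axes <- min(n_axes, ncol(pr$rotation))
  rot <- pr$rotation[, seq_len(n_axes), drop = FALSE]
  for (j in seq_len(n_axes)) {
    if (rot[which.max(abs(rot[, j])), j] < 0) rot[, j] <- -rot[, j]
  }
  eig <- pr$sdev^2 / sum(pr$sdev^2)
  loadings <- as_tibble(rot, .name_repair = "minimal")
  names(loadings) <- paste0("axis", seq_len(n_axes))
  loadings <- bind_cols(tibble(variable = rownames(pr$rotation)), loadings)
  structure(list(loadings = loadings,
                 eig_fraction = eig[seq_len(n_axes)],
                 n_units = nrow(num)),
            class = "site_pca")
}

#' @export
print.site_pca <- function(x, ...) {
  cat(sprintf("Standardised PCA of %d units; variance fractions: %s\n",
              x$n_units,
              paste(sprintf("%.3f", x$eig_fraction), collapse = ", ")))
  print(x$loadings)
  invisible(x)
}
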