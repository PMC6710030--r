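#' One-way analysis of variance on congruence records
#'
#' Classical fixed-effects one-way ANOVA: `F = MS_between / MS_within` with
#' `k - 1` and `N - k` degrees of freedom, upper-tail p from the F
#' distribution. The engine is `stats::oneway.test(var.equal = TRUE)`; this
#' wrapper adds the record-table interface, the degenerate-variance guard
#' and a tidy one-row result.
#'
#' @param data A data frame of records.
#' @param value Unquoted numeric response column (e.g. `itpr`).
#' @param group Unquoted grouping column (e.g. exposure `group`).
#' @return A one-row tibble: `statistic` (F), `df_between`, `df_within`,
#'   `p_value`, `n_groups`, `n_total`.
#' @examples
#' df <- data.frame(y = c(1, 2, 3, 4), g = c("a", "a", "b", "b"))
#' anova_oneway(df, y, g)  # F = 8 on (1, 2) df
#' @export
anova_oneway <- function(data, value, group) {
  y <- dplyr::pull(data, {{ value }})
  g <- as.factor(dplyr::pull(data, {{ group }}))
  check_groups(y, g)
  ft <- stats::oneway.test(y ~ g, var.equal = TRUE)
  tibble::tibble(
    statistic = unname(ft$statistic),
    df_between = as.integer(ft$parameter[["num df"]]),
    df_within = as.integer(ft$parameter[["denom df"]]),
    p_value = unname(ft$p.value),
    n_groups = nlevels(g),
    n_total = length(y))
}

check_groups <- function(y, g) {
  if (any(!is.finite(y))) abort("response values must be finite")
  counts <- table(g)
  if (length(counts) < 2) abort("need at least 2 groups")
  if (any(counts < 2)) abort("every group needs at least 2 observations")
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  if (ssw <= 0) abort("zero within-group variance: F is undefined")
  invisible(ssw)
}

#' Tukey Honest-Significant-Difference post-hoc comparisons
#'
#' All-pairs comparisons after a one-way ANOVA, controlling the family-wise
#' error rate with the studentized-range distribution. For groups i, j:
#' `q_ij = |mean_i - mean_j| / sqrt(MS_within/2 * (1/n_i + 1/n_j))` (the
#' Tukey-Kramer form for unbalanced sizes), with the adjusted p-value from
#' the upper tail of the studentized range with `(k, N - k)` parameters.
#'
#' @inheritParams anova_oneway
#' @param alpha Family-wise significance level for the `significant` flag.
#' @return A tibble with one row per unordered pair: `group1`, `group2`,
#'   `estimate` (mean2 - mean1), `q`, `adj_p_value`, `significant`.
#' @export
tukey_hsd <- function(data, value, group, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  y <- dplyr::pull(data, {{ value }})
  g <- as.factor(dplyr::pull(data, {{ group }}))
  ssw <- check_groups(y, g)
  k <- nlevels(g)
  n <- as.numeric(table(g))
  m <- tapply(y, g, mean)
  df_w <- length(y) - k
  msw <- ssw / df_w
  pairs <- combn(levels(g), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    i1 <- match(g1, levels(g)); i2 <- match(g2, levels(g))
    est <- m[[i2]] - m[[i1]]
    se <- sqrt(msw / 2 * (1 / n[i1] + 1 / n[i2]))
    q <- abs(est) / se
    p <- ptukey(q, nmeans = k, df = df_w, lower.tail = FALSE)
    tibble::tibble(group1 = g1, group2 = g2, estimate = est, q = q,
                   adj_p_value = p, significant = p < alpha)
  })
}

#' Levene's test of homogeneity of variances
#'
#' Variance homogeneity across groups, assessed as a one-way ANOVA on the
#' absolute deviations of each observation from its group centre (the group
#' mean by default — the classical form; pass `center = median` for the
#' Brown-Forsythe variant). When the deviations carry no variance at all
#' (every group equally spread, e.g. two observations per group at equal
#' distance from their mean), W = 0 and p = 1 by convention.
#'
#' @inheritParams anova_oneway
#' @param center Function locating each group's centre (default `mean`).
#' @return A one-row tibble: `statistic` (W), `df_between`, `df_within`,
#'   `p_value`.
#' @export
levene_test <- function(data, value, group, center = mean) {
  y <- dplyr::pull(data, {{ value }})
  g <- as.factor(dplyr::pull(data, {{ group }}))
  counts <- table(g)
  if (length(counts) < 2) abort("need at least 2 groups")
  if (any(counts < 2)) abort("every group needs at least 2 observations")
  dev <- abs(y - stats::ave(y, g, FUN = center))
  k <- nlevels(g)
  df_b <- k - 1L
  df_w <- length(y) - k
  gm <- tapply(dev, g, mean)
  ssb <- sum(as.numeric(counts) * (gm - mean(dev))^2)
  ssw <- sum(tapply(dev, g, function(v) sum((v - mean(v))^2)))
  if (ssw <= 0 && ssb <= 1e-300) {
    return(tibble::tibble(statistic = 0, df_between = df_b,
                          df_within = df_w, p_value = 1))
  }
  if (ssw <= 0) {
    return(tibble::tibble(statistic = Inf, df_between = df_b,
                          df_within = df_w, p_value = 0))
  }
  W <- (ssb / df_b) / (ssw / df_w)
  tibble::tibble(statistic = W, df_between = df_b, df_within = df_w,
                 p_value = pf(W, df_b, df_w, lower.tail = FALSE))
}
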