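#' Reconstruct an exposure group from a vertebral point cloud
#'
#' Emulates the reconstruction of a surface map into the three exposure
#' configurations compared by the study: Group A (bilateral hemilaminae
#' including the spinous process), Group B (one hemilamina plus the
#' ipsilateral base of the spinous process) and Group C (one hemilamina
#' excluding the spinous process entirely).
#'
#' For labelled clouds, `outlier` points are always dropped, sides are the
#' sign of `x` relative to `midline`, Group B keeps the side's `sp_base`
#' points but not `sp_tip`, and Group C drops every spinous-process point.
#' For unlabelled clouds a `midline` and `sp_halfwidth` must be supplied:
#' the midline band `|x - midline| <= sp_halfwidth` plays the role of the
#' spinous process; without per-point protrusion information the band cannot
#' be split into base and tip, so Group B keeps the whole band of its side
#' (a documented approximation).
#'
#' Relative point order is preserved. An empty reconstruction errors.
#'
#' @param cloud A point cloud, labelled or not.
#' @param group `"A"`, `"B"` or `"C"`.
#' @param side `"left"` or `"right"` for Groups B/C; Group A is `"both"`.
#' @param midline x-coordinate of the midsagittal plane (default 0).
#' @param sp_halfwidth Spinous-process band half-width in mm (unlabelled
#'   clouds only).
#' @return A `point_cloud` subset.
#' @export
reconstruct_group <- function(cloud, group = c("A", "B", "C"),
                              side = c("both", "left", "right"),
                              midline = 0, sp_halfwidth = NULL) {
  group <- match.arg(group)
  side <- match.arg(side)
  cloud <- as_point_cloud(cloud)
  labelled <- "label" %in% names(cloud)
  if (!labelled && group != "A" && is.null(sp_halfwidth)) {
    abort("unlabelled clouds need `sp_halfwidth` (and `midline`) to reconstruct Groups B/C")
  }
  if (group != "A" && side == "both") {
    abort("Groups B and C are unilateral: pick side 'left' or 'right'")
  }
  keep <- if (labelled) cloud$label != "outlier" else rep(TRUE, nrow(cloud))
  if (group != "A") {
    side_mask <- if (side == "left") cloud$x < midline else cloud$x >= midline
    if (labelled) {
      sp <- cloud$label %in% c("sp_base", "sp_tip")
      keep <- keep & side_mask &
        if (group == "B") cloud$label != "sp_tip" else !sp
    } else {
      band <- abs(cloud$x - midline) <= sp_halfwidth
      keep <- keep & side_mask & if (group == "B") TRUE else !band
    }
  }
  out <- cloud[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    abort(sprintf("reconstruction of Group %s (%s) is empty", group, side))
  }
  as_point_cloud(out)
}

#' Fit all symmetric primitives to one cloud
#'
#' Runs one [ransac_fit()] per shape kind with per-shape derived seeds
#' (`seed + 1` plane, `+ 2` sphere, `+ 3` cylinder) so the three fits are
#' independent yet reproducible from one base seed.
#'
#' @inheritParams ransac_fit
#' @param shapes Shape kinds to fit.
#' @return A tibble with one row per shape: the [glance()] columns plus a
#'   `fit` list-column holding each `ransac_fit`.
#' @export
congruence_profile <- function(cloud, shapes = c("plane", "sphere", "cylinder"),
                               epsilon = 0.5, iterations = 100, seed = 1,
                               refine = TRUE, normal_k = 20) {
  offsets <- c(plane = 1L, sphere = 2L, cylinder = 3L)
  shapes <- match.arg(shapes, several.ok = TRUE)
  fits <- purrr::map(shapes, function(sh) {
    ransac_fit(cloud, sh, epsilon = epsilon, iterations = iterations,
               seed = seed + offsets[[sh]], refine = refine,
               normal_k = normal_k)
  })
  out <- dplyr::bind_rows(purrr::map(fits, glance))
  out$fit <- fits
  out
}

#' Coefficient of variation of the RANSAC RMSE across repeated fits
#'
#' The tolerance-selection metric: `repeats` independent RANSAC fits are run
#' with seeds `base_seed + 1 .. base_seed + repeats` and the sample
#' SD-to-mean ratio of their inlier RMSE values is returned. A stable
#' (low-variance) RMSE across re-randomised fits indicates the tolerance is
#' neither starving the fit of inliers nor swallowing off-surface points.
#' When all repeats agree exactly, or every RMSE is zero, the value is 0 by
#' convention.
#'
#' @inheritParams ransac_fit
#' @param repeats Number of repeated fits (>= 2).
#' @param base_seed Base RNG seed.
#' @return Non-negative scalar.
#' @export
cov_rmse <- function(cloud, shape, epsilon = 0.5, repeats = 20,
                     base_seed = 1, iterations = 100, refine = TRUE,
                     normal_k = 20) {
  if (repeats < 2) abort("repeats must be at least 2")
  rmses <- vapply(seq_len(repeats), function(i) {
    ransac_fit(cloud, shape, epsilon = epsilon, iterations = iterations,
               seed = base_seed + i, refine = refine, normal_k = normal_k)$rmse
  }, numeric(1))
  cov_from_values(rmses)
}

# SD/mean with the degenerate conventions: identical values or an all-zero
# mean give 0
cov_from_values <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2) return(0)
  m <- mean(values)
  if (m == 0) return(0)
  s <- sd(values)
  if (s == 0) return(0)
  s / m
}

#' Select the maximum inlier error by CoV-RMSE sensitivity analysis
#'
#' Evaluates [cov_rmse()] over a tolerance grid for every cloud x shape
#' combination and picks the tolerance minimising the mean CoV-RMSE, ties
#' going to the smaller tolerance. `choose_epsilon()` applies the argmin/tie
#' rule to a precomputed `(epsilon, cov_rmse)` table and is exposed so the
#' selection logic can be exercised on its own.
#'
#' @param clouds A point cloud or list of point clouds.
#' @param shapes Shape kinds to include.
#' @param grid Candidate tolerances in mm.
#' @param repeats,seed,iterations Passed to [cov_rmse()].
#' @return A `sensitivity_result`: tibble with columns `epsilon`,
#'   `cov_rmse`, `chosen`, and attribute `chosen_epsilon`.
#' @export
select_epsilon <- function(clouds, shapes = c("plane", "sphere", "cylinder"),
                           grid = c(0.1, 0.5, 1, 2), repeats = 5, seed = 1,
                           iterations = 100) {
  if (length(grid) == 0) abort("the tolerance grid must be non-empty")
  if (is.data.frame(clouds)) clouds <- list(clouds)
  combos <- tidyr::expand_grid(ci = seq_along(clouds), shape = shapes)
  tab <- purrr::map_dfr(sort(grid), function(eps) {
    covs <- purrr::pmap_dbl(combos, function(ci, shape) {
      cov_rmse(clouds[[ci]], shape, epsilon = eps, repeats = repeats,
               base_seed = seed + 100L * ci, iterations = iterations)
    })
    tibble::tibble(epsilon = eps, cov_rmse = mean(covs))
  })
  choose_epsilon(tab)
}

#' @rdname select_epsilon
#' @param cov_table A data frame with columns `epsilon` and `cov_rmse`.
#' @export
choose_epsilon <- function(cov_table) {
  stopifnot(all(c("epsilon", "cov_rmse") %in% names(cov_table)))
  tab <- dplyr::arrange(tibble::as_tibble(cov_table), .data$epsilon)
  chosen <- tab$epsilon[which.min(tab$cov_rmse)]  # first min = smallest eps
  tab$chosen <- tab$epsilon == chosen
  attr(tab, "chosen_epsilon") <- chosen
  class(tab) <- unique(c("sensitivity_result", class(tab)))
  tab
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("Tolerance sensitivity: chosen epsilon = %g mm\n",
              attr(x, "chosen_epsilon")))
  NextMethod()
}

#' Percent reduction between two group means
#'
#' `100 * (mean_pre - mean_post) / mean_pre`, rounded to `digits` decimals —
#' the form in which reductions in congruence between exposure groups are
#' reported (e.g. mean unilateral ITPR 0.436 falling to 0.227 bilaterally is
#' a 47.9% reduction). Vectorised; scale-invariant in its two arguments.
#'
#' @param mean_pre Baseline mean(s), strictly positive.
#' @param mean_post Comparison mean(s).
#' @param digits Decimal places in the reported percentage.
#' @return Numeric percentage(s).
#' @examples
#' percent_reduction(0.436, 0.227)  # 47.9
#' @export
percent_reduction <- function(mean_pre, mean_post, digits = 1) {
  if (any(!is.finite(mean_pre)) || any(mean_pre <= 0)) {
    abort("mean_pre must be positive and finite")
  }
  round(100 * (mean_pre - mean_post) / mean_pre, digits)
}
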