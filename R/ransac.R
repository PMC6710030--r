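#' Fit a symmetric primitive to a point cloud by RANSAC
#'
#' The congruence-scoring core: repeated minimal-sample hypotheses (3 points
#' for a plane, 4 for a sphere, 2 oriented points for a cylinder) scored by
#' inlier count under the maximum-inlier-distance tolerance `epsilon`. The
#' loop runs exactly `iterations` hypothesis draws — degenerate samples
#' consume an iteration — and keeps the hypothesis with the most inliers,
#' ties broken by lower inlier RMSE, then by earlier iteration. With
#' `refine = TRUE` the winner is re-estimated by least squares on its inlier
#' set and the inlier mask recomputed once against the refined model.
#'
#' The inliers-to-points ratio (ITPR) of the returned fit is the congruence
#' score: the fraction of the cloud lying within `epsilon` of the fitted
#' symmetric surface. High ITPR marks a surface that is close to globally
#' symmetric and therefore prone to ambiguous surface-based registration.
#'
#' The fit is deterministic given the cloud (order included) and `seed`:
#' one seeded generator drives all draws, sampling without replacement
#' within a draw.
#'
#' @param cloud A point cloud. Cylinder fits need unit normals; if absent
#'   they are estimated on demand via [estimate_normals()] with `normal_k`.
#' @param shape `"plane"`, `"sphere"` or `"cylinder"`.
#' @param epsilon Maximum inlier distance in mm (> 0).
#' @param iterations Number of hypothesis draws (>= 1).
#' @param seed Integer RNG seed.
#' @param refine Refine the winning model by least squares (default `TRUE`).
#' @param normal_k Neighbourhood size for on-demand normal estimation.
#' @return An object of class `ransac_fit`: the winning [shape_model], the
#'   logical inlier mask, `itpr`, inlier `rmse` (and `rmse_all` over the whole
#'   cloud), iteration bookkeeping and the configuration echo. Supports
#'   [tidy()], [glance()], [augment()] and [autoplot][plot_fit_profile].
#' @examples
#' cl <- generate_primitive_patch("plane", shape_plane(c(0, 0, 1), 0),
#'                                n = 200, noise_sd = 0, seed = 1)
#' fit <- ransac_fit(cl, "plane", epsilon = 0.5, seed = 1)
#' fit$itpr  # 1: every point on the plane
#' @export
ransac_fit <- function(cloud, shape = c("plane", "sphere", "cylinder"),
                       epsilon = 0.5, iterations = 100, seed = 1,
                       refine = TRUE, normal_k = 20) {
  shape <- match.arg(shape)
  cloud <- as_point_cloud(cloud)
  if (epsilon <= 0) abort("epsilon must be positive")
  if (iterations < 1) abort("iterations must be at least 1")
  m <- minimal_sample_size(shape)
  n <- nrow(cloud)
  if (n < m) {
    abort(sprintf("insufficient points: %s fit needs at least %d points", shape, m))
  }
  if (shape == "cylinder" && !has_normals(cloud)) {
    cloud <- estimate_normals(cloud, k = normal_k)
  }
  P <- cloud_matrix(cloud)
  NM <- if (shape == "cylinder") normal_matrix(cloud) else NULL

  best <- NULL
  n_degenerate <- 0L
  withr::with_seed(seed, {
    for (i in seq_len(iterations)) {
      s <- sample.int(n, m)
      model <- switch(shape,
        plane = fit_plane_minimal(P[s[1], ], P[s[2], ], P[s[3], ]),
        sphere = fit_sphere_minimal(P[s[1], ], P[s[2], ], P[s[3], ], P[s[4], ]),
        cylinder = fit_cylinder_minimal(P[s[1], ], NM[s[1], ],
                                        P[s[2], ], NM[s[2], ]))
      if (is_degenerate(model)) {
        n_degenerate <- n_degenerate + 1L
        next
      }
      d <- distance_to_shape(model, P)
      inl <- d <= epsilon
      cnt <- sum(inl)
      rmse <- if (cnt > 0) sqrt(mean(d[inl]^2)) else Inf
      if (is.null(best) || cnt > best$cnt ||
          (cnt == best$cnt && rmse < best$rmse)) {
        best <- list(model = model, inliers = inl, cnt = cnt, rmse = rmse,
                     d = d, iter = i)
      }
    }
  })
  if (is.null(best)) abort("no valid hypothesis: all iterations drew degenerate samples")

  converged <- NA
  refined <- FALSE
  if (refine && best$cnt >= m) {
    ref <- refine_fit(best$model, P[best$inliers, , drop = FALSE])
    converged <- isTRUE(attr(ref, "converged"))
    attr(ref, "converged") <- NULL
    d <- distance_to_shape(ref, P)
    inl <- d <= epsilon
    cnt <- sum(inl)
    best <- list(model = ref, inliers = inl, cnt = cnt,
                 rmse = if (cnt > 0) sqrt(mean(d[inl]^2)) else NaN,
                 d = d, iter = best$iter)
    refined <- TRUE
  }

  structure(list(
    shape = shape,
    model = best$model,
    inliers = best$inliers,
    itpr = best$cnt / n,
    rmse = if (best$cnt > 0) best$rmse else NaN,
    rmse_all = sqrt(mean(best$d^2)),
    n_points = n,
    n_inliers = best$cnt,
    iterations_run = iterations,
    n_degenerate = n_degenerate,
    epsilon = epsilon,
    seed = seed,
    refined = refined,
    converged = converged
  ), class = "ransac_fit")
}

#' @export
print.ransac_fit <- function(x, ...) {
  cat(sprintf("RANSAC %s fit: ITPR %.3f (%d/%d inliers at eps %g mm), RMSE %.3g mm\n",
              x$shape, x$itpr, x$n_inliers, x$n_points, x$epsilon, x$rmse))
  print(x$model)
  invisible(x)
}

#' Tidiers for RANSAC fits
#'
#' `tidy()` returns one row per model parameter, `glance()` a one-row fit
#' summary, and `augment()` the input cloud with `.distance` and `.inlier`
#' columns against the fitted surface.
#'
#' @param x A `ransac_fit`.
#' @param data For `augment()`, the point cloud the fit was computed on.
#' @param ... Unused.
#' @return A tibble.
#' @name ransac_tidiers
NULL

#' @rdname ransac_tidiers
#' @export
tidy.ransac_fit <- function(x, ...) {
  m <- x$model
  est <- switch(m$kind,
    plane = c(normal_x = m$normal[1], normal_y = m$normal[2],
              normal_z = m$normal[3], offset = m$offset),
    sphere = c(center_x = m$center[1], center_y = m$center[2],
               center_z = m$center[3], radius = m$radius),
    cylinder = c(anchor_x = m$anchor[1], anchor_y = m$anchor[2],
                 anchor_z = m$anchor[3], axis_x = m$axis[1],
                 axis_y = m$axis[2], axis_z = m$axis[3], radius = m$radius))
  tibble::tibble(term = names(est), estimate = unname(est))
}

#' @rdname ransac_tidiers
#' @export
glance.ransac_fit <- function(x, ...) {
  tibble::tibble(
    shape = x$shape, itpr = x$itpr, rmse = x$rmse, rmse_all = x$rmse_all,
    n_points = x$n_points, n_inliers = x$n_inliers,
    epsilon = x$epsilon, iterations_run = x$iterations_run,
    n_degenerate = x$n_degenerate, seed = x$seed,
    refined = x$refined, converged = x$converged)
}

#' @rdname ransac_tidiers
#' @export
augment.ransac_fit <- function(x, data, ...) {
  data <- as_point_cloud(data)
  if (nrow(data) != x$n_points) {
    abort("data must be the cloud the fit was computed on")
  }
  d <- distance_to_shape(x$model, data)
  data$.distance <- d
  data$.inlier <- d <= x$epsilon
  data
}
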