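#' Parametric symmetric primitives
#'
#' Shape models are the symmetric geometries whose goodness-of-fit measures
#' the congruence of a surface: an infinite plane `{p : n.p + d = 0}`, a
#' sphere (centre, radius) and an infinite circular cylinder (axis anchor,
#' unit axis direction, radius). Representations are canonicalised so model
#' equality is well defined: the lexicographically larger of `{n, -n}`
#' (resp. `{v, -v}`) is stored, and the cylinder anchor is the axis point
#' closest to the origin.
#'
#' @param normal,axis Unit 3-vectors (normalised on input).
#' @param offset Plane offset `d` in mm.
#' @param center,anchor 3-vectors in mm.
#' @param radius Positive radius in mm.
#' @return An object of class `shape_model`.
#' @name shape_model
NULL

#' @rdname shape_model
#' @export
shape_plane <- function(normal, offset) {
  normal <- unitize(normal)
  if (lex_flip(normal)) {
    normal <- -normal
    offset <- -offset
  }
  structure(list(kind = "plane", normal = normal, offset = offset),
            class = "shape_model")
}

#' @rdname shape_model
#' @export
shape_sphere <- function(center, radius) {
  if (radius <= 0) abort("sphere radius must be positive")
  structure(list(kind = "sphere", center = as.numeric(center),
                 radius = radius),
            class = "shape_model")
}

#' @rdname shape_model
#' @export
shape_cylinder <- function(anchor, axis, radius) {
  if (radius <= 0) abort("cylinder radius must be positive")
  axis <- unitize(axis)
  if (lex_flip(axis)) axis <- -axis
  anchor <- as.numeric(anchor)
  anchor <- anchor - sum(anchor * axis) * axis  # closest axis point to origin
  structure(list(kind = "cylinder", anchor = anchor, axis = axis,
                 radius = radius),
            class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  fmt <- function(v) paste0("(", paste(signif(v, 6), collapse = ", "), ")")
  switch(x$kind,
    plane = cat(sprintf("<plane> n = %s, d = %g mm\n", fmt(x$normal), x$offset)),
    sphere = cat(sprintf("<sphere> c = %s, r = %g mm\n", fmt(x$center), x$radius)),
    cylinder = cat(sprintf("<cylinder> a = %s, v = %s, r = %g mm\n",
                           fmt(x$anchor), fmt(x$axis), x$radius)))
  invisible(x)
}

unitize <- function(v) {
  v <- as.numeric(v)
  n <- sqrt(sum(v^2))
  if (n < 1e-12) abort("cannot normalise a zero vector")
  v / n
}

# TRUE when -v is lexicographically larger than v
lex_flip <- function(v) {
  for (i in seq_along(v)) {
    if (v[i] > 1e-12) return(FALSE)
    if (v[i] < -1e-12) return(TRUE)
  }
  FALSE
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Point-to-surface distances
#'
#' Absolute Euclidean distance from each point to the model surface: the
#' RANSAC inlier criterion's metric. Plane: `|n.p + d|`; sphere:
#' `| ||p - c|| - r |`; cylinder: distance to the axis minus the radius, in
#' absolute value.
#'
#' @param model A [shape_model].
#' @param points A point cloud (data frame with `x`,`y`,`z`) or an N x 3 matrix.
#' @return Numeric vector of non-negative distances (mm).
#' @examples
#' distance_to_shape(shape_plane(c(0, 0, 1), 0), data.frame(x = 0, y = 0, z = 1))
#' @export
distance_to_shape <- function(model, points) {
  P <- if (is.matrix(points)) points else cloud_matrix(points)
  switch(model$kind,
    plane = abs(P %*% model$normal + model$offset)[, 1],
    sphere = {
      d <- sweep(P, 2, model$center)
      abs(sqrt(rowSums(d^2)) - model$radius)
    },
    cylinder = {
      d <- sweep(P, 2, model$anchor)
      t <- d %*% model$axis
      radial <- d - t %*% rbind(model$axis)
      abs(sqrt(rowSums(radial^2)) - model$radius)
    },
    abort(paste0("unknown shape kind: ", model$kind)))
}

minimal_sample_size <- function(kind) {
  switch(kind, plane = 3L, sphere = 4L, cylinder = 2L,
         abort(paste0("unknown shape kind: ", kind)))
}

degenerate_sample <- function() {
  structure(class = c("degenerate_sample", "condition"),
            list(message = "degenerate sample", call = NULL))
}

is_degenerate <- function(x) inherits(x, "degenerate_sample")

#' Minimal-sample estimators
#'
#' RANSAC hypothesis generators: the exact primitive through a minimal point
#' sample. `fit_plane_minimal()` takes three non-collinear points;
#' `fit_sphere_minimal()` the circumsphere of four non-coplanar points;
#' `fit_cylinder_minimal()` the two-oriented-point construction standard in
#' primitive-detection work (axis direction `n1 x n2`, axis position the
#' least-squares intersection of the two surface-normal lines projected onto
#' the plane perpendicular to the axis, radius the mean axis distance of the
#' two projected points).
#'
#' Degenerate samples (collinear triple, coplanar quadruple, near-parallel
#' normals) return a `degenerate_sample` condition object, which the RANSAC
#' loop treats as a consumed iteration.
#'
#' @param p1,p2,p3,p4 3-vectors (mm).
#' @param n1,n2 Unit normals at `p1`, `p2`.
#' @return A [shape_model], or a `degenerate_sample` condition.
#' @name minimal_fits
NULL

#' @rdname minimal_fits
#' @export
fit_plane_minimal <- function(p1, p2, p3) {
  u <- p2 - p1
  v <- p3 - p1
  n <- cross3(u, v)
  scale <- max(sqrt(sum(u^2)), sqrt(sum(v^2)), sqrt(sum((p3 - p2)^2)))
  if (sqrt(sum(n^2)) < 1e-9 * max(scale, 1e-12)) return(degenerate_sample())
  n <- unitize(n)
  shape_plane(n, -sum(n * p1))
}

#' @rdname minimal_fits
#' @export
fit_sphere_minimal <- function(p1, p2, p3, p4) {
  # equate squared distances to centre: 2(pi - p1).c = |pi|^2 - |p1|^2
  A <- 2 * rbind(p2 - p1, p3 - p1, p4 - p1)
  b <- c(sum(p2^2) - sum(p1^2), sum(p3^2) - sum(p1^2), sum(p4^2) - sum(p1^2))
  det_a <- det(A)
  if (!is.finite(det_a) || abs(det_a) < 1e-9 * max(abs(A))^3) {
    return(degenerate_sample())
  }
  ctr <- solve(A, b)
  r <- sqrt(sum((p1 - ctr)^2))
  if (!is.finite(r) || r <= 0) return(degenerate_sample())
  shape_sphere(ctr, r)
}

#' @rdname minimal_fits
#' @export
fit_cylinder_minimal <- function(p1, n1, p2, n2) {
  v <- cross3(n1, n2)
  if (sqrt(sum(v^2)) <= 1e-6) return(degenerate_sample())
  v <- unitize(v)
  # project the two oriented lines onto the plane through origin perp to v
  proj <- function(p) p - sum(p * v) * v
  q1 <- proj(p1); m1 <- unitize(proj(n1))
  q2 <- proj(p2); m2 <- unitize(proj(n2))
  # least-squares intersection of lines q_i + t m_i in the projection plane:
  # minimise sum_i || (I - m_i m_i^T)(a - q_i) ||^2
  S <- matrix(0, 3, 3); rhs <- numeric(3)
  for (i in 1:2) {
    m <- if (i == 1) m1 else m2
    q <- if (i == 1) q1 else q2
    Pm <- diag(3) - tcrossprod(m)
    S <- S + Pm
    rhs <- rhs + Pm %*% q
  }
  # constrain the solution to the projection plane
  S <- S + tcrossprod(v)
  a <- solve(S, rhs)[, 1]
  r <- (sqrt(sum((q1 - a)^2)) + sqrt(sum((q2 - a)^2))) / 2
  if (!is.finite(r) || r <= 1e-12) return(degenerate_sample())
  shape_cylinder(a, v, r)
}

#' Least-squares refinement of a fitted primitive
#'
#' Polishes a RANSAC-winning model on its inlier set: the plane by the
#' closed-form principal-direction solution, sphere and cylinder by bounded
#' quasi-Newton minimisation of the summed squared orthogonal distance,
#' initialised at the input model. If the optimiser fails to reduce the
#' residual the input model is returned unchanged with `converged = FALSE`.
#'
#' @param model A [shape_model] to refine.
#' @param points Inlier points (data frame or matrix), at least as many as the
#'   shape's minimal sample size.
#' @return A [shape_model] with attribute `converged` (logical).
#' @export
refine_fit <- function(model, points) {
  P <- if (is.matrix(points)) points else cloud_matrix(points)
  if (nrow(P) < minimal_sample_size(model$kind)) {
    abort("too few inlier points to refine this shape")
  }
  out <- switch(model$kind,
    plane = refine_plane(P),
    sphere = refine_sphere(model, P),
    cylinder = refine_cylinder(model, P))
  old_ss <- sum(distance_to_shape(model, P)^2)
  new_ss <- sum(distance_to_shape(out, P)^2)
  if (!is.finite(new_ss) || new_ss > old_ss + 1e-9) {
    attr(model, "converged") <- FALSE
    warn(paste0("refinement of ", model$kind, " did not improve the fit; ",
                "keeping the unrefined model"))
    return(model)
  }
  attr(out, "converged") <- TRUE
  out
}

refine_plane <- function(P) {
  ctr <- colMeans(P)
  C <- crossprod(sweep(P, 2, ctr)) / nrow(P)
  n <- eigen(C, symmetric = TRUE)$vectors[, 3]
  shape_plane(n, -sum(n * ctr))
}

refine_sphere <- function(model, P) {
  # radius is profiled out: r(c) = mean ||p - c||
  obj <- function(ctr) {
    d <- sqrt(rowSums(sweep(P, 2, ctr)^2))
    sum((d - mean(d))^2)
  }
  fit <- tryCatch(
    optim(model$center, obj, method = "BFGS",
          control = list(maxit = 200, reltol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit)) return(model)
  d <- sqrt(rowSums(sweep(P, 2, fit$par)^2))
  r <- mean(d)
  if (r <= 0) return(model)
  shape_sphere(fit$par, r)
}

refine_cylinder <- function(model, P) {
  # parameters: anchor (3) + axis (3, normalised inside); radius profiled out
  obj <- function(par) {
    v <- par[4:6]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-9) return(1e12)
    v <- v / nv
    d <- sweep(P, 2, par[1:3])
    t <- d %*% v
    rad <- sqrt(rowSums((d - t %*% rbind(v))^2))
    sum((rad - mean(rad))^2)
  }
  start <- c(model$anchor, model$axis)
  fit <- tryCatch(
    optim(start, obj, method = "BFGS",
          control = list(maxit = 300, reltol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit)) return(model)
  v <- unitize(fit$par[4:6])
  d <- sweep(P, 2, fit$par[1:3])
  t <- d %*% v
  r <- mean(sqrt(rowSums((d - t %*% rbind(v))^2)))
  if (!is.finite(r) || r <= 0) return(model)
  shape_cylinder(fit$par[1:3], v, r)
}

#' Apply a rigid motion to a shape model
#'
#' Rotates and translates a primitive: plane normals rotate (offset follows),
#' sphere centres move, cylinder axes transform. Used by equivariance tests
#' and available for registering fitted models between frames.
#'
#' @param model A [shape_model].
#' @param rotation 3 x 3 rotation matrix.
#' @param translation 3-vector (mm).
#' @return The transformed [shape_model].
#' @export
transform_shape <- function(model, rotation = diag(3), translation = c(0, 0, 0)) {
  R <- rotation; tr <- as.numeric(translation)
  switch(model$kind,
    plane = {
      n <- as.numeric(R %*% model$normal)
      # point on old plane: -d * n_old; its image lies on the new plane
      p <- as.numeric(R %*% (-model$offset * model$normal)) + tr
      shape_plane(n, -sum(n * p))
    },
    sphere = shape_sphere(as.numeric(R %*% model$center) + tr, model$radius),
    cylinder = shape_cylinder(as.numeric(R %*% model$anchor) + tr,
                              as.numeric(R %*% model$axis), model$radius))
}
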