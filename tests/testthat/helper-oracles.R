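# independent oracles: exhaustive minimal-sample enumeration and direct
# distance computations, written separately from the package internals

oracle_cross <- function(ax, ay, az, bx, by, bz) {
  list(x = ay * bz - az * by, y = az * bx - ax * bz, z = ax * by - ay * bx)
}

oracle_plane_dist <- function(n, d, P) abs(P[, 1] * n[1] + P[, 2] * n[2] + P[, 3] * n[3] + d)

oracle_sphere_dist <- function(ctr, r, P) {
  abs(sqrt((P[, 1] - ctr[1])^2 + (P[, 2] - ctr[2])^2 + (P[, 3] - ctr[3])^2) - r)
}

oracle_cylinder_dist <- function(a, v, r, P) {
  dx <- P[, 1] - a[1]; dy <- P[, 2] - a[2]; dz <- P[, 3] - a[3]
  t <- dx * v[1] + dy * v[2] + dz * v[3]
  abs(sqrt(pmax((dx - t * v[1])^2 + (dy - t * v[2])^2 + (dz - t * v[3])^2, 0)) - r)
}

# best inlier count over ALL minimal samples (global optimum of the RANSAC
# search space); cloud must carry normals for the cylinder case
oracle_best_inlier_count <- function(cloud, shape, epsilon) {
  P <- as.matrix(cloud[c("x", "y", "z")])
  n <- nrow(P)
  switch(shape,
    plane = {
      idx <- utils::combn(n, 3)
      p1 <- P[idx[1, ], , drop = FALSE]
      e1 <- P[idx[2, ], , drop = FALSE] - p1
      e2 <- P[idx[3, ], , drop = FALSE] - p1
      cr <- oracle_cross(e1[, 1], e1[, 2], e1[, 3], e2[, 1], e2[, 2], e2[, 3])
      nn <- sqrt(cr$x^2 + cr$y^2 + cr$z^2)
      ok <- nn > 1e-9
      nx <- cr$x / nn; ny <- cr$y / nn; nz <- cr$z / nn
      d0 <- -(nx * p1[, 1] + ny * p1[, 2] + nz * p1[, 3])
      counts <- rep(0L, length(nn))
      for (j in seq_len(n)) {
        dist <- abs(P[j, 1] * nx + P[j, 2] * ny + P[j, 3] * nz + d0)
        counts <- counts + (dist <= epsilon)
      }
      max(counts[ok])
    },
    sphere = {
      idx <- utils::combn(n, 4)
      p1 <- P[idx[1, ], , drop = FALSE]
      r1 <- 2 * (P[idx[2, ], , drop = FALSE] - p1)
      r2 <- 2 * (P[idx[3, ], , drop = FALSE] - p1)
      r3 <- 2 * (P[idx[4, ], , drop = FALSE] - p1)
      sq <- rowSums(P^2)
      b1 <- sq[idx[2, ]] - sq[idx[1, ]]
      b2 <- sq[idx[3, ]] - sq[idx[1, ]]
      b3 <- sq[idx[4, ]] - sq[idx[1, ]]
      c23 <- oracle_cross(r2[, 1], r2[, 2], r2[, 3], r3[, 1], r3[, 2], r3[, 3])
      c31 <- oracle_cross(r3[, 1], r3[, 2], r3[, 3], r1[, 1], r1[, 2], r1[, 3])
      c12 <- oracle_cross(r1[, 1], r1[, 2], r1[, 3], r2[, 1], r2[, 2], r2[, 3])
      det <- r1[, 1] * c23$x + r1[, 2] * c23$y + r1[, 3] * c23$z
      scale <- pmax(abs(r1[, 1]), abs(r2[, 2]), abs(r3[, 3]), 1)
      ok <- abs(det) > 1e-9 * scale^3
      cx <- (b1 * c23$x + b2 * c31$x + b3 * c12$x) / det
      cy <- (b1 * c23$y + b2 * c31$y + b3 * c12$y) / det
      cz <- (b1 * c23$z + b2 * c31$z + b3 * c12$z) / det
      rr <- sqrt((p1[, 1] - cx)^2 + (p1[, 2] - cy)^2 + (p1[, 3] - cz)^2)
      counts <- rep(0L, length(det))
      for (j in seq_len(n)) {
        dist <- abs(sqrt((P[j, 1] - cx)^2 + (P[j, 2] - cy)^2 +
                           (P[j, 3] - cz)^2) - rr)
        counts <- counts + (dist <= epsilon)
      }
      max(counts[ok])
    },
    cylinder = {
      NM <- as.matrix(cloud[c("nx", "ny", "nz")])
      idx <- utils::combn(n, 2)
      best <- 0L
      for (h in seq_len(ncol(idx))) {
        i <- idx[1, h]; j <- idx[2, h]
        v <- c(NM[i, 2] * NM[j, 3] - NM[i, 3] * NM[j, 2],
               NM[i, 3] * NM[j, 1] - NM[i, 1] * NM[j, 3],
               NM[i, 1] * NM[j, 2] - NM[i, 2] * NM[j, 1])
        nv <- sqrt(sum(v^2))
        if (nv <= 1e-6) next
        v <- v / nv
        # 2D intersection of the two normal lines in the plane perp to v
        ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        u1 <- ref - sum(ref * v) * v; u1 <- u1 / sqrt(sum(u1^2))
        u2 <- c(v[2] * u1[3] - v[3] * u1[2], v[3] * u1[1] - v[1] * u1[3],
                v[1] * u1[2] - v[2] * u1[1])
        q1 <- c(sum(P[i, ] * u1), sum(P[i, ] * u2))
        q2 <- c(sum(P[j, ] * u1), sum(P[j, ] * u2))
        m1 <- c(sum(NM[i, ] * u1), sum(NM[i, ] * u2))
        m2 <- c(sum(NM[j, ] * u1), sum(NM[j, ] * u2))
        den <- m1[1] * (-m2[2]) - (-m2[1]) * m1[2]
        if (abs(den) < 1e-9) next
        rhs <- q2 - q1
        t1 <- (rhs[1] * (-m2[2]) - (-m2[1]) * rhs[2]) / den
        a2d <- q1 + t1 * m1
        r <- (sqrt(sum((q1 - a2d)^2)) + sqrt(sum((q2 - a2d)^2))) / 2
        if (!is.finite(r) || r <= 1e-9) next
        a3d <- a2d[1] * u1 + a2d[2] * u2
        cnt <- sum(oracle_cylinder_dist(a3d, v, r, P) <= epsilon)
        if (cnt > best) best <- cnt
      }
      best
    })
}

# attach analytic surface normals (randomised on off-surface points) so
# cylinder search is assessed against enumeration over the same oriented
# points, independent of normal-estimation error
with_true_normals <- function(cloud, model, n_surface, seed) {
  P <- as.matrix(cloud[c("x", "y", "z")])
  N <- switch(model$kind,
    plane = matrix(model$normal, nrow(P), 3, byrow = TRUE),
    sphere = {
      d <- sweep(P, 2, model$center)
      d / sqrt(rowSums(d^2))
    },
    cylinder = {
      d <- sweep(P, 2, model$anchor)
      t <- d %*% model$axis
      rad <- d - t %*% rbind(model$axis)
      rad / sqrt(rowSums(rad^2))
    })
  withr::with_seed(seed, {
    R <- matrix(rnorm(3 * nrow(P)), ncol = 3)
  })
  R <- R / sqrt(rowSums(R^2))
  off <- seq_len(nrow(P)) > n_surface
  N[off, ] <- R[off, , drop = FALSE]
  cloud$nx <- N[, 1]; cloud$ny <- N[, 2]; cloud$nz <- N[, 3]
  as_point_cloud(cloud)
}

# 60/40 surface/outlier mixture with known true-model inlier content
mixture_cloud <- function(shape, n_surface = 300, n_outlier = 200, seed = 1,
                          noise_sd = 0.05) {
  model <- switch(shape,
    plane = shape_plane(c(0, 0, 1), 0),
    sphere = shape_sphere(c(0, 0, 0), 10),
    cylinder = shape_cylinder(c(0, 0, 0), c(0, 0, 1), 10))
  surf <- generate_primitive_patch(shape, model, n_surface, noise_sd = noise_sd,
                                   outlier_fraction = 0, seed = seed,
                                   extent = 30)
  withr::with_seed(seed + 1, {
    acc <- NULL
    while (is.null(acc) || nrow(acc) < n_outlier) {
      cand <- cbind(runif(4 * n_outlier, -30, 30), runif(4 * n_outlier, -30, 30),
                    runif(4 * n_outlier, -30, 30))
      keep <- distance_to_shape(model, cand) >= 5
      acc <- rbind(acc, cand[keep, , drop = FALSE])
    }
    out <- acc[seq_len(n_outlier), ]
    cloud <- as_point_cloud(tibble::tibble(
      x = c(surf$x, out[, 1]), y = c(surf$y, out[, 2]), z = c(surf$z, out[, 3])))
    list(cloud = cloud, model = model,
         true_frac = n_surface / (n_surface + n_outlier))
  })
}
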