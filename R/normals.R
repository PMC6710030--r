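#' Estimate per-point surface normals by local PCA
#'
#' Each point's normal is the least-variance principal direction of its `k`
#' nearest neighbours (the point itself included). Needed by the
#' two-oriented-point cylinder hypothesis generator. The sign is fixed to the
#' +z hemisphere (ties broken toward +y, then +x) — an arbitrary but fixed
#' convention; the cylinder estimator is sign-invariant.
#'
#' Neighbour search is exact (blocked brute force) and the 3 x 3 covariance
#' eigenproblem is solved in closed form across all points at once, with an
#' `eigen()` fallback for near-degenerate neighbourhoods.
#'
#' @param cloud A point cloud (data frame with `x`,`y`,`z`).
#' @param k Neighbourhood size (>= 3).
#' @return The cloud with unit `nx`,`ny`,`nz` columns (replacing any present).
#' @examples
#' grid <- expand.grid(x = 1:8, y = 1:8)
#' cl <- estimate_normals(data.frame(x = grid$x, y = grid$y, z = 0), k = 6)
#' stopifnot(all(abs(cl$nz - 1) < 1e-9))
#' @export
estimate_normals <- function(cloud, k = 20) {
  cloud <- as_point_cloud(cloud)
  if (k < 3) abort("k must be at least 3")
  n <- nrow(cloud)
  if (n < k) abort("insufficient points: need at least k points to estimate normals")
  P <- cloud_matrix(cloud)
  idx <- knn_indices(P, k)

  Nx <- matrix(P[, 1][idx], n, k)
  Ny <- matrix(P[, 2][idx], n, k)
  Nz <- matrix(P[, 3][idx], n, k)
  mx <- rowMeans(Nx); my <- rowMeans(Ny); mz <- rowMeans(Nz)
  Sxx <- rowMeans(Nx * Nx) - mx * mx
  Syy <- rowMeans(Ny * Ny) - my * my
  Szz <- rowMeans(Nz * Nz) - mz * mz
  Sxy <- rowMeans(Nx * Ny) - mx * my
  Sxz <- rowMeans(Nx * Nz) - mx * mz
  Syz <- rowMeans(Ny * Nz) - my * mz

  nv <- smallest_eigvec3(Sxx, Syy, Szz, Sxy, Sxz, Syz)

  tol <- 1e-12
  s <- ifelse(nv[, 3] > tol, 1, ifelse(nv[, 3] < -tol, -1,
       ifelse(nv[, 2] > tol, 1, ifelse(nv[, 2] < -tol, -1,
       ifelse(nv[, 1] >= 0, 1, -1)))))
  nv <- nv * s
  cloud$nx <- nv[, 1]; cloud$ny <- nv[, 2]; cloud$nz <- nv[, 3]
  as_point_cloud(cloud)
}

# exact k nearest neighbours (self included), blocked to bound memory
knn_indices <- function(P, k, block = 1024L) {
  n <- nrow(P)
  sq <- rowSums(P^2)
  idx <- matrix(0L, n, k)
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    # squared distances from block rows to all points
    D <- outer(sq[rows], sq, "+") - 2 * tcrossprod(P[rows, , drop = FALSE], P)
    for (i in seq_along(rows)) {
      idx[rows[i], ] <- order(D[i, ])[seq_len(k)]
    }
  }
  idx
}

# smallest-eigenvalue unit eigenvectors of symmetric 3x3 matrices, vectorised
# (trigonometric eigenvalue formula + row-cross-product eigenvectors)
smallest_eigvec3 <- function(Sxx, Syy, Szz, Sxy, Sxz, Syz) {
  n <- length(Sxx)
  q <- (Sxx + Syy + Szz) / 3
  p1 <- Sxy^2 + Sxz^2 + Syz^2
  p2 <- (Sxx - q)^2 + (Syy - q)^2 + (Szz - q)^2 + 2 * p1
  p <- sqrt(pmax(p2 / 6, 0))
  ok <- p > 1e-300
  lam <- q  # default for zero matrices
  if (any(ok)) {
    b11 <- (Sxx - q) / p; b22 <- (Syy - q) / p; b33 <- (Szz - q) / p
    b12 <- Sxy / p; b13 <- Sxz / p; b23 <- Syz / p
    detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    lam_min <- q + 2 * p * cos(phi + 2 * pi / 3)
    lam <- ifelse(ok, lam_min, q)
  }
  # rows of (A - lam I)
  a1x <- Sxx - lam; a1y <- Sxy;       a1z <- Sxz
  a2x <- Sxy;       a2y <- Syy - lam; a2z <- Syz
  a3x <- Sxz;       a3y <- Syz;       a3z <- Szz - lam
  cr <- function(ux, uy, uz, vx, vy, vz) {
    cbind(uy * vz - uz * vy, uz * vx - ux * vz, ux * vy - uy * vx)
  }
  c12 <- cr(a1x, a1y, a1z, a2x, a2y, a2z)
  c13 <- cr(a1x, a1y, a1z, a3x, a3y, a3z)
  c23 <- cr(a2x, a2y, a2z, a3x, a3y, a3z)
  n12 <- rowSums(c12^2); n13 <- rowSums(c13^2); n23 <- rowSums(c23^2)
  best <- pmax(n12, n13, n23)
  V <- c12
  use13 <- n13 == best
  V[use13, ] <- c13[use13, , drop = FALSE]
  use23 <- n23 == best & !use13
  V[use23, ] <- c23[use23, , drop = FALSE]
  nrm <- sqrt(rowSums(V^2))
  scale <- pmax(abs(Sxx), abs(Syy), abs(Szz), 1e-300)
  bad <- which(!is.finite(nrm) | nrm < 1e-12 * scale)
  good <- nrm > 0 & is.finite(nrm)
  V[good, ] <- V[good, , drop = FALSE] / nrm[good]
  for (i in bad) {  # degenerate: fall back to a dense eigensolve
    A <- matrix(c(Sxx[i], Sxy[i], Sxz[i],
                  Sxy[i], Syy[i], Syz[i],
                  Sxz[i], Syz[i], Szz[i]), 3, 3)
    V[i, ] <- eigen(A, symmetric = TRUE)$vectors[, 3]
  }
  V
}
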