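# shared fixture builders; everything is generated in code at test time

rotation_xyz <- function(ax, ay, az) {
  Rx <- matrix(c(1, 0, 0, 0, cos(ax), sin(ax), 0, -sin(ax), cos(ax)), 3, 3)
  Ry <- matrix(c(cos(ay), 0, -sin(ay), 0, 1, 0, sin(ay), 0, cos(ay)), 3, 3)
  Rz <- matrix(c(cos(az), sin(az), 0, -sin(az), cos(az), 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

transform_cloud <- function(cloud, R, tr) {
  P <- as.matrix(cloud[c("x", "y", "z")]) %*% t(R)
  out <- cloud
  out$x <- P[, 1] + tr[1]; out$y <- P[, 2] + tr[2]; out$z <- P[, 3] + tr[3]
  if (all(c("nx", "ny", "nz") %in% names(cloud))) {
    N <- as.matrix(cloud[c("nx", "ny", "nz")]) %*% t(R)
    out$nx <- N[, 1]; out$ny <- N[, 2]; out$nz <- N[, 3]
  }
  out
}

# a flat quiet vertebra: pure arch cylinder, no ridge/facets/noise/outliers
bare_arch_params <- function(n = 800, seed = 1, ...) {
  vertebra_params(sp_height = 0, facet_height = 0, facet_count_per_side = 0,
                  noise_sd = 0, outlier_fraction = 0, points_per_level = n,
                  seed = seed, ...)
}

random_shape_model <- function(kind, seed) {
  withr::with_seed(seed, {
    switch(kind,
      plane = shape_plane(rnorm(3), runif(1, -5, 5)),
      sphere = shape_sphere(runif(3, -10, 10), runif(1, 5, 15)),
      cylinder = shape_cylinder(runif(3, -5, 5), rnorm(3), runif(1, 5, 15)))
  })
}
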