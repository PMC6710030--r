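test_that("point-to-surface distances match hand values", {
  expect_equal(distance_to_shape(shape_plane(c(0, 0, 1), 0),
                                 data.frame(x = 0, y = 0, z = 1)), 1.0)
  expect_equal(distance_to_shape(shape_sphere(c(0, 0, 0), 1),
                                 data.frame(x = 2, y = 0, z = 0)), 1.0)
  expect_equal(distance_to_shape(shape_cylinder(c(0, 0, 0), c(0, 0, 1), 1),
                                 data.frame(x = 2, y = 0, z = 5)), 1.0)
  # vectorised over a matrix, all non-negative
  P <- matrix(rnorm(60), ncol = 3)
  for (kind in c("plane", "sphere", "cylinder")) {
    d <- distance_to_shape(random_shape_model(kind, 4), P)
    expect_length(d, 20)
    expect_true(all(d >= 0))
  }
})

test_that("model representations are canonical", {
  # normal sign: the lexicographically larger of {n, -n} is stored
  p <- shape_plane(c(0, 0, -1), 2)
  expect_equal(p$normal, c(0, 0, 1))
  expect_equal(p$offset, -2)
  cy <- shape_cylinder(c(1, 2, 5), c(0, 0, -1), 3)
  expect_equal(cy$axis, c(0, 0, 1))
  # anchor is the axis point closest to the origin
  expect_equal(cy$anchor, c(1, 2, 0))
  expect_error(shape_sphere(c(0, 0, 0), -1), "radius")
})

test_that("minimal plane estimator is exact and flags collinear triples", {
  p <- fit_plane_minimal(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(p$normal, c(0, 0, 1))
  expect_equal(p$offset, 0)
  p2 <- fit_plane_minimal(c(0, 0, 1), c(1, 0, 1), c(0, 1, 1))
  expect_equal(p2$normal, c(0, 0, 1))
  expect_equal(p2$offset, -1)
  # the defining points lie on the plane to numerical precision
  pts <- matrix(rnorm(9, sd = 5), 3, 3)
  pr <- fit_plane_minimal(pts[1, ], pts[2, ], pts[3, ])
  expect_lt(max(distance_to_shape(pr, pts)), 1e-9)
  expect_true(spinefit:::is_degenerate(
    fit_plane_minimal(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))))
})

test_that("minimal sphere estimator recovers the circumsphere", {
  s <- fit_sphere_minimal(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(s$center, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(s$radius, 1, tolerance = 1e-12)
  expect_true(spinefit:::is_degenerate(
    fit_sphere_minimal(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))))
  # any 4 general-position samples of a known sphere give it back
  truth <- shape_sphere(c(3, -2, 7), 5)
  withr::with_seed(11, {
    for (rep in 1:5) {
      u <- matrix(rnorm(12), 4, 3)
      u <- u / sqrt(rowSums(u^2))
      pts <- sweep(5 * u, 2, -truth$center)
      fit <- fit_sphere_minimal(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
      expect_equal(fit$center, truth$center, tolerance = 1e-6)
      expect_equal(fit$radius, truth$radius, tolerance = 1e-6)
    }
  })
})

test_that("two-oriented-point cylinder estimator works and flags parallels", {
  cy <- fit_cylinder_minimal(c(1, 0, 0), c(1, 0, 0), c(0, 1, 4), c(0, 1, 0))
  expect_equal(abs(cy$axis), c(0, 0, 1))
  expect_equal(cy$anchor, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(cy$radius, 1, tolerance = 1e-9)
  cy2 <- fit_cylinder_minimal(c(2, 0, 0), c(1, 0, 0), c(0, 2, 9), c(0, 1, 0))
  expect_equal(abs(cy2$axis), c(0, 0, 1))
  expect_equal(cy2$radius, 2, tolerance = 1e-9)
  expect_true(spinefit:::is_degenerate(
    fit_cylinder_minimal(c(1, 0, 0), c(0, 0, 1), c(0, 1, 4), c(0, 0, 1))))
  # sign-invariance: flipping either normal leaves the model unchanged
  cy3 <- fit_cylinder_minimal(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 4), c(0, 1, 0))
  expect_equal(cy3$radius, cy$radius, tolerance = 1e-9)
  expect_equal(abs(cy3$axis), abs(cy$axis), tolerance = 1e-9)
})

test_that("least-squares refinement recovers exact shapes and cannot worsen", {
  # exact plane inliers, perturbed initial model
  withr::with_seed(3, {
    P <- cbind(runif(50, -10, 10), runif(50, -10, 10), 0)
  })
  ref <- refine_fit(shape_plane(c(0.05, -0.03, 1), 0.2), P)
  expect_lt(max(distance_to_shape(ref, P)), 1e-9)
  # noise-free sphere samples, radius off by 10%
  withr::with_seed(4, {
    u <- matrix(rnorm(300), ncol = 3); u <- u / sqrt(rowSums(u^2))
  })
  refs <- refine_fit(shape_sphere(c(0.02, 0, -0.01), 1.1), u)
  expect_equal(refs$radius, 1, tolerance = 1e-6)
  expect_equal(refs$center, c(0, 0, 0), tolerance = 1e-6)
  # cylinder: perturbed model converges back
  th <- seq(0, 2 * pi, length.out = 120)
  C <- cbind(10 * cos(th), 10 * sin(th), rep(seq(-5, 5, length.out = 6), 20))
  refc <- refine_fit(shape_cylinder(c(0.3, -0.2, 0), c(0.02, 0.01, 1), 9.5), C)
  expect_equal(refc$radius, 10, tolerance = 1e-5)
  expect_equal(abs(refc$axis), c(0, 0, 1), tolerance = 1e-5)
  # too few inliers is an error
  expect_error(refine_fit(shape_sphere(c(0, 0, 0), 1), matrix(rnorm(6), 2, 3)),
               "few")
})

test_that("transform_shape is consistent with transforming the points", {
  R <- rotation_xyz(0.3, -0.5, 1.1)
  tr <- c(4, -2, 7)
  for (kind in c("plane", "sphere", "cylinder")) {
    m <- random_shape_model(kind, 8)
    withr::with_seed(9, P <- matrix(rnorm(90, sd = 6), ncol = 3))
    d0 <- distance_to_shape(m, P)
    Pt <- P %*% t(R) + matrix(tr, 30, 3, byrow = TRUE)
    d1 <- distance_to_shape(transform_shape(m, R, tr), Pt)
    expect_equal(d1, d0, tolerance = 1e-9)
  }
})
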