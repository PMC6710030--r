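test_that("primitive patches honour their construction guarantees", {
  pl <- shape_plane(c(0, 0, 1), 0)
  cl <- generate_primitive_patch("plane", pl, 100, noise_sd = 0, seed = 1)
  expect_identical(nrow(cl), 100L)
  expect_lt(max(distance_to_shape(pl, cl)), 1e-12)

  sp <- shape_sphere(c(0, 0, 0), 10)
  cl2 <- generate_primitive_patch("sphere", sp, 1000, noise_sd = 0,
                                  outlier_fraction = 0.3, seed = 2)
  expect_identical(sum(cl2$label == "surface"), 700L)
  out <- cl2[cl2$label == "outlier", ]
  expect_gt(min(distance_to_shape(sp, out)), 2)

  expect_error(generate_primitive_patch("plane", pl, 100, outlier_fraction = 1),
               "outlier_fraction")
  # determinism
  expect_identical(generate_primitive_patch("sphere", sp, 200, 0.1, 0.1, seed = 7),
                   generate_primitive_patch("sphere", sp, 200, 0.1, 0.1, seed = 7))
})

test_that("a bare arch lies exactly on its cylinder", {
  v <- generate_vertebra(bare_arch_params(n = 800, seed = 3))
  arch <- attr(v, "arch_model")
  expect_lt(max(distance_to_shape(arch, v)), 1e-9)
  fit <- ransac_fit(v, "cylinder", epsilon = 0.1, seed = 5)
  expect_identical(fit$itpr, 1)
})

test_that("labels partition the cloud and respect the geometry", {
  p <- vertebra_params(points_per_level = 2000, seed = 11)
  v <- generate_vertebra(p)
  expect_identical(nrow(v), 2000L)
  expect_true(all(v$label %in% spinefit_labels()))
  expect_false(anyNA(v$label))
  # spinous-process points sit inside the base half-width band
  sp <- v[v$label %in% c("sp_base", "sp_tip"), ]
  expect_true(all(abs(sp$x) <= p$sp_base_halfwidth + 4 * p$noise_sd))
  # laminae spread well beyond the band
  lam <- v[v$label %in% c("left_hemilamina", "right_hemilamina"), ]
  expect_gt(stats::median(abs(lam$x)), p$sp_base_halfwidth)
  # outlier count by construction
  expect_identical(sum(v$label == "outlier"),
                   2000L - as.integer(ceiling(2000 * (1 - p$outlier_fraction))))
  # determinism
  expect_identical(v, generate_vertebra(p))
})

test_that("mirroring the cloud in the midsagittal plane preserves congruence", {
  v <- generate_vertebra(vertebra_params(points_per_level = 1200, seed = 13))
  arch <- attr(v, "arch_model")
  mirrored <- v
  mirrored$x <- -mirrored$x
  # the arch cylinder is symmetric in x = 0: distance profiles are identical
  d0 <- distance_to_shape(arch, v)
  d1 <- distance_to_shape(arch, mirrored)
  expect_equal(d1, d0, tolerance = 1e-9)
  expect_identical(mean(d1 <= 0.5), mean(d0 <= 0.5))
})

test_that("raising the spinous process monotonically degrades Group B fits", {
  itpr <- vapply(c(0, 4, 8, 12), function(h) {
    p <- vertebra_params(sp_height = h, noise_sd = 0, outlier_fraction = 0,
                         points_per_level = 1500, seed = 17)
    v <- generate_vertebra(p)
    b <- reconstruct_group(v, "B", "left")
    ransac_fit(b, "cylinder", epsilon = 0.5, seed = 19, normal_k = 15)$itpr
  }, numeric(1))
  expect_true(all(diff(itpr) <= 0.02))
  expect_lt(itpr[4], itpr[1])
})

test_that("cohorts have the declared structure and reproducibility", {
  spec <- cohort_spec(n_specimens = 2, levels = c("C1", "C4", "T7", "L3", "S1"),
                      seed = 23, base_params = vertebra_params(points_per_level = 500))
  co <- generate_cohort(spec)
  expect_identical(nrow(co), 10L)
  expect_identical(co$region,
                   rep(c("C1", "cervical", "thoracic", "lumbar", "sacral"), 2))
  expect_identical(co, generate_cohort(spec))
  expect_error(cohort_spec(levels = c("C4", "X9")), "unknown spinal level")
  # zero jitter + shared specimen seeds -> identical clouds per level
  spec0 <- cohort_spec(n_specimens = 2, levels = c("C4", "L3"), jitter_sd = 0,
                       specimen_seeds = c(77L, 77L),
                       base_params = vertebra_params(points_per_level = 500))
  co0 <- generate_cohort(spec0)
  expect_identical(co0$cloud[[1]], co0$cloud[[3]])
  expect_identical(co0$cloud[[2]], co0$cloud[[4]])
})

test_that("cervical preset is more cylinder-congruent than lumbar (noise-free)", {
  mean_itpr <- function(preset, seed) {
    p <- do.call(vertebra_params,
                 c(preset, list(noise_sd = 0, outlier_fraction = 0,
                                points_per_level = 1500, seed = seed)))
    v <- generate_vertebra(p)
    cc <- reconstruct_group(v, "C", "left")
    # oracle: inlier fraction against the true arch, no fitting involved
    mean(distance_to_shape(attr(v, "arch_model"), cc) <= 0.5)
  }
  pres <- region_presets()
  cerv <- mean(vapply(1:3, function(s) mean_itpr(pres$cervical, s), numeric(1)))
  lumb <- mean(vapply(1:3, function(s) mean_itpr(pres$lumbar, s), numeric(1)))
  expect_gt(cerv, lumb)
})
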