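#' Sample a noisy patch of a primitive surface with known outlier content
#'
#' Test-fixture generator with exact ground truth: `ceiling(n * (1 -
#' outlier_fraction))` points are sampled uniformly on a bounded patch of the
#' model surface and perturbed with isotropic Gaussian noise; the remaining
#' points are drawn uniformly in an enlarged bounding box, rejecting anything
#' inside a 2 mm shell of the surface, and labelled `"outlier"`. Surface
#' points are labelled `"surface"`.
#'
#' @param kind `"plane"`, `"sphere"` or `"cylinder"` (must match `model$kind`).
#' @param model A [shape_model] to sample from.
#' @param n Total number of points (>= 10).
#' @param noise_sd Isotropic Gaussian noise SD in mm.
#' @param outlier_fraction Fraction of points drawn off-surface, in `[0, 1)`.
#' @param seed RNG seed; the cloud is deterministic per seed.
#' @param extent Patch extent in mm (plane side length / cylinder axial span).
#' @return A labelled `point_cloud` (surface points first, then outliers).
#' @export
generate_primitive_patch <- function(kind, model, n, noise_sd = 0,
                                     outlier_fraction = 0, seed = 1,
                                     extent = 20) {
  if (!identical(kind, model$kind)) abort("kind must match model$kind")
  if (n < 10) abort("n must be at least 10")
  if (outlier_fraction < 0 || outlier_fraction >= 1) {
    abort("outlier_fraction must be in [0, 1)")
  }
  n_surf <- as.integer(ceiling(n * (1 - outlier_fraction)))
  n_out <- n - n_surf
  withr::with_seed(seed, {
    S <- switch(kind,
      plane = {
        b <- plane_basis(model$normal)
        p0 <- -model$offset * model$normal
        a <- runif(n_surf, -extent / 2, extent / 2)
        c2 <- runif(n_surf, -extent / 2, extent / 2)
        sweep(outer(a, b$u) + outer(c2, b$w), 2, -p0)
      },
      sphere = {
        z <- runif(n_surf, -1, 1)
        th <- runif(n_surf, 0, 2 * pi)
        s <- sqrt(1 - z^2)
        sweep(model$radius * cbind(s * cos(th), s * sin(th), z),
              2, -model$center)
      },
      cylinder = {
        b <- plane_basis(model$axis)
        t <- runif(n_surf, -extent / 2, extent / 2)
        th <- runif(n_surf, 0, 2 * pi)
        ring <- model$radius * (outer(cos(th), b$u) + outer(sin(th), b$w))
        sweep(ring + outer(t, model$axis), 2, -model$anchor)
      })
    if (noise_sd > 0) S <- S + matrix(rnorm(3 * n_surf, 0, noise_sd), ncol = 3)
    O <- sample_outliers(n_out, S, function(P) distance_to_shape(model, P))
    cloud <- tibble::tibble(
      x = c(S[, 1], O[, 1]), y = c(S[, 2], O[, 2]), z = c(S[, 3], O[, 3]),
      label = rep(c("surface", "outlier"), c(n_surf, n_out)))
    as_point_cloud(cloud)
  })
}

# orthonormal basis of the plane perpendicular to unit vector v
plane_basis <- function(v) {
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unitize(cross3(v, ref))
  list(u = u, w = cross3(v, u))
}

# uniform points in the surface bounding box (padded), at least `shell` mm
# from the surface per `distfun`
sample_outliers <- function(n_out, surface_pts, distfun, pad = 10, shell = 2) {
  if (n_out == 0) return(matrix(numeric(0), 0, 3))
  lo <- apply(surface_pts, 2, min) - pad
  hi <- apply(surface_pts, 2, max) + pad
  acc <- matrix(numeric(0), 0, 3)
  tries <- 0
  while (nrow(acc) < n_out && tries < 200) {
    m <- max(4 * (n_out - nrow(acc)), 16)
    cand <- cbind(runif(m, lo[1], hi[1]), runif(m, lo[2], hi[2]),
                  runif(m, lo[3], hi[3]))
    keep <- distfun(cand) > shell
    acc <- rbind(acc, cand[keep, , drop = FALSE])
    tries <- tries + 1
  }
  if (nrow(acc) < n_out) abort("could not place outliers outside the surface shell")
  acc[seq_len(n_out), , drop = FALSE]
}

#' Parameters of the synthetic posterior-element surface
#'
#' The generator is a deliberately minimal parametric composite of the
#' posterior elements exposed in a midline or paramedian approach: a
#' cylindrical laminar arch (the source of cylindrical congruence), a
#' box-like spinous-process ridge on the midline (the feature that breaks
#' symmetry when included in a registration), and hemispherical facet-joint
#' bumps at the lateral ends (regional relief differences). Coordinates are
#' mm, right-handed, +y cranio-caudal, +z dorsal, midline at x = 0.
#'
#' @param arch_radius Laminar arch cylinder radius (mm).
#' @param arch_halfangle Arch sweep each side of the midline (degrees).
#' @param arch_axis_tilt Laminar axis tilt off the cranio-caudal axis (degrees).
#' @param sp_height Spinous-process ridge protrusion (mm); 0 disables.
#' @param sp_length Ridge cranio-caudal extent (mm).
#' @param sp_base_halfwidth Half-width of the ridge footprint about the
#'   midline (mm); ridge points protruding at most `sp_base_frac` of
#'   `sp_height` are labelled `sp_base`, the rest `sp_tip`.
#' @param facet_count_per_side,facet_radius,facet_height Hemispherical
#'   facet-bump relief: bumps per side, footprint radius (mm), peak height
#'   (mm); 0 height or 0 count disables.
#' @param noise_sd Isotropic Gaussian sensor noise SD (mm).
#' @param outlier_fraction Fraction of stray non-surface points, in `[0, 1)`.
#' @param points_per_level Total points per cloud (>= 500 for stable normals).
#' @param level_length Cranio-caudal extent of the cloud (mm).
#' @param sp_base_frac Protrusion fraction below which a ridge point counts
#'   as spinous-process base.
#' @param seed RNG seed.
#' @return A `vertebra_params` list.
#' @export
vertebra_params <- function(arch_radius = 14, arch_halfangle = 55,
                            arch_axis_tilt = 0, sp_height = 12,
                            sp_length = 10, sp_base_halfwidth = 4,
                            facet_count_per_side = 2, facet_radius = 5,
                            facet_height = 2.5, noise_sd = 0.15,
                            outlier_fraction = 0.02, points_per_level = 4000,
                            level_length = 25, sp_base_frac = 0.4, seed = 1) {
  p <- list(arch_radius = arch_radius, arch_halfangle = arch_halfangle,
            arch_axis_tilt = arch_axis_tilt, sp_height = sp_height,
            sp_length = sp_length, sp_base_halfwidth = sp_base_halfwidth,
            facet_count_per_side = facet_count_per_side,
            facet_radius = facet_radius, facet_height = facet_height,
            noise_sd = noise_sd, outlier_fraction = outlier_fraction,
            points_per_level = points_per_level, level_length = level_length,
            sp_base_frac = sp_base_frac, seed = seed)
  if (p$arch_radius <= 0 || p$arch_halfangle <= 0 || p$level_length <= 0) {
    abort("arch_radius, arch_halfangle and level_length must be positive")
  }
  if (p$sp_height < 0 || p$facet_height < 0 || p$noise_sd < 0) {
    abort("sp_height, facet_height and noise_sd must be non-negative")
  }
  if (p$sp_height > 0 && (p$sp_length <= 0 || p$sp_base_halfwidth <= 0)) {
    abort("sp_length and sp_base_halfwidth must be positive when sp_height > 0")
  }
  if (p$outlier_fraction < 0 || p$outlier_fraction >= 1) {
    abort("outlier_fraction must be in [0, 1)")
  }
  if (p$points_per_level < 500) {
    abort("points_per_level must be at least 500 for stable normal estimation")
  }
  structure(p, class = "vertebra_params")
}

#' Generate a labelled vertebra-like posterior-element point cloud
#'
#' Stands in for an optical-topography surface map of one exposed vertebral
#' level. The dorsal surface of the laminar arch (cylinder of
#' `arch_radius`, swept `arch_halfangle` degrees each side of the midline,
#' axis along +y, convex toward +z) carries a box-like spinous-process ridge
#' replacing the arch under its midline footprint, and hemispherical facet
#' bumps at the lateral ends. Every point is labelled by region
#' (`left_hemilamina`, `right_hemilamina`, `sp_base`, `sp_tip`, `facet`,
#' `outlier`); sensor noise and stray outlier points are applied last. The
#' true arch cylinder is attached as attribute `arch_model`.
#'
#' @param params A [vertebra_params()] list.
#' @return A labelled `point_cloud`, deterministic per `params$seed`.
#' @examples
#' cl <- generate_vertebra(vertebra_params(points_per_level = 600, seed = 7))
#' table(cl$label)
#' @export
generate_vertebra <- function(params = vertebra_params()) {
  if (!inherits(params, "vertebra_params")) params <- do.call(vertebra_params, params)
  p <- params
  n <- p$points_per_level
  n_surf <- as.integer(ceiling(n * (1 - p$outlier_fraction)))
  n_out <- n - n_surf
  R <- p$arch_radius
  A <- p$arch_halfangle * pi / 180
  hw <- min(p$sp_base_halfwidth, 0.99 * R)
  th_hw <- asin(hw / R)

  # surface-area-weighted point allocation: an optical scan samples the
  # exposed surface roughly uniformly, so the ridge side walls get their
  # area's share of points in addition to the arch parameter patch
  arch_area <- 2 * A * R * p$level_length
  wall_area <- if (p$sp_height > 0) 2 * p$sp_length * p$sp_height else 0
  n_wall <- as.integer(round(n_surf * wall_area / (arch_area + wall_area)))
  n_arch <- n_surf - n_wall

  withr::with_seed(p$seed, {
    th <- runif(n_arch, -A, A)
    y <- runif(n_arch, -p$level_length / 2, p$level_length / 2)
    x <- R * sin(th)
    z <- R * (cos(th) - 1)
    label <- ifelse(x < 0, "left_hemilamina", "right_hemilamina")
    protr <- rep(0, n_arch)

    # spinous-process ridge: arch points under its footprint become the flat
    # top face; the side walls are sampled separately by area
    if (p$sp_height > 0) {
      z_base <- R * (cos(th_hw) - 1)
      foot <- abs(x) <= hw & abs(y) <= p$sp_length / 2
      z[foot] <- z_base + p$sp_height
      protr[foot] <- p$sp_height
      label[foot] <- "sp_tip"
      th[foot] <- NA  # no longer on the arch
      if (n_wall > 0) {
        wx <- sign(runif(n_wall, -1, 1)) * hw
        wy <- runif(n_wall, -p$sp_length / 2, p$sp_length / 2)
        wp <- runif(n_wall, 0, p$sp_height)
        th <- c(th, rep(NA, n_wall))
        x <- c(x, wx); y <- c(y, wy); z <- c(z, z_base + wp)
        protr <- c(protr, wp)
        label <- c(label, rep("", n_wall))
      }
      sp <- is.na(th)
      label[sp] <- ifelse(protr[sp] <= p$sp_base_frac * p$sp_height,
                          "sp_base", "sp_tip")
    }

    # hemispherical facet bumps at the lateral ends of the patch margins
    if (p$facet_count_per_side > 0 && p$facet_height > 0) {
      fr <- p$facet_radius
      y_c <- if (p$facet_count_per_side == 1) 0 else
        seq(-p$level_length / 2, p$level_length / 2,
            length.out = p$facet_count_per_side)
      arch_pt <- label %in% c("left_hemilamina", "right_hemilamina")
      for (sgn in c(-1, 1)) {
        for (yc in y_c) {
          d_surf <- sqrt((R * (th - sgn * A))^2 + (y - yc)^2)
          hit <- arch_pt & !is.na(d_surf) & d_surf < fr
          if (any(hit)) {
            h <- p$facet_height * sqrt(pmax(1 - (d_surf[hit] / fr)^2, 0))
            x[hit] <- x[hit] + h * sin(th[hit])
            z[hit] <- z[hit] + h * cos(th[hit])
            label[hit] <- "facet"
          }
        }
      }
    }

    P <- cbind(x, y, z)
    arch <- shape_cylinder(c(0, 0, -R), c(0, 1, 0), R)
    if (p$arch_axis_tilt != 0) {
      a <- p$arch_axis_tilt * pi / 180
      Rx <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
      P <- P %*% t(Rx)
      arch <- transform_shape(arch, Rx)
    }
    if (p$noise_sd > 0) P <- P + matrix(rnorm(3 * n_surf, 0, p$noise_sd), ncol = 3)

    O <- sample_outliers(n_out, P, function(Q) {
      # distance to the composite surface approximated by the clean sample
      nn_min_dist(Q, P)
    })
    cloud <- tibble::tibble(
      x = c(P[, 1], O[, 1]), y = c(P[, 2], O[, 2]), z = c(P[, 3], O[, 3]),
      label = c(label, rep("outlier", n_out)))
    cloud <- as_point_cloud(cloud)
    attr(cloud, "params") <- p
    attr(cloud, "arch_model") <- arch
    cloud
  })
}

# min distance from each query row to any reference row (blocked)
nn_min_dist <- function(Q, P, block = 512L) {
  out <- numeric(nrow(Q))
  sqP <- rowSums(P^2)
  for (start in seq(1L, nrow(Q), by = block)) {
    rows <- start:min(start + block - 1L, nrow(Q))
    D <- outer(rowSums(Q[rows, , drop = FALSE]^2), sqP, "+") -
      2 * tcrossprod(Q[rows, , drop = FALSE], P)
    out[rows] <- sqrt(pmax(apply(D, 1, min), 0))
  }
  out
}

#' Spinal levels and region presets
#'
#' `spinal_levels()` lists the 25 levels C1 through S1.
#' `region_of_level()` maps a level name to its stratum (C1, C2, subaxial
#' cervical C3-C7, thoracic, lumbar, sacral); unknown names error.
#' `region_presets()` returns the per-region [vertebra_params()] overrides:
#' cervical levels get a wider, flatter-relief arch with a shorter spinous
#' process, thoracolumbar levels a narrower arch with a taller ridge and
#' stronger facet relief.
#'
#' @param level A level name such as `"C1"`, `"T7"`, `"L4"`, `"S1"`.
#' @return Character vector, character scalar, or named list of overrides.
#' @export
spinal_levels <- function() {
  c(paste0("C", 1:7), paste0("T", 1:12), paste0("L", 1:5), "S1")
}

#' @rdname spinal_levels
#' @export
region_of_level <- function(level) {
  vapply(level, function(lv) {
    if (lv == "C1") return("C1")
    if (lv == "C2") return("C2")
    if (lv %in% paste0("C", 3:7)) return("cervical")
    if (lv %in% paste0("T", 1:12)) return("thoracic")
    if (lv %in% paste0("L", 1:5)) return("lumbar")
    if (lv == "S1") return("sacral")
    abort(paste0("unknown spinal level: ", lv))
  }, character(1), USE.NAMES = FALSE)
}

#' @rdname spinal_levels
#' @export
region_presets <- function() {
  list(
    C1 = list(arch_radius = 16, arch_halfangle = 70, sp_height = 4,
              facet_height = 1.5, facet_radius = 3),
    C2 = list(arch_radius = 15, arch_halfangle = 62, sp_height = 10,
              facet_height = 1.8, facet_radius = 3.5),
    cervical = list(arch_radius = 14, arch_halfangle = 60, sp_height = 8,
                    facet_height = 1.8, facet_radius = 3.5),
    thoracic = list(arch_radius = 13, arch_halfangle = 48, sp_height = 12,
                    facet_height = 2.8, facet_radius = 5),
    lumbar = list(arch_radius = 13, arch_halfangle = 45, sp_height = 14,
                  facet_height = 3.2, facet_radius = 6),
    sacral = list(arch_radius = 15, arch_halfangle = 50, sp_height = 6,
                  facet_height = 3.5, facet_radius = 5.5))
}

#' Specify and generate a synthetic study cohort
#'
#' `cohort_spec()` describes a cohort the way the cadaveric and clinical
#' series are structured: `n_specimens` subjects scanned at each level of
#' `levels`, with region presets applied by level name and specimen-to-
#' specimen multiplicative log-normal jitter on the geometric parameters.
#' `generate_cohort()` realises it as a tibble with one labelled cloud per
#' specimen x level.
#'
#' @param n_specimens Number of specimens (>= 1).
#' @param levels Ordered character vector of level names.
#' @param jitter_sd SD of the log-normal multiplicative jitter applied to the
#'   geometric parameters per specimen x level (0 disables).
#' @param relief_scale Multiplier on facet relief height: values above 1
#'   emulate the coarser, more rounded bony relief seen in older cadaveric
#'   specimens versus the smoother in-vivo surfaces.
#' @param base_params A [vertebra_params()] list giving the defaults the
#'   region presets override.
#' @param seed Cohort RNG seed.
#' @param specimen_seeds Optional integer vector (length `n_specimens`) of
#'   per-specimen seeds; defaults derive from `seed`.
#' @return `cohort_spec()`: a `cohort_spec` list. `generate_cohort()`: a
#'   tibble with columns `specimen`, `level`, `region`, `seed`, `params`
#'   (list) and `cloud` (list of labelled point clouds).
#' @export
cohort_spec <- function(n_specimens = 4, levels = spinal_levels(),
                        jitter_sd = 0.05, relief_scale = 1,
                        base_params = vertebra_params(), seed = 1,
                        specimen_seeds = NULL) {
  if (n_specimens < 1) abort("n_specimens must be at least 1")
  if (jitter_sd < 0) abort("jitter_sd must be non-negative")
  region_of_level(levels)  # validates names
  if (is.null(specimen_seeds)) {
    specimen_seeds <- as.integer((seed + 1000L * seq_len(n_specimens)) %%
                                   .Machine$integer.max)
  }
  if (length(specimen_seeds) != n_specimens) {
    abort("specimen_seeds must have one seed per specimen")
  }
  structure(list(n_specimens = n_specimens, levels = levels,
                 jitter_sd = jitter_sd, relief_scale = relief_scale,
                 base_params = base_params, seed = seed,
                 specimen_seeds = specimen_seeds),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @param spec A `cohort_spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  presets <- region_presets()
  jittered <- c("arch_radius", "arch_halfangle", "sp_height", "sp_length",
                "sp_base_halfwidth", "facet_radius", "facet_height")
  rows <- purrr::map(seq_len(spec$n_specimens), function(si) {
    purrr::map(seq_along(spec$levels), function(li) {
      lv <- spec$levels[li]
      region <- region_of_level(lv)
      cell_seed <- as.integer((spec$specimen_seeds[si] + 17L * li) %%
                                .Machine$integer.max)
      p <- unclass(spec$base_params)
      for (nm in names(presets[[region]])) p[[nm]] <- presets[[region]][[nm]]
      p$facet_height <- p$facet_height * spec$relief_scale
      if (spec$jitter_sd > 0) {
        withr::with_seed(cell_seed + 13L, {
          for (nm in jittered) {
            p[[nm]] <- p[[nm]] * exp(rnorm(1, 0, spec$jitter_sd))
          }
        })
      }
      p$seed <- cell_seed
      params <- do.call(vertebra_params, p)
      cloud <- generate_vertebra(params)
      tibble::tibble(specimen = sprintf("specimen%02d", si), level = lv,
                     region = region, seed = cell_seed,
                     params = list(params), cloud = list(cloud))
    })
  })
  dplyr::bind_rows(purrr::flatten(rows))
}
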