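test_that("phantom specs reject impossible geometry", {
  expect_error(phantom_spec(pedicle_width_mm = 40, body_width_mm = 36),
               class = "pedplan_config_error")
  expect_error(phantom_spec(pedicle_transverse_angle_deg = 45),
               class = "pedplan_config_error")
  expect_error(phantom_spec(cortex_thickness_mm = 0.3,
                            voxel_spacing_mm = c(0.625, 0.625, 0.625)),
               class = "pedplan_config_error")
  expect_error(phantom_spec(body_height_mm = -3),
               class = "pedplan_config_error")
})

test_that("generation is deterministic and truth matches the parameters", {
  spec <- phantom_spec(pedicle_width_mm = 8, rng_seed = 11)
  a <- make_phantom(spec)
  b <- make_phantom(spec)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$labels$data, b$labels$data)
  expect_identical(a$truth$sides$L$width_mm, 8)
  expect_identical(a$truth$sides$R$width_mm, 8)
  # same geometry, different noise seed: labels equal, intensities differ
  c <- make_phantom(phantom_spec(pedicle_width_mm = 8, rng_seed = 12))
  expect_identical(a$labels$data, c$labels$data)
  expect_false(identical(a$volume$data, c$volume$data))
})

test_that("the RNG state of the session is not consumed", {
  set.seed(99)
  before <- .Random.seed
  invisible(make_phantom(phantom_spec(rng_seed = 5)))
  expect_identical(.Random.seed, before)
})

test_that("pedicle corridor cross-section matches the analytic elliptic tube", {
  ph <- make_phantom(phantom_spec(pedicle_width_mm = 8,
                                  voxel_spacing_mm = rep(0.5, 3),
                                  rng_seed = 2))
  tr <- ph$truth$sides$L
  pts <- pedplan:::label_points(ph$labels, label_codes()[["PEDICLE_L"]])
  t <- as.vector(sweep(pts, 2, tr$axis_point_mm) %*% tr$axis_dir)
  seg <- 10  # interior tube segment [1, 11] mm along the axis
  n_seg <- sum(t >= 1 & t <= 11)
  analytic <- pi * (tr$width_mm / 2) * (tr$height_mm / 2) * seg
  voxel <- n_seg * prod(ph$labels$spacing_mm)
  expect_lt(abs(voxel - analytic) / analytic, 0.05)
})

test_that("labels agree with the analytic solids at interior points", {
  spec <- phantom_spec(rng_seed = 3)
  ph <- make_phantom(spec)
  geo <- pedplan:::phantom_geometry(spec)
  labs <- function(pts) pedplan:::labels_at(ph$labels, pts)
  codes <- label_codes()
  margin <- max(spec$voxel_spacing_mm)  # stay clear of voxelized boundaries
  set.seed(42)
  n <- 100

  in_tube <- function(pts, side, scale = 1) {
    s <- geo$sides[[side]]
    dx <- pts[, 1] - s$mouth[1]; dy <- pts[, 2] - s$mouth[2]
    t <- dx * s$dir[1] + dy * s$dir[2]
    dw <- dx * s$dir[2] - dy * s$dir[1]
    wr <- scale * (spec$pedicle_width_mm / 2 + spec$cortex_thickness_mm)
    hr <- scale * (spec$pedicle_height_mm / 2 + spec$cortex_thickness_mm)
    t > -3 & t < spec$pedicle_length_mm + 8 &
      (dw / wr)^2 + (pts[, 3] / hr)^2 <= 1
  }

  # trabecular body core, outside both pedicle tubes
  u <- matrix(runif(3 * 5 * n, -1, 1), ncol = 3)
  pts <- cbind(u[, 1] * (geo$a - spec$cortex_thickness_mm - margin) * 0.95,
               u[, 2] * (geo$b - spec$cortex_thickness_mm - margin) * 0.95,
               u[, 3] * (geo$hz - spec$cortex_thickness_mm - margin) * 0.95)
  keep <- (pts[, 1] / (geo$a - spec$cortex_thickness_mm - margin))^2 +
    (pts[, 2] / (geo$b - spec$cortex_thickness_mm - margin))^2 < 0.9 &
    !in_tube(pts, "L", 1.2) & !in_tube(pts, "R", 1.2)
  pts <- head(pts[keep, , drop = FALSE], n)
  expect_gte(nrow(pts), 50)
  expect_true(all(labs(pts) == codes[["TRABECULAR_BODY"]]))

  # superior endplate slab
  pts <- cbind(runif(n, -0.5, 0.5) * geo$a, runif(n, -0.5, 0.5) * geo$b,
               runif(n, geo$hz - spec$cortex_thickness_mm + margin / 2,
                     geo$hz - margin / 2))
  expect_true(all(labs(pts) == codes[["ENDPLATE_SUP"]]))

  # pedicle corridor interior (free segment, clear of the mouth and body)
  for (side in c("L", "R")) {
    s <- geo$sides[[side]]
    t <- runif(n, 1, spec$pedicle_length_mm - 1)
    ang <- runif(n, 0, 2 * pi)
    rad <- sqrt(runif(n)) * 0.7
    w_hat <- c(s$dir[2], -s$dir[1], 0)
    pts <- cbind(
      s$mouth[1] + t * s$dir[1] +
        rad * cos(ang) * (spec$pedicle_width_mm / 2 - margin / 2) * w_hat[1],
      s$mouth[2] + t * s$dir[2] +
        rad * cos(ang) * (spec$pedicle_width_mm / 2 - margin / 2) * w_hat[2],
      rad * sin(ang) * (spec$pedicle_height_mm / 2 - margin / 2))
    expect_true(all(labs(pts) == codes[[paste0("PEDICLE_", side)]]))
  }

  # background far anterior of the body
  pts <- cbind(runif(n, -5, 5), runif(n, geo$b + 2, geo$b + 4),
               runif(n, -5, 5))
  expect_true(all(labs(pts) == codes[["BACKGROUND"]]))
})

test_that("every voxel carries exactly one known label", {
  ph <- cached_phantom()
  expect_true(all(ph$labels$data %in% label_codes()))
  expect_identical(length(ph$labels$data), as.integer(prod(dim(ph$labels))))
})

test_that("entry discs sit on the posterior surface at the axis", {
  ph <- cached_phantom()
  for (side in c("L", "R")) {
    tr <- ph$truth$sides[[side]]
    disc <- pedplan:::label_points(ph$labels,
                                   pedplan:::side_label(side, "entry_disc"))
    expect_gt(nrow(disc), 10)
    # a thin layer: all disc voxels share one y index
    expect_identical(length(unique(disc[, 2])), 1L)
    d <- sqrt((disc[, 1] - tr$entry_center_mm[1])^2 +
                (disc[, 3] - tr$entry_center_mm[3])^2)
    expect_lte(max(d), tr$entry_radius_mm + max(ph$labels$spacing_mm))
  }
})

test_that("cohorts are reproducible and respect their ranges", {
  ranges <- list(pedicle_width_mm = c(7, 12),
                 pedicle_transverse_angle_deg = c(5, 15))
  a <- make_cohort(4, ranges, seed = 21)
  b <- make_cohort(4, ranges, seed = 21)
  expect_identical(attr(a, "specs"), attr(b, "specs"))
  for (i in seq_along(a)) {
    expect_identical(a[[i]]$labels$data, b[[i]]$labels$data)
    w <- a[[i]]$spec$pedicle_width_mm
    expect_gte(w, 7); expect_lte(w, 12)
    ang <- a[[i]]$spec$pedicle_transverse_angle_deg
    expect_gte(ang, 5); expect_lte(ang, 15)
  }
  # degenerate ranges reduce to make_phantom of that spec
  one <- make_cohort(1, list(pedicle_width_mm = c(9, 9)), seed = 4)
  direct <- make_phantom(phantom_spec(pedicle_width_mm = 9,
                                      rng_seed = one[[1]]$spec$rng_seed))
  expect_identical(one[[1]]$volume$data, direct$volume$data)
  expect_identical(one[[1]]$labels$data, direct$labels$data)
  expect_error(make_cohort(0, ranges, seed = 1),
               class = "pedplan_config_error")
  expect_error(make_cohort(2, list(pedicle_width_mm = c(12, 7)), seed = 1),
               class = "pedplan_config_error")
  expect_error(make_cohort(2, list(bogus_field = c(1, 2)), seed = 1),
               class = "pedplan_config_error")
})

test_that("screw perturbation is unbiased noise with exact edge cases", {
  sc <- screw_spec("L", c(1, 2, 3), c(0.2, 0.95, 0.1), 45, 6.5)
  same <- perturb_screw(sc, 0, 0, seed = 7)
  expect_equal(same$entry_mm, sc$entry_mm)
  expect_equal(same$direction, sc$direction)
  expect_identical(same$length_mm, sc$length_mm)
  expect_identical(same$diameter_mm, sc$diameter_mm)
  # renormalization
  for (i in 1:20) {
    p <- perturb_screw(sc, 2, 10, seed = i)
    expect_equal(sqrt(sum(p$direction^2)), 1, tolerance = 1e-9)
    expect_identical(p$length_mm, sc$length_mm)
  }
  # mean 3-D displacement of isotropic Gaussian noise follows the Maxwell
  # mean sigma * sqrt(8/pi) ~ 1.596 at sigma = 1
  disp <- vapply(1:1000, function(i) {
    sqrt(sum((perturb_screw(sc, 1, 0, seed = i)$entry_mm - sc$entry_mm)^2))
  }, numeric(1))
  expect_lt(abs(mean(disp) - sqrt(8 / pi)) / sqrt(8 / pi), 0.05)
})

test_that("measurements are invariant under sub-voxel rigid translation", {
  base <- make_phantom(phantom_spec(rng_seed = 6))
  shifted <- make_phantom(phantom_spec(rng_seed = 6),
                          center_offset_mm = c(0.31, -0.22, 0.17))
  tol <- max(base$labels$spacing_mm)
  W0 <- measure_pedicle_width(base$labels, "L")
  W1 <- measure_pedicle_width(shifted$labels, "L")
  expect_lt(abs(W0 - W1), tol)
  d0 <- depth_to_anterior(base$labels, base$truth$sides$L$entry_center_mm,
                          base$truth$sides$L$axis_dir)
  d1 <- depth_to_anterior(shifted$labels,
                          shifted$truth$sides$L$entry_center_mm,
                          shifted$truth$sides$L$axis_dir)
  expect_lt(abs(d0 - d1), tol)
})
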