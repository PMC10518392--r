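test_that("pedicle axis recovery is accurate across convergence angles", {
  for (ang in c(0, 15)) {
    ph <- make_phantom(phantom_spec(pedicle_transverse_angle_deg = ang,
                                    rng_seed = ang + 1))
    for (side in c("L", "R")) {
      ax <- estimate_pedicle_axis(ph$labels, side)
      truth <- ph$truth$sides[[side]]$axis_dir
      dev_deg <- acos(min(1, abs(sum(ax$direction * truth)))) * 180 / pi
      expect_lt(dev_deg, 2)
      expect_gt(ax$direction[2], 0)  # oriented posterior -> anterior
    }
  }
})

test_that("missing structures raise typed errors", {
  ph <- cached_phantom()
  erased <- ph$labels
  erased$data[erased$data == label_codes()[["PEDICLE_L"]]] <- 0L
  erased <- anatomy_label_map(erased$data, erased$spacing_mm, erased$origin_mm)
  expect_error(estimate_pedicle_axis(erased, "L"),
               class = "pedplan_missing_structure")
  expect_error(measure_pedicle_width(erased, "L"),
               class = "pedplan_missing_structure")
  no_disc <- ph$labels
  no_disc$data[no_disc$data == label_codes()[["ENTRY_DISC_R"]]] <- 0L
  no_disc <- anatomy_label_map(no_disc$data, no_disc$spacing_mm,
                               no_disc$origin_mm)
  expect_error(entry_candidates(no_disc, "R"),
               class = "pedplan_missing_structure")
})

test_that("pedicle width recovers the ground truth and a bare tube", {
  ph <- make_phantom(phantom_spec(pedicle_width_mm = 8,
                                  voxel_spacing_mm = rep(0.5, 3),
                                  rng_seed = 2))
  W <- measure_pedicle_width(ph$labels, "L")
  expect_lt(abs(W - 8), 0.5)
  # bare circular tube of radius r: W ~ 2r within one voxel
  tube <- bare_tube_labels(width_mm = 6, spacing = rep(0.25, 3))
  ax <- axis_line(c(0, 0, 0), c(0, 1, 0))
  Wt <- measure_pedicle_width(tube, "L", axis = ax)
  expect_lt(abs(Wt - 6), 0.25)
})

test_that("widening the corridor never narrows the measured width", {
  widths <- c(7, 9, 11, 13)
  measured <- vapply(widths, function(w) {
    measure_pedicle_width(
      make_phantom(phantom_spec(pedicle_width_mm = w, rng_seed = 5))$labels, "L")
  }, numeric(1))
  expect_true(all(diff(measured) > 0))
})

test_that("entry candidates tile the disc and respect degenerate grids", {
  ph <- cached_phantom()
  tr <- ph$truth$sides$L
  ec <- entry_candidates(ph$labels, "L", 1)
  expect_gte(nrow(ec), 20)
  expect_lte(nrow(ec), 40)
  # all candidates carry the entry-disc label and stay within the disc
  lab <- pedplan:::labels_at(ph$labels, as.matrix(ec[c("x", "y", "z")]))
  expect_true(all(lab == label_codes()[["ENTRY_DISC_L"]]))
  d <- sqrt((ec$x - tr$entry_center_mm[1])^2 + (ec$z - tr$entry_center_mm[3])^2)
  expect_true(all(d <= tr$entry_radius_mm + max(ph$labels$spacing_mm)))
  # grid step larger than the disc: single candidate nearest the center
  one <- entry_candidates(ph$labels, "L", 50)
  expect_identical(nrow(one), 1L)
  d1 <- sqrt((one$x - tr$entry_center_mm[1])^2 +
               (one$z - tr$entry_center_mm[3])^2)
  expect_lt(d1, max(ph$labels$spacing_mm))
})

test_that("depth to the anterior surface matches the analytic truth", {
  ph <- cached_phantom()
  for (side in c("L", "R")) {
    tr <- ph$truth$sides[[side]]
    d <- depth_to_anterior(ph$labels, tr$entry_center_mm, tr$axis_dir)
    expect_lt(abs(d - tr$anterior_depth_mm), max(ph$labels$spacing_mm))
  }
  # posterior-pointing ray misses bone entirely
  tr <- ph$truth$sides$L
  expect_error(depth_to_anterior(ph$labels, tr$entry_center_mm, -tr$axis_dir),
               class = "pedplan_no_intersection")
  # moving the entry anteriorly along the ray shortens the depth accordingly
  d0 <- depth_to_anterior(ph$labels, tr$entry_center_mm, tr$axis_dir)
  for (adv in c(2, 5, 10)) {
    da <- depth_to_anterior(ph$labels, tr$entry_center_mm + adv * tr$axis_dir,
                            tr$axis_dir)
    expect_lte(da, d0)
    expect_lt(abs((d0 - da) - adv), min(ph$labels$spacing_mm))
  }
})

test_that("wall clearances follow the analytic annulus", {
  ph <- cached_phantom()  # corridor W = 8 with a 1.25 mm cortical wall
  cx <- ph$spec$cortex_thickness_mm
  sc <- axis_screw(ph, "L", 40, 6)
  cl <- wall_clearance(ph$labels, sc)
  # centered screw: medial clearance = (W - d)/2 plus the wall thickness
  expect_equal(cl$medial_clearance_mm, (8 - 6) / 2 + cx, tolerance = 0.35)
  # 1 mm medial translation eats ~1 mm of medial clearance, inferior ~same
  tr <- ph$truth$sides$L
  medial <- c(1, 0, 0)  # left pedicle: medial = +x
  sc2 <- screw_spec("L", tr$entry_center_mm + medial, tr$axis_dir, 40, 6)
  cl2 <- wall_clearance(ph$labels, sc2)
  expect_equal(cl$medial_clearance_mm - cl2$medial_clearance_mm, 1,
               tolerance = 0.3)
  expect_equal(cl2$inferior_clearance_mm, cl$inferior_clearance_mm,
               tolerance = 0.4)
  # bare tube with diameter = width: clearance ~ 0
  tube <- bare_tube_labels(width_mm = 6, spacing = rep(0.25, 3))
  sc3 <- screw_spec("L", c(0, 1, 0), c(0, 1, 0), 25, 6)
  cl3 <- wall_clearance(tube, sc3)
  expect_lt(abs(cl3$medial_clearance_mm), 0.3)
  # a screw that misses the pedicle entirely
  far <- screw_spec("L", tr$entry_center_mm + c(0, 0, 25), tr$axis_dir, 30, 5)
  expect_error(wall_clearance(ph$labels, far),
               class = "pedplan_not_in_pedicle")
})

test_that("wall clearance agrees with a dense surface-sampling oracle", {
  ph <- cached_phantom()
  tr <- ph$truth$sides$L
  ax <- axis_line(tr$axis_point_mm, tr$axis_dir)
  sc <- axis_screw(ph, "L", 40, 6)
  checked <- 0
  for (i in 1:12) {
    s2 <- perturb_screw(sc, 0.8, 2, seed = i)
    impl <- tryCatch(wall_clearance(ph$labels, s2),
                     pedplan_error = function(e) NULL)
    if (is.null(impl)) next
    ora <- oracle_wall_clearance(ph$labels, s2, ax)
    # the oracle floors at 0; compare where the screw is clear of the wall
    if (impl$medial_clearance_mm > 0.3) {
      expect_lt(abs(impl$medial_clearance_mm - ora$medial_clearance_mm), 0.2)
      checked <- checked + 1
    }
    if (impl$inferior_clearance_mm > 0.3) {
      expect_lt(abs(impl$inferior_clearance_mm - ora$inferior_clearance_mm), 0.2)
      checked <- checked + 1
    }
  }
  expect_gte(checked, 10)
})
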