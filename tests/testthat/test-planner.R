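test_that("catalog validation and flooring follow the discrete inventory", {
  expect_error(screw_catalog(allowed_lengths_mm = c(30, 30, 40)),
               class = "pedplan_config_error")
  expect_error(screw_catalog(allowed_diameters_mm = numeric(0)),
               class = "pedplan_config_error")
  cat <- screw_catalog()
  # longest length not exceeding the measured depth
  expect_identical(pedplan:::catalog_floor(52, cat$allowed_lengths_mm), 50)
  expect_identical(pedplan:::catalog_floor(30, cat$allowed_lengths_mm), 30)
  expect_true(is.na(pedplan:::catalog_floor(29, cat$allowed_lengths_mm)))
  # 90% width rule against the diameter inventory
  expect_identical(pedplan:::catalog_floor(0.9 * 25 / 3, cat$allowed_diameters_mm), 7.5)
  expect_identical(pedplan:::catalog_floor(0.9 * 6.0, cat$allowed_diameters_mm), 5.0)
  expect_true(is.na(pedplan:::catalog_floor(0.9 * 5.0, cat$allowed_diameters_mm)))
})

test_that("trajectory enumeration is the entries x angles product", {
  ph <- cached_phantom()
  entries <- entry_candidates(ph$labels, "L", 1)[1:5, ]
  cfg <- plan_config(transverse_range_deg = 3, transverse_step_deg = 3,
                     sagittal_range_deg = 3, sagittal_step_deg = 3)
  tr <- enumerate_trajectories(entries, ph$labels, "L", cfg)
  expect_identical(nrow(tr), 5L * 3L * 3L)
  expect_true(all(tr$dy > 0))
  # zero-width grid reproduces the pedicle axis direction
  cfg0 <- plan_config(transverse_range_deg = 0, transverse_step_deg = 1,
                      sagittal_range_deg = 0, sagittal_step_deg = 1)
  tr0 <- enumerate_trajectories(entries, ph$labels, "L", cfg0)
  ax <- estimate_pedicle_axis(ph$labels, "L")
  expect_identical(nrow(tr0), 5L)
  for (i in seq_len(nrow(tr0))) {
    expect_equal(c(tr0$dx[i], tr0$dy[i], tr0$dz[i]), unname(ax$direction),
                 tolerance = 1e-9)
  }
})

test_that("screw sizing applies the depth, 90%-width and margin rules", {
  ph <- cached_phantom()
  tr <- ph$truth$sides$L
  W <- measure_pedicle_width(ph$labels, "L")
  sz <- size_screw(tr$entry_center_mm, tr$axis_dir, ph$labels, "L", W)
  expect_true(sz$feasible)
  depth <- depth_to_anterior(ph$labels, tr$entry_center_mm, tr$axis_dir)
  expect_identical(sz$length_mm,
                   pedplan:::catalog_floor(depth, screw_catalog()$allowed_lengths_mm))
  expect_lte(sz$diameter_mm, 0.9 * W + 1e-9)
  expect_gte(sz$clearances$medial_clearance_mm, 1)
  expect_gte(sz$clearances$inferior_clearance_mm, 1)
  # a corridor too narrow for the smallest catalog diameter
  narrow <- make_phantom(phantom_spec(pedicle_width_mm = 5, rng_seed = 9))
  ntr <- narrow$truth$sides$L
  nW <- measure_pedicle_width(narrow$labels, "L")
  nsz <- size_screw(ntr$entry_center_mm, ntr$axis_dir, narrow$labels, "L", nW)
  expect_false(nsz$feasible)
  expect_identical(nsz$reason, "pedicle_too_narrow")
  # a ray that never meets bone propagates as infeasible
  away <- size_screw(ntr$entry_center_mm, -ntr$axis_dir, narrow$labels, "L", nW)
  expect_false(away$feasible)
})

test_that("constraint reports flag endplate contact and anterior overrun", {
  ph <- cached_phantom()
  tr <- ph$truth$sides$L
  good <- screw_spec("L", tr$entry_center_mm, tr$axis_dir, 40, 6)
  rep0 <- check_constraints(good, ph$labels)
  expect_true(rep0$feasible)
  expect_false(rep0$endplate_violation)
  expect_identical(rep0$anterior_overrun_mm, 0)
  # translate superiorly into the endplate slab
  up <- screw_spec("L", tr$entry_center_mm + c(0, 0, 10), tr$axis_dir, 40, 6)
  rep1 <- check_constraints(up, ph$labels)
  expect_true(rep1$endplate_violation)
  expect_false(rep1$feasible)
  # length exceeding the anterior surface by ~5 mm
  depth <- depth_to_anterior(ph$labels, tr$entry_center_mm, tr$axis_dir)
  long <- screw_spec("L", tr$entry_center_mm, tr$axis_dir, depth + 5, 6)
  rep2 <- check_constraints(long, ph$labels)
  expect_equal(rep2$anterior_overrun_mm, 5, tolerance = 0.5)
  expect_false(rep2$feasible)
})

test_that("trajectory scoring is exact on constant fields and scales as pi*D*L", {
  dims <- c(60, 60, 60)
  vol <- image_volume(array(250, dims), rep(0.5, 3), c(-15, -15, -15))
  sc <- screw_spec("L", c(0, -14, 0), c(0, 1, 0), 20, 6)
  s1 <- score_trajectory(sc, vol)
  expect_identical(s1$bmd_mean_hu, 250)
  expect_equal(s1$pof_proxy, 250 * pi * 6 * 20)
  sc2 <- screw_spec("L", c(0, -14, 0), c(0, 1, 0), 10, 6)
  s2 <- score_trajectory(sc2, vol)
  expect_equal(s1$pof_proxy / s2$pof_proxy, 2, tolerance = 1e-9)
  # voxel count inside the cylinder approximates the analytic volume
  cyl <- pedplan:::cylinder_voxels(vol, sc)
  analytic <- pi * 3^2 * 20
  expect_lt(abs(length(cyl$lin) * 0.5^3 - analytic) / analytic, 0.05)
  # degenerate cylinder outside the grid
  out <- screw_spec("L", c(500, 500, 500), c(0, 1, 0), 10, 5)
  expect_error(score_trajectory(out, vol), class = "pedplan_degenerate_screw")
})

test_that("planning maximizes the pullout proxy over feasible candidates", {
  ph <- cached_phantom()
  cfg <- coarse_config()
  plan <- plan_side(ph$volume, ph$labels, "L", config = cfg)
  expect_s3_class(plan, "screw_plan")
  expect_true(plan$constraints$feasible)
  n_entries <- nrow(entry_candidates(ph$labels, "L", cfg$entry_step_mm))
  expect_identical(plan$n_candidates_evaluated, n_entries * 7L * 5L)
  # widening the search can only improve the objective: dropping the
  # sagittal sweep explores a strict subset of the same candidates
  tr <- ph$truth$sides$L
  sub_cfg <- plan_config(transverse_range_deg = 9, transverse_step_deg = 3,
                         sagittal_range_deg = 1e-9, sagittal_step_deg = 3,
                         entry_step_mm = 2)
  plan_sub <- plan_side(ph$volume, ph$labels, "L", config = sub_cfg)
  expect_identical(plan_sub$n_candidates_evaluated, n_entries * 7L)
  expect_gte(plan$score$pof_proxy, plan_sub$score$pof_proxy - 1e-6)
  # 90% rule against the ground-truth width, allowing one catalog step
  expect_lte(plan$screw$diameter_mm, 0.9 * tr$width_mm + 0.5)
  # determinism
  plan2 <- plan_side(ph$volume, ph$labels, "L", config = cfg)
  expect_identical(tidy(plan), tidy(plan2))
})

test_that("a 5 mm corridor is reported as planning-infeasible", {
  narrow <- make_phantom(phantom_spec(pedicle_width_mm = 5, rng_seed = 9))
  expect_error(plan_side(narrow$volume, narrow$labels, "L",
                         config = coarse_config()),
               class = "pedplan_planning_infeasible")
})

test_that("vertebra planning mirrors symmetric sides and isolates failures", {
  ph <- cached_phantom()
  plans <- plan_vertebra(ph$volume, ph$labels, config = coarse_config())
  expect_s3_class(plans$L, "screw_plan")
  expect_s3_class(plans$R, "screw_plan")
  # mirror symmetry within one catalog step / one voxel
  expect_lte(abs(plans$L$screw$length_mm - plans$R$screw$length_mm), 5)
  expect_lte(abs(plans$L$screw$diameter_mm - plans$R$screw$diameter_mm), 0.5)
  expect_lt(abs(plans$L$screw$entry_mm[1] + plans$R$screw$entry_mm[1]),
            2 * max(ph$labels$spacing_mm) + 2)
  # planner screws grade A on their own label map
  for (s in c("L", "R")) {
    expect_identical(grade_screw(plans[[s]]$screw, ph$labels)$grade, "A")
  }
  # erasing one pedicle leaves the other side plannable
  half <- ph$labels
  half$data[half$data == label_codes()[["PEDICLE_R"]]] <- 0L
  half <- anatomy_label_map(half$data, half$spacing_mm, half$origin_mm)
  plans2 <- plan_vertebra(ph$volume, half, config = coarse_config())
  expect_s3_class(plans2$L, "screw_plan")
  expect_s3_class(plans2$R, "pedplan_missing_structure")
})

test_that("a richer catalog or a softer margin never hurts the objective", {
  ph <- cached_phantom()
  cfg <- coarse_config()
  plan_fine <- plan_side(ph$volume, ph$labels, "L", screw_catalog(), cfg)
  sparse <- screw_catalog(allowed_lengths_mm = seq(30, 60, 10),
                          allowed_diameters_mm = c(5, 6, 7))
  plan_sparse <- plan_side(ph$volume, ph$labels, "L", sparse, cfg)
  expect_gte(plan_fine$score$pof_proxy, plan_sparse$score$pof_proxy)
  tight <- coarse_config(margin_mm = 1.5)
  plan_tight <- plan_side(ph$volume, ph$labels, "L", screw_catalog(), tight)
  expect_gte(plan_fine$score$pof_proxy, plan_tight$score$pof_proxy)
})
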