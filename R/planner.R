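# Trajectory planner. Enumerates candidate trajectories from the posterior
# entry region, sizes each screw maximally from the catalog under the
# placement rules (longest length up to the anterior cortex, diameter capped
# at 90% of the pedicle width and by the >= 1 mm wall margins), rejects
# candidates violating the endplate/anterior/containment constraints, and
# returns the candidate maximizing a pullout-force proxy.

#' Screw catalog
#'
#' Discrete implant inventory the planner may choose from. Defaults span
#' lengths 30-65 mm in 5 mm steps and diameters 5-7.5 mm in 0.5 mm steps, the
#' dimensional ranges of a standard thoracolumbar pedicle screw set.
#'
#' @param allowed_lengths_mm,allowed_diameters_mm Strictly increasing positive
#'   numeric vectors, mm.
#' @return Object of class `screw_catalog`.
#' @export
screw_catalog <- function(allowed_lengths_mm = seq(30, 65, by = 5),
                          allowed_diameters_mm = seq(5, 7.5, by = 0.5)) {
  for (nm in c("allowed_lengths_mm", "allowed_diameters_mm")) {
    v <- get(nm)
    if (length(v) == 0L || any(!is.finite(v)) || any(v <= 0) ||
        is.unsorted(v, strictly = TRUE)) {
      stop_pedplan("config_error",
                   sprintf("`%s` must be strictly increasing and positive", nm))
    }
  }
  structure(list(allowed_lengths_mm = as.numeric(allowed_lengths_mm),
                 allowed_diameters_mm = as.numeric(allowed_diameters_mm)),
            class = "screw_catalog")
}

# largest catalog value <= x (NA if none)
catalog_floor <- function(x, choices) {
  ok <- choices <= x + 1e-9
  if (!any(ok)) NA_real_ else max(choices[ok])
}

#' Screw specification
#'
#' @param side `"L"` or `"R"`.
#' @param entry_mm Entry point, 3-vector, mm (world).
#' @param direction Direction of insertion; normalized internally.
#' @param length_mm,diameter_mm Screw dimensions, mm.
#' @return Object of class `screw_spec`.
#' @export
screw_spec <- function(side, entry_mm, direction, length_mm, diameter_mm) {
  side <- match.arg(toupper(side), c("L", "R"))
  check_number(length_mm, "length_mm", min = 0, strict_min = TRUE)
  check_number(diameter_mm, "diameter_mm", min = 0, strict_min = TRUE)
  structure(list(side = side, entry_mm = as.numeric(entry_mm),
                 direction = normalize3(as.numeric(direction)),
                 length_mm = length_mm, diameter_mm = diameter_mm),
            class = "screw_spec")
}

#' @export
print.screw_spec <- function(x, ...) {
  cat(sprintf(
    "<screw_spec> %s  %.0f x %.1f mm, entry (%s) mm, direction (%s)\n",
    x$side, x$length_mm, x$diameter_mm,
    paste(sprintf("%.2f", x$entry_mm), collapse = ", "),
    paste(sprintf("%.3f", x$direction), collapse = ", ")))
  invisible(x)
}

screw_tip <- function(screw) screw$entry_mm + screw$length_mm * screw$direction

#' Planner configuration
#'
#' @param transverse_range_deg,transverse_step_deg Transverse (mediolateral)
#'   angular search range about the pedicle axis and its step, degrees.
#' @param sagittal_range_deg,sagittal_step_deg Sagittal (craniocaudal) range
#'   and step, degrees.
#' @param entry_step_mm Entry-candidate grid pitch on the entry disc, mm.
#' @param margin_mm Required medial/inferior wall safety margin, mm.
#' @param bmd_floor_hu Lower clamp applied to the mean intensity before it
#'   enters the pullout-force proxy (keeps the proxy positive and monotone).
#' @return Object of class `plan_config`.
#' @export
plan_config <- function(transverse_range_deg = 15, transverse_step_deg = 3,
                        sagittal_range_deg = 9, sagittal_step_deg = 3,
                        entry_step_mm = 1, margin_mm = 1, bmd_floor_hu = 1) {
  check_number(transverse_range_deg, "transverse_range_deg", min = 0, max = 44)
  check_number(sagittal_range_deg, "sagittal_range_deg", min = 0, max = 44)
  check_number(transverse_step_deg, "transverse_step_deg", min = 0, strict_min = TRUE)
  check_number(sagittal_step_deg, "sagittal_step_deg", min = 0, strict_min = TRUE)
  check_number(entry_step_mm, "entry_step_mm", min = 0, strict_min = TRUE)
  check_number(margin_mm, "margin_mm", min = 0)
  check_number(bmd_floor_hu, "bmd_floor_hu", min = 0, strict_min = TRUE)
  structure(list(transverse_range_deg = as.numeric(transverse_range_deg),
                 transverse_step_deg = as.numeric(transverse_step_deg),
                 sagittal_range_deg = as.numeric(sagittal_range_deg),
                 sagittal_step_deg = as.numeric(sagittal_step_deg),
                 entry_step_mm = as.numeric(entry_step_mm),
                 margin_mm = as.numeric(margin_mm),
                 bmd_floor_hu = as.numeric(bmd_floor_hu)),
            class = "plan_config")
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

rot_axis <- function(k, deg) {
  a <- deg * pi / 180
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' Enumerate candidate trajectories
#'
#' Cartesian product of entry candidates and an angular grid about the
#' pedicle axis: transverse angles rotate about the vertical (z) axis,
#' sagittal angles about the horizontal in-plane axis. All directions point
#' anteriorly.
#'
#' @param entries Tibble/data frame of entry points (`x`, `y`, `z`, mm), as
#'   returned by [entry_candidates()].
#' @param labels An [anatomy_label_map()].
#' @param side `"L"` or `"R"`.
#' @param config A [plan_config()].
#' @param axis Optional precomputed pedicle [axis_line()].
#' @return Tibble with entry coordinates, direction components and the grid
#'   angles (`transverse_deg`, `sagittal_deg`).
#' @export
enumerate_trajectories <- function(entries, labels, side,
                                   config = plan_config(), axis = NULL) {
  if (is.null(dim(entries)) || nrow(entries) == 0L) {
    stop_pedplan("config_error", "`entries` must be a non-empty data frame")
  }
  if (is.null(axis)) axis <- estimate_pedicle_axis(labels, side)
  u0 <- axis$direction
  alphas <- seq(-config$transverse_range_deg, config$transverse_range_deg,
                by = config$transverse_step_deg)
  betas <- seq(-config$sagittal_range_deg, config$sagittal_range_deg,
               by = config$sagittal_step_deg)
  if (length(alphas) == 0L || length(betas) == 0L) {
    stop_pedplan("config_error", "empty angular grid")
  }
  w_hat <- normalize3(cross3(c(0, 0, 1), u0))  # horizontal, perpendicular
  dirs <- expand.grid(transverse_deg = alphas, sagittal_deg = betas,
                      KEEP.OUT.ATTRS = FALSE)
  dmat <- t(vapply(seq_len(nrow(dirs)), function(i) {
    as.vector(rot_z(dirs$transverse_deg[i]) %*%
                (rot_axis(w_hat, dirs$sagittal_deg[i]) %*% u0))
  }, numeric(3)))
  grid <- tidyr::crossing(
    entry_id = seq_len(nrow(entries)), dir_id = seq_len(nrow(dirs)))
  tibble::tibble(
    side = side,
    x = entries$x[grid$entry_id], y = entries$y[grid$entry_id],
    z = entries$z[grid$entry_id],
    dx = dmat[grid$dir_id, 1], dy = dmat[grid$dir_id, 2],
    dz = dmat[grid$dir_id, 3],
    transverse_deg = dirs$transverse_deg[grid$dir_id],
    sagittal_deg = dirs$sagittal_deg[grid$dir_id])
}

#' Size a screw maximally for a trajectory
#'
#' Length: the largest catalog length not exceeding the distance from the
#' entry point to the anterior vertebral surface. Diameter: the largest
#' catalog diameter that is at most 90% of the pedicle width `W` and keeps
#' both the medial and inferior wall clearances at or above `margin_mm`.
#'
#' @param entry,direction Trajectory (mm; unit vector).
#' @param labels An [anatomy_label_map()].
#' @param side `"L"` or `"R"`.
#' @param W Pedicle width, mm (from [measure_pedicle_width()]).
#' @param catalog A [screw_catalog()].
#' @param margin_mm Wall safety margin, mm.
#' @param ctx Optional precomputed side context (internal planning cache).
#' @return List with `feasible` plus, when feasible, `length_mm` and
#'   `diameter_mm`; otherwise a `reason` string.
#' @export
size_screw <- function(entry, direction, labels, side, W,
                       catalog = screw_catalog(), margin_mm = 1, ctx = NULL) {
  depth <- tryCatch(depth_to_anterior(labels, entry, direction),
                    pedplan_no_intersection = function(e) NA_real_)
  if (is.na(depth)) return(list(feasible = FALSE, reason = "no_bone_on_ray"))
  len <- catalog_floor(depth, catalog$allowed_lengths_mm)
  if (is.na(len)) return(list(feasible = FALSE, reason = "too_shallow"))
  dmax <- 0.9 * W
  cand <- catalog$allowed_diameters_mm[catalog$allowed_diameters_mm <= dmax + 1e-9]
  if (length(cand) == 0L) return(list(feasible = FALSE, reason = "pedicle_too_narrow"))
  geom <- wall_exit_geometry(labels, entry, direction, len, side, ctx = ctx)
  if (is.null(geom)) return(list(feasible = FALSE, reason = "misses_pedicle"))
  for (d in rev(cand)) {
    cl <- clearances_from_geometry(geom, d)
    if (cl$medial_clearance_mm >= margin_mm &&
        cl$inferior_clearance_mm >= margin_mm) {
      return(list(feasible = TRUE, length_mm = len, diameter_mm = d,
                  depth_mm = depth, clearances = cl, wall_geometry = geom))
    }
  }
  list(feasible = FALSE, reason = "wall_margin")
}

# voxel centers inside the (optionally dilated/trimmed) screw cylinder;
# returns linear indices plus axial/radial coordinates
cylinder_voxels <- function(grid, screw, radial_pad_mm = 0, axial_pad_mm = 0,
                            t_min_mm = 0) {
  r <- screw$diameter_mm / 2 + radial_pad_mm
  tip <- screw_tip(screw)
  lo <- pmin(screw$entry_mm, tip) - r - axial_pad_mm
  hi <- pmax(screw$entry_mm, tip) + r + axial_pad_mm
  d <- dim(grid$data)
  i0 <- pmax(1, floor((lo - grid$origin_mm) / grid$spacing_mm) + 1)
  i1 <- pmin(d, ceiling((hi - grid$origin_mm) / grid$spacing_mm) + 1)
  if (any(i0 > i1)) {
    return(list(lin = integer(0), t = numeric(0), r2 = numeric(0)))
  }
  ii <- seq.int(i0[1], i1[1]); jj <- seq.int(i0[2], i1[2]); kk <- seq.int(i0[3], i1[3])
  nxs <- length(ii); nys <- length(jj); nzs <- length(kk)
  xs <- grid$origin_mm[1] + (ii - 1) * grid$spacing_mm[1] - screw$entry_mm[1]
  ys <- grid$origin_mm[2] + (jj - 1) * grid$spacing_mm[2] - screw$entry_mm[2]
  zs <- grid$origin_mm[3] + (kk - 1) * grid$spacing_mm[3] - screw$entry_mm[3]
  VX <- rep(xs, times = nys * nzs)
  VY <- rep(rep(ys, each = nxs), times = nzs)
  VZ <- rep(zs, each = nxs * nys)
  u <- screw$direction
  t <- VX * u[1] + VY * u[2] + VZ * u[3]
  r2 <- VX^2 + VY^2 + VZ^2 - t^2
  inside <- t >= t_min_mm & t <= screw$length_mm + axial_pad_mm & r2 <= r^2
  if (!any(inside)) {
    return(list(lin = integer(0), t = numeric(0), r2 = numeric(0)))
  }
  I <- rep(ii, times = nys * nzs)[inside]
  J <- rep(rep(jj, each = nxs), times = nzs)[inside]
  K <- rep(kk, each = nxs * nys)[inside]
  lin <- (K - 1) * (d[1] * d[2]) + (J - 1) * d[1] + I
  list(lin = lin, t = t[inside], r2 = r2[inside])
}

#' Check placement constraints for a screw
#'
#' Evaluates the explicit placement rules: medial and inferior wall
#' clearances at least `margin_mm`, no contact with the superior/inferior
#' endplates, and no overrun of the anterior vertebral surface. Reports
#' rather than throws for any in-grid screw.
#'
#' @param screw A [screw_spec()].
#' @param labels An [anatomy_label_map()].
#' @param margin_mm Wall safety margin, mm.
#' @param axis Optional precomputed pedicle [axis_line()].
#' @return Object of class `constraint_report`: `medial_clearance_mm`,
#'   `inferior_clearance_mm`, `endplate_violation`, `anterior_overrun_mm`,
#'   `feasible`.
#' @export
check_constraints <- function(screw, labels, margin_mm = 1, axis = NULL) {
  stopifnot(inherits(screw, "screw_spec"))
  cl <- tryCatch(wall_clearance(labels, screw, axis = axis),
                 pedplan_error = function(e) {
                   list(medial_clearance_mm = -Inf, inferior_clearance_mm = -Inf)
                 })
  cyl <- cylinder_voxels(labels, screw)
  ep_codes <- label_codes()[c("ENDPLATE_SUP", "ENDPLATE_INF")]
  endplate <- length(cyl$lin) > 0 && any(labels$data[cyl$lin] %in% ep_codes)
  overrun <- tryCatch({
    depth <- depth_to_anterior(labels, screw$entry_mm, screw$direction)
    max(0, screw$length_mm - depth)
  }, pedplan_no_intersection = function(e) screw$length_mm,
  pedplan_grid_truncation = function(e) 0)
  feasible <- is.finite(cl$medial_clearance_mm) &&
    cl$medial_clearance_mm >= margin_mm &&
    cl$inferior_clearance_mm >= margin_mm &&
    !endplate && overrun == 0
  structure(list(medial_clearance_mm = cl$medial_clearance_mm,
                 inferior_clearance_mm = cl$inferior_clearance_mm,
                 endplate_violation = endplate,
                 anterior_overrun_mm = overrun,
                 feasible = feasible),
            class = "constraint_report")
}

#' @export
print.constraint_report <- function(x, ...) {
  cat(sprintf(
    "<constraint_report> medial %.2f mm, inferior %.2f mm, endplate %s, overrun %.2f mm -> %s\n",
    x$medial_clearance_mm, x$inferior_clearance_mm,
    if (x$endplate_violation) "HIT" else "clear", x$anterior_overrun_mm,
    if (x$feasible) "feasible" else "infeasible"))
  invisible(x)
}

#' Score a trajectory by bone density and a pullout-force proxy
#'
#' `bmd_mean_hu` is the mean intensity over voxel centers inside the screw
#' cylinder -- a CT surrogate of the bone mineral density along the
#' trajectory. The pullout-force proxy multiplies the (clamped) density by
#' the thread-bearing lateral surface pi * D * L, so it is strictly
#' increasing in density, diameter and length.
#'
#' @param screw A [screw_spec()].
#' @param volume An [image_volume()].
#' @param bmd_floor_hu Lower clamp for the density entering the proxy.
#' @return Object of class `trajectory_score`: `bmd_mean_hu`, `pof_proxy`.
#' @export
score_trajectory <- function(screw, volume, bmd_floor_hu = 1) {
  cyl <- cylinder_voxels(volume, screw)
  if (length(cyl$lin) == 0L) {
    stop_pedplan("degenerate_screw", "screw cylinder contains no voxel centers")
  }
  bmd <- mean(volume$data[cyl$lin])
  structure(list(
    bmd_mean_hu = bmd,
    pof_proxy = max(bmd, bmd_floor_hu) * pi * screw$diameter_mm * screw$length_mm),
    class = "trajectory_score")
}

# Containment filter: beyond the entry funnel, every voxel center inside the
# cylinder dilated by half the maximum spacing must carry a bone label. This
# is what makes a feasible plan breach-free on its own label map.
screw_contained <- function(labels, screw, entry_skip_mm) {
  # half the voxel diagonal: any point of the screw surface then lies in a
  # voxel whose center is inside the dilated cylinder, so voxel-level
  # containment implies zero sampled breach
  pad <- max(labels$spacing_mm) * sqrt(3) / 2
  cyl <- cylinder_voxels(labels, screw, radial_pad_mm = pad,
                         axial_pad_mm = pad, t_min_mm = entry_skip_mm)
  length(cyl$lin) > 0 && all(labels$data[cyl$lin] %in% bone_labels())
}

# distance along the screw axis to the first bone-labeled sample
first_bone_contact <- function(labels, entry, direction, length_mm) {
  step <- min(labels$spacing_mm) / 2
  tt <- seq(0, length_mm, by = step)
  pts <- cbind(entry[1] + tt * direction[1], entry[2] + tt * direction[2],
               entry[3] + tt * direction[3])
  bone <- labels_at(labels, pts) %in% bone_labels()
  if (!any(bone)) return(NA_real_)
  tt[which(bone)[1]]
}

#' Plan the optimal screw for one pedicle
#'
#' Exhaustively evaluates the entry x angle candidate grid: each candidate is
#' sized maximally ([size_screw()]), checked against the placement
#' constraints ([check_constraints()]) and a bone-containment filter, scored
#' ([score_trajectory()]), and the feasible candidate with the highest
#' pullout-force proxy wins. Ties break on higher density, then smaller
#' angular deviation from the pedicle axis, then entry-point order. Fully
#' deterministic.
#'
#' @param volume An [image_volume()].
#' @param labels The co-registered [anatomy_label_map()].
#' @param side `"L"` or `"R"`.
#' @param catalog A [screw_catalog()].
#' @param config A [plan_config()].
#' @return Object of class `screw_plan`: `screw`, `score`, `constraints`,
#'   `n_candidates_evaluated`, `side`, `width_mm`, `axis`.
#' @export
plan_side <- function(volume, labels, side, catalog = screw_catalog(),
                      config = plan_config()) {
  if (!same_grid(volume, labels)) {
    stop_pedplan("config_error", "volume and labels are not co-registered")
  }
  axis <- estimate_pedicle_axis(labels, side)
  ctx <- side_context(labels, side, axis = axis)
  W <- measure_pedicle_width(labels, side, axis = axis)
  entries <- entry_candidates(labels, side, config$entry_step_mm)
  entries <- entries[order(entries$x, entries$y, entries$z), ]
  cands <- enumerate_trajectories(entries, labels, side, config, axis = axis)
  best <- NULL
  best_key <- NULL
  best_infeasible <- NULL
  for (i in seq_len(nrow(cands))) {
    entry <- c(cands$x[i], cands$y[i], cands$z[i])
    dir <- c(cands$dx[i], cands$dy[i], cands$dz[i])
    sz <- size_screw(entry, dir, labels, side, W, catalog,
                     margin_mm = config$margin_mm, ctx = ctx)
    if (!sz$feasible) next
    screw <- screw_spec(side, entry, dir, sz$length_mm, sz$diameter_mm)
    rep_i <- constraint_report_from_parts(sz, config$margin_mm)
    cyl <- cylinder_voxels(labels, screw)
    ep_codes <- label_codes()[c("ENDPLATE_SUP", "ENDPLATE_INF")]
    rep_i$endplate_violation <-
      length(cyl$lin) > 0 && any(labels$data[cyl$lin] %in% ep_codes)
    rep_i$feasible <- rep_i$feasible && !rep_i$endplate_violation
    if (!rep_i$feasible) {
      best_infeasible <- best_infeasible %||% list(screw = screw, report = rep_i)
      next
    }
    t0 <- first_bone_contact(labels, entry, dir, screw$length_mm)
    if (is.na(t0) ||
        !screw_contained(labels, screw, t0 + screw$diameter_mm)) {
      best_infeasible <- best_infeasible %||% list(screw = screw, report = rep_i)
      next
    }
    sc <- score_trajectory(screw, volume, config$bmd_floor_hu)
    ang_dev <- acos(pmin(1, sum(dir * axis$direction)))
    key <- c(sc$pof_proxy, sc$bmd_mean_hu, -ang_dev)
    if (is.null(best) || key_improves(key, best_key)) {
      best <- list(screw = screw, score = sc, constraints = rep_i)
      best_key <- key
    }
  }
  if (is.null(best)) {
    stop_pedplan("planning_infeasible",
                 sprintf("no feasible screw for side %s (W = %.2f mm)", side, W),
                 best_infeasible = best_infeasible, width_mm = W)
  }
  structure(list(screw = best$screw, score = best$score,
                 constraints = best$constraints,
                 n_candidates_evaluated = nrow(cands),
                 side = side, width_mm = W, axis = axis),
            class = "screw_plan")
}

constraint_report_from_parts <- function(sz, margin_mm) {
  structure(list(
    medial_clearance_mm = sz$clearances$medial_clearance_mm,
    inferior_clearance_mm = sz$clearances$inferior_clearance_mm,
    endplate_violation = FALSE,
    anterior_overrun_mm = max(0, sz$length_mm - sz$depth_mm),
    feasible = sz$clearances$medial_clearance_mm >= margin_mm &&
      sz$clearances$inferior_clearance_mm >= margin_mm &&
      sz$length_mm <= sz$depth_mm),
    class = "constraint_report")
}

# strict lexicographic improvement with a numeric guard band
key_improves <- function(key, ref, tol = 1e-9) {
  for (i in seq_along(key)) {
    if (key[i] > ref[i] + tol) return(TRUE)
    if (key[i] < ref[i] - tol) return(FALSE)
  }
  FALSE  # exact tie: keep the earlier (lexicographically first) candidate
}

#' @export
print.screw_plan <- function(x, ...) {
  cat(sprintf(
    "<screw_plan> side %s: %.0f x %.1f mm screw (W = %.2f mm, %d candidates)\n",
    x$side, x$screw$length_mm, x$screw$diameter_mm, x$width_mm,
    x$n_candidates_evaluated))
  cat(sprintf("  bmd %.1f HU, pof proxy %.0f;", x$score$bmd_mean_hu,
              x$score$pof_proxy))
  cat(sprintf(" clearances medial %.2f / inferior %.2f mm\n",
              x$constraints$medial_clearance_mm,
              x$constraints$inferior_clearance_mm))
  invisible(x)
}

#' Plan both pedicles of a vertebra
#'
#' Applies [plan_side()] independently per side. A side that cannot be
#' planned contributes its error condition instead of a plan, so one
#' impassable pedicle does not abort the other.
#'
#' @inheritParams plan_side
#' @return Object of class `vertebra_plan`: list with elements `L` and `R`,
#'   each a `screw_plan` or an error condition.
#' @export
plan_vertebra <- function(volume, labels, catalog = screw_catalog(),
                          config = plan_config()) {
  out <- lapply(c(L = "L", R = "R"), function(s) {
    tryCatch(plan_side(volume, labels, s, catalog, config),
             pedplan_error = function(e) e)
  })
  structure(out, class = "vertebra_plan")
}

#' @export
print.vertebra_plan <- function(x, ...) {
  for (s in names(x)) {
    if (inherits(x[[s]], "screw_plan")) print(x[[s]])
    else cat(sprintf("<side %s> planning failed: %s\n", s,
                     conditionMessage(x[[s]])))
  }
  invisible(x)
}
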