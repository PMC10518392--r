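# Measurements taken from a label map alone: pedicle axis, corridor width,
# entry candidates, depth to the anterior cortex, and wall clearances. These
# are the quantities the planner's placement rules consume.

#' Pedicle axis line
#'
#' @param point_mm A point on the line, mm.
#' @param direction Unit direction, oriented posterior -> anterior.
#' @return Object of class `axis_line`.
#' @export
axis_line <- function(point_mm, direction) {
  direction <- normalize3(as.numeric(direction))
  structure(list(point_mm = as.numeric(point_mm), direction = direction),
            class = "axis_line")
}

#' @export
print.axis_line <- function(x, ...) {
  cat(sprintf("<axis_line> through (%s) mm, direction (%s)\n",
              paste(sprintf("%.2f", x$point_mm), collapse = ", "),
              paste(sprintf("%.3f", x$direction), collapse = ", ")))
  invisible(x)
}

#' Estimate the pedicle axis from the label map
#'
#' Fits a line through per-slab centroids of the pedicle label: the voxel
#' cloud is sliced into slabs perpendicular to its principal direction, and a
#' total-least-squares line is fitted through the slab centroids. The
#' direction is oriented posterior -> anterior (positive y).
#'
#' @param labels An [anatomy_label_map()].
#' @param side `"L"` or `"R"`.
#' @return An [axis_line()].
#' @export
estimate_pedicle_axis <- function(labels, side) {
  code <- side_label(side, "pedicle")
  pts <- label_points(labels, code)
  if (nrow(pts) == 0L) {
    stop_pedplan("missing_structure",
                 sprintf("pedicle label %s is empty", toupper(side)))
  }
  ctr <- colMeans(pts)
  u0 <- prcomp(pts, center = TRUE, scale. = FALSE)$rotation[, 1]
  t <- as.vector(sweep(pts, 2L, ctr) %*% u0)
  nslab <- max(4L, min(10L, floor(diff(range(t)) / max(labels$spacing_mm))))
  cuts <- cut(t, breaks = nslab, labels = FALSE)
  cents <- t(vapply(split(seq_along(cuts), cuts),
                    function(i) colMeans(pts[i, , drop = FALSE]),
                    numeric(3)))
  if (nrow(cents) < 2L) {
    stop_pedplan("structure_too_small", "too few slabs to fit a pedicle axis")
  }
  dir <- prcomp(cents, center = TRUE, scale. = FALSE)$rotation[, 1]
  if (dir[2] < 0) dir <- -dir
  axis_line(colMeans(cents), dir)
}

# projections of the pedicle voxel cloud onto its axis; used for axial extent
pedicle_axial_range <- function(labels, side, axis, trim = 0.05) {
  pts <- label_points(labels, side_label(side, "pedicle"))
  t <- as.vector(sweep(pts, 2L, axis$point_mm) %*% axis$direction)
  quantile(t, c(trim, 1 - trim), names = FALSE)
}

#' Measure the pedicle width from the label map
#'
#' The width `W` is the minimum, over cross-sections perpendicular to the
#' pedicle axis sampled along the corridor's middle 80%, of the in-plane
#' minimum caliper diameter of the pedicle label footprint. The caliper over
#' voxel centers is compensated by one voxel cube's support along the probe
#' direction, since a labeled voxel occupies half a voxel beyond its center
#' on each side.
#'
#' @inheritParams estimate_pedicle_axis
#' @param axis Optional [axis_line()]; estimated from the labels when `NULL`.
#' @param station_step_mm Spacing between cross-sections (<= 0.5 mm per the
#'   measurement contract).
#' @return Width in mm.
#' @export
measure_pedicle_width <- function(labels, side, axis = NULL,
                                  station_step_mm = 0.5) {
  code <- side_label(side, "pedicle")
  pts <- label_points(labels, code)
  if (nrow(pts) == 0L) {
    stop_pedplan("missing_structure",
                 sprintf("pedicle label %s is empty", toupper(side)))
  }
  if (is.null(axis)) axis <- estimate_pedicle_axis(labels, side)
  u <- axis$direction
  t <- as.vector(sweep(pts, 2L, axis$point_mm) %*% u)
  span <- range(t)
  lo <- span[1] + 0.1 * diff(span)
  hi <- span[2] - 0.1 * diff(span)
  stations <- seq(lo, hi, by = station_step_mm)
  slab_half <- max(labels$spacing_mm) / 2 + 0.26 # overlap so no voxel ring is skipped
  basis <- plane_basis(u)
  rel <- sweep(pts, 2L, axis$point_mm)
  q1 <- as.vector(rel %*% basis$e1)
  q2 <- as.vector(rel %*% basis$e2)
  theta <- seq(0, pi, length.out = 181L)[-181L]
  ct <- cos(theta); st <- sin(theta)
  # full support of a voxel cube along each probe direction (half per side)
  n3 <- outer(ct, basis$e1) + outer(st, basis$e2)
  hsup <- as.vector(abs(n3) %*% labels$spacing_mm)
  widths <- rep(NA_real_, length(stations))
  for (i in seq_along(stations)) {
    sel <- abs(t - stations[i]) <= slab_half
    if (sum(sel) < 8L) next
    hull <- grDevices::chull(q1[sel], q2[sel])
    h1 <- q1[sel][hull]; h2 <- q2[sel][hull]
    proj <- outer(ct, h1) + outer(st, h2)  # directions x hull points
    widths[i] <- min(apply(proj, 1L, max) - apply(proj, 1L, min) + hsup)
  }
  usable <- which(!is.na(widths))
  if (length(usable) < 3L) {
    stop_pedplan("structure_too_small",
                 "fewer than 3 usable pedicle cross-sections")
  }
  min(widths[usable])
}

#' Entry-point candidates on the posterior entry disc
#'
#' Voxel centers of the side's entry-disc label, subsampled on a square grid
#' of pitch `grid_step_mm` centered on the disc centroid (one representative
#' voxel center per grid cell, nearest to the cell center).
#'
#' @inheritParams estimate_pedicle_axis
#' @param grid_step_mm Subsampling pitch, mm.
#' @return Tibble with columns `x`, `y`, `z` (mm, world).
#' @export
entry_candidates <- function(labels, side, grid_step_mm = 1) {
  check_number(grid_step_mm, "grid_step_mm", min = 0, strict_min = TRUE)
  code <- side_label(side, "entry_disc")
  pts <- label_points(labels, code)
  if (nrow(pts) == 0L) {
    stop_pedplan("missing_structure",
                 sprintf("entry disc %s is empty", toupper(side)))
  }
  ctr <- colMeans(pts)
  # the disc is a thin y-layer; bin in x and z
  bx <- round((pts[, 1] - ctr[1]) / grid_step_mm)
  bz <- round((pts[, 3] - ctr[3]) / grid_step_mm)
  d2 <- (pts[, 1] - (ctr[1] + bx * grid_step_mm))^2 +
    (pts[, 3] - (ctr[3] + bz * grid_step_mm))^2
  key <- paste(bx, bz)
  pick <- vapply(split(seq_along(key), key),
                 function(i) i[which.min(d2[i])], integer(1))
  sel <- pts[sort(pick), , drop = FALSE]
  tibble::tibble(x = sel[, 1], y = sel[, 2], z = sel[, 3])
}

#' Depth from an entry point to the anterior vertebral surface
#'
#' Casts a ray from `entry` along `direction` (sampling step: half the
#' minimum voxel spacing) and returns the distance to the last bone-labeled
#' sample -- the outer anterior surface ("vertebral front end") that bounds
#' screw length.
#'
#' @inheritParams estimate_pedicle_axis
#' @param entry 3-vector, mm (world).
#' @param direction Unit 3-vector.
#' @return Depth in mm.
#' @export
depth_to_anterior <- function(labels, entry, direction) {
  direction <- normalize3(as.numeric(direction))
  step <- min(labels$spacing_mm) / 2
  # maximum possible path: grid diagonal
  tmax <- sqrt(sum((dim(labels$data) * labels$spacing_mm)^2)) + 2
  tt <- seq(0, tmax, by = step)
  pts <- cbind(entry[1] + tt * direction[1],
               entry[2] + tt * direction[2],
               entry[3] + tt * direction[3])
  lab <- labels_at(labels, pts)
  bone <- lab %in% bone_labels()
  if (!any(bone)) {
    stop_pedplan("no_intersection", "ray does not intersect bone")
  }
  k <- max(which(bone))
  # the sample after the last bone sample must still be inside the grid,
  # otherwise the anterior surface was clipped by the field of view
  if (k == length(tt) ||
      !in_grid(labels, world_to_index(labels, pts[k + 1, , drop = FALSE]))) {
    stop_pedplan("grid_truncation", "ray exits the grid while still inside bone")
  }
  tt[k]
}

# ---- wall clearance --------------------------------------------------------

# Per-side measurement context, computed once and reused across the many
# candidate evaluations of a planning run.
side_context <- function(labels, side, axis = NULL) {
  if (is.null(axis)) axis <- estimate_pedicle_axis(labels, side)
  ped_pts <- label_points(labels, side_label(side, "pedicle"))
  t <- as.vector(sweep(ped_pts, 2L, axis$point_mm) %*% axis$direction)
  ext <- quantile(t, c(0.05, 0.95), names = FALSE)
  # medial: horizontal, from the pedicle toward the midsagittal plane of the
  # body; inferior: -z. Without a body label (isolated corridors) fall back
  # to the side convention: medial = +x for L, -x for R.
  body_x <- mean(label_points(labels, label_codes()[["TRABECULAR_BODY"]])[, 1])
  sgn <- sign(body_x - mean(ped_pts[, 1]))
  if (!is.finite(sgn) || sgn == 0) sgn <- if (side == "L") 1 else -1
  medial <- c(sgn, 0, 0)
  list(side = side, axis = axis, axial_extent = ext, medial = medial,
       inferior = c(0, 0, -1))
}

# Internal: wall-exit geometry for a trajectory. For each wall direction
# (medial, inferior), the screw axis is sampled in cross-sections every
# `section_step_mm` over the portion inside the pedicle's axial extent; from
# each section the march starts not only at the axis but at a fan of offset
# columns spanning the screw's width (offset along h = u x n), so that the
# minimum over the whole cylinder surface -- including the "corners" facing a
# curved wall -- is captured. Exit distances are measured from the axis level,
# so clearances for any diameter derive from one march:
#   clearance(d) = min over sections/columns of
#                  t_exit(o) - sqrt((d/2)^2 - o^2) / sin_fac
# where sin_fac corrects for the screw axis not being perpendicular to the
# march direction.
wall_exit_geometry <- function(labels, entry, direction, length_mm, side,
                               ctx = NULL, section_step_mm = 0.5,
                               march_step_mm = 0.1, march_max_mm = 15,
                               offset_max_mm = 4, offset_step_mm = 0.5) {
  direction <- normalize3(as.numeric(direction))
  if (is.null(ctx)) ctx <- side_context(labels, side)
  axis <- ctx$axis
  ext <- ctx$axial_extent
  tt <- seq(0, length_mm, by = section_step_mm)
  centers <- cbind(entry[1] + tt * direction[1],
                   entry[2] + tt * direction[2],
                   entry[3] + tt * direction[3])
  proj <- as.vector(sweep(centers, 2L, axis$point_mm) %*% axis$direction)
  keep <- proj >= ext[1] & proj <= ext[2]
  if (!any(keep)) return(NULL)
  centers <- centers[keep, , drop = FALSE]
  offs <- seq(-offset_max_mm, offset_max_mm, by = offset_step_mm)

  one_direction <- function(wdir) {
    h <- normalize3(cross3(direction, wdir))
    nsec <- nrow(centers)
    starts <- cbind(
      rep(centers[, 1], each = length(offs)) + rep(offs, nsec) * h[1],
      rep(centers[, 2], each = length(offs)) + rep(offs, nsec) * h[2],
      rep(centers[, 3], each = length(offs)) + rep(offs, nsec) * h[3])
    texit <- .march_exit(starts, as.numeric(wdir), march_step_mm,
                         march_max_mm, as.vector(labels$data),
                         dim(labels$data), labels$spacing_mm,
                         labels$origin_mm)
    list(texit = matrix(texit, nrow = length(offs)),
         offsets = offs,
         sin_fac = sqrt(max(1e-9, 1 - sum(wdir * direction)^2)))
  }
  list(medial = one_direction(ctx$medial),
       inferior = one_direction(ctx$inferior))
}

clearances_from_geometry <- function(geom, diameter_mm) {
  r <- diameter_mm / 2
  one <- function(g) {
    use <- abs(g$offsets) <= r
    depth <- sqrt(pmax(0, r^2 - g$offsets[use]^2)) / g$sin_fac
    min(g$texit[use, , drop = FALSE] - depth)
  }
  list(medial_clearance_mm = one(geom$medial),
       inferior_clearance_mm = one(geom$inferior))
}

#' Clearance between a screw and the medial/inferior pedicle walls
#'
#' For the portion of the screw cylinder inside the pedicle's axial extent,
#' the clearance is the minimum distance from the cylinder surface to the
#' outer bone surface of the respective wall (medial: toward the spinal
#' canal; inferior: toward the caudal nerve root). Negative values encode
#' penetration of the wall's outer surface.
#'
#' @inheritParams estimate_pedicle_axis
#' @param screw A [screw_spec()].
#' @param axis Optional precomputed pedicle [axis_line()].
#' @return Object of class `clearance_report`: list with
#'   `medial_clearance_mm` and `inferior_clearance_mm`.
#' @export
wall_clearance <- function(labels, screw, axis = NULL) {
  stopifnot(inherits(screw, "screw_spec"))
  code <- side_label(screw$side, "pedicle")
  cyl <- cylinder_voxels(labels, screw)
  if (!any(labels$data[cyl$lin] == code)) {
    stop_pedplan("not_in_pedicle", "screw cylinder misses the pedicle label")
  }
  ctx <- side_context(labels, screw$side, axis = axis)
  geom <- wall_exit_geometry(labels, screw$entry_mm, screw$direction,
                             screw$length_mm, screw$side, ctx = ctx,
                             offset_step_mm = 0.25)
  if (is.null(geom)) {
    stop_pedplan("not_in_pedicle",
                 "screw axis does not traverse the pedicle's axial extent")
  }
  cl <- clearances_from_geometry(geom, screw$diameter_mm)
  structure(cl, class = "clearance_report")
}

#' @export
print.clearance_report <- function(x, ...) {
  cat(sprintf("<clearance_report> medial %.2f mm, inferior %.2f mm\n",
              x$medial_clearance_mm, x$inferior_clearance_mm))
  invisible(x)
}
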