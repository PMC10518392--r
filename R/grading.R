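# Gertzbein-Robbins grading: breach depth of a screw against the bone-label
# union, and the A-E grade it maps to. Breach is measured against ALL bone
# labels (not the pedicle alone), so a screw passing from the pedicle into
# the vertebral body is not a breach -- matching the clinical notion of a
# cortical breach.

#' Maximum breach depth of a screw
#'
#' Samples the screw's lateral cylinder surface and tip cap at
#' `surface_step_mm` spacing; every sample outside the bone-label union
#' contributes its exact distance to the nearest bone voxel center, and the
#' maximum over samples is returned (0 if fully contained).
#'
#' The extramedullary entry segment is not a breach: lateral-surface samples
#' within `entry_exclusion_mm` (default: one screw diameter) beyond the first
#' bone contact along the axis are excluded, mirroring how clinical grading
#' evaluates only the intraosseous tract. The tip cap is always graded.
#'
#' @param screw A [screw_spec()].
#' @param labels An [anatomy_label_map()].
#' @param surface_step_mm Surface sampling pitch, mm.
#' @param entry_exclusion_mm Length of the entry funnel excluded from
#'   lateral-surface grading, mm; `NULL` for one screw diameter.
#' @param dmap Optional precomputed [bone distance map][grade_screw]
#'   (internal reuse across a cohort).
#' @return Breach depth in mm (>= 0).
#' @export
breach_depth <- function(screw, labels, surface_step_mm = 0.3,
                         entry_exclusion_mm = NULL, dmap = NULL) {
  stopifnot(inherits(screw, "screw_spec"))
  samp <- sample_screw_surface(screw, labels, surface_step_mm,
                               entry_exclusion_mm)
  idx <- world_to_index(labels, samp)
  if (!any(in_grid(labels, idx))) {
    stop_pedplan("out_of_grid", "screw lies entirely outside the volume grid")
  }
  outside <- !(labels_at(labels, samp) %in% bone_labels())
  if (!any(outside)) return(0)
  mask <- bone_mask(labels)
  if (!any(mask)) stop_pedplan("missing_structure", "label map contains no bone")
  d <- nearest_mask_dist(labels, mask, samp[outside, , drop = FALSE],
                         dmap = dmap)
  max(d)
}

# lateral surface + tip cap sample points of the screw cylinder
sample_screw_surface <- function(screw, labels, step_mm, entry_exclusion_mm) {
  r <- screw$diameter_mm / 2
  u <- screw$direction
  basis <- plane_basis(u)
  t0 <- first_bone_contact(labels, screw$entry_mm, u, screw$length_mm)
  excl <- entry_exclusion_mm %||% screw$diameter_mm
  t_start <- if (is.na(t0)) 0 else min(t0 + excl, screw$length_mm)
  pts <- NULL
  if (t_start < screw$length_mm) {
    tt <- seq(t_start, screw$length_mm, by = step_mm)
    nang <- max(8L, ceiling(2 * pi * r / step_mm))
    ang <- seq(0, 2 * pi, length.out = nang + 1L)[-(nang + 1L)]
    ring <- outer(cos(ang), basis$e1) + outer(sin(ang), basis$e2)  # nang x 3
    ctr <- cbind(screw$entry_mm[1] + tt * u[1], screw$entry_mm[2] + tt * u[2],
                 screw$entry_mm[3] + tt * u[3])
    pts <- cbind(
      rep(ctr[, 1], each = nang) + r * rep(ring[, 1], length(tt)),
      rep(ctr[, 2], each = nang) + r * rep(ring[, 2], length(tt)),
      rep(ctr[, 3], each = nang) + r * rep(ring[, 3], length(tt)))
  }
  # tip cap: concentric rings
  tip <- screw_tip(screw)
  radii <- seq(0, r, by = step_mm)
  cap <- lapply(radii, function(rho) {
    if (rho == 0) return(matrix(tip, 1L, 3L))
    nang <- max(6L, ceiling(2 * pi * rho / step_mm))
    ang <- seq(0, 2 * pi, length.out = nang + 1L)[-(nang + 1L)]
    ring <- outer(cos(ang), basis$e1) + outer(sin(ang), basis$e2)
    sweep(rho * ring, 2L, tip, "+")
  })
  rbind(pts, do.call(rbind, cap))
}

#' Map a breach depth to a Gertzbein-Robbins grade
#'
#' Grade A: depth <= `epsilon_mm` (no breach at sampling resolution);
#' B: < 2 mm; C: < 4 mm; D: < 6 mm; E: >= 6 mm. Boundaries are half-open
#' upward (a 2.0 mm breach is grade C, 4.0 mm is D, 6.0 mm is E).
#'
#' @param depth_mm Breach depth(s), mm, >= 0.
#' @param epsilon_mm Grade-A tolerance, mm; at sampling resolution breaches
#'   below half a voxel cannot be distinguished from containment.
#' @return Character vector of grades `"A"`..`"E"`.
#' @export
gr_grade <- function(depth_mm, epsilon_mm = 0.3125) {
  if (any(!is.finite(depth_mm)) || any(depth_mm < 0)) {
    stop_pedplan("input_error", "breach depth must be finite and >= 0")
  }
  check_number(epsilon_mm, "epsilon_mm", min = 0, max = 2)
  cut_pts <- c(-Inf, epsilon_mm, 2, 4, 6, Inf)
  # right-open intervals: [eps,2) -> B, [2,4) -> C, [4,6) -> D, [6,Inf) -> E
  as.character(cut(depth_mm, breaks = cut_pts, labels = c("A", "B", "C", "D", "E"),
                   right = FALSE, include.lowest = TRUE))
}

#' Grade a screw placement
#'
#' Composition of [breach_depth()] and [gr_grade()]. The default grade-A
#' tolerance is half the maximum voxel spacing: the label map cannot resolve
#' breaches below that.
#'
#' @inheritParams breach_depth
#' @param epsilon_mm Grade-A tolerance, mm; `NULL` for half the maximum
#'   voxel spacing.
#' @return Object of class `gr_result`: `breach_depth_mm`, `grade`.
#' @export
grade_screw <- function(screw, labels, surface_step_mm = 0.3,
                        epsilon_mm = NULL, entry_exclusion_mm = NULL,
                        dmap = NULL) {
  eps <- epsilon_mm %||% (max(labels$spacing_mm) / 2)
  depth <- breach_depth(screw, labels, surface_step_mm, entry_exclusion_mm,
                        dmap = dmap)
  structure(list(breach_depth_mm = depth, grade = gr_grade(depth, eps)),
            class = "gr_result")
}

#' @export
print.gr_result <- function(x, ...) {
  cat(sprintf("<gr_result> grade %s (breach %.2f mm)\n", x$grade,
              x$breach_depth_mm))
  invisible(x)
}

#' Grade a list of screws against one label map
#'
#' @param screws List of [screw_spec()] objects (optionally named).
#' @inheritParams grade_screw
#' @return Tibble with columns `id`, `side`, `depth_mm`, `grade`.
#' @export
grade_screws <- function(screws, labels, surface_step_mm = 0.3,
                         epsilon_mm = NULL, entry_exclusion_mm = NULL) {
  dmap <- bone_distance_map(labels)
  ids <- names(screws) %||% as.character(seq_along(screws))
  ids[ids == ""] <- as.character(which(ids == ""))
  rows <- purrr::map2(screws, ids, function(s, id) {
    g <- grade_screw(s, labels, surface_step_mm, epsilon_mm,
                     entry_exclusion_mm, dmap = dmap)
    tibble::tibble(id = id, side = s$side, depth_mm = g$breach_depth_mm,
                   grade = g$grade)
  })
  dplyr::bind_rows(rows)
}

#' Reslice a volume perpendicular to a screw axis
#'
#' Multiplanar reconstruction along the screw: `n_planes` square images of
#' side `fov_mm`, sampled on planes perpendicular to the screw direction,
#' evenly spaced from entry to tip, trilinearly interpolated. Pixels (or
#' whole planes) outside the volume are filled with `fill` and flagged.
#'
#' @param volume An [image_volume()].
#' @param screw A [screw_spec()].
#' @param n_planes Number of planes (>= 1).
#' @param fov_mm Field-of-view side length, mm.
#' @param pixel_mm In-plane pixel pitch, mm; defaults to the smallest voxel
#'   spacing.
#' @param fill Value for out-of-volume pixels.
#' @return Object of class `screw_reslice`: a `px x px x n_planes` array with
#'   attributes `plane_t_mm` (axial positions) and `out_of_grid` (logical per
#'   plane, TRUE when a plane has no in-volume pixel).
#' @export
reslice_along_axis <- function(volume, screw, n_planes = 5, fov_mm = 20,
                               pixel_mm = NULL, fill = NA_real_) {
  if (!is.numeric(n_planes) || n_planes < 1) {
    stop_pedplan("config_error", "`n_planes` must be >= 1")
  }
  n_planes <- as.integer(n_planes)
  px_mm <- pixel_mm %||% min(volume$spacing_mm)
  u <- screw$direction
  basis <- plane_basis(u)
  offs <- seq(-fov_mm / 2, fov_mm / 2, by = px_mm)
  npx <- length(offs)
  tt <- if (n_planes == 1L) screw$length_mm / 2 else
    seq(0, screw$length_mm, length.out = n_planes)
  out <- array(fill, dim = c(npx, npx, n_planes))
  oog <- logical(n_planes)
  g1 <- rep(offs, times = npx)
  g2 <- rep(offs, each = npx)
  for (p in seq_len(n_planes)) {
    ctr <- screw$entry_mm + tt[p] * u
    pts <- cbind(ctr[1] + g1 * basis$e1[1] + g2 * basis$e2[1],
                 ctr[2] + g1 * basis$e1[2] + g2 * basis$e2[2],
                 ctr[3] + g1 * basis$e1[3] + g2 * basis$e2[3])
    vals <- interp_trilinear(volume, pts, fill = fill)
    oog[p] <- all(is.na(vals)) && is.na(fill) ||
      !any(in_grid(volume, world_to_index(volume, pts)))
    out[, , p] <- matrix(vals, npx, npx)
  }
  structure(out, plane_t_mm = tt, out_of_grid = oog,
            pixel_mm = px_mm, class = "screw_reslice")
}
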