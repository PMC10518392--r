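# Voxel-grid containers. Both containers share the same grid metadata:
# `spacing_mm` (per-axis voxel pitch) and `origin_mm` (world coordinate of the
# center of voxel [1,1,1]). World axes follow the radiological convention used
# throughout the package: x = left -> right, y = posterior -> anterior,
# z = inferior -> superior, all in millimetres. A point belongs to the voxel
# whose center is nearest (grid-aligned rounding), so voxel ownership extends
# half a voxel beyond the center in every direction.

#' Anatomical label vocabulary
#'
#' Fixed integer codes for the compartments of a segmented vertebra. The
#' "bone" union (everything a screw may legitimately occupy) is every
#' compartment except the background and the entry-region markers.
#'
#' @return `label_codes()`: named integer vector of all codes.
#'   `bone_labels()`: the subset of codes counted as bone.
#' @export
label_codes <- function() {
  c(BACKGROUND = 0L, TRABECULAR_BODY = 1L, CORTICAL_SHELL = 2L,
    PEDICLE_L = 3L, PEDICLE_R = 4L, ENDPLATE_SUP = 5L, ENDPLATE_INF = 6L,
    POSTERIOR_ELEMENTS = 7L, ENTRY_DISC_L = 8L, ENTRY_DISC_R = 9L)
}

#' @rdname label_codes
#' @export
bone_labels <- function() {
  label_codes()[c("TRABECULAR_BODY", "CORTICAL_SHELL", "PEDICLE_L", "PEDICLE_R",
                  "ENDPLATE_SUP", "ENDPLATE_INF", "POSTERIOR_ELEMENTS")]
}

side_label <- function(side, what = c("pedicle", "entry_disc")) {
  what <- match.arg(what)
  side <- match.arg(toupper(side), c("L", "R"))
  codes <- label_codes()
  if (what == "pedicle") unname(codes[paste0("PEDICLE_", side)])
  else unname(codes[paste0("ENTRY_DISC_", side)])
}

validate_grid_meta <- function(data, spacing_mm, origin_mm) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop_pedplan("unsupported_shape", "grid data must be a 3-D array")
  }
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0)) {
    stop_pedplan("config_error", "`spacing_mm` must be three positive finite numbers")
  }
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm))) {
    stop_pedplan("config_error", "`origin_mm` must be three finite numbers")
  }
  invisible(TRUE)
}

#' Image volume (pseudo-Hounsfield intensities on a voxel grid)
#'
#' @param data 3-D numeric array of intensities (pseudo-HU).
#' @param spacing_mm Voxel spacing, 3-vector in mm.
#' @param origin_mm World coordinate (mm) of the center of voxel `[1,1,1]`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing_mm, origin_mm = c(0, 0, 0)) {
  validate_grid_meta(data, spacing_mm, origin_mm)
  if (!all(is.finite(data))) {
    stop_pedplan("format_error", "image intensities must all be finite")
  }
  structure(list(data = data, spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "image_volume")
}

#' Anatomical label map co-registered with an image volume
#'
#' @param data 3-D integer-valued array of label codes (see [label_codes()]).
#' @inheritParams image_volume
#' @return An object of class `anatomy_label_map`.
#' @export
anatomy_label_map <- function(data, spacing_mm, origin_mm = c(0, 0, 0)) {
  validate_grid_meta(data, spacing_mm, origin_mm)
  vals <- unique(as.vector(data))
  if (any(vals != round(vals))) {
    stop_pedplan("format_error", "label data must be integer-valued")
  }
  unknown <- setdiff(as.integer(vals), unname(label_codes()))
  if (length(unknown) > 0L) {
    stop_pedplan("format_error", sprintf(
      "unknown label code(s): %s", paste(unknown, collapse = ", ")))
  }
  storage.mode(data) <- "integer"
  structure(list(data = data, spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "anatomy_label_map")
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' @export
dim.anatomy_label_map <- function(x) dim(x$data)

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels, spacing %s mm, origin (%s) mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing_mm, 4), collapse = "x"),
              paste(signif(x$origin_mm, 4), collapse = ", ")))
  cat(sprintf("  intensity range [%.1f, %.1f] HU\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.anatomy_label_map <- function(x, ...) {
  tab <- table(factor(x$data, levels = unname(label_codes()),
                      labels = names(label_codes())))
  cat(sprintf("<anatomy_label_map> %s voxels, spacing %s mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing_mm, 4), collapse = "x")))
  tab <- tab[tab > 0]
  cat(paste(sprintf("  %-18s %d", names(tab), as.integer(tab)), collapse = "\n"),
      "\n")
  invisible(x)
}

same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$spacing_mm, b$spacing_mm, tolerance = 1e-6)) &&
    isTRUE(all.equal(a$origin_mm, b$origin_mm, tolerance = 1e-6))
}

# ---- coordinate plumbing ---------------------------------------------------

as_point_matrix <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3L)
  if (ncol(pts) != 3L) stop_pedplan("config_error", "points must have 3 columns")
  storage.mode(pts) <- "double"
  pts
}

# nearest-voxel (1-based) indices; may fall outside the grid
world_to_index <- function(grid, pts) {
  pts <- as_point_matrix(pts)
  idx <- sweep(pts, 2L, grid$origin_mm)
  idx <- sweep(idx, 2L, grid$spacing_mm, "/")
  round(idx) + 1
}

index_to_world <- function(grid, idx) {
  idx <- as_point_matrix(idx)
  sweep(sweep(idx - 1, 2L, grid$spacing_mm, "*"), 2L, grid$origin_mm, "+")
}

in_grid <- function(grid, idx) {
  d <- dim(grid$data)
  idx[, 1] >= 1 & idx[, 1] <= d[1] &
    idx[, 2] >= 1 & idx[, 2] <= d[2] &
    idx[, 3] >= 1 & idx[, 3] <= d[3]
}

# label at each world point (nearest-neighbor lookup); BACKGROUND outside grid
labels_at <- function(labels, pts) {
  pts <- as_point_matrix(pts)
  idx <- world_to_index(labels, pts)
  ok <- in_grid(labels, idx)
  out <- rep.int(label_codes()[["BACKGROUND"]], nrow(pts))
  if (any(ok)) {
    d <- dim(labels$data)
    lin <- (idx[ok, 3] - 1) * (d[1] * d[2]) + (idx[ok, 2] - 1) * d[1] + idx[ok, 1]
    out[ok] <- labels$data[lin]
  }
  out
}

# world coordinates of every voxel labeled with `code`
label_points <- function(labels, code) {
  idx <- which(labels$data == code, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(matrix(numeric(0), ncol = 3L))
  index_to_world(labels, idx)
}

bone_mask <- function(labels) {
  array(labels$data %in% bone_labels(), dim = dim(labels$data))
}

# distance (mm) from every voxel center to the nearest bone voxel center
bone_distance_map <- function(labels) {
  m <- bone_mask(labels)
  array(.edt3d(as.vector(m), dim(m), labels$spacing_mm), dim = dim(m))
}

# exact distance from world points to nearest TRUE voxel center of `mask`
nearest_mask_dist <- function(grid, mask, pts, dmap = NULL) {
  pts <- as_point_matrix(pts)
  if (nrow(pts) == 0L) return(numeric(0))
  if (is.null(dmap)) {
    dmap <- .edt3d(as.vector(mask), dim(grid$data), grid$spacing_mm)
  }
  .nearest_mask_distance(pts, as.vector(mask), dim(grid$data),
                         grid$spacing_mm, grid$origin_mm, as.vector(dmap))
}

# trilinear interpolation of an image volume at world points; `fill` outside
interp_trilinear <- function(volume, pts, fill = NA_real_) {
  pts <- as_point_matrix(pts)
  d <- dim(volume$data)
  cont <- sweep(sweep(pts, 2L, volume$origin_mm), 2L, volume$spacing_mm, "/")
  out <- rep.int(fill, nrow(pts))
  i0 <- floor(cont)
  fr <- cont - i0
  ok <- cont[, 1] >= 0 & cont[, 1] <= d[1] - 1 &
    cont[, 2] >= 0 & cont[, 2] <= d[2] - 1 &
    cont[, 3] >= 0 & cont[, 3] <= d[3] - 1
  if (!any(ok)) return(out)
  i0 <- i0[ok, , drop = FALSE] + 1
  fr <- fr[ok, , drop = FALSE]
  # clamp the upper corner for points exactly on the far face
  i1 <- pmin(i0 + 1, matrix(d, nrow(i0), 3, byrow = TRUE))
  n12 <- d[1] * d[2]
  lin <- function(ix, iy, iz) (iz - 1) * n12 + (iy - 1) * d[1] + ix
  v <- volume$data
  acc <- v[lin(i0[, 1], i0[, 2], i0[, 3])] * (1 - fr[, 1]) * (1 - fr[, 2]) * (1 - fr[, 3]) +
    v[lin(i1[, 1], i0[, 2], i0[, 3])] * fr[, 1] * (1 - fr[, 2]) * (1 - fr[, 3]) +
    v[lin(i0[, 1], i1[, 2], i0[, 3])] * (1 - fr[, 1]) * fr[, 2] * (1 - fr[, 3]) +
    v[lin(i1[, 1], i1[, 2], i0[, 3])] * fr[, 1] * fr[, 2] * (1 - fr[, 3]) +
    v[lin(i0[, 1], i0[, 2], i1[, 3])] * (1 - fr[, 1]) * (1 - fr[, 2]) * fr[, 3] +
    v[lin(i1[, 1], i0[, 2], i1[, 3])] * fr[, 1] * (1 - fr[, 2]) * fr[, 3] +
    v[lin(i0[, 1], i1[, 2], i1[, 3])] * (1 - fr[, 1]) * fr[, 2] * fr[, 3] +
    v[lin(i1[, 1], i1[, 2], i1[, 3])] * fr[, 1] * fr[, 2] * fr[, 3]
  out[ok] <- acc
  out
}

normalize3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop_pedplan("config_error", "zero-length direction vector")
  v / n
}

# orthonormal in-plane basis perpendicular to unit vector u
plane_basis <- function(u) {
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- normalize3(cross3(ref, u))
  e2 <- cross3(u, e1)
  list(e1 = e1, e2 = e2)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
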