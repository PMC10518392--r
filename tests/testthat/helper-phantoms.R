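# Shared fixtures and independent oracles. Phantoms are cached per spec so
# that test files can reuse them without regenerating.

.phantom_cache <- new.env(parent = emptyenv())

cached_phantom <- function(...) {
  key <- paste(deparse(list(...)), collapse = "")
  if (is.null(.phantom_cache[[key]])) {
    .phantom_cache[[key]] <- make_phantom(phantom_spec(...))
  }
  .phantom_cache[[key]]
}

# coarse-but-sufficient planner search used throughout the tests
coarse_config <- function(...) {
  plan_config(transverse_range_deg = 9, transverse_step_deg = 3,
              sagittal_range_deg = 6, sagittal_step_deg = 3,
              entry_step_mm = 2, ...)
}

# a screw running down the ground-truth pedicle axis
axis_screw <- function(phantom, side = "L", length_mm = 40, diameter_mm = 6) {
  tr <- phantom$truth$sides[[side]]
  screw_spec(side, tr$entry_center_mm, tr$axis_dir, length_mm, diameter_mm)
}

# bare synthetic tube: a circular corridor of `width_mm` along +y with no
# cortical wall, for analytic clearance/breach checks
bare_tube_labels <- function(width_mm = 5, length_mm = 30,
                             spacing = c(0.25, 0.25, 0.25), pad_mm = 6) {
  r <- width_mm / 2
  ext_xz <- r + pad_mm
  xs <- seq(-ext_xz, ext_xz, by = spacing[1])
  ys <- seq(0, length_mm, by = spacing[2])
  zs <- seq(-ext_xz, ext_xz, by = spacing[3])
  dims <- c(length(xs), length(ys), length(zs))
  X <- array(rep(xs, times = dims[2] * dims[3]), dim = dims)
  Z <- array(rep(zs, each = dims[1] * dims[2]), dim = dims)
  lab <- array(0L, dim = dims)
  lab[X^2 + Z^2 <= r^2] <- label_codes()[["PEDICLE_L"]]
  anatomy_label_map(lab, spacing, c(-ext_xz, 0, -ext_xz))
}

# ---- independent distance oracle (pure R, BLAS brute force) ---------------

# 26-connectivity boundary voxels of the bone mask, as world coordinates
bone_boundary_points <- function(labels) {
  m <- bone_mask(labels)
  d <- dim(m)
  interior <- array(TRUE, dim = d)
  for (sh in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))) {
    shifted <- array(FALSE, dim = d)
    src <- list(seq_len(d[1]) - sh[1], seq_len(d[2]) - sh[2],
                seq_len(d[3]) - sh[3])
    ok <- lapply(1:3, function(a) src[[a]] >= 1 & src[[a]] <= d[a])
    shifted[ok[[1]], ok[[2]], ok[[3]]] <-
      m[src[[1]][ok[[1]]], src[[2]][ok[[2]]], src[[3]][ok[[3]]]]
    interior <- interior & shifted
  }
  bnd <- m & !interior  # bone voxels with a non-bone 6-neighbor
  idx <- which(bnd, arr.ind = TRUE)
  sweep(sweep(idx - 1, 2L, labels$spacing_mm, "*"), 2L, labels$origin_mm, "+")
}

# exact distance from points to the nearest bone voxel center, brute force
oracle_bone_dist <- function(labels, pts, boundary = NULL) {
  if (nrow(pts) == 0L) return(numeric(0))
  B <- boundary %||% bone_boundary_points(labels)
  pad <- 25
  keep <- B[, 1] >= min(pts[, 1]) - pad & B[, 1] <= max(pts[, 1]) + pad &
    B[, 2] >= min(pts[, 2]) - pad & B[, 2] <= max(pts[, 2]) + pad &
    B[, 3] >= min(pts[, 3]) - pad & B[, 3] <= max(pts[, 3]) + pad
  B <- B[keep, , drop = FALSE]
  stopifnot(nrow(B) > 0L)
  b2 <- rowSums(B^2)
  out <- numeric(nrow(pts))
  chunk <- 1000L
  for (s in seq(1L, nrow(pts), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(pts))
    P <- pts[s:e, , drop = FALSE]
    cross <- P %*% t(B)
    d2 <- outer(rowSums(P^2), b2, "+") - 2 * cross
    out[s:e] <- sqrt(pmax(0, apply(d2, 1L, min)))
  }
  out
}

# ---- independent breach oracle --------------------------------------------

# Dense surface sampling with a different pattern than the implementation
# (offset angular phase, sunflower tip cap), same entry-funnel convention.
oracle_breach_depth <- function(screw, labels, step_mm, boundary = NULL) {
  r <- screw$diameter_mm / 2
  u <- screw$direction
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  # entry funnel from an independent, finer ray march
  fine <- min(labels$spacing_mm) / 4
  tt0 <- seq(0, screw$length_mm, by = fine)
  ray <- cbind(screw$entry_mm[1] + tt0 * u[1], screw$entry_mm[2] + tt0 * u[2],
               screw$entry_mm[3] + tt0 * u[3])
  bone <- pedplan:::labels_at(labels, ray) %in% bone_labels()
  t_start <- if (!any(bone)) 0 else
    min(tt0[which(bone)[1]] + screw$diameter_mm, screw$length_mm)
  pts <- NULL
  if (t_start < screw$length_mm) {
    tt <- seq(t_start, screw$length_mm, by = step_mm)
    nang <- max(8L, ceiling(2 * pi * r / step_mm))
    ang <- seq(0, 2 * pi, length.out = nang + 1L)[-(nang + 1L)] +
      pi / (2 * nang)  # phase offset vs implementation
    ring <- outer(cos(ang), e1) + outer(sin(ang), e2)
    ctr <- cbind(screw$entry_mm[1] + tt * u[1], screw$entry_mm[2] + tt * u[2],
                 screw$entry_mm[3] + tt * u[3])
    pts <- cbind(rep(ctr[, 1], each = nang) + r * rep(ring[, 1], length(tt)),
                 rep(ctr[, 2], each = nang) + r * rep(ring[, 2], length(tt)),
                 rep(ctr[, 3], each = nang) + r * rep(ring[, 3], length(tt)))
  }
  # sunflower-pattern tip cap
  tip <- screw$entry_mm + screw$length_mm * u
  ncap <- max(16L, ceiling(pi * r^2 / step_mm^2))
  i <- seq_len(ncap)
  rho <- r * sqrt((i - 0.5) / ncap)
  phi <- i * pi * (3 - sqrt(5))
  cap <- cbind(tip[1] + rho * (cos(phi) * e1[1] + sin(phi) * e2[1]),
               tip[2] + rho * (cos(phi) * e1[2] + sin(phi) * e2[2]),
               tip[3] + rho * (cos(phi) * e1[3] + sin(phi) * e2[3]))
  pts <- rbind(pts, cap)
  outside <- !(pedplan:::labels_at(labels, pts) %in% bone_labels())
  if (!any(outside)) return(0)
  max(oracle_bone_dist(labels, pts[outside, , drop = FALSE],
                       boundary = boundary))
}

# ---- independent wall-clearance oracle ------------------------------------

# Minimum over ~1e4 lateral-surface points (within the pedicle's axial
# extent) of the marched distance to the first non-bone sample along the
# wall direction.
oracle_wall_clearance <- function(labels, screw, truth_axis, n_pts = 10000) {
  u <- screw$direction
  r <- screw$diameter_mm / 2
  ped <- pedplan:::label_points(labels, pedplan:::side_label(screw$side, "pedicle"))
  tproj <- as.vector(sweep(ped, 2L, truth_axis$point_mm) %*% truth_axis$direction)
  ext <- quantile(tproj, c(0.05, 0.95), names = FALSE)
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * u) * u; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  n_side <- ceiling(sqrt(n_pts))
  tt <- seq(0, screw$length_mm, length.out = n_side)
  ang <- seq(0, 2 * pi, length.out = n_side + 1L)[-(n_side + 1L)]
  grid <- expand.grid(t = tt, a = ang)
  pts <- cbind(
    screw$entry_mm[1] + grid$t * u[1] + r * (cos(grid$a) * e1[1] + sin(grid$a) * e2[1]),
    screw$entry_mm[2] + grid$t * u[2] + r * (cos(grid$a) * e1[2] + sin(grid$a) * e2[2]),
    screw$entry_mm[3] + grid$t * u[3] + r * (cos(grid$a) * e1[3] + sin(grid$a) * e2[3]))
  proj <- as.vector(sweep(pts, 2L, truth_axis$point_mm) %*% truth_axis$direction)
  pts <- pts[proj >= ext[1] & proj <= ext[2], , drop = FALSE]
  body_x <- mean(pedplan:::label_points(
    labels, label_codes()[["TRABECULAR_BODY"]])[, 1])
  medial_sign <- sign(body_x - mean(ped[, 1]))
  march <- function(wdir) {
    ss <- seq(0, 20, by = 0.05)
    inb <- matrix(pedplan:::labels_at(
      labels,
      cbind(rep(pts[, 1], each = length(ss)) + rep(ss, nrow(pts)) * wdir[1],
            rep(pts[, 2], each = length(ss)) + rep(ss, nrow(pts)) * wdir[2],
            rep(pts[, 3], each = length(ss)) + rep(ss, nrow(pts)) * wdir[3])) %in%
        bone_labels(), nrow = length(ss))
    lead <- apply(inb, 2L, function(col) {
      w <- which(!col); if (length(w) == 0L) length(col) else w[1] - 1L
    })
    min(ifelse(lead == 0L, 0, ss[pmax(lead, 1L)] + 0.025))
  }
  list(medial_clearance_mm = march(c(medial_sign, 0, 0)),
       inferior_clearance_mm = march(c(0, 0, -1)))
}
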