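# Parametric vertebra phantom. The solids are deliberately simple so that
# every planning constraint has an exact analytic counterpart:
#   - vertebral body: elliptic cylinder (axis = z) with a cortical shell and
#     superior/inferior endplate slabs;
#   - pedicles: elliptic tubes (the trabecular corridor whose transverse width
#     is the "pedicle width" W) wrapped in a cortical wall ring, converging
#     toward the body at a configurable transverse angle;
#   - posterior elements: a bone slab behind the pedicle mouths;
#   - entry regions: one-voxel-thick circular discs sitting on the posterior
#     surface where the (extended) pedicle axes exit.
# All geometry is deterministic; only the intensity noise consumes the RNG.

#' Phantom specification
#'
#' Parameters of the synthetic vertebra generator. Defaults emulate a lumbar
#' vertebra imaged at 0.625 mm isotropic spacing (a common thin-slice CT
#' protocol). `pedicle_width_mm` is the transverse diameter of the trabecular
#' pedicle corridor -- the quantity the planner's 90% diameter rule refers to.
#'
#' @param body_width_mm,body_depth_mm,body_height_mm Vertebral body elliptic
#'   cylinder: full width (x), depth (y), and height (z) in mm.
#' @param pedicle_width_mm Transverse (horizontal) diameter of each pedicle
#'   corridor, mm.
#' @param pedicle_height_mm Vertical diameter of each pedicle corridor, mm.
#'   Defaults to `pedicle_width_mm + 2` so the transverse width is always the
#'   limiting dimension, as in typical lumbar anatomy.
#' @param pedicle_length_mm Free corridor length between the posterior
#'   elements and the body, mm.
#' @param pedicle_transverse_angle_deg Mediolateral convergence of each
#'   pedicle axis toward the midline, degrees; must be in [0, 45).
#' @param cortex_thickness_mm Thickness of the cortical shell, endplates and
#'   pedicle wall rings, mm; at least one voxel.
#' @param entry_disc_radius_mm Radius of the circular posterior entry region
#'   per side, mm.
#' @param voxel_spacing_mm Voxel spacing, 3-vector, mm.
#' @param intensity_trabecular_hu,intensity_cortical_hu,intensity_background_hu
#'   Mean pseudo-Hounsfield intensity per compartment.
#' @param noise_sd_hu Standard deviation of i.i.d. Gaussian intensity noise.
#' @param rng_seed Integer seed controlling the intensity noise.
#' @return A validated list of class `phantom_spec`.
#' @export
phantom_spec <- function(body_width_mm = 36, body_depth_mm = 30,
                         body_height_mm = 28,
                         pedicle_width_mm = 8,
                         pedicle_height_mm = pedicle_width_mm + 2,
                         pedicle_length_mm = 12,
                         pedicle_transverse_angle_deg = 10,
                         cortex_thickness_mm = 1.25,
                         entry_disc_radius_mm = 3,
                         voxel_spacing_mm = c(0.625, 0.625, 0.625),
                         intensity_trabecular_hu = 250,
                         intensity_cortical_hu = 900,
                         intensity_background_hu = -400,
                         noise_sd_hu = 30,
                         rng_seed = 1L) {
  spec <- list(
    body_width_mm = body_width_mm, body_depth_mm = body_depth_mm,
    body_height_mm = body_height_mm, pedicle_width_mm = pedicle_width_mm,
    pedicle_height_mm = pedicle_height_mm,
    pedicle_length_mm = pedicle_length_mm,
    pedicle_transverse_angle_deg = pedicle_transverse_angle_deg,
    cortex_thickness_mm = cortex_thickness_mm,
    entry_disc_radius_mm = entry_disc_radius_mm,
    voxel_spacing_mm = as.numeric(voxel_spacing_mm),
    intensity_trabecular_hu = intensity_trabecular_hu,
    intensity_cortical_hu = intensity_cortical_hu,
    intensity_background_hu = intensity_background_hu,
    noise_sd_hu = noise_sd_hu, rng_seed = as.integer(rng_seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(spec) {
  lin <- c("body_width_mm", "body_depth_mm", "body_height_mm",
           "pedicle_width_mm", "pedicle_height_mm", "pedicle_length_mm",
           "cortex_thickness_mm", "entry_disc_radius_mm")
  for (f in lin) check_number(spec[[f]], f, min = 0, strict_min = TRUE)
  if (length(spec$voxel_spacing_mm) != 3L || any(spec$voxel_spacing_mm <= 0)) {
    stop_pedplan("config_error", "voxel_spacing_mm must be 3 positive numbers")
  }
  if (spec$pedicle_width_mm >= spec$body_width_mm) {
    stop_pedplan("config_error", "pedicle_width_mm must be < body_width_mm")
  }
  if (spec$cortex_thickness_mm < min(spec$voxel_spacing_mm)) {
    stop_pedplan("config_error",
                 "cortex_thickness_mm must be at least one voxel thick")
  }
  check_number(spec$pedicle_transverse_angle_deg,
               "pedicle_transverse_angle_deg", min = 0, max = 45 - 1e-9)
  check_number(spec$noise_sd_hu, "noise_sd_hu", min = 0)
  invisible(spec)
}

# Analytic geometry shared by the generator and the ground truth.
phantom_geometry <- function(spec) {
  a <- spec$body_width_mm / 2
  b <- spec$body_depth_mm / 2
  hz <- spec$body_height_mm / 2
  th <- spec$pedicle_transverse_angle_deg * pi / 180
  xa <- 0.35 * spec$body_width_mm          # pedicle attachment offset
  ya <- -b * sqrt(max(0, 1 - (xa / a)^2))  # body posterior surface at xa
  post_depth <- 8
  sides <- list()
  for (side in c("L", "R")) {
    sgn <- if (side == "L") -1 else 1
    u <- normalize3(c(-sgn * sin(th), cos(th), 0))  # converges to midline
    attach <- c(sgn * xa, ya, 0)
    mouth <- attach - spec$pedicle_length_mm * u
    sides[[side]] <- list(sign = sgn, dir = u, attach = attach, mouth = mouth)
  }
  y_front <- min(sides$L$mouth[2], sides$R$mouth[2])  # posterior-elements face
  y_back <- y_front - post_depth
  x_post <- max(abs(sides$L$mouth[1]), abs(sides$R$mouth[1])) +
    spec$pedicle_width_mm / 2 + spec$cortex_thickness_mm + 2
  z_post <- spec$pedicle_height_mm / 2 + spec$cortex_thickness_mm + 5
  for (side in c("L", "R")) {
    s <- sides[[side]]
    # entry disc center: pedicle axis extended back to the posterior face
    t_back <- (s$mouth[2] - y_back) / s$dir[2]
    sides[[side]]$disc_center <- s$mouth - t_back * s$dir
  }
  list(a = a, b = b, hz = hz, xa = xa, ya = ya, theta = th,
       post_depth = post_depth, y_front = y_front, y_back = y_back,
       x_post = x_post, z_post = z_post, sides = sides)
}

#' Generate a synthetic vertebra phantom
#'
#' Builds the co-registered intensity volume and anatomical label map for a
#' [phantom_spec()], together with the exact analytic ground truth every
#' downstream measurement can be checked against.
#'
#' @param spec A [phantom_spec()].
#' @param center_offset_mm Optional rigid translation (mm) of all solids
#'   relative to the voxel grid; useful for testing translation invariance.
#' @return A list of class `vertebra_phantom` with elements `volume`
#'   ([image_volume]), `labels` ([anatomy_label_map]), `truth` (analytic
#'   geometry: per-side axis, corridor width `W`, entry disc, anterior depth,
#'   endplate planes) and `spec`.
#' @export
make_phantom <- function(spec, center_offset_mm = c(0, 0, 0)) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  validate_phantom_spec(spec)
  geo <- phantom_geometry(spec)
  sp <- spec$voxel_spacing_mm
  off <- as.numeric(center_offset_mm)
  cx <- spec$cortex_thickness_mm
  pad <- 2.5

  # grid extents (world, before offset)
  xr <- c(-1, 1) * (max(geo$a, geo$x_post) + pad)
  yr <- c(geo$y_back - 2 * sp[2] - pad, geo$b + pad)
  zr <- c(-1, 1) * (geo$hz + pad)
  nx <- ceiling(diff(xr) / sp[1]) + 1L
  ny <- ceiling(diff(yr) / sp[2]) + 1L
  nz <- ceiling(diff(zr) / sp[3]) + 1L
  origin <- c(xr[1], yr[1], zr[1]) + off
  dims <- c(nx, ny, nz)

  # voxel center coordinates relative to the (offset) phantom frame
  xs <- origin[1] + (seq_len(nx) - 1) * sp[1] - off[1]
  ys <- origin[2] + (seq_len(ny) - 1) * sp[2] - off[2]
  zs <- origin[3] + (seq_len(nz) - 1) * sp[3] - off[3]
  X <- array(rep(xs, times = ny * nz), dim = dims)
  Y <- array(rep(rep(ys, each = nx), times = nz), dim = dims)
  Z <- array(rep(zs, each = nx * ny), dim = dims)

  codes <- label_codes()
  lab <- array(codes[["BACKGROUND"]], dim = dims)

  # vertebral body: outer ellipse, endplates, shell, trabecular core
  ell_out <- (X / geo$a)^2 + (Y / geo$b)^2 <= 1
  in_z <- abs(Z) <= geo$hz
  body <- ell_out & in_z
  ell_in <- (X / (geo$a - cx))^2 + (Y / (geo$b - cx))^2 <= 1
  sup <- body & Z >= geo$hz - cx
  inf <- body & Z <= -(geo$hz - cx)
  lab[body] <- codes[["CORTICAL_SHELL"]]
  lab[body & ell_in & !sup & !inf] <- codes[["TRABECULAR_BODY"]]
  lab[sup] <- codes[["ENDPLATE_SUP"]]
  lab[inf] <- codes[["ENDPLATE_INF"]]

  # posterior elements slab
  post <- abs(X) <= geo$x_post & Y >= geo$y_back & Y <= geo$y_front &
    abs(Z) <= geo$z_post
  lab[post & lab == codes[["BACKGROUND"]]] <- codes[["POSTERIOR_ELEMENTS"]]

  # Pedicle corridors and their cortical wall rings. The corridor tube is
  # carved a few millimetres past its attachment into the body so that the
  # label is a complete elliptic tube with flat caps: the oblique body
  # surface would otherwise leave crescent-shaped junction slivers that bias
  # axis and width estimation. The carve depth follows the local slope of
  # the body ellipse so the tube's lateral edge is fully swallowed.
  wr <- spec$pedicle_width_mm / 2
  hr <- spec$pedicle_height_mm / 2
  slope <- geo$b * geo$xa / (geo$a^2 * sqrt(max(0.05, 1 - (geo$xa / geo$a)^2)))
  body_codes <- codes[c("TRABECULAR_BODY", "CORTICAL_SHELL",
                        "ENDPLATE_SUP", "ENDPLATE_INF")]
  for (side in c("L", "R")) {
    s <- geo$sides[[side]]
    dx <- X - s$mouth[1]
    dy <- Y - s$mouth[2]
    t <- dx * s$dir[1] + dy * s$dir[2]
    dw <- dx * s$dir[2] - dy * s$dir[1]   # horizontal offset from axis
    len_core <- spec$pedicle_length_mm + slope * wr + 1.5
    len_ring <- spec$pedicle_length_mm + slope * (wr + cx) + 1.5
    core <- t >= 0 & t <= len_core & (dw / wr)^2 + (Z / hr)^2 <= 1
    ring <- t >= -2 & t <= len_ring &
      (dw / (wr + cx))^2 + (Z / (hr + cx))^2 <= 1 & !core
    lab[core & (lab == codes[["BACKGROUND"]] | lab %in% body_codes)] <-
      codes[[paste0("PEDICLE_", side)]]
    lab[ring & lab == codes[["BACKGROUND"]]] <- codes[["CORTICAL_SHELL"]]
  }

  # entry discs: one-voxel layer just posterior to the posterior surface
  j_back <- which(ys >= geo$y_back)[1]
  if (is.na(j_back) || j_back < 2L) {
    stop_pedplan("geometry_infeasible", "no room for the entry disc layer")
  }
  j_disc <- j_back - 1L
  y_disc <- ys[j_disc]
  truth_sides <- list()
  for (side in c("L", "R")) {
    s <- geo$sides[[side]]
    tctr <- (s$mouth[2] - y_disc) / s$dir[2]
    ctr <- s$mouth - tctr * s$dir
    sel_xz <- outer((xs - ctr[1])^2, (zs - ctr[3])^2, "+") <=
      spec$entry_disc_radius_mm^2
    sel <- array(FALSE, dim = dims)
    sel[, j_disc, ][sel_xz] <- TRUE
    sel <- sel & lab == codes[["BACKGROUND"]]
    lab[sel] <- codes[[paste0("ENTRY_DISC_", side)]]
    # analytic anterior depth: from the disc center along the axis to the
    # outer (anterior) body surface
    qa <- (s$dir[1] / geo$a)^2 + (s$dir[2] / geo$b)^2
    qb <- 2 * (ctr[1] * s$dir[1] / geo$a^2 + ctr[2] * s$dir[2] / geo$b^2)
    qc <- (ctr[1] / geo$a)^2 + (ctr[2] / geo$b)^2 - 1
    disc_rad <- qb^2 - 4 * qa * qc
    depth <- if (disc_rad <= 0) NA_real_ else (-qb + sqrt(disc_rad)) / (2 * qa)
    truth_sides[[side]] <- list(
      axis_point_mm = s$mouth + off, axis_dir = s$dir,
      width_mm = spec$pedicle_width_mm,
      height_mm = spec$pedicle_height_mm,
      entry_center_mm = ctr + off,
      entry_radius_mm = spec$entry_disc_radius_mm,
      anterior_depth_mm = depth)
  }

  # connectivity check: each corridor must touch posterior elements and body
  for (side in c("L", "R")) {
    ped <- codes[[paste0("PEDICLE_", side)]]
    if (!any(lab == ped)) {
      stop_pedplan("geometry_infeasible",
                   sprintf("pedicle corridor %s does not fit in the grid", side))
    }
  }

  truth <- structure(list(
    sides = truth_sides,
    endplate_z_mm = c(sup_inner = geo$hz - cx, sup_outer = geo$hz,
                      inf_inner = -(geo$hz - cx), inf_outer = -geo$hz) + off[3],
    body_center_mm = off,
    spec = spec), class = "phantom_truth")

  # intensities: compartment mean + Gaussian noise, seeded
  mean_hu <- c(spec$intensity_background_hu,  # BACKGROUND
               spec$intensity_trabecular_hu,  # TRABECULAR_BODY
               spec$intensity_cortical_hu,    # CORTICAL_SHELL
               spec$intensity_trabecular_hu,  # PEDICLE_L
               spec$intensity_trabecular_hu,  # PEDICLE_R
               spec$intensity_cortical_hu,    # ENDPLATE_SUP
               spec$intensity_cortical_hu,    # ENDPLATE_INF
               spec$intensity_trabecular_hu,  # POSTERIOR_ELEMENTS
               spec$intensity_background_hu,  # ENTRY_DISC_L
               spec$intensity_background_hu)  # ENTRY_DISC_R
  vol_data <- array(mean_hu[lab + 1L], dim = dims)
  if (spec$noise_sd_hu > 0) {
    vol_data <- vol_data + with_preserved_rng(spec$rng_seed, {
      array(rnorm(prod(dims), 0, spec$noise_sd_hu), dim = dims)
    })
  }

  structure(list(
    volume = image_volume(vol_data, sp, origin),
    labels = anatomy_label_map(lab, sp, origin),
    truth = truth, spec = spec), class = "vertebra_phantom")
}

with_preserved_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.vertebra_phantom <- function(x, ...) {
  cat(sprintf(
    "<vertebra_phantom> W = %.2f mm, pedicle length %.1f mm, angle %.1f deg\n",
    x$spec$pedicle_width_mm, x$spec$pedicle_length_mm,
    x$spec$pedicle_transverse_angle_deg))
  print(x$labels)
  invisible(x)
}

#' Generate a cohort of phantoms with parameters drawn from ranges
#'
#' Emulates anatomical variability across a surgical cohort: each phantom's
#' spec fields are drawn independently and uniformly from the supplied ranges.
#'
#' @param n Number of phantoms (>= 1).
#' @param spec_ranges Named list; each element is either a length-1 value or a
#'   `c(min, max)` range for the corresponding [phantom_spec()] argument.
#'   Unnamed fields keep their defaults. Unless overridden,
#'   `pedicle_height_mm` tracks the drawn width (+2 mm).
#' @param seed Integer seed; the cohort (specs and per-phantom noise seeds) is
#'   reproducible from it.
#' @return List of `vertebra_phantom` objects; the drawn specs are attached as
#'   a tibble in `attr(, "specs")`.
#' @export
make_cohort <- function(n, spec_ranges = list(pedicle_width_mm = c(7, 13)),
                        seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop_pedplan("config_error", "`n` must be a positive integer")
  }
  if (length(spec_ranges) > 0 &&
      (is.null(names(spec_ranges)) || any(names(spec_ranges) == ""))) {
    stop_pedplan("config_error", "`spec_ranges` must be a fully named list")
  }
  bad <- setdiff(names(spec_ranges), names(formals(phantom_spec)))
  if (length(bad) > 0) {
    stop_pedplan("config_error", sprintf(
      "unknown phantom_spec field(s): %s", paste(bad, collapse = ", ")))
  }
  for (nm in names(spec_ranges)) {
    r <- spec_ranges[[nm]]
    if (!is.numeric(r) || !length(r) %in% 1:2 || any(!is.finite(r)) ||
        (length(r) == 2 && r[2] < r[1])) {
      stop_pedplan("config_error", sprintf("invalid range for `%s`", nm))
    }
  }
  draws <- with_preserved_rng(seed, {
    vals <- lapply(seq_len(n), function(i) {
      lapply(spec_ranges, function(r) {
        if (length(r) == 1L || r[1] == r[2]) r[1] else runif(1, r[1], r[2])
      })
    })
    seeds <- sample.int(.Machine$integer.max, n)
    list(vals = vals, seeds = seeds)
  })
  phantoms <- vector("list", n)
  specs <- vector("list", n)
  for (i in seq_len(n)) {
    args <- draws$vals[[i]]
    args$rng_seed <- draws$seeds[i]
    spec <- do.call(phantom_spec, args)
    specs[[i]] <- spec
    phantoms[[i]] <- make_phantom(spec)
  }
  attr(phantoms, "specs") <- dplyr::bind_rows(lapply(specs, function(s) {
    tibble::as_tibble(lapply(unclass(s), function(v) {
      if (length(v) > 1) list(v) else v
    }))
  }))
  phantoms
}

#' Perturb a screw pose with Gaussian noise
#'
#' Emulates freehand insertion deviation: the entry point receives isotropic
#' Gaussian translation noise and the direction is rotated about a random
#' perpendicular axis by a Gaussian angle, then renormalized. Length and
#' diameter are unchanged.
#'
#' @param screw A [screw_spec()].
#' @param translation_sd_mm SD of the entry translation per axis, mm (>= 0).
#' @param rotation_sd_deg SD of the rotation angle, degrees (>= 0).
#' @param seed Integer seed.
#' @return A perturbed [screw_spec()].
#' @export
perturb_screw <- function(screw, translation_sd_mm, rotation_sd_deg, seed = 1L) {
  check_number(translation_sd_mm, "translation_sd_mm", min = 0)
  check_number(rotation_sd_deg, "rotation_sd_deg", min = 0)
  stopifnot(inherits(screw, "screw_spec"))
  with_preserved_rng(seed, {
    entry <- screw$entry_mm + rnorm(3, 0, translation_sd_mm)
    dir <- screw$direction
    if (rotation_sd_deg > 0) {
      g <- rnorm(3)
      axis_raw <- g - sum(g * dir) * dir
      while (sqrt(sum(axis_raw^2)) < 1e-9) { # astronomically unlikely redraw
        g <- rnorm(3)
        axis_raw <- g - sum(g * dir) * dir
      }
      k <- normalize3(axis_raw)
      ang <- rnorm(1, 0, rotation_sd_deg) * pi / 180
      dir <- dir * cos(ang) + cross3(k, dir) * sin(ang) +
        k * sum(k * dir) * (1 - cos(ang))
    }
    screw_spec(side = screw$side, entry_mm = entry, direction = normalize3(dir),
               length_mm = screw$length_mm, diameter_mm = screw$diameter_mm)
  })
}
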