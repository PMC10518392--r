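# File interchange: NIfTI-1 volumes/label maps (via RNifti), JSON plan
# documents, JSON screw lists, CSV grade tables, YAML run configuration.

nifti_from_grid <- function(grid, datatype) {
  img <- RNifti::asNifti(grid$data)
  RNifti::pixdim(img) <- grid$spacing_mm
  aff <- diag(4)
  diag(aff)[1:3] <- grid$spacing_mm
  aff[1:3, 4] <- grid$origin_mm
  RNifti::`sform<-`(img, structure(aff, code = 2L))
}

grid_meta_from_nifti <- function(img) {
  aff <- RNifti::xform(img, useQuaternionFirst = FALSE)
  list(spacing = as.numeric(RNifti::pixdim(img)),
       origin = as.numeric(aff[1:3, 4]))
}

#' Read and write volumes and label maps as NIfTI-1
#'
#' Voxel spacing and world origin travel in the NIfTI header (pixdim and an
#' axis-aligned sform). Label maps are stored as int16 and validated against
#' the [label_codes()] vocabulary on read.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param volume,labels Objects to write.
#' @return `read_volume()` an [image_volume()]; `read_labels()` an
#'   [anatomy_label_map()]; the writers return `path` invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) {
    stop_pedplan("unsupported_shape", sprintf(
      "expected a 3-D volume, got %d dimensions", length(dim(arr))))
  }
  meta <- grid_meta_from_nifti(img)
  image_volume(array(as.numeric(arr), dim = dim(arr)), meta$spacing, meta$origin)
}

#' @rdname read_volume
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "image_volume"))
  RNifti::writeNifti(nifti_from_grid(volume, "double"), path,
                     datatype = "double")
  invisible(path)
}

#' @rdname read_volume
#' @export
read_labels <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) {
    stop_pedplan("unsupported_shape", sprintf(
      "expected a 3-D label map, got %d dimensions", length(dim(arr))))
  }
  meta <- grid_meta_from_nifti(img)
  anatomy_label_map(array(as.numeric(arr), dim = dim(arr)),
                    meta$spacing, meta$origin)
}

#' @rdname read_volume
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "anatomy_label_map"))
  RNifti::writeNifti(nifti_from_grid(labels, "int16"), path,
                     datatype = "int16")
  invisible(path)
}

# ---- plan documents --------------------------------------------------------

PLAN_SCHEMA_VERSION <- 1L

screw_to_list <- function(screw) {
  list(side = screw$side, entry_mm = screw$entry_mm,
       direction = screw$direction, length_mm = screw$length_mm,
       diameter_mm = screw$diameter_mm)
}

screw_from_list <- function(x) {
  screw_spec(x$side, as.numeric(unlist(x$entry_mm)),
             as.numeric(unlist(x$direction)),
             as.numeric(x$length_mm), as.numeric(x$diameter_mm))
}

plan_to_list <- function(plan) {
  if (inherits(plan, "screw_plan")) {
    list(status = "ok",
         screw = screw_to_list(plan$screw),
         score = list(bmd_mean_hu = plan$score$bmd_mean_hu,
                      pof_proxy = plan$score$pof_proxy),
         constraints = unclass(plan$constraints),
         n_candidates_evaluated = plan$n_candidates_evaluated,
         width_mm = plan$width_mm)
  } else {
    list(status = "error",
         error_class = class(plan)[1],
         message = conditionMessage(plan))
  }
}

#' Build, write and read plan documents
#'
#' A plan document bundles the per-side planning result with provenance
#' (input paths and MD5 checksums) and the configuration used, and
#' round-trips losslessly through JSON.
#'
#' @param plans A [plan_vertebra()] result (or a list with elements `L`/`R`
#'   of `screw_plan` or error conditions).
#' @param volume_path,labels_path Paths of the inputs the plan was computed
#'   from (checksummed when they exist).
#' @param config The [plan_config()] used.
#' @param doc,path A plan document and a JSON file path.
#' @return `plan_document()` / `read_plan()` a list of class
#'   `plan_document`; `write_plan()` returns `path` invisibly.
#' @export
plan_document <- function(plans, volume_path = NA_character_,
                          labels_path = NA_character_,
                          config = plan_config()) {
  checksum <- function(p) {
    if (is.character(p) && !is.na(p) && file.exists(p)) {
      unname(tools::md5sum(p))
    } else NA_character_
  }
  structure(list(
    schema_version = PLAN_SCHEMA_VERSION,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    provenance = list(
      volume_path = volume_path, volume_md5 = checksum(volume_path),
      labels_path = labels_path, labels_md5 = checksum(labels_path)),
    config = unclass(config),
    sides = lapply(plans, plan_to_list)),
    class = "plan_document")
}

#' @rdname plan_document
#' @export
write_plan <- function(doc, path) {
  stopifnot(inherits(doc, "plan_document"))
  jsonlite::write_json(unclass(doc), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname plan_document
#' @export
read_plan <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (is.null(raw$schema_version) ||
      raw$schema_version != PLAN_SCHEMA_VERSION) {
    stop_pedplan("format_error", sprintf(
      "unsupported plan schema version %s (expected %d)",
      raw$schema_version %||% "<missing>", PLAN_SCHEMA_VERSION))
  }
  raw$schema_version <- as.integer(raw$schema_version)
  raw$sides <- lapply(raw$sides, function(s) {
    s$n_candidates_evaluated <-
      if (!is.null(s$n_candidates_evaluated)) as.integer(s$n_candidates_evaluated)
    s
  })
  structure(raw, class = "plan_document")
}

#' Verify that a plan document matches its input files
#'
#' Emits a provenance warning (class `pedplan_provenance`) when a recorded
#' checksum does not match the file currently on disk, e.g. when grading a
#' plan against a different label map than it was computed from.
#'
#' @param doc A plan document.
#' @param labels_path,volume_path Paths to check against the recorded MD5s.
#' @return TRUE (invisibly) when everything matches, FALSE otherwise.
#' @export
verify_plan_provenance <- function(doc, labels_path = NULL, volume_path = NULL) {
  ok <- TRUE
  chk <- function(path, recorded, what) {
    if (is.null(path) || is.na(recorded)) return(TRUE)
    now <- unname(tools::md5sum(path))
    if (!identical(now, recorded)) {
      warn_pedplan("provenance", sprintf(
        "%s checksum mismatch: plan was computed from a different file", what))
      return(FALSE)
    }
    TRUE
  }
  ok <- chk(labels_path, doc$provenance$labels_md5, "labels") && ok
  ok <- chk(volume_path, doc$provenance$volume_md5, "volume") && ok
  invisible(ok)
}

# ---- screws and grades -----------------------------------------------------

#' Read screw poses from JSON
#'
#' Accepts either a planner [plan_document()] (planned sides become screws)
#' or a hand-written list of poses
#' (`[{"side": "L", "entry_mm": [...], "direction": [...],
#' "length_mm": 45, "diameter_mm": 6.5}, ...]`).
#'
#' @param path JSON file.
#' @return Named list of [screw_spec()] objects.
#' @export
read_screws <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!is.null(raw$schema_version)) {       # a plan document
    doc <- read_plan(path)
    screws <- list()
    for (s in names(doc$sides)) {
      if (identical(doc$sides[[s]]$status, "ok")) {
        screws[[s]] <- screw_from_list(doc$sides[[s]]$screw)
      }
    }
    if (length(screws) == 0L) {
      stop_pedplan("format_error", "plan document contains no planned screws")
    }
    return(screws)
  }
  if (length(raw) == 0L) stop_pedplan("format_error", "no screws in file")
  out <- lapply(raw, screw_from_list)
  names(out) <- names(raw) %||% as.character(seq_along(out))
  out
}

#' @rdname read_screws
#' @param screws Named list of [screw_spec()] objects.
#' @export
write_screws <- function(screws, path) {
  jsonlite::write_json(lapply(screws, screw_to_list), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read and write grade tables as CSV
#'
#' Columns: `id`, `side`, `depth_mm`, `grade` (plus any extra columns such
#' as `length_mm`/`diameter_mm` for dimension comparisons). Comma-separated,
#' header row, '.' decimal, UTF-8.
#'
#' @param grades Data frame of grades.
#' @param path CSV file path.
#' @return `read_grades()` a tibble; `write_grades()` returns `path`.
#' @export
write_grades <- function(grades, path) {
  write.csv(grades, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_grades
#' @export
read_grades <- function(path) {
  df <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE,
                                   fileEncoding = "UTF-8"))
  if (!all(c("id", "side", "grade") %in% names(df))) {
    stop_pedplan("format_error", "grades CSV needs id, side, grade columns")
  }
  df$id <- as.character(df$id)
  df
}

#' Read a run configuration from YAML
#'
#' Recognized top-level keys: `catalog` (`lengths_mm`, `diameters_mm`),
#' `planner` (arguments of [plan_config()]), `phantom` (arguments of
#' [phantom_spec()]), `grading` (`surface_step_mm`, `epsilon_mm`). All keys
#' are optional; values are validated by the respective constructors.
#'
#' @param path YAML file.
#' @return List with elements `catalog`, `planner`, `phantom_args`,
#'   `grading`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop_pedplan("format_error", "config must be a YAML map")
  known <- c("catalog", "planner", "phantom", "grading")
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0L) {
    stop_pedplan("config_error", sprintf(
      "unknown config section(s): %s", paste(bad, collapse = ", ")))
  }
  catalog <- if (!is.null(raw$catalog)) {
    screw_catalog(
      allowed_lengths_mm = raw$catalog$lengths_mm %||% seq(30, 65, 5),
      allowed_diameters_mm = raw$catalog$diameters_mm %||% seq(5, 7.5, 0.5))
  } else screw_catalog()
  planner <- do.call(plan_config, raw$planner %||% list())
  grading <- raw$grading %||% list()
  if (!is.null(grading$surface_step_mm)) {
    check_number(grading$surface_step_mm, "surface_step_mm",
                 min = 0, strict_min = TRUE)
  }
  if (!is.null(grading$epsilon_mm)) {
    check_number(grading$epsilon_mm, "epsilon_mm", min = 0, max = 2)
  }
  list(catalog = catalog, planner = planner,
       phantom_args = raw$phantom %||% list(), grading = grading)
}
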