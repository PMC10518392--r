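# broom-style tidiers for the package's result objects.

#' @rdname pedplan_tidiers
#' @method tidy paired_t_test
#' @export
tidy.paired_t_test <- function(x, ...) {
  tibble::tibble(estimate = x$mean_diff, statistic = x$statistic,
                 p.value = x$p_value, parameter = x$df, n = x$n,
                 method = "paired t-test", alternative = "two.sided")
}

#' @rdname pedplan_tidiers
#' @method tidy fisher_exact_test
#' @export
tidy.fisher_exact_test <- function(x, ...) {
  tibble::tibble(estimate = x$odds_ratio, p.value = x$p_value,
                 method = "Fisher's exact test (2x2)",
                 alternative = "two.sided")
}

#' Tidiers for planning and grading results
#'
#' `tidy()` returns one row per result with the quantities a downstream
#' analysis consumes; `glance()` on a [compare_groups()] result returns the
#' one-row model summary (grade-A proportions and the Fisher p-value).
#'
#' @param x A result object.
#' @param ... Unused.
#' @name pedplan_tidiers
#' @method tidy screw_plan
#' @export
tidy.screw_plan <- function(x, ...) {
  tibble::tibble(
    side = x$side, length_mm = x$screw$length_mm,
    diameter_mm = x$screw$diameter_mm, width_mm = x$width_mm,
    bmd_mean_hu = x$score$bmd_mean_hu, pof_proxy = x$score$pof_proxy,
    medial_clearance_mm = x$constraints$medial_clearance_mm,
    inferior_clearance_mm = x$constraints$inferior_clearance_mm,
    n_candidates = x$n_candidates_evaluated,
    entry_x = x$screw$entry_mm[1], entry_y = x$screw$entry_mm[2],
    entry_z = x$screw$entry_mm[3],
    dir_x = x$screw$direction[1], dir_y = x$screw$direction[2],
    dir_z = x$screw$direction[3])
}

#' @rdname pedplan_tidiers
#' @method tidy vertebra_plan
#' @export
tidy.vertebra_plan <- function(x, ...) {
  purrr::imap(unclass(x), function(p, s) {
    if (inherits(p, "screw_plan")) tidy(p)
    else tibble::tibble(side = s, length_mm = NA_real_, diameter_mm = NA_real_)
  }) |> dplyr::bind_rows()
}

#' @rdname pedplan_tidiers
#' @method tidy gr_result
#' @export
tidy.gr_result <- function(x, ...) {
  tibble::tibble(depth_mm = x$breach_depth_mm, grade = x$grade)
}

#' @rdname pedplan_tidiers
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) {
  if (is.null(x$dimensions)) {
    tibble::tibble()
  } else {
    x$dimensions
  }
}

#' @rdname pedplan_tidiers
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  ov <- x$grades$overall
  tibble::tibble(
    prop_a_pct_a = ov$prop_a_pct[match(x$group_names[1], ov$group)],
    prop_a_pct_b = ov$prop_a_pct[match(x$group_names[2], ov$group)],
    fisher_p = x$fisher$p_value,
    n_a = sum(x$table[1, ]), n_b = sum(x$table[2, ]))
}
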