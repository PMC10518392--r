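# Group-comparison statistics: paired t-test on screw dimensions, Fisher's
# exact test on grade-A proportions, and grade summaries. The tests are
# implemented from their formulas (the package's contract), not by
# delegating to stats::t.test / stats::fisher.test -- those serve as
# independent cross-checks in the test suite.

#' Paired t-test (from the formula)
#'
#' For paired observations the statistic is
#' `t = mean(d) / (sd(d) / sqrt(n))` with `d = a - b` and `df = n - 1`;
#' the p-value is the two-sided tail of the t distribution.
#'
#' @param values_a,values_b Equal-length numeric vectors, paired by index.
#' @return Object of class `paired_t_test`: `statistic`, `df`, `p_value`,
#'   `mean_diff`, `n`.
#' @export
paired_t <- function(values_a, values_b) {
  if (!is.numeric(values_a) || !is.numeric(values_b) ||
      length(values_a) != length(values_b) || length(values_a) < 2L ||
      any(!is.finite(values_a)) || any(!is.finite(values_b))) {
    stop_pedplan("input_error",
                 "paired samples must be equal-length finite vectors (n >= 2)")
  }
  d <- values_a - values_b
  s <- sd(d)
  if (s == 0) {
    stop_pedplan("degenerate_test",
                 "all paired differences are identical (zero variance)")
  }
  n <- length(d)
  t_stat <- mean(d) / (s / sqrt(n))
  structure(list(statistic = t_stat, df = n - 1,
                 p_value = 2 * pt(-abs(t_stat), df = n - 1),
                 mean_diff = mean(d), n = n),
            class = "paired_t_test")
}

#' @export
print.paired_t_test <- function(x, ...) {
  cat(sprintf("Paired t-test: t = %.4f, df = %d, p = %.4g (mean diff %.3f)\n",
              x$statistic, x$df, x$p_value, x$mean_diff))
  invisible(x)
}

#' Fisher's exact test for a 2x2 table (from the hypergeometric formula)
#'
#' Two-sided p-value under the probability-ordering definition: the sum of
#' hypergeometric probabilities, over all tables with the observed margins,
#' that do not exceed the observed table's probability. Probabilities are
#' computed through log-factorials.
#'
#' @param table 2x2 matrix of non-negative integer counts (rows = groups,
#'   columns = outcome), or the four counts `a11, a12, a21, a22`.
#' @param a12,a21,a22 Optional scalar counts when `table` is given as `a11`.
#' @return Object of class `fisher_exact_test`: `p_value`, `table`,
#'   `odds_ratio` (sample odds ratio).
#' @export
fisher_exact_2x2 <- function(table, a12 = NULL, a21 = NULL, a22 = NULL) {
  if (!is.null(a12)) table <- matrix(c(table, a21, a12, a22), 2, 2)
  if (!is.matrix(table) || !all(dim(table) == 2L)) {
    stop_pedplan("input_error", "need a 2x2 table of counts")
  }
  x <- as.vector(table)
  if (any(!is.finite(x)) || any(x < 0) || any(x != round(x))) {
    stop_pedplan("input_error", "counts must be non-negative integers")
  }
  if (sum(x) == 0) stop_pedplan("degenerate_test", "all-zero table")
  a <- table[1, 1]
  r1 <- sum(table[1, ]); c1 <- sum(table[, 1]); n <- sum(table)
  klo <- max(0, r1 + c1 - n); khi <- min(r1, c1)
  k <- klo:khi
  lp <- lgamma(r1 + 1) - lgamma(k + 1) - lgamma(r1 - k + 1) +
    lgamma(n - r1 + 1) - lgamma(c1 - k + 1) - lgamma(n - r1 - c1 + k + 1) -
    (lgamma(n + 1) - lgamma(c1 + 1) - lgamma(n - c1 + 1))
  lp_obs <- lp[k == a]
  p <- sum(exp(lp[lp <= lp_obs + 1e-7]))
  structure(list(p_value = min(1, p), table = table,
                 odds_ratio = (table[1, 1] * table[2, 2]) /
                   (table[1, 2] * table[2, 1])),
            class = "fisher_exact_test")
}

#' @export
print.fisher_exact_test <- function(x, ...) {
  cat(sprintf("Fisher's exact test (2x2): p = %.4g\n", x$p_value))
  invisible(x)
}

#' Summarize Gertzbein-Robbins grades by group and side
#'
#' @param grades Data frame with columns `group`, `side` (`"L"`/`"R"`), and
#'   `grade` (`"A"`..`"E"`); one row per screw placement.
#' @return Object of class `grade_summary`: `counts` (group x side x grade
#'   counts, wide), `by_side` (per-side grade-A proportions), `overall`
#'   (per-group grade-A proportions). Proportions are stored in percent at
#'   full precision and printed to 2 decimals.
#' @export
summarize_grades <- function(grades) {
  if (!is.data.frame(grades) || nrow(grades) == 0L ||
      !all(c("group", "side", "grade") %in% names(grades))) {
    stop_pedplan("input_error",
                 "`grades` needs columns group, side, grade (>= 1 row)")
  }
  grades <- tibble::as_tibble(grades)
  if (!all(grades$grade %in% c("A", "B", "C", "D", "E"))) {
    stop_pedplan("input_error", "grades must be letters A-E")
  }
  if (!all(grades$side %in% c("L", "R"))) {
    stop_pedplan("input_error", "sides must be 'L' or 'R'")
  }
  counts <- grades |>
    dplyr::count(.data$group, .data$side, .data$grade) |>
    tidyr::complete(.data$group, .data$side,
                    grade = c("A", "B", "C", "D", "E"),
                    fill = list(n = 0L)) |>
    tidyr::pivot_wider(names_from = "grade", values_from = "n") |>
    dplyr::mutate(n = .data$A + .data$B + .data$C + .data$D + .data$E)
  by_side <- counts |>
    dplyr::filter(.data$n > 0) |>
    dplyr::transmute(.data$group, .data$side, n_a = .data$A, n = .data$n,
                     prop_a_pct = 100 * .data$A / .data$n)
  overall <- by_side |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n_a = sum(.data$n_a), n = sum(.data$n),
                     prop_a_pct = 100 * sum(.data$n_a) / sum(.data$n),
                     .groups = "drop")
  structure(list(counts = counts, by_side = by_side, overall = overall),
            class = "grade_summary")
}

#' @export
print.grade_summary <- function(x, ...) {
  cat("Gertzbein-Robbins grade summary\n")
  print(as.data.frame(x$counts), row.names = FALSE)
  cat("\nGrade-A proportion by side:\n")
  bs <- x$by_side
  for (i in seq_len(nrow(bs))) {
    cat(sprintf("  %-10s %s  %3d/%3d  %.2f%%\n", bs$group[i], bs$side[i],
                bs$n_a[i], bs$n[i], bs$prop_a_pct[i]))
  }
  cat("Overall:\n")
  ov <- x$overall
  for (i in seq_len(nrow(ov))) {
    cat(sprintf("  %-10s    %3d/%3d  %.2f%%\n", ov$group[i],
                ov$n_a[i], ov$n[i], ov$prop_a_pct[i]))
  }
  invisible(x)
}

#' Grade counts from a published clinical comparison
#'
#' Per-side Gertzbein-Robbins grade counts reported by a published clinical
#' evaluation of AI-planned versus freehand pedicle screw placement
#' (208 screws per arm, thoracolumbar segments). Shipped as a plain-text
#' fixture so the headline proportions and the Fisher test can be reproduced
#' without clinical data.
#'
#' @return `published_grade_counts()`: tibble `group`, `side`, `grade`, `n`.
#'   `published_screw_grades()`: the same counts expanded to one row per
#'   screw (columns `group`, `side`, `grade`).
#' @export
published_grade_counts <- function() {
  path <- system.file("extdata", "published_grade_counts.json",
                      package = "pedplan", mustWork = TRUE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  purrr::imap(raw$counts, function(sides, grp) {
    purrr::imap(sides, function(cnt, side) {
      tibble::tibble(group = grp, side = side, grade = names(cnt),
                     n = as.integer(unlist(cnt)))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

#' @rdname published_grade_counts
#' @export
published_screw_grades <- function() {
  published_grade_counts() |>
    tidyr::uncount(.data$n) |>
    dplyr::select("group", "side", "grade")
}

#' Compare two cohorts of screw placements
#'
#' Reproduces the comparison a clinical evaluation would run: paired t-tests
#' on screw length and diameter (per side and pooled; pairing by `id` +
#' `side`), and Fisher's exact test on grade-A versus other placements.
#'
#' @param group_a,group_b Data frames with columns `id`, `side`, `grade` and
#'   (for the dimension tests) `length_mm`, `diameter_mm`.
#' @param group_names Length-2 character: display names of the two groups.
#' @return Object of class `group_comparison`: `dimensions` (tibble of
#'   paired-t rows; `NULL` when dimensions are absent), `grades`
#'   ([summarize_grades()] result), `fisher` ([fisher_exact_2x2()] result on
#'   A vs other), `table` (the 2x2 counts).
#' @export
compare_groups <- function(group_a, group_b, group_names = c("ai", "freehand")) {
  for (g in list(group_a, group_b)) {
    if (!is.data.frame(g) || !all(c("id", "side", "grade") %in% names(g))) {
      stop_pedplan("input_error", "each group needs columns id, side, grade")
    }
  }
  ga <- tibble::as_tibble(group_a); gb <- tibble::as_tibble(group_b)
  grades <- dplyr::bind_rows(
    dplyr::mutate(ga, group = group_names[1]),
    dplyr::mutate(gb, group = group_names[2])) |>
    dplyr::select("group", "side", "grade")
  gs <- summarize_grades(grades)
  tab <- matrix(c(sum(ga$grade == "A"), sum(gb$grade == "A"),
                  sum(ga$grade != "A"), sum(gb$grade != "A")), 2, 2,
                dimnames = list(group_names, c("A", "other")))
  fish <- fisher_exact_2x2(tab)

  dims <- NULL
  have_dims <- all(c("length_mm", "diameter_mm") %in% names(ga)) &&
    all(c("length_mm", "diameter_mm") %in% names(gb))
  if (have_dims) {
    if (anyDuplicated(ga[c("id", "side")]) || anyDuplicated(gb[c("id", "side")])) {
      stop_pedplan("pairing_error", "duplicate id/side pairs in a group")
    }
    paired <- dplyr::inner_join(ga, gb, by = c("id", "side"),
                                suffix = c("_a", "_b"))
    if (nrow(paired) < 2L || nrow(paired) < max(nrow(ga), nrow(gb))) {
      warn_pedplan("pairing_error", sprintf(
        "only %d of %d placements could be paired; dimension t-tests skipped",
        nrow(paired), max(nrow(ga), nrow(gb))))
    } else {
      slices <- c(list(pooled = paired), split(paired, paired$side))
      dims <- purrr::imap(slices, function(df, label) {
        purrr::map(c(length = "length_mm", diameter = "diameter_mm"),
                   function(col) {
          res <- tryCatch(paired_t(df[[paste0(col, "_a")]],
                                   df[[paste0(col, "_b")]]),
                          pedplan_degenerate_test = function(e) NULL)
          tibble::tibble(
            metric = sub("_mm$", "", col), side = label, n = nrow(df),
            mean_a = mean(df[[paste0(col, "_a")]]),
            mean_b = mean(df[[paste0(col, "_b")]]),
            mean_diff = mean(df[[paste0(col, "_a")]] -
                               df[[paste0(col, "_b")]]),
            t = if (is.null(res)) NA_real_ else res$statistic,
            df = nrow(df) - 1,
            p_value = if (is.null(res)) NA_real_ else res$p_value,
            note = if (is.null(res)) "degenerate" else "")
        }) |> dplyr::bind_rows()
      }) |> dplyr::bind_rows()
    }
  }
  structure(list(dimensions = dims, grades = gs, fisher = fish, table = tab,
                 group_names = group_names),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Comparison: %s vs %s\n\n", x$group_names[1], x$group_names[2]))
  if (!is.null(x$dimensions)) {
    cat("Screw dimensions (paired t):\n")
    print(as.data.frame(x$dimensions), row.names = FALSE, digits = 4)
    cat("\n")
  }
  print(x$grades)
  cat("\nGrade A vs other:\n")
  print(x$table)
  print(x$fisher)
  invisible(x)
}
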