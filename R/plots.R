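# ggplot2 graphics for the result types.

#' Plot a screw-axis reslice stack
#'
#' Displays each perpendicular reconstruction plane as a raster panel, with
#' the screw axis at the panel center. Intensity is mapped to a CT-like
#' gray scale.
#'
#' @param object A [reslice_along_axis()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot screw_reslice
#' @export
autoplot.screw_reslice <- function(object, ...) {
  dims <- dim(object)
  px <- attr(object, "pixel_mm")
  tt <- attr(object, "plane_t_mm")
  half <- (dims[1] - 1) / 2
  df <- purrr::map(seq_len(dims[3]), function(p) {
    tibble::tibble(
      u = rep((seq_len(dims[1]) - 1 - half) * px, times = dims[2]),
      v = rep((seq_len(dims[2]) - 1 - half) * px, each = dims[1]),
      hu = as.vector(object[, , p]),
      plane = sprintf("t = %.1f mm", tt[p]))
  }) |> dplyr::bind_rows()
  df$plane <- factor(df$plane, levels = unique(df$plane))
  ggplot2::ggplot(df, ggplot2::aes(.data$u, .data$v, fill = .data$hu)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 na.value = "grey20", name = "HU") +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~plane) +
    ggplot2::labs(x = "in-plane u (mm)", y = "in-plane v (mm)",
                  title = "Screw-axis cross-sections") +
    ggplot2::theme_minimal()
}

#' Plot a grade summary
#'
#' Stacked bars of Gertzbein-Robbins grade counts per group and side.
#'
#' @param object A [summarize_grades()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot grade_summary
#' @export
autoplot.grade_summary <- function(object, ...) {
  long <- object$counts |>
    tidyr::pivot_longer(cols = c("A", "B", "C", "D", "E"),
                        names_to = "grade", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(.data$side, .data$count,
                                     fill = .data$grade)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~group) +
    ggplot2::scale_fill_brewer(palette = "RdYlGn", direction = -1,
                               name = "GR grade") +
    ggplot2::labs(x = "side", y = "screw placements",
                  title = "Gertzbein-Robbins grade distribution") +
    ggplot2::theme_minimal()
}
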