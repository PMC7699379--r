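#' Plot per-horse total asymmetry trajectories
#'
#' Total asymmetry score over occasions, one line per horse; the
#' truncation point (per-horse maximum) marked.
#'
#' @param asymmetry Tibble `horse`, `occasion`, `score_mm` (from
#'   [asymmetry_score()] or `run_study()$asymmetry`).
#' @return A ggplot object.
#' @export
plot_asymmetry <- function(asymmetry) {
  df <- asymmetry |>
    dplyr::mutate(occasion = factor(.data$occasion,
                                    occasion_levels(.data$occasion)))
  peaks <- df |>
    dplyr::group_by(.data$horse) |>
    dplyr::slice_max(.data$score_mm, n = 1, with_ties = FALSE)
  ggplot2::ggplot(df, ggplot2::aes(.data$occasion, .data$score_mm,
                                   group = .data$horse,
                                   colour = .data$horse)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = peaks, shape = 21, size = 3, stroke = 1,
                        fill = "white") +
    ggplot2::labs(x = "occasion", y = "total asymmetry score (mm)",
                  colour = "horse") +
    ggplot2::theme_minimal()
}

#' Plot a reliability report
#'
#' Kendall's W per item, colored by agreement band; degenerate items
#' are omitted.
#'
#' @param reliability A [reliability_report()] tibble.
#' @return A ggplot object.
#' @export
plot_reliability <- function(reliability) {
  df <- dplyr::filter(reliability, !.data$degenerate) |>
    dplyr::mutate(label = paste0(.data$scale, ": ", .data$item),
                  band = factor(.data$band, c("weak", "moderate", "strong",
                                              "very_strong")))
  ggplot2::ggplot(df, ggplot2::aes(.data$w,
                                   stats::reorder(.data$label, .data$w),
                                   fill = .data$band)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = c(0.5, 0.7, 0.9), linetype = 3) +
    ggplot2::labs(x = "Kendall's W", y = NULL, fill = "agreement") +
    ggplot2::theme_minimal()
}

#' Coefficient plot of a Lasso fit
#'
#' Nonzero coefficients at `lambda_min`, items and horse/observer
#' effects faceted separately (the layout used to read item selections).
#'
#' @param object A [fit_lasso_cv()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lasso_fit
#' @export
autoplot.lasso_fit <- function(object, ...) {
  df <- select_items(object)
  if (nrow(df) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", 0, 0, label = "no items selected") +
             ggplot2::theme_void())
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$coefficient,
                                   stats::reorder(.data$term,
                                                  abs(.data$coefficient)))) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$type), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = "coefficient (mm per indicator)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Category map of an MCA fit
#'
#' Category principal coordinates on two dimensions, scaled by
#' contribution.
#'
#' @param object An [fit_mca()] result.
#' @param dims Two dimension indices (default 1:2).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mca_fit
#' @export
autoplot.mca_fit <- function(object, dims = c(1, 2), ...) {
  df <- tibble::tibble(
    category = rownames(object$col_coords),
    x = object$col_coords[, dims[1]],
    y = object$col_coords[, dims[2]],
    contribution = object$col_contrib[, dims[1]] +
      object$col_contrib[, dims[2]]
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   size = .data$contribution)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_text(ggplot2::aes(label = .data$category), size = 2.6,
                       vjust = -0.8, check_overlap = TRUE) +
    ggplot2::labs(
      x = sprintf("dim %d (%.1f%%)", dims[1],
                  100 * object$explained_fraction[dims[1]]),
      y = sprintf("dim %d (%.1f%%)", dims[2],
                  100 * object$explained_fraction[dims[2]])) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
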