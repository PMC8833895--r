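#' @method autoplot dfo_result
#' @export
autoplot.dfo_result <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(.data$fes, .data$best_error)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = object$config$success_error,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "fitness evaluations", y = "best error",
                  title = "Convergence trace")
}

#' @method autoplot dfo_schedule_result
#' @export
autoplot.dfo_schedule_result <- function(object, ...) {
  switches <- object$trace |>
    dplyr::group_by(.data$segment) |>
    dplyr::summarise(at = min(.data$fes), .groups = "drop")
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(.data$fes, .data$best_error,
                               group = .data$segment)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(data = switches[-1, ],
                        ggplot2::aes(xintercept = .data$at),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "fitness evaluations (continuous)",
                  y = "best error",
                  title = "Dynamic-target optimisation trace")
}

#' Plot a discovered recipe against the inventory
#'
#' Bar chart of the fraction of each ingredient's stock the recipe
#' consumes, grouped by ingredient category.
#'
#' @param result A `dfo_result`.
#' @return A ggplot object.
#' @export
plot_recipe <- function(result) {
  df <- tidy(result)
  ggplot2::ggplot(df, ggplot2::aes(.data$name, .data$stock_fraction,
                                   fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "fraction of stock used",
                  title = "Discovered recipe") +
    ggplot2::ylim(0, 1)
}
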