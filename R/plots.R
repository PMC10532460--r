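# ggplot2 views of fitted objects.

#' Heatmap of a grid search
#'
#' Tiles of mean leave-one-out AUC over window length and MNA level, with
#' the best cell outlined.
#'
#' @param object An `spr_grid`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spr_grid
#' @export
autoplot.spr_grid <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = factor(.data$length),
                               y = factor(.data$level),
                               fill = .data$avg_auc)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = object$best, fill = NA, colour = "black",
                       linewidth = 0.8) +
    ggplot2::scale_fill_viridis_c(name = "mean AUC") +
    ggplot2::labs(x = "peptide window length (residues)",
                  y = "MNA descriptor level") +
    ggplot2::theme_minimal()
}

#' Calibration view of a fitted model
#'
#' Leave-one-out B-score distributions of the resistant and non-resistant
#' training structures; the overlap is what limits Pa/Pi separation.
#'
#' @param object An `spr_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spr_model
#' @export
autoplot.spr_model <- function(object, ...) {
  df <- tibble::tibble(
    B = object$loo_scores,
    class = ifelse(object$labels == 1L, "resistant", "non-resistant")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$B, fill = .data$class)) +
    ggplot2::geom_histogram(position = "identity", alpha = 0.55,
                            bins = 40, boundary = 0) +
    ggplot2::labs(x = "leave-one-out B-score", y = "structures",
                  title = paste0("Endpoint '", object$endpoint, "'")) +
    ggplot2::theme_minimal()
}

#' Sensitivity/specificity trade-off of a threshold scan
#'
#' @param scan Tibble returned by [threshold_scan()].
#' @return A ggplot object.
#' @export
plot_threshold_scan <- function(scan) {
  long <- tidyr::pivot_longer(
    scan, c("sensitivity", "specificity", "balanced_accuracy"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rule, y = .data$value,
                                     colour = .data$metric,
                                     group = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "decision rule", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
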