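#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cluster-extent null calibration
#'
#' Estimated `P(max cluster >= k)` against cluster size k.
#'
#' @param object A `cluster_calibration`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cluster_calibration <- function(object, ...) {
  ggplot2::ggplot(object$prob, ggplot2::aes(x = .data$size, y = .data$prob)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "cluster size k (voxels)",
                  y = "P(max cluster ≥ k)",
                  title = sprintf("FWHM %.1f mm, p < %g, %d iterations",
                                  object$fwhm_mm, object$voxel_p, object$n_iter)) +
    ggplot2::theme_minimal()
}

#' Plot the cross-validated (C, sigma) accuracy surface
#'
#' @param object A `focis_grid_search`.
#' @param ... Unused.
#' @return A ggplot object; the selected optimum is circled.
#' @exportS3Method ggplot2::autoplot
autoplot.focis_grid_search <- function(object, ...) {
  ggplot2::ggplot(object$cv, ggplot2::aes(x = .data$cost, y = .data$sigma,
                                          fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::annotate("point", x = object$best_cost, y = object$best_sigma,
                      shape = 21, size = 3, colour = "white") +
    ggplot2::labs(x = "C", y = expression(sigma), fill = "CV accuracy") +
    ggplot2::theme_minimal()
}

#' Plot feature-selection validation accuracy along the threshold path
#'
#' @param object A `focis_selection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.focis_selection <- function(object, ...) {
  df <- dplyr::select(object$path, -"features")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_features, y = .data$mean_accuracy)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_accuracy - .data$sd_accuracy,
      ymax = .data$mean_accuracy + .data$sd_accuracy)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "features kept", y = "mean validation accuracy") +
    ggplot2::theme_minimal()
}

#' Plot CISOTA of a tracked component across model orders
#'
#' @param tracking Tibble from [track_across_nic()].
#' @return A ggplot object.
#' @export
plot_tracking <- function(tracking) {
  ggplot2::ggplot(tracking, ggplot2::aes(x = .data$nic, y = .data$cisota)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$probability)) +
    ggplot2::labs(x = "NIC", y = "CISOTA", size = "match\nprobability") +
    ggplot2::theme_minimal()
}
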