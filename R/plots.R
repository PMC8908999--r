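#' Plot an ROC curve
#'
#' @param object A `dmi_roc` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dmi_roc <- function(object, ...) {
  curve <- tidy(object)
  opt <- curve[curve$threshold == object$optimal_cutpoint, ]
  ggplot2::ggplot(curve, ggplot2::aes(x = 1 - .data$specificity,
                                      y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::geom_point(data = opt, colour = "red", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("ROC: %s positive (AUC = %.3f)",
                      as.character(object$positive_class), object$auc),
      subtitle = sprintf("Youden cutpoint %.4g (%s)",
                         object$optimal_cutpoint, object$direction)) +
    ggplot2::theme_minimal()
}

#' Boxplots of normalized cohort metrics by group
#'
#' @param cohort A cohort tibble.
#' @param metrics Metric columns to show.
#' @return A ggplot with one facet per metric.
#' @export
plot_cohort_metrics <- function(cohort,
                                metrics = c("v_intra_norm", "v_extra_norm",
                                            "v_csf_norm")) {
  long <- tidyr::pivot_longer(cohort, dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value,
                                     fill = .data$group)) +
    ggplot2::geom_boxplot(alpha = 0.6, outlier.shape = 21) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "NAWM-normalized value") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Mid-axial montage of fraction maps
#'
#' @param maps A [fraction_maps()] object.
#' @param slice Axial slice index (defaults to the mid-slice).
#' @return A ggplot showing the three maps side by side.
#' @export
plot_fraction_maps <- function(maps, slice = NULL) {
  shp <- dim(maps$v_intra)
  slice <- slice %||% ceiling(shp[3] / 2)
  one <- function(m, name) {
    tibble(x = rep(seq_len(shp[1]), shp[2]),
           y = rep(seq_len(shp[2]), each = shp[1]),
           value = as.numeric(m[, , slice]), map = name)
  }
  long <- dplyr::bind_rows(one(maps$v_intra, "V-intra"),
                           one(maps$v_extra, "V-extra"),
                           one(maps$v_csf, "V-CSF"))
  ggplot2::ggplot(long, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~map) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "fraction") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
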