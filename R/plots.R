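#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-cycle joint-angle statistics
#'
#' Mean curve per channel over the normalized stroke cycle with the
#' pointwise extremal envelope.
#'
#' @param object A `cycle_stats` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cycle_stats <- function(object, ...) {
  ggplot2::ggplot(object$curves, ggplot2::aes(x = .data$phase)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$min, ymax = .data$max),
                         fill = "indianred", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), colour = "firebrick") +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(x = "stroke cycle (%)", y = "joint angle (rad)",
                  title = "Joint angles over the normalized stroke cycle")
}

#' Bland-Altman plot of an agreement analysis
#'
#' @param object An `agreement` object from [compare_angle_series()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.agreement <- function(object, ...) {
  df <- tibble::tibble(mean = object$means, difference = object$differences)
  ggplot2::ggplot(df, ggplot2::aes(.data$mean, .data$difference)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = object$bias, colour = "firebrick") +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "mean of methods (rad)", y = "difference (rad)",
                  title = "Bland-Altman agreement")
}

#' ROC curve of a classifier report
#'
#' @param object A `model_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.model_report <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("%s (AUC = %.3f)", object$algorithm,
                                  object$auc))
}

#' PCA score plot
#'
#' @param object A `pca_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pca_summary <- function(object, ...) {
  sc <- object$scores
  p <- ggplot2::ggplot(sc, ggplot2::aes(.data$PC1, .data$PC2))
  p <- if ("label" %in% names(sc))
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$label))
  else p + ggplot2::geom_point()
  p + ggplot2::labs(
    x = sprintf("PC1 (%.1f%%)", 100 * object$explained$ratio[1]),
    y = sprintf("PC2 (%.1f%%)", 100 * object$explained$ratio[2]))
}

#' NCA feature-weight plot
#'
#' @param object An `nca_weights` tibble.
#' @param threshold Selection threshold drawn as a reference line.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nca_weights <- function(object, threshold = 0.1, ...) {
  df <- tibble::tibble(index = seq_len(nrow(object)),
                       weight = object$weight, selected = object$selected)
  ggplot2::ggplot(df, ggplot2::aes(.data$index, .data$weight,
                                   colour = .data$selected)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "feature index", y = "NCA weight")
}

#' @importFrom rlang .data
NULL
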