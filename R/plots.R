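#' Plot a CGR trajectory
#'
#' Scatter of the chaos-game points in the unit square, coloured by base.
#'
#' @param object A [cgr_trajectory()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cgr_trajectory
#' @export
autoplot.cgr_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y,
                                       colour = .data$base)) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(title = "Chaos game representation",
                  x = NULL, y = NULL, colour = "base") +
    ggplot2::theme_minimal()
}

#' Plot SDNE training history
#'
#' @param object An `sdne_fit`.
#' @param ... Unused.
#' @return A ggplot of total loss per epoch.
#' @method autoplot sdne_fit
#' @export
autoplot.sdne_fit <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(x = .data$epoch,
                                               y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = "SDNE training loss", x = "epoch",
                  y = "total loss") +
    ggplot2::theme_minimal()
}

#' Plot per-fold ROC curves of a cross validation
#'
#' @param object An `md_cv` from [run_cv()].
#' @param ... Unused.
#' @return A ggplot with one ROC curve per fold.
#' @method autoplot md_cv
#' @export
autoplot.md_cv <- function(object, ...) {
  roc <- dplyr::group_by(object$scores, .data$fold)
  roc <- dplyr::arrange(roc, dplyr::desc(.data$score), .by_group = TRUE)
  roc <- dplyr::mutate(
    roc,
    tpr = cumsum(.data$label == 1) / sum(.data$label == 1),
    fpr = cumsum(.data$label == 0) / sum(.data$label == 0)
  )
  roc <- dplyr::ungroup(roc)
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                    colour = factor(.data$fold))) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Cross-validation ROC",
                  x = "false positive rate", y = "true positive rate",
                  colour = "fold") +
    ggplot2::theme_minimal()
}
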