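# ggplot2 figures for the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' t-SNE map coloured by class and domain
#'
#' @param object A `voiceda_tsne` tibble from [tsne_map()].
#' @param colour_by `"class_label"` or `"domain_label"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot voiceda_tsne
#' @export
autoplot.voiceda_tsne <- function(object, colour_by = "class_label", ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$dim1, y = .data$dim2))
  if (colour_by %in% names(object)) {
    p <- p + ggplot2::geom_point(
      ggplot2::aes(colour = .data[[colour_by]],
                   shape = if ("domain_label" %in% names(object))
                     .data$domain_label else NULL),
      alpha = 0.8)
    p <- p + ggplot2::labs(colour = colour_by, shape = "domain")
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.8)
  }
  p + ggplot2::theme_minimal() +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2")
}

#' Training curves of a fitted model
#'
#' @param object A `voiceda_fit`.
#' @param ... Unused.
#' @return A ggplot object with loss and validation-accuracy traces.
#' @method autoplot voiceda_fit
#' @export
autoplot.voiceda_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(
    object$history,
    cols = c("train_task_loss", "val_loss", "val_accuracy"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~.data$metric, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::guides(colour = "none")
}

#' Bar chart of intra-class inter-domain KL divergences
#'
#' @param object A `voiceda_divergence` from [divergence_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot voiceda_divergence
#' @export
autoplot.voiceda_divergence <- function(object, ...) {
  kl <- dplyr::mutate(object$kl,
                      pair = paste(.data$domain_a, .data$domain_b,
                                   sep = "-"))
  ggplot2::ggplot(kl, ggplot2::aes(x = .data$pair, y = .data$kl,
                                   fill = .data$class_label)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "domain pair", y = "symmetrised Gaussian KL",
                  fill = "class")
}
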