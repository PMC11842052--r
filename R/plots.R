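# ggplot2 autoplot methods for result objects.

#' Plot a ROC curve
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC curve (AUC = %.3f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Plot autoencoder training losses
#'
#' @param object A fitted `vq_vae`.
#' @param ... Unused.
#' @return A ggplot object of the per-epoch loss components.
#' @method autoplot vq_vae
#' @export
autoplot.vq_vae <- function(object, ...) {
  keep <- if (object$latent == "vq") {
    c("reconstruction", "codebook_term", "commitment_term", "total")
  } else {
    c("reconstruction", "kl", "total")
  }
  long <- tidyr::pivot_longer(object$log[, c("epoch", keep)],
                              -"epoch", names_to = "component",
                              values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = "Loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot classifier training losses and the consistency ramp
#'
#' @param object A fitted `pi_classifier`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pi_classifier
#' @export
autoplot.pi_classifier <- function(object, ...) {
  keep <- intersect(c("supervised", "unsupervised", "total"),
                    names(object$log))
  long <- tidyr::pivot_longer(object$log[, c("epoch", keep)],
                              -"epoch", names_to = "component",
                              values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = "Loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-unit AUC distribution of a scenario
#'
#' @param object A `scenario_result`.
#' @param ... Unused.
#' @return A ggplot object (one bar per evaluation unit).
#' @method autoplot scenario_result
#' @export
autoplot.scenario_result <- function(object, ...) {
  ggplot2::ggplot(object$per_unit,
                  ggplot2::aes(x = .data$unit_id, y = .data$auc)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "AUC", title = object$scenario) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
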