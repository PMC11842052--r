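# broom-style tidiers for the package's fitted objects and results.

#' Tidy a signature set into long format
#'
#' @param x A `signature_set`.
#' @param ... Unused.
#' @return A tibble with `entity_id`, `latent` (dimension index), `value`.
#' @method tidy signature_set
#' @export
tidy.signature_set <- function(x, ...) {
  mat <- x$matrix
  tibble::tibble(
    entity_id = rep(x$ids, times = ncol(mat)),
    latent = rep(seq_len(ncol(mat)), each = nrow(mat)),
    value = as.vector(mat)
  )
}

#' @method glance signature_set
#' @export
glance.signature_set <- function(x, ...) {
  tibble::tibble(kind = x$kind, n_entities = nrow(x$matrix),
                 latent_dim = ncol(x$matrix))
}

#' Tidy the training log of an autoencoder
#'
#' @param x A fitted `vq_vae`.
#' @param ... Unused.
#' @return The per-epoch loss log as a tibble.
#' @method tidy vq_vae
#' @export
tidy.vq_vae <- function(x, ...) {
  x$log
}

#' @method glance vq_vae
#' @export
glance.vq_vae <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  tibble::tibble(
    variant = x$variant %||% NA_character_,
    latent = x$latent,
    H = x$config$H,
    K = if (x$latent == "vq") x$config$K else NA_integer_,
    n_parameters = n_parameters(x),
    final_total = last$total,
    final_reconstruction = last$reconstruction,
    codes_used = if (x$latent == "vq") codebook_usage(x) else NA_integer_
  )
}

#' Tidy the training log of a classifier
#'
#' @param x A fitted `pi_classifier`.
#' @param ... Unused.
#' @return The per-epoch loss log as a tibble.
#' @method tidy pi_classifier
#' @export
tidy.pi_classifier <- function(x, ...) {
  x$log
}

#' @method glance pi_classifier
#' @export
glance.pi_classifier <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  tibble::tibble(
    mode = x$mode,
    sigma = x$sigma,
    n_parameters = n_parameters(x),
    epochs = x$config$epochs,
    final_total = last$total,
    final_supervised = last$supervised
  )
}

#' Tidy a ROC result into its curve points
#'
#' @param x A `roc_result`.
#' @param ... Unused.
#' @return The curve tibble (`threshold`, `fpr`, `tpr`).
#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) {
  x$curve
}

#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Tidy a scenario result into per-unit rows
#'
#' @param x A `scenario_result`.
#' @param ... Unused.
#' @return The per-unit AUC report tibble.
#' @method tidy scenario_result
#' @export
tidy.scenario_result <- function(x, ...) {
  x$per_unit
}

#' @method glance scenario_result
#' @export
glance.scenario_result <- function(x, ...) {
  tibble::tibble(
    scenario = x$scenario,
    mean_auc = x$mean_auc,
    n_units = nrow(x$per_unit),
    pooled_auc = if (is.null(x$pooled)) NA_real_ else x$pooled$auc
  )
}
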