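# The vector-quantization primitive: codebook, discrete posterior, lookup,
# and the three-term loss with its stop-gradient / straight-through
# gradient contract.

#' Initialize a discrete latent codebook
#'
#' Entries are drawn i.i.d. from Uniform(-1/K, 1/K), the conventional small
#' symmetric box that keeps early quantization errors comparable across
#' codebook sizes.
#'
#' @param K Number of latent embedding vectors (rows).
#' @param H Embedding dimension (columns).
#' @param seed Optional integer seed; when `NULL` the ambient RNG stream is
#'   used.
#' @return A `K x H` numeric matrix of class `codebook`.
#' @export
init_codebook <- function(K, H, seed = NULL) {
  if (K < 1 || H < 1) {
    vq_abort("K and H must be positive", "vqtarget_config_error")
  }
  e <- with_seed_if(seed, matrix(runif(K * H, -1 / K, 1 / K), K, H))
  class(e) <- c("codebook", class(e))
  e
}

# squared Euclidean distances, queries (n x H) against codes (K x H)
code_dist2 <- function(z, e) {
  d2 <- matrix(rowSums(z^2), nrow(z), nrow(e)) -
    2 * tcrossprod(z, e) +
    matrix(rowSums(e^2), nrow(z), nrow(e), byrow = TRUE)
  pmax(d2, 0)
}

as_query_matrix <- function(z_e, H) {
  if (is.null(dim(z_e))) {
    z_e <- matrix(z_e, nrow = 1)
  }
  if (ncol(z_e) != H) {
    vq_abort(sprintf("query dimension %d does not match codebook dimension %d",
                     ncol(z_e), H), "vqtarget_shape_error")
  }
  if (any(!is.finite(z_e))) {
    vq_abort("queries must be finite", "vqtarget_nonfinite_error")
  }
  z_e
}

#' Nearest codebook entry and one-hot posterior
#'
#' The posterior over the discrete latent is deterministic: probability 1 on
#' the code minimizing the Euclidean distance to the encoder output (ties
#' broken toward the smallest index), 0 elsewhere.
#'
#' @param z_e Encoder output: a length-`H` vector or an `n x H` matrix.
#' @param codebook A [init_codebook()] matrix.
#' @return A list with `index` (integer vector, one per query row) and
#'   `posterior` (an `n x K` one-hot matrix).
#' @export
nearest_code <- function(z_e, codebook) {
  z <- as_query_matrix(z_e, ncol(codebook))
  d2 <- code_dist2(z, codebook)
  k <- max.col(-d2, ties.method = "first")
  posterior <- matrix(0, nrow(z), nrow(codebook))
  posterior[cbind(seq_len(nrow(z)), k)] <- 1
  list(index = k, posterior = posterior)
}

#' Quantize encoder outputs onto the codebook
#'
#' Each query row is replaced by its nearest codebook row (an exact copy).
#'
#' @inheritParams nearest_code
#' @return A matrix of quantized latents `z_q` with one row per query (a
#'   plain vector if `z_e` was a vector).
#' @export
quantize <- function(z_e, codebook) {
  was_vector <- is.null(dim(z_e))
  z <- as_query_matrix(z_e, ncol(codebook))
  k <- nearest_code(z, codebook)$index
  z_q <- codebook[k, , drop = FALSE]
  dimnames(z_q) <- NULL
  if (was_vector) as.numeric(z_q) else z_q
}

#' Three-term vector-quantization loss
#'
#' Computes the reconstruction error (mean squared error, i.e. a unit
#' variance Gaussian likelihood with constants dropped), the codebook term
#' `||sg(z_e) - e_k||^2` and the commitment term `beta * ||z_e - sg(e_k)||^2`,
#' where `sg` is the stop-gradient operator. Squared norms are summed over
#' latent dimensions and averaged over the batch, so `beta`'s scale does not
#' depend on batch size.
#'
#' The gradient contract (enforced by the trainers and verified by
#' finite-difference tests): the codebook receives gradient only from the
#' codebook term; the encoder receives gradient from the reconstruction
#' (straight-through: the gradient at `z_q` is copied to `z_e`) and from the
#' commitment term, never from the codebook term.
#'
#' @param x Input batch (vector or `n x p` matrix).
#' @param x_hat Reconstruction, same shape as `x`.
#' @param z_e Encoder outputs (vector or `n x H` matrix).
#' @param z_q Quantized latents, same shape as `z_e`.
#' @param beta Commitment weight (default 0.25).
#' @return A list of class `vq_loss_parts` with fields `reconstruction`,
#'   `codebook_term`, `commitment_term`, `beta` and `total`.
#' @export
vq_loss <- function(x, x_hat, z_e, z_q, beta = 0.25) {
  stopifnot(beta >= 0)
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  x_hat <- if (is.null(dim(x_hat))) matrix(x_hat, nrow = 1) else
    as.matrix(x_hat)
  z_e <- if (is.null(dim(z_e))) matrix(z_e, nrow = 1) else as.matrix(z_e)
  z_q <- if (is.null(dim(z_q))) matrix(z_q, nrow = 1) else as.matrix(z_q)
  if (!all(dim(x) == dim(x_hat)) || !all(dim(z_e) == dim(z_q))) {
    vq_abort("shape mismatch in vq_loss", "vqtarget_shape_error")
  }
  reconstruction <- mean((x - x_hat)^2)
  raw <- mean(rowSums((z_e - z_q)^2))
  parts <- list(
    reconstruction = reconstruction,
    codebook_term = raw,
    commitment_term = beta * raw,
    beta = beta,
    total = reconstruction + raw + beta * raw
  )
  class(parts) <- "vq_loss_parts"
  parts
}

#' @export
print.vq_loss_parts <- function(x, ...) {
  cat(sprintf(
    "<vq_loss_parts> total %.6g = recon %.6g + codebook %.6g + commitment %.6g (beta = %g)\n",
    x$total, x$reconstruction, x$codebook_term, x$commitment_term, x$beta
  ))
  invisible(x)
}

# Analytic codebook gradient of the codebook term for a batch:
# d/d e_k (1/n) sum_i ||z_e_i - e_{k_i}||^2 = (2/n) sum_{i: k_i = k} (e_k - z_e_i)
codebook_grad <- function(z_e, codebook, index) {
  n <- nrow(z_e)
  g <- matrix(0, nrow(codebook), ncol(codebook))
  for (k in unique(index)) {
    rows <- which(index == k)
    g[k, ] <- (2 / n) * (length(rows) * codebook[k, ] -
                           colSums(z_e[rows, , drop = FALSE]))
  }
  g
}
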