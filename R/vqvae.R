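# Encoder/decoder architectures and training for protein and
# disease/patient signatures: multimodal (cell-blocked) VQ-VAE, per-cell
# VQ-VAE, averaged-profile VQ-VAE, and an ordinary Gaussian VAE.

#' Autoencoder training configuration
#'
#' @param H Latent dimension (codebook embedding width).
#' @param K Codebook size (number of discrete latent vectors).
#' @param cell_block_width Units per cell block in the first encoder layer.
#' @param fused_widths Two widths for the fully connected fusion layers.
#' @param lr ADAM learning rate.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param beta Commitment-loss weight.
#' @param leaky_slope Negative slope of the leaky-rectifier activations
#'   (non-zero slope counteracts codebook collapse).
#' @param standardize Standardize each input column to zero mean / unit
#'   variance before encoding (transform stored in the model).
#' @param cell_latent Latent width per cell for the cell-specific variant;
#'   default `max(1, round(H / n_cells))` so the concatenated width is
#'   comparable to the multimodal `H`.
#' @param seed Integer seed controlling initialization, batching and (for
#'   the VAE) the reparameterization noise.
#' @return A list of class `vq_config`.
#' @export
vq_config <- function(H = 16, K = 32, cell_block_width = 512,
                      fused_widths = c(256, 64), lr = 1e-3, epochs = 200,
                      batch_size = 16, beta = 0.25, leaky_slope = 0.01,
                      standardize = TRUE, cell_latent = NULL, seed = 1) {
  stopifnot(H >= 1, K >= 1, length(fused_widths) == 2)
  structure(
    list(H = H, K = K, cell_block_width = cell_block_width,
         fused_widths = fused_widths, lr = lr, epochs = epochs,
         batch_size = batch_size, beta = beta, leaky_slope = leaky_slope,
         standardize = standardize, cell_latent = cell_latent, seed = seed),
    class = "vq_config"
  )
}

# encoder: blocks(a -> w per cell) -> f1 -> f2 -> latent (linear)
# decoder mirrors: latent -> f2 -> f1 -> blocks(w -> a per cell, linear)
vqvae_layers <- function(n_cells, input_per_cell, config,
                         latent = c("vq", "gaussian")) {
  latent <- match.arg(latent)
  w <- config$cell_block_width
  f <- config$fused_widths
  s <- config$leaky_slope
  latent_width <- if (latent == "vq") config$H else 2L * config$H
  encoder <- list(
    nn_block(rep(input_per_cell, n_cells), rep(w, n_cells), act = "lrelu",
             slope = s),
    nn_dense(n_cells * w, f[1], act = "lrelu", slope = s),
    nn_dense(f[1], f[2], act = "lrelu", slope = s),
    nn_dense(f[2], latent_width, act = "linear")
  )
  decoder <- list(
    nn_dense(config$H, f[2], act = "lrelu", slope = s),
    nn_dense(f[2], f[1], act = "lrelu", slope = s),
    nn_dense(f[1], n_cells * w, act = "lrelu", slope = s),
    nn_block(rep(w, n_cells), rep(input_per_cell, n_cells), act = "linear")
  )
  list(encoder = encoder, decoder = decoder)
}

gaussian_kl_rows <- function(mu, logvar) {
  0.5 * rowSums(mu^2 + exp(logvar) - 1 - logvar)
}

#' Closed-form Gaussian KL divergence to the standard normal
#'
#' `KL(N(mu, diag(exp(logvar))) || N(0, I))`, summed over latent dimensions
#' and averaged over rows when given matrices.
#'
#' @param mu,logvar Mean and log-variance (vectors or matrices of equal
#'   shape).
#' @return A nonnegative scalar.
#' @export
gaussian_kl <- function(mu, logvar) {
  mu <- if (is.null(dim(mu))) matrix(mu, nrow = 1) else as.matrix(mu)
  logvar <- if (is.null(dim(logvar))) matrix(logvar, nrow = 1) else
    as.matrix(logvar)
  stopifnot(all(dim(mu) == dim(logvar)))
  mean(gaussian_kl_rows(mu, logvar))
}

#' Evidence lower bound loss for the Gaussian VAE
#'
#' Mean-squared-error reconstruction plus the closed-form KL divergence of
#' the approximate posterior from the standard normal prior.
#'
#' @param x,x_hat Input and reconstruction (equal shapes).
#' @param mu,logvar Posterior parameters (equal shapes).
#' @return A scalar loss (minimized during training).
#' @export
elbo_loss <- function(x, x_hat, mu, logvar) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  x_hat <- if (is.null(dim(x_hat))) matrix(x_hat, nrow = 1) else
    as.matrix(x_hat)
  if (!all(dim(x) == dim(x_hat))) {
    vq_abort("shape mismatch in elbo_loss", "vqtarget_shape_error")
  }
  mean((x - x_hat)^2) + gaussian_kl(mu, logvar)
}

# Core training loop shared by all variants. X is entity x feature,
# already laid out per the variant (cells concatenated for multimodal).
vqvae_fit <- function(X, n_cells, input_per_cell, config, latent = "vq") {
  with_seed_if(config$seed, {
    std <- if (config$standardize) standardize_fit(X) else
      list(center = rep(0, ncol(X)), scale = rep(1, ncol(X)))
    Xs <- standardize_apply(X, std)

    net <- vqvae_layers(n_cells, input_per_cell, config, latent)
    codebook <- if (latent == "vq") {
      unclass(init_codebook(config$K, config$H))
    } else {
      NULL
    }
    params <- list(encoder = nn_params(net$encoder),
                   decoder = nn_params(net$decoder))
    if (latent == "vq") params$codebook <- codebook
    opt <- adam_new(params, lr = config$lr)

    n <- nrow(Xs)
    d_x <- ncol(Xs)
    log_rows <- vector("list", config$epochs)
    for (epoch in seq_len(config$epochs)) {
      order <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      acc <- c(reconstruction = 0, codebook_term = 0, commitment_term = 0,
               kl = 0, total = 0)
      for (st in starts) {
        idx <- order[st:min(st + config$batch_size - 1, n)]
        xb <- Xs[idx, , drop = FALSE]
        nb <- nrow(xb)

        fwd_e <- nn_forward(net$encoder, xb)
        if (latent == "vq") {
          z_e <- fwd_e$out
          k <- nearest_code(z_e, params$codebook)$index
          z_q <- params$codebook[k, , drop = FALSE]
          fwd_d <- nn_forward(net$decoder, z_q)
          x_hat <- fwd_d$out

          parts <- vq_loss(xb, x_hat, z_e, z_q, beta = config$beta)
          d_xhat <- 2 * (x_hat - xb) / (nb * d_x)
          back_d <- nn_backward(net$decoder, fwd_d$caches, d_xhat)
          # straight-through: reconstruction gradient at z_q is copied to
          # z_e; commitment adds beta * 2(z_e - sg(e_k)) / n
          d_ze <- back_d$d_x + (2 * config$beta / nb) * (z_e - z_q)
          back_e <- nn_backward(net$encoder, fwd_e$caches, d_ze)
          grads <- list(encoder = back_e$grads, decoder = back_d$grads,
                        codebook = codebook_grad(z_e, params$codebook, k))
          acc <- acc + c(parts$reconstruction, parts$codebook_term,
                         parts$commitment_term, 0, parts$total) * nb
        } else {
          out <- fwd_e$out
          mu <- out[, seq_len(config$H), drop = FALSE]
          logvar <- out[, config$H + seq_len(config$H), drop = FALSE]
          eps <- matrix(rnorm(length(mu)), nrow(mu), ncol(mu))
          sd_z <- exp(logvar / 2)
          z <- mu + sd_z * eps
          fwd_d <- nn_forward(net$decoder, z)
          x_hat <- fwd_d$out

          recon <- mean((xb - x_hat)^2)
          kl <- mean(gaussian_kl_rows(mu, logvar))
          d_xhat <- 2 * (x_hat - xb) / (nb * d_x)
          back_d <- nn_backward(net$decoder, fwd_d$caches, d_xhat)
          d_z <- back_d$d_x
          d_mu <- d_z + mu / nb
          d_logvar <- d_z * eps * sd_z / 2 + (exp(logvar) - 1) / (2 * nb)
          back_e <- nn_backward(net$encoder, fwd_e$caches,
                                cbind(d_mu, d_logvar))
          grads <- list(encoder = back_e$grads, decoder = back_d$grads)
          acc <- acc + c(recon, 0, 0, kl, recon + kl) * nb
        }

        stepped <- adam_step(params, grads, opt)
        params <- stepped$params
        opt <- stepped$state
        net$encoder <- nn_set_params(net$encoder, params$encoder)
        net$decoder <- nn_set_params(net$decoder, params$decoder)
      }
      log_rows[[epoch]] <- tibble::tibble(
        epoch = epoch,
        reconstruction = acc[["reconstruction"]] / n,
        codebook_term = acc[["codebook_term"]] / n,
        commitment_term = acc[["commitment_term"]] / n,
        kl = acc[["kl"]] / n,
        total = acc[["total"]] / n
      )
    }

    # final code assignments over the training set (collapse diagnostic)
    code_counts <- NULL
    if (latent == "vq") {
      z_all <- nn_forward(net$encoder, Xs)$out
      k_all <- nearest_code(z_all, params$codebook)$index
      code_counts <- table(factor(k_all, levels = seq_len(config$K)))
    }

    structure(
      list(encoder = net$encoder, decoder = net$decoder,
           codebook = params$codebook, latent = latent,
           n_cells = n_cells, input_per_cell = input_per_cell,
           n_train = n,
           std = std, config = config,
           log = dplyr::bind_rows(log_rows),
           code_counts = code_counts),
      class = "vq_vae"
    )
  })
}

#' @export
print.vq_vae <- function(x, ...) {
  cat(sprintf(
    "<vq_vae> %s latent (H=%d%s), %d cell block(s) x %d inputs, %d parameters\n",
    x$latent, x$config$H,
    if (x$latent == "vq") sprintf(", K=%d", x$config$K) else "",
    x$n_cells, x$input_per_cell, n_parameters(x)
  ))
  invisible(x)
}

#' Number of trainable parameters
#'
#' @param model A fitted `vq_vae`, `vq_vae_cellspec` or `pi_classifier`.
#' @return Integer parameter count (codebook included for VQ models).
#' @export
n_parameters <- function(model) {
  UseMethod("n_parameters")
}

#' @export
n_parameters.vq_vae <- function(model) {
  as.integer(
    nn_n_parameters(model$encoder) + nn_n_parameters(model$decoder) +
      if (!is.null(model$codebook)) length(model$codebook) else 0L
  )
}

#' @export
n_parameters.vq_vae_cellspec <- function(model) {
  as.integer(sum(vapply(model$models, n_parameters, integer(1))))
}

#' Codes in use after training
#'
#' Counts how many distinct codebook entries the training inputs select; a
#' value of 1 signals codebook collapse.
#'
#' @param model A fitted VQ model.
#' @return Integer count of distinct codes used.
#' @export
codebook_usage <- function(model) {
  UseMethod("codebook_usage")
}

#' @export
codebook_usage.vq_vae <- function(model) {
  if (is.null(model$code_counts)) {
    vq_abort("model has no codebook (Gaussian latent)", "vqtarget_nn_error")
  }
  sum(model$code_counts > 0)
}

#' @export
codebook_usage.vq_vae_cellspec <- function(model) {
  min(vapply(model$models, codebook_usage, numeric(1)))
}

# lay a tensor out as entity x (cell-concatenated genes)
tensor_design <- function(tensor) {
  vals <- tensor$values
  n_cells <- length(tensor$cell_ids)
  a <- length(tensor$gene_ids)
  X <- matrix(0, length(tensor$protein_ids), n_cells * a)
  for (c_ in seq_len(n_cells)) {
    X[, (c_ - 1) * a + seq_len(a)] <- vals[, c_, ]
  }
  rownames(X) <- tensor$protein_ids
  X
}

#' Train a protein signature model
#'
#' Fits one of four representation-learning variants on an imputed
#' perturbation tensor:
#' * `"multimodal"`: one VQ-VAE over the cell-concatenated profile, with a
#'   cell-independent (block-diagonal) first encoder layer and mirrored
#'   decoder, fusing all cell types in one discrete latent;
#' * `"cellspec"`: one VQ-VAE per cell type on that cell's profiles;
#'   signatures are per-cell latents concatenated in cell order;
#' * `"averaged"`: one VQ-VAE on the across-cell mean profile;
#' * `"vae"`: the multimodal architecture with a continuous Gaussian latent
#'   trained on the evidence lower bound.
#'
#' @param tensor An imputed [perturbation_tensor()] (no missing slices).
#' @param variant One of `"multimodal"`, `"cellspec"`, `"averaged"`,
#'   `"vae"`.
#' @param config A [vq_config()].
#' @return A fitted model (`vq_vae`, or `vq_vae_cellspec` for the per-cell
#'   variant) carrying the training log and the standardization transform.
#' @export
train_protein_vqvae <- function(tensor,
                                variant = c("multimodal", "cellspec",
                                            "averaged", "vae"),
                                config = vq_config()) {
  variant <- match.arg(variant)
  stopifnot(inherits(tensor, "perturbation_tensor"))
  if (any(tensor$missing)) {
    vq_abort("tensor has missing slices; run impute_missing() first",
             "vqtarget_missing_error")
  }
  a <- length(tensor$gene_ids)
  n_cells <- length(tensor$cell_ids)

  if (variant == "cellspec") {
    h_cell <- config$cell_latent %||% max(1L, round(config$H / n_cells))
    models <- lapply(seq_len(n_cells), function(c_) {
      cfg <- config
      cfg$H <- h_cell
      cfg$seed <- config$seed + c_ - 1L
      X <- tensor$values[, c_, ]
      rownames(X) <- tensor$protein_ids
      fit <- vqvae_fit(X, 1L, a, cfg, latent = "vq")
      fit$variant <- "cellspec"
      fit$role <- "protein"
      fit$gene_ids <- tensor$gene_ids
      fit$cell_ids <- tensor$cell_ids[c_]
      fit
    })
    return(structure(
      list(models = models, cell_ids = tensor$cell_ids,
           gene_ids = tensor$gene_ids, config = config,
           variant = "cellspec", role = "protein",
           direction = tensor$direction),
      class = "vq_vae_cellspec"
    ))
  }

  if (variant == "averaged") {
    X <- apply(tensor$values, c(1, 3), mean)
    rownames(X) <- tensor$protein_ids
    fit <- vqvae_fit(X, 1L, a, config, latent = "vq")
  } else {
    X <- tensor_design(tensor)
    fit <- vqvae_fit(X, n_cells, a, config,
                     latent = if (variant == "vae") "gaussian" else "vq")
  }
  fit$variant <- variant
  fit$role <- "protein"
  fit$gene_ids <- tensor$gene_ids
  fit$cell_ids <- tensor$cell_ids
  fit$direction <- tensor$direction
  fit
}

#' Train the disease/patient signature model
#'
#' Fits one fully connected VQ-VAE (or VAE) on the union of disease-level
#' rows and patient-level rows, so that heterogeneous patient profiles
#' regularize the disease embedding and both levels share one latent space.
#'
#' @param cohort A [cohort_profiles()] with the disease matrix built.
#' @param config A [vq_config()].
#' @param latent `"vq"` (default) or `"gaussian"`.
#' @return A fitted `vq_vae` with role `"disease"`.
#' @export
train_disease_vqvae <- function(cohort, config = vq_config(),
                                latent = c("vq", "gaussian")) {
  latent <- match.arg(latent)
  stopifnot(inherits(cohort, "cohort_profiles"))
  if (is.null(cohort$disease_matrix)) {
    vq_abort("cohort has no disease matrix; run build_disease_profiles()",
             "vqtarget_cohort_error")
  }
  X <- rbind(cohort$disease_matrix, cohort$patient_matrix)
  fit <- vqvae_fit(X, 1L, ncol(X), config, latent = latent)
  fit$variant <- "disease"
  fit$role <- "disease"
  fit$gene_ids <- cohort$gene_ids
  fit$cell_ids <- NULL
  fit
}

# encoder output before quantization (mu for the Gaussian latent)
encode_matrix <- function(model, X) {
  Xs <- standardize_apply(X, model$std)
  out <- nn_forward(model$encoder, Xs)$out
  if (model$latent == "gaussian") {
    out <- out[, seq_len(model$config$H), drop = FALSE]
  }
  rownames(out) <- rownames(X)
  out
}

signature_set <- function(kind, mat, ids) {
  rownames(mat) <- ids
  structure(list(kind = kind, matrix = mat, ids = ids),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("<signature_set> %s: %d entities x %d latent dims\n",
              x$kind, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Extract latent signatures from a trained model
#'
#' Signatures are the continuous encoder outputs `z_e` *before*
#' quantization (the posterior mean for the Gaussian VAE); the cell-specific
#' variant concatenates per-cell latents in cell order. Extraction is
#' deterministic.
#'
#' @param model A fitted model from [train_protein_vqvae()] or
#'   [train_disease_vqvae()].
#' @param data A [perturbation_tensor()] for protein models; a
#'   [cohort_profiles()] (or plain matrix) for disease models.
#' @param level For disease models: `"disease"` or `"patient"` rows of the
#'   cohort.
#' @param ... Unused.
#' @return A `signature_set` (entity-by-latent matrix plus ids and a kind
#'   tag); `tidy()` turns it into a long tibble.
#' @export
extract_signatures <- function(model, data, ...) {
  UseMethod("extract_signatures")
}

#' @rdname extract_signatures
#' @export
extract_signatures.vq_vae <- function(model, data,
                                      level = c("disease", "patient"), ...) {
  if (model$role == "protein") {
    stopifnot(inherits(data, "perturbation_tensor"))
    if (!identical(data$gene_ids, model$gene_ids)) {
      vq_abort("gene universe differs between model and tensor",
               "vqtarget_shape_error")
    }
    if (model$variant == "averaged") {
      X <- apply(data$values, c(1, 3), mean)
      rownames(X) <- data$protein_ids
    } else {
      if (!identical(data$cell_ids, model$cell_ids)) {
        vq_abort("cell types differ between model and tensor",
                 "vqtarget_shape_error")
      }
      X <- tensor_design(data)
    }
    kind <- paste0("protein_",
                   if (model$latent == "gaussian") "vae" else
                     paste0(model$variant, "_vq"))
    return(signature_set(kind, encode_matrix(model, X), rownames(X)))
  }
  level <- match.arg(level)
  if (inherits(data, "cohort_profiles")) {
    X <- if (level == "disease") data$disease_matrix else data$patient_matrix
  } else {
    X <- as.matrix(data)
  }
  if (ncol(X) != model$input_per_cell) {
    vq_abort("gene universe differs between model and profiles",
             "vqtarget_shape_error")
  }
  kind <- paste0(level, if (model$latent == "gaussian") "_vae" else "_vq")
  signature_set(kind, encode_matrix(model, X), rownames(X))
}

#' @rdname extract_signatures
#' @export
extract_signatures.vq_vae_cellspec <- function(model, data, ...) {
  stopifnot(inherits(data, "perturbation_tensor"))
  if (!identical(data$cell_ids, model$cell_ids)) {
    vq_abort("cell types differ between model and tensor",
             "vqtarget_shape_error")
  }
  parts <- lapply(seq_along(model$models), function(c_) {
    X <- data$values[, c_, ]
    rownames(X) <- data$protein_ids
    encode_matrix(model$models[[c_]], X)
  })
  signature_set("protein_cellspec_vq", do.call(cbind, parts),
                data$protein_ids)
}
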