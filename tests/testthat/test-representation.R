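# representation: architectures, training behaviour, signature extraction,
# and the Gaussian-VAE loss.

test_that("network gradients agree with finite differences", {
  set.seed(20)
  layers <- list(
    vqtarget:::nn_block(c(3, 3), c(4, 4), act = "lrelu", slope = 0.3),
    vqtarget:::nn_dense(8, 5, act = "lrelu", slope = 0.3),
    vqtarget:::nn_dense(5, 2, act = "linear")
  )
  X <- matrix(rnorm(4 * 6), 4, 6)
  Y <- matrix(rnorm(4 * 2), 4, 2)
  loss_of <- function(ls) mean((vqtarget:::nn_forward(ls, X)$out - Y)^2)

  fwd <- vqtarget:::nn_forward(layers, X)
  d_out <- 2 * (fwd$out - Y) / length(Y)
  grads <- vqtarget:::nn_backward(layers, fwd$caches, d_out)$grads

  eps <- 1e-6
  # dense layer weight
  for (idx in list(c(2, 1, 3), c(3, 2, 1))) {
    l <- idx[1]
    lp <- layers; lp[[l]]$W[idx[2], idx[3]] <- lp[[l]]$W[idx[2], idx[3]] + eps
    lm <- layers; lm[[l]]$W[idx[2], idx[3]] <- lm[[l]]$W[idx[2], idx[3]] - eps
    fd <- (loss_of(lp) - loss_of(lm)) / (2 * eps)
    expect_lt(abs(grads[[l]]$W[idx[2], idx[3]] - fd), 1e-6)
  }
  # block layer weight
  lp <- layers; lp[[1]]$Ws[[2]][1, 2] <- lp[[1]]$Ws[[2]][1, 2] + eps
  lm <- layers; lm[[1]]$Ws[[2]][1, 2] <- lm[[1]]$Ws[[2]][1, 2] - eps
  fd <- (loss_of(lp) - loss_of(lm)) / (2 * eps)
  expect_lt(abs(grads[[1]]$Ws[[2]][1, 2] - fd), 1e-6)
})

test_that("first encoder layer is block-diagonal by cell", {
  tens <- tiny_tensor(S = 5, C = 3, a = 6)
  fit <- train_protein_vqvae(tens, "multimodal",
                             fast_vq_config(cell_block_width = 4))
  X <- vqtarget:::standardize_apply(vqtarget:::tensor_design(tens), fit$std)
  h1 <- vqtarget:::nn_layer_forward(fit$encoder[[1]], X)$a
  # zero cell 2's inputs: only block 2 of the first hidden layer moves
  X2 <- X
  X2[, 7:12] <- 0
  h1z <- vqtarget:::nn_layer_forward(fit$encoder[[1]], X2)$a
  blocks <- rep(1:3, each = 4)
  expect_identical(h1[, blocks != 2], h1z[, blocks != 2])
  expect_false(isTRUE(all.equal(h1[, blocks == 2], h1z[, blocks == 2])))

  # Jacobian of layer-1 activations w.r.t. cell-3 inputs vanishes outside
  # block 3 (finite difference)
  Xp <- X
  Xp[1, 13] <- Xp[1, 13] + 1e-4
  h1p <- vqtarget:::nn_layer_forward(fit$encoder[[1]], Xp)$a
  expect_identical(h1p[1, blocks != 3], h1[1, blocks != 3])
})

test_that("architecture bookkeeping: mirror decoder and variant parity", {
  cfg <- fast_vq_config(cell_block_width = 5)
  tens1 <- tiny_tensor(S = 4, C = 1, a = 7)
  multi <- train_protein_vqvae(tens1, "multimodal", cfg)
  cellspec <- train_protein_vqvae(tens1, "cellspec",
                                  { c2 <- cfg; c2$cell_latent <- cfg$H; c2 })

  # multimodal with C = 1 and cell-specific with C = 1 define the same
  # architecture: identical parameter counts
  expect_identical(n_parameters(multi), n_parameters(cellspec))

  # independent parameter-count formula: encoder + mirrored decoder + codes
  a <- 7; w <- 5; f1 <- 12; f2 <- 8; H <- 4; K <- 8
  enc <- (a * w + w) + (w * f1 + f1) + (f1 * f2 + f2) + (f2 * H + H)
  dec <- (H * f2 + f2) + (f2 * f1 + f1) + (f1 * w + w) + (w * a + a)
  expect_identical(n_parameters(multi), as.integer(enc + dec + K * H))

  # decoder mirrors the encoder's widths in reverse
  widths_enc <- vapply(multi$encoder, function(l) {
    if (l$type == "dense") ncol(l$W) else sum(l$out_sizes)
  }, numeric(1))
  widths_dec <- vapply(multi$decoder, function(l) {
    if (l$type == "dense") nrow(l$W) else sum(l$in_sizes)
  }, numeric(1))
  expect_equal(rev(widths_enc[-4]), widths_dec[-1], ignore_attr = TRUE)
})

test_that("training memorizes small data and is seed-reproducible", {
  # single-protein memorization: late loss no worse than the first epoch
  tens <- tiny_tensor(S = 1, C = 2, a = 6)
  fit <- train_protein_vqvae(tens, "multimodal",
                             fast_vq_config(epochs = 50, batch_size = 1))
  expect_lte(fit$log$total[50], fit$log$total[1])

  # trailing moving-average of the total loss is non-increasing overall
  bench <- cached_benchmark(1)
  log <- tidy(bench$sigs$protein_model)
  ma <- stats::filter(log$total, rep(1 / 10, 10), sides = 1)
  ma <- ma[!is.na(ma)]
  expect_lt(ma[length(ma)], ma[1])

  # bit-reproducible under a fixed seed
  f1 <- train_protein_vqvae(tens, "averaged", fast_vq_config(seed = 33))
  f2 <- train_protein_vqvae(tens, "averaged", fast_vq_config(seed = 33))
  expect_identical(serialize(f1, NULL), serialize(f2, NULL))

  # missing slices are rejected
  miss <- matrix(c(TRUE, rep(FALSE, 11)), 6, 2)
  tm <- perturbation_tensor(tiny_tensor()$values, paste0("p", 1:6),
                            paste0("c", 1:2), paste0("g", 1:8),
                            missing = miss)
  expect_error(train_protein_vqvae(tm, "multimodal"),
               class = "vqtarget_missing_error")
})

test_that("signatures are deterministic pre-quantization encodings", {
  tens <- tiny_tensor(S = 6, C = 3, a = 6)
  # duplicate rows encode identically
  vals <- tens$values
  vals[2, , ] <- vals[1, , ]
  tens2 <- perturbation_tensor(vals, tens$protein_ids, tens$cell_ids,
                               tens$gene_ids)
  fit <- train_protein_vqvae(tens2, "multimodal",
                             fast_vq_config(cell_block_width = 4))
  sig <- extract_signatures(fit, tens2)
  expect_equal(sig$matrix[1, ], sig$matrix[2, ], ignore_attr = TRUE)
  expect_equal(ncol(sig$matrix), 4)

  # signature equals the encoder output (z_e), not a codebook row
  X <- vqtarget:::standardize_apply(vqtarget:::tensor_design(tens2), fit$std)
  z_e <- vqtarget:::nn_forward(fit$encoder, X)$out
  expect_equal(unname(sig$matrix), unname(z_e))

  # cell-specific: C = 3 with per-cell latent 4 concatenates to length 12
  cs <- train_protein_vqvae(tens, "cellspec",
                            fast_vq_config(cell_block_width = 4,
                                           cell_latent = 4))
  sig_cs <- extract_signatures(cs, tens)
  expect_equal(ncol(sig_cs$matrix), 12)

  # gene-universe mismatch is rejected
  tens3 <- tiny_tensor(S = 6, C = 3, a = 7)
  expect_error(extract_signatures(fit, tens3),
               class = "vqtarget_shape_error")
})

test_that("positive-protein signatures cluster on the noiseless benchmark", {
  cfg <- sim_config(noise_sd = 0.05, missing_fraction = 0)
  b <- make_benchmark(2, config = cfg)
  # on near-noiseless data the raw scale already carries the signal; skip
  # the per-gene standardization so background proteins stay near zero
  fit <- train_protein_vqvae(b$tensor, "multimodal",
                             vq_config(H = 8, cell_block_width = 16,
                                       fused_widths = c(64, 32),
                                       epochs = 100, leaky_slope = 0.3,
                                       standardize = FALSE,
                                       seed = 2))
  sig <- extract_signatures(fit, b$tensor)
  # centre latent dimensions so similarity reflects deviation from the
  # typical protein, not a shared embedding offset
  Zc <- scale(sig$matrix, center = TRUE, scale = FALSE)
  Z <- Zc / sqrt(rowSums(Zc^2))
  planted <- unique(b$positives$protein_id)
  noise <- setdiff(rownames(Z), planted)
  # pairs of planted proteins sharing a disease are more similar than
  # random protein pairs
  shared <- dplyr::inner_join(b$positives, b$positives,
                              by = "disease_id",
                              relationship = "many-to-many")
  shared <- shared[shared$protein_id.x < shared$protein_id.y, ]
  skip_if(nrow(shared) == 0)
  cos_shared <- mean(rowSums(Z[shared$protein_id.x, , drop = FALSE] *
                               Z[shared$protein_id.y, , drop = FALSE]))
  rand <- t(utils::combn(sample(noise, 10), 2))
  cos_rand <- mean(rowSums(Z[rand[, 1], , drop = FALSE] *
                             Z[rand[, 2], , drop = FALSE]))
  expect_gt(cos_shared, cos_rand)
})

test_that("disease model trains on disease plus patient rows jointly", {
  co <- tiny_cohort(n_dis = 3, per = 2, b = 8)
  fit <- train_disease_vqvae(co, fast_vq_config(cell_block_width = 6))
  expect_identical(fit$n_train, 3L + 6L)

  # 1 disease, 1 patient, noiseless: reconstruction collapses quickly
  pm <- matrix(rep(c(1, -1), 4), 1, 8)
  rownames(pm) <- "patA"
  co1 <- build_disease_profiles(cohort_profiles(pm, c(patA = "dZ")))
  f1 <- train_disease_vqvae(co1, fast_vq_config(epochs = 100,
                                                batch_size = 2,
                                                lr = 0.02,
                                                standardize = FALSE))
  expect_lt(f1$log$reconstruction[100], 0.05)

  # retrieval: disease signatures sit nearest their own patients' mean
  bench <- cached_benchmark(1)
  dsig <- bench$sigs$disease$matrix
  psig <- bench$sigs$patient$matrix
  map <- bench$bundle$cohort$patient_to_disease
  hits <- sapply(rownames(dsig), function(d) {
    centroids <- t(vapply(rownames(dsig), function(dd) {
      colMeans(psig[map$patient_id[map$disease_id == dd], , drop = FALSE])
    }, numeric(ncol(psig))))
    d2 <- rowSums((centroids - matrix(dsig[d, ], nrow(centroids),
                                      ncol(centroids), byrow = TRUE))^2)
    names(which.min(d2)) == d
  })
  expect_gte(mean(hits), 0.8)
})

test_that("VQ training uses several codebook entries", {
  bench <- cached_benchmark(1)
  expect_gte(codebook_usage(bench$sigs$protein_model), 2)
  expect_gte(codebook_usage(bench$sigs$disease_model), 2)
})

test_that("Gaussian VAE losses follow the closed form", {
  expect_equal(gaussian_kl(c(0, 0), c(0, 0)), 0)
  expect_equal(gaussian_kl(c(1, 0), c(0, 0)), 0.5)

  # KL nonnegative over 1000 random draws
  set.seed(21)
  kls <- replicate(1000, gaussian_kl(rnorm(3), rnorm(3)))
  expect_true(all(kls >= 0))

  x <- matrix(rnorm(6), 2, 3)
  expect_equal(elbo_loss(x, x, matrix(0, 2, 2), matrix(0, 2, 2)), 0)
  expect_error(elbo_loss(x, x[, 1:2], matrix(0, 2, 2), matrix(0, 2, 2)),
               class = "vqtarget_shape_error")

  # VAE variant trains and extracts the posterior mean deterministically
  tens <- tiny_tensor(S = 5, C = 2, a = 6)
  vfit <- train_protein_vqvae(tens, "vae", fast_vq_config(epochs = 30))
  expect_identical(vfit$latent, "gaussian")
  s1 <- extract_signatures(vfit, tens)
  s2 <- extract_signatures(vfit, tens)
  expect_identical(s1$matrix, s2$matrix)
  expect_equal(ncol(s1$matrix), 4)
  expect_true(all(c("kl", "reconstruction") %in% names(tidy(vfit))))
})
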