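# Pi-model semi-supervised classifier over concatenated protein-disease
# signatures, and its supervised ablation. The consistency term compares a
# prediction on [protein || disease] features with a second stochastic
# pass on [protein || patient] features for unlabeled diseases.

#' Classifier training configuration
#'
#' @param hidden Three hidden-layer widths.
#' @param dropout Dropout rate on hidden layers (both stochastic passes).
#' @param lr ADAM learning rate.
#' @param epochs Training epochs.
#' @param b_pro,b_dis Proteins / diseases sampled per minibatch; the batch
#'   is their Cartesian product.
#' @param w_max Final unsupervised consistency weight.
#' @param ramp_length Epochs over which the consistency weight ramps up.
#' @param weight_decay L2 penalty on weight matrices (decoupled from the
#'   loss value; applied to the gradients), taming extrapolation on
#'   signatures far from the labeled pairs.
#' @param sigma Positive-label weight; `"auto"` (default) computes the
#'   positive:negative ratio from the training records.
#' @param sigma_inverse If `TRUE`, use the inverse ratio (up-weighting the
#'   rare positive class) instead of the printed positive/negative ratio.
#' @param consistency_all If `TRUE`, apply the consistency term to labeled
#'   diseases as well as unlabeled ones (classic Pi-model behaviour);
#'   default restricts it to the unlabeled set.
#' @param seed Integer seed for initialization, batching, dropout and
#'   patient sampling.
#' @return A list of class `pi_config`.
#' @export
pi_config <- function(hidden = c(128, 64, 32), dropout = 0.2, lr = 1e-3,
                      epochs = 150, b_pro = 16, b_dis = 8, w_max = 1,
                      ramp_length = 80, weight_decay = 1e-3,
                      sigma = "auto",
                      sigma_inverse = FALSE, consistency_all = FALSE,
                      seed = 1) {
  stopifnot(length(hidden) == 3, dropout >= 0, dropout < 1)
  structure(
    list(hidden = hidden, dropout = dropout, lr = lr, epochs = epochs,
         b_pro = b_pro, b_dis = b_dis, w_max = w_max,
         ramp_length = ramp_length, weight_decay = weight_decay,
         sigma = sigma,
         sigma_inverse = sigma_inverse, consistency_all = consistency_all,
         seed = seed),
    class = "pi_config"
  )
}

#' Positive-label weight
#'
#' The ratio of positive to negative labels in the training set, used to
#' weight the positive term of the cross-entropy loss. (With rare
#' positives this ratio down-weights them; see `sigma_inverse` in
#' [pi_config()] for the inverted convention.)
#'
#' @param labels Binary vector (0/1).
#' @return `sum(labels == 1) / sum(labels == 0)`.
#' @export
positive_weight <- function(labels) {
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    vq_abort("need at least one positive and one negative label",
             "vqtarget_label_error")
  }
  n_pos / n_neg
}

#' Consistency ramp-up weight
#'
#' Gaussian ramp `w_max * exp(-5 * (1 - min(tau, T_r) / T_r)^2)`: close to
#' zero at the first epoch, nondecreasing, and equal to `w_max` from epoch
#' `T_r` on, so early training is label-driven.
#'
#' @param tau Epoch index (0-based ramp position).
#' @param w_max Final weight.
#' @param ramp_length Ramp duration `T_r` in epochs.
#' @return The weight at epoch `tau`.
#' @export
ramp_weight <- function(tau, w_max = 1, ramp_length = 80) {
  frac <- pmin(tau, ramp_length) / ramp_length
  w_max * exp(-5 * (1 - frac)^2)
}

#' Weighted binary cross-entropy over the labeled pairs of a minibatch
#'
#' `-(1 / (|B_Pro| * |B_Dis|)) * sum(sigma * y * log(u) + (1 - y) * log(1 - u))`,
#' summed over the labeled pairs present in the batch. Predictions are
#' clamped to `[1e-7, 1 - 1e-7]` before logs.
#'
#' @param u Predicted probabilities for the labeled pairs.
#' @param y Binary labels.
#' @param sigma Positive-label weight (see [positive_weight()]).
#' @param n_bpro,n_bdis Protein and disease minibatch sizes (the
#'   normalizer is their product, not the labeled-pair count).
#' @return A nonnegative scalar.
#' @export
supervised_loss <- function(u, y, sigma, n_bpro, n_bdis) {
  stopifnot(length(u) == length(y))
  u <- clamp_unit(u)
  -(1 / (n_bpro * n_bdis)) *
    sum(sigma * y * log(u) + (1 - y) * log(1 - u))
}

#' Consistency loss between the two stochastic passes
#'
#' `omega * (1 / (2 * |B_Pro| * |B_Dis|)) * sum((u - u_tilde)^2)` over the
#' unlabeled-disease pairs of the minibatch, where `u` is predicted from
#' protein-disease features and `u_tilde` from protein-patient features
#' under an independent dropout draw.
#'
#' @param u,u_tilde Predictions from the two passes (equal lengths).
#' @param omega Ramp weight for the current epoch, see [ramp_weight()].
#' @param n_bpro,n_bdis Protein and disease minibatch sizes.
#' @return A nonnegative scalar, 0 when `omega` is 0.
#' @export
consistency_loss <- function(u, u_tilde, omega, n_bpro, n_bdis) {
  if (length(u) != length(u_tilde)) {
    vq_abort("u and u_tilde must have equal length", "vqtarget_shape_error")
  }
  omega * (1 / (2 * n_bpro * n_bdis)) * sum((u - u_tilde)^2)
}

#' Total training loss
#'
#' @param l_sup Supervised loss, see [supervised_loss()].
#' @param l_uns Consistency loss, see [consistency_loss()].
#' @return Their sum.
#' @export
total_loss <- function(l_sup, l_uns) {
  stopifnot(is.finite(l_sup), is.finite(l_uns))
  l_sup + l_uns
}

#' Randomly select one patient signature for a disease
#'
#' When a disease has several patient-level signatures, the consistency
#' pass uses one drawn uniformly at random (re-drawn every minibatch).
#'
#' @param disease_id Disease identifier.
#' @param patient_sigs A patient-level `signature_set`.
#' @param patient_to_disease Data frame mapping `patient_id` to
#'   `disease_id`.
#' @return The selected patient's signature vector.
#' @export
sample_patient_signature <- function(disease_id, patient_sigs,
                                     patient_to_disease) {
  pats <- patient_to_disease$patient_id[
    patient_to_disease$disease_id == disease_id
  ]
  pats <- intersect(pats, patient_sigs$ids)
  if (length(pats) == 0) {
    vq_abort(sprintf("disease '%s' has no patient signature", disease_id),
             "vqtarget_cohort_error")
  }
  chosen <- pats[sample.int(length(pats), 1L)]
  patient_sigs$matrix[chosen, ]
}

classifier_layers <- function(n_in, config) {
  h <- config$hidden
  list(
    nn_dense(n_in, h[1], act = "relu", dropout = config$dropout),
    nn_dense(h[1], h[2], act = "relu", dropout = config$dropout),
    nn_dense(h[2], h[3], act = "relu", dropout = config$dropout),
    nn_dense(h[3], 1L, act = "sigmoid")
  )
}

# Shared engine behind train_pi_model() / train_supervised().
pi_train_engine <- function(protein_sigs, disease_sigs, patient_sigs,
                            labels, unlabeled_diseases, config,
                            patient_to_disease) {
  records <- labels$records
  r_set <- labels$known_proteins
  m_set <- labels$known_diseases
  n_set <- unlabeled_diseases
  if (length(m_set) == 0) {
    vq_abort("no known diseases to train on", "vqtarget_label_error")
  }
  if (length(r_set) == 0) {
    vq_abort("no known proteins to train on", "vqtarget_label_error")
  }
  all_dis <- c(m_set, n_set)
  missing_p <- setdiff(r_set, protein_sigs$ids)
  missing_d <- setdiff(all_dis, disease_sigs$ids)
  if (length(missing_p) > 0 || length(missing_d) > 0) {
    vq_abort(sprintf("missing signatures for: %s",
                     paste(c(missing_p, missing_d), collapse = ", ")),
             "vqtarget_shape_error")
  }

  sigma <- if (identical(config$sigma, "auto")) {
    positive_weight(records$label)
  } else {
    as.numeric(config$sigma)
  }
  if (config$sigma_inverse) sigma <- 1 / sigma

  h_pro <- ncol(protein_sigs$matrix)
  h_dis <- ncol(disease_sigs$matrix)
  label_key <- paste(records$protein_id, records$disease_id)

  # per-dimension standardization of the signature inputs, fitted on the
  # training entities; patient signatures share the disease transform
  input_std <- list(
    protein = standardize_fit(protein_sigs$matrix[r_set, , drop = FALSE]),
    disease = standardize_fit(disease_sigs$matrix[all_dis, , drop = FALSE])
  )
  protein_sigs$matrix <- standardize_apply(protein_sigs$matrix,
                                           input_std$protein)
  disease_sigs$matrix <- standardize_apply(disease_sigs$matrix,
                                           input_std$disease)
  if (nrow(patient_sigs$matrix) > 0) {
    patient_sigs$matrix <- standardize_apply(patient_sigs$matrix,
                                             input_std$disease)
  }

  with_seed_if(config$seed, {
    layers <- classifier_layers(h_pro + h_dis, config)
    params <- nn_params(layers)
    opt <- adam_new(params, lr = config$lr)

    use_consistency <- config$w_max > 0 && length(n_set) > 0
    cons_dis <- if (config$consistency_all) all_dis else n_set
    log_rows <- vector("list", config$epochs)

    for (epoch in seq_len(config$epochs)) {
      omega <- ramp_weight(epoch - 1, config$w_max, config$ramp_length)
      n_steps <- ceiling(length(r_set) / config$b_pro) *
        ceiling(length(all_dis) / config$b_dis)
      sup_acc <- 0
      uns_acc <- 0
      for (step in seq_len(n_steps)) {
        b_pro <- sample(r_set, min(config$b_pro, length(r_set)))
        b_dis <- sample(all_dis, min(config$b_dis, length(all_dis)))
        n_bpro <- length(b_pro)
        n_bdis <- length(b_dis)

        pairs <- tidyr::expand_grid(protein_id = b_pro, disease_id = b_dis)
        phi <- cbind(protein_sigs$matrix[pairs$protein_id, , drop = FALSE],
                     disease_sigs$matrix[pairs$disease_id, , drop = FALSE])
        fwd <- nn_forward(layers, phi, train = TRUE)
        u <- clamp_unit(as.numeric(fwd$out))

        lab_idx <- match(paste(pairs$protein_id, pairs$disease_id),
                         label_key)
        labeled <- which(!is.na(lab_idx))
        y <- records$label[lab_idx[labeled]]

        d_u <- numeric(length(u))
        l_sup <- 0
        if (length(labeled) > 0) {
          ul <- u[labeled]
          l_sup <- supervised_loss(ul, y, sigma, n_bpro, n_bdis)
          d_u[labeled] <- d_u[labeled] -
            (sigma * y / ul - (1 - y) / (1 - ul)) / (n_bpro * n_bdis)
        }

        l_uns <- 0
        grads2 <- NULL
        if (use_consistency) {
          cons_rows <- which(pairs$disease_id %in% cons_dis)
        } else {
          cons_rows <- integer(0)
        }
        if (length(cons_rows) > 0) {
          b_cons <- unique(pairs$disease_id[cons_rows])
          pat_sig <- vapply(
            b_cons,
            function(d) sample_patient_signature(d, patient_sigs,
                                                 patient_to_disease),
            numeric(ncol(patient_sigs$matrix))
          )
          pat_sig <- t(pat_sig)
          rownames(pat_sig) <- b_cons
          phi_prime <- cbind(
            protein_sigs$matrix[pairs$protein_id[cons_rows], ,
                                drop = FALSE],
            pat_sig[pairs$disease_id[cons_rows], , drop = FALSE]
          )
          fwd2 <- nn_forward(layers, phi_prime, train = TRUE)
          u_tilde <- clamp_unit(as.numeric(fwd2$out))
          uc <- u[cons_rows]
          l_uns <- consistency_loss(uc, u_tilde, omega, n_bpro, n_bdis)
          scale <- omega / (n_bpro * n_bdis)
          d_u[cons_rows] <- d_u[cons_rows] + scale * (uc - u_tilde)
          d_u2 <- -scale * (uc - u_tilde)
          grads2 <- nn_backward(layers, fwd2$caches,
                                matrix(d_u2, ncol = 1))$grads
        }

        grads <- nn_backward(layers, fwd$caches,
                             matrix(d_u, ncol = 1))$grads
        if (!is.null(grads2)) {
          grads <- nn_map2(grads, grads2, `+`)
        }
        if (config$weight_decay > 0) {
          grads <- apply_weight_decay(grads, params, config$weight_decay)
        }
        stepped <- adam_step(params, grads, opt)
        params <- stepped$params
        opt <- stepped$state
        layers <- nn_set_params(layers, params)

        sup_acc <- sup_acc + l_sup
        uns_acc <- uns_acc + l_uns
      }
      log_rows[[epoch]] <- tibble::tibble(
        epoch = epoch,
        supervised = sup_acc / n_steps,
        unsupervised = uns_acc / n_steps,
        omega = omega,
        total = (sup_acc + uns_acc) / n_steps
      )
    }

    structure(
      list(layers = layers, config = config, sigma = sigma,
           input_std = input_std,
           h_pro = h_pro, h_dis = h_dis,
           known_proteins = r_set, known_diseases = m_set,
           unlabeled_diseases = n_set,
           direction = labels$direction,
           log = dplyr::bind_rows(log_rows)),
      class = "pi_classifier"
    )
  })
}

apply_weight_decay <- function(grads, params, wd) {
  for (i in seq_along(grads)) {
    if (!is.null(grads[[i]]$W)) {
      grads[[i]]$W <- grads[[i]]$W + wd * params[[i]]$W
    }
    if (!is.null(grads[[i]]$Ws)) {
      grads[[i]]$Ws <- Map(function(g, p) g + wd * p,
                           grads[[i]]$Ws, params[[i]]$Ws)
    }
  }
  grads
}

nn_map2 <- function(a, b, f) {
  if (is.list(a)) {
    Map(function(x, y) nn_map2(x, y, f), a, b)
  } else {
    f(a, b)
  }
}

#' Train the Pi-model semi-supervised classifier
#'
#' Per epoch and minibatch (a Cartesian product of sampled proteins and
#' diseases), the network is evaluated on protein-disease features for all
#' pairs and, under an independent dropout draw, on protein-patient
#' features for pairs whose disease is unlabeled; the weighted
#' cross-entropy over the labeled pairs plus the ramped consistency loss is
#' minimized with ADAM.
#'
#' @param protein_sigs,disease_sigs,patient_sigs `signature_set`s for
#'   proteins, diseases and patients (patient signatures must cover every
#'   disease in the unlabeled set).
#' @param labels A [labeled_pairs()] table (diseases in its records form
#'   the known set M, its proteins the known set R).
#' @param unlabeled_diseases Character vector of uncharacterized diseases N
#'   (default: the label table's `unlabeled_diseases`).
#' @param patient_to_disease Data frame mapping `patient_id` to
#'   `disease_id`.
#' @param config A [pi_config()].
#' @return A fitted `pi_classifier` with a per-epoch training log
#'   (`supervised`, `unsupervised`, `omega`, `total`).
#' @export
train_pi_model <- function(protein_sigs, disease_sigs, patient_sigs,
                           labels, patient_to_disease,
                           unlabeled_diseases = labels$unlabeled_diseases,
                           config = pi_config()) {
  fit <- pi_train_engine(protein_sigs, disease_sigs, patient_sigs, labels,
                         unlabeled_diseases, config, patient_to_disease)
  fit$mode <- "ssl"
  fit
}

#' Train the supervised ablation
#'
#' Identical architecture and optimization, but only labeled
#' protein-disease pairs contribute: no patient pass, no consistency term.
#' With `w_max = 0` and an empty unlabeled set, [train_pi_model()] and
#' `train_supervised()` follow identical parameter trajectories under the
#' same seed.
#'
#' @inheritParams train_pi_model
#' @return A fitted `pi_classifier` whose log has no unsupervised column.
#' @export
train_supervised <- function(protein_sigs, disease_sigs, labels,
                             config = pi_config()) {
  cfg <- config
  cfg$w_max <- 0
  dummy_patients <- signature_set(
    "patient_vq",
    disease_sigs$matrix[0, , drop = FALSE],
    character(0)
  )
  fit <- pi_train_engine(protein_sigs, disease_sigs, dummy_patients, labels,
                         character(0), cfg,
                         tibble::tibble(patient_id = character(),
                                        disease_id = character()))
  fit$mode <- "sl"
  fit$log <- fit$log[, c("epoch", "supervised", "total")]
  fit
}

#' @export
print.pi_classifier <- function(x, ...) {
  cat(sprintf(
    "<pi_classifier> %s, input %d = %d + %d, hidden (%s), sigma = %.4g, %d epochs\n",
    toupper(x$mode), x$h_pro + x$h_dis, x$h_pro, x$h_dis,
    paste(x$config$hidden, collapse = ", "), x$sigma, x$config$epochs
  ))
  invisible(x)
}

#' @export
n_parameters.pi_classifier <- function(model) {
  as.integer(nn_n_parameters(model$layers))
}

#' Score protein-disease pairs
#'
#' Evaluates the classifier (dropout disabled) on every requested pair;
#' deterministic given the model and signatures.
#'
#' @param model A fitted `pi_classifier`.
#' @param protein_ids,disease_ids Ids to cross; every id must have a
#'   signature.
#' @param protein_sigs,disease_sigs `signature_set`s.
#' @return A tibble with columns `protein_id`, `disease_id`, `score`
#'   (in (0, 1)), one row per pair.
#' @export
predict_pairs <- function(model, protein_ids, disease_ids, protein_sigs,
                          disease_sigs) {
  missing_p <- setdiff(protein_ids, protein_sigs$ids)
  missing_d <- setdiff(disease_ids, disease_sigs$ids)
  if (length(missing_p) > 0 || length(missing_d) > 0) {
    vq_abort(sprintf("unknown id(s): %s",
                     paste(head(c(missing_p, missing_d), 5),
                           collapse = ", ")),
             "vqtarget_id_error")
  }
  pairs <- tidyr::expand_grid(protein_id = protein_ids,
                              disease_id = disease_ids)
  pmat <- protein_sigs$matrix
  dmat <- disease_sigs$matrix
  if (!is.null(model$input_std)) {
    pmat <- standardize_apply(pmat, model$input_std$protein)
    dmat <- standardize_apply(dmat, model$input_std$disease)
  }
  n <- nrow(pairs)
  u <- numeric(n)
  chunk <- 50000L
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    phi <- cbind(
      pmat[pairs$protein_id[idx], , drop = FALSE],
      dmat[pairs$disease_id[idx], , drop = FALSE]
    )
    u[idx] <- as.numeric(nn_forward(model$layers, phi, train = FALSE)$out)
  }
  tibble::tibble(protein_id = pairs$protein_id,
                 disease_id = pairs$disease_id,
                 score = clamp_unit(u))
}
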