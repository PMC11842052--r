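# ROC/AUC computation and the three cold-start evaluation protocols:
# pair-wise target repositioning, new targets for uncharacterized
# diseases, and new indications for uncharacterized proteins.

#' ROC curve and AUC
#'
#' AUC is the probability that a randomly chosen positive outscores a
#' randomly chosen negative, with ties counted half (the Mann-Whitney
#' formulation). The curve sweeps all score thresholds from high to low.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1 or logical), same length.
#' @return An object of class `roc_result`: `auc`, `curve` (tibble of
#'   `threshold`, `fpr`, `tpr` starting at (0,0) and ending at (1,1)),
#'   `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    vq_abort("need at least one positive and one negative label",
             "vqtarget_label_error")
  }
  r <- rank(scores) # midranks: ties get half credit
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  ord <- order(scores, decreasing = TRUE)
  s_sorted <- scores[ord]
  y_sorted <- labels[ord]
  # one curve point per distinct threshold
  last_of_tie <- c(diff(s_sorted) != 0, TRUE)
  tp <- cumsum(y_sorted)[last_of_tie]
  fp <- cumsum(1 - y_sorted)[last_of_tie]
  curve <- tibble::tibble(
    threshold = c(Inf, s_sorted[last_of_tie]),
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos)
  )
  structure(list(auc = auc, curve = curve, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.4f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Pair-wise cross-validation folds
#'
#' Randomly partitions labeled protein-disease pairs into `k` roughly
#' equal folds (sizes differ by at most one); each fold serves as the test
#' set in turn.
#'
#' @param labels A [labeled_pairs()] object or a records data frame.
#' @param k Number of folds.
#' @param seed Optional seed.
#' @return A list of `k` scenario splits, each a list with `scenario`,
#'   `fold`, `train` and `test` record tibbles.
#' @export
pairwise_cv_split <- function(labels, k = 5, seed = NULL) {
  records <- if (inherits(labels, "labeled_pairs")) labels$records else
    tibble::as_tibble(labels)
  n <- nrow(records)
  if (n < k) {
    vq_abort("fewer labeled pairs than folds", "vqtarget_config_error")
  }
  fold_of <- with_seed_if(seed, sample(rep(seq_len(k), length.out = n)))
  lapply(seq_len(k), function(f) {
    list(scenario = "target_repositioning", fold = f,
         train = records[fold_of != f, , drop = FALSE],
         test = records[fold_of == f, , drop = FALSE])
  })
}

#' Rank predictions within each disease
#'
#' Dense ranks per disease, descending by score; tied scores share a rank.
#' Ranks are invariant under strictly increasing transforms of the score.
#'
#' @param predictions A tibble with `protein_id`, `disease_id`, `score`.
#' @return The tibble with a `rank` column added.
#' @export
rank_predictions <- function(predictions) {
  stopifnot(all(is.finite(predictions$score)))
  predictions |>
    dplyr::group_by(.data$disease_id) |>
    dplyr::mutate(rank = dplyr::dense_rank(dplyr::desc(.data$score))) |>
    dplyr::ungroup()
}

# ---- the benchmark pipeline --------------------------------------------

#' Desk-scale pipeline configuration
#'
#' Bundles the representation and classifier configurations used on the
#' synthetic benchmark. Layer widths are scaled to the 60-gene fixtures so
#' the full pipeline trains in seconds on one CPU; all values are plain
#' config keys.
#'
#' @param variant Protein representation variant, see
#'   [train_protein_vqvae()].
#' @param mode `"ssl"` (Pi-model with unlabeled diseases) or `"sl"`
#'   (supervised ablation).
#' @param protein_vq,disease_vq [vq_config()]s for the two signature
#'   models. The desk-scale defaults use a narrow cell block and a large
#'   leaky-rectifier slope (near-linear encoders keep additively planted
#'   perturbation programs additive in latent space).
#' @param classifier A [pi_config()]; the desk-scale default shrinks the
#'   hidden widths and raises the weight decay so the decision surface
#'   stays smooth over signatures far from the few labeled pairs.
#' @param seed Master seed; overrides the component seeds.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(variant = "multimodal", mode = "ssl",
                            protein_vq = vq_config(H = 8,
                                                   cell_block_width = 16,
                                                   fused_widths = c(64, 32),
                                                   epochs = 150,
                                                   leaky_slope = 0.3),
                            disease_vq = vq_config(H = 8,
                                                   cell_block_width = 64,
                                                   fused_widths = c(256, 64),
                                                   epochs = 150,
                                                   leaky_slope = 0.3),
                            classifier = pi_config(hidden = c(64, 32, 16),
                                                   weight_decay = 1e-2),
                            seed = 1) {
  protein_vq$seed <- seed
  disease_vq$seed <- seed + 1L
  classifier$seed <- seed + 2L
  structure(
    list(variant = variant, mode = mode, protein_vq = protein_vq,
         disease_vq = disease_vq, classifier = classifier, seed = seed),
    class = "pipeline_config"
  )
}

#' Train both signature models on a benchmark bundle
#'
#' Imputes the tensor if needed, trains the protein representation (chosen
#' variant) and the disease/patient representation, and extracts the three
#' signature sets the classifier consumes.
#'
#' @param bundle A [make_benchmark()] bundle (or any list with `tensor`
#'   and `cohort`).
#' @param config A [pipeline_config()].
#' @return A list with `protein`, `disease`, `patient` signature sets and
#'   the two fitted models.
#' @export
benchmark_signatures <- function(bundle, config = pipeline_config()) {
  tensor <- if (any(bundle$tensor$missing)) impute_missing(bundle$tensor)
    else bundle$tensor
  protein_model <- train_protein_vqvae(tensor, variant = config$variant,
                                       config = config$protein_vq)
  disease_model <- train_disease_vqvae(
    bundle$cohort, config = config$disease_vq,
    latent = if (config$variant == "vae") "gaussian" else "vq"
  )
  list(
    protein = extract_signatures(protein_model, tensor),
    disease = extract_signatures(disease_model, bundle$cohort,
                                 level = "disease"),
    patient = extract_signatures(disease_model, bundle$cohort,
                                 level = "patient"),
    protein_model = protein_model,
    disease_model = disease_model
  )
}

fit_classifier <- function(sigs, labels, bundle, config,
                           unlabeled = labels$unlabeled_diseases) {
  if (config$mode == "ssl") {
    train_pi_model(sigs$protein, sigs$disease, sigs$patient, labels,
                   patient_to_disease = bundle$cohort$patient_to_disease,
                   unlabeled_diseases = unlabeled,
                   config = config$classifier)
  } else {
    train_supervised(sigs$protein, sigs$disease, labels,
                     config = config$classifier)
  }
}

#' Run one evaluation scenario on a benchmark bundle
#'
#' * `"repositioning"`: 5-fold pair-wise cross-validation over the label
#'   records; scores are pooled over folds into one ROC.
#' * `"new_targets"`: train on all records (known diseases M), score every
#'   known protein against every uncharacterized disease in N, and compute
#'   a per-disease ROC against the held-out truth (unlabeled scored pairs
#'   count as negatives).
#' * `"new_indications"`: train on all records, score each held-out
#'   protein (no training labels) against all diseases, per-protein ROC
#'   against the held-out truth.
#'
#' @param scenario One of `"repositioning"`, `"new_targets"`,
#'   `"new_indications"`.
#' @param bundle A [make_benchmark()] bundle.
#' @param config A [pipeline_config()].
#' @param signatures Optional precomputed [benchmark_signatures()] result
#'   (reused across scenarios or label permutations).
#' @param labels Optional replacement [labeled_pairs()] (e.g. permuted
#'   labels for a null check); defaults to the bundle's.
#' @param scorer Optional scoring function replacing the trained pipeline:
#'   takes a tibble of pairs (`protein_id`, `disease_id`, plus `label` for
#'   cross-validated test pairs) and returns numeric scores. Used to probe
#'   the evaluation protocol itself (oracle or constant scorers).
#' @return An object of class `scenario_result`: `scenario`, `per_unit`
#'   (tibble of `unit_id`, `n_pos`, `n_neg`, `auc`), `pooled`
#'   ([roc_auc()] result or `NULL`), `predictions`, `mean_auc`.
#' @export
run_scenario <- function(scenario = c("repositioning", "new_targets",
                                      "new_indications"),
                         bundle, config = pipeline_config(),
                         signatures = NULL, labels = NULL, scorer = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(bundle, "benchmark_bundle"))
  labels <- labels %||% bundle$labels
  sigs <- if (is.null(scorer)) signatures %||%
    benchmark_signatures(bundle, config) else NULL

  if (scenario == "repositioning") {
    folds <- pairwise_cv_split(labels, k = 5, seed = config$seed)
    scored <- lapply(folds, function(fold) {
      if (nrow(fold$test) == 0) return(NULL)
      if (!is.null(scorer)) {
        return(dplyr::mutate(fold$test, score = scorer(fold$test),
                             fold = fold$fold))
      }
      fold_labels <- labeled_pairs(
        fold$train, unlabeled_diseases = labels$unlabeled_diseases,
        direction = labels$direction
      )
      model <- fit_classifier(sigs, fold_labels, bundle, config)
      preds <- predict_pairs(model, unique(fold$test$protein_id),
                             unique(fold$test$disease_id),
                             sigs$protein, sigs$disease)
      dplyr::inner_join(fold$test, preds,
                        by = c("protein_id", "disease_id")) |>
        dplyr::mutate(fold = fold$fold)
    })
    scored <- dplyr::bind_rows(scored)
    pooled <- roc_auc(scored$score, scored$label)
    per_unit <- tibble::tibble(unit_id = "pooled", n_pos = pooled$n_pos,
                               n_neg = pooled$n_neg, auc = pooled$auc)
    return(structure(
      list(scenario = scenario, per_unit = per_unit, pooled = pooled,
           predictions = scored, mean_auc = pooled$auc),
      class = "scenario_result"
    ))
  }

  model <- if (is.null(scorer)) fit_classifier(sigs, labels, bundle, config)
    else NULL
  score_grid <- function(protein_ids, disease_ids) {
    if (is.null(scorer)) {
      predict_pairs(model, protein_ids, disease_ids,
                    sigs$protein, sigs$disease)
    } else {
      pairs <- tidyr::expand_grid(protein_id = protein_ids,
                                  disease_id = disease_ids)
      dplyr::mutate(pairs, score = scorer(pairs))
    }
  }

  if (scenario == "new_targets") {
    truth <- bundle$scenario2_truth
    test_diseases <- bundle$unlabeled_diseases
    overlap <- intersect(
      paste(labels$records$protein_id, labels$records$disease_id),
      paste(truth$protein_id, truth$disease_id)
    )
    if (length(overlap) > 0) {
      vq_abort("held-out truth overlaps training labels",
               "vqtarget_leak_error")
    }
    # candidate targets: every profiled protein (full-grid scoring), so
    # cold diseases are ranked against proteins the labels never mention;
    # the disjoint uncharacterized-protein test set is evaluated in
    # scenario 3 and excluded here
    candidates <- setdiff(bundle$protein_ids, bundle$heldout_proteins)
    preds <- score_grid(candidates, test_diseases)
    per_unit <- per_unit_roc(preds, truth, unit = "disease_id")
  } else {
    truth <- bundle$scenario3_truth
    test_proteins <- setdiff(bundle$heldout_proteins,
                             labels$known_proteins)
    if (length(test_proteins) == 0) {
      vq_abort("no held-out proteins outside the training labels",
               "vqtarget_leak_error")
    }
    all_diseases <- c(labels$known_diseases, labels$unlabeled_diseases)
    preds <- score_grid(test_proteins, all_diseases)
    per_unit <- per_unit_roc(preds, truth, unit = "protein_id")
  }

  structure(
    list(scenario = scenario, per_unit = per_unit, pooled = NULL,
         predictions = preds, mean_auc = mean(per_unit$auc)),
    class = "scenario_result"
  )
}

# Per-disease (or per-protein) ROC of a prediction grid against curated
# positives; every scored pair absent from the truth set is a negative.
per_unit_roc <- function(preds, truth, unit) {
  truth_key <- paste(truth$protein_id, truth$disease_id)
  preds$label <- as.integer(
    paste(preds$protein_id, preds$disease_id) %in% truth_key
  )
  units <- unique(preds[[unit]][preds$label == 1])
  rows <- lapply(units, function(uid) {
    sub <- preds[preds[[unit]] == uid, ]
    r <- roc_auc(sub$score, sub$label)
    tibble::tibble(unit_id = uid, n_pos = r$n_pos, n_neg = r$n_neg,
                   auc = r$auc)
  })
  dplyr::bind_rows(rows)
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s: mean AUC %.4f over %d unit(s)\n",
              x$scenario, x$mean_auc, nrow(x$per_unit)))
  invisible(x)
}

#' Permute labels for a null-signal check
#'
#' Returns a copy of the label table with the label column randomly
#' permuted across records; a classifier trained on it should score at
#' chance.
#'
#' @param labels A [labeled_pairs()] object.
#' @param seed Optional seed.
#' @return A [labeled_pairs()] with permuted labels.
#' @export
permute_labels <- function(labels, seed = NULL) {
  records <- labels$records
  records$label <- with_seed_if(seed, sample(records$label))
  labeled_pairs(records, unlabeled_diseases = labels$unlabeled_diseases,
                direction = labels$direction)
}
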