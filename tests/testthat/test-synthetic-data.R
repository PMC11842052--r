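# synthetic_data: planted-signal generator and benchmark bundle.

test_that("disease cohort generator plants its programs", {
  # noiseless limit: every patient of a disease identical, disease row too
  cfg0 <- sim_config(n_diseases = 3, patients_per_disease = 2,
                     n_genes_disease = 12, module_size = 3,
                     noise_sd = 0, seed = 4)
  sim0 <- simulate_disease_cohort(cfg0)
  pm <- sim0$cohort$patient_matrix
  expect_equal(pm[1, ], pm[2, ])
  expect_equal(as.numeric(sim0$cohort$disease_matrix[1, ]),
               unname(pm[1, ]))

  # determinism: same config twice is bit-identical
  expect_identical(simulate_disease_cohort(cfg0),
                   simulate_disease_cohort(cfg0))

  # sampling oracle: program-gene minus background mean ~ effect_size
  cfg <- sim_config(n_diseases = 2, patients_per_disease = 20,
                    n_genes_disease = 30, module_size = 5,
                    effect_size = 3, noise_sd = 1, seed = 8)
  sim <- simulate_disease_cohort(cfg)
  d <- sim$cohort$disease_ids[1]
  prog <- sim$programs[[d]]
  rows <- sim$cohort$patient_matrix[
    sim$cohort$patient_to_disease$patient_id[
      sim$cohort$patient_to_disease$disease_id == d], ]
  gap <- mean(rows[, prog]) - mean(rows[, setdiff(colnames(rows), prog)])
  se <- 1 / sqrt(length(rows[, prog]))
  expect_lt(abs(gap - 3), 3 * se)

  # disjoint programs cover distinct genes
  expect_length(unique(unlist(sim$programs)), 2 * 5)
  expect_error(sim_config(n_diseases = 5, module_size = 10,
                          n_genes_disease = 20),
               class = "vqtarget_config_error")
})

test_that("perturbation tensor plants therapeutic reversals", {
  cfg <- sim_config(n_proteins = 10, n_cells = 4, n_genes_perturb = 20,
                    n_genes_disease = 20, n_diseases = 4, module_size = 5,
                    n_positive_pairs = 3, missing_fraction = 0.5,
                    noise_sd = 0, seed = 2)
  sim_d <- simulate_disease_cohort(cfg)
  sim_p <- simulate_perturbation_tensor(cfg, sim_d$programs)

  # missing-count arithmetic: half of 10 x 4 slices masked
  expect_equal(sum(sim_p$tensor$missing), 20)

  # noiseless limit: program genes show exactly -effect_size x cell scale
  pos <- sim_p$positives[1, ]
  prog <- sim_d$programs[[pos$disease_id]]
  s <- match(pos$protein_id, sim_p$tensor$protein_ids)
  for (c_ in seq_len(cfg$n_cells)) {
    expect_equal(
      unname(sim_p$tensor$values[s, c_, prog]),
      rep(-cfg$effect_size * unname(sim_p$cell_scales[c_]), 5),
      tolerance = 1e-12
    )
  }
  # cell scales drawn once per cell, inside (0.5, 1.5)
  expect_true(all(sim_p$cell_scales > 0.5 & sim_p$cell_scales < 1.5))

  # label table: positives and an equal number of sampled negatives,
  # unplanted diseases assigned to N
  expect_equal(sum(sim_p$labels$records$label == 1), 3)
  expect_equal(sum(sim_p$labels$records$label == 0), 3)
  expect_setequal(
    c(sim_p$labels$known_diseases, sim_p$labels$unlabeled_diseases),
    names(sim_d$programs)
  )

  expect_error(
    simulate_perturbation_tensor(
      cfg, sim_d$programs,
      positives = tibble::tibble(protein_id = "nope", disease_id = "d")
    ),
    class = "vqtarget_config_error"
  )
})

test_that("planted positives anti-correlate with their disease profile", {
  # Monte-Carlo oracle: cell-averaged positive slice vs disease row
  neg_frac <- mean(sapply(1:100, function(s) {
    cfg <- sim_config(n_proteins = 6, n_cells = 2, n_genes_perturb = 24,
                      n_genes_disease = 24, n_diseases = 3,
                      patients_per_disease = 4, module_size = 4,
                      n_positive_pairs = 2, missing_fraction = 0, seed = s)
    sd_ <- simulate_disease_cohort(cfg)
    sp <- simulate_perturbation_tensor(cfg, sd_$programs)
    pos <- sp$positives[1, ]
    slice <- colMeans(sp$tensor$values[pos$protein_id, , ])
    drow <- sd_$cohort$disease_matrix[pos$disease_id, ]
    cor(slice, drow) < 0
  }))
  expect_gte(neg_frac, 0.95)
})

test_that("benchmark bundle is deterministic with the documented shape", {
  b1 <- make_benchmark(123)
  b2 <- make_benchmark(123)
  expect_identical(serialize(b1, NULL), serialize(b2, NULL))

  expect_length(b1$known_diseases, 8)
  expect_length(b1$unlabeled_diseases, 4)
  expect_equal(sum(b1$labels$records$label == 1), 10)
  expect_equal(sum(b1$labels$records$label == 0), 10)
  expect_equal(dim(b1$tensor$values), c(40, 3, 60))
  expect_equal(nrow(b1$cohort$patient_matrix), 72)

  # all labeled records live on known diseases; truth sets are disjoint
  # from the records and from each other
  expect_true(all(b1$labels$records$disease_id %in% b1$known_diseases))
  key <- function(df) paste(df$protein_id, df$disease_id)
  expect_length(intersect(key(b1$labels$records), key(b1$scenario2_truth)), 0)
  expect_length(intersect(key(b1$labels$records), key(b1$scenario3_truth)), 0)
  expect_true(all(b1$scenario2_truth$disease_id %in% b1$unlabeled_diseases))
  expect_false(any(b1$scenario3_truth$protein_id %in%
                     b1$labels$records$protein_id))

  # generated shapes satisfy the tensor/cohort invariants
  expect_s3_class(b1$tensor, "perturbation_tensor")
  expect_true(all(is.finite(b1$cohort$patient_matrix)))
  imp <- impute_missing(b1$tensor)
  expect_false(any(imp$missing))
  expect_true(all(is.finite(imp$values)))
})

test_that("with zero effect size a profile-based scorer is at chance", {
  # null-signal property: score by raw anti-correlation between protein
  # slice and disease profile; without planted effect the truth labels
  # carry no signal
  aucs <- sapply(1:6, function(s) {
    cfg <- sim_config(effect_size = 0, seed = s)
    b <- make_benchmark(s, config = cfg)
    tn <- impute_missing(b$tensor)
    avg <- apply(tn$values, c(1, 3), mean)
    scores <- -cor(t(avg), t(b$cohort$disease_matrix))
    truth_key <- paste(b$scenario2_truth$protein_id,
                       b$scenario2_truth$disease_id)
    grid <- tidyr::expand_grid(protein_id = rownames(avg),
                               disease_id = b$unlabeled_diseases)
    grid$score <- scores[cbind(grid$protein_id, grid$disease_id)]
    grid$label <- as.integer(paste(grid$protein_id, grid$disease_id)
                             %in% truth_key)
    roc_auc(grid$score, grid$label)$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("synthetic association tables favour planted targets", {
  b <- make_benchmark(6)
  pv <- snp_pv_score(b$associations$pvalues)
  eq <- snp_eqtl_score(b$associations$eqtl)
  truth_key <- paste(b$positives$protein_id, b$positives$disease_id)
  pv$is_target <- paste(pv$gene_id, pv$disease_id) %in% truth_key
  # planted targets reach genome-wide significance, background does not
  expect_gt(min(pv$score[pv$is_target]), max(pv$score[!pv$is_target]))
  eq$is_target <- paste(eq$gene_id, eq$disease_id) %in% truth_key
  expect_true(all(eq$direction[eq$is_target] == "inhibitory"))
})
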