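# Synthetic benchmark generator: L1000/CREEDS-like fixtures with planted
# target-disease structure, so the whole pipeline is testable without any
# external download.

#' Simulation configuration
#'
#' Desk-scale defaults emulate the shapes of landmark-gene perturbation
#' screens (a protein x cell x gene tensor) and a disease cohort compendium
#' (patient x gene matrix), with a recoverable planted signal: each disease
#' owns a gene program, its patients over-express that program, and a
#' therapeutic-target protein's knockdown slice reverses it.
#'
#' @param n_proteins,n_cells Number of perturbed proteins and cell types.
#' @param n_genes_perturb Genes in the perturbation tensor (desk-scale
#'   stand-in for the 978 landmark genes).
#' @param n_diseases,patients_per_disease Cohort composition.
#' @param n_genes_disease Genes in the disease/patient profiles (the
#'   defaults share one gene universe with the tensor so the planted
#'   reversal is expressible).
#' @param n_positive_pairs Number of labeled positive target-disease pairs.
#' @param module_size Genes per disease program; programs are disjoint, so
#'   `module_size * n_diseases <= n_genes_disease` is required.
#' @param effect_size Mean shift of program genes (in noise-SD units when
#'   `noise_sd = 1`).
#' @param noise_sd Baseline noise standard deviation.
#' @param missing_fraction Fraction of protein-by-cell slices masked as
#'   unmeasured, in `[0, 1)`.
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 40, n_cells = 3, n_genes_perturb = 60,
                       n_diseases = 12, patients_per_disease = 6,
                       n_genes_disease = 60, n_positive_pairs = 10,
                       module_size = 5, effect_size = 3, noise_sd = 1,
                       missing_fraction = 0.1, seed = 1) {
  cfg <- list(
    n_proteins = n_proteins, n_cells = n_cells,
    n_genes_perturb = n_genes_perturb, n_diseases = n_diseases,
    patients_per_disease = patients_per_disease,
    n_genes_disease = n_genes_disease, n_positive_pairs = n_positive_pairs,
    module_size = module_size, effect_size = effect_size,
    noise_sd = noise_sd, missing_fraction = missing_fraction,
    seed = seed
  )
  counts <- cfg[c("n_proteins", "n_cells", "n_genes_perturb", "n_diseases",
                  "patients_per_disease", "n_genes_disease", "module_size")]
  if (any(unlist(counts) < 1)) {
    vq_abort("all counts must be >= 1", "vqtarget_config_error")
  }
  if (missing_fraction < 0 || missing_fraction >= 1) {
    vq_abort("missing_fraction must lie in [0, 1)", "vqtarget_config_error")
  }
  if (module_size * n_diseases > n_genes_disease) {
    vq_abort("disjoint disease programs need module_size * n_diseases <= n_genes_disease",
             "vqtarget_config_error")
  }
  structure(cfg, class = "sim_config")
}

sim_gene_ids <- function(n) sprintf("g%03d", seq_len(n))
sim_protein_ids <- function(n) sprintf("prot%03d", seq_len(n))
sim_disease_ids <- function(n) sprintf("dis%02d", seq_len(n))
sim_cell_ids <- function(n) sprintf("cell%d", seq_len(n))

#' Simulate a disease cohort with planted gene programs
#'
#' Each disease owns a disjoint random program of `module_size` genes; each
#' patient vector is baseline Gaussian noise plus `effect_size` on its
#' disease's program genes. Disease rows are patient means via
#' [build_disease_profiles()].
#'
#' @param config A [sim_config()].
#' @return A list with `cohort` (a [cohort_profiles()] with disease matrix)
#'   and `programs` (named list: disease id -> program gene ids).
#' @export
simulate_disease_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_if(config$seed, simulate_disease_cohort_impl(config))
}

simulate_disease_cohort_impl <- function(config) {
  genes <- sim_gene_ids(config$n_genes_disease)
  diseases <- sim_disease_ids(config$n_diseases)
  pool <- sample(genes)
  programs <- lapply(seq_along(diseases), function(i) {
    sort(pool[seq((i - 1) * config$module_size + 1,
                  i * config$module_size)])
  })
  names(programs) <- diseases

  n_pat <- config$n_diseases * config$patients_per_disease
  patient_ids <- sprintf("pat%03d", seq_len(n_pat))
  disease_of <- rep(diseases, each = config$patients_per_disease)
  pm <- matrix(rnorm(n_pat * config$n_genes_disease, sd = config$noise_sd),
               nrow = n_pat, dimnames = list(patient_ids, genes))
  for (i in seq_len(n_pat)) {
    pm[i, programs[[disease_of[i]]]] <-
      pm[i, programs[[disease_of[i]]]] + config$effect_size
  }
  cohort <- cohort_profiles(
    pm,
    tibble::tibble(patient_id = patient_ids, disease_id = disease_of)
  )
  list(cohort = build_disease_profiles(cohort), programs = programs)
}

#' Simulate a perturbation tensor with planted therapeutic reversals
#'
#' For each planted positive (protein, disease) pair the protein's slice in
#' every cell shows `-effect_size` (times a mild cell-specific scale drawn
#' once per cell from Uniform(0.5, 1.5)) on that disease's program genes: a
#' therapeutic knockdown reverses the disease program. All other entries are
#' Gaussian noise, and `missing_fraction` of protein-by-cell slices are
#' masked.
#'
#' @param config A [sim_config()].
#' @param programs Named list of per-disease program gene ids, from
#'   [simulate_disease_cohort()].
#' @param positives Data frame with columns `protein_id`, `disease_id` of
#'   planted pairs; defaults to `n_positive_pairs` pairs over distinct
#'   proteins and diseases sampled with replacement from the disease set.
#' @return A list with `tensor` (a [perturbation_tensor()]), `labels` (a
#'   [labeled_pairs()] of the planted positives plus an equal number of
#'   sampled negatives), `positives` and `cell_scales`.
#' @export
simulate_perturbation_tensor <- function(config, programs, positives = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_if(
    config$seed + 1L,
    simulate_perturbation_tensor_impl(config, programs, positives)
  )
}

simulate_perturbation_tensor_impl <- function(config, programs,
                                              positives = NULL) {
  genes <- sim_gene_ids(config$n_genes_perturb)
  proteins <- sim_protein_ids(config$n_proteins)
  cells <- sim_cell_ids(config$n_cells)
  diseases <- names(programs)

  if (config$n_positive_pairs > config$n_proteins * length(diseases)) {
    vq_abort("more positive pairs than protein x disease combinations",
             "vqtarget_config_error")
  }
  if (is.null(positives)) {
    positives <- tibble::tibble(
      protein_id = sample(proteins, config$n_positive_pairs),
      disease_id = sample(diseases, config$n_positive_pairs, replace = TRUE)
    )
  }
  positives <- tibble::as_tibble(positives)
  if (!all(positives$protein_id %in% proteins) ||
      !all(positives$disease_id %in% diseases)) {
    vq_abort("positives reference unknown proteins or diseases",
             "vqtarget_config_error")
  }

  cell_scales <- runif(config$n_cells, 0.5, 1.5)
  names(cell_scales) <- cells
  values <- array(
    rnorm(config$n_proteins * config$n_cells * config$n_genes_perturb,
          sd = config$noise_sd),
    dim = c(config$n_proteins, config$n_cells, config$n_genes_perturb),
    dimnames = list(proteins, cells, genes)
  )
  for (i in seq_len(nrow(positives))) {
    s <- match(positives$protein_id[i], proteins)
    prog <- intersect(programs[[positives$disease_id[i]]], genes)
    g_idx <- match(prog, genes)
    for (c_ in seq_len(config$n_cells)) {
      values[s, c_, g_idx] <- values[s, c_, g_idx] -
        config$effect_size * cell_scales[c_]
    }
  }

  n_slices <- config$n_proteins * config$n_cells
  n_missing <- floor(config$missing_fraction * n_slices)
  missing <- matrix(FALSE, config$n_proteins, config$n_cells)
  if (n_missing > 0) {
    repeat {
      idx <- sample.int(n_slices, n_missing)
      cand <- matrix(FALSE, config$n_proteins, config$n_cells)
      cand[idx] <- TRUE
      # keep at least one observed slice per protein and per cell so the
      # two-mean imputation is defined
      if (all(rowSums(!cand) > 0) && all(colSums(!cand) > 0)) {
        missing <- cand
        break
      }
    }
  }
  tensor <- perturbation_tensor(values, proteins, cells, genes,
                                missing = missing, direction = "inhibitory")

  planted_key <- paste(positives$protein_id, positives$disease_id)
  m_set <- unique(positives$disease_id)
  grid <- tidyr::expand_grid(protein_id = proteins, disease_id = m_set)
  grid <- grid[!(paste(grid$protein_id, grid$disease_id) %in% planted_key), ]
  neg_idx <- sample.int(nrow(grid), min(nrow(positives), nrow(grid)))
  records <- dplyr::bind_rows(
    dplyr::mutate(positives, label = 1),
    dplyr::mutate(grid[neg_idx, ], label = 0)
  )
  labels <- labeled_pairs(records,
                          unlabeled_diseases = setdiff(diseases, m_set),
                          direction = "inhibitory")
  list(tensor = tensor, labels = labels, positives = positives,
       cell_scales = cell_scales)
}

#' Build the default desk-scale benchmark bundle
#'
#' One call yields a complete fixture partitioned for the three evaluation
#' scenarios: 40 proteins in 3 cell types over 60 genes, 12 diseases (8
#' known, 4 uncharacterized) with 6 patients each, 10 labeled positive
#' pairs plus 10 sampled negatives, and disjoint held-out truth sets for
#' the uncharacterized-disease and uncharacterized-protein scenarios.
#'
#' Beyond the labeled positives (known proteins x known diseases M), one
#' positive is planted per uncharacterized disease (scenario-2 truth; those
#' proteins enter the known-protein set R through negative records so they
#' are scored in the cold-disease grid), and positives are planted for
#' held-out proteins on known diseases (scenario-3 truth).
#'
#' @param seed Integer seed.
#' @param config A [sim_config()]; its `seed` is overridden by `seed`.
#' @param n_uncharacterized Number of diseases assigned to the unlabeled set
#'   N.
#' @param n_heldout_proteins Number of proteins reserved as uncharacterized
#'   (scenario 3), one planted positive each.
#' @return A list of class `benchmark_bundle` with elements `tensor`,
#'   `cohort`, `programs`, `labels`, `scenario2_truth`, `scenario3_truth`,
#'   `known_diseases`, `unlabeled_diseases`, `protein_ids`, `cell_scales`,
#'   `associations` (synthetic SNP tables) and `config`.
#' @export
make_benchmark <- function(seed = 1, config = NULL, n_uncharacterized = 4,
                           n_heldout_proteins = 4) {
  config <- config %||% sim_config()
  config$seed <- as.integer(seed)
  with_seed_if(config$seed,
               make_benchmark_impl(config, n_uncharacterized,
                                   n_heldout_proteins))
}

make_benchmark_impl <- function(config, n_uncharacterized,
                                n_heldout_proteins) {
  diseases <- sim_disease_ids(config$n_diseases)
  proteins <- sim_protein_ids(config$n_proteins)
  n_set <- sample(diseases, n_uncharacterized)
  m_set <- setdiff(diseases, n_set)

  need <- config$n_positive_pairs + n_heldout_proteins
  if (need > config$n_proteins || n_uncharacterized > config$n_positive_pairs) {
    vq_abort("not enough proteins for the requested planted pairs",
             "vqtarget_config_error")
  }
  picked <- sample(proteins, need)
  p_lab <- picked[seq_len(config$n_positive_pairs)]
  p_s3 <- picked[config$n_positive_pairs + seq_len(n_heldout_proteins)]

  # labeled positives cover every known disease at least once
  d_lab <- c(sample(m_set), sample(m_set, config$n_positive_pairs -
                                     length(m_set), replace = TRUE))
  d_lab <- d_lab[seq_len(config$n_positive_pairs)]
  lab_pos <- tibble::tibble(protein_id = p_lab, disease_id = d_lab)
  # scenario-2 truth: known target proteins repurposed toward the
  # uncharacterized diseases (their slices reverse both programs), the
  # cold-disease analogue of target repositioning
  p_s2 <- sample(p_lab, n_uncharacterized)
  s2_truth <- tibble::tibble(protein_id = p_s2, disease_id = n_set)
  s3_truth <- tibble::tibble(protein_id = p_s3,
                             disease_id = sample(m_set, n_heldout_proteins,
                                                 replace = TRUE))
  planted <- dplyr::bind_rows(lab_pos, s2_truth, s3_truth)

  sim_d <- simulate_disease_cohort_impl(config)
  sim_p <- simulate_perturbation_tensor_impl(config, sim_d$programs,
                                             positives = planted)

  # Label records: the labeled positives plus an equal number of negatives
  # sampled uniformly over pairs of unplanted proteins with known diseases
  # (a curated negative set of non-target proteins). Held-out proteins
  # (scenario-3 truth) never appear in records, so the cold-protein
  # scenario is genuinely cold.
  planted_key <- paste(planted$protein_id, planted$disease_id)
  pool <- tidyr::expand_grid(
    protein_id = setdiff(proteins, c(p_lab, p_s3)),
    disease_id = m_set
  )
  neg <- pool[sample.int(nrow(pool), config$n_positive_pairs), ]
  records <- dplyr::bind_rows(
    dplyr::mutate(lab_pos, label = 1),
    dplyr::mutate(neg, label = 0)
  )
  labels <- labeled_pairs(records, unlabeled_diseases = n_set,
                          direction = "inhibitory")

  associations <- simulate_gene_associations_impl(
    planted = planted, protein_ids = proteins, disease_ids = diseases
  )

  structure(
    list(tensor = sim_p$tensor, cohort = sim_d$cohort,
         programs = sim_d$programs, labels = labels,
         positives = planted,
         scenario2_truth = s2_truth, scenario3_truth = s3_truth,
         known_diseases = m_set, unlabeled_diseases = n_set,
         heldout_proteins = p_s3,
         protein_ids = proteins, cell_scales = sim_p$cell_scales,
         associations = associations, config = config),
    class = "benchmark_bundle"
  )
}

#' @export
print.benchmark_bundle <- function(x, ...) {
  cat(sprintf(
    "<benchmark_bundle> %d proteins x %d cells x %d genes; %d diseases (|M|=%d, |N|=%d); %d label records\n",
    length(x$protein_ids), length(x$tensor$cell_ids),
    length(x$tensor$gene_ids), x$config$n_diseases,
    length(x$known_diseases), length(x$unlabeled_diseases),
    nrow(x$labels$records)
  ))
  invisible(x)
}

#' Simulate gene-disease association tables for the SNP baselines
#'
#' Emits GWAS-style p-values and signed eQTL effects per (gene, disease)
#' record, where genes are identified with their proteins. Planted targets
#' receive genome-wide-significant p-values (10^-Uniform(4, 8)) and large
#' positive eQTL effects (inhibitory-direction convention); background
#' genes receive Uniform(0.001, 1) p-values and N(0, 0.5) effects. Each
#' disease reports the planted target plus a random ~30% of the remaining
#' genes, with one or two entries per gene to exercise the averaging and
#' summing rules.
#'
#' @param planted Data frame of planted positive pairs (`protein_id`,
#'   `disease_id`).
#' @param protein_ids,disease_ids Full id universes.
#' @param seed Optional seed (draws from the ambient RNG when `NULL`).
#' @return A list with tibbles `pvalues` and `eqtl`, each with columns
#'   `gene_id`, `disease_id`, `value`.
#' @export
simulate_gene_associations <- function(planted, protein_ids, disease_ids,
                                       seed = NULL) {
  with_seed_if(seed, simulate_gene_associations_impl(planted, protein_ids,
                                                     disease_ids))
}

simulate_gene_associations_impl <- function(planted, protein_ids,
                                            disease_ids) {
  one_disease <- function(d) {
    targets <- planted$protein_id[planted$disease_id == d]
    background <- setdiff(protein_ids, targets)
    reported <- c(targets,
                  sample(background, ceiling(0.3 * length(background))))
    n_entries <- sample(1:2, length(reported), replace = TRUE)
    gene <- rep(reported, n_entries)
    is_target <- gene %in% targets
    pv <- ifelse(is_target, 10^-runif(length(gene), 4, 8),
                 runif(length(gene), 0.001, 1))
    eff <- ifelse(is_target, abs(rnorm(length(gene), 2, 0.5)),
                  rnorm(length(gene), 0, 0.5))
    list(
      pvalues = tibble::tibble(gene_id = gene, disease_id = d, value = pv),
      eqtl = tibble::tibble(gene_id = gene, disease_id = d, value = eff)
    )
  }
  parts <- lapply(disease_ids, one_disease)
  list(
    pvalues = dplyr::bind_rows(lapply(parts, `[[`, "pvalues")),
    eqtl = dplyr::bind_rows(lapply(parts, `[[`, "eqtl"))
  )
}
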