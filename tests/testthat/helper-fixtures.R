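# Shared fixtures: tiny deterministic objects plus one lazily built (and
# cached) desk-scale benchmark with trained signatures, reused across
# test files to keep the suite fast.

tiny_tensor <- function(seed = 42, S = 6, C = 2, a = 8) {
  withr::with_seed(seed, {
    vals <- array(rnorm(S * C * a), dim = c(S, C, a))
    perturbation_tensor(vals, paste0("p", seq_len(S)),
                        paste0("c", seq_len(C)), paste0("g", seq_len(a)))
  })
}

tiny_cohort <- function(seed = 42, n_dis = 3, per = 2, b = 8) {
  withr::with_seed(seed, {
    pm <- matrix(rnorm(n_dis * per * b), n_dis * per, b)
    rownames(pm) <- paste0("pat", seq_len(nrow(pm)))
    map <- tibble::tibble(
      patient_id = rownames(pm),
      disease_id = rep(paste0("d", seq_len(n_dis)), each = per)
    )
    build_disease_profiles(cohort_profiles(pm, map))
  })
}

fast_vq_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(H = 4, K = 8, cell_block_width = 6, fused_widths = c(12, 8),
         epochs = 40, batch_size = 8, seed = seed),
    list(...)
  )
  do.call(vq_config, args)
}

random_signatures <- function(ids, h, kind = "protein_multimodal_vq",
                              seed = 7) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(length(ids) * h), length(ids), h)
    rownames(m) <- ids
    vqtarget:::signature_set(kind, m, ids)
  })
}

# small labeled-pair setup over random signatures, for classifier tests
toy_pair_setup <- function(seed = 11, n_prot = 8, n_dis = 4, n_unlab = 2,
                           h = 4) {
  withr::with_seed(seed, {
    prot <- paste0("p", seq_len(n_prot))
    dis <- paste0("d", seq_len(n_dis + n_unlab))
    m_set <- dis[seq_len(n_dis)]
    n_set <- dis[n_dis + seq_len(n_unlab)]
    grid <- tidyr::expand_grid(protein_id = prot, disease_id = m_set)
    rec <- grid[sample.int(nrow(grid), 8), ]
    rec$label <- rep(c(1, 0), each = 4)
    pats <- paste0("pat", seq_len(2 * length(dis)))
    map <- tibble::tibble(patient_id = pats,
                          disease_id = rep(dis, each = 2))
    list(
      labels = labeled_pairs(rec, unlabeled_diseases = n_set),
      protein_sigs = random_signatures(prot, h, seed = seed + 1),
      disease_sigs = random_signatures(dis, h, "disease_vq",
                                       seed = seed + 2),
      patient_sigs = random_signatures(pats, h, "patient_vq",
                                       seed = seed + 3),
      patient_to_disease = map,
      m_set = m_set, n_set = n_set, proteins = prot
    )
  })
}

fast_pi_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(hidden = c(16, 8, 4), epochs = 30, b_pro = 4, b_dis = 3,
         ramp_length = 10, seed = seed),
    list(...)
  )
  do.call(pi_config, args)
}

# cached benchmark + signatures (built once per test run)
.bench_cache <- new.env(parent = emptyenv())

cached_benchmark <- function(seed = 1) {
  key <- paste0("b", seed)
  if (is.null(.bench_cache[[key]])) {
    bundle <- make_benchmark(seed)
    config <- pipeline_config(seed = seed)
    .bench_cache[[key]] <- list(
      bundle = bundle, config = config,
      sigs = benchmark_signatures(bundle, config)
    )
  }
  .bench_cache[[key]]
}
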