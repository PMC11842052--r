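# ssl_classifier: losses, ramp, patient sampling, training behaviour and
# prediction.

test_that("positive weight is the positive:negative ratio", {
  expect_equal(positive_weight(c(1, 1, rep(0, 8))), 0.25)
  expect_equal(positive_weight(c(1, 1, 0, 0)), 1)
  # gold-standard-sized label sets: 529 positives, 6671 negatives
  expect_equal(positive_weight(c(rep(1, 529), rep(0, 6671))), 529 / 6671,
               tolerance = 1e-12)
  expect_equal(round(529 / 6671, 4), 0.0793)
  expect_error(positive_weight(c(1, 1)), class = "vqtarget_label_error")
})

test_that("supervised loss matches hand computations and a scalar loop", {
  # perfect prediction limit (pre-clamp values at the boundary)
  expect_lt(supervised_loss(c(1, 0), c(1, 0), 1, 1, 2), 1e-5)
  # single pair: y = 1, u = 0.5, sigma = 1 -> log 2
  expect_equal(supervised_loss(0.5, 1, 1, 1, 1), log(2))
  # sigma = 0 removes the positive term
  u <- c(0.8, 0.3)
  y <- c(1, 0)
  expect_equal(supervised_loss(u, y, 0, 1, 2),
               -(log(1 - 0.3)) / 2)

  # random batches vs independent scalar loop
  set.seed(30)
  for (rep in 1:5) {
    n <- sample(3:10, 1)
    u <- runif(n, 0.05, 0.95)
    y <- rbinom(n, 1, 0.5)
    if (all(y == y[1])) y[1] <- 1 - y[1]
    sigma <- runif(1, 0.1, 2)
    bp <- sample(2:5, 1); bd <- sample(2:5, 1)
    acc <- 0
    for (i in seq_len(n)) {
      acc <- acc + sigma * y[i] * log(u[i]) + (1 - y[i]) * log(1 - u[i])
    }
    expect_lt(abs(supervised_loss(u, y, sigma, bp, bd) - (-acc / (bp * bd))),
              1e-6)
  }
})

test_that("consistency loss matches hand computations and scales with omega", {
  expect_equal(consistency_loss(c(0.4, 0.7), c(0.4, 0.7), 1, 2, 2), 0)
  # one pair: u = 0.8, u~ = 0.6, omega = 1 -> 0.5 * 0.04 = 0.02
  expect_equal(consistency_loss(0.8, 0.6, 1, 1, 1), 0.02)
  # linear in omega
  u <- runif(5); v <- runif(5)
  expect_equal(consistency_loss(u, v, 2, 3, 4),
               2 * consistency_loss(u, v, 1, 3, 4))
  expect_equal(consistency_loss(u, v, 0, 3, 4), 0)

  # scalar-loop oracle
  set.seed(31)
  u <- runif(7); v <- runif(7)
  acc <- 0
  for (i in 1:7) acc <- acc + (u[i] - v[i])^2
  expect_lt(abs(consistency_loss(u, v, 0.7, 4, 2) -
                0.7 * acc / (2 * 4 * 2)), 1e-6)

  expect_error(consistency_loss(u, v[1:3], 1, 1, 1),
               class = "vqtarget_shape_error")
})

test_that("total loss adds its parts", {
  expect_equal(total_loss(0.5, 0.02), 0.52)
  expect_equal(total_loss(0.3, 0), 0.3)
  expect_equal(total_loss(0, 0), 0)
})

test_that("ramp weight rises from ~0 to w_max", {
  expect_equal(ramp_weight(0, 1, 80), exp(-5))
  expect_equal(ramp_weight(80, 1, 80), 1)
  expect_equal(ramp_weight(200, 0.5, 80), 0.5)
  taus <- seq(0, 120, by = 1)
  w <- ramp_weight(taus, 1, 80)
  expect_true(all(diff(w) >= 0))
})

test_that("patient signature sampling is uniform and seeded", {
  setup <- toy_pair_setup()
  map <- setup$patient_to_disease
  # degenerate draw: single patient
  one_map <- map[map$patient_id == "pat1", ]
  got <- withr::with_seed(1, sample_patient_signature(
    one_map$disease_id[1], setup$patient_sigs, one_map
  ))
  expect_equal(got, setup$patient_sigs$matrix["pat1", ])

  # multinomial oracle: 3 patients, 3000 draws, each close to 1/3
  map3 <- tibble::tibble(patient_id = paste0("pat", 1:3),
                         disease_id = "d1")
  draws <- withr::with_seed(2, replicate(3000, {
    sig <- sample_patient_signature("d1", setup$patient_sigs, map3)
    which(apply(setup$patient_sigs$matrix[1:3, ], 1,
                function(r) all(r == sig)))
  }))
  freq <- table(factor(draws, levels = 1:3)) / 3000
  se <- sqrt((1 / 3) * (2 / 3) / 3000)
  expect_true(all(abs(freq - 1 / 3) < 3 * se))

  # determinism under a seed
  s1 <- withr::with_seed(9, replicate(10, sample_patient_signature(
    "d1", setup$patient_sigs, map3
  )))
  s2 <- withr::with_seed(9, replicate(10, sample_patient_signature(
    "d1", setup$patient_sigs, map3
  )))
  expect_identical(s1, s2)

  expect_error(sample_patient_signature("dXX", setup$patient_sigs, map3),
               class = "vqtarget_cohort_error")
})

test_that("semi-supervised training reduces exactly to supervised", {
  setup <- toy_pair_setup()
  ssl0 <- train_pi_model(setup$protein_sigs, setup$disease_sigs,
                         setup$patient_sigs, setup$labels,
                         setup$patient_to_disease,
                         unlabeled_diseases = character(0),
                         config = fast_pi_config(w_max = 0))
  sl <- train_supervised(setup$protein_sigs, setup$disease_sigs,
                         setup$labels, config = fast_pi_config())
  expect_identical(ssl0$log$supervised, sl$log$supervised)
  expect_identical(ssl0$log$total, sl$log$total)
  # identical parameter trajectories, not just losses
  expect_identical(serialize(ssl0$layers, NULL), serialize(sl$layers, NULL))
  # supervised log carries no unsupervised column
  expect_false("unsupervised" %in% names(sl$log))
})

test_that("training logs expose the ramp and both loss components", {
  setup <- toy_pair_setup()
  fit <- train_pi_model(setup$protein_sigs, setup$disease_sigs,
                        setup$patient_sigs, setup$labels,
                        setup$patient_to_disease,
                        config = fast_pi_config(w_max = 0.8,
                                                ramp_length = 10))
  log <- tidy(fit)
  expect_true(all(diff(log$omega) >= 0))
  expect_equal(max(log$omega), 0.8)
  expect_true(any(log$unsupervised > 0))
  expect_equal(log$total, log$supervised + log$unsupervised)
  expect_equal(fit$sigma, 1) # four positives, four negatives
  # sigma override honours the printed convention and its inverse
  fit_inv <- train_pi_model(setup$protein_sigs, setup$disease_sigs,
                            setup$patient_sigs, setup$labels,
                            setup$patient_to_disease,
                            config = fast_pi_config(sigma = 0.25,
                                                    sigma_inverse = TRUE))
  expect_equal(fit_inv$sigma, 4)
})

test_that("dropout makes the patient pass stochastic but scoring deterministic", {
  setup <- toy_pair_setup()
  fit <- train_pi_model(setup$protein_sigs, setup$disease_sigs,
                        setup$patient_sigs, setup$labels,
                        setup$patient_to_disease,
                        config = fast_pi_config(dropout = 0.3))
  phi <- cbind(setup$protein_sigs$matrix[rep(1, 8), ],
               setup$disease_sigs$matrix[rep(1, 8), ])
  set.seed(40)
  f1 <- vqtarget:::nn_forward(fit$layers, phi, train = TRUE)$out
  f2 <- vqtarget:::nn_forward(fit$layers, phi, train = TRUE)$out
  expect_false(isTRUE(all.equal(f1, f2)))

  # with dropout off and patient signature equal to the disease signature,
  # the consistency summand vanishes
  u1 <- vqtarget:::nn_forward(fit$layers, phi, train = FALSE)$out
  u2 <- vqtarget:::nn_forward(fit$layers, phi, train = FALSE)$out
  expect_equal(consistency_loss(as.numeric(u1), as.numeric(u2), 1, 2, 2), 0)

  # predict_pairs: deterministic, in (0,1), errors on unknown ids
  p1 <- predict_pairs(fit, setup$proteins, setup$m_set,
                      setup$protein_sigs, setup$disease_sigs)
  p2 <- predict_pairs(fit, setup$proteins, setup$m_set,
                      setup$protein_sigs, setup$disease_sigs)
  expect_identical(p1, p2)
  expect_true(all(p1$score > 0 & p1$score < 1))
  expect_equal(nrow(p1), length(setup$proteins) * length(setup$m_set))
  expect_error(predict_pairs(fit, "ghost", setup$m_set,
                             setup$protein_sigs, setup$disease_sigs),
               class = "vqtarget_id_error")
})

test_that("label permutation removes the planted signal", {
  bench <- cached_benchmark(1)
  aucs <- sapply(1:10, function(i) {
    perm <- permute_labels(bench$bundle$labels, seed = 100 + i)
    cfg <- pipeline_config(
      seed = 1,
      classifier = pi_config(hidden = c(64, 32, 16), weight_decay = 1e-2,
                             seed = i)
    )
    run_scenario("new_targets", bench$bundle, cfg,
                 signatures = bench$sigs, labels = perm)$mean_auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})
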