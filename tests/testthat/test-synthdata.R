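test_that("profile generation is seeded, validated and distributionally correct", {
  p1 <- generate_profiles(3, 5, 1, seed = 7)
  p2 <- generate_profiles(3, 5, 1, seed = 7)
  expect_identical(p1$cells, p2$cells)

  expect_error(generate_profiles(3, 0, 1, seed = 1), "n_genes")
  expect_error(generate_profiles(0, 5, 1, seed = 1), "n_genes|n_cells")

  # Monte-Carlo check against the stated generating distribution
  p <- generate_profiles(200, 500, 2, seed = 1)
  xb <- t(vapply(p$cells, function(C) C[1, ], numeric(500)))
  emp_mean <- colMeans(xb)
  se <- p$gene_sd / sqrt(200)
  expect_true(all(abs(emp_mean - p$gene_mu) < 4 * se))
})

test_that("planted truth respects its invariants and its seed", {
  tr <- plant_truth(40, 10, 8, seed = 3)
  expect_length(tr$causal_genes, 10)
  expect_true(all(tr$causal_genes %in% 1:40))
  expect_false(any(tr$decoy_genes %in% tr$causal_genes))
  expect_true(all(abs(tr$gene_effects) >= 0.5 & abs(tr$gene_effects) <= 1.5))
  expect_identical(tr, plant_truth(40, 10, 8, seed = 3))

  expect_error(plant_truth(40, 21, 8, seed = 1), "k_causal")
  tr0 <- plant_truth(40, 0, 8, seed = 1)
  expect_length(tr0$causal_genes, 0)
})

test_that("decoy genes track the confounding correlation dial", {
  for (rho in c(0, 0.6)) {
    tr <- plant_truth(30, 5, 6, confound_rho = rho, seed = 2)
    p <- generate_profiles(1500, 30, 1, seed = 5, truth = tr)
    xb <- profile_means(p)
    cors <- vapply(seq_along(tr$causal_genes), function(i) {
      stats::cor(xb[, tr$causal_genes[i]], xb[, tr$decoy_genes[i]])
    }, numeric(1))
    if (rho == 0) {
      expect_true(all(abs(cors) < 0.1))
    } else {
      expect_true(all(abs(cors - rho) < 0.05))
    }
  }
})

test_that("noise-free labels are exactly linear in the causal interaction features", {
  tr <- plant_truth(20, 4, 6, noise_sd = 0, seed = 4)
  p <- generate_profiles(30, 20, 1, seed = 4, truth = tr)
  dr <- generate_drugs(6, seed = 4)
  ex <- generate_labels(p, dr, tr, 400, seed = 4)
  ai <- match(ex$drug_a, dr$drug_id)
  bi <- match(ex$drug_b, dr$drug_id)
  ci <- match(ex$cell_id, p$cell_ids)
  s <- rowSums(tr$drug_latents[ai, ] * tr$drug_latents[bi, ])
  xb <- profile_means(p)
  feats <- xb[ci, tr$causal_genes, drop = FALSE] * s
  fit <- stats::lm(ex$y ~ feats)
  expect_gt(summary(fit)$r.squared, 1 - 1e-8)
})

test_that("with no causal genes the labels are an unpredictable null", {
  tr <- plant_truth(20, 0, 8, noise_sd = 1, seed = 6)
  p <- generate_profiles(40, 20, 1, seed = 6, truth = tr)
  dr <- generate_drugs(8, seed = 6)
  ex <- generate_labels(p, dr, tr, 5000, seed = 6)
  ai <- match(ex$drug_a, dr$drug_id)
  bi <- match(ex$drug_b, dr$drug_id)
  ci <- match(ex$cell_id, p$cell_ids)
  xb <- profile_means(p)
  # oracle regression on the full interaction feature set, out of sample
  s <- rowSums(tr$drug_latents[ai, ] * tr$drug_latents[bi, ])
  feats <- cbind(xb[ci, 1:10, drop = FALSE] * s, s)
  trn <- 1:2500
  tst <- 2501:5000
  fit <- stats::lm.fit(cbind(1, feats[trn, ]), ex$y[trn])
  pred <- cbind(1, feats[tst, ]) %*% fit$coefficients
  r2 <- 1 - sum((ex$y[tst] - pred)^2) / sum((ex$y[tst] - mean(ex$y[tst]))^2)
  expect_lt(r2, 0.05)
})

test_that("label variance matches the closed-form variance of the generative model", {
  # drug and cell pools large enough that the realized moments sit within
  # the oracle's 10% band
  tr <- plant_truth(20, 4, 2000, d_lat = 4, noise_sd = 0.5, confound_rho = 0,
                    seed = 8)
  p <- generate_profiles(2000, 20, 1, seed = 8, truth = tr)
  dr <- generate_drugs(2000, seed = 8)
  ex <- generate_labels(p, dr, tr, 20000, seed = 8)
  w <- tr$gene_effects
  mu <- p$gene_mu[tr$causal_genes]
  sd_g <- p$gene_sd[tr$causal_genes]
  # Var(s * t) = E[s^2] E[t^2]; s, t independent and E[s] = 0
  v_analytic <- tr$d_lat * (sum(w^2 * sd_g^2) + sum(w * mu)^2) + tr$noise_sd^2
  expect_lt(abs(stats::var(ex$y_raw) - v_analytic) / v_analytic, 0.10)
})

test_that("only causal genes carry label signal (signal locality)", {
  tr <- plant_truth(20, 4, 6, noise_sd = 0, seed = 10)
  p <- generate_profiles(25, 20, 1, seed = 10, truth = tr)
  dr <- generate_drugs(6, seed = 10)
  ex <- generate_labels(p, dr, tr, 300, seed = 11)

  scramble <- function(prof, genes) {
    set.seed(99)
    perm <- sample(length(prof$cell_ids))
    for (g in genes) {
      vals <- vapply(prof$cells, function(C) C[1, g], numeric(1))[perm]
      for (i in seq_along(prof$cells)) prof$cells[[i]][1, g] <- vals[i]
    }
    prof
  }
  non_causal <- setdiff(seq_len(20), tr$causal_genes)
  ex_nc <- generate_labels(scramble(p, non_causal), dr, tr, 300, seed = 11)
  expect_equal(ex$y_raw, ex_nc$y_raw, tolerance = 1e-12)

  ex_c <- generate_labels(scramble(p, tr$causal_genes[1]), dr, tr, 300,
                          seed = 11)
  expect_false(isTRUE(all.equal(ex$y_raw, ex_c$y_raw)))
})

test_that("whole-dataset simulation is reproducible bit for bit", {
  d1 <- simulate_synergy(n_cells = 6, n_genes = 20, k_causal = 3, n_drugs = 5,
                         n_examples = 50, seed = 123)
  d2 <- simulate_synergy(n_cells = 6, n_genes = 20, k_causal = 3, n_drugs = 5,
                         n_examples = 50, seed = 123)
  expect_identical(d1$examples, d2$examples)
  expect_identical(d1$profiles$cells, d2$profiles$cells)
  expect_identical(d1$truth, d2$truth)
  # examples reference existing entities
  expect_true(all(d1$examples$drug_a %in% d1$drugs$drug_id))
  expect_true(all(d1$examples$cell_id %in% d1$profiles$cell_ids))
  expect_true(all(d1$examples$drug_a != d1$examples$drug_b))
  expect_true(all(is.finite(d1$examples$y)))
  expect_true(all(d1$examples$score_type %in%
                    c("loewe", "hsa", "bliss", "zip", "s_score")))
  # standardization stored and consistent
  st <- d1$standardize
  expect_equal((d1$examples$y_raw - st$mean) / st$sd, d1$examples$y,
               tolerance = 1e-12)
})

test_that("drug-pair interaction is symmetric under pair swap", {
  tr <- plant_truth(20, 3, 10, seed = 12)
  s_ab <- tr$drug_latents %*% t(tr$drug_latents)
  expect_equal(s_ab, t(s_ab), tolerance = 1e-12)
})

test_that("synthetic drugs are distinct, tokenizable and chemically valid", {
  dr <- generate_drugs(40, seed = 5)
  expect_equal(anyDuplicated(dr$smiles), 0L)
  toks <- lapply(dr$smiles, tokenize_smiles)
  expect_true(all(lengths(toks) >= 3))
  g <- build_graph(dr$smiles[1])
  expect_gt(nrow(g$atoms), 0)
})
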