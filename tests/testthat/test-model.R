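test_that("the dual loss decomposes exactly into its branch terms", {
  expect_equal(cads_loss(c(1, -1), c(0, 0), c(1, -1))$loss, 0)
  expect_equal(cads_loss(c(2, 0), c(0, 0), c(1, -1))$loss, 1)
  set.seed(1)
  yc <- runif(50, -1, 1); yt <- runif(50, -1, 1); y <- rnorm(50)
  rep <- cads_loss(yc, yt, y)
  expect_equal(rep$loss_causal, mean((yc - y)^2), tolerance = 1e-7)
  expect_equal(rep$loss_trivial, mean(yt^2), tolerance = 1e-7)
  expect_equal(rep$loss, rep$loss_causal + rep$loss_trivial, tolerance = 1e-7)
  expect_true(all(unlist(rep) >= 0))
})

test_that("identical branch parameters and identical inputs give identical outputs", {
  ds <- tiny_dataset()
  cfg <- cads_config(epochs = 1, d_model = 8, d_g = 8, hidden = 16, seed = 2)
  ns <- asNamespace("cads")
  ms <- ns$build_model_state(ds$profiles, ds$drugs, cfg)
  # copy causal-branch parameters into the trivial branch
  for (nm in grep("^c_", names(ms$params), value = TRUE)) {
    ms$params[[sub("^c_", "t_", nm)]] <- ms$params[[nm]]
  }
  # force Mc = Mt = 1/2 so both branches see the same masked profile
  ms$params$mask_W2 <- ms$params$mask_W2 * 0
  ms$params$mask_U <- ms$params$mask_U * 0
  leaves <- lapply(ms$params, ns$ad_leaf)
  out <- ns$predict_rows(ms, leaves, c(1L, 2L, 3L), c(2L, 3L, 4L), c(1L, 2L, 3L))
  expect_equal(out$yc, out$yt, tolerance = 1e-12)
})

test_that("eval-mode forward is batch invariant and deterministic", {
  fit <- tiny_fit()
  ex <- fit$examples[1:40, ]
  p1 <- predict(fit, ex)
  p2 <- predict(fit, ex[7, ])
  expect_equal(p1$y_c[7], p2$y_c, tolerance = 1e-10)
  # chunked prediction concatenates to the same vector
  ns <- asNamespace("cads")
  ms <- ns$fit_state(fit)
  leaves <- lapply(ms$params, ns$ad_leaf)
  ai <- match(ex$drug_a, fit$drug_ids)
  bi <- match(ex$drug_b, fit$drug_ids)
  ci <- match(ex$cell_id, fit$cell_ids)
  big <- ns$predict_rows(ms, leaves, ai, bi, ci, chunk = 1000L)
  small <- ns$predict_rows(ms, leaves, ai, bi, ci, chunk = 7L)
  expect_equal(big$yc, small$yc, tolerance = 1e-12)
  # repeated prediction is identical
  expect_identical(p1$y_c, predict(fit, ex)$y_c)
  expect_true(all(is.finite(p1$y_hat)))
})

test_that("training is reproducible for a fixed seed and logs its history", {
  ds <- tiny_dataset()
  cfg <- cads_config(epochs = 3, batch_size = 64, hidden = 16, d_model = 8,
                     d_g = 8, seed = 11)
  f1 <- cads_train(ds, cfg)
  f2 <- cads_train(ds, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
  expect_named(f1$history,
               c("epoch", "train_loss", "train_loss_causal",
                 "train_loss_trivial", "val_rmse", "val_pcc", "mean_abs_yt",
                 "lr"))
  # loss additivity holds on the logged history
  expect_equal(f1$history$train_loss,
               f1$history$train_loss_causal + f1$history$train_loss_trivial,
               tolerance = 1e-7)
})

test_that("unknown identifiers are rejected at train and predict time", {
  ds <- tiny_dataset()
  bad <- ds
  bad$examples$drug_a[1] <- "nonexistent"
  expect_error(cads_train(bad, cads_config(epochs = 1, seed = 1)),
               "unknown drug or cell")
  fit <- tiny_fit()
  ex <- fit$examples[1, ]
  ex$cell_id <- "cell999"
  expect_error(predict(fit, ex), "unknown drug or cell")
})

test_that("label standardization round-trips", {
  fit <- tiny_fit()
  y <- rnorm(20, 3, 5)
  expect_equal(inverse_standardize(standardize_labels(y, fit$standardize),
                                   fit$standardize),
               y, tolerance = 1e-9)
})

test_that("causal scores are exposed per cell and summarized by tidy()", {
  fit <- tiny_fit()
  sc <- causal_scores(fit)
  expect_equal(nrow(sc), fit$n_cells * fit$n_genes)
  expect_true(all(sc$alpha_c > 0 & sc$alpha_c < 1))
  td <- tidy(fit)
  expect_equal(nrow(td), fit$n_genes)
  agg <- tapply(sc$alpha_c, sc$gene_id, mean)[td$gene_id]
  expect_equal(as.numeric(agg), td$mean_alpha_c, tolerance = 1e-12)
  g <- glance(fit)
  expect_equal(g$backbone, "mlp")
  expect_true(is.finite(g$test_rmse))
})

test_that("the graph backbone trains end to end at toy scale", {
  ds <- tiny_dataset()
  cfg <- cads_config(backbone = "graph", epochs = 2, batch_size = 64,
                     hidden = 16, d_g = 8, graph_hidden = 8, seed = 3)
  fit <- cads_train(ds, cfg)
  pr <- predict(fit, ds$examples[1:5, ])
  expect_true(all(is.finite(pr$y_c)))
  expect_true(all(abs(pr$y_c) <= 1))
})

test_that("the cross-attention backbone trains end to end at toy scale", {
  ds <- simulate_synergy(n_cells = 4, n_genes = 12, k_causal = 2, n_drugs = 4,
                         n_examples = 40, seed = 21)
  cfg <- cads_config(backbone = "xattn", epochs = 2, batch_size = 20,
                     hidden = 8, d_model = 8, d_g = 4, seed = 3)
  fit <- cads_train(ds, cfg)
  pr <- predict(fit, ds$examples[1:5, ])
  expect_true(all(is.finite(pr$y_c)))
  expect_true(all(abs(pr$y_c) <= 1))
  expect_true(all(abs(pr$y_t) <= 1))
})

test_that("single-branch ablation trains without a trivial head", {
  ds <- tiny_dataset()
  cfg <- cads_config(epochs = 2, batch_size = 64, hidden = 16, seed = 5,
                     dual_branch = FALSE)
  fit <- cads_train(ds, cfg)
  pr <- predict(fit, ds$examples[1:5, ])
  expect_true(all(is.na(pr$y_t)))
  expect_true(all(is.finite(pr$y_c)))
})
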