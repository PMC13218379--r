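test_that("regression metrics match hand-computed values and flag degeneracy", {
  y <- c(0, 1, 2)
  m <- regression_metrics(y, y)
  expect_equal(as.numeric(m[1, c("mae", "rmse", "r2", "pcc")]), c(0, 0, 1, 1))

  m2 <- regression_metrics(y, c(0, 1, 4))
  expect_equal(m2$mae, 2 / 3, tolerance = 1e-12)
  expect_equal(m2$rmse, sqrt(4 / 3), tolerance = 1e-12)

  expect_warning(m3 <- regression_metrics(y, rep(mean(y), 3)), "zero variance")
  expect_equal(m3$r2, 0)
  expect_true(is.na(m3$pcc))
  expect_true(m3$degenerate)

  expect_error(regression_metrics(1, 1), "equal length")
  expect_error(regression_metrics(c(1, NA), c(1, 2)), "finite")

  set.seed(1)
  for (i in 1:5) {
    mm <- regression_metrics(rnorm(30), rnorm(30))
    expect_lte(mm$mae, mm$rmse)
    expect_lte(mm$r2, 1)
    expect_lte(abs(mm$pcc), 1)
  }
})

test_that("few-shot line fits are exact least squares", {
  f <- fewshot_fit_line(c(0.3, 0.5, 0.7), 2 * c(0.3, 0.5, 0.7) + 1)
  expect_equal(f$k, 2, tolerance = 1e-12)
  expect_equal(f$b, 1, tolerance = 1e-12)
  expect_equal(fewshot_fit_line(c(0.3, 0.5, 0.7), rep(0.4, 3))$k, 0,
               tolerance = 1e-12)
  # normal-equations oracle on noisy points
  set.seed(2)
  x <- runif(10); yv <- 0.7 * x + rnorm(10, 0, 0.1)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% yv)
  f2 <- fewshot_fit_line(x, yv)
  expect_equal(f2$b, beta[1], tolerance = 1e-10)
  expect_equal(f2$k, beta[2], tolerance = 1e-10)
})

test_that("causal score statistics pool runs exactly", {
  one <- tibble::tibble(cell_id = "c1", gene_id = c("g1", "g2"),
                        alpha_c = c(0.4, 0.6))
  st <- causal_score_stats(one)
  expect_equal(st$sd, c(0, 0))
  expect_equal(st$n, c(1L, 1L))

  const <- tibble::tibble(cell_id = rep(c("c1", "c2"), each = 3),
                          gene_id = rep(c("g1", "g2", "g3"), 2),
                          alpha_c = 0.5)
  stc <- causal_score_stats(const)
  expect_equal(stc$mean, rep(0.5, 3))
  expect_equal(stc$sd, rep(0, 3))

  # streaming vs two-pass oracle on a random table
  set.seed(3)
  tab <- tibble::tibble(
    cell_id = rep(sprintf("c%02d", 1:20), times = 15),
    gene_id = rep(sprintf("g%02d", 1:15), each = 20),
    alpha_c = runif(300, 0.01, 0.99)
  )
  st2 <- causal_score_stats(tab)
  for (g in unique(tab$gene_id)) {
    v <- tab$alpha_c[tab$gene_id == g]
    i <- which(st2$gene_id == g)
    expect_equal(st2$mean[i], mean(v), tolerance = 1e-12)
    expect_equal(st2$sd[i], stats::sd(v), tolerance = 1e-12)
  }

  # multiple runs pool, mismatched panels are rejected
  st3 <- causal_score_stats(list(tab, tab))
  expect_equal(st3$n, rep(40L, 15))
  expect_equal(st3$mean, st2$mean, tolerance = 1e-12)
  bad <- tab
  bad$gene_id <- sub("g01", "gXX", bad$gene_id)
  expect_error(causal_score_stats(list(tab, bad)), "panels differ")
})

test_that("within-class distance matches direct recomputation", {
  # singletons sit on their own centroid
  x <- matrix(rnorm(10), 5, 2)
  expect_equal(within_class_distance(x, 1:5), 0)
  # two points at distance 2 around their midpoint
  expect_equal(within_class_distance(rbind(c(0, 0), c(2, 0)), c(1, 1)), 1)
  # brute-force oracle on a random two-class set
  set.seed(4)
  x2 <- matrix(rnorm(40), 20, 2)
  lab <- rep(c("a", "b"), each = 10)
  direct <- mean(vapply(seq_len(20), function(i) {
    cent <- colMeans(x2[lab == lab[i], , drop = FALSE])
    sqrt(sum((x2[i, ] - cent)^2))
  }, numeric(1)))
  expect_equal(within_class_distance(x2, lab), direct, tolerance = 1e-10)
  expect_error(within_class_distance(matrix(0, 0, 2), character(0)), "empty")
})

test_that("integrated gradients are exact for linear maps and complete for smooth ones", {
  ns <- asNamespace("cads")
  w <- c(0.5, -1.2, 2, 0.3)
  x <- matrix(c(1, 2, -1, 0.5), 1)
  f_lin <- function(leaf) ns$ad_matmul(leaf, matrix(w, 4, 1))
  for (steps in c(1, 8, 64)) {
    ig <- integrated_gradients(f_lin, x, steps = steps)
    expect_equal(as.numeric(ig), w * as.numeric(x), tolerance = 1e-10)
  }
  # x == baseline -> all-zero attribution
  ig0 <- integrated_gradients(f_lin, x, baseline = x, steps = 16)
  expect_equal(as.numeric(ig0), rep(0, 4))

  # quadratic toy: analytic path integral gives x_i^2; the right-endpoint
  # Riemann sum has completeness gap exactly f(x)/steps
  xq <- matrix(c(0.3, -0.25, 0.35, 0.2), 1)
  f_quad <- function(leaf) ns$ad_sum(ns$ad_square(leaf))
  ig_q <- integrated_gradients(f_quad, xq, steps = 512)
  expect_equal(as.numeric(ig_q), as.numeric(xq)^2, tolerance = 1e-2)
  expect_lt(attr(ig_q, "completeness_gap"), 1e-3)
  gap64 <- attr(integrated_gradients(f_quad, xq, steps = 64), "completeness_gap")
  expect_lt(attr(ig_q, "completeness_gap"), gap64)
  expect_error(integrated_gradients(f_quad, xq, steps = 0), "steps")
})

test_that("integrated gradients on a fit attribute the causal branch per gene", {
  fit <- tiny_fit()
  ex <- fit$examples[1, ]
  ig <- integrated_gradients(fit, ex, steps = 64)
  expect_equal(nrow(ig), fit$n_genes)
  expect_true(all(is.finite(ig$attribution)))
  fx <- attr(ig, "f_x"); fb <- attr(ig, "f_baseline")
  expect_lt(attr(ig, "completeness_gap"), 0.05 * max(abs(fx - fb), 0.01))
  # more steps tighten completeness
  gap8 <- attr(integrated_gradients(fit, ex, steps = 8), "completeness_gap")
  gap256 <- attr(integrated_gradients(fit, ex, steps = 256), "completeness_gap")
  expect_lte(gap256, gap8 + 1e-8)
})

test_that("gene ablation is a faithful no-op at k = 0 and degenerate at k = N", {
  fit <- tiny_fit()
  a0 <- ablate_top_genes(fit, "causal", 0)
  expect_equal(a0$before, a0$after, tolerance = 1e-12)
  expect_equal(a0$loss, rep(0, 4))

  ac <- ablate_top_genes(fit, "causal", fit$n_genes)
  at <- ablate_top_genes(fit, "trivial", fit$n_genes)
  expect_equal(ac$after, at$after, tolerance = 1e-12)

  expect_error(ablate_top_genes(fit, "causal", fit$n_genes + 1), "k must")
  a5 <- ablate_top_genes(fit, "trivial", 5)
  expect_named(a5, c("branch", "k", "metric", "before", "after", "loss"))
  expect_equal(a5$k, rep(5L, 4))
})

test_that("the few-shot curve trains on nested fractions against a fixed test split", {
  ds <- tiny_dataset()
  cfg <- cads_config(epochs = 2, batch_size = 64, hidden = 8, d_g = 4,
                     seed = 13)
  fs <- fewshot_curve(ds, fractions = c(0.5, 1), config = cfg, seeds = 1L)
  expect_s3_class(fs, "cads_fewshot")
  expect_equal(nrow(fs$points), 4L)  # 2 fractions x 2 models
  expect_equal(sort(unique(fs$points$model)), c("cads", "single_branch"))
  expect_equal(nrow(fs$slopes), 2L * 4L)  # per model x metric
  expect_true(all(is.finite(fs$slopes$k)))
  expect_error(fewshot_curve(ds, fractions = 1e-5, config = cfg), "empty")
})
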