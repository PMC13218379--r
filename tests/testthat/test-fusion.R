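test_that("cross-attention handles singleton and degenerate key sets", {
  params <- init_attention(8, n_heads = 2, seed = 1)
  X1 <- matrix(rnorm(24), 3, 8)

  # one key position: softmax over a singleton is 1 for every query
  X2 <- matrix(rnorm(8), 1, 8)
  out <- cross_attention(X1, X2, params)
  att <- attr(out, "attention")
  for (A in att) expect_equal(A, matrix(1, 3, 1), tolerance = 1e-12)
  oracle <- matrix(rep(X2 %*% params$WV, each = 3), 3) %*% params$WO
  expect_equal(unclass(out), oracle, tolerance = 1e-10, ignore_attr = TRUE)

  # identical keys everywhere: uniform attention, mean of value projections
  X2r <- matrix(rep(rnorm(8), 4), 4, 8, byrow = TRUE)
  out2 <- cross_attention(X1, X2r, params)
  for (A in attr(out2, "attention")) {
    expect_equal(A, matrix(0.25, 3, 4), tolerance = 1e-8)
  }
})

test_that("cross-attention matches the brute-force dense oracle", {
  set.seed(2)
  for (n_heads in c(1L, 2L)) {
    params <- init_attention(4, n_heads = n_heads, seed = 3)
    # fixed small integer weights for the single-head case
    if (n_heads == 1L) {
      params$WQ <- matrix(c(1, 0, -1, 2, 0, 1, 1, 0, 2, -1, 0, 1, 1, 1, 0, -2), 4)
      params$WK <- diag(4)
      params$WV <- matrix(c(0, 1, 1, 0, 1, 0, 0, 1, 1, 1, 0, 0, 0, 0, 1, 1), 4)
      params$WO <- diag(4)
    }
    X1 <- matrix(rnorm(8), 2, 4)
    X2 <- matrix(rnorm(12), 3, 4)
    got <- cross_attention(X1, X2, params)
    want <- brute_attention(X1, X2, params$WQ, params$WK, params$WV,
                            params$WO, n_heads)
    expect_equal(unclass(got), want, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("attention rows are probability vectors and padding is excluded", {
  params <- init_attention(8, n_heads = 4, seed = 4)
  X1 <- matrix(rnorm(32), 4, 8)
  X2 <- matrix(rnorm(40), 5, 8)
  out <- cross_attention(X1, X2, params, key_mask = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  for (A in attr(out, "attention")) {
    expect_equal(rowSums(A), rep(1, 4), tolerance = 1e-6)
    expect_true(all(A[, 4:5] < 1e-10))
    expect_true(all(A >= 0))
  }
})

test_that("self-attention is definitionally cross-attention with itself", {
  params <- init_attention(8, n_heads = 2, seed = 5)
  X <- matrix(rnorm(40), 5, 8)
  expect_identical(unclass(multihead_self_attention(X, params)),
                   unclass(cross_attention(X, X, params)))
  # length-1 sequence: value projection of the single element
  x1 <- matrix(rnorm(8), 1, 8)
  expect_equal(unclass(multihead_self_attention(x1, params)),
               (x1 %*% params$WV) %*% params$WO,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("drug-cell exchange composes cross-attention calls and keeps shapes", {
  params <- init_attention(8, n_heads = 2, seed = 6)
  G <- matrix(rnorm(48), 6, 8)
  DA <- matrix(rnorm(24), 3, 8)
  DB <- matrix(rnorm(16), 2, 8)
  ex <- drug_cell_exchange(G, DA, DB, params)
  expect_equal(dim(ex$G_prime), dim(G))
  expect_equal(dim(ex$DA_prime), dim(DA))
  expect_equal(dim(ex$DB_prime), dim(DB))
  # composition oracle: two brute-force attention computations
  expect_equal(unclass(ex$G_prime),
               brute_attention(G, rbind(DA, DB), params$WQ, params$WK,
                               params$WV, params$WO, 2L),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(unclass(ex$DA_prime),
               brute_attention(DA, G, params$WQ, params$WK, params$WV,
                               params$WO, 2L),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(drug_cell_exchange(G, NULL, DB, params), "both drugs")
})

test_that("drug-drug exchange is covariant under pair swap", {
  params <- init_attention(8, n_heads = 2, seed = 7)
  DA <- matrix(rnorm(24), 3, 8)
  DB <- matrix(rnorm(24), 3, 8)
  ex <- drug_drug_exchange(DA, DB, params)
  sw <- drug_drug_exchange(DB, DA, params)
  expect_identical(unclass(ex$DA), unclass(sw$DB))
  expect_identical(unclass(ex$DB), unclass(sw$DA))
  # identical inputs give identical outputs
  same <- drug_drug_exchange(DA, DA, params)
  expect_identical(unclass(same$DA), unclass(same$DB))
  # brute-force oracle
  expect_equal(unclass(ex$DA),
               brute_attention(DA, DB, params$WQ, params$WK, params$WV,
                               params$WO, 2L),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(drug_drug_exchange(NULL, DB, params), "both")
})

test_that("the prediction head is a bounded tanh MLP over Gi || DA || DB", {
  mlp <- init_mlp(12, hidden = 6, seed = 8)
  G <- matrix(rnorm(20), 5, 4)
  DA <- matrix(rnorm(12), 3, 4)
  DB <- matrix(rnorm(8), 2, 4)

  # zero final layer -> tanh(0) = 0
  mlp0 <- mlp
  mlp0$layers$W2 <- mlp0$layers$W2 * 0
  expect_equal(predict_head(G, DA, DB, mlp0)$Yi, 0)

  out <- predict_head(G, DA, DB, mlp)
  expect_lte(abs(out$Yi), 1)
  expect_equal(out$branch, "causal")

  # the printed concatenation order matters for generic weights
  swapped <- predict_head(DA, G, DB, mlp)
  expect_false(isTRUE(all.equal(out$Yi, swapped$Yi)))

  # mlp_fusion is the same head on pre-pooled inputs
  expect_equal(mlp_fusion(colMeans(G), colMeans(DA), colMeans(DB), mlp)$Yi,
               out$Yi, tolerance = 1e-12)
  expect_error(predict_head(G * NaN, DA, DB, mlp), "non-finite")
})
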