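test_that("the tokenizer segments SMILES deterministically", {
  expect_identical(tokenize_smiles("CCO"), c("C", "C", "O"))
  expect_identical(tokenize_smiles("C(Cl)Br"), c("C", "(", "Cl", ")", "Br"))
  expect_identical(tokenize_smiles("c1ccccc1"),
                   c("c", "1", "c", "c", "c", "c", "c", "1"))
  expect_identical(tokenize_smiles("C[NH2+]C"), c("C", "[NH2+]", "C"))
  expect_identical(tokenize_smiles("C%12CC%12"), c("C", "%12", "C", "C", "%12"))
  expect_error(tokenize_smiles(""), "non-empty")
})

test_that("vocabulary lookup pads, truncates and handles unknown tokens", {
  vocab <- smiles_vocab(c("CCO", "C(Cl)Br"), max_len = 8)
  ts <- tokenize_smiles("CCO", vocab)
  expect_s3_class(ts, "cads_tokens")
  expect_equal(ts$length, 3L)
  expect_length(ts$tokens, 8L)
  expect_identical(ts$pad_mask, c(rep(TRUE, 3), rep(FALSE, 5)))
  expect_identical(detokenize_smiles(ts, vocab), "CCO")

  # unknown token maps to <unk>
  tu <- tokenize_smiles("CSO", vocab)
  expect_true(vocab$unk_id %in% tu$tokens)

  # no <unk> configured -> parse error
  v2 <- smiles_vocab("CCO", add_unk = FALSE)
  expect_error(tokenize_smiles("N", v2), "not in vocabulary")

  # truncation at max_len
  tl <- tokenize_smiles(strrep("C", 20), vocab)
  expect_equal(tl$length, 8L)
})

test_that("tokenize o detokenize is the identity on in-vocabulary strings", {
  smiles <- c("CCO", "C(Cl)Br", "c1ccccc1", "CN(C)C=O")
  vocab <- smiles_vocab(smiles, max_len = 16)
  for (s in smiles) {
    expect_identical(detokenize_smiles(tokenize_smiles(s, vocab), vocab), s)
  }
})

test_that("positional encoding rows have unit norm", {
  for (d in c(8, 32)) {
    P <- positional_encoding(64, d)
    expect_equal(sqrt(rowSums(P^2)), rep(1, 64), tolerance = 1e-6)
  }
  expect_error(positional_encoding(10, 7))
})

test_that("sequence encoding is layer-normalized token + position", {
  vocab <- smiles_vocab(c("CCO", "NCC"), max_len = 6)
  pe <- positional_encoding(6, 8)
  params <- init_sequence_encoder(length(vocab$tokens), 8, seed = 1)
  ts <- tokenize_smiles("CCO", vocab)
  out <- encode_sequence(ts, pe, params)
  expect_equal(dim(out$H), c(6L, 8L))
  # with default gain 1 / bias 0 the rows are the pre-affine normalization
  H <- out$H[out$pad_mask, ]
  expect_equal(rowMeans(H), rep(0, 3), tolerance = 1e-5)
  expect_equal(apply(H, 1, function(r) mean(r^2)), rep(1, 3), tolerance = 1e-3)

  # all-zero embedding table: output depends on positions only
  pz <- params
  pz$emb <- pz$emb * 0
  o1 <- encode_sequence(tokenize_smiles("CCO", vocab), pe, pz)
  o2 <- encode_sequence(tokenize_smiles("NCC", vocab), pe, pz)
  expect_equal(o1$H, o2$H, tolerance = 1e-12)

  # single-token sequence round-trips with the right shape
  v1 <- smiles_vocab("C", max_len = 1)
  t1 <- tokenize_smiles("C", v1)
  o3 <- encode_sequence(t1, positional_encoding(1, 8), params)
  expect_equal(dim(o3$H), c(1L, 8L))
  expect_equal(o3$pooled, o3$H[1, , drop = FALSE])

  expect_error(encode_sequence(ts, positional_encoding(6, 4), params),
               "width")
})

test_that("molecular graphs carry the expected topology", {
  g <- build_graph("CCO")
  expect_equal(nrow(g$atoms), 3L)
  expect_equal(nrow(g$bonds), 2L)
  expect_identical(g$atoms$element, c("C", "C", "O"))
  expect_false(any(g$atoms$in_ring))

  benzene <- build_graph("c1ccccc1")
  expect_equal(nrow(benzene$atoms), 6L)
  expect_equal(nrow(benzene$bonds), 6L)
  expect_true(all(benzene$atoms$in_ring))

  expect_error(build_graph("C("), "invalid SMILES")
  expect_error(build_graph(""), "non-empty")
})

test_that("graph encoding is permutation invariant and isomorphism consistent", {
  params <- init_graph_encoder(d_in = 16, hidden = 16, n_heads = 4, seed = 2)
  # same molecule entered in two atom orders
  e1 <- encode_graph(build_graph("CCO"), params)
  e2 <- encode_graph(build_graph("OCC"), params)
  expect_lt(max(abs(e1$pooled - e2$pooled)), 1e-5)

  # two isomorphic graphs with identical features -> identical embeddings
  r1 <- encode_graph(build_graph("C1CCCCC1"), params)
  r2 <- encode_graph(build_graph("C2CCCCC2"), params)
  expect_equal(r1$pooled, r2$pooled, tolerance = 1e-10)

  # single atom: no neighbours to aggregate, output defined and finite
  s <- encode_graph(build_graph("C"), params)
  expect_equal(dim(s$nodes), c(1L, 16L))
  expect_equal(s$pooled, s$nodes[1, , drop = FALSE])
  expect_true(all(is.finite(s$pooled)))
})
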