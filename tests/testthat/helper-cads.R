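# Shared helpers: small fixtures are built in code, expensive fits are
# trained once per session and cached.

.fixtures <- new.env(parent = emptyenv())

# rank-based AUROC of `score` for binary `label`
auroc <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label)
  n0 <- sum(!label)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# a tiny synthetic dataset for fast structural tests
tiny_dataset <- function() {
  if (is.null(.fixtures$tiny_ds)) {
    .fixtures$tiny_ds <- simulate_synergy(
      n_cells = 8L, n_genes = 30L, k_causal = 4L, n_drugs = 6L,
      n_examples = 200L, noise_sd = 0.2, confound_rho = 0.3, seed = 42L)
  }
  .fixtures$tiny_ds
}

# a quick, deliberately under-trained fit for interface-level tests
tiny_fit <- function() {
  if (is.null(.fixtures$tiny_fit)) {
    cfg <- cads_config(epochs = 4L, batch_size = 64L, hidden = 32L,
                       d_model = 8L, d_g = 8L, seed = 7L, patience = 10L)
    .fixtures$tiny_fit <- cads_train(tiny_dataset(), cfg)
  }
  .fixtures$tiny_fit
}

# dense single-head scaled dot-product attention, written independently of
# the package implementation (the brute-force oracle)
brute_attention <- function(X1, X2, WQ, WK, WV, WO, n_heads) {
  d <- ncol(WQ)
  dk <- d / n_heads
  Q <- X1 %*% WQ
  K <- X2 %*% WK
  V <- X2 %*% WV
  out <- NULL
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1) * dk + 1):(h * dk)
    S <- Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE]) / sqrt(dk)
    E <- exp(S - apply(S, 1, max))
    A <- E / rowSums(E)
    out <- cbind(out, A %*% V[, idx, drop = FALSE])
  }
  out %*% WO
}

# central finite-difference gradient of scalar-valued f at matrix V
numeric_grad <- function(f, V, eps = 1e-6) {
  g <- V * 0
  for (i in seq_along(V)) {
    Vp <- V; Vp[i] <- V[i] + eps
    Vm <- V; Vm[i] <- V[i] - eps
    g[i] <- (f(Vp) - f(Vm)) / (2 * eps)
  }
  g
}
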