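#' Initialize the causal mask encoder
#'
#' Per-gene features are computed from each gene's F-dimensional omics
#' column by a parameter-shared fully-connected map, which keeps the
#' parameter count independent of the gene panel and guarantees that every
#' attention score is traceable to an individual gene. The two-channel
#' attention logits add a per-gene offset (zero-initialized), so genes with
#' identical omics values can still be separated by what they contribute to
#' the synergy signal during training.
#'
#' @param n_genes gene panel size N.
#' @param n_omics omics layer count F.
#' @param d_g per-gene feature width.
#' @param seed integer seed.
#' @param activation feature nonlinearity, `"tanh"` (default) or
#'   `"identity"`.
#' @param gene_bias include the per-gene two-channel offset.
#' @return a `cads_mask_encoder` parameter list.
#' @export
init_mask_encoder <- function(n_genes, n_omics = 1L, d_g = 16L, seed = 1L,
                              activation = c("tanh", "identity"),
                              gene_bias = TRUE) {
  activation <- match.arg(activation)
  set.seed(as.integer(seed))
  structure(
    list(
      W1 = ad_init_dense(n_omics, d_g),
      b1 = matrix(0, 1L, d_g),
      W2 = ad_init_dense(d_g, 2L),
      U = matrix(0, n_genes, 2L),
      n_genes = as.integer(n_genes),
      n_omics = as.integer(n_omics),
      d_g = as.integer(d_g),
      activation = activation,
      gene_bias = isTRUE(gene_bias)
    ),
    class = "cads_mask_encoder"
  )
}

#' Extract per-gene features from a cell-line profile
#'
#' Applies the shared fully-connected map to every gene's omics column of
#' `C` (an `F x N` matrix), yielding the `N x d_g` feature matrix whose row
#' `i` is the feature vector of gene `i`. Two genes with identical omics
#' columns always receive identical features.
#'
#' @param C `F x N` omics matrix for one cell line.
#' @param encoder a `cads_mask_encoder`.
#' @return `N x d_g` numeric matrix.
#' @export
extract_gene_features <- function(C, encoder) {
  stopifnot(inherits(encoder, "cads_mask_encoder"))
  C <- as.matrix(C)
  if (nrow(C) != encoder$n_omics) {
    stop(sprintf("extract_gene_features: profile has %d omics rows, encoder expects %d",
                 nrow(C), encoder$n_omics), call. = FALSE)
  }
  Z <- sweep(t(C) %*% encoder$W1, 2L, as.numeric(encoder$b1), "+")
  if (encoder$activation == "tanh") Z <- tanh(Z)
  Z
}

#' Two-channel gene attention and complementary soft masks
#'
#' Computes per-gene logits `z_i = W g_i (+ u_i)` and applies a softmax
#' across the two channels of each gene, yielding the causal and trivial
#' attention weights `alpha_c[i] + alpha_t[i] = 1` exactly. The soft masks
#' are `Mc = alpha_c` and `Mt = alpha_t`, so `Mc + Mt = 1` structurally,
#' for arbitrary parameters and inputs.
#'
#' @param features `N x d_g` gene feature matrix from
#'   [extract_gene_features()].
#' @param encoder a `cads_mask_encoder`.
#' @return a `cads_masks` object with `alpha_c`, `alpha_t`, `Mc`, `Mt`.
#' @export
gene_attention <- function(features, encoder) {
  stopifnot(inherits(encoder, "cads_mask_encoder"))
  features <- as.matrix(features)
  Z <- features %*% encoder$W2
  if (encoder$gene_bias) {
    if (nrow(Z) != nrow(encoder$U)) {
      stop("gene_attention: feature rows do not match the encoder's gene panel",
           call. = FALSE)
    }
    Z <- Z + encoder$U
  }
  if (!all(is.finite(Z))) {
    bad <- which(!is.finite(rowSums(Z)))
    stop(sprintf("gene_attention: non-finite logits at gene index %s",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  m <- pmax(Z[, 1L], Z[, 2L])
  ec <- exp(Z[, 1L] - m)
  et <- exp(Z[, 2L] - m)
  alpha_c <- ec / (ec + et)
  structure(
    list(alpha_c = alpha_c, alpha_t = 1 - alpha_c,
         Mc = alpha_c, Mt = 1 - alpha_c),
    class = "cads_masks"
  )
}

#' Apply complementary soft masks to a profile
#'
#' Hadamard products `Gc = C (*) Mc` and `Gt = C (*) Mt`, with the
#' gene-length masks broadcast across the omics rows. By mask
#' complementarity, `Gc + Gt = C`.
#'
#' @param C `F x N` omics matrix.
#' @param masks a `cads_masks` object (or list with `Mc`, `Mt`).
#' @return list with matrices `Gc` and `Gt`.
#' @export
apply_masks <- function(C, masks) {
  C <- as.matrix(C)
  if (length(masks$Mc) != ncol(C)) {
    stop("apply_masks: mask length does not match the gene dimension of C",
         call. = FALSE)
  }
  Gc <- sweep(C, 2L, masks$Mc, "*")
  Gt <- sweep(C, 2L, masks$Mt, "*")
  list(Gc = Gc, Gt = Gt)
}

#' Complement of a soft mask
#'
#' Returns `1 - M` elementwise; an involution on `[0, 1]^N`.
#'
#' @param M numeric mask vector with entries in `[0, 1]`.
#' @return numeric vector `1 - M`.
#' @export
complement_mask <- function(M) {
  M <- as.numeric(M)
  if (any(M < 0 | M > 1)) {
    stop("complement_mask: entries must lie in [0, 1]", call. = FALSE)
  }
  1 - M
}

#' Compute masks for one cell-line profile
#'
#' Convenience wrapper chaining [extract_gene_features()] and
#' [gene_attention()].
#'
#' @inheritParams extract_gene_features
#' @return a `cads_masks` object.
#' @export
compute_masks <- function(C, encoder) {
  gene_attention(extract_gene_features(C, encoder), encoder)
}

# Mask computation on ad nodes for a stack of cells. `X_all` is the
# ((n_cells * N) x F) leaf of gene omics columns in cell-major order;
# returns the (n_cells x N) causal mask node.
mask_forward_ad <- function(X_all, p, n_cells, n_genes, activation = "tanh",
                            gene_bias = TRUE) {
  G <- ad_add(ad_matmul(X_all, p$mask_W1), p$mask_b1)
  if (activation == "tanh") G <- ad_tanh(G)
  Z <- ad_matmul(G, p$mask_W2)
  if (gene_bias) Z <- ad_add(Z, ad_rows(p$mask_U, rep(seq_len(n_genes), n_cells)))
  alpha <- ad_softmax_rows(Z)
  mc_col <- ad_matmul(alpha, ad_leaf(matrix(c(1, 0), 2L, 1L)))
  ad_transpose(ad_reshape(mc_col, n_genes, n_cells))
}
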