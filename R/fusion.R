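#' Initialize multi-head attention parameters
#'
#' @param d_model model width; must be divisible by `n_heads`.
#' @param n_heads number of attention heads.
#' @param seed integer seed.
#' @return a `cads_attention` parameter list (`WQ`, `WK`, `WV`, `WO`,
#'   `n_heads`, `dk`).
#' @export
init_attention <- function(d_model, n_heads = 4L, seed = 1L) {
  if (d_model %% n_heads != 0) {
    stop("init_attention: d_model must be divisible by n_heads", call. = FALSE)
  }
  set.seed(as.integer(seed))
  structure(
    list(WQ = ad_init_dense(d_model, d_model),
         WK = ad_init_dense(d_model, d_model),
         WV = ad_init_dense(d_model, d_model),
         WO = ad_init_dense(d_model, d_model),
         n_heads = as.integer(n_heads),
         dk = as.integer(d_model / n_heads)),
    class = "cads_attention"
  )
}

# Cross-attention on ad nodes. key_mask is a logical vector over X2's rows
# (FALSE = padded key, excluded from the softmax); add_mask an arbitrary
# additive logit mask matrix (overrides key_mask).
ca_ad <- function(X1, X2, p, n_heads, dk, key_mask = NULL, add_mask = NULL) {
  Q <- ad_matmul(X1, p$WQ)
  K <- ad_matmul(X2, p$WK)
  V <- ad_matmul(X2, p$WV)
  n1 <- nrow(Q$val)
  n2 <- nrow(K$val)
  if (is.null(add_mask) && !is.null(key_mask)) {
    add_mask <- matrix(ifelse(rep(key_mask, each = n1), 0, -1e30), n1, n2)
  }
  heads <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * dk + 1L):(h * dk)
    Qh <- ad_node(Q$val[, idx, drop = FALSE], list(Q), local({
      idx <- idx
      function(node, g) {
        gq <- matrix(0, nrow(g), ncol(node$parents[[1]]$val))
        gq[, idx] <- g
        list(gq)
      }
    }))
    Kh <- ad_node(K$val[, idx, drop = FALSE], list(K), local({
      idx <- idx
      function(node, g) {
        gk <- matrix(0, nrow(g), ncol(node$parents[[1]]$val))
        gk[, idx] <- g
        list(gk)
      }
    }))
    Vh <- ad_node(V$val[, idx, drop = FALSE], list(V), local({
      idx <- idx
      function(node, g) {
        gv <- matrix(0, nrow(g), ncol(node$parents[[1]]$val))
        gv[, idx] <- g
        list(gv)
      }
    }))
    S <- ad_softmax_rows(ad_scale(ad_matmul(Qh, ad_transpose(Kh)), 1 / sqrt(dk)),
                         add_mask = add_mask)
    heads[[h]] <- ad_matmul(S, Vh)
  }
  O <- if (n_heads > 1) do.call(ad_cbind, heads) else heads[[1]]
  ad_matmul(O, p$WO)
}

attn_leaves <- function(params) {
  list(WQ = ad_leaf(params$WQ), WK = ad_leaf(params$WK),
       WV = ad_leaf(params$WV), WO = ad_leaf(params$WO))
}

#' Cross-attention between two sequences
#'
#' Per-head scaled dot-product attention of the query sequence `X1` over the
#' key/value sequence `X2`:
#' `CA(X1, X2) = softmax((X1 WQ)(X2 WK)^T / sqrt(dk)) (X2 WV)`,
#' heads concatenated and output-projected. Padded key positions (where
#' `key_mask` is `FALSE`) receive zero attention.
#'
#' @param X1 query matrix (`n1 x d_model`).
#' @param X2 key/value matrix (`n2 x d_model`).
#' @param params a `cads_attention` parameter list.
#' @param key_mask optional logical vector of length `n2`.
#' @return `n1 x d_model` matrix; attribute `"attention"` holds the per-head
#'   attention weight matrices.
#' @export
cross_attention <- function(X1, X2, params, key_mask = NULL) {
  stopifnot(inherits(params, "cads_attention"))
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  if (ncol(X1) != nrow(params$WQ) || ncol(X2) != nrow(params$WK)) {
    stop("cross_attention: input width does not match attention parameters",
         call. = FALSE)
  }
  ad_tape_reset()
  p <- attn_leaves(params)
  Q <- ad_matmul(ad_leaf(X1), p$WQ)
  K <- ad_matmul(ad_leaf(X2), p$WK)
  V <- ad_matmul(ad_leaf(X2), p$WV)
  n1 <- nrow(X1); n2 <- nrow(X2)
  add_mask <- NULL
  if (!is.null(key_mask)) {
    add_mask <- matrix(ifelse(rep(key_mask, each = n1), 0, -1e30), n1, n2)
  }
  dk <- params$dk
  heads <- vector("list", params$n_heads)
  att <- vector("list", params$n_heads)
  for (h in seq_len(params$n_heads)) {
    idx <- ((h - 1L) * dk + 1L):(h * dk)
    Sh <- ad_softmax_rows(
      ad_scale(ad_matmul(ad_leaf(Q$val[, idx, drop = FALSE]),
                         ad_transpose(ad_leaf(K$val[, idx, drop = FALSE]))),
               1 / sqrt(dk)),
      add_mask = add_mask)
    att[[h]] <- Sh$val
    heads[[h]] <- Sh$val %*% V$val[, idx, drop = FALSE]
  }
  out <- do.call(cbind, heads) %*% params$WO
  attr(out, "attention") <- att
  out
}

#' Multi-head self-attention
#'
#' Definitional identity `MSA(X) = CA(X, X)` with the same parameters.
#'
#' @param X input sequence matrix.
#' @inheritParams cross_attention
#' @return as [cross_attention()].
#' @export
multihead_self_attention <- function(X, params, key_mask = NULL) {
  cross_attention(X, X, params, key_mask = key_mask)
}

#' Drug-cell cross-modal exchange
#'
#' One round of cross-modal communication: the branch's masked cell
#' representation attends over the two drugs' stacked token representations
#' (`Gi' = CA(Gi, D)`), and each drug attends over the cell
#' (`Dk' = CA(Dk, Gi)`). One shared parameter set serves all three calls.
#'
#' @param G masked cell representation (`positions x d_model`).
#' @param DA,DB drug token representations.
#' @param params a `cads_attention` parameter list.
#' @return list with `G_prime`, `DA_prime`, `DB_prime`.
#' @export
drug_cell_exchange <- function(G, DA, DB, params) {
  if (is.null(DA) || is.null(DB)) {
    stop("drug_cell_exchange: both drugs must be present", call. = FALSE)
  }
  list(
    G_prime = cross_attention(G, rbind(DA, DB), params),
    DA_prime = cross_attention(DA, G, params),
    DB_prime = cross_attention(DB, G, params)
  )
}

#' Drug-drug cross-attention exchange
#'
#' Both directions are computed with the same shared parameters:
#' `DA = CA(DA', DB')` and `DB = CA(DB', DA')`. By parameter sharing,
#' swapping the inputs swaps the outputs exactly.
#'
#' @param DA_prime,DB_prime updated drug representations.
#' @param params a `cads_attention` parameter list.
#' @return list with `DA`, `DB`.
#' @export
drug_drug_exchange <- function(DA_prime, DB_prime, params) {
  if (is.null(DA_prime) || is.null(DB_prime)) {
    stop("drug_drug_exchange: both drug representations must be present",
         call. = FALSE)
  }
  list(DA = cross_attention(DA_prime, DB_prime, params),
       DB = cross_attention(DB_prime, DA_prime, params))
}

#' Initialize an MLP head
#'
#' @param d_in input width.
#' @param hidden integer vector of hidden layer sizes.
#' @param seed integer seed.
#' @return a `cads_mlp` parameter list.
#' @export
init_mlp <- function(d_in, hidden = c(64L, 32L), seed = 1L) {
  set.seed(as.integer(seed))
  sizes <- c(d_in, hidden, 1L)
  params <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    params[[paste0("W", l)]] <- ad_init_dense(sizes[l], sizes[l + 1L])
    params[[paste0("b", l)]] <- matrix(0, 1L, sizes[l + 1L])
  }
  structure(list(layers = params, n_layers = length(sizes) - 1L),
            class = "cads_mlp")
}

# MLP forward on ad nodes: ReLU hidden layers, Tanh output.
mlp_forward_ad <- function(x, layers, n_layers) {
  h <- x
  for (l in seq_len(n_layers)) {
    h <- ad_add(ad_matmul(h, layers[[paste0("W", l)]]),
                layers[[paste0("b", l)]])
    if (l < n_layers) h <- ad_relu(h)
  }
  ad_tanh(h)
}

pool_rows <- function(x) {
  if (!is.matrix(x)) return(matrix(x, 1L))   # plain vectors are row vectors
  if (nrow(x) == 1L) x else matrix(colMeans(x), 1L)
}

#' Branch prediction head
#'
#' Mean-pools the fused cell and drug representations to fixed-length
#' vectors, concatenates them in the order `Gi || DA || DB`, and applies an
#' MLP with a final Tanh, so the output lies in `[-1, 1]` on the
#' standardized label scale.
#'
#' @param G fused cell representation (matrix or vector).
#' @param DA,DB fused drug representations.
#' @param params a `cads_mlp` from [init_mlp()].
#' @param branch branch tag, `"causal"` or `"trivial"`.
#' @return list with `Yi` (scalar prediction) and `branch`.
#' @export
predict_head <- function(G, DA, DB, params, branch = "causal") {
  stopifnot(inherits(params, "cads_mlp"))
  x <- cbind(pool_rows(G), pool_rows(DA), pool_rows(DB))
  if (!all(is.finite(x))) {
    stop("predict_head: non-finite input representation", call. = FALSE)
  }
  ad_tape_reset()
  layers <- lapply(params$layers, ad_leaf)
  y <- mlp_forward_ad(ad_leaf(x), layers, params$n_layers)
  list(Yi = as.numeric(y$val), branch = branch)
}

#' Concatenation + MLP fusion (no attention exchange)
#'
#' The no-attention fusion used by the MLP and graph backbones: the masked
#' cell vector and the pooled drug representations are concatenated and fed
#' to the prediction head directly.
#'
#' @inheritParams predict_head
#' @return list with `Yi` and `branch`.
#' @export
mlp_fusion <- function(G, DA, DB, params, branch = "causal") {
  predict_head(G, DA, DB, params, branch = branch)
}
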