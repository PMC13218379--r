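#' SMILES tokenization
#'
#' Deterministic regex-style segmentation of a SMILES string into chemical
#' substructure tokens: bracket atoms (`[nH]`, `[C@@H]`, ...), two-character
#' organic-subset atoms (`Cl`, `Br`), aromatic and aliphatic atoms, ring
#' closure digits (including `%nn`), and bond/branch symbols each become one
#' token. With a vocabulary the tokens are mapped to integer indices,
#' truncated/padded to `max_len`, and a padding mask is attached; tokens
#' absent from the vocabulary map to its `<unk>` entry.
#'
#' @param smiles a single non-empty SMILES string.
#' @param vocab optional [smiles_vocab()] object; when `NULL` the raw token
#'   strings are returned.
#' @param max_len pad/truncate length (defaults to the vocabulary's).
#' @return With a vocabulary, a `cads_tokens` object
#'   (`tokens`, `length`, `pad_mask`, `token_strings`); otherwise a
#'   character vector of tokens.
#' @export
tokenize_smiles <- function(smiles, vocab = NULL, max_len = NULL) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles)) {
    stop("tokenize_smiles: `smiles` must be a single non-empty string",
         call. = FALSE)
  }
  toks <- smiles_scan(smiles)
  if (is.null(vocab)) return(toks)
  stopifnot(inherits(vocab, "cads_vocab"))
  if (is.null(max_len)) max_len <- vocab$max_len
  idx <- match(toks, vocab$tokens)
  if (anyNA(idx)) {
    if (is.na(vocab$unk_id)) {
      stop(sprintf("tokenize_smiles: token(s) %s not in vocabulary and no <unk> configured",
                   paste(unique(toks[is.na(idx)]), collapse = ", ")),
           call. = FALSE)
    }
    idx[is.na(idx)] <- vocab$unk_id
  }
  idx <- idx[seq_len(min(length(idx), max_len))]
  len <- length(idx)
  pad <- rep(vocab$pad_id, max_len - len)
  structure(
    list(tokens = c(idx, pad), length = len,
         pad_mask = c(rep(TRUE, len), rep(FALSE, max_len - len)),
         token_strings = toks),
    class = "cads_tokens"
  )
}

# Greedy left-to-right SMILES scanner. Multi-character units are matched
# first; any remaining single character becomes its own (possibly unknown)
# token, so the scan is total.
smiles_scan <- function(smiles) {
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- character(0)
  i <- 1L
  two_char <- c("Cl", "Br", "@@")
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("tokenize_smiles: unterminated bracket atom", call. = FALSE)
      toks <- c(toks, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else if (ch == "%" && i + 2L <= n) {
      toks <- c(toks, paste(chars[i:(i + 2L)], collapse = ""))
      i <- i + 3L
    } else if (i < n && paste0(ch, chars[i + 1L]) %in% two_char) {
      toks <- c(toks, paste0(ch, chars[i + 1L]))
      i <- i + 2L
    } else {
      toks <- c(toks, ch)
      i <- i + 1L
    }
  }
  toks
}

#' Reassemble a SMILES string from tokens
#'
#' Inverse of [tokenize_smiles()] for in-vocabulary sequences; padding is
#' dropped.
#'
#' @param tokens a `cads_tokens` object or character vector of tokens.
#' @param vocab the vocabulary used for tokenization.
#' @return single SMILES string.
#' @export
detokenize_smiles <- function(tokens, vocab = NULL) {
  if (inherits(tokens, "cads_tokens")) {
    stopifnot(!is.null(vocab))
    toks <- vocab$tokens[tokens$tokens[tokens$pad_mask]]
  } else {
    toks <- tokens
  }
  paste(toks, collapse = "")
}

#' Build a token vocabulary from training SMILES
#'
#' @param smiles character vector of SMILES strings.
#' @param max_len default pad/truncate length for sequences.
#' @param add_unk include an `<unk>` fallback token.
#' @return a `cads_vocab` object (`tokens`, `pad_id`, `unk_id`, `max_len`).
#' @export
smiles_vocab <- function(smiles, max_len = 128L, add_unk = TRUE) {
  toks <- sort(unique(unlist(lapply(smiles, smiles_scan))))
  tokens <- c("<pad>", if (add_unk) "<unk>", toks)
  structure(
    list(tokens = tokens, pad_id = 1L,
         unk_id = if (add_unk) 2L else NA_integer_,
         max_len = as.integer(max_len)),
    class = "cads_vocab"
  )
}

#' @export
print.cads_vocab <- function(x, ...) {
  cat(sprintf("<cads_vocab> %d tokens, max_len %d\n", length(x$tokens), x$max_len))
  invisible(x)
}

#' Sinusoidal positional encoding with unit-norm rows
#'
#' Standard transformer sine/cosine positional encodings in which every row
#' is rescaled to unit L2 norm, so `||P[i, ]||_2 = 1` holds exactly (within
#' floating point) by construction.
#'
#' @param max_len number of positions.
#' @param d_model embedding width (even).
#' @return `max_len x d_model` matrix.
#' @export
positional_encoding <- function(max_len, d_model) {
  stopifnot(d_model >= 2, d_model %% 2 == 0)
  pos <- seq_len(max_len) - 1
  i <- seq_len(d_model / 2) - 1
  angle <- outer(pos, 1 / (10000^(2 * i / d_model)))
  P <- matrix(0, max_len, d_model)
  P[, seq(1, d_model, by = 2)] <- sin(angle)
  P[, seq(2, d_model, by = 2)] <- cos(angle)
  P / sqrt(rowSums(P^2))
}

#' Initialize a sequence drug encoder
#'
#' Token embedding table plus layer-normalization gain/bias. The positional
#' encoding is fixed (not learned).
#'
#' @param vocab_size number of vocabulary entries.
#' @param d_model embedding width.
#' @param seed integer seed for the embedding initialisation.
#' @return named list of parameter matrices.
#' @export
init_sequence_encoder <- function(vocab_size, d_model, seed = 1L) {
  set.seed(as.integer(seed))
  list(
    # unit-scale init keeps token identity dominant over the (fixed,
    # drug-independent) positional rows after layer normalization
    emb = matrix(stats::rnorm(vocab_size * d_model), vocab_size, d_model),
    ln_gamma = matrix(1, 1L, d_model),
    ln_beta = matrix(0, 1L, d_model)
  )
}

# Sequence-encoder forward on ad nodes. `tokens` is an integer vector
# (padded), `pe` the positional matrix; returns the (max_len x d_model)
# layer-normalized representation node.
seq_encode_ad <- function(tokens, pe, params) {
  emb <- ad_rows(params$emb, tokens)
  x <- ad_add(emb, ad_leaf(pe[seq_along(tokens), , drop = FALSE]))
  ad_layernorm_rows(x, params$ln_gamma, params$ln_beta)
}

#' Encode a tokenized drug through the sequence pathway
#'
#' Token embeddings are combined with the positional encoding by element-wise
#' addition and each position is layer-normalized: `Dk = LN(T + P)`. Padded
#' positions carry no information downstream: they are excluded from the
#' pooled vector and masked out of any later attention.
#'
#' @param seq a `cads_tokens` object.
#' @param pe positional encoding matrix from [positional_encoding()].
#' @param params parameters from [init_sequence_encoder()].
#' @return list with `H` (`max_len x d_model` matrix), `pooled`
#'   (`1 x d_model`, mean over non-pad positions) and `pad_mask`.
#' @export
encode_sequence <- function(seq, pe, params) {
  stopifnot(inherits(seq, "cads_tokens"))
  if (ncol(params$emb) != ncol(pe)) {
    stop("encode_sequence: embedding width and positional encoding width differ",
         call. = FALSE)
  }
  if (length(seq$tokens) > nrow(pe)) {
    stop("encode_sequence: sequence longer than positional encoding",
         call. = FALSE)
  }
  ad_tape_reset()
  p <- lapply(params, ad_leaf)
  H <- seq_encode_ad(seq$tokens, pe, p)
  Hv <- H$val
  pooled <- matrix(colMeans(Hv[seq$pad_mask, , drop = FALSE]), 1L)
  list(H = Hv, pooled = pooled, pad_mask = seq$pad_mask)
}

## ---- molecular graphs -------------------------------------------------------

graph_elements <- c("C", "N", "O", "S", "F", "P", "Cl", "Br", "I", "other")

#' Build a molecular graph from SMILES
#'
#' Parses the SMILES with ChemmineR/ChemmineOB into an atom/bond graph.
#' Atoms carry element one-hot, degree one-hot and in-ring features; bonds
#' carry bond-order one-hot and in-ring features. Each bond is stored once
#' and treated as undirected.
#'
#' @param smiles a single chemically valid SMILES string.
#' @return a `cads_graph` object: `atoms` tibble, `bonds` tibble, and the
#'   atom feature matrix `features`.
#' @export
build_graph <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles)) {
    stop("build_graph: `smiles` must be a single non-empty string", call. = FALSE)
  }
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop("build_graph requires the ChemmineR package", call. = FALSE)
  }
  # bond-free molecules (single heavy atom) don't survive the SDF round
  # trip, so they are constructed directly
  single <- regmatches(smiles,
                       regexec("^(\\[([A-Za-z][a-z]?)[^\\]]*\\]|Cl|Br|[BCNOPSFI])$",
                               smiles))[[1]]
  if (length(single)) {
    el <- if (nzchar(single[3])) single[3] else single[2]
    atoms <- tibble::tibble(idx = 1L, element = el, degree = 0L,
                            in_ring = FALSE)
    return(structure(
      list(atoms = atoms,
           bonds = tibble::tibble(from = integer(0), to = integer(0),
                                  order = integer(0), in_ring = logical(0)),
           features = atom_features(atoms), smiles = smiles),
      class = "cads_graph"))
  }
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  mol <- sdf[[1]]
  ab <- ChemmineR::atomblock(mol)
  # a failed parse yields a stub block without element_index row names
  if (is.null(ab) || nrow(ab) == 0 || !all(grepl("_", rownames(ab)))) {
    stop(sprintf("build_graph: invalid SMILES '%s'", smiles), call. = FALSE)
  }
  bb <- ChemmineR::bondblock(mol)
  element <- sub("_.*$", "", rownames(ab))
  n_atoms <- length(element)
  if (is.null(bb) || nrow(as.matrix(bb)) == 0) {
    bonds <- tibble::tibble(from = integer(0), to = integer(0),
                            order = integer(0), in_ring = logical(0))
  } else {
    bm <- matrix(as.numeric(as.matrix(bb)), nrow = nrow(as.matrix(bb)))
    bonds <- tibble::tibble(from = as.integer(bm[, 1]), to = as.integer(bm[, 2]),
                            order = as.integer(bm[, 3]))
    bonds$in_ring <- bond_in_ring(bonds, n_atoms)
  }
  degree <- tabulate(c(bonds$from, bonds$to), nbins = n_atoms)
  in_ring_atom <- rep(FALSE, n_atoms)
  if (nrow(bonds)) {
    in_ring_atom[unique(c(bonds$from[bonds$in_ring], bonds$to[bonds$in_ring]))] <- TRUE
  }
  atoms <- tibble::tibble(idx = seq_len(n_atoms), element = element,
                          degree = degree, in_ring = in_ring_atom)
  structure(
    list(atoms = atoms, bonds = bonds, features = atom_features(atoms),
         smiles = smiles),
    class = "cads_graph"
  )
}

# A bond is in a ring iff it is not a bridge of the molecular graph.
bond_in_ring <- function(bonds, n_atoms) {
  if (!nrow(bonds)) return(logical(0))
  vapply(seq_len(nrow(bonds)), function(i) {
    keep <- bonds[-i, , drop = FALSE]
    still_connected(bonds$from[i], bonds$to[i], keep, n_atoms)
  }, logical(1))
}

still_connected <- function(a, b, bonds, n_atoms) {
  adj <- vector("list", n_atoms)
  for (i in seq_len(nrow(bonds))) {
    adj[[bonds$from[i]]] <- c(adj[[bonds$from[i]]], bonds$to[i])
    adj[[bonds$to[i]]] <- c(adj[[bonds$to[i]]], bonds$from[i])
  }
  seen <- rep(FALSE, n_atoms)
  queue <- a
  seen[a] <- TRUE
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    if (v == b) return(TRUE)
    nb <- adj[[v]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  FALSE
}

atom_features <- function(atoms) {
  el <- ifelse(atoms$element %in% graph_elements, atoms$element, "other")
  el_oh <- outer(el, graph_elements, "==") * 1
  deg <- pmin(atoms$degree, 4L)
  deg_oh <- outer(deg, 0:4, "==") * 1
  cbind(el_oh, deg_oh, ring = as.numeric(atoms$in_ring))
}

#' @export
print.cads_graph <- function(x, ...) {
  cat(sprintf("<cads_graph> %s: %d atoms, %d bonds\n", x$smiles,
              nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

#' Initialize a graph drug encoder
#'
#' One multi-head graph-attention layer followed by two graph-convolution
#' layers and global mean pooling. Depth and widths follow the package
#' defaults (they are architecture configuration, not fixed by the model).
#'
#' @param d_in atom feature dimension (16 for [build_graph()] features).
#' @param hidden hidden width (divisible by `n_heads`).
#' @param n_heads number of attention heads in the GAT layer.
#' @param seed integer seed.
#' @return named list of parameter matrices.
#' @export
init_graph_encoder <- function(d_in = 16L, hidden = 64L, n_heads = 4L, seed = 1L) {
  stopifnot(hidden %% n_heads == 0)
  set.seed(as.integer(seed))
  dh <- hidden %/% n_heads
  params <- list()
  for (h in seq_len(n_heads)) {
    params[[paste0("gat_W", h)]] <- ad_init_dense(d_in, dh)
    params[[paste0("gat_asrc", h)]] <- ad_init_dense(dh, 1L)
    params[[paste0("gat_adst", h)]] <- ad_init_dense(dh, 1L)
  }
  params$gcn_W1 <- ad_init_dense(hidden, hidden)
  params$gcn_W2 <- ad_init_dense(hidden, hidden)
  params$n_heads <- n_heads
  params
}

# Graph encoder forward on ad nodes. `graph` is a cads_graph; parameters are
# ad leaves (except n_heads).
graph_encode_ad <- function(graph, params) {
  n <- nrow(graph$atoms)
  A <- diag(1, n)
  if (nrow(graph$bonds)) {
    for (i in seq_len(nrow(graph$bonds))) {
      A[graph$bonds$from[i], graph$bonds$to[i]] <- 1
      A[graph$bonds$to[i], graph$bonds$from[i]] <- 1
    }
  }
  neg_mask <- ifelse(A > 0, 0, -1e30)
  X <- ad_leaf(graph$features)
  ones_row <- ad_leaf(matrix(1, 1L, n))
  heads <- vector("list", params$n_heads)
  for (h in seq_len(params$n_heads)) {
    Hh <- ad_matmul(X, params[[paste0("gat_W", h)]])
    es <- ad_matmul(Hh, params[[paste0("gat_asrc", h)]])   # n x 1
    ed <- ad_matmul(Hh, params[[paste0("gat_adst", h)]])   # n x 1
    scores <- ad_add(ad_matmul(es, ones_row),
                     ad_transpose(ad_matmul(ed, ones_row)))
    att <- ad_softmax_rows(ad_leaky_relu(scores), add_mask = neg_mask)
    heads[[h]] <- ad_matmul(att, Hh)
  }
  H <- if (length(heads) > 1) do.call(ad_cbind, heads) else heads[[1]]
  H <- ad_relu(H)
  deg <- rowSums(A)
  Ahat <- ad_leaf(A / sqrt(outer(deg, deg)))   # sym-normalized adjacency + self-loops
  H <- ad_relu(ad_matmul(ad_matmul(Ahat, H), params$gcn_W1))
  H <- ad_relu(ad_matmul(ad_matmul(Ahat, H), params$gcn_W2))
  list(nodes = H, pooled = ad_colmeans_row(H))
}

#' Encode a molecular graph through the GAT/GCN pathway
#'
#' A graph-attention layer captures local neighbourhood structure, two
#' graph-convolution layers propagate it globally, and global mean pooling
#' yields the drug vector: `Dk = GCN(GAT(V, E))`. The output is invariant to
#' atom-index permutation.
#'
#' @param graph a `cads_graph` from [build_graph()].
#' @param params parameters from [init_graph_encoder()].
#' @return list with `nodes` (atoms x hidden matrix) and `pooled`
#'   (`1 x hidden` drug vector).
#' @export
encode_graph <- function(graph, params) {
  stopifnot(inherits(graph, "cads_graph"))
  if (nrow(graph$atoms) == 0) {
    stop("encode_graph: empty atom set", call. = FALSE)
  }
  ad_tape_reset()
  p <- params
  for (nm in names(p)) if (is.matrix(p[[nm]])) p[[nm]] <- ad_leaf(p[[nm]])
  out <- graph_encode_ad(graph, p)
  list(nodes = out$nodes$val, pooled = out$pooled$val)
}
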