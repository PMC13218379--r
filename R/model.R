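#' Training configuration for the dual-branch model
#'
#' Collects architecture and optimization settings. The defaults are the
#' package's reference desk-scale configuration; all of them are tunable.
#'
#' @param backbone `"mlp"` (concatenation fusion over sequence-encoded
#'   drugs), `"graph"` (GAT/GCN drug encoder with concatenation fusion) or
#'   `"xattn"` (cross-attention drug-cell fusion).
#' @param d_model drug embedding width (sequence pathway).
#' @param d_g per-gene feature width in the mask encoder.
#' @param n_heads attention heads (xattn and graph backbones).
#' @param hidden integer vector of hidden sizes for the branch MLP heads.
#' @param cell_proj width of the per-branch linear projection that maps the
#'   masked cell vector into the shared fusion space before concatenation
#'   (the drug and cell representations are projected to a common feature
#'   space prior to fusion). A narrow bottleneck concentrates the
#'   drug-by-cell interaction signal and speeds up its discovery.
#' @param hidden_act hidden activation of the branch MLPs.
#' @param graph_hidden hidden width of the graph drug encoder.
#' @param lr Adam learning rate; held constant through liftoff, then reduced
#'   to `lr/3` and `lr/6` by a validation-plateau rule in the final third of
#'   the epoch budget.
#' @param epochs maximum training epochs.
#' @param batch_size minibatch size.
#' @param patience early-stopping patience (epochs without validation RMSE
#'   improvement).
#' @param val_frac,test_frac fractions of examples held out for validation
#'   and test.
#' @param split `"random"` (by example) or `"cell"` (leave-cell-out test
#'   split).
#' @param n_msa number of self-attention blocks in the shared sequence drug
#'   encoder stack.
#' @param drug_gain constant gain on the mean-pooled drug vector. Mean
#'   pooling over L layer-normalized token rows shrinks the vector's
#'   magnitude by roughly `1/sqrt(L)`; a gain near `sqrt(L)` gives the drug
#'   representation full weight in the fusion head from the first epoch,
#'   which is what makes the drug-by-cell interaction discoverable reliably.
#' @param max_len token sequence pad/truncate length.
#' @param proj_l2 L2 penalty on the per-branch cell projections. Penalizing
#'   the projection makes carrying signal amplitude through the soft mask
#'   cheaper than through the projection weights, which drives informative
#'   genes' causal attention away from the uninformative 1/2 and sharpens
#'   causal-gene recovery.
#' @param warmup_epochs,min_liftoff training restarts with a reseeded
#'   initialisation (up to `max_restarts` times) if the validation
#'   correlation has not reached `min_liftoff` after `warmup_epochs` — the
#'   multiplicative drug-by-cell structure makes the first phase of training
#'   a saddle that a small fraction of initialisations fail to leave.
#' @param max_restarts maximum reinitialisation attempts.
#' @param label_scale internal label scaling: training targets are
#'   `(y - mean) / (label_scale * sd)`. The branch heads end in Tanh, so
#'   targets must fit inside (-1, 1); with heavy-tailed synergy scores a
#'   unit-variance scaling would clip the tails against the head's range,
#'   while `label_scale = 3` keeps essentially all targets representable.
#'   The inverse transform is applied at prediction time.
#' @param mask_l2 L2 penalty on the per-gene attention offsets; keeps
#'   uninformative genes' causal scores anchored at 1/2.
#' @param dual_branch set `FALSE` for the single-branch ablation (causal
#'   branch only, no null-information loss).
#' @param seed integer seed governing initialisation, splits and batching.
#' @param verbose print per-epoch progress.
#' @return a `cads_config` list.
#' @export
cads_config <- function(backbone = c("mlp", "graph", "xattn"),
                        d_model = 8L, d_g = 16L, n_heads = 4L,
                        hidden = 256L, cell_proj = 2L,
                        hidden_act = c("tanh", "relu"), graph_hidden = 32L,
                        lr = 6e-3, epochs = 400L, batch_size = 512L,
                        patience = 150L, val_frac = 0.15, test_frac = 0.15,
                        split = c("random", "cell"), n_msa = 1L,
                        drug_gain = 3, max_len = 32L, label_scale = 3,
                        mask_l2 = 1e-5, proj_l2 = 1e-3,
                        warmup_epochs = 150L, min_liftoff = 0.10,
                        max_restarts = 2L,
                        dual_branch = TRUE, seed = 1L,
                        verbose = FALSE) {
  backbone <- match.arg(backbone)
  split <- match.arg(split)
  hidden_act <- match.arg(hidden_act)
  stopifnot(d_model > 0, d_g > 0, n_heads > 0, all(hidden > 0), lr > 0,
            epochs > 0, batch_size > 0, cell_proj > 0, n_msa >= 0,
            d_model %% n_heads == 0)
  structure(
    list(backbone = backbone, d_model = as.integer(d_model),
         d_g = as.integer(d_g), n_heads = as.integer(n_heads),
         hidden = as.integer(hidden), cell_proj = as.integer(cell_proj),
         hidden_act = hidden_act, graph_hidden = as.integer(graph_hidden),
         n_msa = as.integer(n_msa), drug_gain = drug_gain,
         label_scale = label_scale,
         lr = lr, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), patience = as.integer(patience),
         val_frac = val_frac, test_frac = test_frac, split = split,
         max_len = as.integer(max_len), mask_l2 = mask_l2,
         proj_l2 = proj_l2, warmup_epochs = as.integer(warmup_epochs),
         min_liftoff = min_liftoff, max_restarts = as.integer(max_restarts),
         dual_branch = isTRUE(dual_branch), seed = as.integer(seed),
         verbose = isTRUE(verbose)),
    class = "cads_config"
  )
}

# Assemble model state: parameter matrices plus the constant tensors the
# forward pass needs (token index tables, positional encodings, stacked
# profiles, id maps).
build_model_state <- function(profiles, drugs, config) {
  cfg <- config
  n_genes <- length(profiles$gene_ids)
  n_cells <- length(profiles$cell_ids)
  n_omics <- profiles$n_omics
  n_drugs <- nrow(drugs)

  set.seed(cfg$seed)
  vocab <- smiles_vocab(drugs$smiles, max_len = cfg$max_len)
  toks <- lapply(drugs$smiles, tokenize_smiles, vocab = vocab)
  tok_mat <- do.call(rbind, lapply(toks, function(t) t$tokens))
  pad_mat <- do.call(rbind, lapply(toks, function(t) t$pad_mask))
  # trim the shared pad length to the longest observed sequence
  L_eff <- max(vapply(toks, function(t) t$length, integer(1)))
  tok_mat <- tok_mat[, seq_len(L_eff), drop = FALSE]
  pad_mat <- pad_mat[, seq_len(L_eff), drop = FALSE]
  cfg$max_len <- L_eff
  pe <- positional_encoding(cfg$max_len, cfg$d_model)

  # cell-major stack of gene omics columns: rows = (cell, gene)
  X_all <- do.call(rbind, lapply(profiles$cells, t))
  # per-(gene, layer) standardization across cells: neural inputs are on a
  # comparable scale regardless of each gene's location and spread
  gene_of_row <- rep(seq_len(n_genes), n_cells)
  mu_gl <- rowsum(X_all, gene_of_row) / n_cells
  sd_gl <- sqrt(pmax(rowsum(X_all^2, gene_of_row) / n_cells - mu_gl^2, 0) *
                  n_cells / max(n_cells - 1L, 1L))
  sd_gl[sd_gl < 1e-12] <- 1
  X_all_std <- (X_all - mu_gl[gene_of_row, , drop = FALSE]) /
    sd_gl[gene_of_row, , drop = FALSE]
  Xbar_std <- t(matrix(rowMeans(X_all_std), n_genes, n_cells))
  dimnames(Xbar_std) <- list(profiles$cell_ids, profiles$gene_ids)

  mask_enc <- init_mask_encoder(n_genes, n_omics, d_g = cfg$d_g,
                                seed = cfg$seed)
  seq_enc <- init_sequence_encoder(length(vocab$tokens), cfg$d_model,
                                   seed = cfg$seed + 1L)
  params <- list(
    emb = seq_enc$emb, ln_gamma = seq_enc$ln_gamma, ln_beta = seq_enc$ln_beta,
    mask_W1 = mask_enc$W1, mask_b1 = mask_enc$b1, mask_W2 = mask_enc$W2,
    mask_U = mask_enc$U
  )
  # multi-head self-attention blocks (residual + layer norm) inside the
  # shared sequence drug encoder stack
  for (blk in seq_len(cfg$n_msa)) {
    msa <- init_attention(cfg$d_model, cfg$n_heads, seed = cfg$seed + 2L + blk)
    for (nm in c("WQ", "WK", "WV", "WO")) {
      params[[sprintf("msa%d_%s", blk, nm)]] <- msa[[nm]]
    }
    params[[sprintf("msa%d_ln_gamma", blk)]] <- matrix(1, 1L, cfg$d_model)
    params[[sprintf("msa%d_ln_beta", blk)]] <- matrix(0, 1L, cfg$d_model)
  }

  d_drug <- switch(cfg$backbone,
                   mlp = cfg$d_model,
                   graph = cfg$graph_hidden,
                   xattn = cfg$d_model)
  d_in <- switch(cfg$backbone,
                 mlp = cfg$cell_proj + 2L * d_drug,
                 graph = cfg$cell_proj + 2L * d_drug,
                 xattn = 3L * cfg$d_model)
  branches <- if (cfg$dual_branch) c("c", "t") else "c"
  for (br in branches) {
    head <- init_mlp(d_in, hidden = cfg$hidden,
                     seed = cfg$seed + 10L + match(br, c("c", "t")))
    for (nm in names(head$layers)) {
      params[[paste0(br, "_", nm)]] <- head$layers[[nm]]
    }
    if (cfg$backbone %in% c("mlp", "graph")) {
      set.seed(cfg$seed + 40L + match(br, c("c", "t")))
      # scale 2/sqrt(N): unit-variance projection of the half-strength
      # (mask-attenuated) cell input at initialization
      params[[paste0(br, "_P")]] <- matrix(
        stats::rnorm(n_genes * cfg$cell_proj, 0, 2 / sqrt(n_genes)),
        n_genes, cfg$cell_proj)
    }
    if (cfg$backbone == "xattn") {
      set.seed(cfg$seed + 20L + match(br, c("c", "t")))
      params[[paste0(br, "_gene_emb")]] <- ad_init_dense(n_genes, cfg$d_model)
      for (blk in c("attn1", "attn2")) {
        at <- init_attention(cfg$d_model, cfg$n_heads,
                             seed = cfg$seed + 30L + match(br, c("c", "t")) +
                               10L * match(blk, c("attn1", "attn2")))
        for (nm in c("WQ", "WK", "WV", "WO")) {
          params[[paste0(br, "_", blk, "_", nm)]] <- at[[nm]]
        }
      }
    }
  }

  graphs <- NULL
  if (cfg$backbone == "graph") {
    graphs <- lapply(drugs$smiles, build_graph)
    ge <- init_graph_encoder(d_in = ncol(graphs[[1]]$features),
                             hidden = cfg$graph_hidden, n_heads = cfg$n_heads,
                             seed = cfg$seed + 2L)
    for (nm in names(ge)) {
      if (is.matrix(ge[[nm]])) params[[paste0("g_", nm)]] <- ge[[nm]]
    }
  }

  list(
    params = params, config = cfg, n_layers = length(cfg$hidden) + 1L,
    vocab = vocab, tok_mat = tok_mat, pad_mat = pad_mat, pe = pe,
    tok_flat = as.integer(t(tok_mat)),
    tok_group = rep(seq_len(n_drugs), each = cfg$max_len),
    tok_w = as.numeric(t(pad_mat)),
    pe_rep = pe[rep(seq_len(cfg$max_len), n_drugs), , drop = FALSE],
    msa_mask = local({
      grp <- rep(seq_len(n_drugs), each = cfg$max_len)
      keyok <- as.logical(t(pad_mat))
      m <- outer(grp, grp, "==") & rep(keyok, each = length(grp))
      ifelse(m, 0, -1e30)
    }),
    graphs = graphs,
    gene_ids = profiles$gene_ids, cell_ids = profiles$cell_ids,
    drug_ids = drugs$drug_id, smiles = drugs$smiles,
    n_genes = n_genes, n_cells = n_cells, n_omics = n_omics,
    n_drugs = n_drugs, X_all = X_all, X_all_std = X_all_std,
    Xbar_std = Xbar_std, gene_mu = mu_gl, gene_sd = sd_gl
  )
}

branch_mlp_ad <- function(x, p, prefix, n_layers, act = "tanh") {
  h <- x
  for (l in seq_len(n_layers)) {
    h <- ad_add(ad_matmul(h, p[[paste0(prefix, "_W", l)]]),
                p[[paste0(prefix, "_b", l)]])
    if (l < n_layers) h <- if (act == "relu") ad_relu(h) else ad_tanh(h)
  }
  ad_tanh(h)
}

# Shared sequence drug matrix: embedding + positional encoding + layer norm,
# one self-attention block over each drug's tokens (batched across drugs via
# a block-diagonal attention mask), residual + layer norm, mean pooling.
drug_matrix_seq_ad <- function(ms, p) {
  emb <- ad_rows(p$emb, ms$tok_flat)
  x <- ad_add(emb, ad_leaf(ms$pe_rep))
  h <- ad_layernorm_rows(x, p$ln_gamma, p$ln_beta)
  cfg <- ms$config
  dk <- cfg$d_model %/% cfg$n_heads
  for (blk in seq_len(cfg$n_msa)) {
    att <- ca_ad(h, h,
                 list(WQ = p[[sprintf("msa%d_WQ", blk)]],
                      WK = p[[sprintf("msa%d_WK", blk)]],
                      WV = p[[sprintf("msa%d_WV", blk)]],
                      WO = p[[sprintf("msa%d_WO", blk)]]),
                 cfg$n_heads, dk, add_mask = ms$msa_mask)
    h <- ad_layernorm_rows(ad_add(h, att),
                           p[[sprintf("msa%d_ln_gamma", blk)]],
                           p[[sprintf("msa%d_ln_beta", blk)]])
  }
  ad_scale(ad_group_rowmeans(h, ms$tok_group, ms$n_drugs, w = ms$tok_w),
           cfg$drug_gain)
}

drug_matrix_graph_ad <- function(ms, p) {
  gp <- p[grep("^g_", names(p))]
  names(gp) <- sub("^g_", "", names(gp))
  gp$n_heads <- ms$config$n_heads
  pooled <- lapply(ms$graphs, function(g) graph_encode_ad(g, gp)$pooled)
  ad_scale(do.call(ad_rbind, pooled), ms$config$drug_gain)
}

# Forward pass for the concatenation backbones (mlp, graph): everything is
# batched through matrix ops. Returns prediction nodes and the causal mask.
forward_dense_ad <- function(ms, p, ai, bi, ci) {
  cfg <- ms$config
  Mc <- mask_forward_ad(ad_leaf(ms$X_all_std), p, ms$n_cells, ms$n_genes)
  Xbar <- ad_leaf(ms$Xbar_std)
  Gc <- ad_mul(Xbar, Mc)
  Dmat <- if (cfg$backbone == "graph") drug_matrix_graph_ad(ms, p)
          else drug_matrix_seq_ad(ms, p)
  da <- ad_rows(Dmat, ai)
  db <- ad_rows(Dmat, bi)
  cp_c <- ad_matmul(ad_rows(Gc, ci), p$c_P)
  yc <- branch_mlp_ad(ad_cbind(cp_c, da, db), p, "c", ms$n_layers,
                      cfg$hidden_act)
  yt <- NULL
  if (cfg$dual_branch) {
    Gt <- ad_mul(Xbar, ad_add(ad_scale(Mc, -1), matrix(1, 1L, 1L)))
    cp_t <- ad_matmul(ad_rows(Gt, ci), p$t_P)
    yt <- branch_mlp_ad(ad_cbind(cp_t, da, db), p, "t", ms$n_layers,
                        cfg$hidden_act)
  }
  list(yc = yc, yt = yt, Mc = Mc)
}

xattn_branch_example_ad <- function(ms, p, br, gvec_col, HA, HB, mA, mB) {
  cfg <- ms$config
  Gi <- ad_mul_colvec(p[[paste0(br, "_gene_emb")]], gvec_col)
  a1 <- list(WQ = p[[paste0(br, "_attn1_WQ")]], WK = p[[paste0(br, "_attn1_WK")]],
             WV = p[[paste0(br, "_attn1_WV")]], WO = p[[paste0(br, "_attn1_WO")]])
  a2 <- list(WQ = p[[paste0(br, "_attn2_WQ")]], WK = p[[paste0(br, "_attn2_WK")]],
             WV = p[[paste0(br, "_attn2_WV")]], WO = p[[paste0(br, "_attn2_WO")]])
  dk <- cfg$d_model %/% cfg$n_heads
  D_stack <- ad_rbind(HA, HB)
  Gp <- ca_ad(Gi, D_stack, a1, cfg$n_heads, dk, key_mask = c(mA, mB))
  DAp <- ca_ad(HA, Gi, a1, cfg$n_heads, dk)
  DBp <- ca_ad(HB, Gi, a1, cfg$n_heads, dk)
  DA2 <- ca_ad(DAp, DBp, a2, cfg$n_heads, dk, key_mask = mB)
  DB2 <- ca_ad(DBp, DAp, a2, cfg$n_heads, dk, key_mask = mA)
  gpool <- ad_colmeans_row(Gp)
  apool <- ad_group_rowmeans(DA2, rep(1L, nrow(DA2$val)), 1L, w = as.numeric(mA))
  bpool <- ad_group_rowmeans(DB2, rep(1L, nrow(DB2$val)), 1L, w = as.numeric(mB))
  branch_mlp_ad(ad_cbind(gpool, apool, bpool), p, br, ms$n_layers,
                cfg$hidden_act)
}

forward_xattn_ad <- function(ms, p, ai, bi, ci) {
  cfg <- ms$config
  Mc <- mask_forward_ad(ad_leaf(ms$X_all_std), p, ms$n_cells, ms$n_genes)
  Xbar <- ad_leaf(ms$Xbar_std)
  Gc <- ad_mul(Xbar, Mc)
  Gt <- ad_mul(Xbar, ad_add(ad_scale(Mc, -1), matrix(1, 1L, 1L)))
  H <- lapply(seq_len(ms$n_drugs), function(d) {
    seq_encode_ad(ms$tok_mat[d, ], ms$pe, p)
  })
  ycs <- vector("list", length(ai))
  yts <- if (cfg$dual_branch) vector("list", length(ai)) else NULL
  for (e in seq_along(ai)) {
    mA <- ms$pad_mat[ai[e], ]
    mB <- ms$pad_mat[bi[e], ]
    gc_col <- ad_transpose(ad_rows(Gc, ci[e]))
    ycs[[e]] <- xattn_branch_example_ad(ms, p, "c", gc_col,
                                        H[[ai[e]]], H[[bi[e]]], mA, mB)
    if (cfg$dual_branch) {
      gt_col <- ad_transpose(ad_rows(Gt, ci[e]))
      yts[[e]] <- xattn_branch_example_ad(ms, p, "t", gt_col,
                                          H[[ai[e]]], H[[bi[e]]], mA, mB)
    }
  }
  list(yc = do.call(ad_rbind, ycs),
       yt = if (cfg$dual_branch) do.call(ad_rbind, yts) else NULL,
       Mc = Mc)
}

forward_model_ad <- function(ms, p, ai, bi, ci) {
  if (ms$config$backbone == "xattn") forward_xattn_ad(ms, p, ai, bi, ci)
  else forward_dense_ad(ms, p, ai, bi, ci)
}

#' Dual-branch loss decomposition
#'
#' Mean-squared error of the causal branch against the observed labels plus
#' mean-squared error of the trivial branch against the all-zero
#' null-information target; the total is their exact sum.
#'
#' @param y_c causal-branch predictions (standardized scale).
#' @param y_t trivial-branch predictions (`NULL` for single-branch models).
#' @param y standardized labels.
#' @return one-row tibble with `loss`, `loss_causal`, `loss_trivial`.
#' @export
cads_loss <- function(y_c, y_t, y) {
  stopifnot(length(y_c) == length(y), all(is.finite(y)))
  lc <- mean((y_c - y)^2)
  lt <- if (is.null(y_t)) 0 else mean(y_t^2)
  tibble::tibble(loss = lc + lt, loss_causal = lc, loss_trivial = lt)
}

split_examples <- function(examples, cell_ids, config) {
  n <- nrow(examples)
  set.seed(config$seed + 1000L)
  if (config$split == "cell") {
    n_test_cells <- max(1L, round(config$test_frac * length(cell_ids)))
    test_cells <- sample(cell_ids, n_test_cells)
    test <- which(examples$cell_id %in% test_cells)
    rest <- setdiff(seq_len(n), test)
    val <- sample(rest, round(config$val_frac * n))
  } else {
    perm <- sample.int(n)
    n_test <- round(config$test_frac * n)
    n_val <- round(config$val_frac * n)
    test <- perm[seq_len(n_test)]
    val <- perm[n_test + seq_len(n_val)]
  }
  train <- setdiff(seq_len(n), c(test, val))
  list(train = sort(train), val = sort(val), test = sort(test))
}

#' Train the dual-branch synergy model
#'
#' Jointly trains the shared drug encoder, the causal mask encoder and the
#' two branch networks by minibatch Adam on the summed loss: the causal
#' branch regresses the observed synergy score, the trivial branch
#' regresses the all-zero null-information target. Because the masks are
#' complementary and both branches backpropagate into the mask encoder,
#' genes that carry synergy signal are pushed toward the causal channel.
#' The best checkpoint by validation RMSE is kept.
#'
#' @param dataset a `cads_dataset` from [simulate_synergy()], or a list with
#'   `profiles` (a `cads_profiles`), `drugs` (tibble `drug_id`, `smiles`)
#'   and `examples` (tibble `drug_a`, `drug_b`, `cell_id`, `y`).
#' @param config a [cads_config()].
#' @param split optional explicit split: list with integer index vectors
#'   `train`, `val`, `test` into `dataset$examples` (used e.g. by
#'   [fewshot_curve()] to hold the evaluation splits fixed while
#'   subsampling training data).
#' @return a `cads_fit` object with elements `params`, `history`, `split`,
#'   `standardize`, `best_epoch` and the model metadata needed by
#'   [predict.cads_fit()] and [causal_scores()].
#' @export
cads_train <- function(dataset, config = cads_config(), split = NULL) {
  stopifnot(inherits(config, "cads_config"))
  profiles <- dataset$profiles
  drugs <- dataset$drugs
  examples <- dataset$examples
  if (!all(c("drug_a", "drug_b", "cell_id", "y") %in% names(examples))) {
    stop("cads_train: examples need columns drug_a, drug_b, cell_id, y",
         call. = FALSE)
  }
  ai <- match(examples$drug_a, drugs$drug_id)
  bi <- match(examples$drug_b, drugs$drug_id)
  ci <- match(examples$cell_id, profiles$cell_ids)
  if (anyNA(ai) || anyNA(bi) || anyNA(ci)) {
    stop("cads_train: examples reference unknown drug or cell ids",
         call. = FALSE)
  }

  if (is.null(split)) {
    split <- split_examples(examples, profiles$cell_ids, config)
  }
  m <- mean(examples$y[split$train])
  s <- stats::sd(examples$y[split$train]) * config$label_scale
  if (!is.finite(s) || s == 0) s <- 1
  y_std <- (examples$y - m) / s

  wd_base <- list(mask_U = config$mask_l2, c_P = 0, t_P = 0)
  # the projection penalty switches on only once validation correlation has
  # lifted off: during the early saddle phase the cell signal must flow
  # freely through the projection, afterwards penalizing it pushes amplitude
  # into the causal mask
  wd_lifted <- list(mask_U = config$mask_l2,
                    c_P = config$proj_l2, t_P = config$proj_l2)

  # One optimization attempt from a given initialisation seed. The drug-by-
  # cell interaction makes early training a saddle; if validation correlation
  # has not lifted off after `warmup_epochs`, the caller reinitializes.
  run_attempt <- function(init_seed, allow_abort) {
    cfg_i <- config
    cfg_i$seed <- init_seed
    ms_i <- build_model_state(profiles, drugs, cfg_i)
    leaves <- lapply(ms_i$params, ad_leaf)
    opt <- adam_state(leaves)

    eval_split <- function(rows) {
      out <- predict_rows(ms_i, leaves, ai[rows], bi[rows], ci[rows])
      rmse <- sqrt(mean((out$yc - y_std[rows])^2))
      pcc <- suppressWarnings(stats::cor(out$yc, y_std[rows]))
      list(rmse = rmse, pcc = pcc,
           mean_abs_yt = if (is.null(out$yt)) NA_real_ else mean(abs(out$yt)))
    }

    set.seed(init_seed + 2000L)
    hist <- vector("list", config$epochs)
    best <- list(rmse = Inf, params = NULL, epoch = 0L)
    stale <- 0L
    # learning rate: constant until the validation correlation lifts off,
    # then plateau-based reductions (/3, /6) when validation RMSE stalls
    lr_level <- 0L
    lr_stale <- 0L
    lifted <- FALSE
    aborted <- FALSE
    for (epoch in seq_len(config$epochs)) {
      lr_now <- config$lr / c(1, 3, 6)[lr_level + 1L]
      idx <- sample(split$train)
      nb <- ceiling(length(idx) / config$batch_size)
      ep_loss <- ep_lc <- ep_lt <- 0
      for (b in seq_len(nb)) {
        rows <- idx[((b - 1L) * config$batch_size + 1L):min(b * config$batch_size,
                                                            length(idx))]
        ad_tape_reset()
        fw <- forward_model_ad(ms_i, leaves, ai[rows], bi[rows], ci[rows])
        dlt <- ad_sub(fw$yc, matrix(y_std[rows], ncol = 1L))
        Lc <- ad_mean(ad_square(dlt))
        L <- if (config$dual_branch) ad_add(Lc, ad_mean(ad_square(fw$yt))) else Lc
        if (!is.finite(L$val[1])) {
          stop(sprintf("cads_train: non-finite loss at epoch %d batch %d (diverged)",
                       epoch, b), call. = FALSE)
        }
        ad_backward(L)
        opt <- adam_step(leaves, opt, lr = lr_now,
                         weight_decay = if (lifted) wd_lifted else wd_base)
        ad_zero_grads(leaves)
        ep_loss <- ep_loss + L$val[1] * length(rows)
        ep_lc <- ep_lc + Lc$val[1] * length(rows)
        ep_lt <- ep_lt + (L$val[1] - Lc$val[1]) * length(rows)
      }
      ev <- eval_split(split$val)
      if (!lifted && is.finite(ev$pcc) && ev$pcc >= 0.3) lifted <- TRUE
      hist[[epoch]] <- tibble::tibble(
        epoch = epoch,
        train_loss = ep_loss / length(idx),
        train_loss_causal = ep_lc / length(idx),
        train_loss_trivial = ep_lt / length(idx),
        val_rmse = ev$rmse, val_pcc = ev$pcc, mean_abs_yt = ev$mean_abs_yt,
        lr = lr_now
      )
      if (config$verbose) {
        message(sprintf("epoch %3d  loss %.4f  val_rmse %.4f  val_pcc %.3f  lr %.2g",
                        epoch, ep_loss / length(idx), ev$rmse, ev$pcc, lr_now))
      }
      if (ev$rmse < best$rmse - 1e-6) {
        best <- list(rmse = ev$rmse, params = lapply(leaves, function(l) l$val),
                     epoch = epoch)
        stale <- 0L
        lr_stale <- 0L
      } else {
        stale <- stale + 1L
        lr_stale <- lr_stale + 1L
        # plateau reductions only in the final third of the budget: early
        # decay locks runs into half-converged representations
        if (lifted && epoch > (2 / 3) * config$epochs &&
            lr_stale >= 30L && lr_level < 2L) {
          lr_level <- lr_level + 1L
          lr_stale <- 0L
        }
        if (stale >= config$patience) break
      }
      if (allow_abort && config$warmup_epochs > 0L &&
          epoch == config$warmup_epochs &&
          (!is.finite(ev$pcc) || ev$pcc < config$min_liftoff)) {
        aborted <- TRUE
        break
      }
    }
    if (is.null(best$params)) {
      best <- list(rmse = NA_real_, params = lapply(leaves, function(l) l$val),
                   epoch = 0L)
    }
    list(ms = ms_i, best = best, aborted = aborted,
         history = dplyr::bind_rows(hist[!vapply(hist, is.null, logical(1))]))
  }

  attempt <- 0L
  repeat {
    res <- run_attempt(config$seed + 1009L * attempt,
                       allow_abort = attempt < config$max_restarts)
    if (!res$aborted) break
    attempt <- attempt + 1L
    if (config$verbose) {
      message(sprintf("cads_train: no liftoff after %d epochs; restart %d",
                      config$warmup_epochs, attempt))
    }
  }
  ms <- res$ms
  best <- res$best

  structure(
    list(params = best$params, config = ms$config,
         vocab = ms$vocab, tok_mat = ms$tok_mat, pad_mat = ms$pad_mat,
         pe = ms$pe, tok_flat = ms$tok_flat, tok_group = ms$tok_group,
         tok_w = ms$tok_w, pe_rep = ms$pe_rep, msa_mask = ms$msa_mask,
         graphs = ms$graphs,
         gene_ids = ms$gene_ids, cell_ids = ms$cell_ids,
         drug_ids = ms$drug_ids, smiles = ms$smiles,
         n_genes = ms$n_genes, n_cells = ms$n_cells, n_omics = ms$n_omics,
         n_drugs = ms$n_drugs, n_layers = ms$n_layers,
         X_all = ms$X_all, X_all_std = ms$X_all_std, Xbar_std = ms$Xbar_std,
         gene_mu = ms$gene_mu, gene_sd = ms$gene_sd,
         examples = examples, split = split,
         standardize = list(mean = m, sd = s),
         history = res$history,
         best_epoch = best$epoch, restarts = attempt),
    class = "cads_fit"
  )
}

# Value-only forward for a set of example rows; batches to bound memory.
predict_rows <- function(ms, leaves, ai, bi, ci, chunk = 2048L) {
  n <- length(ai)
  yc <- numeric(n)
  yt <- if (ms$config$dual_branch) numeric(n) else NULL
  for (st in seq(1L, n, by = chunk)) {
    en <- min(st + chunk - 1L, n)
    ad_tape_reset()
    fw <- forward_model_ad(ms, leaves, ai[st:en], bi[st:en], ci[st:en])
    yc[st:en] <- as.numeric(fw$yc$val)
    if (!is.null(yt)) yt[st:en] <- as.numeric(fw$yt$val)
  }
  ad_tape_reset()
  list(yc = yc, yt = yt)
}

fit_state <- function(fit) {
  ms <- unclass(fit)
  ms$config <- fit$config
  ms
}

#' @export
print.cads_fit <- function(x, ...) {
  cat(sprintf(paste0("<cads_fit> backbone=%s | %d genes, %d cells, %d drugs | ",
                     "best epoch %d (val RMSE %.4f)\n"),
              x$config$backbone, x$n_genes, x$n_cells, x$n_drugs,
              x$best_epoch,
              x$history$val_rmse[match(x$best_epoch, x$history$epoch)]))
  invisible(x)
}

#' Predict synergy scores
#'
#' Runs the trained model and returns both branch outputs on the
#' standardized scale plus the de-standardized final prediction, which is
#' taken from the causal branch only; the trivial branch is exposed purely
#' as a diagnostic.
#'
#' @param object a `cads_fit`.
#' @param examples tibble with `drug_a`, `drug_b`, `cell_id` (defaults to
#'   the training dataset's examples).
#' @param zero_genes optional integer indices (or gene ids) whose values
#'   are zeroed throughout the profiles before inference (zero-masking
#'   ablation).
#' @param ... unused.
#' @return tibble: the example columns plus `y_c`, `y_t` (standardized) and
#'   `y_hat` (de-standardized causal prediction).
#' @export
predict.cads_fit <- function(object, examples = NULL, zero_genes = NULL, ...) {
  if (is.null(examples)) examples <- object$examples
  ms <- fit_state(object)
  if (!is.null(zero_genes)) {
    zz <- zero_gene_state(ms, zero_genes)
    ms$Xbar_std <- zz$Xbar_std
    ms$X_all_std <- zz$X_all_std
  }
  ai <- match(examples$drug_a, ms$drug_ids)
  bi <- match(examples$drug_b, ms$drug_ids)
  ci <- match(examples$cell_id, ms$cell_ids)
  if (anyNA(ai) || anyNA(bi) || anyNA(ci)) {
    stop("predict.cads_fit: unknown drug or cell id", call. = FALSE)
  }
  leaves <- lapply(ms$params, ad_leaf)
  out <- predict_rows(ms, leaves, ai, bi, ci)
  res <- tibble::as_tibble(examples)
  res$y_c <- out$yc
  res$y_t <- if (is.null(out$yt)) NA_real_ else out$yt
  res$y_hat <- inverse_standardize(out$yc, object$standardize)
  res
}

#' Undo label standardization
#'
#' @param y_std standardized values.
#' @param st list with `mean` and `sd`.
#' @return values on the original label scale.
#' @export
inverse_standardize <- function(y_std, st) y_std * st$sd + st$mean

#' Apply label standardization
#'
#' @param y raw values.
#' @param st list with `mean` and `sd`.
#' @return standardized values.
#' @export
standardize_labels <- function(y, st) (y - st$mean) / st$sd

# Zero-masking on the model's (standardized) input scale: the ablated
# genes' values are set to the uninformative population mean.
zero_gene_state <- function(ms, zero_genes) {
  g <- if (is.character(zero_genes)) match(zero_genes, ms$gene_ids)
       else as.integer(zero_genes)
  if (anyNA(g) || any(g < 1 | g > ms$n_genes)) {
    stop("zero_genes: unknown gene indices", call. = FALSE)
  }
  Xbar_std <- ms$Xbar_std
  Xbar_std[, g] <- 0
  X_all_std <- ms$X_all_std
  rows <- as.integer(outer(g, (seq_len(ms$n_cells) - 1L) * ms$n_genes, "+"))
  X_all_std[rows, ] <- 0
  list(Xbar_std = Xbar_std, X_all_std = X_all_std)
}

#' Per-cell causal scores from a trained model
#'
#' The causal score of gene `i` in cell `c` is its causal-channel attention
#' weight `alpha_c`. Returned in long form, one row per (cell, gene).
#'
#' @param fit a `cads_fit`.
#' @return tibble with `cell_id`, `gene_id`, `alpha_c`.
#' @export
causal_scores <- function(fit) {
  stopifnot(inherits(fit, "cads_fit"))
  M <- causal_mask_matrix(fit)
  tibble::tibble(
    cell_id = rep(fit$cell_ids, each = fit$n_genes),
    gene_id = rep(fit$gene_ids, times = fit$n_cells),
    alpha_c = as.numeric(t(M))
  )
}

# cells x genes matrix of causal-channel attention weights.
causal_mask_matrix <- function(fit) {
  ms <- fit_state(fit)
  ad_tape_reset()
  leaves <- lapply(ms$params, ad_leaf)
  Mc <- mask_forward_ad(ad_leaf(ms$X_all_std), leaves, ms$n_cells, ms$n_genes)
  val <- Mc$val
  ad_tape_reset()
  dimnames(val) <- list(fit$cell_ids, fit$gene_ids)
  val
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-gene causal-score summary
#'
#' @param x a `cads_fit`.
#' @param ... unused.
#' @return tibble with per-gene mean and standard deviation of the causal
#'   score across cells.
#' @export
tidy.cads_fit <- function(x, ...) {
  M <- causal_mask_matrix(x)
  tibble::tibble(
    gene_id = x$gene_ids,
    mean_alpha_c = unname(colMeans(M)),
    sd_alpha_c = unname(apply(M, 2L, stats::sd))
  )
}

#' One-row model summary
#'
#' @param x a `cads_fit`.
#' @param ... unused.
#' @return tibble with backbone, epochs run, best epoch and held-out
#'   metrics of the causal branch on the fit's test split.
#' @export
glance.cads_fit <- function(x, ...) {
  te <- x$split$test
  pr <- predict(x, x$examples[te, , drop = FALSE])
  y_std <- standardize_labels(x$examples$y[te], x$standardize)
  met <- regression_metrics(y_std, pr$y_c)
  tibble::tibble(
    backbone = x$config$backbone,
    epochs_run = nrow(x$history),
    best_epoch = x$best_epoch,
    test_rmse = met$rmse, test_mae = met$mae,
    test_r2 = met$r2, test_pcc = met$pcc,
    n_test = length(te)
  )
}
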