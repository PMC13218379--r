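#' Generate synthetic cell-line omics profiles
#'
#' Draws an `n_omics` x `n_genes` expression-like matrix for each cell line.
#' Gene `g` has a generating location `mu_g ~ N(0, 1)` and scale
#' `sigma_g ~ U(0.5, 1.5)` shared across cell lines; cell values are
#' `mu_g + sigma_g * z` with `z` standard normal per (cell, gene). Omics
#' layers beyond the first are correlated copies of layer 1 (latent
#' correlation 0.7), a cheap stand-in for correlated multi-omics. When a
#' planted `truth` is supplied, each decoy gene's latent `z` is generated
#' with correlation `truth$confound_rho` to its paired causal gene's `z`.
#'
#' @param n_cells number of cell lines (>= 1).
#' @param n_genes number of genes (>= 2).
#' @param n_omics number of omics layers (>= 1).
#' @param seed integer seed; identical seeds reproduce identical profiles.
#' @param truth optional [plant_truth()] object used to induce the
#'   causal/decoy correlation structure.
#' @return A `cads_profiles` object: list with `cells` (named list of
#'   `n_omics x n_genes` matrices), `gene_ids`, `cell_ids`, and the
#'   generating `gene_mu`/`gene_sd`.
#' @export
generate_profiles <- function(n_cells, n_genes, n_omics = 1L, seed = 1L,
                              truth = NULL) {
  if (n_cells < 1 || n_genes < 2 || n_omics < 1) {
    stop("generate_profiles: need n_cells >= 1, n_genes >= 2, n_omics >= 1",
         call. = FALSE)
  }
  if (!is.null(truth) && truth$n_genes != n_genes) {
    stop("generate_profiles: truth was planted for a different gene panel",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  cell_ids <- sprintf("cell%03d", seq_len(n_cells))
  gene_mu <- stats::rnorm(n_genes)
  gene_sd <- stats::runif(n_genes, 0.5, 1.5)

  z <- matrix(stats::rnorm(n_cells * n_genes), n_cells, n_genes)
  if (!is.null(truth) && length(truth$causal_genes)) {
    rho <- truth$confound_rho
    ci <- truth$causal_genes
    di <- truth$decoy_genes
    z[, di] <- rho * z[, ci, drop = FALSE] +
      sqrt(1 - rho^2) * z[, di, drop = FALSE]
  }

  layer_rho <- 0.7
  layers <- vector("list", n_omics)
  layers[[1]] <- z
  if (n_omics > 1) {
    for (l in 2:n_omics) {
      e <- matrix(stats::rnorm(n_cells * n_genes), n_cells, n_genes)
      layers[[l]] <- layer_rho * z + sqrt(1 - layer_rho^2) * e
    }
  }

  cells <- lapply(seq_len(n_cells), function(i) {
    m <- do.call(rbind, lapply(layers, function(L) gene_mu + gene_sd * L[i, ]))
    dimnames(m) <- list(paste0("omics", seq_len(n_omics)), gene_ids)
    m
  })
  names(cells) <- cell_ids
  structure(
    list(cells = cells, gene_ids = gene_ids, cell_ids = cell_ids,
         gene_mu = gene_mu, gene_sd = gene_sd, n_omics = n_omics,
         seed = as.integer(seed)),
    class = "cads_profiles"
  )
}

#' @export
print.cads_profiles <- function(x, ...) {
  cat(sprintf("<cads_profiles> %d cell lines x %d genes x %d omics layer(s)\n",
              length(x$cell_ids), length(x$gene_ids), x$n_omics))
  invisible(x)
}

#' Omics-averaged expression matrix
#'
#' Collapses each cell line's `F x N` profile to its per-gene mean across
#' omics layers, returning a cells x genes matrix. This is the per-gene
#' value the synthetic label model and the MLP fusion backbone consume.
#'
#' @param profiles a `cads_profiles` object.
#' @return numeric matrix (`n_cells x n_genes`) with dimnames.
#' @export
profile_means <- function(profiles) {
  stopifnot(inherits(profiles, "cads_profiles"))
  out <- t(vapply(profiles$cells, colMeans, numeric(length(profiles$gene_ids))))
  dimnames(out) <- list(profiles$cell_ids, profiles$gene_ids)
  out
}

#' Plant a ground-truth causal structure
#'
#' Samples the causal gene set, per-gene effect weights, decoy pairings and
#' per-drug latent vectors that define a synthetic synergy generative model.
#' Each causal gene is paired with one decoy ("trivial but confounded") gene
#' whose expression will be generated with correlation `confound_rho` to it.
#' Effect weights are drawn from +/- Uniform(0.5, 1.5), so every causal gene
#' has a non-vanishing effect.
#'
#' @param n_genes gene panel size.
#' @param k_causal number of causal genes; must not exceed `n_genes / 2`
#'   so that each causal gene can receive a distinct decoy partner.
#' @param n_drugs number of drugs with latent interaction vectors.
#' @param d_lat latent dimension of the drug vectors (>= 1).
#' @param noise_sd standard deviation of the additive label noise (>= 0).
#' @param confound_rho correlation in `[0, 1)` between each decoy gene and
#'   its causal partner.
#' @param seed integer seed.
#' @return A `cads_truth` object.
#' @export
plant_truth <- function(n_genes, k_causal, n_drugs, d_lat = 4L,
                        noise_sd = 0.3, confound_rho = 0.6, seed = 1L) {
  if (k_causal < 0 || k_causal > n_genes / 2) {
    stop("plant_truth: need 0 <= k_causal <= n_genes / 2", call. = FALSE)
  }
  if (d_lat < 1) stop("plant_truth: d_lat must be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("plant_truth: noise_sd must be >= 0", call. = FALSE)
  if (confound_rho < 0 || confound_rho >= 1) {
    stop("plant_truth: confound_rho must be in [0, 1)", call. = FALSE)
  }
  set.seed(as.integer(seed))
  causal <- sort(sample.int(n_genes, k_causal))
  decoys <- if (k_causal > 0) {
    sample(setdiff(seq_len(n_genes), causal), k_causal)
  } else integer(0)
  effects <- if (k_causal > 0) {
    sample(c(-1, 1), k_causal, replace = TRUE) * stats::runif(k_causal, 0.5, 1.5)
  } else numeric(0)
  latents <- matrix(stats::rnorm(n_drugs * d_lat), n_drugs, d_lat)
  rownames(latents) <- sprintf("drug%03d", seq_len(n_drugs))
  structure(
    list(n_genes = as.integer(n_genes), causal_genes = causal,
         decoy_genes = decoys, gene_effects = effects,
         drug_latents = latents, d_lat = as.integer(d_lat),
         noise_sd = noise_sd, confound_rho = confound_rho,
         seed = as.integer(seed)),
    class = "cads_truth"
  )
}

#' @export
print.cads_truth <- function(x, ...) {
  cat(sprintf(paste0("<cads_truth> %d causal of %d genes, %d drugs ",
                     "(d_lat=%d), noise_sd=%.3g, confound_rho=%.3g\n"),
              length(x$causal_genes), x$n_genes, nrow(x$drug_latents),
              x$d_lat, x$noise_sd, x$confound_rho))
  invisible(x)
}

# Valence-safe synthetic SMILES: simple chains of C/N/O/S with optional
# carbon-hosted branches and an optional all-carbon ring. Every emitted
# string parses with a standard cheminformatics toolkit.
random_smiles <- function() {
  n <- sample(3:7, 1L)
  internal <- c("C", "C", "C", "N", "O", "S")
  terminal <- c("C", "C", "N", "O")
  atoms <- c(sample(terminal, 1L),
             sample(internal, max(n - 2L, 0L), replace = TRUE),
             sample(terminal, 1L))[seq_len(n)]
  if (n >= 5 && stats::runif(1) < 0.3) {
    return(paste0("C1", paste(rep("C", n - 2L), collapse = ""), "C1"))
  }
  body <- atoms
  if (n >= 4 && stats::runif(1) < 0.6) {
    pos <- sample(2:(n - 1L), 1L)
    body[pos] <- paste0("C(", sample(c("C", "O", "N", "Cl", "Br", "F"), 1L), ")")
  }
  paste(body, collapse = "")
}

#' Generate a synthetic drug table
#'
#' Produces `n_drugs` records with distinct, chemically valid miniature
#' SMILES strings, so that both the sequence and the molecular-graph drug
#' pathways can run without an external compound library.
#'
#' @param n_drugs number of drugs.
#' @param seed integer seed.
#' @return tibble with columns `drug_id`, `smiles`.
#' @export
generate_drugs <- function(n_drugs, seed = 1L) {
  if (n_drugs < 1) stop("generate_drugs: n_drugs must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  smiles <- character(0)
  guard <- 0L
  while (length(smiles) < n_drugs) {
    cand <- random_smiles()
    if (!cand %in% smiles) smiles <- c(smiles, cand)
    guard <- guard + 1L
    if (guard > 10000L) stop("generate_drugs: could not find distinct SMILES")
  }
  tibble::tibble(drug_id = sprintf("drug%03d", seq_len(n_drugs)),
                 smiles = smiles)
}

score_type_levels <- c("loewe", "hsa", "bliss", "zip", "s_score")

#' Generate synergy labels from planted causal genes
#'
#' Samples drug pairs and cell lines uniformly and produces labels from the
#' generative model `y_raw = s(A, B) * sum_g w_g * x_{c,g} + eps`, where the
#' sum runs over planted causal genes only, `x_{c,g}` is the omics-averaged
#' expression, `s(A, B)` is the dot product of the two drugs' latent vectors
#' (symmetric in A and B by construction) and `eps ~ N(0, noise_sd^2)`.
#' Labels are standardized to zero mean and unit variance; the transform is
#' stored in the `"standardize"` attribute and the pre-standardization
#' values in column `y_raw`.
#'
#' @param profiles a `cads_profiles` object.
#' @param drugs drug table (`drug_id`, `smiles`), rows aligned with
#'   `truth$drug_latents`.
#' @param truth a `cads_truth` object planted for the same gene panel.
#' @param n_examples number of synergy examples (>= 1).
#' @param seed integer seed.
#' @return tibble with columns `drug_a`, `drug_b`, `cell_id`, `score_type`,
#'   `y` (standardized) and `y_raw`, plus a `"standardize"` attribute
#'   `list(mean, sd)`.
#' @export
generate_labels <- function(profiles, drugs, truth, n_examples, seed = 1L) {
  stopifnot(inherits(profiles, "cads_profiles"), inherits(truth, "cads_truth"))
  if (n_examples < 1) {
    stop("generate_labels: n_examples must be >= 1", call. = FALSE)
  }
  if (truth$n_genes != length(profiles$gene_ids)) {
    stop("generate_labels: truth and profiles disagree on the gene panel",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  n_drugs <- nrow(truth$drug_latents)
  xbar <- profile_means(profiles)
  t_cell <- if (length(truth$causal_genes)) {
    as.numeric(xbar[, truth$causal_genes, drop = FALSE] %*% truth$gene_effects)
  } else rep(0, nrow(xbar))

  a <- sample.int(n_drugs, n_examples, replace = TRUE)
  b_off <- sample.int(n_drugs - 1L, n_examples, replace = TRUE)
  b <- 1L + (a - 1L + b_off) %% n_drugs  # uniform over drugs != a
  cell <- sample.int(length(profiles$cell_ids), n_examples, replace = TRUE)
  s_ab <- unname(rowSums(truth$drug_latents[a, , drop = FALSE] *
                           truth$drug_latents[b, , drop = FALSE]))
  y_raw <- s_ab * t_cell[cell] + stats::rnorm(n_examples, 0, truth$noise_sd)
  m <- mean(y_raw)
  s <- stats::sd(y_raw)
  if (!is.finite(s) || s == 0) s <- 1
  out <- tibble::tibble(
    drug_a = drugs$drug_id[a],
    drug_b = drugs$drug_id[b],
    cell_id = profiles$cell_ids[cell],
    score_type = sample(score_type_levels, n_examples, replace = TRUE),
    y = (y_raw - m) / s,
    y_raw = y_raw
  )
  attr(out, "standardize") <- list(mean = m, sd = s)
  out
}

#' Simulate a complete synthetic synergy dataset
#'
#' Convenience wrapper tying [plant_truth()], [generate_profiles()],
#' [generate_drugs()] and [generate_labels()] together. The defaults are the
#' package's reference benchmark: 60 cell lines, a 300-gene panel with 15
#' planted causal genes each paired with a confounded decoy
#' (`confound_rho = 0.6`), 30 drugs and 6000 examples at `noise_sd = 0.3`.
#' All randomness derives from the single root `seed`.
#'
#' @param n_cells,n_genes,n_omics,k_causal,n_drugs,d_lat,noise_sd,confound_rho,n_examples
#'   generator dimensions; see the individual generator functions.
#' @param seed root integer seed; sub-seeds for each component are derived
#'   from it deterministically.
#' @return A `cads_dataset`: list with `profiles`, `drugs`, `examples`,
#'   `truth` and `standardize`.
#' @export
simulate_synergy <- function(n_cells = 60L, n_genes = 300L, k_causal = 15L,
                             n_drugs = 30L, n_omics = 1L, d_lat = 4L,
                             noise_sd = 0.3, confound_rho = 0.6,
                             n_examples = 6000L, seed = 1L) {
  seed <- as.integer(seed)
  sub <- derive_seeds(seed, 4L)
  truth <- plant_truth(n_genes, k_causal, n_drugs, d_lat = d_lat,
                       noise_sd = noise_sd, confound_rho = confound_rho,
                       seed = sub[1])
  profiles <- generate_profiles(n_cells, n_genes, n_omics = n_omics,
                                seed = sub[2], truth = truth)
  drugs <- generate_drugs(n_drugs, seed = sub[3])
  examples <- generate_labels(profiles, drugs, truth, n_examples,
                              seed = sub[4])
  structure(
    list(profiles = profiles, drugs = drugs, examples = examples,
         truth = truth, standardize = attr(examples, "standardize"),
         seed = seed),
    class = "cads_dataset"
  )
}

#' @export
print.cads_dataset <- function(x, ...) {
  cat(sprintf(paste0("<cads_dataset> %d examples | %d cells x %d genes | ",
                     "%d drugs | %d planted causal genes (seed %d)\n"),
              nrow(x$examples), length(x$profiles$cell_ids),
              length(x$profiles$gene_ids), nrow(x$drugs),
              length(x$truth$causal_genes), x$seed))
  invisible(x)
}

# Derive k child seeds from one root seed, staying inside 32-bit range.
derive_seeds <- function(seed, k) {
  (as.integer(seed) * 7919L + 104729L * seq_len(k)) %% 2147483629L
}
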