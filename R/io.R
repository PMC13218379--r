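canonical_synonyms <- list(
  drug_a = c("drug_a", "drug_row", "druga", "drug1"),
  drug_b = c("drug_b", "drug_col", "drugb", "drug2"),
  cell_id = c("cell_id", "cell_line", "cell", "cell_line_name"),
  score_type = c("score_type", "synergy_type"),
  y = c("y", "synergy", "score", "synergy_score")
)

sniff_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a synergy table
#'
#' Reads a DrugComb-style CSV/TSV of synergy measurements. Canonical
#' columns are `drug_a`, `drug_b`, `cell_id`, `score_type`, `y`; common
#' synonyms (`drug_row`, `cell_line`, ...) are accepted. Alternatively the
#' file may carry one column per synergy model (`loewe`, `hsa`, `bliss`,
#' `zip`, `s_score`), in which case `score_type` selects which becomes
#' `y`. Duplicate `(drug_a, drug_b, cell_id, score_type)` rows are flagged
#' with a warning; drug-pair order is preserved as given.
#'
#' @param path file path.
#' @param score_type synergy model to extract when the file has per-model
#'   columns.
#' @return tibble with the canonical columns.
#' @export
read_synergy_table <- function(path, score_type = NULL) {
  delim <- sniff_delim(path)
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  names(raw) <- tolower(names(raw))
  out <- tibble::tibble(.rows = nrow(raw))
  for (canon in c("drug_a", "drug_b", "cell_id")) {
    hit <- intersect(canonical_synonyms[[canon]], names(raw))
    if (!length(hit)) {
      stop(sprintf("read_synergy_table: missing required column '%s' (or a synonym)",
                   canon), call. = FALSE)
    }
    out[[canon]] <- raw[[hit[1]]]
  }
  score_cols <- intersect(score_type_levels, names(raw))
  y_hit <- intersect(canonical_synonyms$y, names(raw))
  if (!is.null(score_type) && score_type %in% score_cols) {
    out$score_type <- score_type
    ycol <- score_type
  } else if (length(y_hit)) {
    st_hit <- intersect(canonical_synonyms$score_type, names(raw))
    out$score_type <- if (length(st_hit)) raw[[st_hit[1]]]
                      else if (!is.null(score_type)) score_type
                      else NA_character_
    ycol <- y_hit[1]
  } else if (length(score_cols)) {
    sel <- if (!is.null(score_type)) score_type else score_cols[1]
    if (!sel %in% score_cols) {
      stop(sprintf("read_synergy_table: no column for score_type '%s'", sel),
           call. = FALSE)
    }
    out$score_type <- sel
    ycol <- sel
  } else {
    stop("read_synergy_table: missing required column 'y' (or a synergy score column)",
         call. = FALSE)
  }
  yv <- suppressWarnings(as.numeric(raw[[ycol]]))
  bad <- which(!is.finite(yv))
  if (length(bad)) {
    stop(sprintf("read_synergy_table: non-numeric synergy value in data row %d (file line %d)",
                 bad[1], bad[1] + 1L), call. = FALSE)
  }
  out$y <- yv
  dup <- duplicated(out[, c("drug_a", "drug_b", "cell_id", "score_type")])
  if (any(dup)) {
    warning(sprintf("read_synergy_table: %d duplicate (drug_a, drug_b, cell, score_type) rows",
                    sum(dup)))
  }
  out$duplicate <- dup
  out
}

#' Read cell-line expression matrices
#'
#' Each file holds one omics layer as a TSV with `cell_id` in the first
#' column and gene identifiers as remaining column names. The first file
#' fixes the gene order; later layers are reordered to match and must
#' contain exactly the same genes and cells. Missing values are an error.
#'
#' @param paths character vector of layer file paths (in layer order).
#' @return a `cads_profiles` object (`F x N` matrix per cell).
#' @export
read_expression_matrix <- function(paths) {
  stopifnot(length(paths) >= 1)
  layers <- vector("list", length(paths))
  gene_ids <- NULL
  cell_ids <- NULL
  for (l in seq_along(paths)) {
    d <- readr::read_tsv(paths[l], show_col_types = FALSE, progress = FALSE)
    if (names(d)[1] != "cell_id") names(d)[1] <- "cell_id"
    genes <- names(d)[-1]
    if (l == 1L) {
      gene_ids <- genes
      cell_ids <- d$cell_id
    } else {
      if (!setequal(genes, gene_ids)) {
        missing <- setdiff(gene_ids, genes)
        stop(sprintf("read_expression_matrix: layer %d is missing gene(s): %s",
                     l, paste(utils::head(missing, 5L), collapse = ", ")),
             call. = FALSE)
      }
      d <- d[match(cell_ids, d$cell_id), c("cell_id", gene_ids)]
      if (anyNA(d$cell_id)) {
        stop(sprintf("read_expression_matrix: layer %d is missing cell lines", l),
             call. = FALSE)
      }
    }
    m <- as.matrix(d[, -1, drop = FALSE])
    if (any(!is.finite(m))) {
      bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
      stop(sprintf("read_expression_matrix: non-finite value in layer %d, cell '%s', gene '%s'",
                   l, d$cell_id[bad[1]], colnames(m)[bad[2]]), call. = FALSE)
    }
    layers[[l]] <- m
  }
  cells <- lapply(seq_along(cell_ids), function(i) {
    mat <- do.call(rbind, lapply(layers, function(L) L[i, ]))
    dimnames(mat) <- list(paste0("omics", seq_along(layers)), gene_ids)
    mat
  })
  names(cells) <- cell_ids
  structure(
    list(cells = cells, gene_ids = gene_ids, cell_ids = cell_ids,
         gene_mu = NULL, gene_sd = NULL, n_omics = length(paths),
         seed = NA_integer_),
    class = "cads_profiles"
  )
}

#' Write a synthetic dataset to disk
#'
#' Writes `profiles_layer<k>.tsv` (one per omics layer, cells x genes),
#' `drugs.tsv`, `examples.csv`, `truth.json` and a `manifest.json` that
#' records the file paths, the gene-panel hash, the label standardization
#' and the root seed — enough to regenerate any number in any downstream
#' report.
#'
#' @param dataset a `cads_dataset`.
#' @param dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "cads_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prof <- dataset$profiles
  n_omics <- prof$n_omics
  prof_paths <- character(n_omics)
  for (l in seq_len(n_omics)) {
    m <- t(vapply(prof$cells, function(C) C[l, ], numeric(length(prof$gene_ids))))
    d <- tibble::as_tibble(m)
    names(d) <- prof$gene_ids
    d <- dplyr::bind_cols(tibble::tibble(cell_id = prof$cell_ids), d)
    prof_paths[l] <- file.path(dir, sprintf("profiles_layer%d.tsv", l))
    readr::write_tsv(d, prof_paths[l])
  }
  drugs_path <- file.path(dir, "drugs.tsv")
  readr::write_tsv(dataset$drugs, drugs_path)
  ex_path <- file.path(dir, "examples.csv")
  readr::write_csv(dataset$examples[, c("drug_a", "drug_b", "cell_id",
                                        "score_type", "y")], ex_path)
  truth_path <- file.path(dir, "truth.json")
  tr <- dataset$truth
  jsonlite::write_json(
    list(n_genes = tr$n_genes, causal_genes = tr$causal_genes,
         decoy_genes = tr$decoy_genes, gene_effects = tr$gene_effects,
         drug_latents = tr$drug_latents, d_lat = tr$d_lat,
         noise_sd = tr$noise_sd, confound_rho = tr$confound_rho,
         seed = tr$seed),
    truth_path, digits = NA, auto_unbox = TRUE)
  manifest <- list(
    profiles = basename(prof_paths), drugs = basename(drugs_path),
    examples = basename(ex_path), truth = basename(truth_path),
    gene_panel_hash = rlang::hash(prof$gene_ids),
    standardize = dataset$standardize,
    seed = dataset$seed
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(manifest)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir dataset directory containing a `manifest.json`.
#' @return a `cads_dataset`.
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  profiles <- read_expression_matrix(file.path(dir, manifest$profiles))
  if (!identical(rlang::hash(profiles$gene_ids), manifest$gene_panel_hash)) {
    stop("read_dataset: gene panel hash mismatch", call. = FALSE)
  }
  drugs <- readr::read_tsv(file.path(dir, manifest$drugs),
                           show_col_types = FALSE, progress = FALSE)
  examples <- read_synergy_table(file.path(dir, manifest$examples))
  examples$duplicate <- NULL
  tr <- jsonlite::read_json(file.path(dir, manifest$truth),
                            simplifyVector = TRUE)
  truth <- structure(
    list(n_genes = as.integer(tr$n_genes),
         causal_genes = as.integer(tr$causal_genes),
         decoy_genes = as.integer(tr$decoy_genes),
         gene_effects = as.numeric(tr$gene_effects),
         drug_latents = if (is.matrix(tr$drug_latents)) tr$drug_latents
                        else matrix(unlist(tr$drug_latents),
                                    nrow = length(tr$drug_latents),
                                    byrow = TRUE),
         d_lat = as.integer(tr$d_lat), noise_sd = tr$noise_sd,
         confound_rho = tr$confound_rho, seed = as.integer(tr$seed)),
    class = "cads_truth"
  )
  structure(
    list(profiles = profiles, drugs = drugs, examples = examples,
         truth = truth, standardize = manifest$standardize,
         seed = as.integer(manifest$seed)),
    class = "cads_dataset"
  )
}

#' Export a ranked gene list
#'
#' Two-column, headerless TSV (gene id, score) sorted by decreasing score —
#' the `.rnk` layout consumed by external enrichment tools.
#'
#' @param stats a `cads_score_stats` tibble (or any tibble with `gene_id`
#'   and a score column).
#' @param path output path.
#' @param score column to rank by.
#' @return the path, invisibly.
#' @export
write_ranked_genes <- function(stats, path, score = "mean") {
  d <- tibble::tibble(gene_id = stats$gene_id, score = stats[[score]])
  d <- d[order(-d$score), ]
  readr::write_tsv(d, path, col_names = FALSE)
  invisible(path)
}
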