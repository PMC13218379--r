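#' Regression metrics
#'
#' Standard regression metrics: `mae = mean |e|`, `rmse = sqrt(mean e^2)`,
#' `r2 = 1 - SSE/SST` and the Pearson correlation. When `y_true` has zero
#' variance, `r2` and `pcc` are undefined; the report flags this in the
#' `degenerate` column (and warns) instead of silently returning NaN.
#'
#' @param y_true,y_pred numeric vectors of equal length (>= 2), finite.
#' @return one-row tibble with `mae`, `rmse`, `r2`, `pcc`, `n`,
#'   `degenerate`.
#' @export
regression_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 2) {
    stop("regression_metrics: inputs must have equal length >= 2",
         call. = FALSE)
  }
  if (!all(is.finite(y_true)) || !all(is.finite(y_pred))) {
    stop("regression_metrics: inputs must be finite", call. = FALSE)
  }
  e <- y_pred - y_true
  sst <- sum((y_true - mean(y_true))^2)
  degenerate <- sst == 0 || stats::sd(y_pred) == 0
  if (degenerate) {
    warning("regression_metrics: zero variance; r2/pcc flagged as undefined")
  }
  tibble::tibble(
    mae = mean(abs(e)),
    rmse = sqrt(mean(e^2)),
    r2 = if (sst == 0) NA_real_ else 1 - sum(e^2) / sst,
    pcc = if (degenerate) NA_real_ else stats::cor(y_true, y_pred),
    n = length(y_true),
    degenerate = degenerate
  )
}

#' Zero-masking ablation of top-ranked genes
#'
#' Ranks genes by their mean attention weight in the requested branch
#' (mean `alpha_c` across cells for the causal branch, mean `alpha_t` for
#' the trivial branch; ties broken by gene index), zeroes the top `k`
#' genes' values throughout the profiles, and recomputes the held-out
#' metrics. If the model truly relies on causal genes, ablating the top
#' causal genes should degrade performance more than ablating the top
#' trivial genes.
#'
#' @param fit a `cads_fit`.
#' @param branch `"causal"` or `"trivial"`.
#' @param k number of genes to zero (`0 <= k <= N`).
#' @param examples evaluation examples; defaults to the fit's test split.
#' @return tibble with `branch`, `k`, `metric`, `before`, `after` and
#'   `loss` (degradation: increase for error metrics, decrease for
#'   r2/pcc).
#' @export
ablate_top_genes <- function(fit, branch = c("causal", "trivial"), k,
                             examples = NULL) {
  branch <- match.arg(branch)
  stopifnot(inherits(fit, "cads_fit"))
  if (k < 0 || k > fit$n_genes) {
    stop("ablate_top_genes: k must satisfy 0 <= k <= N", call. = FALSE)
  }
  if (is.null(examples)) examples <- fit$examples[fit$split$test, , drop = FALSE]
  y_std <- standardize_labels(examples$y, fit$standardize)

  score <- colMeans(causal_mask_matrix(fit))
  if (branch == "trivial") score <- 1 - score
  top <- order(-score, seq_along(score))[seq_len(k)]

  before <- regression_metrics(y_std, predict(fit, examples)$y_c)
  after <- if (k == 0) before else {
    regression_metrics(y_std, predict(fit, examples, zero_genes = top)$y_c)
  }
  metrics <- c("mae", "rmse", "r2", "pcc")
  sign_flip <- c(mae = 1, rmse = 1, r2 = -1, pcc = -1)
  b <- as.numeric(unlist(before[1, metrics]))
  a <- as.numeric(unlist(after[1, metrics]))
  tibble::tibble(
    branch = branch, k = as.integer(k), metric = metrics,
    before = b, after = a,
    loss = unname(sign_flip[metrics]) * (a - b)
  )
}

#' Least-squares line fit for few-shot curves
#'
#' Exact least-squares fit of `y = k x + b`.
#'
#' @param x,y numeric vectors (length >= 2 with distinct `x`).
#' @return list with slope `k` and intercept `b`.
#' @export
fewshot_fit_line <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  fit <- stats::lm.fit(cbind(1, x), y)
  list(k = unname(fit$coefficients[2]), b = unname(fit$coefficients[1]))
}

#' Few-shot robustness curves and slopes
#'
#' Trains the model on subsampled fractions of the training split (the
#' validation and test splits stay fixed across fractions), evaluates each
#' on the common test split, and fits a least-squares line
#' `metric = k * fraction + b` per model and seed. A smaller `|k|` for the
#' dual-branch model than for the single-branch ablation indicates
#' robustness to data scarcity.
#'
#' @param dataset a `cads_dataset` (or compatible list).
#' @param fractions training fractions in `(0, 1]`.
#' @param config a [cads_config()] used for every run (seed overridden per
#'   run).
#' @param seeds integer vector of replicate seeds.
#' @param models subset of `c("cads", "single_branch")`.
#' @return a `cads_fewshot` list with `points` (per-run metrics) and
#'   `slopes` (per model/seed/metric line fits).
#' @export
fewshot_curve <- function(dataset, fractions = c(0.3, 0.5, 0.7),
                          config = cads_config(), seeds = 1L,
                          models = c("cads", "single_branch")) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  models <- match.arg(models, several.ok = TRUE)
  base_split <- split_examples(dataset$examples, dataset$profiles$cell_ids,
                               config)
  points <- list()
  for (seed in seeds) {
    for (fr in fractions) {
      n_sub <- floor(fr * length(base_split$train))
      if (n_sub < 1) {
        stop(sprintf("fewshot_curve: fraction %.2f yields an empty training set", fr),
             call. = FALSE)
      }
      set.seed(as.integer(seed) * 131L + round(1000 * fr))
      sub <- sort(sample(base_split$train, n_sub))
      split <- list(train = sub, val = base_split$val, test = base_split$test)
      for (mdl in models) {
        cfg <- config
        cfg$seed <- as.integer(seed)
        cfg$dual_branch <- mdl == "cads"
        fit <- cads_train(dataset, cfg, split = split)
        te <- split$test
        y_std <- standardize_labels(dataset$examples$y[te], fit$standardize)
        pr <- predict(fit, dataset$examples[te, , drop = FALSE])
        met <- regression_metrics(y_std, pr$y_c)
        points[[length(points) + 1L]] <- tibble::tibble(
          model = mdl, seed = as.integer(seed), fraction = fr,
          mae = met$mae, rmse = met$rmse, r2 = met$r2, pcc = met$pcc
        )
      }
    }
  }
  points <- dplyr::bind_rows(points)
  slopes <- points |>
    tidyr::pivot_longer(cols = c("mae", "rmse", "r2", "pcc"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$model, .data$seed, .data$metric) |>
    dplyr::summarise(
      k = fewshot_fit_line(.data$fraction, .data$value)$k,
      b = fewshot_fit_line(.data$fraction, .data$value)$b,
      .groups = "drop"
    )
  structure(list(points = points, slopes = slopes, fractions = fractions),
            class = "cads_fewshot")
}

#' Pooled per-gene causal-score statistics
#'
#' Pools causal scores across cells and replicate runs and reports the
#' per-gene mean and standard deviation in a single streaming pass
#' (shifted sum / sum-of-squares accumulators, so the result matches a
#' two-pass computation to machine precision).
#'
#' @param scores a tibble with columns `cell_id`, `gene_id`, `alpha_c` and
#'   optionally `run`, or a list of such tibbles (one per replicate run).
#' @return a `cads_score_stats` tibble with `gene_id`, `mean`, `sd`, `n`.
#' @export
causal_score_stats <- function(scores) {
  if (is.list(scores) && !is.data.frame(scores)) {
    panels <- lapply(scores, function(s) sort(unique(s$gene_id)))
    if (length(unique(vapply(panels, paste, character(1), collapse = "|"))) != 1) {
      stop("causal_score_stats: gene panels differ across runs", call. = FALSE)
    }
    scores <- dplyr::bind_rows(scores, .id = "run")
  }
  stopifnot(all(c("gene_id", "alpha_c") %in% names(scores)))
  g <- factor(scores$gene_id)
  a <- scores$alpha_c
  if (any(a <= 0 | a >= 1)) {
    stop("causal_score_stats: alpha_c must lie strictly in (0, 1)",
         call. = FALSE)
  }
  # one pass: per-gene shifted accumulators
  gi <- as.integer(g)
  first_idx <- match(seq_along(levels(g)), gi)
  shift <- a[first_idx]
  d <- a - shift[gi]
  n <- as.numeric(rowsum(rep(1, length(a)), gi))
  s1 <- as.numeric(rowsum(d, gi))
  s2 <- as.numeric(rowsum(d * d, gi))
  v <- ifelse(n > 1, pmax(s2 - s1^2 / n, 0) / (n - 1), 0)
  out <- tibble::tibble(
    gene_id = levels(g),
    mean = shift + s1 / n,
    sd = sqrt(v),
    n = as.integer(n)
  )
  class(out) <- c("cads_score_stats", class(out))
  out
}

#' Mean within-class distance
#'
#' Average Euclidean distance of each embedded point to its class
#' centroid, averaged over all points. Larger values indicate more spread
#' within classes. Singleton classes contribute zero.
#'
#' @param x numeric matrix (points x dimensions).
#' @param labels class label per row.
#' @return single numeric value.
#' @export
within_class_distance <- function(x, labels) {
  x <- as.matrix(x)
  if (nrow(x) == 0) {
    stop("within_class_distance: empty input", call. = FALSE)
  }
  if (length(labels) != nrow(x)) {
    stop("within_class_distance: one label per row required", call. = FALSE)
  }
  f <- as.integer(factor(labels))
  centroids <- rowsum(x, f) / as.numeric(tabulate(f))
  d <- sqrt(rowSums((x - centroids[f, , drop = FALSE])^2))
  mean(d)
}

#' Integrated Gradients attribution
#'
#' Riemann approximation of the path integral of gradients from a baseline
#' to the input:
#' `IG_i = (x_i - b_i) * (1/steps) * sum_m d f / d x_i` evaluated at
#' `b + (m/steps) (x - b)`. Satisfies the completeness axiom
#' `sum(IG) ~= f(x) - f(b)` up to the discretization error, which shrinks
#' as `O(1/steps)`.
#'
#' For a `cads_fit`, `f` is the causal-branch output (standardized scale)
#' as a function of the raw `F x N` cell profile, so both the mask encoder
#' and the downstream network are attributed; the result is summed over
#' omics layers into per-gene scores. Alternatively `model` may be a
#' function taking an `ad` leaf node (matrix-valued) and returning a scalar
#' `ad` node, in which case attributions have the shape of `x`.
#'
#' @param model a `cads_fit` or an ad-graph function.
#' @param example for a `cads_fit`: one-row tibble with `drug_a`, `drug_b`,
#'   `cell_id`; otherwise the input matrix `x`.
#' @param baseline baseline input (defaults to all zeros).
#' @param steps number of Riemann steps (>= 1).
#' @return For a fit: tibble `gene_id`, `attribution` with attributes
#'   `f_x`, `f_baseline`, `completeness_gap`. For a function: a matrix of
#'   attributions with the same attributes.
#' @export
integrated_gradients <- function(model, example, baseline = NULL, steps = 64L) {
  if (steps < 1) stop("integrated_gradients: steps must be >= 1", call. = FALSE)
  if (inherits(model, "cads_fit")) {
    ig_fit(model, example, baseline, steps)
  } else if (is.function(model)) {
    ig_fn(model, example, baseline, steps)
  } else {
    stop("integrated_gradients: unsupported model type", call. = FALSE)
  }
}

ig_fn <- function(f, x, baseline, steps) {
  x <- as.matrix(x)
  b <- if (is.null(baseline)) x * 0 else as.matrix(baseline)
  stopifnot(identical(dim(x), dim(b)))
  grad_sum <- x * 0
  for (m in seq_len(steps)) {
    xm <- b + (m / steps) * (x - b)
    ad_tape_reset()
    leaf <- ad_leaf(xm)
    out <- f(leaf)
    ad_backward(out)
    grad_sum <- grad_sum + leaf$grad
    ad_tape_reset()
  }
  ig <- (x - b) * grad_sum / steps
  f_at <- function(z) {
    ad_tape_reset()
    v <- f(ad_leaf(z))$val[1]
    ad_tape_reset()
    v
  }
  fx <- f_at(x); fb <- f_at(b)
  attr(ig, "f_x") <- fx
  attr(ig, "f_baseline") <- fb
  attr(ig, "completeness_gap") <- abs(sum(ig) - (fx - fb))
  ig
}

# Causal-branch output as an ad function of one cell's raw F x N profile.
fit_output_fn <- function(fit, drug_a, drug_b) {
  ms <- fit_state(fit)
  leaves <- lapply(ms$params, ad_leaf)
  ai <- match(drug_a, ms$drug_ids)
  bi <- match(drug_b, ms$drug_ids)
  if (is.na(ai) || is.na(bi)) {
    stop("integrated_gradients: unknown drug id", call. = FALSE)
  }
  cfg <- ms$config
  mu_FN <- t(ms$gene_mu)            # F x N standardization constants
  inv_FN <- 1 / t(ms$gene_sd)
  function(Cleaf) {
    std_C <- ad_mul(ad_add(Cleaf, ad_leaf(-mu_FN)), ad_leaf(inv_FN))
    xbar_row <- ad_colmeans_row(std_C)                  # 1 x N
    mc_row <- mask_forward_ad(ad_transpose(std_C), leaves, 1L, ms$n_genes)
    gc <- ad_mul(xbar_row, mc_row)
    if (cfg$backbone == "xattn") {
      H <- lapply(c(ai, bi), function(d) seq_encode_ad(ms$tok_mat[d, ], ms$pe, leaves))
      xattn_branch_example_ad(ms, leaves, "c", ad_transpose(gc),
                              H[[1]], H[[2]], ms$pad_mat[ai, ], ms$pad_mat[bi, ])
    } else {
      Dmat <- if (cfg$backbone == "graph") drug_matrix_graph_ad(ms, leaves)
              else drug_matrix_seq_ad(ms, leaves)
      branch_mlp_ad(ad_cbind(ad_matmul(gc, leaves$c_P),
                             ad_rows(Dmat, ai), ad_rows(Dmat, bi)),
                    leaves, "c", ms$n_layers, cfg$hidden_act)
    }
  }
}

ig_fit <- function(fit, example, baseline, steps) {
  stopifnot(nrow(example) == 1L)
  ci <- match(example$cell_id, fit$cell_ids)
  if (is.na(ci)) stop("integrated_gradients: unknown cell id", call. = FALSE)
  rows <- (ci - 1L) * fit$n_genes + seq_len(fit$n_genes)
  C <- t(fit$X_all[rows, , drop = FALSE])               # F x N
  f <- fit_output_fn(fit, example$drug_a, example$drug_b)
  ig <- ig_fn(f, C, baseline, steps)
  out <- tibble::tibble(gene_id = fit$gene_ids,
                        attribution = as.numeric(colSums(ig)))
  attr(out, "f_x") <- attr(ig, "f_x")
  attr(out, "f_baseline") <- attr(ig, "f_baseline")
  attr(out, "completeness_gap") <- attr(ig, "completeness_gap")
  out
}
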