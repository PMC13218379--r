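# Minimal reverse-mode automatic differentiation over dense matrices.
#
# Every differentiable quantity is an `ad_node`: an environment holding the
# forward value (`val`, always a base matrix), an accumulated gradient
# (`grad`), its parent nodes and a backward function. Non-leaf nodes are
# appended to a tape in creation order; ad_backward() walks the tape in
# reverse, which is a valid reverse-topological order because parents are
# always created before children. The engine is deliberately small: it
# supports exactly the operations the dual-branch model, the attention
# backbones and Integrated Gradients need.

ad_env <- new.env(parent = emptyenv())
ad_env$tape <- list()
ad_env$n <- 0L

ad_tape_reset <- function() {
  ad_env$tape <- vector("list", 512L)
  ad_env$n <- 0L
  invisible(NULL)
}

ad_as_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

ad_node <- function(val, parents = list(), backfn = NULL) {
  node <- new.env(parent = emptyenv())
  node$val <- val
  node$grad <- NULL
  node$parents <- parents
  node$backfn <- backfn
  class(node) <- "ad_node"
  if (!is.null(backfn)) {
    ad_env$n <- ad_env$n + 1L
    if (ad_env$n > length(ad_env$tape)) {
      length(ad_env$tape) <- 2L * length(ad_env$tape)
    }
    ad_env$tape[[ad_env$n]] <- node
  }
  node
}

#' @noRd
ad_leaf <- function(val) ad_node(ad_as_matrix(val))

is_ad <- function(x) inherits(x, "ad_node")

ad_wrap <- function(x) if (is_ad(x)) x else ad_leaf(x)

ad_value <- function(x) if (is_ad(x)) x$val else ad_as_matrix(x)

# Accumulate gradients from the loss node back to every reachable node.
ad_backward <- function(loss) {
  stopifnot(is_ad(loss), length(loss$val) == 1L)
  loss$grad <- matrix(1, 1L, 1L)
  if (ad_env$n == 0L) return(invisible(NULL))
  for (i in seq.int(ad_env$n, 1L)) {
    node <- ad_env$tape[[i]]
    if (is.null(node$grad)) next
    gs <- node$backfn(node, node$grad)
    ps <- node$parents
    for (j in seq_along(ps)) {
      gj <- gs[[j]]
      if (is.null(gj)) next
      p <- ps[[j]]
      p$grad <- if (is.null(p$grad)) gj else p$grad + gj
    }
  }
  invisible(NULL)
}

ad_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

## ---- operations ------------------------------------------------------------

ad_matmul <- function(a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  ad_node(a$val %*% b$val, list(a, b), function(node, g) {
    list(g %*% t(node$parents[[2]]$val), t(node$parents[[1]]$val) %*% g)
  })
}

# Addition with limited broadcasting: equal shapes, or `b` a 1 x d row vector
# broadcast over rows (bias), or `b` a 1 x 1 scalar.
ad_add <- function(a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  av <- a$val; bv <- b$val
  val <- if (identical(dim(av), dim(bv))) {
    av + bv
  } else if (nrow(bv) == 1L && ncol(bv) == ncol(av)) {
    av + rep(as.numeric(bv), each = nrow(av))
  } else if (length(bv) == 1L) {
    av + as.numeric(bv)
  } else stop("ad_add: incompatible shapes")
  ad_node(val, list(a, b), function(node, g) {
    bv <- node$parents[[2]]$val
    gb <- if (identical(dim(bv), dim(g))) g
      else if (nrow(bv) == 1L && ncol(bv) == ncol(g)) matrix(colSums(g), 1L)
      else matrix(sum(g), 1L, 1L)
    list(g, gb)
  })
}

ad_sub <- function(a, b) ad_add(a, ad_scale(b, -1))

ad_scale <- function(a, k) {
  a <- ad_wrap(a)
  force(k)
  ad_node(a$val * k, list(a), function(node, g) list(g * k))
}

# Elementwise product of equal-shaped nodes.
ad_mul <- function(a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  stopifnot(identical(dim(a$val), dim(b$val)))
  ad_node(a$val * b$val, list(a, b), function(node, g) {
    list(g * node$parents[[2]]$val, g * node$parents[[1]]$val)
  })
}

# a (n x d) scaled per column by row vector r (1 x d).
ad_mul_rowvec <- function(a, r) {
  a <- ad_wrap(a); r <- ad_wrap(r)
  stopifnot(nrow(r$val) == 1L, ncol(r$val) == ncol(a$val))
  ad_node(a$val * rep(as.numeric(r$val), each = nrow(a$val)),
          list(a, r), function(node, g) {
    av <- node$parents[[1]]$val
    rv <- as.numeric(node$parents[[2]]$val)
    list(g * rep(rv, each = nrow(g)), matrix(colSums(g * av), 1L))
  })
}

ad_tanh <- function(a) {
  a <- ad_wrap(a)
  ad_node(tanh(a$val), list(a), function(node, g) list(g * (1 - node$val^2)))
}

ad_relu <- function(a) {
  a <- ad_wrap(a)
  ad_node(pmax(a$val, 0), list(a), function(node, g) list(g * (node$val > 0)))
}

ad_leaky_relu <- function(a, slope = 0.2) {
  a <- ad_wrap(a)
  force(slope)
  ad_node(ifelse(a$val > 0, a$val, slope * a$val), list(a), function(node, g) {
    list(g * ifelse(node$parents[[1]]$val > 0, 1, slope))
  })
}

ad_sigmoid <- function(a) {
  a <- ad_wrap(a)
  ad_node(1 / (1 + exp(-a$val)), list(a), function(node, g) {
    list(g * node$val * (1 - node$val))
  })
}

ad_square <- function(a) {
  a <- ad_wrap(a)
  ad_node(a$val^2, list(a), function(node, g) list(2 * g * node$parents[[1]]$val))
}

ad_sum <- function(a) {
  a <- ad_wrap(a)
  ad_node(matrix(sum(a$val), 1L, 1L), list(a), function(node, g) {
    p <- node$parents[[1]]$val
    list(matrix(as.numeric(g), nrow(p), ncol(p)))
  })
}

ad_mean <- function(a) {
  a <- ad_wrap(a)
  n <- length(a$val)
  ad_node(matrix(mean(a$val), 1L, 1L), list(a), function(node, g) {
    p <- node$parents[[1]]$val
    list(matrix(as.numeric(g) / length(p), nrow(p), ncol(p)))
  })
}

ad_transpose <- function(a) {
  a <- ad_wrap(a)
  ad_node(t(a$val), list(a), function(node, g) list(t(g)))
}

# Row gather with scatter-add backward; idx may repeat.
ad_rows <- function(a, idx) {
  a <- ad_wrap(a)
  idx <- as.integer(idx)
  force(idx)
  ad_node(a$val[idx, , drop = FALSE], list(a), function(node, g) {
    p <- node$parents[[1]]$val
    gb <- matrix(0, nrow(p), ncol(p))
    rs <- rowsum(g, group = idx, reorder = FALSE)
    gb[as.integer(rownames(rs)), ] <- gb[as.integer(rownames(rs)), , drop = FALSE] + rs
    list(gb)
  })
}

ad_cbind <- function(...) {
  nodes <- lapply(list(...), ad_wrap)
  widths <- vapply(nodes, function(n) ncol(n$val), integer(1))
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1L) + 1L)
  ad_node(do.call(cbind, lapply(nodes, function(n) n$val)), nodes, function(node, g) {
    lapply(seq_along(node$parents), function(j) g[, starts[j]:ends[j], drop = FALSE])
  })
}

# Softmax across each row; `add_mask` is an optional constant matrix added to
# the logits (use -Inf/-1e30 entries to exclude padded keys).
ad_softmax_rows <- function(a, add_mask = NULL) {
  a <- ad_wrap(a)
  z <- a$val
  if (!is.null(add_mask)) z <- z + add_mask
  rowmax <- if (ncol(z) == 2L) pmax(z[, 1L], z[, 2L])
            else z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
  z <- z - rowmax
  e <- exp(z)
  s <- e / rowSums(e)
  ad_node(s, list(a), function(node, g) {
    sv <- node$val
    list(sv * (g - rowSums(g * sv)))
  })
}

# Row-wise layer normalization with affine gain/bias (1 x d nodes).
# Normalization statistics are computed per row before the affine transform.
ad_layernorm_rows <- function(a, gamma, beta, eps = 1e-5) {
  a <- ad_wrap(a); gamma <- ad_wrap(gamma); beta <- ad_wrap(beta)
  x <- a$val
  d <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  n <- nrow(x)
  val <- xhat * rep(as.numeric(gamma$val), each = n) +
    rep(as.numeric(beta$val), each = n)
  node <- ad_node(val, list(a, gamma, beta), function(node, g) {
    xhat <- node$xhat; inv <- node$inv
    gv <- as.numeric(node$parents[[2]]$val)
    dxhat <- g * rep(gv, each = nrow(g))
    d <- ncol(g)
    dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
    list(dx, matrix(colSums(g * xhat), 1L), matrix(colSums(g), 1L))
  })
  node$xhat <- xhat
  node$inv <- inv
  node
}

# Weighted within-group row means: rows of `a` are pooled into `ngroups`
# output rows; w gives each row's weight (e.g. 0 for padding). Weights are
# normalized within each group at construction time.
ad_group_rowmeans <- function(a, group, ngroups, w = NULL) {
  a <- ad_wrap(a)
  group <- as.integer(group)
  if (is.null(w)) w <- rep(1, nrow(a$val))
  tot <- rowsum(w, group = group, reorder = FALSE)
  key <- as.integer(rownames(tot))
  denom <- numeric(ngroups)
  denom[key] <- tot
  cf <- w / pmax(denom[group], .Machine$double.eps)
  force(ngroups)
  val <- matrix(0, ngroups, ncol(a$val))
  rs <- rowsum(a$val * cf, group = group, reorder = FALSE)
  val[as.integer(rownames(rs)), ] <- rs
  ad_node(val, list(a), function(node, g) {
    list(g[group, , drop = FALSE] * cf)
  })
}

# Mean over rows, returned as a 1 x d row vector.
ad_colmeans_row <- function(a) {
  a <- ad_wrap(a)
  n <- nrow(a$val)
  ad_node(matrix(colMeans(a$val), 1L), list(a), function(node, g) {
    p <- node$parents[[1]]$val
    list(matrix(rep(as.numeric(g) / nrow(p), each = nrow(p)), nrow(p)))
  })
}

ad_rbind <- function(...) {
  nodes <- lapply(list(...), ad_wrap)
  heights <- vapply(nodes, function(n) nrow(n$val), integer(1))
  ends <- cumsum(heights)
  starts <- c(1L, head(ends, -1L) + 1L)
  ad_node(do.call(rbind, lapply(nodes, function(n) n$val)), nodes, function(node, g) {
    lapply(seq_along(node$parents), function(j) g[starts[j]:ends[j], , drop = FALSE])
  })
}

# a (n x d) scaled per row by column vector v (n x 1).
ad_mul_colvec <- function(a, v) {
  a <- ad_wrap(a); v <- ad_wrap(v)
  stopifnot(ncol(v$val) == 1L, nrow(v$val) == nrow(a$val))
  ad_node(a$val * as.numeric(v$val), list(a, v), function(node, g) {
    av <- node$parents[[1]]$val
    vv <- as.numeric(node$parents[[2]]$val)
    list(g * vv, matrix(rowSums(g * av), ncol = 1L))
  })
}

# Multiply a matrix node by a 1x1 scalar node.
ad_scale_node <- function(a, s) {
  a <- ad_wrap(a); s <- ad_wrap(s)
  stopifnot(length(s$val) == 1L)
  ad_node(a$val * as.numeric(s$val), list(a, s), function(node, g) {
    list(g * as.numeric(node$parents[[2]]$val),
         matrix(sum(g * node$parents[[1]]$val), 1L, 1L))
  })
}

# Column-major reshape preserving element order.
ad_reshape <- function(a, nrow, ncol) {
  a <- ad_wrap(a)
  stopifnot(length(a$val) == nrow * ncol)
  dn <- dim(a$val)
  force(dn)
  ad_node(matrix(as.numeric(a$val), nrow, ncol), list(a), function(node, g) {
    list(matrix(as.numeric(g), dn[1], dn[2]))
  })
}

## ---- parameters and optimizer ----------------------------------------------

# Glorot-uniform initialisation, the default for all dense maps here.
ad_init_dense <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

adam_state <- function(params) {
  lapply(params, function(p) list(m = p$val * 0, v = p$val * 0, t = 0L))
}

adam_step <- function(params, state, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = NULL) {
  for (nm in names(params)) {
    p <- params[[nm]]
    if (is.null(p$grad)) next
    g <- p$grad
    wd <- if (!is.null(weight_decay)) weight_decay[[nm]] else NULL
    if (!is.null(wd) && wd > 0) g <- g + wd * p$val
    st <- state[[nm]]
    st$t <- st$t + 1L
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    mh <- st$m / (1 - beta1^st$t)
    vh <- st$v / (1 - beta2^st$t)
    p$val <- p$val - lr * mh / (sqrt(vh) + eps)
    state[[nm]] <- st
  }
  state
}
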