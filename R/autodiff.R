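# Minimal reverse-mode automatic differentiation over dense matrices.
#
# The risk models (embeddings, GRU / attention / pooling encoders, prediction
# heads) are differentiated through a tape: every operation records its value
# and vector-Jacobian products against its node parents. Constants (plain
# matrices/vectors) may be mixed freely with nodes; only nodes accumulate
# gradients. All values are base-R numeric matrices, so the engine needs
# nothing beyond BLAS-backed %*% and elementwise primitives.
#
# Internal API (not exported): a forward pass builds nodes on an `ad_tape()`,
# `ad_backward()` sweeps the tape in reverse creation order, and leaf nodes
# created with `ad_leaf()` end up with `$grad` set. Nodes are bare
# environments with an `is_ad` marker rather than S3 objects: node creation
# dominates the cost of a training step, so the hot path avoids `inherits()`
# dispatch and keeps per-op allocations minimal.

# the tape is an intrusive linked list: each node keeps a `prev` pointer to
# the node created before it, so recording is O(1) with no list reallocation
ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$last <- NULL
  t
}

is_ad_node <- function(x) is.environment(x) && isTRUE(x$is_ad)

ad_val <- function(x) if (is.environment(x)) x$value else x

# parents: list of ad_node; vjps: parallel list of function(g) -> gradient
ad_node <- function(tape, value, parents, vjps) {
  n <- new.env(parent = emptyenv())
  n$is_ad <- TRUE
  n$value <- value
  n$parents <- parents
  n$vjps <- vjps
  n$prev <- tape$last
  tape$last <- n
  n
}

ad_leaf <- function(tape, value) ad_node(tape, value, list(), list())

# helper for two-argument ops: keep vjps only for node arguments
ad_node2 <- function(tape, value, a, b, vjp_a, vjp_b) {
  an <- is.environment(a)
  bn <- is.environment(b)
  if (an && bn) ad_node(tape, value, list(a, b), list(vjp_a, vjp_b))
  else if (an) ad_node(tape, value, list(a), list(vjp_a))
  else if (bn) ad_node(tape, value, list(b), list(vjp_b))
  else ad_node(tape, value, list(), list())
}

ad_node1 <- function(tape, value, a, vjp_a) {
  if (is.environment(a)) ad_node(tape, value, list(a), list(vjp_a))
  else ad_node(tape, value, list(), list())
}

ad_matmul <- function(tape, a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  ad_node2(tape, av %*% bv, a, b,
           function(g) tcrossprod(g, bv),
           function(g) crossprod(av, g))
}

ad_add <- function(tape, a, b) {
  ad_node2(tape, ad_val(a) + ad_val(b), a, b,
           function(g) g, function(g) g)
}

# add a 1 x k bias row to every row of an m x k matrix
ad_add_bias <- function(tape, a, bias) {
  av <- ad_val(a); bv <- ad_val(bias)
  ad_node2(tape, av + rep(as.numeric(bv), each = nrow(av)), a, bias,
           function(g) g,
           function(g) matrix(colSums(g), 1L))
}

# elementwise product of same-shape matrices
ad_emul <- function(tape, a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  ad_node2(tape, av * bv, a, b,
           function(g) g * bv, function(g) g * av)
}

# multiply each row i by constant scalar w[i] (length-nrow numeric vector)
ad_rowscale <- function(tape, a, w) {
  ad_node1(tape, ad_val(a) * w, a, function(g) g * w)
}

ad_scale <- function(tape, a, s) {
  ad_node1(tape, ad_val(a) * s, a, function(g) g * s)
}

ad_addconst <- function(tape, a, c) {
  ad_node1(tape, ad_val(a) + c, a, function(g) g)
}

ad_sigmoid <- function(tape, a) {
  v <- 1 / (1 + exp(-ad_val(a)))
  ad_node1(tape, v, a, function(g) g * v * (1 - v))
}

ad_tanh <- function(tape, a) {
  v <- tanh(ad_val(a))
  ad_node1(tape, v, a, function(g) g * (1 - v * v))
}

ad_softplus <- function(tape, a) {
  av <- ad_val(a)
  v <- ifelse(av > 30, av, log1p(exp(pmin(av, 30))))
  s <- 1 / (1 + exp(-av))
  ad_node1(tape, v, a, function(g) g * s)
}

ad_log <- function(tape, a) {
  av <- ad_val(a)
  ad_node1(tape, log(av), a, function(g) g / av)
}

# clamp with zero gradient outside [lo, hi]
ad_clamp <- function(tape, a, lo, hi) {
  av <- ad_val(a)
  inside <- (av > lo & av < hi) * 1
  ad_node1(tape, pmin(pmax(av, lo), hi), a, function(g) g * inside)
}

ad_sum <- function(tape, a) {
  av <- ad_val(a)
  d1 <- nrow(av); d2 <- ncol(av)
  ad_node1(tape, matrix(sum(av), 1L, 1L), a,
           function(g) matrix(as.numeric(g), d1, d2))
}

ad_rowsums <- function(tape, a) {
  av <- ad_val(a)
  k <- ncol(av); m <- nrow(av)
  ad_node1(tape, matrix(rowSums(av), ncol = 1L), a,
           function(g) matrix(g[, 1L], m, k))
}

ad_colmeans <- function(tape, a) {
  av <- ad_val(a)
  m <- nrow(av); k <- ncol(av)
  ad_node1(tape, matrix(colMeans(av), 1L), a,
           function(g) matrix(as.numeric(g), m, k, byrow = TRUE) / m)
}

ad_cbind <- function(tape, a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  ka <- ncol(av)
  ad_node2(tape, cbind(av, bv), a, b,
           function(g) g[, seq_len(ka), drop = FALSE],
           function(g) g[, -seq_len(ka), drop = FALSE])
}

ad_cols <- function(tape, a, idx) {
  av <- ad_val(a)
  nr <- nrow(av); nc <- ncol(av)
  ad_node1(tape, av[, idx, drop = FALSE], a, function(g) {
    z <- matrix(0, nr, nc)
    z[, idx] <- z[, idx] + g
    z
  })
}

ad_rbind2 <- function(tape, a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  na <- nrow(av)
  ad_node2(tape, rbind(av, bv), a, b,
           function(g) g[seq_len(na), , drop = FALSE],
           function(g) g[-seq_len(na), , drop = FALSE])
}

# row gather (embedding lookup); duplicate indices accumulate on backward
ad_rows <- function(tape, a, idx) {
  av <- ad_val(a)
  nr <- nrow(av); nc <- ncol(av)
  ad_node1(tape, av[idx, , drop = FALSE], a, function(g) {
    z <- matrix(0, nr, nc)
    acc <- rowsum(g, group = idx)
    z[as.integer(rownames(acc)), ] <- acc
    z
  })
}

# stack 1 x k row nodes into an m x k matrix
ad_stack_rows <- function(tape, rows) {
  value <- do.call(rbind, lapply(rows, ad_val))
  keep <- vapply(rows, is_ad_node, logical(1))
  parents <- rows[keep]
  which_rows <- which(keep)
  vjps <- lapply(which_rows, function(i) {
    force(i)
    function(g) g[i, , drop = FALSE]
  })
  ad_node(tape, value, parents, vjps)
}

ad_transpose <- function(tape, a) {
  ad_node1(tape, t(ad_val(a)), a, function(g) t(g))
}

# row-wise softmax
ad_softmax_rows <- function(tape, a) {
  av <- ad_val(a)
  z <- exp(av - apply(av, 1L, max))
  v <- z / rowSums(z)
  ad_node1(tape, v, a, function(g) {
    gs <- rowSums(g * v)
    v * (g - gs) # length-m gs recycles down columns => per-row subtraction
  })
}

# reverse sweep; `seed` is the upstream gradient of `node` (default all-ones,
# valid both for scalar losses and for per-row-independent vector outputs)
ad_backward <- function(tape, node, seed = NULL) {
  if (is.null(seed)) {
    seed <- matrix(1, nrow(node$value), ncol(node$value))
  }
  node$grad <- seed
  n <- tape$last
  while (!is.null(n)) {
    g <- n$grad
    if (!is.null(g)) {
      parents <- n$parents
      np <- length(parents)
      if (np > 0L) {
        vjps <- n$vjps
        for (j in seq_len(np)) {
          p <- parents[[j]]
          contrib <- vjps[[j]](g)
          pg <- p$grad
          p$grad <- if (is.null(pg)) contrib else pg + contrib
        }
        n$grad <- NULL # free intermediate gradients early
      }
    }
    n <- n$prev
  }
  invisible(NULL)
}

# elementwise maximum of two same-shape matrices; ties route gradient to a
ad_pairmax <- function(tape, a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  take_a <- (av >= bv) * 1
  ad_node2(tape, pmax(av, bv), a, b,
           function(g) g * take_a,
           function(g) g * (1 - take_a))
}
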