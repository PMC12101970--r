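# Minimal reverse-mode automatic differentiation on matrices.
#
# A tape records nodes in creation order; each node carries its value (a
# dense matrix; scalars are 1 x 1), an accumulated gradient, and a backward
# closure that pushes its gradient into its parents. The network layers
# below are composed from ~20 coarse matrix operations so all heavy work is
# BLAS. Gradient correctness is pinned by finite-difference tests.

ad_tape <- function(training = FALSE) {
  t <- new.env(parent = emptyenv())
  t$last <- NULL          # nodes form a linked list via $prev
  t$training <- training
  t
}

ad_node <- function(tape, value, backward = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$backward <- backward
  n$prev <- tape$last
  tape$last <- n
  class(n) <- "ad_node"
  n
}

is_node <- function(x) inherits(x, "ad_node")
ad_value <- function(x) if (is_node(x)) x$value else x

ad_acc <- function(node, g) {
  if (is_node(node)) {
    node$grad <- if (is.null(node$grad)) g else node$grad + g
  }
  invisible(NULL)
}

# run the backward pass from a scalar loss node; walks the tape in reverse
# creation order
ad_backward <- function(tape, loss) {
  loss$grad <- matrix(1, 1L, 1L)
  nd <- tape$last
  while (!is.null(nd)) {
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd$grad)
    nd <- nd$prev
  }
  invisible(NULL)
}

# ---- primitive operations ------------------------------------------------

ad_mm <- function(tape, a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  ad_node(tape, av %*% bv, function(g) {
    if (is_node(a)) ad_acc(a, tcrossprod(g, bv))
    if (is_node(b)) ad_acc(b, crossprod(av, g))
  })
}

# compressed-sparse-column form of a constant sparse operator, for the
# compiled multiply kernels
csc_operator <- function(A) {
  A <- methods::as(A, "CsparseMatrix")
  list(p = A@p, i = A@i, x = A@x, nrow = nrow(A))
}

# constant sparse operator (from csc_operator) times a node, with an
# optional fused ReLU
ad_spmm <- function(tape, A, b, relu = FALSE) {
  bv <- ad_value(b)
  v <- spmm_cpp(A$p, A$i, A$x, A$nrow, bv)
  if (relu) add_bias_relu_inplace(v, numeric(ncol(v)), TRUE)
  ad_node(tape, v, function(g) {
    if (relu) g <- relu_mask_mul(g, v)
    ad_acc(b, spmm_t_cpp(A$p, A$i, A$x, g))
  })
}

# fused linear layer x %*% W + bias (bias a 1 x k row), optionally ReLU'd;
# the bias add and activation mutate the freshly allocated product in place
ad_linear <- function(tape, x, W, bias, relu = FALSE) {
  xv <- ad_value(x); Wv <- ad_value(W)
  v <- xv %*% Wv
  add_bias_relu_inplace(v, as.vector(ad_value(bias)), relu)
  ad_node(tape, v, function(g) {
    if (relu) g <- relu_mask_mul(g, v)
    if (is_node(x)) ad_acc(x, tcrossprod(g, Wv))
    ad_acc(W, crossprod(xv, g))
    ad_acc(bias, matrix(colSums(g), 1L))
  })
}

ad_add <- function(tape, a, b) {
  ad_node(tape, ad_value(a) + ad_value(b), function(g) {
    ad_acc(a, g); ad_acc(b, g)
  })
}

ad_sub <- function(tape, a, b) {
  ad_node(tape, ad_value(a) - ad_value(b), function(g) {
    ad_acc(a, g); ad_acc(b, -g)
  })
}

ad_mul <- function(tape, a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  ad_node(tape, av * bv, function(g) {
    ad_acc(a, g * bv); ad_acc(b, g * av)
  })
}

ad_scale <- function(tape, a, s) {
  ad_node(tape, ad_value(a) * s, function(g) ad_acc(a, g * s))
}

# add a 1 x k bias row to every row of a
ad_addbias <- function(tape, a, bias) {
  av <- ad_value(a); bv <- ad_value(bias)
  ad_node(tape, sweep(av, 2L, as.vector(bv), "+"), function(g) {
    ad_acc(a, g)
    ad_acc(bias, matrix(colSums(g), 1L))
  })
}

ad_relu <- function(tape, a) {
  av <- ad_value(a)
  mask <- av > 0
  ad_node(tape, av * mask, function(g) ad_acc(a, g * mask))
}

ad_tanh <- function(tape, a) {
  v <- tanh(ad_value(a))
  ad_node(tape, v, function(g) ad_acc(a, g * (1 - v^2)))
}

ad_dropout <- function(tape, a, p) {
  if (!tape$training || p <= 0) return(a)
  av <- ad_value(a)
  keep <- matrix(stats::runif(length(av)) >= p, nrow(av), ncol(av)) / (1 - p)
  ad_node(tape, av * keep, function(g) ad_acc(a, g * keep))
}

ad_transpose <- function(tape, a) {
  ad_node(tape, t(ad_value(a)), function(g) ad_acc(a, t(g)))
}

ad_rbind2 <- function(tape, a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  na <- nrow(av)
  ad_node(tape, rbind(av, bv), function(g) {
    ad_acc(a, g[seq_len(na), , drop = FALSE])
    ad_acc(b, g[-seq_len(na), , drop = FALSE])
  })
}

ad_cbind2 <- function(tape, a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  ka <- ncol(av)
  ad_node(tape, cbind(av, bv), function(g) {
    ad_acc(a, g[, seq_len(ka), drop = FALSE])
    ad_acc(b, g[, -seq_len(ka), drop = FALSE])
  })
}

ad_cols <- function(tape, a, idx) {
  av <- ad_value(a)
  ad_node(tape, av[, idx, drop = FALSE], function(g) {
    full <- matrix(0, nrow(av), ncol(av))
    full[, idx] <- g
    ad_acc(a, full)
  })
}

ad_rows <- function(tape, a, idx) {
  av <- ad_value(a)
  ad_node(tape, av[idx, , drop = FALSE], function(g) {
    full <- matrix(0, nrow(av), ncol(av))
    full[idx, ] <- g
    ad_acc(a, full)
  })
}

# repeat a 1 x k row n times
ad_rowrep <- function(tape, a, n) {
  av <- ad_value(a)
  ad_node(tape, matrix(as.vector(av), n, ncol(av), byrow = TRUE),
          function(g) ad_acc(a, matrix(colSums(g), 1L)))
}

ad_mean_rows <- function(tape, a) {
  av <- ad_value(a)
  n <- nrow(av)
  ad_node(tape, matrix(colMeans(av), 1L), function(g) {
    ad_acc(a, matrix(as.vector(g), n, ncol(av), byrow = TRUE) / n)
  })
}

ad_softmax_rows <- function(tape, a) {
  av <- ad_value(a)
  m <- av - av[cbind(seq_len(nrow(av)), max.col(av, "first"))]
  e <- exp(m)
  s <- e / rowSums(e)
  ad_node(tape, s, function(g) {
    ad_acc(a, s * (g - rowSums(g * s)))
  })
}

# row-wise layer normalization with learnable gain/bias rows (1 x k)
ad_layernorm <- function(tape, x, gain, bias, eps = 1e-5) {
  xv <- ad_value(x); gv <- as.vector(ad_value(gain))
  mu <- rowMeans(xv)
  xc <- xv - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  y <- sweep(sweep(xhat, 2L, gv, "*"), 2L, as.vector(ad_value(bias)), "+")
  ad_node(tape, y, function(g) {
    dxhat <- sweep(g, 2L, gv, "*")
    rm1 <- rowMeans(dxhat)
    rm2 <- rowMeans(dxhat * xhat)
    ad_acc(x, inv * (dxhat - rm1 - xhat * rm2))
    ad_acc(gain, matrix(colSums(g * xhat), 1L))
    ad_acc(bias, matrix(colSums(g), 1L))
  })
}

# fused three-layer graph convolution with per-frame mean pooling, on a
# constant coordinate matrix X stacked over frames; A is the per-frame
# adjacency operator (applied block-diagonally); parameters are nodes, the
# input carries no gradient
ad_gcn3_pooled <- function(tape, X, W1, b1, W2, b2, W3, b3, A) {
  need_grad <- is_node(W1)
  fw <- gcn3_pooled_forward(
    A$p, A$i, A$x, A$nrow, X,
    ad_value(W1), as.vector(ad_value(b1)),
    ad_value(W2), as.vector(ad_value(b2)),
    ad_value(W3), as.vector(ad_value(b3)), need_grad)
  if (!need_grad) return(ad_node(tape, fw$pooled))
  ad_node(tape, fw$pooled, function(g) {
    bw <- gcn3_pooled_backward(A$p, A$i, A$x, A$nrow, X, ad_value(W1),
                               ad_value(W2), ad_value(W3),
                               fw$H1, fw$H2, fw$H3, g)
    ad_acc(W1, bw$gW1); ad_acc(b1, bw$gb1)
    ad_acc(W2, bw$gW2); ad_acc(b2, bw$gb2)
    ad_acc(W3, bw$gW3); ad_acc(b3, bw$gb3)
  })
}

# add a constant matrix (same shape); gradient passes through unchanged
ad_shift <- function(tape, a, k) {
  ad_node(tape, ad_value(a) + k, function(g) ad_acc(a, g))
}

ad_exp <- function(tape, a) {
  v <- exp(ad_value(a))
  ad_node(tape, v, function(g) ad_acc(a, g * v))
}

# reinterpret a T x 3V matrix (row t = c(x_1..x_V, y_1..y_V, z_1..z_V)) as
# stacked per-frame coordinate blocks, a (T*V) x 3 matrix
ad_rows_to_coords <- function(tape, a, V) {
  av <- ad_value(a)
  Tn <- nrow(av)
  val <- matrix(aperm(array(t(av), c(V, 3L, Tn)), c(1L, 3L, 2L)),
                Tn * V, 3L)
  ad_node(tape, val, function(g) {
    ad_acc(a, t(matrix(aperm(array(g, c(V, Tn, 3L)), c(1L, 3L, 2L)),
                       3L * V, Tn)))
  })
}

# ---- loss primitives -----------------------------------------------------

# mean over frames of the Chamfer distance between corresponding V x 3
# blocks of pred (a (T*V) x 3 node) and target (a fixed (T*V) x 3 matrix);
# the nearest-neighbour search and subgradient run in compiled code
ad_chamfer_frames <- function(tape, pred, target, V) {
  Tn <- nrow(ad_value(pred)) / V
  res <- chamfer_frames_cpp(ad_value(pred), target, V)
  ad_node(tape, matrix(res$value, 1L, 1L), function(g) {
    ad_acc(pred, res$grad * (as.vector(g) / Tn))  # value is the frame mean
  })
}

# mean over frames of the Laplacian smoothness of V x 3 blocks; Mbig is the
# block-diagonal row-normalized neighbour-mean operator over all frames, in
# csc_operator form
ad_laplacian_frames <- function(tape, pred, Mbig) {
  pv <- ad_value(pred)
  D <- spmm_cpp(Mbig$p, Mbig$i, Mbig$x, Mbig$nrow, pv) - pv
  r <- sqrt(rowSums(D^2))
  n <- nrow(pv)
  ad_node(tape, matrix(mean(r), 1L, 1L), function(g) {
    dD <- D / (n * pmax(r, 1e-12))
    ad_acc(pred, as.vector(g) *
             (spmm_t_cpp(Mbig$p, Mbig$i, Mbig$x, dD) - dD))
  })
}

# beta-weighted KL divergence of N(mu, diag(sigma^2)) from N(0, I), with
# sigma = exp(log_sigma); mu and log_sigma are 1 x d nodes
ad_kl_gaussian <- function(tape, mu, log_sigma, beta) {
  mv <- ad_value(mu); lv <- ad_value(log_sigma)
  s2 <- exp(2 * lv)
  val <- beta * 0.5 * sum(s2 + mv^2 - 1 - 2 * lv)
  ad_node(tape, matrix(val, 1L, 1L), function(g) {
    gg <- as.vector(g) * beta
    ad_acc(mu, gg * mv)
    ad_acc(log_sigma, gg * (s2 - 1))
  })
}
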