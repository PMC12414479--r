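# Reverse-mode automatic differentiation on a flat tape of matrix nodes.
#
# Every op records its output value and a closure that, given the gradient of
# the loss w.r.t. the output, accumulates gradients into its parent nodes.
# Layers that would otherwise expand into dozens of primitive nodes
# (convolution, LayerNorm, multi-head attention, ...) are fused into single
# nodes with hand-derived backward passes; the analytic gradients are checked
# against finite differences in the test suite.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

ad_node <- function(tape, value, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- backward
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

# leaf (input or parameter) node; no backward of its own
ad_leaf <- function(tape, value) ad_node(tape, value)

ad_acc <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

# run the tape backwards from `loss`, seeding d loss / d loss = seed
ad_backward <- function(tape, loss, seed = 1) {
  loss$grad <- seed
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd$grad)
  }
  invisible(NULL)
}

## ---- primitive ops ---------------------------------------------------------

ad_mm <- function(tape, a, b) {
  ad_node(tape, a$value %*% b$value, function(g) {
    ad_acc(a, tcrossprod(g, b$value))
    ad_acc(b, crossprod(a$value, g))
  })
}

ad_add <- function(tape, a, b) {
  ad_node(tape, a$value + b$value, function(g) {
    ad_acc(a, g)
    ad_acc(b, g)
  })
}

# add a length-d bias vector to every row of an n x d matrix
ad_bias <- function(tape, x, b) {
  bv <- as.numeric(b$value)
  n <- nrow(x$value)
  ad_node(tape, x$value + rep(bv, each = n), function(g) {
    ad_acc(x, g)
    ad_acc(b, matrix(colSums(g), 1L))
  })
}

ad_gelu <- function(tape, x) {
  xv <- x$value
  ad_node(tape, cpp_gelu_forward(xv), function(g) {
    ad_acc(x, cpp_gelu_backward(g, xv))
  })
}

ad_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$value))
  ad_node(tape, s, function(g) ad_acc(x, g * s * (1 - s)))
}

ad_mul <- function(tape, a, b) {
  ad_node(tape, a$value * b$value, function(g) {
    ad_acc(a, g * b$value)
    ad_acc(b, g * a$value)
  })
}

# scalar (1x1 node) times matrix
ad_smul <- function(tape, s, x) {
  sv <- as.numeric(s$value)
  ad_node(tape, sv * x$value, function(g) {
    ad_acc(x, sv * g)
    ad_acc(s, matrix(sum(g * x$value), 1L, 1L))
  })
}

ad_one_minus <- function(tape, s) {
  ad_node(tape, 1 - s$value, function(g) ad_acc(s, -g))
}

ad_row <- function(tape, x, i) {
  ad_node(tape, x$value[i, , drop = FALSE], function(g) {
    gx <- matrix(0, nrow(x$value), ncol(x$value))
    gx[i, ] <- g
    ad_acc(x, gx)
  })
}

ad_rbind2 <- function(tape, a, b) {
  na <- nrow(a$value)
  ad_node(tape, rbind(a$value, b$value), function(g) {
    ad_acc(a, g[seq_len(na), , drop = FALSE])
    ad_acc(b, g[-seq_len(na), , drop = FALSE])
  })
}

ad_cbind3 <- function(tape, a, b, c) {
  da <- ncol(a$value); db <- ncol(b$value)
  ad_node(tape, cbind(a$value, b$value, c$value), function(g) {
    ad_acc(a, g[, seq_len(da), drop = FALSE])
    ad_acc(b, g[, da + seq_len(db), drop = FALSE])
    ad_acc(c, g[, -seq_len(da + db), drop = FALSE])
  })
}

# column sums over a masked subset of rows -> 1 x d
ad_sum_rows <- function(tape, x, mask = NULL) {
  n <- nrow(x$value)
  keep <- if (is.null(mask)) rep(TRUE, n) else as.logical(mask)
  if (!any(keep)) stop("all rows masked in pooling", call. = FALSE)
  ad_node(tape, matrix(colSums(x$value[keep, , drop = FALSE]), 1L), function(g) {
    gx <- matrix(0, n, ncol(x$value))
    gx[keep, ] <- matrix(g, sum(keep), ncol(x$value), byrow = TRUE)
    ad_acc(x, gx)
  })
}

ad_mean_rows <- function(tape, x, mask = NULL) {
  n <- nrow(x$value)
  keep <- if (is.null(mask)) rep(TRUE, n) else as.logical(mask)
  m <- sum(keep)
  if (m == 0L) stop("all rows masked in pooling", call. = FALSE)
  ad_node(tape, matrix(colSums(x$value[keep, , drop = FALSE]) / m, 1L), function(g) {
    gx <- matrix(0, n, ncol(x$value))
    gx[keep, ] <- matrix(g / m, m, ncol(x$value), byrow = TRUE)
    ad_acc(x, gx)
  })
}

## ---- fused layers ----------------------------------------------------------

# LayerNorm over the feature (column) dimension of each row, with affine
# parameters gamma, beta (length-d vectors stored as 1 x d).
ad_layernorm <- function(tape, x, gamma, beta, eps = 1e-5) {
  fw <- cpp_layernorm_forward(x$value, as.numeric(gamma$value),
                              as.numeric(beta$value), eps)
  ad_node(tape, fw$y, function(g) {
    bw <- cpp_layernorm_backward(g, fw$xhat, fw$inv, as.numeric(gamma$value))
    ad_acc(x, bw$dx)
    ad_acc(gamma, matrix(bw$dgamma, 1L))
    ad_acc(beta, matrix(bw$dbeta, 1L))
  })
}

# GroupNorm on a 1 x d feature vector: the d features are split into `groups`
# contiguous groups, each normalized to zero mean / unit variance, then an
# affine transform over all d features is applied.
ad_groupnorm <- function(tape, x, gamma, beta, groups, eps = 1e-5) {
  xv <- as.numeric(x$value)
  d <- length(xv)
  stopifnot(d %% groups == 0L)
  gs <- d / groups
  idx <- matrix(seq_len(d), nrow = gs)  # column j = indices of group j
  mu <- colMeans(matrix(xv[idx], nrow = gs))
  xc <- xv - rep(mu, each = gs)
  va <- colMeans(matrix(xc[idx]^2, nrow = gs))
  inv <- rep(1 / sqrt(va + eps), each = gs)
  xhat <- xc * inv
  gv <- as.numeric(gamma$value)
  y <- matrix(xhat * gv + as.numeric(beta$value), 1L)
  ad_node(tape, y, function(g) {
    g <- as.numeric(g)
    dxhat <- g * gv
    m1 <- rep(colMeans(matrix(dxhat[idx], nrow = gs)), each = gs)
    m2 <- rep(colMeans(matrix((dxhat * xhat)[idx], nrow = gs)), each = gs)
    ad_acc(x, matrix(inv * (dxhat - m1 - xhat * m2), 1L))
    ad_acc(gamma, matrix(g * xhat, 1L))
    ad_acc(beta, matrix(g, 1L))
  })
}

# im2col for a same-padded 1D convolution with odd kernel k over an L x d
# input: row i of the result is the concatenation of rows i-hw..i+hw
# (out-of-range rows are zero). Compiled kernels do the heavy lifting.
conv_im2col <- function(x, k) cpp_im2col(x, k)

conv_col2im <- function(g2, k, L, d) cpp_col2im(g2, k, L, d)

# same-length 1D convolution: x (L x din), w ((k*din) x dout), b (1 x dout)
ad_conv1d <- function(tape, x, w, b, kernel_size) {
  L <- nrow(x$value); din <- ncol(x$value)
  x2 <- conv_im2col(x$value, kernel_size)
  y <- x2 %*% w$value + rep(as.numeric(b$value), each = L)
  ad_node(tape, y, function(g) {
    ad_acc(w, crossprod(x2, g))
    ad_acc(b, matrix(colSums(g), 1L))
    ad_acc(x, conv_col2im(tcrossprod(g, w$value), kernel_size, L, din))
  })
}

softmax_rows <- function(s) {
  m <- s[cbind(seq_len(nrow(s)), max.col(s, ties.method = "first"))]
  e <- exp(s - m)
  e / rowSums(e)
}

# fused multi-head attention: queries from x_q, keys/values from x_kv,
# projections Wq/Wk/Wv/Wo (d x d, bias-free), `heads` heads over contiguous
# column blocks, optional logical key mask (FALSE keys get no attention).
ad_mha <- function(tape, x_q, x_kv, Wq, Wk, Wv, Wo, heads, key_mask = NULL) {
  d <- ncol(Wq$value)
  stopifnot(d %% heads == 0L)
  if (is.null(key_mask)) {
    key_mask <- integer(0)
  } else {
    key_mask <- as.integer(as.logical(key_mask))
    if (!any(key_mask == 1L)) stop("all keys masked in attention", call. = FALSE)
  }
  fw <- cpp_mha_forward(x_q$value, x_kv$value, Wq$value, Wk$value, Wv$value,
                        Wo$value, heads, key_mask)
  ad_node(tape, fw$out, function(g) {
    bw <- cpp_mha_backward(g, x_q$value, x_kv$value, fw$Q, fw$K, fw$V, fw$A,
                           fw$O, Wq$value, Wk$value, Wv$value, Wo$value, heads)
    ad_acc(Wq, bw$dWq); ad_acc(Wk, bw$dWk)
    ad_acc(Wv, bw$dWv); ad_acc(Wo, bw$dWo)
    ad_acc(x_q, bw$dxq); ad_acc(x_kv, bw$dxkv)
  })
}

# fused softmax + cross-entropy for a single sample: logits 1 x 2,
# label in {0, 1}. Returns a 1 x 1 loss node; the backward seed carries any
# per-sample weight.
ad_softmax_ce <- function(tape, logits, label) {
  z <- as.numeric(logits$value)
  z <- z - max(z)
  p <- exp(z) / sum(exp(z))
  loss <- -log(max(p[label + 1L], 1e-12))
  nd <- ad_node(tape, matrix(loss, 1L, 1L), function(g) {
    onehot <- c(1 - label, label)
    ad_acc(logits, matrix(as.numeric(g) * (p - onehot), 1L))
  })
  nd$probs <- p
  nd
}
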