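#' Gaussian error linear unit
#'
#' Exact GELU activation, `x * pnorm(x)`, using the Gaussian CDF through the
#' exact error function rather than the tanh approximation. Applied
#' elementwise over vectors, matrices and arrays.
#'
#' @param x A numeric vector, matrix or array.
#' @return An object of the same shape as `x`.
#' @examples
#' gelu(0)       # 0
#' gelu(1)       # 1 * pnorm(1) = 0.8413...
#' gelu(c(-10, 10))
#' @export
gelu <- function(x) {
  stopifnot(is.numeric(x))
  x * stats::pnorm(x)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Gated linear unit
#'
#' Computes `(X W1 + b1) * sigmoid(X W2 + b2)` (elementwise product), the
#' gating nonlinearity used in the convolutional blocks of the transformer
#' effect model.
#'
#' @param X Numeric matrix of inputs (rows are positions).
#' @param W1,W2 Weight matrices with `ncol(X)` rows.
#' @param b1,b2 Bias vectors of length `ncol(W1)` / `ncol(W2)`.
#' @return A numeric matrix of shape `nrow(X)` x `ncol(W1)`.
#' @examples
#' X <- matrix(1:4, 2)
#' glu(X, diag(2), c(0, 0), matrix(0, 2, 2), c(0, 0))  # 0.5 * X
#' @export
glu <- function(X, W1, b1, W2, b2) {
  X <- as.matrix(X)
  a <- sweep(X %*% W1, 2L, as.numeric(b1), "+")
  g <- sweep(X %*% W2, 2L, as.numeric(b2), "+")
  a * sigmoid(g)
}

#' Scaled dot-product attention
#'
#' Single-head attention `softmax(Q K' / sqrt(d_k)) V`. Rows of the softmax
#' matrix sum to one over the unmasked keys.
#'
#' @param Q Query matrix (n_q x d_k).
#' @param K Key matrix (n_k x d_k).
#' @param V Value matrix (n_k x d_v).
#' @param key_mask Optional logical vector of length n_k; `FALSE` keys
#'   receive zero attention weight.
#' @return The n_q x d_v attended output matrix.
#' @examples
#' Q <- matrix(c(1, 0), 1)
#' K <- diag(2)
#' V <- matrix(c(10, 20), 2)
#' attention(100 * Q, K, V)  # saturates onto the first value row
#' @export
attention <- function(Q, K, V, key_mask = NULL) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  stopifnot(ncol(Q) == ncol(K), nrow(K) == nrow(V))
  S <- tcrossprod(Q, K) / sqrt(ncol(Q))
  if (!is.null(key_mask)) {
    key_mask <- as.logical(key_mask)
    if (!any(key_mask)) stop("all keys are masked", call. = FALSE)
    S[, !key_mask] <- -Inf
  }
  softmax_rows(S) %*% V
}

#' Sigmoid-gated fusion of local and global features
#'
#' Computes the scalar gate `alpha = sigmoid(W_alpha [h_l; h_gA; h_gB] +
#' b_alpha)` and the fused vector `h = alpha * h_l + alpha * h_gA +
#' (1 - alpha) * h_gB`. The three coefficients deliberately do not sum to
#' one; `normalize = TRUE` divides the fused vector by `1 + alpha` for a
#' convex variant used in ablations.
#'
#' @param h_l,h_gA,h_gB Numeric vectors of equal length: local-window
#'   features of protein A and pooled global features of proteins A and B.
#' @param W_alpha Weight vector of length `3 * length(h_l)`.
#' @param b_alpha Scalar bias.
#' @param normalize Divide by the total weight `1 + alpha`? Default `FALSE`.
#' @return A list with elements `alpha` (scalar in (0, 1)) and `h` (numeric
#'   vector).
#' @export
attention_fusion <- function(h_l, h_gA, h_gB, W_alpha, b_alpha = 0,
                             normalize = FALSE) {
  h_l <- as.numeric(h_l); h_gA <- as.numeric(h_gA); h_gB <- as.numeric(h_gB)
  if (length(h_l) != length(h_gA) || length(h_l) != length(h_gB)) {
    stop("h_l, h_gA and h_gB must have equal length", call. = FALSE)
  }
  z <- c(h_l, h_gA, h_gB)
  W_alpha <- as.numeric(W_alpha)
  if (length(W_alpha) != length(z)) {
    stop("W_alpha must have length 3 * length(h_l)", call. = FALSE)
  }
  alpha <- sigmoid(sum(W_alpha * z) + as.numeric(b_alpha))
  h <- alpha * h_l + alpha * h_gA + (1 - alpha) * h_gB
  if (normalize) h <- h / (1 + alpha)
  list(alpha = alpha, h = h)
}

## ---- losses ----------------------------------------------------------------

check_prob_pairs <- function(probs) {
  probs <- rbind(probs)
  dimnames(probs) <- NULL
  stopifnot(ncol(probs) == 2L)
  if (any(abs(rowSums(probs) - 1) > 1e-6)) {
    stop("each probability pair must sum to 1", call. = FALSE)
  }
  probs
}

#' Cross-entropy loss for binary probability pairs
#'
#' Mean negative log-probability of the true class, with probabilities
#' clamped at 1e-12.
#'
#' @param probs A numeric matrix with two columns `(p_class0, p_class1)`
#'   (a single pair may be given as a length-2 vector); rows sum to 1.
#' @param labels Integer vector of labels in `{0, 1}`.
#' @return The scalar loss.
#' @examples
#' cross_entropy(c(0.5, 0.5), 1)  # log(2)
#' @export
cross_entropy <- function(probs, labels) {
  probs <- check_prob_pairs(probs)
  labels <- as.integer(labels)
  stopifnot(nrow(probs) == length(labels), all(labels %in% 0:1))
  p <- probs[cbind(seq_along(labels), labels + 1L)]
  mean(-log(pmax(p, 1e-12)))
}

#' Batch-weighted cross-entropy for imbalanced batches
#'
#' Each sample is weighted by the inverse in-batch frequency of its class,
#' `w_c = n / (2 * n_c)` with `n_c` counted from this batch, and the loss is
#' the weighted mean `sum(w_i * -log p_i) / sum(w_i)`. On a class-balanced
#' batch all weights equal 1 and the loss reduces exactly to
#' [cross_entropy()]; a class absent from the batch contributes nothing.
#'
#' @inheritParams cross_entropy
#' @return The scalar loss.
#' @export
batch_weighted_ce <- function(probs, labels) {
  probs <- check_prob_pairs(probs)
  labels <- as.integer(labels)
  stopifnot(nrow(probs) >= 1L, nrow(probs) == length(labels),
            all(labels %in% 0:1))
  n <- length(labels)
  nc <- c(sum(labels == 0L), sum(labels == 1L))
  w_class <- ifelse(nc > 0, n / (2 * nc), 0)
  w <- w_class[labels + 1L]
  p <- probs[cbind(seq_len(n), labels + 1L)]
  sum(w * -log(pmax(p, 1e-12))) / sum(w)
}

batch_ce_weights <- function(labels, loss = c("cross_entropy", "batch_weighted")) {
  loss <- match.arg(loss)
  n <- length(labels)
  if (loss == "cross_entropy") return(rep(1 / n, n))
  nc <- c(sum(labels == 0L), sum(labels == 1L))
  w_class <- ifelse(nc > 0, n / (2 * nc), 0)
  w <- w_class[labels + 1L]
  w / sum(w)
}

## ---- voting ----------------------------------------------------------------

vote_label <- function(p1, threshold = 0.5) as.integer(p1 > threshold)

#' Soft-voting ensemble of two probability pairs
#'
#' Averages the class probabilities of the two submodels elementwise; the
#' hard label is 1 when the averaged positive-class probability exceeds the
#' threshold (an exact tie predicts class 0).
#'
#' @param p1,p2 Probability pairs `(p_class0, p_class1)`: length-2 vectors
#'   or two-column matrices with matching row counts.
#' @param threshold Decision threshold on the positive-class probability.
#' @return A [tibble::tibble()] with columns `p0`, `p1` (fused
#'   probabilities) and `label`.
#' @examples
#' soft_vote(c(0.6, 0.4), c(0.8, 0.2))
#' @export
soft_vote <- function(p1, p2, threshold = 0.5) {
  p1 <- check_prob_pairs(p1); p2 <- check_prob_pairs(p2)
  stopifnot(nrow(p1) == nrow(p2))
  m <- (p1 + p2) / 2
  tibble::tibble(p0 = m[, 1L], p1 = m[, 2L],
                 label = vote_label(m[, 2L], threshold))
}

#' Hard-voting ensemble of two probability pairs
#'
#' Each submodel casts the label from its own thresholded positive-class
#' probability. When the two votes agree that label is returned; a 1-1 tie
#' falls back to the soft-vote label.
#'
#' @inheritParams soft_vote
#' @return An integer vector of labels.
#' @export
hard_vote <- function(p1, p2, threshold = 0.5) {
  p1 <- check_prob_pairs(p1); p2 <- check_prob_pairs(p2)
  l1 <- vote_label(p1[, 2L], threshold)
  l2 <- vote_label(p2[, 2L], threshold)
  out <- l1
  tie <- l1 != l2
  if (any(tie)) {
    out[tie] <- soft_vote(p1[tie, , drop = FALSE],
                          p2[tie, , drop = FALSE], threshold)$label
  }
  out
}

#' Max-confidence ensemble of two probability pairs
#'
#' Returns the probability pair of the submodel whose larger class
#' probability is higher; an exact confidence tie falls back to the soft
#' vote.
#'
#' @inheritParams soft_vote
#' @return A [tibble::tibble()] with columns `p0`, `p1` and `label`.
#' @export
max_confidence_vote <- function(p1, p2, threshold = 0.5) {
  p1 <- check_prob_pairs(p1); p2 <- check_prob_pairs(p2)
  c1 <- pmax(p1[, 1L], p1[, 2L])
  c2 <- pmax(p2[, 1L], p2[, 2L])
  pick1 <- c1 > c2
  tie <- c1 == c2
  m <- p2
  m[pick1, ] <- p1[pick1, , drop = FALSE]
  m[tie, ] <- (p1[tie, , drop = FALSE] + p2[tie, , drop = FALSE]) / 2
  tibble::tibble(p0 = m[, 1L], p1 = m[, 2L],
                 label = vote_label(m[, 2L], threshold))
}
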