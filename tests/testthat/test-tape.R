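# Finite-difference validation of the analytic gradients. One spot check
# per architecture exercises every fused backward pass (conv1d, LayerNorm,
# GroupNorm, multi-head attention with and without masks, GLU, gated
# fusion, pooling) and confirms that no parameter is left without gradient
# flow.

fd_gradient_check <- function(model, sample, n_entries = 3L, eps = 1e-5) {
  # the output layer is zero-initialized by design; perturb it so gradient
  # flow through every upstream parameter is actually exercised
  model$params[["cls3.W"]][] <-
    0.3 * phosppi:::rng_local(7)$rnorm(length(model$params[["cls3.W"]]))
  tape <- phosppi:::ad_tape()
  pn <- phosppi:::param_nodes(tape, model$params)
  logits <- phosppi:::model_logits(tape, pn, model, sample)
  loss <- phosppi:::ad_softmax_ce(tape, logits, sample$label)
  phosppi:::ad_backward(tape, loss)
  loss_at <- function(params) {
    m <- model; m$params <- params
    t2 <- phosppi:::ad_tape()
    pn2 <- phosppi:::param_nodes(t2, params)
    phosppi:::ad_softmax_ce(t2, phosppi:::model_logits(t2, pn2, m, sample),
                            sample$label)$value[1L]
  }
  rng <- phosppi:::rng_local(99)
  worst <- 0
  for (nm in names(model$params)) {
    g <- pn[[nm]]$grad
    expect_false(is.null(g), info = paste("no gradient reaches", nm))
    k <- min(n_entries, length(model$params[[nm]]))
    for (j in rng$sample_n(length(model$params[[nm]]), k)) {
      up <- model$params; up[[nm]][j] <- up[[nm]][j] + eps
      dn <- model$params; dn[[nm]][j] <- dn[[nm]][j] - eps
      fd <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      rel <- abs(fd - g[j]) / max(1e-6, abs(fd), abs(g[j]))
      worst <- max(worst, rel)
    }
  }
  worst
}

make_effect_sample <- function(rng, D, label) {
  list(xl = matrix(rng$rnorm(7 * D), 7, D),
       ml = c(0L, 1L, 1L, 1L, 1L, 1L, 0L),
       xa = matrix(rng$rnorm(10 * D), 10, D),
       xb = matrix(rng$rnorm(9 * D), 9, D),
       label = label)
}

test_that("site-model gradients match finite differences everywhere", {
  rng <- phosppi:::rng_local(42)
  D <- 8L
  model <- new_model(site_model_config(D, model_dim = 16L, heads = 4L),
                     seed = 3)
  sample <- list(x = matrix(rng$rnorm(12 * D), 12, D), pos = 5L, label = 1L)
  expect_lt(fd_gradient_check(model, sample), 1e-4)
})

test_that("attcnn gradients match finite differences everywhere", {
  rng <- phosppi:::rng_local(43)
  model <- new_model(attcnn_config(8L, model_dim = 16L,
                                   classifier_hidden = 16L,
                                   groupnorm_groups = 4L), seed = 3)
  expect_lt(fd_gradient_check(model, make_effect_sample(rng, 8L, 0L)), 1e-4)
  # the convex fusion variant differentiates through the normalizer too
  model_n <- new_model(attcnn_config(8L, model_dim = 16L,
                                     classifier_hidden = 16L,
                                     groupnorm_groups = 4L,
                                     normalize_fusion = TRUE), seed = 4)
  expect_lt(fd_gradient_check(model_n, make_effect_sample(rng, 8L, 1L)), 1e-4)
})

test_that("transformer gradients match finite differences everywhere", {
  rng <- phosppi:::rng_local(44)
  model <- new_model(transformer_config(8L, model_dim = 16L, heads = 4L,
                                        ffn_dim = 24L,
                                        classifier_hidden = 16L), seed = 3)
  expect_lt(fd_gradient_check(model, make_effect_sample(rng, 8L, 1L)), 1e-4)
})

test_that("masked attention assigns pads zero weight and errors when empty", {
  rng <- phosppi:::rng_local(45)
  tape <- phosppi:::ad_tape()
  d <- 8L
  xq <- phosppi:::ad_leaf(tape, matrix(rng$rnorm(3 * d), 3, d))
  xkv <- phosppi:::ad_leaf(tape, matrix(rng$rnorm(5 * d), 5, d))
  W <- lapply(1:4, function(i) phosppi:::ad_leaf(tape, diag(d)))
  mask <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  out <- phosppi:::ad_mha(tape, xq, xkv, W[[1]], W[[2]], W[[3]], W[[4]],
                          heads = 2L, key_mask = mask)
  # identical output when the masked rows are replaced by garbage
  xkv2 <- xkv$value
  xkv2[!mask, ] <- 1e3
  tape2 <- phosppi:::ad_tape()
  out2 <- phosppi:::ad_mha(tape2, phosppi:::ad_leaf(tape2, xq$value),
                           phosppi:::ad_leaf(tape2, xkv2),
                           W[[1]], W[[2]], W[[3]], W[[4]],
                           heads = 2L, key_mask = mask)
  expect_equal(out$value, out2$value, tolerance = 1e-12)
  expect_error(
    phosppi:::ad_mha(tape, xq, xkv, W[[1]], W[[2]], W[[3]], W[[4]],
                     heads = 2L, key_mask = rep(FALSE, 5)),
    "all keys masked")
})

test_that("single-key cross attention returns that key's value projection", {
  tape <- phosppi:::ad_tape()
  d <- 4L
  xq <- phosppi:::ad_leaf(tape, matrix(rnorm(d), 1, d))
  xkv <- phosppi:::ad_leaf(tape, matrix(c(1, 2, 3, 4), 1, d))
  W <- lapply(1:4, function(i) phosppi:::ad_leaf(tape, diag(d)))
  out <- phosppi:::ad_mha(tape, xq, xkv, W[[1]], W[[2]], W[[3]], W[[4]],
                          heads = 2L)
  # softmax over one key is 1 regardless of the query
  expect_equal(as.numeric(out$value), c(1, 2, 3, 4), tolerance = 1e-12)
})
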