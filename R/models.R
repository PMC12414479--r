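# Model configurations, parameter initialization and tape-based forward
# passes for the three architectures:
#   * site model      -- conv encoder + attention decoder over the full
#                        sequence, classifying one S/T/Y residue (task 1)
#   * attcnn          -- three conv+sum-pool branches fused by a sigmoid
#                        gate (task 2)
#   * transformer     -- projected streams, GLU conv blocks on the globals,
#                        3-block cross-attention decoder over the 31-window
#                        (task 2)

## ---- configs ---------------------------------------------------------------

#' Model configurations
#'
#' `site_model_config()` describes the functional-site classifier: a D ->
#' `model_dim` linear projection, `conv_layers` stacked same-padded 1D
#' convolutions (GELU + LayerNorm + residual), a decoder whose query is the
#' encoded row of the target residue (self-attention then cross-attention
#' with the encoder output), and a three-layer softmax classifier.
#'
#' `attcnn_config()` describes the attention-gated CNN effect model: one
#' conv + GELU + LayerNorm + sum-pooling branch per input stream (local
#' window of A, global A, global B; separate weights), sigmoid-gated fusion
#' `alpha h_l + alpha h_gA + (1 - alpha) h_gB`, and a classifier with GELU
#' and GroupNorm.
#'
#' `transformer_config()` describes the cross-attention transformer effect
#' model: per-stream projection to `model_dim`, conv + GLU + residual +
#' LayerNorm blocks on the global streams, a decoder of exactly three
#' blocks (pad-masked self-attention over the 31 local positions,
#' cross-attention into the concatenated encoded A and B rows, and a
#' position-wise feed-forward net), masked mean pooling, and a three-layer
#' classifier.
#'
#' @param input_dim Embedding dimension D of the backend.
#' @param model_dim Internal width (default 64; divisible by `heads`).
#' @param conv_layers Number of stacked conv blocks in the site encoder.
#' @param kernel_size Odd convolution kernel size (default 7).
#' @param heads Attention heads (default 8).
#' @param decoder_blocks Decoder blocks (site model default 1; the
#'   transformer effect model always uses 3).
#' @param classifier_hidden Hidden width of the classifier layers.
#' @param groupnorm_groups Groups for GroupNorm in the attcnn classifier.
#' @param normalize_fusion Use the convex variant of the fusion gate
#'   (divide by `1 + alpha`)? Default `FALSE`, matching the non-normalized
#'   gate as specified.
#' @param ffn_dim Hidden width of the transformer feed-forward net.
#' @return A config list of the corresponding class.
#' @export
site_model_config <- function(input_dim, model_dim = 64L, conv_layers = 3L,
                              kernel_size = 7L, heads = 8L,
                              decoder_blocks = 1L, classifier_hidden = 64L) {
  stopifnot(model_dim %% heads == 0L, kernel_size %% 2L == 1L,
            input_dim > 0L, conv_layers >= 1L, decoder_blocks >= 1L)
  structure(list(input_dim = as.integer(input_dim),
                 model_dim = as.integer(model_dim),
                 conv_layers = as.integer(conv_layers),
                 kernel_size = as.integer(kernel_size),
                 heads = as.integer(heads),
                 decoder_blocks = as.integer(decoder_blocks),
                 classifier_hidden = as.integer(classifier_hidden)),
            class = c("site_model_config", "phosppi_config"))
}

#' @rdname site_model_config
#' @export
attcnn_config <- function(input_dim, model_dim = 64L, kernel_size = 7L,
                          classifier_hidden = 64L, groupnorm_groups = 8L,
                          normalize_fusion = FALSE) {
  stopifnot(kernel_size %% 2L == 1L, classifier_hidden %% groupnorm_groups == 0L)
  structure(list(input_dim = as.integer(input_dim),
                 model_dim = as.integer(model_dim),
                 kernel_size = as.integer(kernel_size),
                 classifier_hidden = as.integer(classifier_hidden),
                 groupnorm_groups = as.integer(groupnorm_groups),
                 normalize_fusion = isTRUE(normalize_fusion)),
            class = c("attcnn_config", "phosppi_config"))
}

#' @rdname site_model_config
#' @export
transformer_config <- function(input_dim, model_dim = 64L, heads = 8L,
                               kernel_size = 7L, ffn_dim = 128L,
                               classifier_hidden = 64L) {
  stopifnot(model_dim %% heads == 0L, kernel_size %% 2L == 1L)
  structure(list(input_dim = as.integer(input_dim),
                 model_dim = as.integer(model_dim),
                 heads = as.integer(heads),
                 decoder_blocks = 3L,
                 kernel_size = as.integer(kernel_size),
                 ffn_dim = as.integer(ffn_dim),
                 classifier_hidden = as.integer(classifier_hidden)),
            class = c("transformer_config", "phosppi_config"))
}

## ---- parameter initialization ---------------------------------------------

glorot <- function(rng, din, dout) {
  matrix(rng$rnorm(din * dout) * sqrt(2 / (din + dout)), din, dout)
}

init_linear <- function(params, name, rng, din, dout) {
  params[[paste0(name, ".W")]] <- glorot(rng, din, dout)
  params[[paste0(name, ".b")]] <- matrix(0, 1L, dout)
  params
}

init_ln <- function(params, name, d) {
  params[[paste0(name, ".g")]] <- matrix(1, 1L, d)
  params[[paste0(name, ".b")]] <- matrix(0, 1L, d)
  params
}

init_attn <- function(params, name, rng, d) {
  for (w in c("Wq", "Wk", "Wv", "Wo")) {
    params[[paste0(name, ".", w)]] <- glorot(rng, d, d)
  }
  params
}

#' Create an untrained model
#'
#' Initializes the parameter set of a model described by a config produced
#' by [site_model_config()], [attcnn_config()] or [transformer_config()],
#' with seeded Glorot-normal weights. The final classifier layer starts at
#' zero so every model opens at the uninformative (0.5, 0.5) prediction;
#' sum-pooled features are large enough that a random output layer would
#' start training from saturated, overconfident logits.
#'
#' @param config A `phosppi_config`.
#' @param seed Integer seed for weight initialization.
#' @return A list of class `phosppi_model` with elements `type`, `config`
#'   and `params` (a flat named list of matrices).
#' @export
new_model <- function(config, seed = 1L) {
  rng <- rng_local(derive_seed(seed, 17))
  m <- config$model_dim
  p <- list()
  if (inherits(config, "site_model_config")) {
    p <- init_linear(p, "proj", rng, config$input_dim, m)
    for (l in seq_len(config$conv_layers)) {
      nm <- paste0("conv", l)
      p <- init_linear(p, nm, rng, config$kernel_size * m, m)
      p <- init_ln(p, paste0(nm, ".ln"), m)
    }
    for (b in seq_len(config$decoder_blocks)) {
      p <- init_attn(p, paste0("dec", b, ".sa"), rng, m)
      p <- init_ln(p, paste0("dec", b, ".ln1"), m)
      p <- init_attn(p, paste0("dec", b, ".ca"), rng, m)
      p <- init_ln(p, paste0("dec", b, ".ln2"), m)
    }
    h <- config$classifier_hidden
    p <- init_linear(p, "cls1", rng, m, h)
    p <- init_linear(p, "cls2", rng, h, h)
    p <- init_linear(p, "cls3", rng, h, 2L)
    type <- "site"
  } else if (inherits(config, "attcnn_config")) {
    for (br in c("local", "global_a", "global_b")) {
      nm <- paste0("branch.", br)
      p <- init_linear(p, nm, rng, config$kernel_size * config$input_dim, m)
      p <- init_ln(p, paste0(nm, ".ln"), m)
    }
    # zero-init the fusion gate so alpha starts at 1/2 and every stream is
    # visible to the classifier from the first step (pooled sums are large
    # enough to saturate a randomly initialized sigmoid)
    p[["fus.W"]] <- matrix(0, 3L * m, 1L)
    p[["fus.b"]] <- matrix(0, 1L, 1L)
    h <- config$classifier_hidden
    p <- init_linear(p, "cls1", rng, m, h)
    p <- init_ln(p, "gn1", h)
    p <- init_linear(p, "cls2", rng, h, h)
    p <- init_ln(p, "gn2", h)
    p <- init_linear(p, "cls3", rng, h, 2L)
    type <- "attcnn"
  } else if (inherits(config, "transformer_config")) {
    p <- init_linear(p, "proj_l", rng, config$input_dim, m)
    p <- init_linear(p, "proj_a", rng, config$input_dim, m)
    p <- init_linear(p, "proj_b", rng, config$input_dim, m)
    for (s in c("enc_a", "enc_b")) {
      p <- init_linear(p, paste0(s, ".conv"), rng, config$kernel_size * m, m)
      p <- init_linear(p, paste0(s, ".glu1"), rng, m, m)
      p <- init_linear(p, paste0(s, ".glu2"), rng, m, m)
      p <- init_ln(p, paste0(s, ".ln"), m)
    }
    for (b in seq_len(config$decoder_blocks)) {
      nm <- paste0("dec", b)
      p <- init_attn(p, paste0(nm, ".sa"), rng, m)
      p <- init_ln(p, paste0(nm, ".ln1"), m)
      p <- init_attn(p, paste0(nm, ".ca"), rng, m)
      p <- init_ln(p, paste0(nm, ".ln2"), m)
      p <- init_linear(p, paste0(nm, ".ffn1"), rng, m, config$ffn_dim)
      p <- init_linear(p, paste0(nm, ".ffn2"), rng, config$ffn_dim, m)
      p <- init_ln(p, paste0(nm, ".ln3"), m)
    }
    h <- config$classifier_hidden
    p <- init_linear(p, "cls1", rng, m, h)
    p <- init_linear(p, "cls2", rng, h, h)
    p <- init_linear(p, "cls3", rng, h, 2L)
    type <- "transformer"
  } else {
    stop("unknown config class", call. = FALSE)
  }
  p[["cls3.W"]][] <- 0
  structure(list(type = type, config = config, params = p),
            class = "phosppi_model")
}

#' @export
print.phosppi_model <- function(x, ...) {
  n <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<phosppi_model> %s (%d parameters, D = %d, model_dim = %d)\n",
              x$type, n, x$config$input_dim, x$config$model_dim))
  invisible(x)
}

## ---- forward passes --------------------------------------------------------

# wrap every parameter as a leaf node on the tape
param_nodes <- function(tape, params) {
  lapply(params, function(v) ad_leaf(tape, v))
}

linear_fwd <- function(tape, pn, name, x) {
  ad_bias(tape, ad_mm(tape, x, pn[[paste0(name, ".W")]]), pn[[paste0(name, ".b")]])
}

ln_fwd <- function(tape, pn, name, x) {
  ad_layernorm(tape, x, pn[[paste0(name, ".g")]], pn[[paste0(name, ".b")]])
}

mha_fwd <- function(tape, pn, name, xq, xkv, heads, key_mask = NULL) {
  ad_mha(tape, xq, xkv,
         pn[[paste0(name, ".Wq")]], pn[[paste0(name, ".Wk")]],
         pn[[paste0(name, ".Wv")]], pn[[paste0(name, ".Wo")]],
         heads, key_mask)
}

# site model: x is an L x D leaf node, pos the 1-based target row
site_forward <- function(tape, pn, cfg, x, pos) {
  H <- linear_fwd(tape, pn, "proj", x)
  for (l in seq_len(cfg$conv_layers)) {
    nm <- paste0("conv", l)
    C <- ad_conv1d(tape, H, pn[[paste0(nm, ".W")]], pn[[paste0(nm, ".b")]],
                   cfg$kernel_size)
    N <- ln_fwd(tape, pn, paste0(nm, ".ln"), ad_gelu(tape, C))
    H <- ad_add(tape, H, N)  # residual after normalization
  }
  q <- ad_row(tape, H, pos)
  for (b in seq_len(cfg$decoder_blocks)) {
    nm <- paste0("dec", b)
    sa <- mha_fwd(tape, pn, paste0(nm, ".sa"), q, q, cfg$heads)
    q <- ad_add(tape, q, ln_fwd(tape, pn, paste0(nm, ".ln1"), sa))
    ca <- mha_fwd(tape, pn, paste0(nm, ".ca"), q, H, cfg$heads)
    q <- ad_add(tape, q, ln_fwd(tape, pn, paste0(nm, ".ln2"), ca))
  }
  h <- ad_gelu(tape, linear_fwd(tape, pn, "cls1", q))
  h <- ad_gelu(tape, linear_fwd(tape, pn, "cls2", h))
  linear_fwd(tape, pn, "cls3", h)
}

# one attcnn branch: conv -> GELU -> LayerNorm -> masked sum pooling
conv_pool_branch_fwd <- function(tape, pn, name, x, kernel_size, mask = NULL) {
  C <- ad_conv1d(tape, x, pn[[paste0(name, ".W")]], pn[[paste0(name, ".b")]],
                 kernel_size)
  N <- ln_fwd(tape, pn, paste0(name, ".ln"), ad_gelu(tape, C))
  ad_sum_rows(tape, N, mask)
}

attcnn_forward <- function(tape, pn, cfg, xl, ml, xa, xb) {
  hl <- conv_pool_branch_fwd(tape, pn, "branch.local", xl, cfg$kernel_size, ml)
  ha <- conv_pool_branch_fwd(tape, pn, "branch.global_a", xa, cfg$kernel_size)
  hb <- conv_pool_branch_fwd(tape, pn, "branch.global_b", xb, cfg$kernel_size)
  z <- ad_cbind3(tape, hl, ha, hb)
  alpha <- ad_sigmoid(tape, ad_bias(tape, ad_mm(tape, z, pn[["fus.W"]]),
                                    pn[["fus.b"]]))
  h <- ad_add(tape, ad_add(tape, ad_smul(tape, alpha, hl),
                           ad_smul(tape, alpha, ha)),
              ad_smul(tape, ad_one_minus(tape, alpha), hb))
  if (cfg$normalize_fusion) {
    total <- ad_node(tape, 1 + alpha$value, function(g) ad_acc(alpha, g))
    inv <- ad_node(tape, 1 / total$value,
                   function(g) ad_acc(total, -g / total$value^2))
    h <- ad_smul(tape, inv, h)
  }
  h <- ad_groupnorm(tape, ad_gelu(tape, linear_fwd(tape, pn, "cls1", h)),
                    pn[["gn1.g"]], pn[["gn1.b"]], cfg$groupnorm_groups)
  h <- ad_groupnorm(tape, ad_gelu(tape, linear_fwd(tape, pn, "cls2", h)),
                    pn[["gn2.g"]], pn[["gn2.b"]], cfg$groupnorm_groups)
  linear_fwd(tape, pn, "cls3", h)
}

# transformer encoder for one global stream: FC, then conv -> GLU ->
# residual -> LayerNorm
transformer_stream_fwd <- function(tape, pn, cfg, name, x) {
  H0 <- linear_fwd(tape, pn, paste0("proj_", sub("enc_", "", name)), x)
  C <- ad_conv1d(tape, H0, pn[[paste0(name, ".conv.W")]],
                 pn[[paste0(name, ".conv.b")]], cfg$kernel_size)
  a <- linear_fwd(tape, pn, paste0(name, ".glu1"), C)
  g <- ad_sigmoid(tape, linear_fwd(tape, pn, paste0(name, ".glu2"), C))
  ln_fwd(tape, pn, paste0(name, ".ln"), ad_add(tape, H0, ad_mul(tape, a, g)))
}

transformer_forward <- function(tape, pn, cfg, xl, ml, xa, xb) {
  Hl <- linear_fwd(tape, pn, "proj_l", xl)
  mem <- ad_rbind2(tape,
                   transformer_stream_fwd(tape, pn, cfg, "enc_a", xa),
                   transformer_stream_fwd(tape, pn, cfg, "enc_b", xb))
  if (!any(ml == 1L)) stop("all-pad window", call. = FALSE)
  for (b in seq_len(cfg$decoder_blocks)) {
    nm <- paste0("dec", b)
    sa <- mha_fwd(tape, pn, paste0(nm, ".sa"), Hl, Hl, cfg$heads,
                  key_mask = ml == 1L)
    Hl <- ln_fwd(tape, pn, paste0(nm, ".ln1"), ad_add(tape, Hl, sa))
    ca <- mha_fwd(tape, pn, paste0(nm, ".ca"), Hl, mem, cfg$heads)
    Hl <- ln_fwd(tape, pn, paste0(nm, ".ln2"), ad_add(tape, Hl, ca))
    f <- linear_fwd(tape, pn, paste0(nm, ".ffn2"),
                    ad_gelu(tape, linear_fwd(tape, pn, paste0(nm, ".ffn1"), Hl)))
    Hl <- ln_fwd(tape, pn, paste0(nm, ".ln3"), ad_add(tape, Hl, f))
  }
  h <- ad_mean_rows(tape, Hl, ml == 1L)
  h <- ad_gelu(tape, linear_fwd(tape, pn, "cls1", h))
  h <- ad_gelu(tape, linear_fwd(tape, pn, "cls2", h))
  linear_fwd(tape, pn, "cls3", h)
}

# dispatch: sample is a list with the fields the architecture needs
model_logits <- function(tape, pn, model, sample) {
  cfg <- model$config
  switch(model$type,
    site = site_forward(tape, pn, cfg, ad_leaf(tape, sample$x), sample$pos),
    attcnn = attcnn_forward(tape, pn, cfg, ad_leaf(tape, sample$xl),
                            sample$ml, ad_leaf(tape, sample$xa),
                            ad_leaf(tape, sample$xb)),
    transformer = transformer_forward(tape, pn, cfg, ad_leaf(tape, sample$xl),
                                      sample$ml, ad_leaf(tape, sample$xa),
                                      ad_leaf(tape, sample$xb)),
    stop("unknown model type", call. = FALSE)
  )
}

softmax2 <- function(z) {
  z <- as.numeric(z)
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# n x 2 matrix of class probabilities for a list of samples
model_probs <- function(model, samples) {
  out <- matrix(0, length(samples), 2L)
  for (i in seq_along(samples)) {
    tape <- ad_tape()
    pn <- param_nodes(tape, model$params)
    logits <- model_logits(tape, pn, model, samples[[i]])
    if (any(!is.finite(logits$value))) {
      stop("non-finite logits in forward pass", call. = FALSE)
    }
    out[i, ] <- softmax2(logits$value)
  }
  out
}

#' Classify a site feature vector
#'
#' Applies a site model's three-layer classifier head (GELU between layers,
#' softmax output) to a `model_dim`-length feature vector. Probabilities
#' sum to 1; the hard label is the argmax with ties going to class 0.
#'
#' @param feature Numeric vector of length `model_dim`.
#' @param model A `phosppi_model` of type `"site"` (or any model carrying
#'   `cls1`..`cls3` layers of matching width).
#' @return A one-row tibble with `p0`, `p1` and `label`.
#' @export
classify_site <- function(feature, model) {
  stopifnot(all(is.finite(feature)))
  p <- model$params
  h <- matrix(as.numeric(feature), 1L)
  h <- gelu(sweep(h %*% p[["cls1.W"]], 2L, as.numeric(p[["cls1.b"]]), "+"))
  h <- gelu(sweep(h %*% p[["cls2.W"]], 2L, as.numeric(p[["cls2.b"]]), "+"))
  z <- sweep(h %*% p[["cls3.W"]], 2L, as.numeric(p[["cls3.b"]]), "+")
  pr <- softmax2(z)
  tibble::tibble(p0 = pr[1L], p1 = pr[2L], label = vote_label(pr[2L]))
}
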