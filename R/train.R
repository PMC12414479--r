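#' Training configuration
#'
#' @param epochs Number of passes over the training set.
#' @param learning_rate RAdam learning rate (default 5e-4).
#' @param batch_size Minibatch size (default 128; at least 2 for the
#'   batch-weighted loss).
#' @param seed Integer seed controlling shuffling (and, through
#'   [fit_site_model()]/[fit_effect_model()], weight initialization).
#' @param loss `"cross_entropy"` (task 1 default) or `"batch_weighted"`
#'   (task 2 default), the in-batch inverse-frequency weighting of
#'   [batch_weighted_ce()].
#' @param lookahead_k Lookahead synchronization period (default 5;
#'   `k <= 1` disables Lookahead, leaving plain RAdam).
#' @param lookahead_alpha Lookahead interpolation step (default 0.5).
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs, learning_rate = 5e-4, batch_size = 128L,
                         seed = 1L,
                         loss = c("cross_entropy", "batch_weighted"),
                         lookahead_k = 5L, lookahead_alpha = 0.5) {
  loss <- match.arg(loss)
  stopifnot(learning_rate > 0, epochs >= 1L,
            batch_size >= if (loss == "batch_weighted") 2L else 1L)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 loss = loss, lookahead_k = as.integer(lookahead_k),
                 lookahead_alpha = lookahead_alpha),
            class = "train_config")
}

# mean loss of a model over a sample list (no gradient)
eval_loss <- function(model, samples) {
  probs <- model_probs(model, samples)
  labels <- vapply(samples, `[[`, integer(1), "label")
  cross_entropy(probs, labels)
}

#' Train a model by minibatch gradient descent
#'
#' Runs seeded minibatch training with the RAdam optimizer wrapped in
#' Lookahead. When a validation sample list is supplied the parameters
#' from the epoch with the lowest validation loss are returned; otherwise
#' the final parameters.
#'
#' This is the engine underneath [fit_site_model()] and
#' [fit_effect_model()]; it operates on assembled sample lists
#' (see [assemble_site_samples()] / [assemble_effect_samples()]).
#'
#' @param model A `phosppi_model` from [new_model()].
#' @param samples List of training samples with integer `label` fields.
#' @param cfg A [train_config()].
#' @param validation Optional list of validation samples.
#' @return The model with trained `params` and a `history` tibble
#'   (`epoch`, `loss`, and `val_loss` when validation is supplied).
#' @export
train_model <- function(model, samples, cfg, validation = NULL) {
  stopifnot(inherits(cfg, "train_config"), length(samples) >= 1L)
  rng <- rng_local(derive_seed(cfg$seed, 101))
  opt <- radam_new(model$params, cfg$learning_rate,
                   lookahead_k = cfg$lookahead_k,
                   lookahead_alpha = cfg$lookahead_alpha)
  params <- model$params
  n <- length(samples)
  history <- vector("list", cfg$epochs)
  best <- list(loss = Inf, params = params, epoch = 0L)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- rng$shuffle(n)
    epoch_loss <- 0
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      labels <- vapply(samples[idx], `[[`, integer(1), "label")
      w <- batch_ce_weights(labels, cfg$loss)
      grads <- list()
      batch_loss <- 0
      for (j in seq_along(idx)) {
        tape <- ad_tape()
        pn <- param_nodes(tape, params)
        logits <- model_logits(tape, pn, list(type = model$type,
                                              config = model$config),
                               samples[[idx[j]]])
        lossnd <- ad_softmax_ce(tape, logits, labels[j])
        batch_loss <- batch_loss + w[j] * lossnd$value[1L]
        ad_backward(tape, lossnd, seed = w[j])
        for (nm in names(params)) {
          g <- pn[[nm]]$grad
          if (is.null(g)) next
          grads[[nm]] <- if (is.null(grads[[nm]])) g else grads[[nm]] + g
        }
      }
      if (!is.finite(batch_loss)) {
        stop("training loss became non-finite at epoch ", epoch, call. = FALSE)
      }
      params <- radam_step(opt, params, grads)
      epoch_loss <- epoch_loss + batch_loss * length(idx)
    }
    epoch_loss <- epoch_loss / n
    row <- tibble::tibble(epoch = epoch, loss = epoch_loss)
    if (!is.null(validation)) {
      model$params <- params
      vl <- eval_loss(model, validation)
      row$val_loss <- vl
      if (vl < best$loss) best <- list(loss = vl, params = params, epoch = epoch)
    }
    history[[epoch]] <- row
  }
  model$params <- if (!is.null(validation)) best$params else params
  model$history <- dplyr::bind_rows(history)
  model$best_epoch <- if (!is.null(validation)) best$epoch else cfg$epochs
  model
}

## ---- sample assembly -------------------------------------------------------

#' Assemble model-ready samples from tables
#'
#' `assemble_site_samples()` embeds each distinct protein once through the
#' backend and pairs every site record with its full-sequence embedding and
#' target row. `assemble_effect_samples()` additionally cuts the
#' `2 * half_width + 1` local window around the site on protein A.
#'
#' @param sites Tibble of site records.
#' @param pairs Tibble of interaction-effect records.
#' @param proteins Tibble of protein records.
#' @param backend A `phosppi_backend`.
#' @param half_width Window half-width for the local stream (default 15).
#' @param cache_dir Optional embedding cache directory.
#' @return A list of samples consumable by [train_model()].
#' @export
assemble_site_samples <- function(sites, proteins, backend, cache_dir = NULL) {
  sites <- validate_sites(sites, proteins)
  embs <- embed_all(proteins, unique(sites$protein_id), backend, cache_dir)
  lapply(seq_len(nrow(sites)), function(i) {
    emb <- embs[[sites$protein_id[i]]]
    if (sites$position[i] > nrow(emb$values)) {
      stop(sprintf("site %s:%d lies beyond the truncated embedding",
                   sites$protein_id[i], sites$position[i]), call. = FALSE)
    }
    list(x = emb$values, pos = sites$position[i], label = sites$label[i])
  })
}

#' @rdname assemble_site_samples
#' @export
assemble_effect_samples <- function(pairs, proteins, backend,
                                    half_width = 15L, cache_dir = NULL) {
  pairs <- validate_pairs(pairs, proteins)
  ids <- unique(c(pairs$protein_a_id, pairs$protein_b_id))
  embs <- embed_all(proteins, ids, backend, cache_dir)
  seqs <- stats::setNames(proteins$sequence, proteins$id)
  lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$protein_a_id[i]
    w <- extract_window(list(id = a, sequence = seqs[[a]]),
                        pairs$position[i], half_width)
    w <- window_embedding(w, embs[[a]])
    list(xl = w$window_emb, ml = w$mask,
         xa = embs[[a]]$values,
         xb = embs[[pairs$protein_b_id[i]]]$values,
         label = pairs$label[i])
  })
}

embed_all <- function(proteins, ids, backend, cache_dir = NULL) {
  idx <- match(ids, proteins$id)
  if (anyNA(idx)) {
    stop("unknown protein id: ", ids[which(is.na(idx))[1L]], call. = FALSE)
  }
  out <- lapply(idx, function(i) {
    embed_sequence(backend, proteins[i, ], cache_dir)
  })
  stats::setNames(out, ids)
}
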