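#' Fit the functional-site classifier
#'
#' Trains the conv-encoder / attention-decoder site model on a table of
#' candidate S/T/Y sites. Each protein is embedded once through the
#' backend; the model classifies each site from the full-sequence embedding
#' with the target residue as the decoder query.
#'
#' @param sites Tibble of site records (`protein_id`, `position`,
#'   `residue`, `label`).
#' @param proteins Tibble of protein records (`id`, `sequence`).
#' @param backend A `phosppi_backend` (default [mock_backend()]).
#' @param epochs Training epochs.
#' @param config Optional [site_model_config()]; defaults to the standard
#'   configuration at the backend's dimension.
#' @param train_cfg Optional [train_config()]; defaults to the standard
#'   settings (learning rate 5e-4, batch 128, cross-entropy loss).
#' @param validation_sites Optional site tibble; when given, the epoch with
#'   the lowest validation loss supplies the returned parameters.
#' @param seed Integer seed for initialization and shuffling.
#' @param cache_dir Optional embedding cache directory.
#' @return A `phosppi_site_fit` object supporting [predict()],
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @export
fit_site_model <- function(sites, proteins, backend = mock_backend(),
                           epochs = 60L, config = NULL, train_cfg = NULL,
                           validation_sites = NULL, seed = 1L,
                           cache_dir = NULL) {
  if (is.null(config)) config <- site_model_config(backend$dim)
  if (is.null(train_cfg)) train_cfg <- train_config(epochs, seed = seed)
  samples <- assemble_site_samples(sites, proteins, backend, cache_dir)
  val <- if (!is.null(validation_sites)) {
    assemble_site_samples(validation_sites, proteins, backend, cache_dir)
  }
  model <- train_model(new_model(config, seed), samples, train_cfg, val)
  structure(list(model = model, backend = backend, train_cfg = train_cfg,
                 n_train = length(samples)),
            class = c("phosppi_site_fit", "phosppi_fit"))
}

#' Fit an interaction-effect submodel
#'
#' Trains one of the two effect architectures — the attention-gated CNN
#' (`"attcnn"`) or the cross-attention transformer (`"transformer"`) — on
#' a table of (protein A, protein B, site) records, using the batch-weighted
#' cross-entropy by default to counter the enhancement/inhibition
#' imbalance.
#'
#' @param pairs Tibble of effect records (`protein_a_id`, `protein_b_id`,
#'   `position`, `label`; 1 = enhancement).
#' @param architecture `"attcnn"` or `"transformer"`.
#' @param half_width Local-window half-width (default 15, i.e. 31 residues).
#' @param validation_pairs Optional effect tibble for best-epoch selection.
#' @inheritParams fit_site_model
#' @return A `phosppi_effect_fit` object.
#' @export
fit_effect_model <- function(pairs, proteins,
                             architecture = c("attcnn", "transformer"),
                             backend = mock_backend(), epochs = 90L,
                             config = NULL, train_cfg = NULL,
                             validation_pairs = NULL, half_width = 15L,
                             seed = 1L, cache_dir = NULL) {
  architecture <- match.arg(architecture)
  if (is.null(config)) {
    config <- if (architecture == "attcnn") attcnn_config(backend$dim)
              else transformer_config(backend$dim)
  }
  if (is.null(train_cfg)) {
    train_cfg <- train_config(epochs, seed = seed, loss = "batch_weighted")
  }
  samples <- assemble_effect_samples(pairs, proteins, backend, half_width,
                                     cache_dir)
  val <- if (!is.null(validation_pairs)) {
    assemble_effect_samples(validation_pairs, proteins, backend, half_width,
                            cache_dir)
  }
  model <- train_model(new_model(config, seed), samples, train_cfg, val)
  structure(list(model = model, backend = backend, train_cfg = train_cfg,
                 architecture = architecture, half_width = half_width,
                 n_train = length(samples)),
            class = c("phosppi_effect_fit", "phosppi_fit"))
}

#' @export
print.phosppi_fit <- function(x, ...) {
  cat(sprintf("<%s> %s model, %d training samples, %d epochs (final loss %.4f)\n",
              class(x)[1L], x$model$type, x$n_train,
              nrow(x$model$history), utils::tail(x$model$history$loss, 1L)))
  invisible(x)
}

#' Predict functional-site probabilities
#'
#' @param object A `phosppi_site_fit`.
#' @param sites Tibble of candidate site records.
#' @param proteins Tibble of protein records.
#' @param cache_dir Optional embedding cache directory.
#' @param ... Unused.
#' @return `sites` with columns `p_functional` and `label_pred`.
#' @export
predict.phosppi_site_fit <- function(object, sites, proteins,
                                     cache_dir = NULL, ...) {
  samples <- assemble_site_samples(sites, proteins, object$backend, cache_dir)
  probs <- model_probs(object$model, samples)
  dplyr::mutate(tibble::as_tibble(sites),
                p_functional = probs[, 2L],
                label_pred = vote_label(probs[, 2L]))
}

#' Predict interaction-effect probabilities
#'
#' @param object A `phosppi_effect_fit`.
#' @param pairs Tibble of effect records.
#' @inheritParams predict.phosppi_site_fit
#' @return `pairs` with columns `p_enhancement` and `label_pred`.
#' @export
predict.phosppi_effect_fit <- function(object, pairs, proteins,
                                       cache_dir = NULL, ...) {
  samples <- assemble_effect_samples(pairs, proteins, object$backend,
                                     object$half_width, cache_dir)
  probs <- model_probs(object$model, samples)
  dplyr::mutate(tibble::as_tibble(pairs),
                p_enhancement = probs[, 2L],
                label_pred = vote_label(probs[, 2L]))
}

#' Ensemble prediction from the two effect submodels
#'
#' Scores the pair table with both fitted submodels and fuses them with
#' the chosen voting mechanism (soft voting by default).
#'
#' @param fit_a,fit_b The two `phosppi_effect_fit` objects (typically the
#'   attcnn and transformer submodels).
#' @param pairs Tibble of effect records.
#' @param proteins Tibble of protein records.
#' @param vote `"soft"`, `"hard"` or `"max_confidence"`.
#' @param threshold Decision threshold (default 0.5).
#' @param cache_dir Optional embedding cache directory.
#' @return `pairs` with per-submodel probabilities (`p_a`, `p_b`), the
#'   fused `p_enhancement` (label votes only, for hard voting) and
#'   `label_pred`.
#' @export
predict_effect_ensemble <- function(fit_a, fit_b, pairs, proteins,
                                    vote = c("soft", "hard", "max_confidence"),
                                    threshold = 0.5, cache_dir = NULL) {
  vote <- match.arg(vote)
  pa <- predict(fit_a, pairs, proteins, cache_dir)$p_enhancement
  pb <- predict(fit_b, pairs, proteins, cache_dir)$p_enhancement
  m1 <- cbind(1 - pa, pa)
  m2 <- cbind(1 - pb, pb)
  out <- tibble::as_tibble(pairs)
  out$p_a <- pa
  out$p_b <- pb
  if (vote == "soft") {
    v <- soft_vote(m1, m2, threshold)
    out$p_enhancement <- v$p1
    out$label_pred <- v$label
  } else if (vote == "max_confidence") {
    v <- max_confidence_vote(m1, m2, threshold)
    out$p_enhancement <- v$p1
    out$label_pred <- v$label
  } else {
    out$p_enhancement <- (pa + pb) / 2  # reported score; labels are voted
    out$label_pred <- hard_vote(m1, m2, threshold)
  }
  out
}

## ---- broom-style methods ---------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-epoch training history of a fit
#'
#' @param x A `phosppi_fit`.
#' @param ... Unused.
#' @return A tibble with `epoch`, `loss` and, when validation was
#'   supplied, `val_loss`.
#' @export
tidy.phosppi_fit <- function(x, ...) {
  x$model$history
}

#' One-row summary of a fit
#'
#' @param x A `phosppi_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the architecture, parameter count,
#'   training size, epochs, final loss and best epoch.
#' @export
glance.phosppi_fit <- function(x, ...) {
  tibble::tibble(
    architecture = x$model$type,
    n_parameters = sum(vapply(x$model$params, length, integer(1))),
    n_train = x$n_train,
    epochs = nrow(x$model$history),
    final_loss = utils::tail(x$model$history$loss, 1L),
    best_epoch = x$model$best_epoch
  )
}

#' Training-curve plot of a fit
#'
#' @param object A `phosppi_fit`.
#' @param ... Unused.
#' @return A [ggplot2::ggplot] of loss (and validation loss) per epoch.
#' @export
autoplot.phosppi_fit <- function(object, ...) {
  h <- tidy(object)
  long <- tidyr::pivot_longer(h, -"epoch", names_to = "series",
                              values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}

## ---- checkpoints ------------------------------------------------------------

#' Save and load model checkpoints
#'
#' Checkpoints are plain JSON: a flat named-parameter archive plus the
#' configuration, so they survive text-only storage and diffing.
#'
#' @param fit A `phosppi_fit` (or bare `phosppi_model`).
#' @param path Output / input file path.
#' @return `write_checkpoint()` returns `path` invisibly;
#'   `read_checkpoint()` returns a `phosppi_model`.
#' @export
write_checkpoint <- function(fit, path) {
  model <- if (inherits(fit, "phosppi_fit")) fit$model else fit
  stopifnot(inherits(model, "phosppi_model"))
  params <- lapply(model$params, function(p) {
    list(dim = dim(p), data = as.numeric(p))
  })
  jsonlite::write_json(
    list(type = model$type,
         config_class = class(model$config)[1L],
         config = unclass(model$config),
         params = params),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  ck <- jsonlite::read_json(path, simplifyVector = TRUE)
  maker <- switch(ck$config_class,
                  site_model_config = site_model_config,
                  attcnn_config = attcnn_config,
                  transformer_config = transformer_config,
                  stop("unknown config class in checkpoint", call. = FALSE))
  cfg_args <- ck$config[names(ck$config) %in% names(formals(maker))]
  config <- do.call(maker, cfg_args)
  params <- lapply(ck$params, function(p) {
    matrix(p$data, p$dim[1L], p$dim[2L])
  })
  structure(list(type = ck$type, config = config, params = params),
            class = "phosppi_model")
}
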