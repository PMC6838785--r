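#' Training configuration
#'
#' Bundles the hyperparameters of the classifier training loop. Defaults
#' follow the method's published settings where stated (dropout 0.2, Adam
#' with learning rate 0.001, up to 100 epochs) and documented package
#' choices elsewhere (hidden size 64 per direction, batch size 128, 10%
#' stratified validation split for checkpointing).
#'
#' @param dropout Dropout rate applied to each BiGRU layer's output during
#'   training, in `[0, 1)`.
#' @param learning_rate Adam learning rate.
#' @param epochs Maximum number of epochs (>= 1).
#' @param batch_size Minibatch size.
#' @param hidden Hidden units per direction per layer.
#' @param layers Number of stacked bidirectional layers.
#' @param validation_fraction Fraction of records held out (stratified) for
#'   the best-epoch checkpoint; ignored when a validation set is supplied.
#' @param seed Integer seed controlling initialization, the split, batch
#'   order and dropout masks.
#' @return A list of class `training_config`.
#' @export
training_config <- function(dropout = 0.2, learning_rate = 1e-3, epochs = 100L,
                            batch_size = 128L, hidden = 64L, layers = 3L,
                            validation_fraction = 0.1, seed = 1L) {
  stopifnot(dropout >= 0, dropout < 1, epochs >= 1, batch_size >= 1,
            hidden >= 1, layers >= 1,
            validation_fraction >= 0, validation_fraction < 1)
  structure(
    list(dropout = dropout, learning_rate = learning_rate,
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         hidden = as.integer(hidden), layers = as.integer(layers),
         validation_fraction = validation_fraction, seed = as.integer(seed)),
    class = "training_config"
  )
}

check_pair_frame <- function(pairs) {
  need <- c("allele", "peptide", "label")
  miss <- setdiff(need, names(pairs))
  if (length(miss) > 0L) {
    abort(sprintf("pairs must have columns %s; missing: %s",
                  paste(need, collapse = ", "), paste(miss, collapse = ", ")))
  }
  if (nrow(pairs) == 0L) abort("pairs is empty")
  if (!all(pairs$label %in% c(0, 1))) abort("label must be binary (0/1)")
  if (length(unique(pairs$label)) < 2L) {
    abort("pairs contains a single class; both binders and non-binders are required")
  }
  invisible(pairs)
}

# Stratified index split: returns validation indices.
stratified_validation_idx <- function(labels, fraction) {
  idx <- integer(0)
  for (cl in unique(labels)) {
    pool <- which(labels == cl)
    k <- max(1L, round(length(pool) * fraction))
    idx <- c(idx, sample(pool, k))
  }
  sort(idx)
}

#' Train the BiGRU-attention classifier on labeled HLA-peptide pairs
#'
#' Fits the stacked bidirectional GRU with attention by minimizing binary
#' cross-entropy with Adam. Dropout is applied to each recurrent layer's
#' output during training only. After every epoch the model is evaluated on
#' a held-out validation set and the parameter snapshot with the best
#' validation accuracy so far is retained; the returned model carries that
#' snapshot, not the last epoch's. The whole run is reproducible given
#' `config$seed`.
#'
#' @param pairs A data frame with columns `allele`, `peptide` and binary
#'   `label` (1 = positive). Both classes must be present.
#' @param pseudo Pseudo-sequence table from [load_pseudo_sequences()] or
#'   [make_alleles()].
#' @param config A [training_config()].
#' @param validation Optional data frame of the same shape used for
#'   checkpointing instead of an internal split.
#' @return An object of class `hla_model`: the best network, the final
#'   network, a per-epoch training log, and the configuration.
#' @export
#' @seealso [hla_predict()], [tidy.hla_model()], [glance.hla_model()]
hla_train <- function(pairs, pseudo, config = training_config(),
                      validation = NULL) {
  pairs <- as_tibble(pairs)
  check_pair_frame(pairs)
  withr::local_seed(config$seed)
  if (is.null(validation)) {
    if (config$validation_fraction <= 0) {
      abort("validation_fraction must be > 0 when no validation set is supplied")
    }
    vi <- stratified_validation_idx(pairs$label, config$validation_fraction)
    validation <- pairs[vi, ]
    train <- pairs[-vi, ]
  } else {
    validation <- as_tibble(validation)
    train <- pairs
  }
  if (length(unique(train$label)) < 2L) {
    abort("training split contains a single class")
  }
  x_train <- encode_batch(train$peptide, train$allele, pseudo)
  y_train <- as.numeric(train$label)
  x_val <- encode_batch(validation$peptide, validation$allele, pseudo)
  y_val <- as.numeric(validation$label)

  net <- new_network(input_dim = length(aa_alphabet()), hidden = config$hidden,
                     layers = config$layers, seed = config$seed)
  params <- net[c("layers", "attn", "out")]
  opt <- adam_init(params)
  n <- length(y_train)
  best_acc <- -Inf
  best_params <- params
  log <- vector("list", config$epochs)

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1L, n, by = config$batch_size)) {
      take <- ord[start:min(start + config$batch_size - 1L, n)]
      xb <- x_train[take, , , drop = FALSE]
      yb <- y_train[take]
      net[c("layers", "attn", "out")] <- params
      fw <- network_forward(xb, net, dropout = config$dropout,
                            training = TRUE, keep_cache = TRUE)
      losses <- c(losses, bce_loss(fw$p, yb))
      dlogits <- (fw$p - yb) / length(yb)
      grads <- network_backward(dlogits, fw, net)
      upd <- adam_update(params, grads, opt, lr = config$learning_rate)
      params <- upd$params
      opt <- upd$state
    }
    net[c("layers", "attn", "out")] <- params
    p_val <- predict_in_batches(x_val, net)
    acc <- mean((p_val >= 0.5) == y_val)
    if (acc > best_acc) {
      best_acc <- acc
      best_params <- params
    }
    log[[epoch]] <- tibble(epoch = epoch, train_loss = mean(losses),
                           val_accuracy = acc)
  }
  net[c("layers", "attn", "out")] <- best_params
  final_net <- net
  structure(
    list(network = final_net, last_params = params,
         log = dplyr::bind_rows(log), config = config,
         best_val_accuracy = best_acc, alphabet = aa_alphabet(),
         n_train = n, n_validation = length(y_val)),
    class = "hla_model"
  )
}

predict_in_batches <- function(x, net, batch = 256L) {
  n <- dim(x)[1L]
  if (n == 0L) return(numeric(0))
  out <- numeric(n)
  for (start in seq(1L, n, by = batch)) {
    take <- start:min(start + batch - 1L, n)
    out[take] <- network_forward(x[take, , , drop = FALSE], net)$p
  }
  out
}

#' Score HLA-peptide pairs with a trained model
#'
#' @param pairs A data frame with columns `allele` and `peptide`.
#' @param model An `hla_model` from [hla_train()].
#' @param pseudo Pseudo-sequence table; every allele in `pairs` must be
#'   present.
#' @return The input tibble with a `score` column appended, rows in input
#'   order.
#' @export
hla_predict <- function(pairs, model, pseudo) {
  pairs <- as_tibble(pairs)
  if (nrow(pairs) == 0L) {
    return(dplyr::mutate(pairs, score = numeric(0)))
  }
  unknown <- which(!pairs$allele %in% pseudo$allele)
  if (length(unknown) > 0L) {
    abort(sprintf("unknown allele '%s' at pair index %d",
                  pairs$allele[unknown[1L]], unknown[1L]))
  }
  x <- encode_batch(pairs$peptide, pairs$allele, pseudo)
  dplyr::mutate(pairs, score = predict_in_batches(x, model$network))
}

#' Score peptide/allele vectors with a trained model
#'
#' Vector convenience wrapper around [hla_predict()]; scores are returned
#' in input order and equal the per-pair forward-pass results.
#'
#' @param peptides,alleles Character vectors of equal length.
#' @inheritParams hla_predict
#' @return Numeric vector of scores in (0, 1).
#' @export
predict_scores <- function(peptides, alleles, model, pseudo) {
  if (length(peptides) == 0L) return(numeric(0))
  hla_predict(tibble(allele = alleles, peptide = peptides), model, pseudo)$score
}

#' @export
print.hla_model <- function(x, ...) {
  cat(sprintf(
    "<hla_model> %d-layer BiGRU(%d/dir)+attention | %d training pairs | best val acc %.3f\n",
    x$config$layers, x$config$hidden, x$n_train, x$best_val_accuracy))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the training log of a fitted model
#'
#' @param x An `hla_model`.
#' @param ... Unused.
#' @return A tibble with one row per epoch: `epoch`, `train_loss`,
#'   `val_accuracy`.
#' @method tidy hla_model
#' @export
tidy.hla_model <- function(x, ...) x$log

#' One-row summary of a fitted model
#'
#' @param x An `hla_model`.
#' @param ... Unused.
#' @return A one-row tibble: layer/hidden dimensions, epochs run, final
#'   training loss, best validation accuracy.
#' @method glance hla_model
#' @export
glance.hla_model <- function(x, ...) {
  tibble(
    layers = x$config$layers, hidden = x$config$hidden,
    epochs = nrow(x$log), n_train = x$n_train,
    n_validation = x$n_validation,
    final_train_loss = x$log$train_loss[nrow(x$log)],
    best_val_accuracy = x$best_val_accuracy
  )
}

#' Save / load a fitted model
#'
#' Models are stored as a single self-describing RDS file: the object
#' embeds the alphabet ordering, layer dimensions and full training
#' configuration, so a loaded model carries everything needed to validate
#' inputs against it.
#'
#' @param model An `hla_model`.
#' @param path File path.
#' @return `write_model` returns `path` invisibly; `read_model` returns the
#'   model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "hla_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "hla_model")) abort("file does not contain an hla_model")
  if (!identical(m$alphabet, aa_alphabet())) {
    abort("model alphabet does not match this package's alphabet ordering")
  }
  m
}

#' Plot the training log
#'
#' @param object An `hla_model`.
#' @param ... Unused.
#' @return A ggplot: training loss and validation accuracy per epoch.
#' @method autoplot hla_model
#' @export
autoplot.hla_model <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log, c("train_loss", "val_accuracy"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}
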