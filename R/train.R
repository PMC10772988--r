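#' Fit the temperature-dependent kcat model
#'
#' End-to-end training on a kinetics table: entry-level split, oversampling
#' of sparse temperature ranges on the training partition only, vocabulary
#' and normalization fitting on the training partition, then mini-batch Adam
#' on the mean squared error of log10(kcat). The checkpoint with the best
#' validation RMSE is retained alongside the final parameters.
#'
#' @param data Kinetics data frame (`smiles`, `sequence`, `temperature_C`,
#'   `kcat_s`).
#' @param config A [model_config()]; defaults to the `"small"` preset.
#' @param control A [train_config()].
#' @param oversample Apply low/high-temperature oversampling to the training
#'   partition (default TRUE).
#' @param split_by `"entry"` or `"protein"` (passed to [split_kinetics()]).
#' @param verbose Print per-epoch metrics.
#' @return A fitted `kcat_model` object; see [tidy.kcat_model()],
#'   [glance.kcat_model()], [predict.kcat_model()].
#' @export
train_kcat_model <- function(data, config = model_config("small"),
                             control = train_config(), oversample = TRUE,
                             split_by = "entry", verbose = FALSE) {
  data <- validate_kinetics(data)
  splits <- split_kinetics(data, control$split_fractions, seed = control$seed,
                           by = split_by)
  train_df <- splits$train
  if (oversample) {
    train_df <- oversample_kinetics(train_df, seed = control$seed)
  }

  stats <- fit_thermo_stats(train_df$temperature_C)
  atom_vocab <- new_vocab()
  kmer_vocab <- new_vocab()
  train_feats <- featurize_kinetics(train_df, atom_vocab, kmer_vocab, stats)
  vocab_freeze(atom_vocab); vocab_freeze(kmer_vocab)
  val_feats <- featurize_kinetics(splits$val, atom_vocab, kmer_vocab, stats)

  params <- init_model_params(config, vocab_size(atom_vocab),
                              vocab_size(kmer_vocab), seed = control$seed)
  opt <- adam_init(params)
  y_train <- train_df$log10_kcat
  y_val <- splits$val$log10_kcat
  n <- length(train_feats)
  history <- list()
  best <- list(rmse = Inf, params = params, epoch = 0L)

  for (epoch in seq_len(control$epochs)) {
    lr <- learning_rate_schedule(epoch - 1L, control$lr0, control$lr_decay,
                                 control$decay_every)
    order_idx <- withr::with_seed(control$seed + epoch, sample(n))
    batches <- split(order_idx, ceiling(seq_along(order_idx) / control$batch_size))
    for (b in batches) {
      step <- batch_gradients(train_feats[b], y_train[b], params, config)
      if (!is.finite(step$loss)) {
        abort(sprintf(
          "Training diverged (non-finite loss) at epoch %d; try a lower learning rate",
          epoch))
      }
      params <- adam_step(opt, params, step$grads, lr)
    }

    pred_tr <- forward_many(train_feats, params, config)
    pred_va <- forward_many(val_feats, params, config)
    m_tr <- suppressWarnings(eval_metrics(pred_tr, y_train))
    m_va <- suppressWarnings(eval_metrics(pred_va, y_val))
    history[[length(history) + 1]] <- dplyr::bind_rows(
      dplyr::mutate(m_tr, split = "train"),
      dplyr::mutate(m_va, split = "val")
    ) |> dplyr::mutate(epoch = epoch, lr = lr)
    if (is.finite(m_va$rmse) && m_va$rmse < best$rmse) {
      best <- list(rmse = m_va$rmse, params = params, epoch = epoch)
    }
    if (verbose) {
      message(sprintf(
        "epoch %3d  lr %.5f | train rmse %.4f r2 %.3f | val rmse %.4f r2 %.3f",
        epoch, lr, m_tr$rmse, m_tr$r2, m_va$rmse, m_va$r2))
    }
  }

  structure(list(
    params = params,
    best_params = best$params,
    best_epoch = best$epoch,
    config = config,
    control = control,
    atom_vocab = atom_vocab,
    kmer_vocab = kmer_vocab,
    thermo_stats = stats,
    history = dplyr::bind_rows(history) |>
      dplyr::select("epoch", "split", "rmse", "mae", "r2", "lr"),
    splits = splits
  ), class = "kcat_model")
}

# Forward-only predictions for a list of featurized samples.
forward_many <- function(feats, params, cfg) {
  vapply(feats, function(f) forward_sample(f, params, cfg)$y, numeric(1))
}

# One mini-batch: mean-squared-error loss and its gradient tree.
batch_gradients <- function(feats, y, params, cfg) {
  B <- length(feats)
  g_dense <- NULL
  g_atom <- matrix(0, nrow(params$atom_emb), ncol(params$atom_emb))
  g_kmer <- matrix(0, nrow(params$kmer_emb), ncol(params$kmer_emb))
  loss <- 0
  for (i in seq_len(B)) {
    fw <- forward_sample(feats[[i]], params, cfg, cache = TRUE)
    err <- fw$y - y[i]
    loss <- loss + err^2 / B
    bs <- backward_sample(fw$cache, 2 * err / B, params, cfg)
    g_dense <- if (is.null(g_dense)) bs$grads else {
      tree_map(`+`, g_dense, bs$grads)
    }
    a <- bs$atom_emb_rows
    g_atom[a$idx, ] <- g_atom[a$idx, , drop = FALSE] + a$rows
    k <- bs$kmer_emb_rows
    g_kmer[k$idx, ] <- g_kmer[k$idx, , drop = FALSE] + k$rows
  }
  grads <- c(list(atom_emb = g_atom, kmer_emb = g_kmer), g_dense)
  list(loss = loss, grads = grads[names(params)])
}

# Featurize each row of a kinetics table, caching unique compounds and
# sequences.
featurize_kinetics <- function(data, atom_vocab, kmer_vocab, stats,
                               quiet = TRUE) {
  graphs <- lapply(unique(data$smiles), smiles_to_graph, atom_vocab = atom_vocab)
  names(graphs) <- unique(data$smiles)
  toks <- lapply(unique(data$sequence), protein_to_kmers, kmer_vocab = kmer_vocab)
  names(toks) <- unique(data$sequence)
  lapply(seq_len(nrow(data)), function(i) {
    g <- graphs[[data$smiles[i]]]
    tk <- toks[[data$sequence[i]]]
    th <- normalize_temperature(data$temperature_C[i], stats, quiet = quiet)
    list(atom_tokens = g$atom_tokens, edges = g$edges,
         kmer_tokens = tk$kmer_tokens, fingerprint = g$fingerprint,
         t_norm = th$t_norm, invt_norm = th$invt_norm)
  })
}

#' Predict log10(kcat) for new substrate/enzyme/temperature rows
#'
#' @param object A fitted `kcat_model`.
#' @param newdata Data frame with `smiles`, `sequence`, `temperature_C`.
#' @param use_best Use the best-validation-RMSE checkpoint (default) rather
#'   than the final epoch's parameters.
#' @param ... Unused.
#' @return `newdata` as a tibble with added columns `pred_log10_kcat` and
#'   `pred_kcat_s`.
#' @export
predict.kcat_model <- function(object, newdata, use_best = TRUE, ...) {
  need <- c("smiles", "sequence", "temperature_C")
  miss <- setdiff(need, names(newdata))
  if (length(miss) > 0) {
    abort(paste("newdata is missing column(s):", paste(miss, collapse = ", ")))
  }
  params <- if (use_best) object$best_params else object$params
  feats <- featurize_kinetics(newdata, object$atom_vocab, object$kmer_vocab,
                              object$thermo_stats)
  pred <- forward_many(feats, params, object$config)
  tibble::as_tibble(newdata) |>
    dplyr::mutate(pred_log10_kcat = pred, pred_kcat_s = 10^pred)
}

#' Evaluate a fitted model on a labelled kinetics table
#'
#' @param object A fitted `kcat_model`.
#' @param data Kinetics data frame with `kcat_s`.
#' @param ... Passed to [predict.kcat_model()].
#' @return One-row metrics tibble ([eval_metrics()]).
#' @export
evaluate_kcat_model <- function(object, data, ...) {
  data <- validate_kinetics(data)
  pred <- predict(object, data, ...)
  eval_metrics(pred$pred_log10_kcat, data$log10_kcat)
}

#' @export
print.kcat_model <- function(x, ...) {
  last <- dplyr::filter(x$history, .data$epoch == max(.data$epoch))
  va <- dplyr::filter(last, .data$split == "val")
  cat(sprintf(
    "<kcat_model: %d epochs | d=%d, %d attention heads | best val RMSE %.4f (epoch %d)>\n",
    max(x$history$epoch), x$config$d, x$config$attn_heads,
    min(dplyr::filter(x$history, .data$split == "val")$rmse), x$best_epoch))
  if (nrow(va) > 0) {
    cat(sprintf("  final val: rmse %.4f, mae %.4f, r2 %.4f\n",
                va$rmse, va$mae, va$r2))
  }
  invisible(x)
}

#' @describeIn train_kcat_model Per-epoch training history as a tibble
#'   (columns epoch, split, rmse, mae, r2, lr).
#' @param x A fitted `kcat_model`.
#' @export
tidy.kcat_model <- function(x, ...) x$history

#' @describeIn train_kcat_model One-row model summary: best validation RMSE
#'   and epoch, final metrics, parameter count.
#' @export
glance.kcat_model <- function(x, ...) {
  val <- dplyr::filter(x$history, .data$split == "val")
  fin <- dplyr::filter(val, .data$epoch == max(.data$epoch))
  tibble::tibble(
    epochs = max(x$history$epoch),
    n_parameters = tree_count(x$params),
    best_epoch = x$best_epoch,
    best_val_rmse = min(val$rmse),
    val_rmse = fin$rmse, val_mae = fin$mae, val_r2 = fin$r2
  )
}

#' @describeIn train_kcat_model Training-history curves (RMSE and R2 per
#'   epoch and split).
#' @export
autoplot.kcat_model <- function(object, ...) {
  hist_long <- tidyr::pivot_longer(object$history, c("rmse", "r2"),
                                   names_to = "metric")
  ggplot2::ggplot(hist_long,
                  ggplot2::aes(x = .data$epoch, y = .data$value,
                               colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "log10(kcat) regression during training") +
    ggplot2::theme_minimal()
}
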