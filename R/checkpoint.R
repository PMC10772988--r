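#' Save and load fitted models
#'
#' Checkpoints carry the model configuration, all learnable parameters (the
#' final and the best-validation sets), both token vocabularies and the
#' temperature-normalization statistics, plus a format version. Loading
#' verifies that the stored parameter shapes match the stored configuration
#' and fails loudly on any mismatch.
#'
#' @param object A fitted `kcat_model`.
#' @param path File path (RDS).
#' @export
save_kcat_model <- function(object, path) {
  stopifnot(inherits(object, "kcat_model"))
  payload <- list(
    format_version = 1L,
    config = object$config,
    control = object$control,
    params = object$params,
    best_params = object$best_params,
    best_epoch = object$best_epoch,
    atom_vocab = vocab_to_list(object$atom_vocab),
    kmer_vocab = vocab_to_list(object$kmer_vocab),
    thermo_stats = object$thermo_stats,
    history = object$history
  )
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_kcat_model
#' @export
load_kcat_model <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$format_version, 1L)) {
    abort(sprintf("Unsupported checkpoint format version: %s",
                  payload$format_version %||% "<missing>"))
  }
  check_param_shapes(payload$params, payload$config,
                     length(payload$atom_vocab$map),
                     length(payload$kmer_vocab$map))
  structure(list(
    params = payload$params,
    best_params = payload$best_params,
    best_epoch = payload$best_epoch,
    config = payload$config,
    control = payload$control,
    atom_vocab = vocab_from_list(payload$atom_vocab),
    kmer_vocab = vocab_from_list(payload$kmer_vocab),
    thermo_stats = payload$thermo_stats,
    history = payload$history
  ), class = "kcat_model")
}

check_param_shapes <- function(params, cfg, atom_vocab_size, kmer_vocab_size) {
  expect_dim <- function(m, nr, nc, what) {
    if (!is.matrix(m) || nrow(m) != nr || ncol(m) != nc) {
      abort(sprintf(
        "Checkpoint/config mismatch: %s should be %d x %d", what, nr, nc),
        class = "thermokcat_checkpoint_error")
    }
  }
  expect_dim(params$atom_emb, atom_vocab_size, cfg$H_c, "atom embedding table")
  expect_dim(params$kmer_emb, kmer_vocab_size, cfg$H_p, "k-mer embedding table")
  if (length(params$gat) != cfg$gat_heads ||
      length(params$attn) != cfg$attn_heads ||
      length(params$conv) != cfg$conv_layers ||
      length(params$dense) != cfg$dense_layers) {
    abort("Checkpoint/config mismatch: head or layer counts differ",
          class = "thermokcat_checkpoint_error")
  }
  expect_dim(params$gat[[1]]$W, cfg$H_c, cfg$H_c_prime, "GAT transform")
  expect_dim(params$attn[[1]]$Wv, cfg$H_c, cfg$d, "attention W_v")
  expect_dim(params$attn[[1]]$Wr, cfg$H_p, cfg$d, "attention W_r")
  invisible(TRUE)
}
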