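# Learnable parameters, stored as a nested list of plain matrices/vectors.
# Weight matrices are oriented for right-multiplication (input x output), so
# a paper-style map W in R^{d x H} acting as W v appears here as its
# transpose.

xavier <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Initialize model parameters
#'
#' @param cfg A [model_config()].
#' @param atom_vocab_size,kmer_vocab_size Embedding-table sizes (including
#'   the unknown token at index 1).
#' @param seed Integer RNG seed.
#' @return A `model_params` nested list.
#' @export
init_model_params <- function(cfg, atom_vocab_size, kmer_vocab_size,
                              seed = 1L) {
  set.seed(seed)
  Hc <- cfg$H_c; Hcp <- cfg$H_c_prime; Hp <- cfg$H_p; d <- cfg$d
  K <- cfg$conv_kernel
  emb_init <- function(V, H) matrix(runif(V * H, -sqrt(3 / H), sqrt(3 / H)), V, H)
  p <- list(
    atom_emb = emb_init(atom_vocab_size, Hc),
    kmer_emb = emb_init(kmer_vocab_size, Hp),
    gat = lapply(seq_len(cfg$gat_heads), function(h) list(
      W = xavier(Hc, Hcp),
      a_self = runif(Hcp, -0.1, 0.1),
      a_nbr = runif(Hcp, -0.1, 0.1)
    )),
    gat_proj = list(W = xavier(cfg$gat_heads * Hcp, Hc), b = numeric(Hc)),
    conv = lapply(seq_len(cfg$conv_layers), function(l) list(
      W = xavier(K * Hp, Hp), b = numeric(Hp)
    )),
    fp = list(W1 = xavier(1024L, cfg$fp_hidden), b1 = numeric(cfg$fp_hidden),
              W2 = xavier(cfg$fp_hidden, Hc), b2 = numeric(Hc)),
    attn = lapply(seq_len(cfg$attn_heads), function(h) list(
      Wv = xavier(Hc, d), Wr = xavier(Hp, d),
      U = xavier(d, d), Wa2r = xavier(d, d), Wr2a = xavier(d, d),
      Wp = xavier(d, d), Wc = xavier(d, d),
      a_r2a = runif(2 * d, -0.1, 0.1),
      a_a2r = runif(2 * d, -0.1, 0.1)
    )),
    Wf = xavier(Hc, d),
    merge_c = list(W = xavier(cfg$attn_heads * d, d), b = numeric(d)),
    merge_p = list(W = xavier(cfg$attn_heads * d, d), b = numeric(d)),
    dense = {
      w <- dense_widths(cfg)
      lapply(seq_len(cfg$dense_layers), function(l) list(
        W = xavier(w[l], w[l + 1]), b = numeric(w[l + 1])
      ))
    }
  )
  structure(p, class = "model_params")
}

# Elementwise binary/unary maps over a parameter tree (used by Adam and by
# gradient accumulation). Leaves are numeric vectors/matrices.
tree_map <- function(f, x, ...) {
  more <- list(...)
  if (is.list(x)) {
    out <- lapply(seq_along(x), function(i) {
      do.call(tree_map, c(list(f, x[[i]]), lapply(more, `[[`, i)))
    })
    names(out) <- names(x)
    attributes_keep <- attributes(x)
    if (!is.null(attributes_keep$class)) class(out) <- attributes_keep$class
    out
  } else {
    do.call(f, c(list(x), more))
  }
}

tree_zero_like <- function(x) tree_map(function(a) a * 0, x)

# Sum of squares across all leaves (diagnostics).
tree_sumsq <- function(x) {
  if (is.list(x)) sum(vapply(x, tree_sumsq, numeric(1))) else sum(x^2)
}

tree_count <- function(x) {
  if (is.list(x)) sum(vapply(x, tree_count, numeric(1))) else length(x)
}
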