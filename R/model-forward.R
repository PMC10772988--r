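#' Network forward pass
#'
#' The network has four feature paths that meet in a multi-head bidirectional
#' attention block:
#' * a one-layer, multi-head graph-attention (GAT) encoder over the molecular
#'   graph producing per-atom features `v_i` in `R^{H_c}`,
#' * a stack of same-padded 1-D convolutions over 3-mer embeddings producing
#'   per-residue features `r_i` in `R^{H_p}`,
#' * a two-layer perceptron over the 1024-bit circular fingerprint producing
#'   `f` in `R^{H_c}`,
#' * per head, atoms and residues are projected to a shared latent space
#'   (`c_i = LeakyReLU(W_v v_i)`, `p_j = LeakyReLU(W_r r_j)`), a soft
#'   alignment matrix `A = tanh(C U P^T)` couples them, and attention weights
#'   are computed in both directions:
#'   `I_p = A^T tanh(C W_a2r)`, `alpha_r2a = softmax([P W_p || I_p] a_r2a)`
#'   (residue direction), with the atom direction mirror-imaged. Head outputs
#'   are concatenated and projected back to `d`.
#'
#' The concatenation `h_c_final || h_f || h_p_final || [T, 1/T]` (width
#' `3d + 2`) feeds the dense regression stack that outputs `log10(kcat)`.
#'
#' @name network-forward
NULL

# ---- GAT compound encoder ----

gat_forward <- function(atom_tokens, edges, params, cfg, cache = FALSE) {
  n <- length(atom_tokens)
  if (n == 0) abort("Empty molecular graph")
  slope <- cfg$leaky_slope
  X <- params$atom_emb[atom_tokens, , drop = FALSE]
  mask <- diag(TRUE, n)
  if (NROW(edges) > 0) {
    mask[edges] <- TRUE
    mask[edges[, c(2, 1), drop = FALSE]] <- TRUE
  }
  heads <- vector("list", cfg$gat_heads)
  outs <- vector("list", cfg$gat_heads)
  for (h in seq_len(cfg$gat_heads)) {
    ph <- params$gat[[h]]
    Z <- X %*% ph$W
    s <- drop(Z %*% ph$a_self)
    t <- drop(Z %*% ph$a_nbr)
    E_pre <- outer(s, rep(1, n)) + outer(rep(1, n), t)
    E <- leaky_relu(E_pre, slope)
    Alpha <- masked_row_softmax(E, mask)
    Agg <- Alpha %*% Z
    H_head <- leaky_relu(Agg, slope)
    outs[[h]] <- H_head
    if (cache) heads[[h]] <- list(Z = Z, E_pre = E_pre, Alpha = Alpha, Agg = Agg)
  }
  Concat <- do.call(cbind, outs)
  V <- sweep(Concat %*% params$gat_proj$W, 2, params$gat_proj$b, "+")
  if (cache) {
    list(V = V, X = X, mask = mask, heads = heads, Concat = Concat,
         atom_tokens = atom_tokens)
  } else {
    list(V = V)
  }
}

#' Encode a molecular graph with the multi-head graph-attention encoder
#'
#' @param graph A [smiles_to_graph()] result.
#' @param params Model parameters ([init_model_params()]).
#' @param cfg The matching [model_config()].
#' @return Numeric matrix of per-atom features, `n_atoms` x `H_c`.
#' @export
gat_encode <- function(graph, params, cfg) {
  stopifnot(inherits(graph, "compound_graph"))
  gat_forward(graph$atom_tokens, graph$edges, params, cfg)$V
}

# ---- CNN protein encoder ----

im2col <- function(X, K) {
  n <- nrow(X); H <- ncol(X); pad <- (K - 1L) %/% 2L
  Xp <- rbind(matrix(0, pad, H), X, matrix(0, pad, H))
  do.call(cbind, lapply(0:(K - 1L), function(o) Xp[(1 + o):(n + o), , drop = FALSE]))
}

col2im <- function(dCols, n, H, K) {
  pad <- (K - 1L) %/% 2L
  dXp <- matrix(0, n + 2L * pad, H)
  for (o in 0:(K - 1L)) {
    dXp[(1 + o):(n + o), ] <- dXp[(1 + o):(n + o), ] +
      dCols[, (o * H + 1):((o + 1) * H), drop = FALSE]
  }
  dXp[(pad + 1):(pad + n), , drop = FALSE]
}

cnn_forward <- function(kmer_tokens, params, cfg, cache = FALSE) {
  if (length(kmer_tokens) < 1) abort("Need at least one k-mer token")
  slope <- cfg$leaky_slope
  X <- params$kmer_emb[kmer_tokens, , drop = FALSE]
  layers <- vector("list", cfg$conv_layers)
  Xl <- X
  for (l in seq_len(cfg$conv_layers)) {
    cols <- im2col(Xl, cfg$conv_kernel)
    pre <- sweep(cols %*% params$conv[[l]]$W, 2, params$conv[[l]]$b, "+")
    Xnext <- leaky_relu(pre, slope)
    if (cache) layers[[l]] <- list(cols = cols, pre = pre)
    Xl <- Xnext
  }
  if (cache) {
    list(R = Xl, X0 = X, layers = layers, kmer_tokens = kmer_tokens)
  } else {
    list(R = Xl)
  }
}

#' Encode protein 3-mer tokens with the convolutional encoder
#'
#' Same-padded 1-D convolutions preserve length: one output row per k-mer.
#'
#' @param tokens A [protein_to_kmers()] result.
#' @inheritParams gat_encode
#' @return Numeric matrix of per-residue features, `n_kmers` x `H_p`.
#' @export
cnn_encode <- function(tokens, params, cfg) {
  stopifnot(inherits(tokens, "protein_tokens"))
  cnn_forward(tokens$kmer_tokens, params, cfg)$R
}

# ---- Fingerprint encoder ----

fp_forward <- function(bits, params, cfg, cache = FALSE) {
  if (length(bits) != nrow(params$fp$W1)) {
    abort(sprintf("Fingerprint must have %d bits, got %d",
                  nrow(params$fp$W1), length(bits)),
          class = "thermokcat_shape_error")
  }
  slope <- cfg$leaky_slope
  bits <- as.numeric(bits)
  h1_pre <- drop(bits %*% params$fp$W1) + params$fp$b1
  h1 <- leaky_relu(h1_pre, slope)
  f <- drop(h1 %*% params$fp$W2) + params$fp$b2
  if (cache) list(f = f, bits = bits, h1_pre = h1_pre, h1 = h1) else list(f = f)
}

#' Encode a circular fingerprint into the compound feature space
#'
#' @param bits 0/1 vector of length 1024.
#' @inheritParams gat_encode
#' @return Numeric vector of length `H_c`.
#' @export
fingerprint_encode <- function(bits, params, cfg) {
  fp_forward(bits, params, cfg)$f
}

# ---- Bidirectional attention ----

attention_head_forward <- function(V, R, ph, slope, cache = FALSE) {
  C_pre <- V %*% ph$Wv
  C <- leaky_relu(C_pre, slope)
  P_pre <- R %*% ph$Wr
  P <- leaky_relu(P_pre, slope)
  d <- ncol(C)
  M <- C %*% ph$U %*% t(P)
  A <- tanh(M)
  Tc <- tanh(C %*% ph$Wa2r)
  I_p <- crossprod(A, Tc)                      # N_r x d
  G_p <- P %*% ph$Wp
  logits_r <- drop(G_p %*% ph$a_r2a[1:d] + I_p %*% ph$a_r2a[(d + 1):(2 * d)])
  alpha_r2a <- softmax_vec(logits_r)
  Tp <- tanh(P %*% ph$Wr2a)
  I_c <- A %*% Tp                              # N_v x d
  G_c <- C %*% ph$Wc
  logits_a <- drop(G_c %*% ph$a_a2r[1:d] + I_c %*% ph$a_a2r[(d + 1):(2 * d)])
  alpha_a2r <- softmax_vec(logits_a)
  h_c <- drop(crossprod(C, alpha_a2r))
  h_p <- drop(crossprod(P, alpha_r2a))
  out <- list(h_c = h_c, h_p = h_p, alpha_a2r = alpha_a2r,
              alpha_r2a = alpha_r2a, A = A)
  if (cache) {
    out <- c(out, list(C_pre = C_pre, C = C, P_pre = P_pre, P = P,
                       Tc = Tc, Tp = Tp, I_p = I_p, I_c = I_c,
                       G_p = G_p, G_c = G_c))
  }
  out
}

attention_forward <- function(V, R, f, params, cfg, cache = FALSE) {
  if (nrow(V) < 1 || nrow(R) < 1) abort("Attention needs at least one atom and one residue")
  if (ncol(V) != nrow(params$attn[[1]]$Wv) || ncol(R) != nrow(params$attn[[1]]$Wr)) {
    abort("Feature widths do not match the attention parameters",
          class = "thermokcat_shape_error")
  }
  slope <- cfg$leaky_slope
  heads <- lapply(params$attn, function(ph) {
    attention_head_forward(V, R, ph, slope, cache = cache)
  })
  hc_cat <- unlist(lapply(heads, `[[`, "h_c"))
  hp_cat <- unlist(lapply(heads, `[[`, "h_p"))
  h_c_final <- drop(hc_cat %*% params$merge_c$W) + params$merge_c$b
  h_p_final <- drop(hp_cat %*% params$merge_p$W) + params$merge_p$b
  h_f <- drop(f %*% params$Wf)
  out <- list(
    h_c_final = h_c_final, h_p_final = h_p_final, h_f = h_f,
    alpha_a2r = do.call(rbind, lapply(heads, `[[`, "alpha_a2r")),
    alpha_r2a = do.call(rbind, lapply(heads, `[[`, "alpha_r2a")),
    A = lapply(heads, `[[`, "A")
  )
  if (cache) out$heads <- heads
  out
}

#' Multi-head bidirectional atom-residue attention
#'
#' @param V Atom feature matrix (`N_v` x `H_c`) from [gat_encode()].
#' @param R Residue feature matrix (`N_r` x `H_p`) from [cnn_encode()].
#' @param f Fingerprint feature vector (length `H_c`) from
#'   [fingerprint_encode()].
#' @inheritParams gat_encode
#' @return An `attention_output` list: `h_c_final`, `h_p_final`, `h_f`
#'   (length-`d` vectors), `alpha_a2r` (`heads` x `N_v`), `alpha_r2a`
#'   (`heads` x `N_r`), and `A`, the per-head list of `N_v` x `N_r` soft
#'   alignment matrices with entries in \[-1, 1\].
#' @export
bidirectional_attention <- function(V, R, f, params, cfg) {
  out <- attention_forward(V, R, f, params, cfg)
  structure(out, class = "attention_output")
}

# ---- Dense regressor ----

dense_forward <- function(x, params, cfg, cache = FALSE) {
  slope <- cfg$leaky_slope
  L <- length(params$dense)
  layers <- vector("list", L)
  a <- x
  for (l in seq_len(L)) {
    pre <- drop(a %*% params$dense[[l]]$W) + params$dense[[l]]$b
    if (cache) layers[[l]] <- list(a_in = a, pre = pre)
    a <- if (l < L) leaky_relu(pre, slope) else pre
  }
  if (cache) list(y = a, layers = layers) else list(y = a)
}

# ---- Whole-model forward ----

# feats: list(atom_tokens, edges, kmer_tokens, fingerprint, t_norm, invt_norm)
forward_sample <- function(feats, params, cfg, cache = FALSE) {
  gat <- gat_forward(feats$atom_tokens, feats$edges, params, cfg, cache = cache)
  cnn <- cnn_forward(feats$kmer_tokens, params, cfg, cache = cache)
  fp <- fp_forward(feats$fingerprint, params, cfg, cache = cache)
  att <- attention_forward(gat$V, cnn$R, fp$f, params, cfg, cache = cache)
  x <- c(att$h_c_final, att$h_f, att$h_p_final, feats$t_norm, feats$invt_norm)
  dn <- dense_forward(x, params, cfg, cache = cache)
  out <- list(y = dn$y, attention = att)
  if (cache) out$cache <- list(gat = gat, cnn = cnn, fp = fp, att = att,
                               dense = dn, x = x, feats = feats)
  out
}

#' Predict log10(kcat) for one featurized input
#'
#' @param graph A [smiles_to_graph()] result.
#' @param tokens A [protein_to_kmers()] result.
#' @param thermo A [normalize_temperature()] result.
#' @inheritParams gat_encode
#' @return The predicted `log10(kcat)` (kcat in 1/s), a single number.
#' @export
predict_log10kcat <- function(graph, tokens, thermo, params, cfg) {
  stopifnot(inherits(graph, "compound_graph"),
            inherits(tokens, "protein_tokens"))
  if (!inherits(thermo, "thermo_features")) {
    abort("`thermo` must come from normalize_temperature(); fit thermo stats first",
          class = "thermokcat_config_error")
  }
  feats <- list(atom_tokens = graph$atom_tokens, edges = graph$edges,
                kmer_tokens = tokens$kmer_tokens,
                fingerprint = graph$fingerprint,
                t_norm = thermo$t_norm, invt_norm = thermo$invt_norm)
  forward_sample(feats, params, cfg)$y
}
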