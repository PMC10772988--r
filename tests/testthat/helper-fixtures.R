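# Shared fixtures: tiny configurations, random featurized samples, and an
# independent scalar-loop oracle for the bidirectional attention equations.

tiny_cfg <- function(d = 8L, H_c = 10L, H_p = 10L) {
  suppressMessages(model_config("small", d = d, H_c = H_c, H_c_prime = 6L,
                                H_p = H_p, conv_layers = 2L, dense_layers = 3L,
                                fp_hidden = 12L))
}

rand_feats <- function(n_atoms = 4L, n_kmers = 5L, atom_vocab = 6L,
                       kmer_vocab = 9L) {
  edges <- if (n_atoms > 1) {
    cbind(from = seq_len(n_atoms - 1L), to = seq_len(n_atoms - 1L) + 1L)
  } else {
    matrix(integer(), ncol = 2, dimnames = list(NULL, c("from", "to")))
  }
  list(
    atom_tokens = sample(2:atom_vocab, n_atoms, replace = TRUE),
    edges = edges,
    kmer_tokens = sample(2:kmer_vocab, n_kmers, replace = TRUE),
    fingerprint = as.integer(runif(1024) < 0.05),
    t_norm = runif(1), invt_norm = runif(1)
  )
}

# Scalar-loop implementation of one bidirectional-attention head: the
# residue direction follows the published equations
#   c_i = LeakyReLU(W_v v_i);  p_j = LeakyReLU(W_r r_j)
#   A = tanh(C U P^T);  I_p = A^T tanh(C W_a2r)
#   alpha_r2a = softmax([P W_p || I_p] a_r2a)
# and the atom direction mirrors them. Written with explicit nested loops,
# independent of the vectorized implementation.
oracle_attention_head <- function(V, R, ph, slope) {
  lrelu <- function(x) ifelse(x >= 0, x, slope * x)
  Nv <- nrow(V); Nr <- nrow(R); d <- ncol(ph$Wv)
  C <- matrix(0, Nv, d); P <- matrix(0, Nr, d)
  for (i in seq_len(Nv)) for (k in seq_len(d)) {
    C[i, k] <- lrelu(sum(V[i, ] * ph$Wv[, k]))
  }
  for (j in seq_len(Nr)) for (k in seq_len(d)) {
    P[j, k] <- lrelu(sum(R[j, ] * ph$Wr[, k]))
  }
  A <- matrix(0, Nv, Nr)
  for (i in seq_len(Nv)) for (j in seq_len(Nr)) {
    s <- 0
    for (k in seq_len(d)) for (l in seq_len(d)) {
      s <- s + C[i, k] * ph$U[k, l] * P[j, l]
    }
    A[i, j] <- tanh(s)
  }
  TanCW <- matrix(0, Nv, d)
  for (i in seq_len(Nv)) for (k in seq_len(d)) {
    TanCW[i, k] <- tanh(sum(C[i, ] * ph$Wa2r[, k]))
  }
  I_p <- matrix(0, Nr, d)
  for (j in seq_len(Nr)) for (k in seq_len(d)) {
    I_p[j, k] <- sum(A[, j] * TanCW[, k])
  }
  logit_r <- numeric(Nr)
  for (j in seq_len(Nr)) {
    pw <- numeric(d)
    for (k in seq_len(d)) pw[k] <- sum(P[j, ] * ph$Wp[, k])
    logit_r[j] <- sum(c(pw, I_p[j, ]) * ph$a_r2a)
  }
  alpha_r2a <- exp(logit_r - max(logit_r))
  alpha_r2a <- alpha_r2a / sum(alpha_r2a)

  TanPW <- matrix(0, Nr, d)
  for (j in seq_len(Nr)) for (k in seq_len(d)) {
    TanPW[j, k] <- tanh(sum(P[j, ] * ph$Wr2a[, k]))
  }
  I_c <- matrix(0, Nv, d)
  for (i in seq_len(Nv)) for (k in seq_len(d)) {
    I_c[i, k] <- sum(A[i, ] * TanPW[, k])
  }
  logit_a <- numeric(Nv)
  for (i in seq_len(Nv)) {
    cw <- numeric(d)
    for (k in seq_len(d)) cw[k] <- sum(C[i, ] * ph$Wc[, k])
    logit_a[i] <- sum(c(cw, I_c[i, ]) * ph$a_a2r)
  }
  alpha_a2r <- exp(logit_a - max(logit_a))
  alpha_a2r <- alpha_a2r / sum(alpha_a2r)

  h_c <- numeric(d); h_p <- numeric(d)
  for (k in seq_len(d)) {
    h_c[k] <- sum(alpha_a2r * C[, k])
    h_p[k] <- sum(alpha_r2a * P[, k])
  }
  list(alpha_r2a = alpha_r2a, alpha_a2r = alpha_a2r, A = A,
       h_c = h_c, h_p = h_p)
}

# A small labelled kinetics table built from real parseable molecules.
toy_kinetics <- function(n_temps = 3) {
  smiles <- c("CCO", "CC(=O)O", "c1ccccc1O", "CCN")
  seqs <- c("MKVLWAALLVTFLAGCQAKVEQ", "MAHHHHHHVGTGSNARRKWNE",
            "MSTNPKPQRKTKRNTNRRPQDV", "MGSSHHHHHHSSGLVPRGSHML")
  grid <- expand.grid(pair = 1:4, ti = seq_len(n_temps))
  tibble::tibble(
    smiles = smiles[grid$pair],
    sequence = seqs[grid$pair],
    temperature_C = c(15, 30, 45)[grid$ti],
    kcat_s = 10^(grid$pair / 2 - 0.2 * grid$ti)
  )
}
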