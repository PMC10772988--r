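# Reverse-mode gradients for the whole network, written against the cached
# forward pass in model-forward.R. Verified against central finite
# differences in the test suite; any edit here must keep that check green.

dense_backward <- function(dn, dy, params, cfg) {
  slope <- cfg$leaky_slope
  L <- length(params$dense)
  grads <- vector("list", L)
  da <- dy
  for (l in rev(seq_len(L))) {
    ly <- dn$layers[[l]]
    dpre <- if (l < L) da * leaky_relu_grad(ly$pre, slope) else da
    grads[[l]] <- list(W = outer(ly$a_in, dpre), b = dpre)
    da <- drop(params$dense[[l]]$W %*% dpre)
  }
  list(grads = grads, dx = da)
}

attention_head_backward <- function(ch, dh_c, dh_p, ph, V, R, slope) {
  d <- length(dh_c)
  a1 <- ph$a_a2r[1:d]; a2 <- ph$a_a2r[(d + 1):(2 * d)]
  b1 <- ph$a_r2a[1:d]; b2 <- ph$a_r2a[(d + 1):(2 * d)]

  dalpha_a <- drop(ch$C %*% dh_c)
  dC <- outer(ch$alpha_a2r, dh_c)
  dalpha_r <- drop(ch$P %*% dh_p)
  dP <- outer(ch$alpha_r2a, dh_p)

  dlog_a <- softmax_backward(ch$alpha_a2r, dalpha_a)
  dlog_r <- softmax_backward(ch$alpha_r2a, dalpha_r)

  # atom-direction logits: [C Wc || I_c] a_a2r
  dG_c <- outer(dlog_a, a1)
  dI_c <- outer(dlog_a, a2)
  da_a2r <- c(drop(crossprod(ch$G_c, dlog_a)), drop(crossprod(ch$I_c, dlog_a)))
  dWc <- crossprod(ch$C, dG_c)
  dC <- dC + dG_c %*% t(ph$Wc)
  dA <- dI_c %*% t(ch$Tp)
  dTp <- crossprod(ch$A, dI_c)
  dPW2 <- dTp * (1 - ch$Tp^2)
  dWr2a <- crossprod(ch$P, dPW2)
  dP <- dP + dPW2 %*% t(ph$Wr2a)

  # residue-direction logits: [P Wp || I_p] a_r2a
  dG_p <- outer(dlog_r, b1)
  dI_p <- outer(dlog_r, b2)
  da_r2a <- c(drop(crossprod(ch$G_p, dlog_r)), drop(crossprod(ch$I_p, dlog_r)))
  dWp <- crossprod(ch$P, dG_p)
  dP <- dP + dG_p %*% t(ph$Wp)
  dA <- dA + ch$Tc %*% t(dI_p)
  dTc <- ch$A %*% dI_p
  dCW <- dTc * (1 - ch$Tc^2)
  dWa2r <- crossprod(ch$C, dCW)
  dC <- dC + dCW %*% t(ph$Wa2r)

  # soft alignment A = tanh(C U P^T)
  dM <- dA * (1 - ch$A^2)
  dMP <- dM %*% ch$P
  dC <- dC + dMP %*% t(ph$U)
  dU <- crossprod(ch$C, dMP)
  dP <- dP + crossprod(dM, ch$C) %*% ph$U

  dC_pre <- dC * leaky_relu_grad(ch$C_pre, slope)
  dWv <- crossprod(V, dC_pre)
  dV <- dC_pre %*% t(ph$Wv)
  dP_pre <- dP * leaky_relu_grad(ch$P_pre, slope)
  dWr <- crossprod(R, dP_pre)
  dR <- dP_pre %*% t(ph$Wr)

  list(grads = list(Wv = dWv, Wr = dWr, U = dU, Wa2r = dWa2r, Wr2a = dWr2a,
                    Wp = dWp, Wc = dWc, a_r2a = da_r2a, a_a2r = da_a2r),
       dV = dV, dR = dR)
}

cnn_backward <- function(cn, dR, params, cfg) {
  slope <- cfg$leaky_slope
  K <- cfg$conv_kernel
  H <- ncol(dR); n <- nrow(dR)
  L <- length(params$conv)
  grads <- vector("list", L)
  dXl <- dR
  for (l in rev(seq_len(L))) {
    ly <- cn$layers[[l]]
    dpre <- dXl * leaky_relu_grad(ly$pre, slope)
    grads[[l]] <- list(W = crossprod(ly$cols, dpre), b = colSums(dpre))
    dXl <- col2im(dpre %*% t(params$conv[[l]]$W), n, H, K)
  }
  list(grads = grads, dX0 = dXl)
}

gat_backward <- function(gt, dV, params, cfg) {
  slope <- cfg$leaky_slope
  Hcp <- cfg$H_c_prime
  n <- nrow(dV)
  dConcat <- dV %*% t(params$gat_proj$W)
  proj_grads <- list(W = crossprod(gt$Concat, dV), b = colSums(dV))
  dX <- matrix(0, n, ncol(gt$X))
  head_grads <- vector("list", cfg$gat_heads)
  for (h in seq_len(cfg$gat_heads)) {
    ph <- params$gat[[h]]
    chh <- gt$heads[[h]]
    dH_head <- dConcat[, ((h - 1) * Hcp + 1):(h * Hcp), drop = FALSE]
    dAgg <- dH_head * leaky_relu_grad(chh$Agg, slope)
    dAlpha <- dAgg %*% t(chh$Z)
    dZ <- crossprod(chh$Alpha, dAgg)
    S <- rowSums(chh$Alpha * dAlpha)
    dE <- chh$Alpha * (dAlpha - S)
    dE_pre <- dE * leaky_relu_grad(chh$E_pre, slope)
    ds <- rowSums(dE_pre); dt <- colSums(dE_pre)
    da_self <- drop(crossprod(chh$Z, ds))
    da_nbr <- drop(crossprod(chh$Z, dt))
    dZ <- dZ + outer(ds, ph$a_self) + outer(dt, ph$a_nbr)
    head_grads[[h]] <- list(W = crossprod(gt$X, dZ), a_self = da_self,
                            a_nbr = da_nbr)
    dX <- dX + dZ %*% t(ph$W)
  }
  list(grads = head_grads, proj_grads = proj_grads, dX = dX)
}

fp_backward <- function(fc, df, params, cfg) {
  slope <- cfg$leaky_slope
  dW2 <- outer(fc$h1, df)
  db2 <- df
  dh1 <- drop(params$fp$W2 %*% df)
  dh1_pre <- dh1 * leaky_relu_grad(fc$h1_pre, slope)
  on_bits <- which(fc$bits != 0)
  dW1 <- matrix(0, length(fc$bits), length(dh1_pre))
  if (length(on_bits) > 0) {
    dW1[on_bits, ] <- matrix(dh1_pre, length(on_bits), length(dh1_pre),
                             byrow = TRUE)
  }
  list(grads = list(W1 = dW1, b1 = dh1_pre, W2 = dW2, b2 = db2))
}

# Full-model backward for one sample. Returns the gradient tree for all
# dense parameters plus sparse row-gradients for the two embedding tables.
backward_sample <- function(cache, dy, params, cfg) {
  d <- cfg$d
  dn_back <- dense_backward(cache$dense, dy, params, cfg)
  dx <- dn_back$dx
  d_hc_final <- dx[1:d]
  d_hf <- dx[(d + 1):(2 * d)]
  d_hp_final <- dx[(2 * d + 1):(3 * d)]

  att <- cache$att
  hc_cat <- unlist(lapply(att$heads, `[[`, "h_c"))
  hp_cat <- unlist(lapply(att$heads, `[[`, "h_p"))
  merge_c_grads <- list(W = outer(hc_cat, d_hc_final), b = d_hc_final)
  merge_p_grads <- list(W = outer(hp_cat, d_hp_final), b = d_hp_final)
  dhc_cat <- drop(params$merge_c$W %*% d_hc_final)
  dhp_cat <- drop(params$merge_p$W %*% d_hp_final)

  f <- cache$fp$f
  dWf <- outer(f, d_hf)
  df <- drop(params$Wf %*% d_hf)

  V <- cache$gat$V; R <- cache$cnn$R
  dV <- matrix(0, nrow(V), ncol(V))
  dR <- matrix(0, nrow(R), ncol(R))
  attn_grads <- vector("list", cfg$attn_heads)
  for (h in seq_len(cfg$attn_heads)) {
    hb <- attention_head_backward(
      att$heads[[h]],
      dhc_cat[((h - 1) * d + 1):(h * d)],
      dhp_cat[((h - 1) * d + 1):(h * d)],
      params$attn[[h]], V, R, cfg$leaky_slope)
    attn_grads[[h]] <- hb$grads
    dV <- dV + hb$dV
    dR <- dR + hb$dR
  }

  gat_back <- gat_backward(cache$gat, dV, params, cfg)
  cnn_back <- cnn_backward(cache$cnn, dR, params, cfg)
  fp_back <- fp_backward(cache$fp, df, params, cfg)

  atom_rows <- rowsum(gat_back$dX, cache$gat$atom_tokens)
  kmer_rows <- rowsum(cnn_back$dX0, cache$cnn$kmer_tokens)

  list(
    grads = list(
      gat = gat_back$grads,
      gat_proj = gat_back$proj_grads,
      conv = cnn_back$grads,
      fp = fp_back$grads,
      attn = attn_grads,
      Wf = dWf,
      merge_c = merge_c_grads,
      merge_p = merge_p_grads,
      dense = dn_back$grads
    ),
    atom_emb_rows = list(idx = as.integer(rownames(atom_rows)), rows = atom_rows),
    kmer_emb_rows = list(idx = as.integer(rownames(kmer_rows)), rows = kmer_rows)
  )
}
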