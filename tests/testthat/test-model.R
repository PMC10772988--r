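test_that("encoder outputs have the configured shapes", {
  set.seed(1)
  cfg <- tiny_cfg()
  params <- init_model_params(cfg, 6, 9, seed = 2)
  av <- new_vocab(); kv <- new_vocab()
  g <- smiles_to_graph("CC(=O)O", av)
  tk <- protein_to_kmers("MKVLWAAL", kmer_vocab = kv)
  params <- init_model_params(cfg, vocab_size(av), vocab_size(kv), seed = 2)

  V <- gat_encode(g, params, cfg)
  expect_equal(dim(V), c(g$n_atoms, cfg$H_c))
  R <- cnn_encode(tk, params, cfg)
  expect_equal(dim(R), c(tk$n_kmers, cfg$H_p))
  expect_true(all(is.finite(R)))
  f <- fingerprint_encode(g$fingerprint, params, cfg)
  expect_length(f, cfg$H_c)
  expect_error(fingerprint_encode(rep(0, 100), params, cfg),
               class = "thermokcat_shape_error")

  # all-zero fingerprint propagates biases to a finite output
  f0 <- fingerprint_encode(rep(0L, 1024), params, cfg)
  expect_true(all(is.finite(f0)))
  expect_identical(f0, fingerprint_encode(rep(0L, 1024), params, cfg))

  att <- bidirectional_attention(V, R, f, params, cfg)
  expect_length(att$h_c_final, cfg$d)
  expect_length(att$h_p_final, cfg$d)
  expect_equal(dim(att$alpha_a2r), c(cfg$attn_heads, g$n_atoms))
  expect_equal(dim(att$alpha_r2a), c(cfg$attn_heads, tk$n_kmers))
  expect_true(all(vapply(att$A, function(A) all(abs(A) <= 1), logical(1))))
})

test_that("single-atom, single-residue attention collapses to the identity", {
  set.seed(3)
  cfg <- tiny_cfg()
  params <- init_model_params(cfg, 5, 5, seed = 3)
  V <- matrix(rnorm(cfg$H_c), 1)
  R <- matrix(rnorm(cfg$H_p), 1)
  f <- rnorm(cfg$H_c)
  att <- bidirectional_attention(V, R, f, params, cfg)
  expect_equal(unname(att$alpha_a2r[, 1]), rep(1, cfg$attn_heads))
  expect_equal(unname(att$alpha_r2a[, 1]), rep(1, cfg$attn_heads))
  # h_c equals c_1, h_p equals p_1 for every head
  for (h in seq_len(cfg$attn_heads)) {
    hd <- thermokcat:::attention_head_forward(V, R, params$attn[[h]],
                                              cfg$leaky_slope)
    expect_equal(hd$h_c, drop(thermokcat:::leaky_relu(V %*% params$attn[[h]]$Wv,
                                         cfg$leaky_slope)))
    expect_equal(hd$h_p, drop(thermokcat:::leaky_relu(R %*% params$attn[[h]]$Wr,
                                         cfg$leaky_slope)))
  }

  # singleton GAT: the atom attends only to itself
  g1 <- thermokcat:::gat_forward(2L,
                                 matrix(integer(), ncol = 2), params, cfg,
                                 cache = TRUE)
  for (h in seq_along(g1$heads)) {
    expect_equal(drop(g1$heads[[h]]$Alpha), 1)
  }
  expect_equal(dim(g1$V), c(1, cfg$H_c))
})

test_that("zero attention weight vector gives uniform residue attention", {
  set.seed(4)
  cfg <- tiny_cfg()
  params <- init_model_params(cfg, 5, 5, seed = 4)
  for (h in seq_len(cfg$attn_heads)) params$attn[[h]]$a_r2a[] <- 0
  V <- matrix(rnorm(3 * cfg$H_c), 3)
  R <- matrix(rnorm(7 * cfg$H_p), 7)
  att <- bidirectional_attention(V, R, rnorm(cfg$H_c), params, cfg)
  expect_equal(unname(att$alpha_r2a),
               matrix(1 / 7, cfg$attn_heads, 7), tolerance = 1e-12)
})

test_that("vectorized attention matches the scalar-loop oracle", {
  set.seed(5)
  for (rep in 1:25) {
    Nv <- sample(1:5, 1); Nr <- sample(1:5, 1); d <- sample(2:8, 1)
    Hc <- sample(3:7, 1); Hp <- sample(3:7, 1)
    cfg <- tiny_cfg(d = d, H_c = Hc, H_p = Hp)
    params <- init_model_params(cfg, 5, 5, seed = rep)
    V <- matrix(rnorm(Nv * Hc), Nv)
    R <- matrix(rnorm(Nr * Hp), Nr)
    for (h in seq_len(cfg$attn_heads)) {
      got <- thermokcat:::attention_head_forward(V, R, params$attn[[h]],
                                                 cfg$leaky_slope)
      want <- oracle_attention_head(V, R, params$attn[[h]], cfg$leaky_slope)
      expect_equal(got$alpha_r2a, want$alpha_r2a, tolerance = 1e-6)
      expect_equal(got$alpha_a2r, want$alpha_a2r, tolerance = 1e-6)
      expect_equal(got$A, want$A, tolerance = 1e-6)
      expect_equal(got$h_c, want$h_c, tolerance = 1e-6)
      expect_equal(got$h_p, want$h_p, tolerance = 1e-6)
    }
  }
})

test_that("predictions are deterministic, finite, and permutation-invariant", {
  set.seed(6)
  cfg <- tiny_cfg()
  av <- new_vocab(); kv <- new_vocab()
  g <- smiles_to_graph("CC(C)CO", av)
  tk <- protein_to_kmers("MKVLWAALLVTF", kmer_vocab = kv)
  st <- fit_thermo_stats(c(10, 60))
  th <- normalize_temperature(30, st)
  params <- init_model_params(cfg, vocab_size(av), vocab_size(kv), seed = 6)

  y1 <- predict_log10kcat(g, tk, th, params, cfg)
  y2 <- predict_log10kcat(g, tk, th, params, cfg)
  expect_identical(y1, y2)
  expect_true(is.finite(y1))

  # atom relabeling: permute tokens and relabel edges
  for (k in 1:5) {
    perm <- sample(g$n_atoms)
    inv <- order(perm)
    g2 <- g
    g2$atom_tokens <- g$atom_tokens[perm]
    g2$edges <- cbind(from = inv[g$edges[, 1]], to = inv[g$edges[, 2]])
    y3 <- predict_log10kcat(g2, tk, th, params, cfg)
    expect_equal(y3, y1, tolerance = 1e-5)
    # GAT output rows are permuted accordingly
    V1 <- gat_encode(g, params, cfg)
    V2 <- gat_encode(g2, params, cfg)
    expect_equal(V2, V1[perm, , drop = FALSE], tolerance = 1e-6)
  }
})

test_that("zeroing the temperature input weights removes temperature sensitivity", {
  set.seed(7)
  cfg <- tiny_cfg()
  av <- new_vocab(); kv <- new_vocab()
  g <- smiles_to_graph("CCO", av)
  tk <- protein_to_kmers("MKVLWAAL", kmer_vocab = kv)
  st <- fit_thermo_stats(c(10, 60))
  params <- init_model_params(cfg, vocab_size(av), vocab_size(kv), seed = 7)

  cold <- predict_log10kcat(g, tk, normalize_temperature(10, st), params, cfg)
  hot <- predict_log10kcat(g, tk, normalize_temperature(60, st), params, cfg)
  expect_false(isTRUE(all.equal(cold, hot)))

  n_in <- 3 * cfg$d + 2
  params$dense[[1]]$W[(n_in - 1):n_in, ] <- 0
  cold0 <- predict_log10kcat(g, tk, normalize_temperature(10, st), params, cfg)
  hot0 <- predict_log10kcat(g, tk, normalize_temperature(60, st), params, cfg)
  expect_equal(cold0, hot0, tolerance = 1e-12)
})

test_that("outputs stay finite over many random inputs", {
  set.seed(8)
  cfg <- tiny_cfg()
  params <- init_model_params(cfg, 12, 20, seed = 8)
  for (i in 1:200) {
    feats <- rand_feats(n_atoms = sample(1:8, 1), n_kmers = sample(1:12, 1),
                        atom_vocab = 12, kmer_vocab = 20)
    y <- thermokcat:::forward_sample(feats, params, cfg)$y
    expect_true(is.finite(y))
  }
})

test_that("checkpoints round-trip and reject mismatched configurations", {
  df <- toy_kinetics()
  ctl <- train_config(epochs = 2, batch_size = 4, seed = 9,
                      split_fractions = c(0.6, 0.2, 0.2))
  m <- train_kcat_model(df, config = tiny_cfg(), control = ctl,
                        oversample = FALSE)
  path <- withr::local_tempfile(fileext = ".rds")
  save_kcat_model(m, path)
  m2 <- load_kcat_model(path)
  p1 <- predict(m, df)$pred_log10_kcat
  p2 <- predict(m2, df)$pred_log10_kcat
  expect_equal(p1, p2)

  bad <- readRDS(path)
  bad$config$d <- 64L
  bad_path <- withr::local_tempfile(fileext = ".rds")
  saveRDS(bad, bad_path)
  expect_error(load_kcat_model(bad_path), class = "thermokcat_checkpoint_error")
})
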