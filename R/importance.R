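#' Temperature feature-permutation importance
#'
#' Measures how much the model relies on its temperature inputs: the
#' normalized (T, 1/T) pairs are shuffled jointly across entries, predictions
#' are recomputed, and the degradation of RMSE/MAE/R2 relative to the
#' unshuffled baseline is collected over repeats. Because temperature enters
#' the network only at the dense-regressor input, the attention-level
#' representations are computed once and reused across permutations.
#'
#' @param object A fitted `kcat_model`.
#' @param data Labelled kinetics data frame.
#' @param n_repeats Number of random permutations (may be 0).
#' @param seed Integer RNG seed.
#' @param use_best Use the best-validation checkpoint (default TRUE).
#' @return A `temperature_importance` object: list with `baseline` (one-row
#'   metrics tibble) and `shuffled` (one row per repeat).
#' @export
permute_temperature_importance <- function(object, data, n_repeats = 20L,
                                           seed = 1L, use_best = TRUE) {
  data <- validate_kinetics(data)
  if (length(unique(data$temperature_C)) < 2) {
    abort("Need at least two distinct temperatures; permutation would be the identity")
  }
  params <- if (use_best) object$best_params else object$params
  cfg <- object$config
  feats <- featurize_kinetics(data, object$atom_vocab, object$kmer_vocab,
                              object$thermo_stats)
  repr <- t(vapply(feats, function(f) {
    gat <- gat_forward(f$atom_tokens, f$edges, params, cfg)
    cnn <- cnn_forward(f$kmer_tokens, params, cfg)
    fp <- fp_forward(f$fingerprint, params, cfg)
    att <- attention_forward(gat$V, cnn$R, fp$f, params, cfg)
    c(att$h_c_final, att$h_f, att$h_p_final)
  }, numeric(3 * cfg$d)))
  thermo <- cbind(vapply(feats, `[[`, numeric(1), "t_norm"),
                  vapply(feats, `[[`, numeric(1), "invt_norm"))
  predict_with_thermo <- function(th) {
    vapply(seq_len(nrow(repr)), function(i) {
      dense_forward(c(repr[i, ], th[i, ]), params, cfg)$y
    }, numeric(1))
  }
  baseline <- suppressWarnings(
    eval_metrics(predict_with_thermo(thermo), data$log10_kcat))
  shuffled <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_repeats), function(r) {
      perm <- sample(nrow(thermo))
      m <- suppressWarnings(
        eval_metrics(predict_with_thermo(thermo[perm, , drop = FALSE]),
                     data$log10_kcat))
      dplyr::mutate(m, repeat_id = r)
    })
  })
  structure(list(baseline = baseline, shuffled = shuffled,
                 n_repeats = as.integer(n_repeats)),
            class = "temperature_importance")
}

#' @export
print.temperature_importance <- function(x, ...) {
  cat(sprintf("<temperature_importance: %d repeats>\n", x$n_repeats))
  cat(sprintf("  baseline rmse %.4f | median shuffled rmse %s\n",
              x$baseline$rmse,
              if (nrow(x$shuffled) > 0) sprintf("%.4f", stats::median(x$shuffled$rmse))
              else "(no repeats)"))
  invisible(x)
}

#' @describeIn permute_temperature_importance Shuffled-vs-baseline metric
#'   rows in long form.
#' @param x A `temperature_importance` object.
#' @export
tidy.temperature_importance <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$baseline, condition = "unshuffled", repeat_id = NA_integer_),
    dplyr::mutate(x$shuffled, condition = "shuffled")
  )
}

#' @describeIn permute_temperature_importance Distributions of shuffled
#'   metrics against the unshuffled baseline.
#' @export
autoplot.temperature_importance <- function(object, ...) {
  long <- tidyr::pivot_longer(object$shuffled, c("rmse", "mae", "r2"),
                              names_to = "metric")
  base_long <- tidyr::pivot_longer(object$baseline, c("rmse", "mae", "r2"),
                                   names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_point(data = base_long, colour = "red", size = 2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free") +
    ggplot2::labs(title = "Temperature feature-permutation importance",
                  subtitle = "red: unshuffled baseline", x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
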