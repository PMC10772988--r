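#' Model architecture configuration
#'
#' Hyperparameters of the compound-protein interaction network. The published
#' architecture uses atom embeddings of width `H_c = 80` transformed to
#' `H_c' = 50` per graph-attention head (3 heads), residue embeddings of
#' width `H_p = 80` refined by four convolutional layers, a unified latent
#' dimension `d` of 40 or 64 for the bidirectional attention (3 heads), and
#' 3-6 dense layers for the final regression. The `"small"` preset (d = 40,
#' two convolutional layers, narrower embeddings) is used for desk-scale
#' benchmarks.
#'
#' @param preset `"default"` or `"small"`.
#' @param H_c Compound embedding width.
#' @param H_c_prime Per-head graph-attention output width.
#' @param gat_heads Number of graph-attention heads.
#' @param H_p Protein embedding width.
#' @param conv_layers Number of convolutional layers.
#' @param conv_kernel Odd convolution kernel size.
#' @param d Unified latent dimension of the bidirectional attention.
#' @param attn_heads Number of bidirectional-attention heads.
#' @param dense_layers Number of dense regression layers (3-6).
#' @param fp_hidden Hidden width of the fingerprint encoder.
#' @param leaky_slope Negative slope of every leaky ReLU.
#' @return A `model_config` list.
#' @export
model_config <- function(preset = c("default", "small"),
                         H_c = NULL, H_c_prime = NULL, gat_heads = 3L,
                         H_p = NULL, conv_layers = NULL, conv_kernel = 3L,
                         d = NULL, attn_heads = 3L, dense_layers = NULL,
                         fp_hidden = NULL, leaky_slope = 0.1) {
  preset <- match.arg(preset)
  def <- if (preset == "default") {
    list(H_c = 80L, H_c_prime = 50L, H_p = 80L, conv_layers = 4L,
         d = 64L, dense_layers = 4L, fp_hidden = 256L)
  } else {
    list(H_c = 40L, H_c_prime = 25L, H_p = 40L, conv_layers = 2L,
         d = 40L, dense_layers = 3L, fp_hidden = 64L)
  }
  cfg <- list(
    H_c = as.integer(H_c %||% def$H_c),
    H_c_prime = as.integer(H_c_prime %||% def$H_c_prime),
    gat_heads = as.integer(gat_heads),
    H_p = as.integer(H_p %||% def$H_p),
    conv_layers = as.integer(conv_layers %||% def$conv_layers),
    conv_kernel = as.integer(conv_kernel),
    d = as.integer(d %||% def$d),
    attn_heads = as.integer(attn_heads),
    dense_layers = as.integer(dense_layers %||% def$dense_layers),
    fp_hidden = as.integer(fp_hidden %||% def$fp_hidden),
    leaky_slope = leaky_slope
  )
  validate_model_config(cfg)
}

validate_model_config <- function(cfg) {
  widths <- c(cfg$H_c, cfg$H_c_prime, cfg$gat_heads, cfg$H_p, cfg$conv_layers,
              cfg$conv_kernel, cfg$d, cfg$attn_heads, cfg$dense_layers,
              cfg$fp_hidden)
  if (any(widths <= 0)) abort("All model_config widths must be positive")
  if (cfg$conv_kernel %% 2 == 0) abort("conv_kernel must be odd (same-padding)")
  if (cfg$dense_layers < 3 || cfg$dense_layers > 6) {
    abort("dense_layers must lie in [3, 6]")
  }
  if (cfg$d %notin% c(40L, 64L)) {
    message(sprintf("model_config: d = %d is outside the published {40, 64}", cfg$d))
  }
  structure(cfg, class = "model_config")
}

# Widths of the dense regression stack: geometric taper from the input
# (3d + 2: compound, fingerprint and protein vectors plus the two
# temperature features) down to the scalar output.
dense_widths <- function(cfg) {
  n_in <- 3L * cfg$d + 2L
  L <- cfg$dense_layers
  round(exp(seq(log(n_in), log(1), length.out = L + 1)))
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf(
    "<model_config: H_c=%d H_c'=%d (%d GAT heads) | H_p=%d (%d conv) | d=%d (%d attn heads) | %d dense>\n",
    x$H_c, x$H_c_prime, x$gat_heads, x$H_p, x$conv_layers, x$d, x$attn_heads,
    x$dense_layers))
  invisible(x)
}
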