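# Adam optimizer over a parameter tree, plus the step-wise learning-rate
# schedule: the rate starts at lr0 and is halved every `decay_every` epochs.

adam_init <- function(params) {
  e <- new.env(parent = emptyenv())
  e$m <- tree_zero_like(params)
  e$v <- tree_zero_like(params)
  e$t <- 0L
  e
}

adam_step <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  tree_map(function(p, m, v) p - lr * (m / bc1) / (sqrt(v / bc2) + eps),
           params, state$m, state$v)
}

#' Learning-rate schedule
#'
#' The initial rate decays by 50% every 10 epochs (both configurable):
#' epochs 0-9 run at `lr0`, epochs 10-19 at `lr0 / 2`, and so on.
#'
#' @param epoch Zero-based epoch index (scalar or vector).
#' @param lr0 Initial learning rate (default 0.001).
#' @param decay Multiplicative decay factor (default 0.5).
#' @param decay_every Epochs between decays (default 10).
#' @return Learning rate(s).
#' @export
learning_rate_schedule <- function(epoch, lr0 = 0.001, decay = 0.5,
                                   decay_every = 10L) {
  lr0 * decay^(epoch %/% decay_every)
}

#' Training-loop configuration
#'
#' Defaults follow the published training recipe: mini-batches of 32, Adam
#' with initial learning rate 0.001 halved every 10 epochs, mean squared
#' error loss, 20 epochs.
#'
#' @param batch_size Mini-batch size.
#' @param lr0 Initial learning rate.
#' @param lr_decay Decay factor.
#' @param decay_every Epochs between decays.
#' @param epochs Number of training epochs.
#' @param seed Integer seed controlling initialization, splitting, shuffling.
#' @param split_fractions Train/val/test fractions (sum to 1).
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 32L, lr0 = 0.001, lr_decay = 0.5,
                         decay_every = 10L, epochs = 20L, seed = 1L,
                         split_fractions = c(0.8, 0.1, 0.1)) {
  stopifnot(batch_size >= 1, epochs >= 1,
            abs(sum(split_fractions) - 1) < 1e-8)
  structure(list(batch_size = as.integer(batch_size), lr0 = lr0,
                 lr_decay = lr_decay, decay_every = as.integer(decay_every),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 split_fractions = split_fractions),
            class = "train_config")
}
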