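# Small numeric helpers shared across the network code.

leaky_relu <- function(x, slope = 0.1) {
  ifelse(x >= 0, x, slope * x)
}

leaky_relu_grad <- function(x, slope = 0.1) {
  ifelse(x >= 0, 1, slope)
}

# Numerically stable softmax over a vector.
softmax_vec <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

# Row-wise masked softmax: entries where mask is FALSE get zero weight.
# Every row must have at least one TRUE entry.
masked_row_softmax <- function(logits, mask) {
  logits[!mask] <- -Inf
  m <- apply(logits, 1, max)
  z <- exp(logits - m)
  z[!mask] <- 0
  z / rowSums(z)
}

# Backward through a softmax vector: given alpha = softmax(logits) and
# dL/dalpha, returns dL/dlogits.
softmax_backward <- function(alpha, dalpha) {
  alpha * (dalpha - sum(alpha * dalpha))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

`%notin%` <- function(x, table) !(x %in% table)
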