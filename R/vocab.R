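#' Token vocabularies
#'
#' A vocabulary maps string token keys (atom feature keys or protein 3-mers)
#' to integer embedding indices. Index 1 is always reserved for the unknown
#' token `<UNK>`: once a vocabulary is frozen (at the end of training), keys
#' never seen before map to 1 instead of growing the table.
#'
#' @param tokens Optional character vector of initial tokens.
#' @return A `token_vocab` object.
#' @export
new_vocab <- function(tokens = character()) {
  env <- new.env(parent = emptyenv())
  env$map <- c("<UNK>" = 1L)
  env$frozen <- FALSE
  v <- structure(list(env = env), class = "token_vocab")
  if (length(tokens) > 0) vocab_lookup(v, tokens)
  v
}

#' Look up (and possibly add) tokens in a vocabulary
#'
#' @param vocab A `token_vocab`.
#' @param tokens Character vector of token keys.
#' @return Integer vector of indices, same length as `tokens`.
#' @export
vocab_lookup <- function(vocab, tokens) {
  stopifnot(inherits(vocab, "token_vocab"))
  env <- vocab$env
  idx <- unname(env$map[tokens])
  miss <- is.na(idx)
  if (any(miss)) {
    if (env$frozen) {
      idx[miss] <- 1L
    } else {
      new_tok <- unique(tokens[miss])
      new_idx <- seq_along(new_tok) + length(env$map)
      env$map <- c(env$map, stats::setNames(as.integer(new_idx), new_tok))
      idx <- unname(env$map[tokens])
    }
  }
  as.integer(idx)
}

#' @rdname new_vocab
#' @export
vocab_size <- function(vocab) length(vocab$env$map)

#' @rdname new_vocab
#' @export
vocab_freeze <- function(vocab) {
  vocab$env$frozen <- TRUE
  invisible(vocab)
}

#' @rdname new_vocab
#' @export
vocab_is_frozen <- function(vocab) isTRUE(vocab$env$frozen)

#' Serialize / restore a vocabulary as a plain list (for JSON checkpoints)
#' @param vocab A `token_vocab`.
#' @export
vocab_to_list <- function(vocab) {
  list(map = as.list(vocab$env$map), frozen = vocab$env$frozen)
}

#' @param x A list produced by [vocab_to_list()].
#' @rdname vocab_to_list
#' @export
vocab_from_list <- function(x) {
  v <- new_vocab()
  v$env$map <- stats::setNames(as.integer(unlist(x$map)), names(x$map))
  v$env$frozen <- isTRUE(x$frozen)
  v
}

#' Write / read a vocabulary as a JSON token-to-index map
#' @param vocab A `token_vocab`.
#' @param path File path.
#' @export
write_vocab_json <- function(vocab, path) {
  jsonlite::write_json(vocab_to_list(vocab), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_vocab_json
#' @export
read_vocab_json <- function(path) {
  vocab_from_list(jsonlite::read_json(path))
}

#' @export
print.token_vocab <- function(x, ...) {
  cat(sprintf("<token_vocab: %d tokens%s>\n", vocab_size(x),
              if (vocab_is_frozen(x)) ", frozen" else ""))
  invisible(x)
}
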