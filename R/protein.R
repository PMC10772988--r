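#' Protein featurization and mutation handling
#'
#' Protein sequences are tokenized as overlapping k-mers (default 3-mers,
#' stride 1), the token unit of the convolutional encoder. Mutation
#' specifications use the conventional "RefPosAlt" notation with 1-based
#' positions, multiple substitutions joined by "/" (e.g. "Y227C/E277G").
#'
#' @name protein-featurization
NULL

AA_STANDARD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Tokenize a protein sequence into overlapping k-mers
#'
#' Any k-mer containing a non-standard residue letter (B, J, O, U, X, Z, ...)
#' maps to the unknown token rather than erroring, so real database sequences
#' pass through.
#'
#' @param sequence Amino-acid string (one-letter codes).
#' @param k Window size (default 3).
#' @param kmer_vocab A [new_vocab()] vocabulary (mutated in place).
#' @return A `protein_tokens` object: list with `kmer_tokens`, `kmers`,
#'   `n_kmers`.
#' @export
protein_to_kmers <- function(sequence, k = 3L, kmer_vocab = new_vocab()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(trimws(sequence))
  len <- nchar(sequence)
  if (len < k) {
    abort(sprintf("Sequence of length %d is shorter than k = %d", len, k),
          class = "thermokcat_sequence_length_error")
  }
  n <- len - k + 1L
  kmers <- substring(sequence, seq_len(n), seq_len(n) + k - 1L)
  nonstd <- vapply(kmers, function(s) {
    any(strsplit(s, "")[[1]] %notin% AA_STANDARD)
  }, logical(1))
  tokens <- integer(n)
  tokens[nonstd] <- 1L  # UNK
  if (any(!nonstd)) tokens[!nonstd] <- vocab_lookup(kmer_vocab, kmers[!nonstd])
  structure(list(kmer_tokens = tokens, kmers = unname(kmers), n_kmers = n),
            class = "protein_tokens")
}

#' Apply point-mutation specifications to a wild-type sequence
#'
#' @param wild_type Amino-acid string.
#' @param spec Substitution spec like "A2G" or "Y227C/E277G"; positions are
#'   1-based and the reference letter is verified against `wild_type`.
#' @return The mutated sequence.
#' @export
apply_mutations <- function(wild_type, spec) {
  stopifnot(is.character(wild_type), length(wild_type) == 1L,
            is.character(spec), length(spec) == 1L)
  chars <- strsplit(wild_type, "")[[1]]
  parts <- strsplit(trimws(spec), "/", fixed = TRUE)[[1]]
  for (p in parts) {
    m <- regmatches(p, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", p))[[1]]
    if (length(m) != 4) {
      abort(sprintf(
        "Unsupported mutation spec '%s': only single-residue substitutions (RefPosAlt) are handled",
        p), class = "thermokcat_mutation_unsupported_error")
    }
    ref <- toupper(m[2]); pos <- as.integer(m[3]); alt <- toupper(m[4])
    if (pos < 1 || pos > length(chars)) {
      abort(sprintf("Mutation position %d is outside the sequence (length %d)",
                    pos, length(chars)),
            class = "thermokcat_mutation_range_error")
    }
    if (chars[pos] != ref) {
      abort(sprintf(
        "Reference mismatch at position %d: spec says '%s' but sequence has '%s'",
        pos, ref, chars[pos]),
        class = "thermokcat_mutation_mismatch_error")
    }
    chars[pos] <- alt
  }
  paste(chars, collapse = "")
}

#' Read sequences from a FASTA file as a tibble
#'
#' Convenience reader for supplying sequences keyed by an id column. Uses
#' Biostrings when available, otherwise a plain-text fallback.
#'
#' @param path FASTA file path.
#' @return Tibble with columns `id`, `sequence`.
#' @export
read_fasta_sequences <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    aa <- Biostrings::readAAStringSet(path)
    ids <- vapply(strsplit(names(aa), "[ \t]"), `[`, character(1), 1)
    return(tibble::tibble(id = ids, sequence = unname(as.character(aa))))
  }
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  grp <- cumsum(hdr)
  ids <- sub("^>([^ \t]+).*$", "\\1", lines[hdr])
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1), collapse = "")
  tibble::tibble(id = ids, sequence = unname(seqs))
}

#' @export
print.protein_tokens <- function(x, ...) {
  cat(sprintf("<protein_tokens: %d overlapping %d-mers>\n", x$n_kmers,
              nchar(x$kmers[1])))
  invisible(x)
}
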