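#' Compound featurization
#'
#' SMILES strings are parsed with OpenBabel (via ChemmineOB). Every molecule
#' is first rewritten as its canonical SMILES so that different spellings of
#' the same structure ("CCO" vs "OCC") produce identical graphs and
#' fingerprints, then converted to a MOL2 block from which heavy atoms,
#' aromaticity flags and bonds are read.
#'
#' @name compound-featurization
NULL

# Canonical SMILES via OpenBabel; errors name the offending string.
canonicalize_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", smiles)),
    error = function(e) ""
  )
  can <- strsplit(trimws(out), "[ \t\n]")[[1]][1]
  if (is.na(can) || !nzchar(can)) {
    abort(sprintf("Cannot parse SMILES string: '%s'", smiles),
          class = "thermokcat_smiles_parse_error")
  }
  can
}

# Parse the ATOM/BOND sections of an OpenBabel MOL2 block into element
# symbols, aromaticity flags and a 2-column bond matrix (1-based indices).
parse_mol2 <- function(mol2) {
  lines <- strsplit(mol2, "\n", fixed = TRUE)[[1]]
  sect <- cumsum(grepl("^@<TRIPOS>", lines))
  tags <- lines[grepl("^@<TRIPOS>", lines)]
  get_section <- function(tag) {
    k <- which(tags == tag)
    if (length(k) == 0) return(character())
    body <- lines[sect == k[1]][-1]
    body[nzchar(trimws(body))]
  }
  atom_lines <- get_section("@<TRIPOS>ATOM")
  bond_lines <- get_section("@<TRIPOS>BOND")
  atoms <- do.call(rbind, lapply(strsplit(trimws(atom_lines), "[ \t]+"), function(f) {
    sybyl <- f[6]
    c(element = sub("\\..*$", "", sybyl),
      aromatic = grepl("\\.ar$", sybyl))
  }))
  bonds <- if (length(bond_lines) > 0) {
    m <- do.call(rbind, lapply(strsplit(trimws(bond_lines), "[ \t]+"), function(f) {
      as.integer(f[2:3])
    }))
    colnames(m) <- c("from", "to")
    m
  } else {
    matrix(integer(), ncol = 2, dimnames = list(NULL, c("from", "to")))
  }
  list(element = unname(atoms[, "element"]),
       aromatic = as.logical(atoms[, "aromatic"]),
       bonds = bonds)
}

#' Convert a SMILES string to a molecular graph
#'
#' Atoms (heavy atoms only, hydrogens implicit) become vertices and chemical
#' bonds undirected edges. Each atom is assigned a token for the embedding
#' table keyed by `(element, aromatic flag, heavy-atom degree)`; unseen keys
#' extend `atom_vocab` unless it is frozen, in which case they map to the
#' unknown index.
#'
#' @param smiles A single SMILES string.
#' @param atom_vocab A [new_vocab()] token vocabulary (mutated in place).
#' @param fp_radius Circular-fingerprint radius (default 2, ECFP4-equivalent).
#' @param fp_bits Fingerprint length in bits (default 1024).
#' @return A `compound_graph`: list with `atom_tokens`, `atom_keys`, `edges`
#'   (2-column matrix), `fingerprint` (0/1 integer vector), `n_atoms`,
#'   `smiles_canonical`.
#' @export
smiles_to_graph <- function(smiles, atom_vocab = new_vocab(),
                            fp_radius = 2L, fp_bits = 1024L) {
  can <- canonicalize_smiles(smiles)
  mol2 <- suppressWarnings(ChemmineOB::convertFormat("SMI", "MOL2", can))
  mol <- parse_mol2(mol2)
  n <- length(mol$element)
  if (n == 0) {
    abort(sprintf("SMILES '%s' yields an empty molecule", smiles),
          class = "thermokcat_smiles_parse_error")
  }
  edges <- mol$bonds
  if (nrow(edges) > 0) {
    if (any(edges[, 1] == edges[, 2])) abort("self-loop bond in molecular graph")
    if (any(edges > n)) abort("bond references a missing atom")
    edges <- cbind(from = pmin(edges[, 1], edges[, 2]),
                   to = pmax(edges[, 1], edges[, 2]))
  }
  degree <- tabulate(c(edges[, 1], edges[, 2]), nbins = n)
  keys <- sprintf("%s|%s|%d", mol$element,
                  ifelse(mol$aromatic, "ar", "al"), degree)
  structure(list(
    atom_tokens = vocab_lookup(atom_vocab, keys),
    atom_keys = keys,
    edges = edges,
    fingerprint = morgan_fingerprint(mol$element, mol$aromatic, edges,
                                     radius = fp_radius, nbits = fp_bits),
    n_atoms = n,
    smiles_canonical = can
  ), class = "compound_graph")
}

#' Circular (Morgan-style) fingerprint of a SMILES string
#'
#' Iteratively hashes each atom's environment out to `radius` bonds (initial
#' invariant: element, aromaticity, degree) and folds every environment
#' identifier into an `nbits`-long bit vector. Because neighbor identifiers
#' are sorted before hashing, the result is invariant to atom ordering and
#' hence to SMILES re-spelling.
#'
#' @param smiles A single SMILES string.
#' @param radius Environment radius in bonds (default 2).
#' @param nbits Number of bits (default 1024).
#' @return Integer 0/1 vector of length `nbits`.
#' @export
compute_fingerprint <- function(smiles, radius = 2L, nbits = 1024L) {
  g <- smiles_to_graph(smiles, new_vocab(), fp_radius = radius, fp_bits = nbits)
  g$fingerprint
}

# Deterministic 31-bit string hash (polynomial rolling hash; exact in
# doubles since intermediate values stay below 2^53).
hash_string <- function(s) {
  h <- 7
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  h
}

morgan_fingerprint <- function(element, aromatic, edges, radius = 2L,
                               nbits = 1024L) {
  n <- length(element)
  nbrs <- vector("list", n)
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      i <- edges[k, 1]; j <- edges[k, 2]
      nbrs[[i]] <- c(nbrs[[i]], j)
      nbrs[[j]] <- c(nbrs[[j]], i)
    }
  }
  degree <- lengths(nbrs)
  ids <- vapply(seq_len(n), function(i) {
    hash_string(sprintf("%s|%s|%d", element[i],
                        if (aromatic[i]) "ar" else "al", degree[i]))
  }, numeric(1))
  all_ids <- ids
  for (r in seq_len(radius)) {
    ids <- vapply(seq_len(n), function(i) {
      env_key <- paste(c(ids[i], sort(ids[nbrs[[i]]])), collapse = ",")
      hash_string(paste0("r", r, ":", env_key))
    }, numeric(1))
    all_ids <- c(all_ids, ids)
  }
  fp <- integer(nbits)
  fp[(all_ids %% nbits) + 1] <- 1L
  fp
}

#' @export
print.compound_graph <- function(x, ...) {
  cat(sprintf("<compound_graph: %s | %d atoms, %d bonds, %d fingerprint bits set>\n",
              x$smiles_canonical, x$n_atoms, nrow(x$edges), sum(x$fingerprint)))
  invisible(x)
}
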