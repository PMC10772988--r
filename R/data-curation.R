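#' Kinetics tables
#'
#' The package's tabular interchange format is a data frame with columns
#' `smiles` (substrate), `sequence` (enzyme amino acids), `temperature_C`
#' (degrees Celsius) and `kcat_s` (turnover number, 1/s). All curation verbs
#' take such a data frame first and return a tibble, so they chain with the
#' pipe.
#'
#' @name kinetics-tables
NULL

#' Read a kinetics CSV
#'
#' Expects UTF-8, '.' decimal, header columns `smiles`, `sequence`,
#' `temperature_C`, `kcat_s`. If `fasta` is given, a `sequence_id` column is
#' resolved against the FASTA ids instead of an inline `sequence` column.
#'
#' @param path CSV path.
#' @param fasta Optional FASTA path for sequences keyed by `sequence_id`.
#' @return A validated kinetics tibble with a `log10_kcat` column added.
#' @export
read_kinetics_csv <- function(path, fasta = NULL) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (!is.null(fasta)) {
    seqs <- read_fasta_sequences(fasta)
    if ("sequence_id" %notin% names(df)) {
      abort("With `fasta`, the CSV must carry a sequence_id column")
    }
    df <- dplyr::left_join(df, dplyr::rename(seqs, sequence_id = "id"),
                           by = "sequence_id")
  }
  validate_kinetics(df)
}

#' Validate a kinetics table and derive log10(kcat)
#'
#' @param data Kinetics data frame.
#' @return The data as a tibble with `log10_kcat` (re)computed.
#' @export
validate_kinetics <- function(data) {
  need <- c("smiles", "sequence", "temperature_C", "kcat_s")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    abort(paste("Kinetics table is missing column(s):",
                paste(miss, collapse = ", ")))
  }
  if (any(!is.finite(data$kcat_s)) || any(data$kcat_s <= 0)) {
    abort("kcat_s must be finite and strictly positive")
  }
  dplyr::mutate(tibble::as_tibble(data), log10_kcat = log10(.data$kcat_s))
}

#' Deduplicate kinetics entries
#'
#' Among entries sharing (smiles, sequence, temperature), only the one with
#' the largest kcat is kept; exact duplicates collapse to a single row. The
#' operation is idempotent.
#'
#' @param data Kinetics data frame.
#' @return Deduplicated tibble.
#' @export
deduplicate_kinetics <- function(data) {
  data <- validate_kinetics(data)
  data |>
    dplyr::group_by(.data$smiles, .data$sequence, .data$temperature_C) |>
    dplyr::arrange(dplyr::desc(.data$kcat_s), .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}

#' Oversample low- and high-temperature entries
#'
#' Entries below `t_low` or above `t_high` degrees Celsius are supplemented
#' with `factor` times their count of randomly drawn (with replacement)
#' duplicates, so each sparse range ends up at `factor + 1` times its
#' original multiplicity. Mid-range entries are untouched. The returned
#' order is shuffled deterministically by `seed`.
#'
#' @param data Kinetics data frame (deduplicated).
#' @param t_low,t_high Range bounds in degrees Celsius (defaults 20 and 40).
#' @param factor Integer number of extra copies per existing entry.
#' @param seed Integer RNG seed.
#' @return Oversampled tibble.
#' @export
oversample_kinetics <- function(data, t_low = 20, t_high = 40, factor = 2L,
                                seed = 1L) {
  data <- validate_kinetics(data)
  withr::with_seed(seed, {
    low <- which(data$temperature_C < t_low)
    high <- which(data$temperature_C > t_high)
    extra <- c(
      if (length(low) > 0) sample(low, factor * length(low), replace = TRUE),
      if (length(high) > 0) sample(high, factor * length(high), replace = TRUE)
    )
    out <- dplyr::bind_rows(data, data[extra, , drop = FALSE])
    out[sample(nrow(out)), , drop = FALSE]
  })
}

#' Split a kinetics table into train/validation/test partitions
#'
#' Random by entry (default) or protein-disjoint (`by = "protein"`: no
#' sequence appears in more than one partition). Partition sizes follow the
#' largest-remainder rule, so each is within one entry of `fraction * n`.
#' Oversampling, if used, should be applied to the training partition only,
#' after splitting, so duplicated entries cannot leak across partitions.
#'
#' @param data Kinetics data frame.
#' @param fractions Numeric triple (train, val, test) summing to 1.
#' @param seed Integer RNG seed.
#' @param by `"entry"` or `"protein"`.
#' @return Named list of tibbles: `train`, `val`, `test`.
#' @export
split_kinetics <- function(data, fractions = c(0.8, 0.1, 0.1), seed = 1L,
                           by = c("entry", "protein")) {
  by <- match.arg(by)
  data <- validate_kinetics(data)
  stopifnot(length(fractions) == 3, all(fractions > 0))
  if (abs(sum(fractions) - 1) > 1e-8) abort("Split fractions must sum to 1")
  units <- if (by == "entry") seq_len(nrow(data)) else unique(data$sequence)
  if (length(units) < 3) abort("Fewer units than partitions")
  sizes <- largest_remainder(length(units) * fractions)
  while (any(sizes == 0)) {  # every partition gets at least one unit
    sizes[which.max(sizes)] <- max(sizes) - 1L
    sizes[which.min(sizes)] <- min(sizes) + 1L
  }
  withr::with_seed(seed, {
    perm <- sample(length(units))
  })
  cut1 <- sizes[1]; cut2 <- sizes[1] + sizes[2]
  groups <- list(train = perm[seq_len(cut1)],
                 val = perm[(cut1 + 1):cut2],
                 test = perm[(cut2 + 1):length(units)])
  if (by == "entry") {
    lapply(groups, function(i) data[sort(i), , drop = FALSE])
  } else {
    lapply(groups, function(i) {
      data[data$sequence %in% units[i], , drop = FALSE]
    })
  }
}

largest_remainder <- function(target) {
  fl <- floor(target)
  rem <- sum(round(sum(target))) - sum(fl)
  if (rem > 0) {
    order_rem <- order(target - fl, decreasing = TRUE)
    fl[order_rem[seq_len(rem)]] <- fl[order_rem[seq_len(rem)]] + 1
  }
  as.integer(fl)
}
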