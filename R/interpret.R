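#' Residue attention weights for one substrate/enzyme/temperature input
#'
#' Extracts the residue-direction attention vectors (`alpha_r2a`) of every
#' head from the model's forward pass — the same code path used for
#' prediction, so the profile is bit-identical to what the regressor saw.
#' The weight of 3-mer `j` is assigned to its center residue (1-based
#' position `j + 1`).
#'
#' @param object A fitted `kcat_model`.
#' @param smiles Substrate SMILES.
#' @param sequence Enzyme amino-acid sequence.
#' @param temperature_C Temperature in degrees Celsius.
#' @param use_best Use the best-validation checkpoint (default TRUE).
#' @return A `residue_attention` object: `per_head` (heads x N_r matrix),
#'   `mean_profile`, `positions` (center residue of each 3-mer), `sequence`.
#' @export
residue_attention <- function(object, smiles, sequence, temperature_C,
                              use_best = TRUE) {
  params <- if (use_best) object$best_params else object$params
  cfg <- object$config
  g <- smiles_to_graph(smiles, object$atom_vocab)
  tk <- protein_to_kmers(sequence, kmer_vocab = object$kmer_vocab)
  th <- normalize_temperature(temperature_C, object$thermo_stats, quiet = TRUE)
  feats <- list(atom_tokens = g$atom_tokens, edges = g$edges,
                kmer_tokens = tk$kmer_tokens, fingerprint = g$fingerprint,
                t_norm = th$t_norm, invt_norm = th$invt_norm)
  fw <- forward_sample(feats, params, cfg)
  per_head <- fw$attention$alpha_r2a
  mean_profile <- colMeans(per_head)
  structure(list(per_head = per_head,
                 mean_profile = mean_profile,
                 positions = seq_len(tk$n_kmers) + 1L,
                 sequence = sequence,
                 prediction = fw$y),
            class = "residue_attention")
}

#' @describeIn residue_attention Long-format tibble: position, head, weight.
#' @param x A `residue_attention` object.
#' @export
tidy.residue_attention <- function(x, ...) {
  n_head <- nrow(x$per_head)
  dplyr::bind_rows(
    purrr::map_dfr(seq_len(n_head), function(h) {
      tibble::tibble(position = x$positions, head = paste0("head", h),
                     weight = x$per_head[h, ])
    }),
    tibble::tibble(position = x$positions, head = "mean",
                   weight = x$mean_profile)
  )
}

#' @describeIn residue_attention Attention profile along the sequence.
#' @export
autoplot.residue_attention <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$weight,
                                   colour = .data$head)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "residue position", y = "attention weight",
                  title = "Residue attention profile") +
    ggplot2::theme_minimal()
}

#' @export
print.residue_attention <- function(x, ...) {
  cat(sprintf("<residue_attention: %d heads x %d residues | predicted log10(kcat) %.3f>\n",
              nrow(x$per_head), length(x$mean_profile), x$prediction))
  invisible(x)
}

# Local maxima of a profile. A maximal run (plateau) counts as one peak at
# its leftmost position; a run is a peak only if every existing neighbor run
# is strictly lower, and a constant profile has no peaks.
profile_peaks <- function(values, positions = seq_along(values)) {
  r <- rle(values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- vapply(seq_along(r$values), function(k) {
    left_ok <- k == 1 || r$values[k - 1] < r$values[k]
    right_ok <- k == length(r$values) || r$values[k + 1] < r$values[k]
    has_nbr <- length(r$values) > 1
    has_nbr && left_ok && right_ok
  }, logical(1))
  positions[starts[keep]]
}

#' Relate mutation sites to peaks of a residue attention profile
#'
#' For each annotated mutation, reports the distance (in residues) to the
#' nearest local maximum of the mean attention profile, and summarizes the
#' fraction of severe mutations (fold change below `severe_threshold`)
#' lying within `window` residues of a peak. Ties in nearest-peak distance
#' resolve to the lower peak position. Peak finding depends only on the
#' ordering of weights, so the report is invariant to uniform rescaling of
#' the profile.
#'
#' @param profile A [residue_attention()] object.
#' @param annotations Data frame with columns `position` (1-based residue
#'   index) and `fold_change` (mutant/WT kcat ratio, > 0).
#' @param window Peak-proximity window in residues (default 10).
#' @param severe_threshold Fold change below which a mutation counts as
#'   severe (default 0.1, i.e. <0.1-fold of wild-type kcat).
#' @return A `mutation_report`: list with `report` (per-mutation tibble),
#'   `peaks`, and `summary` (one-row tibble).
#' @export
annotate_mutations <- function(profile, annotations, window = 10L,
                               severe_threshold = 0.1) {
  stopifnot(inherits(profile, "residue_attention"))
  annotations <- tibble::as_tibble(annotations)
  if (nrow(annotations) > 0) {
    stopifnot(all(c("position", "fold_change") %in% names(annotations)))
    if (any(annotations$fold_change <= 0)) abort("fold_change must be > 0")
    seq_len_aa <- nchar(profile$sequence)
    if (any(annotations$position < 1 | annotations$position > seq_len_aa)) {
      abort("Mutation position outside the sequence")
    }
  }
  peaks <- profile_peaks(profile$mean_profile, profile$positions)
  report <- if (nrow(annotations) == 0) {
    tibble::tibble(position = integer(), fold_change = numeric(),
                   severe = logical(), nearest_peak = integer(),
                   distance = numeric())
  } else {
    annotations |>
      dplyr::mutate(
        severe = .data$fold_change < severe_threshold,
        nearest_peak = vapply(.data$position, function(p) {
          if (length(peaks) == 0) return(NA_integer_)
          dd <- abs(peaks - p)
          as.integer(min(peaks[dd == min(dd)]))
        }, integer(1)),
        distance = abs(.data$nearest_peak - .data$position)
      )
  }
  n_severe <- sum(report$severe)
  summary <- tibble::tibble(
    n_mutations = nrow(report),
    n_severe = n_severe,
    n_peaks = length(peaks),
    frac_severe_near_peak = if (n_severe == 0) NA_real_ else {
      sum(report$severe & !is.na(report$distance) &
            report$distance <= window) / n_severe
    },
    window = as.integer(window)
  )
  structure(list(report = report, peaks = peaks, summary = summary),
            class = "mutation_report")
}

#' @export
print.mutation_report <- function(x, ...) {
  cat(sprintf("<mutation_report: %d mutations, %d peaks>\n",
              x$summary$n_mutations, x$summary$n_peaks))
  print(x$summary)
  invisible(x)
}

#' Predict kcat for a panel of enzyme variants across temperatures
#'
#' Applies each mutation spec to the wild-type sequence and predicts
#' log10(kcat) for every variant at every temperature. The wild type is
#' always included as the baseline, and fold changes are reported against
#' the wild-type prediction at the same temperature.
#'
#' @param object A fitted `kcat_model`.
#' @param wild_type Wild-type amino-acid sequence.
#' @param specs Character vector of mutation specs ("Y227C", "A240D/E277G");
#'   may be empty.
#' @param smiles Substrate SMILES.
#' @param temps_C Numeric vector of temperatures (degrees Celsius).
#' @param use_best Use the best-validation checkpoint.
#' @return Tibble with one row per variant x temperature: `variant`, `spec`,
#'   `temperature_C`, `pred_log10_kcat`, `pred_kcat_s`, `fold_change_vs_wt`.
#' @export
mutant_scan <- function(object, wild_type, specs, smiles, temps_C,
                        use_best = TRUE) {
  variants <- tibble::tibble(
    variant = c("WT", if (length(specs) > 0) specs),
    spec = c(NA_character_, if (length(specs) > 0) specs),
    sequence = c(wild_type, vapply(specs, apply_mutations,
                                   character(1), wild_type = wild_type))
  )
  grid <- tidyr::crossing(variants, temperature_C = temps_C) |>
    dplyr::mutate(smiles = smiles)
  pred <- predict(object, grid, use_best = use_best)
  wt <- pred |>
    dplyr::filter(.data$variant == "WT") |>
    dplyr::select("temperature_C", wt_log10 = "pred_log10_kcat")
  pred |>
    dplyr::left_join(wt, by = "temperature_C") |>
    dplyr::mutate(fold_change_vs_wt = 10^(.data$pred_log10_kcat - .data$wt_log10)) |>
    dplyr::select("variant", "spec", "temperature_C", "pred_log10_kcat",
                  "pred_kcat_s", "fold_change_vs_wt")
}
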