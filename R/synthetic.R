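#' Synthetic Arrhenius kinetics data
#'
#' Generates desk-scale datasets with the statistical structure the model
#' assumes: each compound-protein pair has a pre-exponential amplitude
#' (log10 A) and an activation energy Ea, and its turnover number follows
#' the Arrhenius law `kcat(T) = 10^logA * exp(-Ea / (R T))` with
#' multiplicative log-normal noise. So that sequence and compound encoders
#' can in principle learn the kinetics, logA is a linear function of the
#' counts of three designated 3-mer motifs planted in the protein sequence,
#' and Ea is tied to the substrate's heteroatom count.
#'
#' @name synthetic-data
NULL

GAS_CONSTANT <- 8.314  # J/(mol K)

ARRHENIUS_MOTIFS <- c("WWH", "KKY", "DDF")

#' Specification of a synthetic Arrhenius dataset
#'
#' Defaults emulate the temperature structure of curated kinetics databases:
#' six measurement temperatures with most in the 20-40 degC range and sparse
#' coverage below 20 and above 40 degC, 60 compound-protein pairs, log10
#' amplitudes in \[6, 12\] combined with the 20-80 kJ/mol activation
#' energies typical of enzymatic reactions (together spanning several orders
#' of magnitude in kcat, mirroring the heavy-tailed spread of database
#' entries), and multiplicative noise of 0.1 log10 units.
#'
#' @param n_pairs Number of compound-protein pairs.
#' @param temps_C Measurement temperatures (degrees Celsius).
#' @param logA_range Range of log10 pre-exponential amplitudes (log10 1/s).
#' @param Ea_range Range of activation energies (J/mol).
#' @param noise_sigma Multiplicative noise, log10 units.
#' @param seq_len_range Protein sequence length range.
#' @param seed Integer RNG seed.
#' @return An `arrhenius_spec` list.
#' @export
arrhenius_spec <- function(n_pairs = 60L, temps_C = c(10, 20, 25, 30, 37, 50),
                           logA_range = c(6, 12),
                           Ea_range = c(20000, 80000), noise_sigma = 0.1,
                           seq_len_range = c(50L, 300L), seed = 1L) {
  stopifnot(n_pairs >= 1, length(temps_C) >= 1,
            logA_range[1] <= logA_range[2], Ea_range[1] <= Ea_range[2],
            noise_sigma >= 0, seq_len_range[1] >= 3)
  structure(list(n_pairs = as.integer(n_pairs), temps_C = temps_C,
                 logA_range = logA_range, Ea_range = Ea_range,
                 noise_sigma = noise_sigma,
                 seq_len_range = as.integer(seq_len_range),
                 R = GAS_CONSTANT, seed = as.integer(seed)),
            class = "arrhenius_spec")
}

# ~50 small-molecule templates; decoration prepends a short alkyl chain,
# which keeps every template valid (all start with an aliphatic carbon or
# are used undecorated).
smiles_templates <- function() {
  c("C", "CC", "CCC", "CCCC", "CCCCC", "CCO", "CCCO", "CCCCO",
    "CC(=O)O", "CCC(=O)O", "CCCC(=O)O", "CC(N)C(=O)O", "CC(O)C(=O)O",
    "CCN", "CCCN", "CC(C)O", "CC(C)C", "CC(C)CO", "CCOC", "CCOCC",
    "CC(=O)C", "CCC(=O)C", "CSC", "CCSC", "CC=CC", "C=CCO", "CC(C)(C)O",
    "CC(=O)C(=O)O", "CC(=O)N", "CCC#N", "C1CCCCC1", "C1CCCC1",
    "C1CCCCC1O", "Cc1ccccc1", "Cc1ccccc1O", "Cc1ccccc1N", "CC(=O)Oc1ccccc1",
    "OCC(O)CO", "OCC(O)C(O)CO", "OC(=O)C(O)C(O)C(=O)O", "OCCO", "OCCCO",
    "OC(=O)CCC(=O)O", "NCCO", "NCCCO", "OC(=O)CO", "OCC(=O)CO",
    "NC(=O)CC", "OCC1OC(O)C(O)C(O)C1O", "c1ccccc1")
}

decorate_smiles <- function(template, n_extra) {
  if (n_extra <= 0 || !startsWith(template, "C")) return(template)
  paste0(strrep("C", n_extra), template)
}

random_sequence <- function(len, motif_counts) {
  chars <- sample(AA_STANDARD, len, replace = TRUE)
  # plant designated motifs at non-overlapping positions
  slots <- seq(1, len - 2, by = 3)
  needed <- sum(motif_counts)
  if (needed > 0) {
    at <- sample(slots, min(needed, length(slots)))
    motifs <- rep(ARRHENIUS_MOTIFS, times = motif_counts)[seq_along(at)]
    for (k in seq_along(at)) {
      chars[at[k]:(at[k] + 2)] <- strsplit(motifs[k], "")[[1]]
    }
  }
  paste(chars, collapse = "")
}

count_heteroatoms <- function(smiles) {
  sum(strsplit(toupper(smiles), "")[[1]] %in% c("O", "N", "S"))
}

#' Generate a synthetic Arrhenius kinetics dataset
#'
#' @param spec An [arrhenius_spec()].
#' @return A `synthetic_kinetics` object: `entries` (kinetics tibble with
#'   `pair_id`) and `truth` (per-pair tibble with the generating `logA`,
#'   `Ea`).
#' @export
generate_arrhenius_dataset <- function(spec = arrhenius_spec()) {
  stopifnot(inherits(spec, "arrhenius_spec"))
  withr::with_seed(spec$seed, {
    lib <- smiles_templates()
    pairs <- purrr::map_dfr(seq_len(spec$n_pairs), function(i) {
      template <- lib[(i - 1) %% length(lib) + 1]
      smiles <- decorate_smiles(template, (i - 1) %/% length(lib))
      motif_counts <- sample(0:4, 3, replace = TRUE)
      len <- sample(spec$seq_len_range[1]:spec$seq_len_range[2], 1)
      sequence <- random_sequence(len, motif_counts)
      # logA: linear in planted motif counts (range-normalized), small jitter
      frac <- sum(motif_counts) / 12
      logA <- spec$logA_range[1] +
        diff(spec$logA_range) * pmin(pmax(frac + rnorm(1, 0, 0.03), 0), 1)
      # Ea: tied to substrate heteroatom count
      h <- min(count_heteroatoms(smiles), 6)
      Ea <- spec$Ea_range[1] + diff(spec$Ea_range) * h / 6
      tibble::tibble(pair_id = sprintf("pair%03d", i), smiles = smiles,
                     sequence = sequence, logA = logA, Ea = Ea)
    })
    entries <- tidyr::crossing(pairs, temperature_C = spec$temps_C) |>
      dplyr::mutate(
        t_K = celsius_to_kelvin(.data$temperature_C),
        eps = rnorm(dplyr::n(), 0, spec$noise_sigma),
        kcat_s = 10^(.data$logA + .data$eps) * exp(-.data$Ea / (spec$R * .data$t_K)),
        log10_kcat = log10(.data$kcat_s)
      ) |>
      dplyr::select("pair_id", "smiles", "sequence", "temperature_C",
                    "kcat_s", "log10_kcat")
    structure(list(entries = entries,
                   truth = dplyr::select(pairs, "pair_id", "smiles",
                                         "sequence", "logA", "Ea"),
                   spec = spec),
              class = "synthetic_kinetics")
  })
}

#' @export
print.synthetic_kinetics <- function(x, ...) {
  cat(sprintf("<synthetic_kinetics: %d entries, %d pairs, %d temperatures>\n",
              nrow(x$entries), nrow(x$truth),
              length(unique(x$entries$temperature_C))))
  invisible(x)
}

#' Add mutant enzymes with shifted amplitudes to a synthetic dataset
#'
#' For `n_mutants` randomly chosen pairs, a point-mutated copy of the
#' sequence is added whose true log10 amplitude is shifted by a uniform
#' draw from `[-effect_range, effect_range]`; the mutated position is
#' recorded as ground truth.
#'
#' @param dataset A [generate_arrhenius_dataset()] result.
#' @param n_mutants Number of mutants (at most the number of pairs).
#' @param effect_range Half-width of the amplitude shift, log10 units.
#' @param seed Integer RNG seed.
#' @return The dataset with mutant entries appended and a `mutants` tibble
#'   (`pair_id`, `parent_id`, `position`, `ref`, `alt`, `delta_logA`).
#' @export
inject_mutation_effects <- function(dataset, n_mutants, effect_range = 1,
                                    seed = 1L) {
  stopifnot(inherits(dataset, "synthetic_kinetics"), n_mutants >= 0)
  if (n_mutants > nrow(dataset$truth)) {
    abort("n_mutants exceeds the number of available pairs")
  }
  spec <- dataset$spec
  withr::with_seed(seed, {
    chosen <- sample(nrow(dataset$truth), n_mutants)
    muts <- purrr::map_dfr(seq_along(chosen), function(k) {
      parent <- dataset$truth[chosen[k], ]
      chars <- strsplit(parent$sequence, "")[[1]]
      pos <- sample(length(chars), 1)
      ref <- chars[pos]
      alt <- sample(setdiff(AA_STANDARD, ref), 1)
      chars[pos] <- alt
      delta <- runif(1, -effect_range, effect_range)
      tibble::tibble(pair_id = sprintf("%s_m%d", parent$pair_id, k),
                     parent_id = parent$pair_id,
                     smiles = parent$smiles,
                     sequence = paste(chars, collapse = ""),
                     position = pos, ref = ref, alt = alt,
                     delta_logA = delta,
                     logA = parent$logA + delta, Ea = parent$Ea)
    })
    if (nrow(muts) > 0) {
      new_entries <- tidyr::crossing(
        dplyr::select(muts, "pair_id", "smiles", "sequence", "logA", "Ea"),
        temperature_C = spec$temps_C) |>
        dplyr::mutate(
          t_K = celsius_to_kelvin(.data$temperature_C),
          eps = rnorm(dplyr::n(), 0, spec$noise_sigma),
          kcat_s = 10^(.data$logA + .data$eps) *
            exp(-.data$Ea / (spec$R * .data$t_K)),
          log10_kcat = log10(.data$kcat_s)
        ) |>
        dplyr::select("pair_id", "smiles", "sequence", "temperature_C",
                      "kcat_s", "log10_kcat")
      dataset$entries <- dplyr::bind_rows(dataset$entries, new_entries)
      dataset$truth <- dplyr::bind_rows(
        dataset$truth,
        dplyr::select(muts, "pair_id", "smiles", "sequence", "logA", "Ea"))
    }
    dataset$mutants <- dplyr::select(muts, "pair_id", "parent_id", "position",
                                     "ref", "alt", "delta_logA")
    dataset
  })
}

#' Generate a toy metabolic model with proteome sectors
#'
#' Builds a ~10-reaction fermentation chain (carbon uptake, five catabolic
#' steps with randomized turnover numbers and molar masses, lactate and
#' acetate export, ATP maintenance, a ribosome-driven biomass reaction)
#' that is feasible and bounded. The analytically derived optimum of the
#' proteome-constrained problem is recorded alongside for verification:
#' growth is the smaller of the uptake-limited value and the
#' sector-budget-limited value.
#'
#' @param seed Integer RNG seed.
#' @param uptake_ub Carbon uptake bound (mmol/gDW/h, default 10).
#' @return List with `model` ([metabolic_model()]), `sectors`
#'   ([proteome_sector_spec()]), `hand_optimum` (closed-form
#'   proteome-constrained optimum), `unconstrained_optimum` (closed-form
#'   plain-FBA optimum).
#' @export
generate_toy_gsmm <- function(seed = 1L, uptake_ub = 10) {
  withr::with_seed(seed, {
    kcats <- stats::setNames(runif(5, 20, 200),
                             c("GLYC", "GAPD", "PGK", "LDH", "PTA"))
    mws <- stats::setNames(runif(5, 3e4, 2e5), names(kcats))
  })
  reactions <- tibble::tibble(
    id = c("GLC_upt", "GLYC", "GAPD", "PGK", "LDH", "PTA",
           "LAC_ex", "AC_ex", "ATPM", "BIOMASS"),
    stoichiometry = list(
      c(glc = 1),                        # uptake
      c(glc = -1, g3p = 2),              # glucose -> 2 triose-P
      c(g3p = -1, bpg = 1),              # oxidation
      c(bpg = -1, pyr = 1, atp = 1),     # substrate-level phosphorylation
      c(pyr = -1, lac = 1),              # lactate branch
      c(pyr = -1, ac = 1),               # acetate branch
      c(lac = -1),
      c(ac = -1),
      c(atp = -1),                       # maintenance / ATP sink
      c(pyr = -1.5, atp = -2.5)          # biomass
    ),
    lb = rep(0, 10),
    ub = c(uptake_ub, rep(Inf, 9))
  )
  model <- metabolic_model(reactions, objective = "BIOMASS")
  sectors <- proteome_sector_spec(
    catabolic = tibble::tibble(
      id = names(kcats), mode = "turnover",
      kcat_s = unname(kcats), MW_g_per_mol = unname(mws)
    ),
    transport_CT = "GLC_upt", transport_AT = c("LAC_ex", "AC_ex")
  )

  # Closed-form optimum. Per unit growth mu: biomass needs 1.5 pyr and
  # 2.5 atp; ATP forces uptake u = 1.25 mu (ATPM = 0 at optimum), so GAPD
  # and PGK carry 2.5 mu, and 1.0 mu of excess pyruvate leaves through the
  # cheaper of the two export branches. Growth is capped by uptake
  # (mu <= 0.8 * uptake_ub) and by the sector budget B = (1 - phi_Q) P_TOT.
  w <- (mws / 1000) / (kcats * 3600)
  branch <- min(w[["LDH"]], w[["PTA"]]) + 1 / sectors$a_AT
  cost_per_mu <- 1 / sectors$a_ribosome +
    1.25 * w[["GLYC"]] + 2.5 * (w[["GAPD"]] + w[["PGK"]]) +
    branch + 1.25 / sectors$a_CT
  budget <- (1 - sectors$phi_Q) * sectors$P_TOT
  hand_optimum <- min(0.8 * uptake_ub, budget / cost_per_mu)

  list(model = model, sectors = sectors, hand_optimum = hand_optimum,
       unconstrained_optimum = 0.8 * uptake_ub)
}

#' Write a synthetic dataset to the standard kinetics CSV schema
#'
#' @param dataset A `synthetic_kinetics` object.
#' @param data_path CSV path for the entries.
#' @param truth_path Optional CSV path for the generating parameters.
#' @export
write_synthetic_csv <- function(dataset, data_path, truth_path = NULL) {
  utils::write.csv(
    dplyr::select(dataset$entries, "smiles", "sequence", "temperature_C",
                  "kcat_s"),
    data_path, row.names = FALSE)
  if (!is.null(truth_path)) {
    utils::write.csv(dataset$truth, truth_path, row.names = FALSE)
  }
  invisible(data_path)
}
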