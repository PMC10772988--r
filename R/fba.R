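#' Metabolic models and flux balance analysis
#'
#' A minimal constraint-based model: stoichiometric matrix `S` (metabolites
#' x reactions), per-reaction flux bounds (mmol/gDW/h) and a growth
#' objective. FBA maximizes the objective flux subject to steady state
#' (`S v = 0`) and the bounds; the proteome extension adds a single linear
#' enzyme-capacity constraint over flux magnitudes.
#'
#' @name fba-module
NULL

#' Construct a metabolic model
#'
#' @param reactions A data frame (or tibble) with columns `id` (character),
#'   `stoichiometry` (list-column of named numeric vectors, negative =
#'   consumed), `lb`, `ub` (numeric bounds, `-Inf`/`Inf` allowed).
#' @param objective Reaction id to maximize (the growth reaction).
#' @return A `metabolic_model` object.
#' @export
metabolic_model <- function(reactions, objective) {
  reactions <- tibble::as_tibble(reactions)
  stopifnot(all(c("id", "stoichiometry", "lb", "ub") %in% names(reactions)))
  if (anyDuplicated(reactions$id)) abort("Duplicate reaction ids")
  if (objective %notin% reactions$id) {
    abort(sprintf("Objective reaction '%s' not in the model", objective))
  }
  if (any(reactions$lb > reactions$ub)) abort("lb > ub for some reaction")
  mets <- sort(unique(unlist(lapply(reactions$stoichiometry, names))))
  S <- matrix(0, length(mets), nrow(reactions),
              dimnames = list(mets, reactions$id))
  for (j in seq_len(nrow(reactions))) {
    st <- reactions$stoichiometry[[j]]
    if (length(st) > 0) S[names(st), j] <- st
  }
  structure(list(S = S, reaction_ids = reactions$id, metabolite_ids = mets,
                 lb = stats::setNames(reactions$lb, reactions$id),
                 ub = stats::setNames(reactions$ub, reactions$id),
                 objective = objective, proteome = NULL),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model: %d metabolites x %d reactions | objective %s%s>\n",
              nrow(x$S), ncol(x$S), x$objective,
              if (!is.null(x$proteome)) " | proteome-constrained" else ""))
  invisible(x)
}

#' Read / write the native JSON model dialect
#'
#' @param path JSON file path.
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path)
  reactions <- tibble::tibble(
    id = vapply(doc$reactions, `[[`, character(1), "id"),
    stoichiometry = lapply(doc$reactions, function(r) {
      unlist(r$stoichiometry) %||% stats::setNames(numeric(), character())
    }),
    lb = vapply(doc$reactions, function(r) json_num(r$lb), numeric(1)),
    ub = vapply(doc$reactions, function(r) json_num(r$ub), numeric(1))
  )
  metabolic_model(reactions, doc$objective)
}

json_num <- function(x) {
  if (is.character(x)) {
    switch(x, "Inf" = Inf, "-Inf" = -Inf, as.numeric(x))
  } else {
    as.numeric(x)
  }
}

#' @param model A `metabolic_model`.
#' @rdname read_model_json
#' @export
write_model_json <- function(model, path) {
  doc <- list(
    objective = model$objective,
    reactions = lapply(model$reaction_ids, function(id) {
      st <- model$S[, id]
      st <- st[st != 0]
      list(id = id, stoichiometry = as.list(st),
           lb = if (is.finite(model$lb[[id]])) model$lb[[id]] else
             as.character(model$lb[[id]]),
           ub = if (is.finite(model$ub[[id]])) model$ub[[id]] else
             as.character(model$ub[[id]]))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an SBML Level 3 model (core + fbc bounds)
#'
#' Supports the subset needed for genome-scale FBA: species, reactions with
#' reactant/product stoichiometries, flux bounds from fbc attributes and
#' global parameters (falling back to the `reversible` flag with default
#' bounds of +/-1000), and the fbc objective (falling back to a reaction id
#' matching "biomass" or "growth").
#'
#' @param path SBML file path.
#' @param default_bound Magnitude used when no explicit bound is present.
#' @return A `metabolic_model`.
#' @export
read_sbml_model <- function(path, default_bound = 1000) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))
  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (length(rx_nodes) == 0) abort("No reactions found in SBML file")
  get_stoich <- function(node) {
    sp <- function(xp, sgn) {
      refs <- xml2::xml_find_all(node, xp)
      if (length(refs) == 0) return(stats::setNames(numeric(), character()))
      coef <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      coef[is.na(coef)] <- 1
      stats::setNames(sgn * coef, xml2::xml_attr(refs, "species"))
    }
    r <- sp("./listOfReactants/speciesReference", -1)
    p <- sp("./listOfProducts/speciesReference", +1)
    both <- c(r, p)
    tapply(both, names(both), sum)[unique(names(both))]
  }
  ids <- xml2::xml_attr(rx_nodes, "id")
  reversible <- xml2::xml_attr(rx_nodes, "reversible") %in% c("true", "1")
  lb_ref <- xml2::xml_attr(rx_nodes, "lowerFluxBound")
  ub_ref <- xml2::xml_attr(rx_nodes, "upperFluxBound")
  lb <- ifelse(!is.na(lb_ref) & lb_ref %in% names(pval), pval[lb_ref],
               ifelse(reversible, -default_bound, 0))
  ub <- ifelse(!is.na(ub_ref) & ub_ref %in% names(pval), pval[ub_ref],
               default_bound)
  reactions <- tibble::tibble(
    id = ids,
    stoichiometry = lapply(rx_nodes, function(n) {
      s <- get_stoich(n)
      stats::setNames(as.numeric(s), names(s))
    }),
    lb = as.numeric(lb), ub = as.numeric(ub)
  )
  obj_node <- xml2::xml_find_first(doc, ".//listOfObjectives//fluxObjective")
  objective <- if (!inherits(obj_node, "xml_missing")) {
    xml2::xml_attr(obj_node, "reaction")
  } else {
    hit <- grep("biomass|growth", ids, ignore.case = TRUE, value = TRUE)
    if (length(hit) == 0) abort("No objective found in SBML file")
    hit[1]
  }
  metabolic_model(reactions, objective)
}

#' Proteome sector specification
#'
#' Splits the proteome into an inflexible housekeeping sector (mass fraction
#' `phi_Q`, 50% by default) and flexible anabolic, catabolic and transport
#' sectors sharing the remaining `(1 - phi_Q) * P_TOT` grams of protein per
#' gDW. Ribosome activity defaults to 107.4 mmol/h/gE, acid export to
#' 6360 mmol/h/gE and carbon uptake to 361.14 mmol/h/gE (the glucose
#' phosphotransferase value; use 540 for a lactose antiporter).
#'
#' @param catabolic Data frame with columns `id`, `mode` ("turnover" or
#'   "specific_activity"), and `kcat_s` + `MW_g_per_mol` (turnover mode) or
#'   `a_umol_min_mg` (specific-activity mode).
#' @param transport_CT,transport_AT Character vectors of carbon-uptake and
#'   acid-export reaction ids.
#' @param phi_Q Housekeeping mass fraction (0.5).
#' @param P_TOT Total proteome mass per gDW (g/gDW, default 0.5).
#' @param a_ribosome,a_AT,a_CT Specific activities in mmol/h/gE.
#' @return A `proteome_sectors` object.
#' @export
proteome_sector_spec <- function(catabolic, transport_CT = character(),
                                 transport_AT = character(), phi_Q = 0.5,
                                 P_TOT = 0.5, a_ribosome = 107.4,
                                 a_AT = 6360, a_CT = 361.14) {
  stopifnot(phi_Q > 0, phi_Q < 1, P_TOT > 0, a_ribosome > 0, a_AT > 0, a_CT > 0)
  catabolic <- tibble::as_tibble(catabolic)
  stopifnot(all(c("id", "mode") %in% names(catabolic)))
  for (i in seq_len(nrow(catabolic))) {
    m <- catabolic$mode[i]
    if (m == "turnover") {
      if (!is_scalar_number(catabolic$kcat_s[i]) || catabolic$kcat_s[i] <= 0 ||
          !is_scalar_number(catabolic$MW_g_per_mol[i]) || catabolic$MW_g_per_mol[i] <= 0) {
        abort(sprintf("Catabolic reaction '%s' (turnover mode) needs positive kcat_s and MW_g_per_mol",
                      catabolic$id[i]))
      }
    } else if (m == "specific_activity") {
      if (!is_scalar_number(catabolic$a_umol_min_mg[i]) || catabolic$a_umol_min_mg[i] <= 0) {
        abort(sprintf("Catabolic reaction '%s' (specific-activity mode) needs positive a_umol_min_mg",
                      catabolic$id[i]))
      }
    } else {
      abort(sprintf("Unknown catabolic mode '%s'", m))
    }
  }
  structure(list(catabolic = catabolic, transport_CT = transport_CT,
                 transport_AT = transport_AT, phi_Q = phi_Q, P_TOT = P_TOT,
                 a_ribosome = a_ribosome, a_AT = a_AT, a_CT = a_CT),
            class = "proteome_sectors")
}

# Per-reaction proteome-mass cost (g of enzyme per unit flux, g*h/mmol).
# Unit conversions are centralized here: kcat 1/s -> 3600/h; MW g/mol ->
# g/mmol by /1000; specific activity umol/min/mg == mmol/h/g after *60.
proteome_weights <- function(model, sectors) {
  w <- stats::setNames(numeric(length(model$reaction_ids)), model$reaction_ids)
  w[model$objective] <- 1 / sectors$a_ribosome
  for (i in seq_len(nrow(sectors$catabolic))) {
    id <- sectors$catabolic$id[i]
    if (id %notin% model$reaction_ids) {
      abort(sprintf("Catabolic reaction '%s' is not in the model", id),
            class = "thermokcat_config_error")
    }
    w[id] <- if (sectors$catabolic$mode[i] == "turnover") {
      (sectors$catabolic$MW_g_per_mol[i] / 1000) /
        (sectors$catabolic$kcat_s[i] * 3600)
    } else {
      1 / (sectors$catabolic$a_umol_min_mg[i] * 60)
    }
  }
  for (id in sectors$transport_CT) w[id] <- 1 / sectors$a_CT
  for (id in sectors$transport_AT) w[id] <- 1 / sectors$a_AT
  w
}

#' Add the proteome-sector constraint to a model
#'
#' Adds the single pooled linear constraint
#' `v_growth/a_ribosome + sum_i |v_i| MW_i/k_i (or |v_i|/a_i) + v_AT/a_AT +
#' v_CT/a_CT <= (1 - phi_Q) P_TOT`. Reversible reactions are split into
#' forward/backward fluxes at solve time so each direction consumes enzyme
#' capacity.
#'
#' @param model A `metabolic_model`.
#' @param sectors A [proteome_sector_spec()].
#' @return The constrained model.
#' @export
add_proteome_constraints <- function(model, sectors) {
  stopifnot(inherits(model, "metabolic_model"),
            inherits(sectors, "proteome_sectors"))
  model$proteome <- list(
    weights = proteome_weights(model, sectors),
    rhs = (1 - sectors$phi_Q) * sectors$P_TOT,
    sectors = sectors
  )
  model
}

#' Flux balance analysis
#'
#' Maximizes the objective flux subject to `S v = 0`, the flux bounds and
#' (if present) the proteome constraint. Reversible reactions are split into
#' non-negative forward/backward components for the LP.
#'
#' @param model A `metabolic_model`.
#' @return An `fba_solution`: list with `growth` (objective value), `fluxes`
#'   (named vector), `status` ("optimal", "infeasible" or "unbounded") and
#'   `proteome_usage` (left-hand side of the sector constraint, or NA).
#' @export
fba <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  rid <- model$reaction_ids
  lb <- model$lb; ub <- model$ub
  # forward/backward split: x_fwd in [max(lb,0), max(ub,0)],
  # x_bwd in [max(-ub,0), max(-lb,0)]
  fwd_lb <- pmax(lb, 0); fwd_ub <- pmax(ub, 0)
  bwd_lb <- pmax(-ub, 0); bwd_ub <- pmax(-lb, 0)
  has_bwd <- lb < 0
  nb <- sum(has_bwd)
  Aeq <- cbind(model$S, if (nb > 0) -model$S[, has_bwd, drop = FALSE])
  ncols <- ncol(Aeq)
  col_ub <- c(fwd_ub, bwd_ub[has_bwd])
  col_lb <- c(fwd_lb, bwd_lb[has_bwd])
  cc <- numeric(ncols)
  obj_j <- match(model$objective, rid)
  cc[obj_j] <- 1
  if (has_bwd[obj_j]) cc[ncol(model$S) + match(obj_j, which(has_bwd))] <- -1

  # cap free columns at a large finite bound: keeps the simplex bounded and
  # lets unboundedness be detected from the solution hitting the cap
  BIG <- 1e9
  col_ub[!is.finite(col_ub)] <- BIG
  rows <- list(); rhs <- numeric()
  fin <- which(is.finite(col_ub))
  for (k in fin) {
    r <- numeric(ncols); r[k] <- 1
    rows[[length(rows) + 1]] <- r; rhs <- c(rhs, col_ub[k])
  }
  pos <- which(col_lb > 0)
  for (k in pos) {
    r <- numeric(ncols); r[k] <- -1
    rows[[length(rows) + 1]] <- r; rhs <- c(rhs, -col_lb[k])
  }
  w_split <- NULL
  if (!is.null(model$proteome)) {
    w <- model$proteome$weights
    w_split <- c(w, w[has_bwd])
    rows[[length(rows) + 1]] <- w_split
    rhs <- c(rhs, model$proteome$rhs)
  }
  A <- do.call(rbind, rows)

  sol <- tryCatch(
    pracma::linprog(cc, A = A, b = rhs, Aeq = Aeq, beq = numeric(nrow(Aeq)),
                    maximize = TRUE, maxiter = max(200L, 20L * ncols)),
    error = function(e) list(errno = -99, message = conditionMessage(e), x = NULL)
  )
  status <- if (identical(sol$errno, 1)) "optimal"
            else if (identical(sol$errno, -99) &&
                     grepl("infeasible|No feasible", sol$message, ignore.case = TRUE)) "infeasible"
            else if (identical(sol$errno, -99)) "infeasible"
            else if (identical(sol$errno, 3) || grepl("unbounded", sol$message %||% "",
                                                      ignore.case = TRUE)) "unbounded"
            else "infeasible"
  if (status != "optimal") {
    return(structure(list(growth = NA_real_, fluxes = NULL, status = status,
                          proteome_usage = NA_real_,
                          message = sol$message %||% status),
                     class = "fba_solution"))
  }
  x <- sol$x
  v <- x[seq_along(rid)]
  if (nb > 0) v[has_bwd] <- v[has_bwd] - x[(length(rid) + 1):ncols]
  names(v) <- rid
  if (abs(v[[model$objective]]) >= BIG * 1e-3) {
    return(structure(list(growth = NA_real_, fluxes = NULL,
                          status = "unbounded", proteome_usage = NA_real_,
                          message = sprintf(
                            "Objective '%s' is unbounded", model$objective)),
                     class = "fba_solution"))
  }
  usage <- if (!is.null(w_split)) sum(w_split * x) else NA_real_
  structure(list(growth = unname(v[model$objective]), fluxes = v,
                 status = "optimal", proteome_usage = usage),
            class = "fba_solution")
}

#' @export
print.fba_solution <- function(x, ...) {
  if (x$status == "optimal") {
    cat(sprintf("<fba_solution: optimal | growth = %.6g>\n", x$growth))
  } else {
    cat(sprintf("<fba_solution: %s>\n", x$status))
  }
  invisible(x)
}

#' Growth-versus-temperature curves from a kcat table
#'
#' Updates the turnover numbers of the catabolic sector from per-temperature
#' kcat predictions and re-solves the proteome-constrained FBA at each
#' temperature. Reactions missing from a temperature's table keep their
#' static kcat (the mechanism for per-reaction manual overrides). An
#' infeasible temperature is recorded as zero growth with a flag rather
#' than an error.
#'
#' @param model A `metabolic_model`.
#' @param sectors A [proteome_sector_spec()].
#' @param kcat_table Data frame with columns `reaction_id`, `temperature_C`,
#'   `kcat_s`.
#' @return A `growth_curve` object: `curve` tibble (temperature_C, growth,
#'   feasible) and `kcat_fold_change` tibble with per-reaction log2
#'   fold-changes between the lowest and highest temperature.
#' @export
growth_vs_temperature <- function(model, sectors, kcat_table) {
  kcat_table <- tibble::as_tibble(kcat_table)
  stopifnot(all(c("reaction_id", "temperature_C", "kcat_s") %in% names(kcat_table)))
  temps <- sort(unique(kcat_table$temperature_C))
  curve <- purrr::map_dfr(temps, function(tc) {
    kt <- dplyr::filter(kcat_table, .data$temperature_C == tc)
    sec_t <- sectors
    idx <- match(sec_t$catabolic$id, kt$reaction_id)
    hit <- !is.na(idx) & sec_t$catabolic$mode == "turnover"
    sec_t$catabolic$kcat_s[hit] <- kt$kcat_s[idx[hit]]
    sol <- fba(add_proteome_constraints(model, sec_t))
    tibble::tibble(temperature_C = tc,
                   growth = if (sol$status == "optimal") sol$growth else 0,
                   feasible = sol$status == "optimal")
  })
  fc <- kcat_table |>
    dplyr::filter(.data$temperature_C %in% range(temps)) |>
    tidyr::pivot_wider(names_from = "temperature_C", values_from = "kcat_s",
                       names_prefix = "T") |>
    dplyr::mutate(log2_fold_change =
                    log2(.data[[paste0("T", max(temps))]] /
                           .data[[paste0("T", min(temps))]]))
  structure(list(curve = curve, kcat_fold_change = fc,
                 t_low = min(temps), t_high = max(temps)),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat("<growth_curve>\n")
  print(x$curve)
  invisible(x)
}

#' @describeIn growth_vs_temperature The curve tibble.
#' @param x A `growth_curve` object.
#' @export
tidy.growth_curve <- function(x, ...) x$curve

#' @describeIn growth_vs_temperature Growth rate against temperature.
#' @export
autoplot.growth_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$temperature_C, y = .data$growth)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$feasible)) +
    ggplot2::labs(x = "temperature (deg C)", y = "growth (1/h equivalent flux)",
                  title = "Proteome-constrained growth vs temperature") +
    ggplot2::theme_minimal()
}

#' Select one kcat per reaction from per-protein, per-substrate predictions
#'
#' The kcat of a reaction's flagged primary substrate is selected for each
#' enzyme, and across isozymes catalyzing the same reaction the largest
#' kcat is taken. When no substrate is flagged primary, the first listed is
#' used.
#'
#' @param predictions Data frame with columns `reaction_id`, `kcat_s` and
#'   optionally `protein_id` (isozymes) and `primary` (logical substrate
#'   flag).
#' @return Tibble with one row per reaction: `reaction_id`, `kcat_s`.
#' @export
select_reaction_kcat <- function(predictions) {
  predictions <- tibble::as_tibble(predictions)
  stopifnot(all(c("reaction_id", "kcat_s") %in% names(predictions)))
  if (nrow(predictions) == 0) abort("Empty candidate list")
  if ("protein_id" %notin% names(predictions)) {
    predictions$protein_id <- "enzyme1"
  }
  if ("primary" %notin% names(predictions)) predictions$primary <- NA
  per_isozyme <- predictions |>
    dplyr::group_by(.data$reaction_id, .data$protein_id) |>
    dplyr::summarise(kcat_s = {
      if (any(.data$primary %in% TRUE)) .data$kcat_s[which(.data$primary %in% TRUE)[1]]
      else .data$kcat_s[1]
    }, .groups = "drop")
  per_isozyme |>
    dplyr::group_by(.data$reaction_id) |>
    dplyr::summarise(kcat_s = max(.data$kcat_s), .groups = "drop")
}
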