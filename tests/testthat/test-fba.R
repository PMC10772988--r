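chain_model <- function(uptake_ub = 10) {
  metabolic_model(tibble::tibble(
    id = c("UPT", "CONV", "GROWTH"),
    stoichiometry = list(c(A = 1), c(A = -1, B = 1), c(B = -1)),
    lb = c(0, 0, 0), ub = c(uptake_ub, Inf, Inf)
  ), objective = "GROWTH")
}

test_that("plain FBA solves hand-computable toy models", {
  sol <- fba(chain_model())
  expect_equal(sol$status, "optimal")
  expect_equal(sol$growth, 10, tolerance = 1e-6)
  expect_lt(max(abs(sol$fluxes %*% t(chain_model()$S))), 1e-6)

  # nothing enters: zero growth
  closed <- chain_model(uptake_ub = 0)
  sol0 <- fba(closed)
  expect_equal(sol0$growth, 0, tolerance = 1e-9)

  # branched: two parallel routes with bottlenecks 10 and 4 -> growth 14
  branched <- metabolic_model(tibble::tibble(
    id = c("UPT1", "UPT2", "GROWTH"),
    stoichiometry = list(c(B = 1), c(B = 1), c(B = -1)),
    lb = c(0, 0, 0), ub = c(10, 4, Inf)
  ), objective = "GROWTH")
  solb <- fba(branched)
  expect_equal(solb$growth, 14, tolerance = 1e-6)
})

test_that("infeasible and unbounded problems are reported, not crashed", {
  infeasible <- metabolic_model(tibble::tibble(
    id = c("UPT", "GROWTH"),
    stoichiometry = list(c(A = 1), c(A = -1)),
    lb = c(0, 5), ub = c(2, Inf)  # demands 5 through a cap of 2
  ), objective = "GROWTH")
  sol_i <- fba(infeasible)
  expect_equal(sol_i$status, "infeasible")
  expect_true(is.na(sol_i$growth))

  unbounded <- metabolic_model(tibble::tibble(
    id = c("MAKE", "GROWTH"),
    stoichiometry = list(c(A = 1), c(A = -1)),
    lb = c(0, 0), ub = c(Inf, Inf)
  ), objective = "GROWTH")
  sol_u <- fba(unbounded)
  expect_equal(sol_u$status, "unbounded")
  expect_match(sol_u$message, "GROWTH")  # names the objective
})

test_that("steady state holds and reversible fluxes are recombined", {
  m <- metabolic_model(tibble::tibble(
    id = c("EX_A", "REV", "GROWTH"),
    stoichiometry = list(c(A = 1), c(A = -1, B = 1), c(B = -1)),
    lb = c(0, -5, 0), ub = c(7, 5, Inf)
  ), objective = "GROWTH")
  sol <- fba(m)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$growth, 5, tolerance = 1e-6)  # reversible cap binds
  expect_lt(max(abs(m$S %*% sol$fluxes)), 1e-6)
  expect_true(all(sol$fluxes >= m$lb - 1e-9 & sol$fluxes <= m$ub + 1e-9))
})

test_that("the ribosome-only proteome bound reproduces the sector arithmetic", {
  # only the growth reaction consumes capacity: max growth =
  # (1 - phi_Q) * P_TOT * a_ribosome = 0.5 * 0.5 * 107.4 = 26.85
  m <- metabolic_model(tibble::tibble(
    id = c("UPT", "GROWTH"),
    stoichiometry = list(c(A = 1), c(A = -1)),
    lb = c(0, 0), ub = c(Inf, Inf)
  ), objective = "GROWTH")
  sectors <- proteome_sector_spec(
    catabolic = tibble::tibble(id = character(), mode = character(),
                               kcat_s = numeric(), MW_g_per_mol = numeric()))
  mc <- add_proteome_constraints(m, sectors)
  sol <- fba(mc)
  expect_equal(sol$growth, 0.5 * 0.5 * 107.4, tolerance = 1e-6)
  expect_equal(sol$growth, 26.85, tolerance = 1e-6)
  # the sector constraint is tight at the optimum
  expect_equal(sol$proteome_usage, (1 - 0.5) * 0.5, tolerance = 1e-6)
})

test_that("proteome-constrained growth is monotone in kcat and P_TOT", {
  toy <- generate_toy_gsmm(seed = 4)
  base <- fba(add_proteome_constraints(toy$model, toy$sectors))
  expect_equal(base$status, "optimal")

  # doubling every kcat cannot decrease growth
  sec2 <- toy$sectors
  sec2$catabolic$kcat_s <- sec2$catabolic$kcat_s * 2
  sol2 <- fba(add_proteome_constraints(toy$model, sec2))
  expect_gte(sol2$growth, base$growth - 1e-9)

  # random positive kcat perturbations keep monotonicity
  set.seed(99)
  for (i in 1:5) {
    up <- toy$sectors
    up$catabolic$kcat_s <- up$catabolic$kcat_s * runif(nrow(up$catabolic), 1, 3)
    solu <- fba(add_proteome_constraints(toy$model, up))
    expect_gte(solu$growth, base$growth - 1e-9)
  }

  # enormous P_TOT makes the sector constraint vacuous: plain-FBA optimum
  sec_inf <- toy$sectors
  sec_inf$P_TOT <- 1e9
  sol_inf <- fba(add_proteome_constraints(toy$model, sec_inf))
  plain <- fba(toy$model)
  expect_equal(sol_inf$growth, plain$growth, tolerance = 1e-6)

  # without sectors, fba() on the same model is exactly plain FBA
  toy$model$proteome <- NULL
  expect_equal(fba(toy$model)$growth, plain$growth)
})

test_that("at the optimum the sector constraint is tight or another bound is", {
  toy <- generate_toy_gsmm(seed = 8)
  sol <- fba(add_proteome_constraints(toy$model, toy$sectors))
  budget <- (1 - toy$sectors$phi_Q) * toy$sectors$P_TOT
  sector_tight <- abs(sol$proteome_usage - budget) < 1e-6
  uptake_tight <- abs(sol$fluxes[["GLC_upt"]] -
                        toy$model$ub[["GLC_upt"]]) < 1e-6
  expect_true(sector_tight || uptake_tight)
})

test_that("growth_vs_temperature produces curves and fold changes", {
  toy <- generate_toy_gsmm(seed = 2)
  cat_ids <- toy$sectors$catabolic$id
  # constant kcat across T: flat growth curve
  flat <- tidyr::crossing(reaction_id = cat_ids,
                          temperature_C = c(30, 34, 38)) |>
    dplyr::mutate(kcat_s = 50)
  gc_flat <- growth_vs_temperature(toy$model, toy$sectors, flat)
  expect_equal(length(unique(round(gc_flat$curve$growth, 9))), 1)

  # doubling all kcat cannot reduce growth; log2 fold-change is exact
  warm <- dplyr::bind_rows(
    tibble::tibble(reaction_id = cat_ids, temperature_C = 30, kcat_s = 2),
    tibble::tibble(reaction_id = cat_ids, temperature_C = 38, kcat_s = 8)
  )
  gc <- growth_vs_temperature(toy$model, toy$sectors, warm)
  expect_gte(gc$curve$growth[gc$curve$temperature_C == 38],
             gc$curve$growth[gc$curve$temperature_C == 30] - 1e-9)
  expect_equal(unique(gc$kcat_fold_change$log2_fold_change), 2)
  expect_s3_class(tidy(gc), "tbl_df")
})

test_that("reaction kcat selection honors primary substrates and isozyme max", {
  expect_equal(select_reaction_kcat(tibble::tibble(
    reaction_id = "R1",
    protein_id = c("E1", "E2", "E3"),
    kcat_s = c(2, 5, 3)
  ))$kcat_s, 5)
  expect_equal(select_reaction_kcat(tibble::tibble(
    reaction_id = "R1", kcat_s = 7
  ))$kcat_s, 7)
  # flagged primary substrate wins regardless of magnitude
  got <- select_reaction_kcat(tibble::tibble(
    reaction_id = "R1", protein_id = "E1",
    kcat_s = c(10, 1, 99), primary = c(FALSE, TRUE, FALSE)
  ))
  expect_equal(got$kcat_s, 1)
  expect_error(select_reaction_kcat(tibble::tibble(reaction_id = character(),
                                                   kcat_s = numeric())),
               "Empty")
})

test_that("models round-trip through the JSON dialect and read from SBML", {
  toy <- generate_toy_gsmm(seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(toy$model, path)
  back <- read_model_json(path)
  expect_equal(back$S[rownames(toy$model$S), colnames(toy$model$S)],
               toy$model$S)
  expect_equal(back$lb, toy$model$lb)
  expect_equal(back$ub, toy$model$ub)
  expect_equal(fba(back)$growth, fba(toy$model)$growth, tolerance = 1e-9)

  sbml <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="toy">',
    '<listOfParameters>',
    '<parameter id="ub10" value="10" constant="true"/>',
    '<parameter id="zero" value="0" constant="true"/>',
    '</listOfParameters>',
    '<listOfSpecies><species id="A"/><species id="B"/></listOfSpecies>',
    '<listOfReactions>',
    '<reaction id="UPT" reversible="false" fbc:lowerFluxBound="zero" fbc:upperFluxBound="ub10" xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2">',
    '<listOfProducts><speciesReference species="A" stoichiometry="1"/></listOfProducts>',
    '</reaction>',
    '<reaction id="CONV" reversible="false">',
    '<listOfReactants><speciesReference species="A" stoichiometry="1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="B" stoichiometry="1"/></listOfProducts>',
    '</reaction>',
    '<reaction id="BIOMASS_c" reversible="false">',
    '<listOfReactants><speciesReference species="B" stoichiometry="1"/></listOfReactants>',
    '</reaction>',
    '</listOfReactions>',
    '</model></sbml>'
  ), sbml)
  sm <- read_sbml_model(sbml)
  expect_equal(sort(sm$reaction_ids), c("BIOMASS_c", "CONV", "UPT"))
  expect_equal(sm$objective, "BIOMASS_c")
  expect_equal(unname(sm$ub[["UPT"]]), 10)
  expect_equal(fba(sm)$growth, 10, tolerance = 1e-6)
})
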