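# thermokcat

Temperature-dependent enzyme turnover prediction with bidirectional
attention, plus proteome-constrained flux balance analysis.

## What this is for

The turnover number kcat (substrate molecules converted per enzyme per
second) governs how fast metabolism can run, and it changes with
temperature following the Arrhenius law

    kcat(T) = A * exp(-Ea / (R T)),

so log10(kcat) is linear in 1/T. Measuring kcat is slow and expensive;
`thermokcat` is for computational biologists and enzyme engineers who want
to *predict* it — for a substrate (SMILES), an enzyme (amino-acid
sequence) and a temperature — and to propagate those predictions into
metabolic models.

The predictor is a compound–protein interaction network: a multi-head
graph-attention encoder over the molecular graph, a convolutional encoder
over overlapping 3-mer protein tokens, a 1024-bit circular-fingerprint
branch, and a 3-head bidirectional attention block that couples atoms and
residues through a soft alignment matrix A = tanh(C U Pᵀ), with residue
attention weights alpha_r2a = softmax([P W_p ‖ I_p] a_r2a),
I_p = Aᵀ tanh(C W_a2r) (and the mirror-image atom direction). Normalized
T and 1/T join the concatenated features before a dense regressor outputs
log10(kcat). The network and its training gradients are implemented in
plain R matrix algebra, with the backward pass verified against finite
differences in the test suite.

Around the predictor:

* **Curation** — deduplication (largest kcat wins among colliding
  substrate/sequence/temperature entries) and oversampling of sparse
  temperature ranges (T < 20 °C, T > 40 °C), applied to the training
  partition only.
* **Interpretation** — per-residue attention profiles, mutation-site
  peak-proximity reports, and mutant panel scans ("Y227C/E277G"-style
  specs).
* **Feature importance** — joint permutation of the (T, 1/T) features with
  RMSE/MAE/R² degradation distributions.
* **Proteome-constrained FBA** — linear enzyme-capacity constraint
  v_growth/a_ribosome + Σ |v_i| MW_i/k_i + v_AT/a_AT + v_CT/a_CT
  ≤ (1 − φ_Q) P_TOT over a stoichiometric model (native JSON dialect or
  SBML), producing growth-versus-temperature curves from predicted kcat
  tables.
* **Synthetic data** — an Arrhenius-kinetics generator (with planted
  sequence motifs and substrate features carrying the kinetic signal) and
  a toy metabolic model with a closed-form optimum, so everything is
  testable offline at desk scale.

## Worked example

```r
library(thermokcat)

# 60 synthetic compound–protein pairs, 6 temperatures, Arrhenius kinetics
ds <- generate_arrhenius_dataset(arrhenius_spec(seed = 101))

model <- train_kcat_model(ds$entries, config = model_config("small"),
                          control = train_config(epochs = 60, seed = 101))
evaluate_kcat_model(model, model$splits$test)
#> # A tibble: 1 x 3
#>    rmse   mae    r2
#>   <dbl> <dbl> <dbl>
#> 1 0.131 0.109 0.998
```

The held-out RMSE of 0.13 log10 units sits just above the generator's
noise floor (sigma = 0.1): the network has recovered the planted
amplitude/activation-energy structure. Shuffling the temperature features
degrades it, which quantifies how much the model actually uses T and 1/T:

```r
imp <- permute_temperature_importance(model, model$splits$test)
imp
#> <temperature_importance: 20 repeats>
#>   baseline rmse 0.1312 | median shuffled rmse 0.3626
```

Predictions for an engineered variant panel, and a growth curve from a
kcat table:

```r
mutant_scan(model, wild_type, c("Y227C", "A240D/E277G"),
            smiles = "OCC1OC(O)C(O)C(O)C1O", temps_C = c(30, 55))

toy <- generate_toy_gsmm(seed = 1)
fba(add_proteome_constraints(toy$model, toy$sectors))
#> <fba_solution: optimal | growth = 8>
```

Fitted models have `tidy()` (per-epoch history), `glance()` (one-row
summary) and `autoplot()` methods; attention profiles, importance results
and growth curves are plotted with `autoplot()` as well. A thin
command-line dispatcher over these functions ships in
`inst/scripts/thermokcat-cli.R`.

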