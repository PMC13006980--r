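# survgate

Cancer-type-aware multimodal survival modelling with discrete-time
hazards, in pure R.

The model pools precomputed histopathology patch features (2048-d), RNA
embeddings (256-d) and clinical-text token embeddings (768-d) into
per-patient vectors, projects each modality to a shared 32-d space, and
fuses them with an **availability-masked softmax gate**: modalities
flagged missing receive a −10⁹ logit penalty, so their gate weight is
numerically zero and prediction degrades gracefully instead of silently
consuming zero-imputed features. The fused embedding passes through a
shared pre-norm transformer encoder, and cancer-type-specific heads emit
per-time-bin hazards trained under the censored discrete-time negative
log-likelihood. Forward and backward passes are hand-written in base R
and verified against finite differences.

The package also ships the full evaluation protocol around the model:

- a synthetic cohort generator with plantable per-modality prognostic
  signal, institution-specific feature shifts, exponential outcomes and
  exactly tuned censoring — plus the oracle C-index ceiling of each
  cohort for parameter-recovery checks;
- patient-stratified and institution-grouped train/val/test splits
  (4:2:4 and 7:1:2) with zero site leakage;
- missing-modality stress protocols and rate sweeps;
- multi-seed experiments aggregated with paired t-tests (Bonferroni
  α/7) and variance F-tests;
- an unmasked early-fusion comparator used as a robustness foil.

## Worked example

```r
library(survgate)

scfg <- sim_config(n = 600, n_cancers = 3, signal_strength = 20)
cohort <- generate_cohort(scfg, seed = 123)
print(cohort)
#> survgate cohort: 600 patients, 3 cancer types, 12 institutions
#>   censoring: 0.37  rna available: 1  txt available: 1

split <- make_split(cohort$meta, ratios = c(4, 2, 4), mode = "patient", seed = 123)
fit <- sg_train(cohort,
                split_idx(split, cohort, "train"),
                split_idx(split, cohort, "val"),
                model_config(n_cancers = 3),
                train_config(seed = 123))
print(fit)
#> survgate fit: gated fusion, 47 epochs run, best epoch 32 (val C-index 0.714), seed 123

test_idx <- split_idx(split, cohort, "test")
ev <- sg_evaluate(fit, cohort, test_idx)
print(ev$per_cancer)
#>   cancer_type    cindex  n
#> 1           1 0.7064097 81
#> 2           2 0.7179161 81
#> 3           3 0.6829766 77
cat(sprintf("mean test C-index %.3f (oracle ceiling %.3f)\n",
            ev$mean, oracle_cindex_ceiling(cohort, test_idx)$overall))
#> mean test C-index 0.702 (oracle ceiling 0.767)

print(sweep_missing(fit, cohort, test_idx, modality = "rna"))
#>   rate    cindex
#> 1  0.0 0.7024341
#> 2  0.2 0.6833908
#> 3  0.5 0.6536555
#> 4  0.8 0.6269350
```

Training takes a few seconds per cohort on one CPU; everything above is
bit-reproducible given the seeds.

## Command line

A thin front-end over the same functions lives in
`inst/scripts/survgate.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts", "survgate.R", package = "survgate"))')" \
  run-all --config experiment.yaml --seed 123 --out results/
```

Subcommands: `simulate`, `preprocess`, `train`, `evaluate`,
`sweep-missing`, `stats`, `run-all`. Each stage writes CSV/JSON
artifacts plus a manifest; re-running with an unchanged config and seed
reuses cached stages.

## Reproduction

- `R CMD INSTALL .` then
  `Rscript -e 'testthat::test_dir("tests/testthat", package = "survgate", load_package = "installed")'`
  runs the full suite, including the acceptance criteria (boundary
  C-index targets, oracle equivalence of the concordance implementation,
  masked-softmax and survival-curve properties, a finite-difference
  gradient check of the full model, planted-signal parameter recovery
  against the oracle ceiling, the gated-vs-early-fusion robustness
  comparison over five seeds, statistical-harness calibration, and
  split-leakage checks). The whole suite runs in under two minutes on
  one CPU.
- `Rscript scripts/acceptance.R --seed 1 --out acceptance.json` writes
  the two quantitative boundary targets of the concordance index
  (perfect anti-ordering → exactly 1; outcome-independent risks →
  mean 0.5 over 100 simulations).

See the vignette in `vignettes/` for the model equations, the generator
design, the numerical choices, and the optimizer rationale.
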