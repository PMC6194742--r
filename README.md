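# lipidens

Ensemble biomarker selection and reverse-causality screening for
untargeted LC-MS lipidomics case-control studies.

## What it is for

In prospective matched case-control designs, serum collected years before
diagnosis is profiled by untargeted LC-MS, yielding thousands of features
(unique m/z × retention-time ions) on ~100–150 samples. `lipidens`
implements the full downstream analysis for such a study:

1. **Feature filtering** against reagent blanks (study/blank mean
   fold-change ≥ 1.5) and pooled-QC reproducibility (CV ≤ 30%).
2. **Normalization**: per-feature removal of batch and gel-status
   artifacts by OLS on the log scale,
   `log Y = β0 + β1·gel + β2·batch + ε`, followed by upper-quantile
   (75th percentile) scaling.
3. **Ensemble variable selection** — a feature is selected only when it
   simultaneously (i) ranks in the top 1% by the nominal p-value of the
   case-control coefficient β1 in
   `log Y = β0 + β1·caco + β2·gel + β3·batch + β4·age + β5·gender + ε`,
   (ii) is retained by bootstrap-LASSO stability selection (nonzero
   coefficient in ≥ 10% of 500 pair-resampled penalized logistic fits,
   across a wide penalty range), and (iii) ranks in the top 1% by
   random-forest out-of-bag permutation importance.
4. **Time-to-diagnosis (ttd) classification**: pair-level
   `logFC = log(case) − log(control)` is regressed on ttd; a
   non-significant slope (p > 0.05) labels the feature **C** (potentially
   causal), a significant slope with the fitted |difference| shrinking
   toward zero over the observed ttd range labels it **R** (potentially
   reactive — a signature of reverse causality), otherwise **I**.
5. **Reporting**: cohort descriptive table (rank-sum / chi-square),
   volcano export, in-sample classification rate (with its optimism
   caveat), JSON report with stage accounting.
6. **Mass annotation arithmetic**: monoisotopic masses from molecular
   formulas, deprotonated `[M-H]-` and acetate-adduct `[M+HAc-H]-` m/z,
   Δppm deviations, neutral-loss assignment of MS2 fragments (H2O, CO2,
   2×H2O, CO2+H2O, acetic acid), and Pearson-correlation feature
   clustering.

A first-class synthetic-cohort generator (`generate_cohort()`) produces
matched cohorts with planted causal/reactive effects, batch/gel
artifacts, QC replicates and blanks, so every stage is testable against a
known truth.

## Worked example

```r
library(lipidens)

# a 66-pair cohort with 400 features: 3 causal + 3 reactive planted
des <- cohort_design(n_pairs = 66, p_features = 400, seed = 101)
eff <- standard_effects(400, n_causal = 3, n_reactive = 3,
                        beta0 = 1.0, decay_span = 10)
coh <- generate_cohort(des, eff)

cfg <- pipeline_config(out_dir = "demo_out", B = 100, n_trees = 500,
                       top_frac = 0.025, seed = 42)
res <- run_pipeline(cfg, tables = coh)
#> [lipidens] input: 400 features, 148 samples (seed 42)
#> [lipidens] filters: 400 -> 400 (blank) -> 361 (qc)
#> [lipidens] selected: 6 feature(s)

res$selection[res$selection$selected,
              c("feature_id", "p_value", "fold_change",
                "stability_freq", "rf_rank")]
#>  feature_id  p_value fold_change stability_freq rf_rank
#>      F00001 4.77e-19       2.646           1.00       2
#>      F00002 3.71e-21       0.341           1.00       1
#>      F00003 2.52e-17       2.437           1.00       3
#>      F00004 7.15e-08       1.650           0.83       4
#>      F00010 3.17e-03       0.771           0.44       6
#>      F00237 2.50e-03       1.270           0.60       5

res$ttd[, c("feature_id", "intercept", "slope", "slope_p", "class")]
#>  feature_id intercept    slope slope_p class
#>      F00001     1.299 -0.04477  0.0669     C
#>      F00002    -1.023 -0.00496  0.8455     C
#>      F00003     1.028 -0.01602  0.5064     C
#>      F00004     0.916 -0.05739  0.0196     R
#>      F00010    -0.120 -0.01561  0.5052     C
#>      F00237     0.574 -0.04362  0.0446     R
```

Reading the output: the three planted causal features (F00001–F00003,
pair fold-changes e^±1 ≈ 2.6 / 0.34 on the natural scale) are selected
and labeled C — their case-control difference does not change with time
to diagnosis. Planted reactive feature F00004 is selected and correctly
labeled R: its difference (intercept 0.92 at ttd = 0) decays with ttd
(slope −0.057/y, p = 0.02), the reverse-causality signature. Two null
features (F00010, F00237) slip through the triple intersection — a couple
of false positives per run is expected at these rank cutoffs — and the in-sample classification rate (`res$rate$rate`,
0.95 here) is deliberately flagged as optimistic.

Mass annotation:

```r
mass_match("C28H52O5", 467.3744)
#>    formula species  mz_calc   mz_obs delta_ppm
#> 1 C28H52O5  [M-H]- 467.3736 467.3744 -1.605282

match_neutral_losses(453.3592, c(409.3687, 435.3462))[, c("fragment", "loss")]
#>   fragment loss
#> 1 409.3687  CO2
#> 2 435.3462  H2O
```

## Command line

```sh
Rscript inst/cli/lipidens.R simulate --pairs 66 --p 2000 --out fixture --seed 1
Rscript inst/cli/lipidens.R run --features fixture/features.tsv \
    --samples fixture/samples.tsv --out results --boot 500 --seed 1
Rscript inst/cli/lipidens.R annotate --formula C28H52O5 --mz 467.3744
```

Subcommands: `simulate | filter | normalize | select | classify |
annotate | report | run`; exit codes 0 (ok), 1 (stage failure),
2 (bad input).

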