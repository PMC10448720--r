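# ketox

Pathway-based evaluation of chemical hepatotoxicity from
high-throughput screening (HTS) data, with toxicokinetics.

Animal models predict human liver injury poorly, which has pushed the
field toward *adverse outcome pathway* (AOP) approaches: instead of a
single apical endpoint, chemicals are profiled against the measurable
*key events* (KEs) — receptor activation, DNA damage, mitochondrial
dysfunction, and so on — that lead to toxicity. Public screening
programs tested thousands of chemicals in over a thousand in vitro
assays and published the fitted concentration-response parameters.
`ketox` implements an end-to-end computational strategy that turns
those curve-fit summaries into KE-level hepatotoxicity models:

1. **Curve reconstruction** (`build_grid`, `hill_response`,
   `build_surfaces`): for each chemical × assay, the best-scoring fit
   (lowest curve error) is evaluated as a Hill curve
   `f(c) = top / (1 + (AC50/c)^slope)` on a shared log10 grid from
   1 pM to 100 mM, and each assay is normalized to [0, 1].
2. **Assay selection** (`select_relevant_assays`): assays whose binary
   hit calls are positively associated with hepatocellular and/or
   hepatobiliary toxicity by Fisher's exact test, with
   Benjamini–Hochberg control at FDR 0.15 per endpoint.
3. **KE scoring** (`ke_score_table`, `ke_roc_auc`): assays grouped by
   biological target are composed into a per-chemical KE curve (mean
   of member responses, zeros for untested); the KE *score* is the
   area under that curve in the log10-concentration domain, scaled so
   the most active chemical in each KE scores 1. Each KE's
   hepatotoxicity predictivity is summarized by ROC AUC.
4. **Toxicokinetic overlay** (`realized_ke_score`,
   `flag_unrealizable`): the 95th-percentile steady-state plasma
   concentration (Css, external input) truncates each KE curve at the
   exposure the body can actually reach, quantifying the *realized*
   fraction of in vitro activity.
5. **Structure clustering** (`morgan_fingerprints`, `butina_cluster`,
   `enriched_clusters`): Butina sphere-exclusion clustering at
   Tanimoto ≥ 0.70 on 2048-bit Morgan fingerprints; clusters in which
   more than 2/3 of liver-annotated members are hepatotoxicants are
   reported with their mean KE-score signatures.
6. **Hepatotoxicity models** (`loo_cv`, `compare_models`): ridge
   logistic regression with leave-one-out validation on a
   class-balanced (undersampled) set — Model 1 from KE scores alone,
   Model 2 adding log10 Css and Lipinski descriptors; probability
   \> 0.5 classifies a chemical as hepatotoxicant.
7. **Synthetic data** (`generator_config`, `generate`): a generator
   with known ground truth (which assays are associated, which
   chemicals are "TK-rescued" — active in vitro but never reaching
   their active concentrations in vivo) so the whole pipeline is
   testable offline.

Structure handling (SMILES → fingerprints/descriptors) is delegated
to the Python RDKit toolkit via a bundled helper script; `python`
with `rdkit` must be on the PATH.

## Worked example

```r
library(ketox)

cfg <- generator_config(n_chemicals = 200, n_assays = 40, n_kes = 8,
                        tk_modulation = TRUE, seed = 42)
bundle <- generate(cfg)
dir <- tempfile(); write_bundle(bundle, dir)

pcfg <- pipeline_config(
  curve_fits = file.path(dir, "curve_fits.csv"),
  labels     = file.path(dir, "labels.csv"),
  css        = file.path(dir, "css.csv"),
  ke_map     = file.path(dir, "ke_map.csv"),
  smiles     = file.path(dir, "smiles.csv"),
  seed = 1)
res <- run_all(pcfg, tempfile())

length(res$selection$union)
#> [1] 5
recovery_score(res$selection$union, ground_truth(bundle), NULL)
#> $sensitivity
#> [1] 0.75
#> $fdr
#> [1] 0.4
head(res$roc)
#>   ke_id n_pos n_neg   roc_auc
#> 1  KE02    91   109 0.5513157
#> 2  KE03    91   109 0.5362436
#> 3  KE07    91   109 0.5376550
#> 4  KE08    91   109 0.5964311
res$models$model1
#> <aop_model_result> Model 1: n=182  acc=0.604  recall=0.407  (TP 37, FP 18, TN 73, FN 54)
res$models$model2
#> <aop_model_result> Model 2: n=182  acc=0.637  recall=0.604  (TP 55, FP 30, TN 61, FN 36)
```

Reading the output: 5 assays pass Fisher + BH selection, recovering 3
of the 4 truly associated assays the generator planted (with two false
positives — at 200 chemicals and 40 assays the FDR estimate is noisy;
at the 500 × 100 scale used in the acceptance suite recovery is
≥ 9/10). The per-KE ROC AUCs hover just above chance, as expected when
each KE mixes one informative assay with several null ones. Model 2
(KE scores + Css + Lipinski descriptors) beats Model 1 (KE scores
only) because the generator's TK-modulation plants chemicals that are
active in vitro but whose Css lies below their activity onset; only a
model that sees bioavailability can call them correctly. Averaged over
five seeds at full scale, Model 2 gains about 6 accuracy points with
TK modulation on, and nothing with it off (the no-free-lunch check).

A command-line front end covers the same stages:

```sh
inst/cli/ketox simulate --seed 4 --out-dir bundle/
inst/cli/ketox run-all --config pipeline.cfg --out-dir out/
```

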