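# concord

Cross-cancer drug-response prediction via co-expression concordance, in R.

## The problem

Drug-sensitivity gene signatures are usually discovered on in vitro cell-line
panels and validated — if at all — in the cancer type they were tuned on.
`concord` implements a pipeline for deciding **whether and where** such a
signature can be carried to a *different* cancer type, and for doing the
transfer with a frozen model and decision threshold so the validation is
genuinely prospective. It is aimed at computational biologists working with
bulk expression matrices (cell panels, patient cohorts) and binary
response / survival endpoints.

## The method

The central quantity is the per-gene co-expression concordance coefficient.
For a biomarker set of size *n*, build the gene–gene Pearson correlation
matrices *U* and *V* of the set in two systems, and for each gene *j*:

```
rc(j) = cor( U[, j], V[, j] )        (over partners k ≠ j by default)
```

`rc(j)` ≈ 1 means gene *j* keeps the same co-expression relationships with
the other biomarkers in both systems. The pipeline:

1. **Discover** activity-associated biomarkers on the cell panel
   (Pearson correlation with −log GI50, or Welch t-test between sensitive
   and resistant tertiles; BH FDR < 0.05), choosing the most informative
   panel when several exist.
2. **Gate cancer types**: within-type concordance distributions (wCOXEN, all
   pairs of original-type cohorts) vs between-type (bCOXEN); a candidate type
   passes when a one-sided Wilcoxon test (Bonferroni, alpha = 0.025) cannot
   show it is worse than the *lowest-median* within-type pair.
3. **Triage three-way concordant biomarkers**: keep genes significant at
   BH FDR < 0.2 — against a gene-identity permutation null with a
   98th-percentile cut-off — in all three pairs among cell panel, original
   cancer, and new cancer.
4. **Train** principal-component regressions over a nested biomarker-size
   grid, **select** on the largest original-cancer cohort (significant and
   maximal AUC, parsimony tie-break), and fix the percentile-score threshold
   maximizing Youden's J.
5. **Validate prospectively**: per-cohort suitability re-check, ROC/AUC with
   DeLong SE/CI, PPV enrichment over the observed response rate (exact
   binomial), Kaplan–Meier + log-rank stratification at the frozen threshold.

A synthetic multi-system generator with planted concordant, pairwise-only,
and null genes makes the whole pipeline testable without external data; see
`vignettes/concord-methods.Rmd` for the model, its assumptions, and the
design decisions.

## Worked example

```r
library(concord)

ds  <- generate_synthetic_dataset(synthetic_config(seed = 1))
res <- run_concord_synthetic(ds)
print(res)
```

```
 - discovery (correlation_pearson): 14 of 100 genes significant at FDR < 0.05
 - discovery fallback: topped up to 20 genes by |statistic| ranking
 - gate: chose cancer type 'new' (median bCOXEN 0.880)
 - three-way triage: 20 -> 15 genes (per-pair survivors: 16/17/19)
 - selection: 12-gene model, eval AUC 0.831, threshold 0.427 (J = 0.516)
 - validation original_val: suitable = TRUE, AUC 0.874 (p = 1.46e-08)
 - validation new_val: suitable = TRUE, AUC 0.896 (p = 1.71e-09)
 - validation unsuitable: suitable = FALSE, AUC 0.557 (p = 0.235)
```

Reading this: 14 genes pass the discovery screen (topped up to the
20-biomarker working set), the matched new cancer type passes the gate, 15 of
20 biomarkers are concordant in all three systems, and a 12-gene
PC-regression model with threshold 0.427 is frozen on the evaluation cohort.
On the held-out new-type cohort:

```r
print(res$validations$new_val)
```

```
<validation_report> new_val (n = 100): suitable, threshold 0.427
<roc_result> AUC 0.896 (SE 0.034, 95% CI 0.829-0.963), MWW p = 1.71e-09 [one-sided (AUC > 0.5)], 25 pos / 75 neg
<ppv_result> PPV 41.4% (24/58) vs baseline 25.0%, exact binomial p = 0.00454 [one-sided (PPV > baseline)]
<survival_comparison> log-rank chi-square 6.088 (1 df), p = 0.0136 [groups: negative vs positive]
```

The predicted-positive group is enriched for responders (41.4% vs the
cohort's unselected 25.0%) and separates in survival — while the
gene-scrambled `unsuitable` cohort is flagged by the suitability gate, and
its threshold-based stratification is correctly not trusted.

File-based workflows use `write_fixture()` / `run_pipeline()` (JSON run
config, TSV matrices), or the command-line veneer in `inst/cli/concord.R`
(`simulate | discover | coxen | gate | threeway | train | score | validate |
run-all`).

## Acceptance script

`scripts/acceptance.R` re-runs the full pipeline from scratch on the default
synthetic world (generation, discovery, gating, triage, training, threshold
selection, prospective validation), seeded by `--seed`, and writes its JSON
output to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
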