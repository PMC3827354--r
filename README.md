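# mdrer

Multifactor dimensionality reduction (MDR) for case-control SNP data whose
classes are **imbalanced**.

MDR detects gene-gene interaction by collapsing every n-locus genotype
combination ("cell") into a high- or low-risk label — classically, high
when the cell's case:control ratio reaches a threshold *T* = 1 — and
searching all locus sets with 10-fold cross-validation for the best such
dichotomy. When controls outnumber cases several-fold, almost no cell
reaches *T*, the fitted models predict low-risk everywhere, and both the
error rate and the true-positive count become misleading. This package
implements the two standard corrections alongside classic MDR:

* **`mdr_e`** — scores models with the balanced error
  `1 − (sensitivity + specificity)/2` instead of the raw
  misclassification error;
* **`mdr_er`** — additionally replaces the cell classifier with the
  percentage ratio
  `s = (c/P*) / (k/N*) = N*·c / (P*·k)`,
  the cell's share of all cases over its share of all controls
  (`c`, `k`: cell counts; `P*`, `N*`: training totals), labelling the cell
  high-risk when `s ≥ T`.

Around that core: exhaustive cross-validated search with
cross-validation-consistency model selection (`run_search`,
`repeated_runs`), contingency statistics with Woolf odds-ratio intervals
and chi-square tests (`model_stats`), a model-landscape diagnostic
(`model_landscape`), MDR flat-file I/O, control under-sampling, a
Hardy-Weinberg penetrance-model simulator for planting epistatic effects
in imbalanced cohorts (`generate_dataset`), and a CLI
(`inst/cli/mdrer`: `search`, `simulate`, `landscape`).

## Worked example

A published 2-locus model is defined by its per-cell case:control counts;
rebuilding it as an executable dataset and refitting reproduces the
printed analysis:

```r
library(mdrer)
cells <- list("0,0" = c(114L, 342L), "0,1" = c(57L, 280L),
              "1,0" = c(5L, 27L),   "1,1" = c(17L, 55L))
ds <- fixture_from_cells(cells)                      # 193 cases / 704 controls
model <- label_cells(count_cells(ds, c(1, 2)), "percentage_ratio", threshold = 1)
model
#> risk_model (percentage_ratio, T = 1) over loci (1, 2)
#>  key case_count control_count score label
#>  0,0        114           342  1.22  high
#>  0,1         57           280  0.74   low
#>  1,0          5            27  0.68   low
#>  1,1         17            55  1.13  high
model_stats(apply_model(model, ds))
#> error (raw) 0.51 | error (balanced) 0.44 | accuracy (balanced) 0.56
#> sensitivity 0.679 | specificity 0.436
#> OR 1.63 (1.17-2.29) | chi-square p 0.00408
```

The first cell holds 114 of the 193 cases but 342 of the 704 controls:
its raw ratio 0.33 is low-risk, yet its percentage ratio
`(704·114)/(193·342) = 1.22` correctly flags it as case-enriched. The
classic ratio classifier labels all four cells low-risk (sensitivity 0,
balanced error exactly 0.5); the corrected classifier recovers 131 true
positives and a sensitivity of 0.679 at specificity 0.436.

A full search on simulated data:

```r
spec <- penetrance_spec(causal_loci = c(1, 2),
                        penetrance = xor_penetrance(0.10, 0.25),
                        mafs = 0.3, n_cases = 50, n_controls = 200)
ds <- generate_dataset(spec, n_snps = 8, seed = 1)
res <- run_search(ds, order = 2, method = "mdr_er",
                  cv_plan = make_cv_plan(ds, 10, seed = 1))
res$final_locus_set   # the planted pair, c(1, 2), in most replicates
res$cvc               # folds won per candidate locus set
```

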