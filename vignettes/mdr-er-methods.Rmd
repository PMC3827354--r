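---
title: "Detecting epistasis in imbalanced case-control cohorts with mdrer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting epistasis in imbalanced case-control cohorts with mdrer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdrer)
```

## The problem

Multifactor dimensionality reduction (MDR) screens all combinations of
`n` SNPs for gene-gene interaction by collapsing each n-locus genotype
combination ("cell") into a single binary attribute: a cell is called
high-risk when its case:control ratio reaches a threshold `T`
(conventionally 1), low-risk otherwise. An exhaustive search with 10-fold
cross-validation then picks the locus set whose dichotomy classifies best.

This machinery quietly assumes the two classes have similar size. In a
cohort with, say, 193 cases and 704 controls (control:case ratio 3.65:1),
nearly every cell contains more controls than cases, so the classic ratio
`cases/controls` almost never reaches `T = 1`: the fitted model predicts
"low risk" for everyone, its raw misclassification error converges on the
case fraction, and true positives all but vanish. Both the classifier and
the error functional need correcting.

## The two corrections

**Balanced error** (variant `mdr_e`). Instead of the raw error
`(FP + FN) / total`, use the complement of the mean of sensitivity and
specificity:

$$\mathrm{err}_{bal} = 1 - \tfrac12\left(\frac{TP}{TP+FN} + \frac{TN}{TN+FP}\right).$$

Each class contributes equally regardless of its size; a
majority-class-only model scores exactly 0.5 rather than an
impressive-looking small number. When the classes are exactly balanced the
two errors coincide algebraically (a property the test suite checks, and
which the implementation preserves bit-for-bit by evaluating the balanced
error in the single-division rational form
`(FN·N + FP·P) / (2PN)`).

**Percentage-ratio classifier** (variant `mdr_er`, on top of the balanced
error). Compare each cell's *share of all cases* with its *share of all
controls*:

$$s = \frac{c_{cell}/P^{*}}{k_{cell}/N^{*}} = \frac{N^{*} c_{cell}}{P^{*} k_{cell}},$$

where `c`/`k` are the cell's case/control counts and `P*`/`N*` the training
totals. A cell holding 114 of 193 cases and 342 of 704 controls has raw
ratio 0.33 — low-risk under the classic rule — but percentage ratio
`(704·114)/(193·342) = 1.22`: the cell is genuinely case-enriched relative
to the cohort, and `mdr_er` labels it high-risk. With `P* = N*` the score
reduces to the classic ratio, so the correction is free on balanced data.

Conventions at the boundaries: a score exactly at `T` is high-risk; a
non-empty cell with zero controls scores `Inf` (high), with zero cases 0
(low); these are the limits of both formulas. Cells observed in a test
fold but absent from training are predicted low-risk — conservative toward
the majority class — and their count is reported
(`unseen_cell_individuals`) so the effect can be audited.

## Threshold choice

`T = 1` is the default for both classifiers. A common alternative sets the
classic threshold to the training case:control ratio; that variant is
available by passing `threshold = n_cases/n_controls`, but the default
follows the worked examples that define the method, and for the
percentage-ratio score 1 is the natural neutral point (a cell's case share
equals its control share).

## Search, cross-validation, and model selection

`run_search()` implements the standard MDR loop: for each of 10 folds, fit
every locus set of the requested order on the training complement, keep
the set with minimal training error (ties go to the set enumerated first —
enumeration is lexicographic over index tuples), and record its prediction
error on the held-out fold. The cross-validation consistency (CVC) of a
locus set is the number of folds it wins. The final model maximises CVC,
with ties broken by lower mean prediction error and then enumeration
order; it is refit on the full dataset and its statistics reported there,
matching how the per-cell breakdowns of published best models are
tabulated. The tie-break hierarchy resolves an ambiguity in the usual
"highest CVC with lowest error" phrasing; it is deterministic, so a fixed
CV seed reproduces a search bit-for-bit.

CV folds are dealt round-robin from a uniform random permutation,
*without* stratification by default: a plain random split is what produces
the observed drift of training-set imbalance across folds (about 3.4-4.0
controls per case around a 3.65:1 cohort), and stratification would hide
exactly the phenomenon the balanced methods address. `stratified = TRUE`
is available when equal-ratio folds are wanted.

`repeated_runs()` repeats the whole search over distinct CV seeds and
reports each locus set's selection frequency plus the modal ("best
candidate") model — the consistency figure used when comparing methods.
`model_landscape()` evaluates every locus set of one order on the full
data, sorts by balanced error and keeps a systematic sample, reporting TP
and TN on a log10-percentage scale (131 of 193 cases is 67.88%, log10
value 1.83) together with the high/low-risk cell counts — the standard
diagnostic of how severely a classifier favours the majority class.

## Statistics reported

`model_stats()` reports both errors, sensitivity, specificity, balanced
accuracy (`1 - err_bal`; this is the "accuracy" quoted for MDR-E/MDR-ER
best models), the odds ratio `(TP·TN)/(FP·FN)` with the Woolf
log-OR interval `exp(log OR ± 1.96·sqrt(1/TP + 1/FP + 1/FN + 1/TN))`
(Haldane-Anscombe +0.5 on all cells when any is zero), and a Pearson
chi-square p-value (1 df, no continuity correction) on the risk-by-class
2×2 table. The Woolf interval was chosen because it is the standard
closed-form interval for 2×2 tables at this sample size; the chi-square
test is the conventional significance screen for such tables (the
asymptotic p-value is approximate when expected counts are small). No
multiple-testing correction is applied across locus sets.

Display convention: errors, odds ratios and accuracies are printed to 2
decimals, sensitivity/specificity to 3; all values are stored at full
precision.

## The synthetic generator

The cohort the method was developed on (193 chronic-dialysis cases, 704
controls, 77 mitochondrial D-loop SNPs) is not publicly deposited, so the
package ships a generator that emulates its shape. `generate_dataset()`
draws genotypes per SNP under Hardy-Weinberg equilibrium from its minor
allele frequency, assigns disease status from a penetrance table over the
causal genotype combination, and keeps drawing until the case and control
quotas are filled exactly (rejection sampling). Because non-causal SNPs
are independent of status, the case-control conditioning introduces no
spurious association outside the causal loci. `study_profile_spec()`
packages the study shape (77 SNPs, 193/704, MAF 0.3) with a moderate
two-locus XOR effect; `fixture_from_cells()` goes the other way and turns
a printed per-cell case/control breakdown into an executable dataset, which
is how the worked examples are verified.

What the generator does *not* emulate: linkage disequilibrium between
SNPs, population stratification, genotyping error, and missingness. Tests
passing on these simulations therefore demonstrate the combinatorial and
statistical machinery, not robustness to the correlation structure of real
genotype panels.

### Frozen experimental conditions

Two simulation designs are fixed in the test suite and used unchanged:

* **Planted-effect recovery** — 50 cases / 200 controls (the 1:4 imbalance
  of interest), 8 SNPs, MAF 0.3, XOR penetrance with baseline 0.10 and
  effect 0.25. This effect size was chosen (by a one-off pilot, before
  freezing) so that neither method recovers the causal pair every time,
  which is the regime where the classifier correction should show: over 50
  replicates the percentage-ratio variant must find the causal pair at
  least as often as classic MDR.
* **Null calibration** — flat penetrance 0.3, 150 cases / 350 controls, 15
  SNPs. Each 2-locus model is fitted on a stratified half and its
  chi-square evaluated on the held-out half; with no true signal the
  rejection rate at α = 0.05 should sit near 5%. The held-out design
  matters: testing a data-driven dichotomy on the data that shaped it is
  anticonservative, so in-sample chi-square p-values from `model_stats()`
  on a *selected* model should be read as descriptive.

Problem sizes throughout the suite (60-row oracle instances, 6-15 SNP
panels, 50-replicate recovery) are chosen so the entire suite exercises
every code path in seconds while keeping the stochastic checks inside
comfortable tolerance bands.

## Worked example

```{r example}
cells <- list("0,0" = c(114L, 342L), "0,1" = c(57L, 280L),
              "1,0" = c(5L, 27L),   "1,1" = c(17L, 55L))
ds <- fixture_from_cells(cells)
model <- label_cells(count_cells(ds, c(1, 2)), "percentage_ratio", threshold = 1)
model
stats <- model_stats(apply_model(model, ds))
stats
```

The classic ratio classifier labels all four of these cells low-risk
(every cell is control-heavy), giving sensitivity 0 and balanced error
exactly 0.5; the percentage-ratio classifier recovers two case-enriched
cells and a sensitivity of 0.679.

## Known limitations

* Exhaustive enumeration scales as `choose(n_snps, order)`; orders 2-5 on
  a 77-SNP panel are practical, genome-wide panels are not the target.
* The in-sample chi-square of a selected model is anticonservative (see
  above); use held-out evaluation for calibrated p-values.
* Genotype codes are treated as unordered categories; dominant/recessive
  encodings are the caller's responsibility.
* Up-sampling of the minority class is deliberately not provided;
  `undersample()` exists to reproduce under-sampling comparisons, with the
  caveat that discarding controls loses information — which is the
  argument for correcting the classifier instead.
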