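---
title: "Methods: cell-type-resolved toxicity scoring and the pseudo-bulk dilution analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-type-resolved toxicity scoring and the pseudo-bulk dilution analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(celltox)
```

`celltox` asks two linked questions about drug toxicity in a
heterogeneous tissue: *which cell types respond differently to toxic
drugs*, and *how much of that signal survives bulk-style averaging*.
This vignette documents the models, the tunable parameters, the
numerical choices, and the limits of what the synthetic data can show.

## The drug score model

For a drug $d$ with target-gene set $T_d$ and a log-normalized
expression matrix $x_{gc}$, the raw score of cell $c$ is

$$ s_{cd} = \frac{1}{|T_d \cap G|} \sum_{g \in T_d \cap G} x_{gc}, $$

the mean expression of the drug's targets present in the matrix ($G$ is
the gene universe after QC). Targets absent from $G$ are simply dropped
and the per-drug coverage is reported; drugs with zero coverage are
removed. The score is then log-transformed,
$\ell_{cd} = \ln(s_{cd} + \varepsilon)$, to make the heavily
right-skewed score distribution roughly symmetric before t-testing.

Two conventions matter downstream:

* **Natural logarithms throughout.** Cell-type fold changes are defined
  as $\mathrm{FC} = e^{\Delta}$, where $\Delta$ is the difference in
  mean logged scores between toxic and non-toxic drugs. Published
  worked-example tables in this analysis style only reconcile
  (printed $\mathrm{FC} = \exp(\text{printed log FC})$ at three
  decimals) under the natural-log convention; base-2 and base-10 fail
  for every row, and the acceptance suite checks exactly this.
* **The pseudocount.** Raw scores can be exactly zero (all targets
  undetected in a cell), so the log needs an offset. The default
  $\varepsilon = 10^{-9}$ is small enough not to distort nonzero
  scores; it is exposed in `log_transform_scores()` and recorded in the
  score object.

Scoring uses all genes surviving QC, not just the highly-variable set —
drug targets are fixed external knowledge, and restricting to HVGs would
silently drop targets. `score_drugs(restrict_hvg = TRUE)` exposes the
alternative.

## Cell-type statistics

Logged scores are averaged per cell type (every cell of the type
contributes, giving a types × drugs table) at two annotation
resolutions: a 4-type *abstract* level (Nephron, Endothelium, Immune,
Stroma) and a 32-subtype *detailed* level nested inside it. For each
cell type, a two-sample t-test compares toxic against non-toxic drugs;
the replicate unit is the **drug**, never the cell — cells of one tissue
are not independent replicates of a drug effect.

* **Welch, not pooled.** With unbalanced groups (the motivating panels
  are roughly 1:3 toxic:non-toxic) and no reason to assume equal
  variances, the unequal-variance test is the safe default;
  `var_equal = TRUE` gives Student's t for sensitivity analysis.
* **CI construction.** The 95% CI on the fold change is the
  exponential of the Welch CI of the mean difference of logged scores,
  so `ci_lower <= fold_change <= ci_upper` holds by construction.
* **Multiplicity.** Benjamini–Hochberg correction is applied within an
  annotation level (4 or 32 tests), matching how the per-level result
  tables are read. `fdr_correct()` wraps `stats::p.adjust(method =
  "BH")`; the test suite verifies it against an independent
  sort/scale/cummin implementation.

## The dilution simulation

The central claim — cell-type-mediated toxicity is diluted away by
bulk averaging — is tested by construction:

1. Subsample 10% of cells, preserving each type's prevalence exactly
   (largest-remainder quotas, uniform draws within type).
2. Randomly halve the samples into a treated and a control arm (12 vs
   12 under the generator defaults).
3. In the treated arm, choose `round(response_rate × n_mediator)`
   mediator-type cells uniformly and multiply **all** their gene
   expression (linear normalized scale) by $(1 + e)$; effect sizes $e$
   sweep $10^{-3}$–$10$ on a 9-point log grid, response rates are 0.3,
   0.8, 0.95.
4. Measure power twice, where power = significant genes / total genes
   (per-gene Welch t-tests on $\ln(1+x)$, BH-FDR < 0.05):
   * **single-cell**: treated-arm cells vs control-arm cells;
   * **pseudo-bulk**: per-sample all-cell means, arm vs arm.

Design choices worth stating:

* **Pseudo-bulk is the prevalence-weighted (all-cells) mean.** The
  alternative — averaging cell-type mean profiles — would up-weight
  minority mediators by a factor of $1/(Kp)$ and largely undo the
  dilution being studied; it is available as
  `pseudobulk_mode = "typemean"`. Under the all-cells mean, the expected
  treated/control ratio per gene is the analytic core of the argument:
  $1 + p\,r\,e$ for mediator prevalence $p$, response rate $r$, effect
  $e$ (a property test verifies this identity at Monte-Carlo accuracy).
  For Endothelium ($p \approx 0.078$) even $e = 10$ moves a gene by a
  factor ≈ 1.6 at the sample level, against donor-level variability of
  comparable magnitude — hence single-digit pseudo-bulk power.
* **Arms are disjoint sample halves.** This gives the pseudo-bulk test
  honest biological replicates (donors), and means the single-cell
  comparison inherits donor-to-donor variability as confounding — cells
  are pseudo-replicates of their donor, which inflates single-cell
  rejection rates at all effect sizes. That inflation is a real and
  known property of cell-level testing, and it is part of why
  single-cell "power" by the genes-called-significant definition
  dominates pseudo-bulk power everywhere; the package reports it as
  measured rather than correcting it away.
* **The multiplier hits all genes** of a responding cell, modelling a
  global transcriptional response of the affected type rather than a
  pathway-specific one.

## The synthetic data generator

The generator produces the study conditions, not a dial to turn until
tests pass:

* **Composition.** 24 samples × 500 cells; abstract prevalences
  0.824/0.078/0.071/0.026 renormalized to sum to one (the printed
  approximations total 99.9%). Per-sample type counts are deterministic
  largest-remainder quotas — (412, 39, 36, 13) at 500 cells — so
  composition checks are exact, not distributional. Detailed subtypes
  (20/5/5/2 per abstract type, 32 total) are uniform within their
  abstract type and exist as nested placeholders (`Nephron_7`), not a
  real ontology.
* **Counts.** Negative binomial with dispersion 0.5 around
  $\mu_{gc} = \beta_g \cdot f_{gs} \cdot \lambda_c \cdot
  m^{[g \in M_t, c \in t]}$: log-normal per-gene base means
  ($\ln\beta \sim N(\ln 0.5, 1)$), a per-sample per-gene log-normal
  donor factor (sd 0.8 — this is what makes pseudo-bulk testing
  realistically hard), a per-cell log-normal library factor (sd 0.3),
  and a marker-fold multiplier $m = 3$ on each type's 50 marker genes.
  The count model and these magnitudes are the package's own choices —
  the analysis being reproduced does not specify a count distribution —
  selected once to give realistic sparsity (~35% detected genes per
  cell) and QC attrition (~22% of cells fail the novelty-score filter
  at defaults).
* **Planted drug signal.** Toxic drugs draw 70% of their 1–5 targets
  from the susceptible type's markers; all other targets come from
  non-marker genes, so with enrichment 0 the toxic and non-toxic panels
  are exchangeable and every downstream test is null-calibrated (the
  acceptance suite checks the type-I rate against its binomial band).

What the generator does **not** emulate: doublets, ambient RNA,
batch/chemistry effects, gene-gene correlation beyond the shared donor
factor, real marker-gene biology, or the marginal distributions of any
real atlas. Passing tests therefore demonstrate that the *machinery* is
correct and that dilution follows from composition and donor variance —
not that any particular real tissue will show a specific power value.

## QC and normalization choices

The cell filters (UMI ≥ 500, genes ≥ 250, novelty score
log10(genes)/log10(UMI) strictly > 0.85) and the gene filter (detected
in ≥ 10 cells, inclusive) follow standard single-cell practice; the
novelty-score formula is the standard definition, and the strict
inequality follows the usual "greater than" reading. LogNormalize uses
the de-facto scale factor 10,000. HVG selection is VST-style:
per-gene standardized variance under a fitted mean–variance trend
(second-degree polynomial of log10 variance on log10 mean), standardized
counts clipped at $\sqrt{N}$, top 2000 flagged. No doublet detection is
applied, and HVG flags are advisory (see scoring above). Degenerate
inputs fail loudly: all cells or all genes removed, zero-count cells at
normalization, and all-constant genes at HVG selection are errors, not
warnings.

## Bulk stage and classifiers

Replicate collapsing parses sample ids with a regex (default
`^(.*)_rep[0-9]+$`) and averages replicates per drug; unparseable ids
are an error listing the offenders. Differential expression is per-gene
Welch on (already log-scale) signature values with the joint filter
p < 0.05 **and** |log2FC| ≥ 1 — the threshold is read as a lower bound
on effect size, the only reading consistent with hit lists whose every
member exceeds it; both thresholds are arguments. Empirical-Bayes
moderation is deliberately out of scope.

Classifier evaluation uses a stratified 80–20 split, a fixed 0.5
decision threshold (accuracy, F1, sensitivity, specificity), AUROC via
`pROC`, and a 1000-replicate stratified bootstrap for the AUROC CI
(the CI method is a package choice). The representative model set is
logistic regression, a random-forest-style ensemble (`ranger`),
gradient-boosted trees (`xgboost`) and an RBF SVM (`e1071`); MLPs and
voting/stacking ensembles add no distinct logic and are omitted.
External validation reuses fitted models on a new feature table aligned
by cell-type name, never refitting.

## Reproducibility and problem sizes

All randomness flows from explicit seeds; `run_pipeline()` derives
per-stage seeds from one master seed and writes a manifest with the
config snapshot and md5 checksums of every output, so a rerun is
verifiable bit for bit. The test suite runs its replicate loops
(50-seed signal recovery, 200-test null calibration, shuffled-label
checks) on a scaled-down generator configuration — 400 genes, 4 samples
× 150 cells, with QC thresholds scaled to the resulting library sizes —
chosen so that one hundred full pipeline replicates remain a
routine test-suite run; the dilution bound itself is always checked at
the full default scale (2000 genes, 24 × 500 cells). Monte-Carlo
assertions state their tolerance in binomial standard deviations of the
quantity being estimated, and interval-coverage assertions are made over
replicate draws (a correct 95% CI misses its target 5% of the time).

## Known limitations

* Drug identity is normalized lexically (case, whitespace); synonym and
  structure-based resolution are out of scope, so the same compound
  under two names stays two drugs.
* The single-cell arm of the power comparison pools all cells of the
  subsample; a per-cell-type test would be more powerful for the
  mediator and is not implemented.
* The t-test treats aggregated cell-type scores as one observation per
  drug; hierarchical models of cell-level variation are out of scope.
* Power values from the simulation describe the synthetic conditions;
  they transfer to real tissue only qualitatively (minority-mediated
  signal dilutes as $p\,r\,e$).
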