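# celltox

Cell-type-resolved drug toxicity scoring and pseudo-bulk dilution
analysis for single-cell RNA-seq.

## The problem

Drug-induced organ injury — the motivating case is drug-induced acute
kidney injury — is often mediated by particular cell types: a compound
whose targets are expressed mainly in, say, endothelial cells will
injure tissue through that compartment. Bulk RNA-seq averages expression
over all cells, so a toxicity signal confined to a minority cell type is
diluted roughly in proportion to that type's prevalence and can become
statistically undetectable. `celltox` implements, end to end, the
analysis that makes this argument quantitative:

1. **Drug-target-toxicity database.** Per-source drug→target tables
   (DrugBank/ChEMBL-style exports) are merged by set union; per-source
   binary toxicity labels (e.g. Ryan reference, FDA-label collections,
   DIRIL-style lists) are merged by **logical OR** — a drug is toxic if
   at least one source says so. Drugs without targets, labels, or an
   allowed approval status are dropped with an exclusion tally.
2. **Single-cell QC and normalization.** Cells need ≥ 500 UMIs, ≥ 250
   detected genes and a novelty score log10(genes)/log10(UMIs) > 0.85;
   genes must be detected in ≥ 10 cells. Counts are log-normalized,
   value = ln(1 + count · 10⁴ / cell total), and the top 2000 genes by
   VST-style standardized variance are flagged as highly variable.
3. **Per-cell drug scores.** score(cell, drug) = mean log-normalized
   expression of the drug's target genes in that cell, then a natural-log
   transform, logged = ln(score + ε). This is the Drug2Cell-style
   statistic at the core of the package.
4. **Cell-type statistics.** Scores are averaged per cell type (at a
   4-type "abstract" and a 32-type "detailed" resolution), and for each
   cell type a Welch t-test compares toxic vs non-toxic drugs. Reported
   per type: t, logFC (difference of group means, natural log), fold
   change = exp(logFC), a 95% CI on the fold change, and BH-FDR-corrected
   p-values.
5. **Dilution simulation.** From a 10% prevalence-preserving subsample,
   samples are halved into treated/control arms; in the treated arm a
   response-rate fraction of mediator-type cells has all expression
   multiplied by (1 + effect), effect swept 0.001–10 on a log grid.
   Power (significant genes / total genes, per-gene Welch tests on
   ln(1+x), BH-FDR < 0.05) is measured at single-cell resolution and
   after per-sample pseudo-bulking — the averaging that models bulk
   RNA-seq.
6. **Bulk DE and classifiers.** LINCS-style replicate-encoded signature
   matrices are collapsed by regex (`DRUG_rep1`, …) and tested per gene;
   cell-type score tables become drug-level feature tables for toxicity
   classifiers (logistic, random-forest, gradient-boosted trees, RBF
   SVM) with stratified 80–20 evaluation, bootstrap AUROC CIs and
   external validation.

A negative-binomial synthetic-data generator reproduces the study
conditions (24 samples × 500 cells, four cell types at ≈ 82.4 / 7.8 /
7.1 / 2.6% prevalence, donor-level expression variability, marker genes,
drug panels with planted toxic-target enrichment), so the entire
pipeline runs and is tested without any external download.

## Worked example

```r
library(celltox)

pop    <- generate_cell_population(synth_config())   # defaults, seed 42
qc     <- run_qc(pop)
db     <- generate_drug_panel(drug_panel_config(), pop)
scores <- log_transform_scores(score_drugs(qc$data, db))
test_celltypes(aggregate_by_celltype(scores, "abstract"), drug_labels(db))
```

```
Cell-type toxic vs non-toxic drug-score tests (abstract level, 40 toxic vs 120 non-toxic drugs)
   cell_type t_statistic log_fold_change fold_change ci_lower ci_upper  p_value p_corrected
 Endothelium       4.680           3.840       46.70    9.150    239.0 9.84e-06    3.94e-05
      Immune       0.668           0.602        1.83    0.304     11.0 5.06e-01    5.76e-01
     Nephron       0.659           0.599        1.82    0.297     11.1 5.12e-01    5.76e-01
      Stroma       0.562           0.509        1.66    0.274     10.1 5.76e-01    5.76e-01
```

The generator planted the toxic drugs' targets in Endothelium marker
genes (70% enrichment); the test recovers exactly that type — its toxic
drugs score e^3.84 ≈ 47-fold higher than non-toxic drugs, with a
corrected p of 4 × 10⁻⁵, while the other three types are null. Note the
fold change is the *natural* exponential of the log fold change.

The dilution simulation on the same data:

```r
sw <- run_power_sweep(qc$data, sim_config(effect_sizes = c(0.1, 1, 10),
                                          response_rates = 0.8, seed = 42))
sw
```

```
 effect_size response_rate  data_level power
         0.1           0.8 single_cell 0.404
         0.1           0.8 pseudo_bulk 0.000
         1.0           0.8 single_cell 0.408
         1.0           0.8 pseudo_bulk 0.000
        10.0           0.8 single_cell 0.422
        10.0           0.8 pseudo_bulk 0.002
```

Even at an 11× expression multiplier in 80% of Endothelium cells
(≈ 7.8% of the tissue), per-sample averaging leaves pseudo-bulk power
near zero — far below single-cell resolution and far below any usable
detection threshold. `plot(sw)` draws the power curves.

`run_pipeline(default_pipeline_config(seed = 42), outdir = "out")` runs
every stage and writes a manifest (config, derived seeds, md5 checksums)
that makes the run reproducible bit for bit.

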