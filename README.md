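# tabvital

Self-supervised sequential-attention models for vital-status prediction
from multi-omic tabular data.

## What problem this solves

For cancer cohorts of the kind distributed by TCGA/GDC, a clinically
interesting question is whether a patient's **vital status** (0 =
survived, 1 = deceased at last follow-up) can be predicted from
gene-level measurements. Labelled cohorts are small (hundreds of
patients) while unlabelled tumour profiles are plentiful (thousands),
which is exactly the regime where self-supervised pretraining on
unlabelled data should help a tabular deep model close the gap to — and
pass — classical supervised learners.

`tabvital` implements that study design end-to-end, for
bioinformaticians and ML researchers who want a tested, reproducible
pipeline rather than a notebook:

* **Quantification** — TPM, FPKM and upper-quartile FPKM from raw
  gene-level counts:
  `FPKM_g = C_g·10⁹ / ((Σᵢ Cᵢ)·L_g)` and
  `FPKM-UQ_g = C_g·10⁹ / (C_qtl(0.75)·G·L_g)`, with the per-sample total
  over protein-coding genes, `L_g` the exon-union length, and `G` the
  protein-coding autosomal gene count.
* **Feature reduction** — per-gene two-sample t-test (p < 0.01), L1
  logistic selection, and PCA at a 99.9% variance target on expression;
  top-2000-variance then top-256-chi-squared on copy-number categories;
  a missingness threshold plus explicit missing-category encoding on
  clinical columns. Fitted selections transfer verbatim to unlabelled
  corpora.
* **A from-scratch sequential-attention tabular network** — sparse
  per-sample feature masks via (capacity-capped) sparsemax, a
  γ-relaxed prior controlling feature reuse across decision steps,
  gated-linear-unit feature transformers, masked-feature reconstruction
  pretraining, supervised fine-tuning, and aggregate-mask feature
  importances `Σᵢ η_b[i]·M_b,j[i]` normalized to a per-sample
  distribution. Gradients come from a small reverse-mode autodiff tape
  written in R and verified against finite differences.
* **Multimodal early fusion** — submitter-ID matching (patients absent
  from any modality are dropped from all), modality-prefixed feature
  blocks, and a manifest accounting for every column.
* **Evaluation** — stratified 5-fold cross-validated ROC-AUC
  (rank/Mann–Whitney, ties half), mean ± sample SD, seeded random
  hyperparameter search, ranked importance export.
* **Synthetic cohorts** — a generator that plants known signal
  (log-scale standardized shifts in a minority of genes,
  label-dependent copy-number states, heavy clinical missingness,
  per-modality patient dropout, a jittered 10× unlabelled corpus) so
  every claim above is testable offline.

## Worked example

Simulate a linked cohort, reduce features on the labelled data, pretrain
on the unlabelled corpus, and compare pretrained against cold-start
fine-tuning:

```r
library(tabvital)

cfg <- synthetic_config(n_labelled = 300, n_unlabelled = 2000,
                        n_genes = 500, n_informative = 20,
                        effect_size = 1, modality_dropout = 0, seed = 1)
cohort <- generate_cohort(cfg)
cohort
#> multi_omic_cohort
#>   labelled: 300 patients (68 deceased), 500 genes
#>   modalities present: expression 300, cnv 300, clinical 300 patients
#>   unlabelled corpus: 2000 samples

y   <- cohort$labels[rownames(cohort$expression)]
sel <- ttest_select(cohort$expression, y, alpha = 0.01)
sel
#> selection_result: ttest; 500 -> 31 features

X <- apply_selection(sel, cohort$expression)   # labelled, reduced
U <- apply_selection(sel, cohort$unlabelled)   # corpus, same features

scfg <- ssl_config(seed = 1, max_epochs = 40, patience = 8)
pre  <- pretrain(U, scfg)

cross_validate(tabnet_learner(scfg, pre), X, y, k = 5, seed = 1)
#> cv_report [tabnet_ssl]: ROC-AUC 0.969 +/- 0.023 over 5 folds
#>   folds: 0.953, 0.986, 0.958, 1.000, 0.946
cross_validate(tabnet_learner(scfg), X, y, k = 5, seed = 1)
#> cv_report [tabnet_cold]: ROC-AUC 0.963 +/- 0.028 over 5 folds
#>   folds: 0.989, 0.953, 0.953, 0.993, 0.926
```

The t-test keeps 31 of 500 genes (the 20 planted plus a handful of
α-level false positives). Pretraining on the corpus then fine-tuning
reaches a mean ROC-AUC of 0.969 against 0.963 for the identical model
trained from scratch — the directional benefit of self-supervision at
this desk scale. Feature importances from the aggregate attention
masks rank the planted genes on top:

```r
model <- finetune(pre, X, y, scfg)
head(export_importances(tabnet_explain(model, X)), 5)
#>        feature_id importance
#> 1 ENSG00000000492 0.23116664
#> 2 ENSG00000000102 0.18068886
#> 3 ENSG00000000431 0.11635013
#> 4 ENSG00000000218 0.09377312
#> 5 ENSG00000000078 0.08280095
```

`export_importances(iv, path = ...)` writes the full ranked two-column
list, ready as ordered input for enrichment tools.

For file-based runs, `run_pipeline(run_config(...))` chains the stages
(`supervised`, `ssl`, or `multimodal` workflow) over TSV cohorts and
writes the CV report, selection, importances, fusion manifest and logs
into a run directory; `inst/cli/tabvital.R` wraps the same functions
for the shell.

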