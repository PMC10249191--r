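---
title: "Methods: self-supervised sequential-attention models for vital-status prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: self-supervised sequential-attention models for vital-status prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

`tabvital` predicts the vital status of cancer patients — a binary
outcome, 0 for survived and 1 for deceased at last follow-up — from
gene-level molecular and clinical data of the kind distributed for
TCGA-style cohorts. The pipeline covers three study designs:

1. **Supervised, unimodal**: feature-reduce the labelled expression
   matrix, train a classical classifier, report stratified 5-fold
   cross-validated ROC-AUC.
2. **Self-supervised, unimodal**: fit the feature reduction on the
   labelled cohort, transfer it to a much larger unlabelled corpus of
   related tumours, pretrain a sequential-attention tabular network by
   masked-feature reconstruction on that corpus, then fine-tune it on
   the labelled cohort inside the cross-validation loop.
3. **Multimodal**: add per-gene copy-number categories and clinical
   attributes, preprocess each modality, join patients by submitter ID
   (a patient absent from any modality is discarded from all), and run
   the self-supervised workflow on the early-fused matrix.

Because the package is exercised end-to-end on synthetic cohorts, every
stage is testable without external downloads.

## Abundance units

Raw gene-level read counts are converted with the standard GDC-style
formulas. For gene $g$ with count $C_g$ and exon-union length $L_g$:

$$\mathrm{FPKM}_g = \frac{C_g \cdot 10^9}{\left(\sum_i C_i\right) L_g},
\qquad
\mathrm{FPKM\text{-}UQ}_g = \frac{C_g \cdot 10^9}{C_{qtl(0.75)} \cdot G \cdot L_g},$$

where the total $\sum_i C_i$ runs over protein-coding genes, $C_{qtl(0.75)}$
is the per-sample 75th-percentile protein-coding count, and $G$ counts
protein-coding autosomal genes. TPM rescales length-normalized rates so
each sample sums to exactly $10^6$.

Conventions the formulas leave open, and what this package does:

* **Quantile estimator.** $C_{qtl(0.75)}$ uses the linear-interpolation
  quantile (R type 7) over *all* protein-coding counts; a
  `nonzero_only` switch restricts to nonzero counts. Both the estimator
  type and the filter are arguments of `compute_fpkm_uq()`.
* **Denominator scope.** Non-coding genes never enter the FPKM
  denominator total; they can still be quantified in the numerator.
* **No implicit transform.** Outputs are stored untransformed. Any log
  transform is a deliberate downstream step, not something the
  quantification layer does silently.

## Feature reduction

Three labelled-data strategies, all returned as `selection_result`
objects that can be transferred verbatim to another matrix (that
transfer is how the unlabelled corpus is reduced — the corpus itself
never influences the selection, which the test suite asserts as a
leakage guard):

* **t-test** (`ttest_select`): two-sided two-sample test per gene,
  selected if $p < \alpha$ (default 0.01). The *Welch*
  unequal-variance form is the default — with a 3:1 class imbalance,
  pooled-variance statistics are the less safe choice — and Student's
  pooled form is a switch. No multiple-testing correction by default,
  matching the conventional raw-cutoff screen; a Benjamini–Hochberg switch
  exists. Features constant in both classes have an undefined
  statistic and are excluded with a message.
* **Lasso** (`lasso_select`): L1-penalized logistic regression at a
  single penalty, expressed as an inverse regularisation strength
  `inv_reg` (default 0.001); coefficients with magnitude above $10^{-8}$
  count as selected. Columns are standardized with statistics from the
  fitting data only. The solver is glmnet's coordinate descent,
  warm-started along a short decreasing lambda path; `inv_reg` = $C$
  maps to glmnet's `lambda` $= 1/(nC)$ so the penalized objective
  matches the per-observation convention.
* **PCA** (`pca_fit`): standardized principal components, keeping the
  minimal number whose cumulative explained variance reaches the
  target (default 99.9%).

The copy-number modality uses a two-stage reduction
(`preprocess_cnv`): keep the 2000 highest-variance genes, then the 256
most label-associated by the Pearson chi-squared statistic of the
category-by-label contingency table (no continuity correction;
single-category features score 0). Both stage sizes are arguments.

The clinical modality (`preprocess_clinical`) drops columns whose
missing fraction reaches a threshold (default 0.5 — there is no
canonical threshold, so the value is an explicit, logged argument), integer-encodes categorical columns with a dedicated
extra *missing* category, and flags missing numeric entries with a
companion indicator column (the numeric fill is the observed median;
no other imputation happens anywhere).

## The sequential-attention network

The model is implemented from scratch on a small reverse-mode
automatic-differentiation tape (`R/autodiff.R`); every operation's
vector–Jacobian product is verified against central finite differences
in the test suite.

**Encoder.** Input features are standardized with training-set
statistics frozen into the model. The encoder runs `n_steps` decision
steps. At step $i$ an attentive transformer maps the previous step's
attention features through a linear layer, gates the result with a
multiplicative prior, and projects it onto the probability simplex with
**sparsemax**, giving a sparse per-sample feature mask $M[i]$ whose
rows sum to 1. Masked features ($M[i] \odot x$) pass through a feature
transformer — gated-linear-unit blocks, the first shared across steps,
one step-specific — whose output splits into a ReLU-rectified decision
vector and the next attention features. Decision vectors accumulate
across steps; a linear head on the accumulated representation produces
the classification logit, and each step's weight
$\eta_b[i]$ is the ReLU-derived row sum of its decision vector.

**Feature reuse and the capacity cap.** The prior after step $i$ is
$\mathrm{prior} \odot (\gamma - M[i])$: with $\gamma = 1$ a consumed
feature's gate goes to 0, larger $\gamma$ relaxes it. Gating logits
multiplicatively cannot by itself guarantee the intended budget — once
every gated logit in a row ties at zero, the simplex projection returns
a uniform row and a spent feature would regain mass. The attentive
transformer therefore projects onto the simplex *intersected with a
box*: each feature's mask weight is additionally capped by its
remaining attention capacity
$\mathrm{clip}\left(1 + (i-1)(\gamma-1) - \sum_{j<i} M[j],\ 0,\ 1\right)$.
This makes the $\gamma = 1$ budget (cumulative mask at most 1 per
feature) exact, degrades gracefully to ordinary sparsemax when
capacity is not binding, and treats the cap as a constant in the
backward pass. The capped projection is solved by bisection on the
shift parameter followed by an exact active-set refinement. If a row's
total capacity falls below 1 (possible only with more decision steps
than features at $\gamma = 1$) the projection falls back to the
uncapped form.

**Pretraining.** Per minibatch, a Bernoulli(`mask_prob`, default 0.2 —
a choice, the masking ratio is not prescribed anywhere) binary matrix
$S$ marks cells to hide; the encoder sees the standardized features
with masked cells zeroed, and a gated-linear-unit decoder reconstructs
them. The loss is

$$\sum_{b}\sum_{j}
\left|\frac{(\hat f_{b,j} - f_{b,j})\, S_{b,j}}
{\sqrt{\sum_b \left(f_{b,j} - \tfrac1B \sum_b f_{b,j}\right)^2}}\right|^2 ,$$

i.e. squared residuals, gated by the mask, normalized per feature by
the root *sum* of squared deviations from the batch mean — exactly as
printed, with no extra $1/B$ on the normalizer (the package's worked
hand example, $B=2$, $f=(0,2)$, $\hat f=(1,1)$, all-ones $S$, gives
loss 1 under this convention). Features constant within a batch have an
undefined normalizer: the standalone `reconstruction_loss()` treats a
masked constant feature as an error, while the training loop simply
excludes such features from that batch's loss.

**Importances.** Per sample, step masks are combined as
$\sum_i \eta_b[i]\, M_{b,j}[i]$ and normalized so the result is a
distribution over features; the dataset-level importance is the mean
over samples. The variant that squares the mask term in the normalizer
is available (`squared_denominator = TRUE`) for audit, but it is not
the default because it breaks the sum-to-one property that makes
importances comparable across samples.

**Optimization.** Adam (the standard adaptive-moment estimates), with
the learning rate halved after half the early-stopping patience passes
without improvement (a plateau schedule), and early stopping on
pretraining epoch loss / fine-tuning validation ROC-AUC with the best
checkpoint retained. Pretraining uses minibatches of 256; fine-tuning
defaults to 64, because labelled cohorts of a few hundred samples make
a 256 batch effectively full-batch and starve the optimizer of updates
per epoch. A discriminative fine-tuning option (`encoder_lr_scale`)
can slow the pretrained encoder relative to the fresh head; it is off
by default so that pretrained and cold-start fine-tuning follow
identical protocols and a paired comparison isolates the effect of the
pretrained initialization. All randomness (initialization, batch
order, masks, splits) derives from the configuration seed; identical
configuration and data reproduce identical weights.

**Normalization choice.** Internal batch normalization (ghost or
plain) is deliberately absent: input standardization with frozen
training statistics plus gated-linear-unit blocks trains stably at
these scales, keeps the hand-written gradients exact, and removes
train/eval-mode discrepancies. This is a simplification relative to
the reference architecture and is listed under limitations.

## Evaluation

ROC-AUC uses the rank (Mann–Whitney) formulation with ties counted
one half; the suite checks it against exhaustive pair enumeration.
Cross-validation is stratified by default (each fold's class ratio
within one sample of the global ratio, fold sizes within one sample of
each other); the reported spread is the sample standard deviation over
fold scores. Pretraining happens once, outside the fold loop — the
corpus is label-free, so this leaks nothing into held-out folds — while
feature selection and fine-tuning are refitted per fold as appropriate
to the workflow. Hyperparameter search is a seeded random search over
a declared space, evaluating each draw by cross-validation; it
replaces Bayesian tuning deliberately (reproducible with a single
integer seed, trivially parallelizable, and adequate at the scales the
package targets).

## The synthetic cohort generator

`generate_cohort()` emulates the structure the pipeline needs to be
tested against:

* **Expression:** per-gene log-normal marginals (location
  $\mathcal N(3, 2^2)$, log-scale sd uniform on $[0.3, 0.8]$ across
  genes), mimicking the positive skew and inter-gene scale spread of
  upper-quartile-normalized values. A minority of *informative* genes
  is shifted upward on the log scale by `effect_size` standard
  deviations in the deceased class — so `effect_size` is a
  standardized effect in the natural (log) scale of the data.
* **Labels:** deceased fraction defaults to 101/445 ≈ 0.227, the class
  balance of a 445-patient colorectal cohort with 101 deceased.
* **Unlabelled corpus:** ~10× the labelled cohort, same genes, same
  latent class mixture, with per-gene location jitter
  (sd `corpus_jitter_sd`, default 0.2) emulating a related-but-broader
  family of tumours. The jitter magnitude is a free knob with no
  canonical value; 0.2 keeps the corpus recognizably related while
  shifting every gene's location.
* **CNV:** integer categories 0..4 concentrated around the neutral
  state with gene-specific spread (so a variance filter is
  meaningful); a configurable subset of genes skews toward high copy
  states in the deceased class.
* **Clinical:** alternating categorical and numeric columns whose
  missingness rates are spread evenly across `missing_rate_range`
  (default 0.05–0.95), guaranteeing that moderate retention thresholds
  both keep and drop columns.
* **Linkage:** all modalities share a master submitter-ID list; each
  modality independently loses `modality_dropout` of its patients so
  the intersection-only fusion rule always has work to do.

Default sizes are 445 labelled / 4450 unlabelled patients and 2000
genes. Real cohorts carry ~60,000 gene-level features; the generator
default is smaller because the pipeline's first reduction stages
(protein-coding filter, t-test) make column count a throughput knob
rather than a behavioral one, and 2000 genes already exercises
high-dimensionality (p ≫ informative) honestly.

What the generator does **not** emulate — and hence what green tests do
not certify about real data: batch and depth artifacts, realistic
gene–gene correlation networks beyond the single latent class factor,
dependence between modalities beyond the shared label, non-random
missingness in clinical columns, and TCGA barcode semantics. Synthetic
IDs are opaque strings (`PT-000001`).

## Problem sizes and numeric choices in the shipped checks

The test suite and acceptance script run at desk scale, chosen to keep
the full suite in minutes while leaving each check statistically
meaningful: calibration tests use 1200–2000 null genes; the planted
recovery check uses effect size 1.5 with 150 samples per class (the
t-test's noncentrality there is ≈ 13, so ≥ 90% recovery is a
conservative bar); the self-supervision comparison uses five
seed-paired cohorts of 2000 unlabelled / 300 labelled samples and 500
genes (20 informative), with pretraining capped at 40 epochs and
patience 8. Oracle equivalences are asserted at $10^{-9}$ (closed-form
arithmetic), $10^{-6}$ (loss vs. naive three-loop evaluation), and
exactly (rank-AUC vs. pair enumeration). Sparsemax bisection runs 60
iterations followed by exact refinement; lasso "non-zero" means
$|{\rm coef}| > 10^{-8}$; tie-breaks in every ranking are stable in
original column order.

## Known limitations

* The paired pretraining benefit on the default synthetic conditions
  is real but small relative to seed-to-seed training noise; it is
  reported as a directional comparison, not as an effect-size claim.
* No internal batch normalization, no sparsity-entropy regularizer,
  and embedding width 1 for categorical fused columns — deliberate
  simplifications at desk scale, all noted above.
* The multimodal corpus lacks unlabelled CNV/clinical measurements in
  the synthetic setting; those blocks are filled with the labelled
  modal category / the explicit missing code, which is a documented
  deviation knob rather than a claim about real corpora.
* `lasso_select` inherits glmnet's solver determinism: results are
  reproducible given identical inputs, but coefficient paths may
  differ in the last ulp across BLAS builds.
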