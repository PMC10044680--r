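---
title: "Calibrating panel TMB to exomic TMB with mixture density regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating panel TMB to exomic TMB with mixture density regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmbcal)
```

## The problem

Tumor mutational burden (TMB) — nonsynonymous mutations per megabase of
sequenced coding territory — is used to select patients for immune
checkpoint blockade, with cutoffs (commonly 10 mutations/Mb) defined against
exome-wide measurements. In practice TMB is usually measured on targeted
gene panels covering 1–4 Mb. Panel TMB is a biased, noisy estimate of exomic
TMB, for two structural reasons this package models explicitly:

1. **Hotspot-enriched subsampling.** Panels concentrate on genes recurrently
   mutated in cancer, so a mutation at a hotspot site is far more likely to
   be captured than a background mutation. Raw panel TMB therefore
   overestimates exomic TMB, most severely at low burden, and the relation
   between the two is nonlinear with heteroscedastic, right-skewed error.
2. **Private germline contamination.** Most clinical panels are run
   tumor-only. Germline variants are removed by population-frequency
   filtering, but variants too rare for the databases ("private" germline
   variants) survive and inflate the count, by an amount that varies across
   samples and depends on genetic ancestry (both intrinsic diversity and
   database representation differ by population).

A homoscedastic linear regression of exomic TMB on panel TMB misrepresents
both the central tendency and the error distribution of these data. The
package instead fits a *mixture density network*: a fully connected network
mapping the panel-derived predictor vector to the parameters of a mixture of
log-normal distributions over exomic TMB.

## The model

For predictor vector $x$ (per-Mb panel counts, optionally ancestry), the
network outputs weights $w_k(x)$, log-scale means $\mu_k(x)$ and log-scale
SDs $\sigma_k(x)$ of a $K$-component log-normal mixture, and training
minimizes the negative log-likelihood

$$\mathrm{NLL}(x, y) = -\log \sum_{k=1}^{K} w_k(x)\,
\frac{1}{y\,\sigma_k(x)\sqrt{2\pi}}
\exp\!\left(-\frac{(\ln y - \mu_k(x))^2}{2\sigma_k(x)^2}\right),$$

computed in log-space with a max shift. The architecture is three hidden
layers of 128/64/32 units with softplus activations. Weights come from a
softmax over $K$ logits; SDs from a softplus plus a floor of $10^{-3}$
(preventing component collapse onto single observations); means are
unconstrained. The predictive *median* (by bisection on the mixture CDF,
relative tolerance $10^{-8}$) is the point estimate; mean, arbitrary
quantiles and exceedance probabilities $P(Y > t \mid x)$ are available in
closed or near-closed form. The homoscedastic linear baseline
(`linear_baseline_fit()`) is ordinary least squares with a single residual
variance, i.e. the normal fixed-variance model that minimizing MSE implies;
its `Normal(x'\beta, MSE)` predictive distribution supplies the comparison
quantiles and exceedance probabilities.

### Choices the architecture leaves open

* **Number of components.** $K$ defaults to 3: the conditional distributions
  range from strongly right-skewed at low input to roughly symmetric at high
  input, which a small mixture captures; larger $K$ gains nothing on these
  shapes and slows the quantile inversions.
* **Input transform.** Per-Mb counts enter as $\log(1+x)$. The
  input–response relation is close to linear on log-log axes, and the
  transform keeps the zero-count samples (which are legal inputs and carry
  real mass) finite. No further standardization is applied.
* **Label offset.** Exomic TMB can be exactly zero, which lies outside
  log-normal support, so $\delta = 0.01$ mutations/Mb is added to the label
  before the likelihood. All reported NLLs share the offset and remain
  comparable; the offset is negligible against the 10/Mb decision scale.
* **Optimization.** Adam (learning rate $10^{-3}$, batch 512), early
  stopping on a 10% validation split with patience 20, up to 1000 epochs.
  Gradients are derived analytically (softmax–responsibility form for the
  mixture head, standard backpropagation below) and verified against finite
  differences in the test suite. One integer seed fixes initialization, the
  validation split and batch order, making every fit bit-reproducible.
* **Training-set cap.** To avoid rare outliers dominating training, samples
  above the 98th percentile of the *panel-derived input* are excluded.
  Capping the input — never the exomic label — avoids truncating the target
  distribution being modeled. The percentile uses linear interpolation
  between order statistics, ties retained, and is computed per input
  configuration.

## From variants to the regression table

`read_maf()`, `read_bed()`, `read_hotspots()`, `annotate_af()` and
`read_ancestry()` bring MAF-style calls, BED footprints, VCF-style hotspot
catalogs and frequency annotations into plain data.frames. All interval
arithmetic is 0-based half-open (GenomicRanges underneath); MAF positions
stay 1-based in the `pos` column and are converted at the boundary.

Multi-caller call sets report dinucleotide substitutions as two single-base
rows. `merge_dinucleotides()` treats adjacent calls with similar variant
allele counts as in phase and merges them into one nonsynonymous event. The
similarity rule — relative alt-count difference at most 0.2, greedy
left-to-right pairing — is a deterministic, documented choice; the tolerance
is configurable. `footprint_mb()` intersects each sample's coverage mask
with the coding model so every sample gets its own exomic denominator, and
`panel_inputs()` assembles the per-Mb nonsynonymous / all-mutation / hotspot
counts under the configurable input scheme (hotspot-removed configurations
subtract hotspot variants from both counts before normalization). The
default consequence dictionary maps missense/nonsense/frameshift/splice
terms to nonsynonymous and silent to synonymous; terms outside the
dictionary are counted as `other` with a warning, and the dictionary is
replaceable for non-MC3 vocabularies.

## Tumor-only construction and filtering

`spike_germline()` reintroduces origin-labeled germline calls into somatic
profiles; `apply_filter()` then removes a variant iff any database popmax
allele frequency exceeds the policy threshold (permissive 1%, stringent
0.1%), or any overall frequency exceeds its threshold (0.1% vs 0.01%), or
the self-cohort carrier fraction exceeds the popmax threshold at a
non-hotspot site. Three semantics matter and are tested:

* *Absence is not zero.* A variant missing from a database passes that
  database's checks — a database can only exclude what it has seen.
* *Strictly greater than.* A variant exactly at a threshold is retained.
* *Hotspot whitelist.* Recurrent somatic hotspots would look "common" to a
  self-cohort filter; whitelisting spares them. The self-cohort frequency is
  computed as the carrier fraction across samples when not supplied — with
  the corollary that it is only meaningful when the cohort is large enough
  that a singleton sits below the threshold.

Classification metrics treat somatic as the positive class: sensitivity is
the retained fraction of somatic variants, specificity the removed fraction
of germline. Samples with fewer than 400 pre-filter germline calls over the
reference region are excluded from tumor-only training sets as incompletely
genotyped.

## What the simulator emulates — and what it does not

`simulate_cohort()` draws, per sample: ancestry; exomic TMB from a
two-component log-normal mixture (weights 0.9/0.1, medians 2.5 and 20
mutations/Mb, log-SDs 0.8/0.5 — a right-skewed bulk plus a hypermutated
tail); an exomic footprint uniform on 28–38 Mb; Poisson exome counts;
Bernoulli thinning into the panel with 10-fold hotspot enrichment; and
per-policy private germline counts Poisson with ancestry-specific means per
4 Mb (EUR 15, AFR 60, EAS 30, AMR 25, SAS 35, OTHER 25 under stringent
filtering, all ×2.15 under permissive — the ratio chosen so the two
stringencies sit at their documented 20:43 relation in expectation; the
ancestry ordering reflects differential database representation, with the
absolute values illustrative rather than estimated). Ancestry proportions
default to a TCGA-like composition (80% EUR). Germline variants split
0.55/0.45 into nonsynonymous-like/synonymous-like, reflecting that rare
coding germline variants are predominantly missense-like.

Capture is modeled as independent per-mutation thinning on *counts*;
positions are synthesized only in `simulate_variant_tables()`, whose toy
4 Mb region and gnomAD-shaped frequency classes exercise the filtering
stack at the variant level. The simulator deliberately omits sequencing
depth, tumor purity and clonality effects, panel-specific gene sets, and
calling-pipeline variability. Passing tests therefore demonstrate that the
methods recover the structure this generator encodes — nonlinear bias,
heteroscedastic skewed error, ancestry-dependent contamination — not that
they are calibrated for any particular real assay, which requires fitting
to that assay's paired data.

One property worth stating precisely: raising germline contamination does
*not* widen the absolute conditional spread of truth given input in this
generator — at a fixed input value, heavier contamination crowds out signal
counts and compresses truth toward zero. What grows uniformly is the
relative spread (the 95% band divided by the conditional median), alongside
the downward shift of the median; the property tests assert that form, as
computed by the Monte-Carlo oracle `oracle_conditional()`.

## Evaluation and uncertainty gating

`kfold_predict()` gives every sample one out-of-fold predictive mixture
(seeded uniform shuffle, no stratification). `mae_spearman()` reports MAE
and Spearman rho (average ranks for ties) over samples with panel input ≥ 5
mutations/Mb, where rank information is meaningful. `tripartite()` labels a
sample confidently-above / confidently-below / indeterminate according to
whether at least 95% of predictive mass lies on one side of the threshold,
and `stratification_report()` scores PPV over the confident-above stratum
and NPV over confident-below only — the indeterminate stratum is the model
declining to call, which is the clinically actionable output of
uncertainty modeling. `calibration_diagnostics()` reports central-interval
coverage at several nominal levels and the probability integral transform
with a Kolmogorov–Smirnov distance from uniformity.

## Problem sizes and reproducibility

The packaged analyses run at sizes chosen to make Monte-Carlo noise small
relative to the effects being demonstrated while staying desk-scale: 20,000
training and 5,000 test samples for model comparisons and calibration,
50,000 samples for simulator-fidelity means, 10,000 draws for the
closed-form recovery check, and 1,000 random variant tables for filter
monotonicity. `scripts/acceptance.R --seed <s> --out <path>` recomputes the
headline quantities from scratch; every random draw derives from the one
seed, and repeated runs with the same seed are identical.

## Known limitations

* The network trains on CPU in base R matrix algebra; it is fast at these
  problem sizes but not built for millions of samples or dozens of inputs.
* The self-cohort carrier-fraction filter needs cohorts of at least a few
  thousand samples before its thresholds are meaningful.
* Calibration is demonstrated on the simulator's data-generating process;
  applying a model trained on tumor-normal data to tumor-only inputs is
  exactly the mismatch the tumor-only construction exists to expose, and
  nothing in the package makes that substitution safe.
* Survival analysis and threshold-outcome optimization are out of scope;
  the stratification outputs are designed to feed such analyses downstream.
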