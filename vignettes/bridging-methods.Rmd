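---
title: "Bridging a microarray classifier to a qRT-PCR assay: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bridging a microarray classifier to a qRT-PCR assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gepbridge)
```

## The problem

A diagnostic gene-expression classifier is trained once, on one measurement
platform, and is then wanted on another. Here the source platform is a
whole-blood microarray (log2 intensities over 13 probes) carrying a linear
classifier for Kawasaki disease (KD) against other febrile conditions, and
the target platform is a 15-target qRT-PCR assay (13 classifier genes plus
2 reference genes). Retraining on the target platform is unattractive when
the available paired cohort is small — a refit model would be underpowered
and would no longer be the validated classifier. Bridging keeps the
original model fixed and instead learns how the two platforms' measurements
relate.

## The bridging model

Let $x_j$ denote the source-platform value of feature $j$ and $t_k$ the
target-platform $\Delta\mathrm{Ct}$ of target $k$. The original classifier
is

$$s = w_0 + \sum_j w_j x_j .$$

On paired samples (the same RNA measured on both platforms) each source
feature is regressed, by ordinary least squares, on *all* included target
features:

$$x_j \approx \beta_{0j} + \sum_k \beta_{jk} t_k ,$$

and the regressions are substituted into the classifier:

$$s \approx \Big(w_0 + \sum_j w_j \beta_{0j}\Big) +
  \sum_k \Big(\sum_j w_j \beta_{jk}\Big) t_k .$$

`fit_bridge()` fits all $J$ regressions from one QR decomposition (they
share the design), `reweight()` performs the substitution, and `score()`
applies either model. The substitution is linear in the original weights,
which the test suite asserts directly.

Two properties make this construction attractive and testable:

* **Noiseless-affine oracle.** If every target feature is an exact affine
  transform of its cognate source feature, the regressions invert that map
  and bridged scores equal original scores to machine precision. The suite
  uses this as an exact end-to-end oracle.
* **Information recovery under co-regulation.** Because each source feature
  is regressed on *all* target features, a target feature dropped from the
  assay (an unstable construct) does not lose its information entirely:
  correlated retained features absorb it. The regression against the full
  panel can predict the dropped feature's source values better than its own
  noisy cognate measurement alone.

Regressions are deliberately unregularized: the coefficients themselves are
substituted into a published model, and shrinkage would bias them silently.
A rank-deficient design is a hard error naming the collinear features.

## $\Delta$Ct and its conventions

`compute_delta_ct()` implements
$\Delta\mathrm{Ct}_t = \tfrac12(\mathrm{Ct}_{ref1} + \mathrm{Ct}_{ref2}) - \mathrm{Ct}_t$.
Lower Ct means more template, so higher $\Delta$Ct means higher expression;
the suite checks the sign convention explicitly. Amplification efficiency
is assumed constant within a gene (a hook for per-gene scaling exists but
defaults to off). A sample whose *reference* Ct is undetermined is dropped
entirely — $\Delta$Ct is undefined without both anchors and imputation
would distort the bridge — while an undetermined *target* Ct yields a
missing value for that entry only. `assess_stability()` excludes targets
missing in more than 5% of samples by default; the real assay's unstable
construct (DDIAS, undetermined in a large fraction of reactions) is the
motivating case, and the threshold is a package choice since the original
analysis excluded the construct outright without stating one.

## Model representations

The classifier exists in three equivalent forms: on microarray log2
intensities, on mean/SD-normalized $\Delta$Ct values, and on raw
$\Delta$Ct values. With $z_k = (t_k - \mu_k)/\sigma_k$,

$$w^{raw}_k = w^{norm}_k/\sigma_k, \qquad
  c^{raw} = c^{norm} - \sum_k w^{norm}_k \mu_k/\sigma_k ,$$

implemented by `to_raw()` / `to_normalized()`, which are exact inverses.
Applied to the packaged published model, every per-gene raw weight
reproduces the published value at 3 decimals; the intercept lands within
0.001–0.002 of the published one because the published table was computed
from full-precision inputs before rounding to 3 decimals, and the packaged
fixture can only start from the printed values. When *fitting* on data, the
normalization parameters are computed from the training samples at hand;
the published $\mu/\sigma$ are used only when applying the published model.

## Reference-gene screening

`screen_references()` retains genes that (1) have mean log2 expression in
an inclusive window, default [11, 15]; (2) show no differential expression
across condition groups at $\alpha = 0.05$; and (3) have at most 3 outlier
samples by the robust Z score
$z_i = 0.6745\,(x_i - \mathrm{median})/\mathrm{MAD}$ with threshold 3.5
(unscaled MAD; the 0.6745 factor calibrates to a normal Z). Survivors are
ranked by increasing variance, ties broken lexicographically for
determinism. Choices worth noting:

* Outliers are counted on $|z|$ (both tails). The screening formula as
  printed is one-sided, almost certainly a typographical simplification for
  a stability screen; a `two_sided` switch preserves the literal reading.
* A constant gene has MAD = 0; it is treated as maximally stable (zero
  outliers, DE p = 1) rather than as an error.
* The DE criterion defaults to an ordinary one-way F-test so that the
  screen does not depend on any single ecosystem's implementation; a
  moderated empirical-Bayes variant (`moderated = TRUE`, via limma) is
  available and is what the screening literature itself uses. The
  distinction matters for exactly the genes the screen wants: under the
  plain F-test a truly stable gene is still false-excluded at the nominal
  $\alpha$ (5%), whereas moderation shrinks a low-variance gene's variance
  estimate toward the common prior, making its DE p-value conservative and
  its exclusion rare. The planted-gene recovery experiment therefore runs
  the moderated screen; the calibration and power tests exercise the plain
  F-test against its nominal properties.

## Cross-validation and evaluation

`loocv()` leaves one sample out, fits all bridge regressions and reweights
the classifier on the rest, scores the held-out sample, and pools the
out-of-fold scores into a single ROC (one cross-validated AUC). Inner fits
are allowed to be exactly identifiable ($n-1 = K+1$); below that the run
refuses. A failed inner fold (collinearity) is logged and skipped rather
than aborting the run.

ROC, AUC, the DeLong confidence interval and the Youden point come from
pROC (`roc_metrics()`), with ties at the Youden plateau broken toward
higher specificity and a stratified-bootstrap CI as an option. The test
suite checks the AUC against a brute-force pair-counting oracle to 1e-12.
Headline runs include only samples with RIN strictly greater than 8.0 and
exclude healthy controls from the ROC (KD vs retained febrile conditions);
excluded samples remain scorable, and `rin_bias_test()` compares score
distributions across RIN strata with a Wilcoxon rank-sum test, exact
whenever group sizes permit and there are no ties. Per-condition summaries
use linear-interpolation quantiles (R type 7).

## The synthetic cohort generator

`generate_cohort()` draws, per condition, a latent log2 expression vector
from a multivariate normal with compound-symmetric correlation
($\rho = 0.3$ by default — the co-regulation that lets a dropped feature's
information be recovered), adds measurement noise for the microarray
(SD 0.15 log2 units), and maps the latent value through a per-gene affine
transform onto $\Delta$Ct (unit slopes by default, intercepts anchored so
that $\Delta$Ct means sit at the published per-gene normalization means),
realized as Ct values against two stably generated reference genes
(Ct noise SD 0.25 cycles). Defaults describe a 107-sample cohort over five
conditions (27 KD) with per-gene latent SDs taken from the published
normalization SDs, and a KD effect of 0.92 latent SDs per gene (signed by
the original model's weight signs, attenuated for bacterial and uncertain
infections), chosen once so that the generator's closed-form AUC for the
original classifier is about 0.96 — the cross-validated regime the real
assay reported. Two assay pathologies are modeled:

* the unstable construct: one target's Ct set undetermined with probability
  0.3, missing-completely-at-random by default, with a left-censoring
  option (low abundance being the suspected mechanism in reality);
* genomic-DNA contamination of an intronless gene: its $\Delta$Ct inflated
  by 0.6 cycles per RIN unit below 8, with RIN drawn from a mixture that
  populates both quality strata and includes occasional unquantifiable
  values.

The generator returns a truth object (latent matrix, affine parameters,
noise-free scores, class-conditional score moments and the closed-form AUC,
which for a normal mixture is
$\sum_c \pi_c \Phi\big((\mu_{KD}-\mu_c)/\sqrt{2\sigma^2}\big)$), so tests
can compare pipeline output against the generating process. What it does
*not* emulate: site batch effects, non-linear platform relationships,
amplification-efficiency drift, heavy-tailed noise, and any treatment or
outcome structure. Passing tests therefore show the machinery is correct
under the stated statistical structure, not that the published performance
transfers to new clinical data.

`generate_transcriptome()` builds a three-gene toy transcriptome realizing
the probe-design scenarios that drive cross-platform concordance: identical
match sets (single isoform), platform-exclusive isoforms via exon skipping
with per-sample isoform switching, and an intronless gene whose amplicon
cannot span a junction. Probe matching is exact substring search against
spliced transcript sequences (both orientations; N in a probe is a
wildcard, at most 20% N); genome alignment is intentionally not modeled, as
matching spliced sequences is equivalent for aggregation purposes at this
scale. Per-sample TPM columns sum to 1e6.

## Numerical choices and degenerate inputs

* Bridge fits: shared QR decomposition; coefficient standard errors from
  the unscaled inverse cross-product; saturated fits carry NA standard
  errors and are accepted only where cross-validation needs them.
* $R^2$ is clamped to [0, 1]; a constant response with zero residual is
  reported as 1, with a nonzero residual as NA.
* Quantiles: R type 7 everywhere, stated once and fixed.
* Scoring requires every weighted feature finite and errors per sample
  otherwise; no silent imputation anywhere in the pipeline.
* All simulation randomness flows from a single integer seed; identical
  (config, seed) pairs reproduce bit-for-bit.

## Problem sizes used by the test suite

The suite favors sizes that make the distributional checks sharp but quick:
DE-screen calibration uses 2000 null genes and 500 powered genes in one
vectorized call; coefficient-coverage checks run 200 replicates of an
n = 80, 12-feature bridge; the planted-reference recovery runs 200
replicates of a 52-gene, 120-sample screen; the closed-form-AUC check uses
a 5000-sample cohort; oracle comparisons for ROC run at n ≤ 200 where the
brute-force pair count is exact. The full suite completes in well under a
minute on one core.

## Limitations

The bridge assumes linear platform relationships on the chosen scales and
a fixed, correct original model; it reproduces neither the discovery
cohort, the published shortlist of reference genes, nor the published AUCs,
because the underlying qRT-PCR measurements are not publicly deposited. The
packaged published weights are 3-decimal printed values, so conversions
between representations inherit that rounding (visible as a 0.001-level
discrepancy on the converted intercept). Whether the published
normalization parameters were computed on the RIN-filtered subset or the
full bridging cohort is not stated; when fitting, this package computes
them from the training samples in use, per fold, so no fold sees its
held-out sample.
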