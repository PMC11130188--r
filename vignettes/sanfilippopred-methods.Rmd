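---
title: "SanfilippoPred: model, priors, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SanfilippoPred: model, priors, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SanfilippoPred)
```

## The scientific setting

Sanfilippo syndrome (mucopolysaccharidosis type III) is an autosomal
recessive lysosomal storage disease caused by loss-of-function variants
in one of four heparan-sulfate degradation genes (*NAGLU*, *SGSH*,
*HGSNAT*, *GNS*). Most missense variants reported for these genes carry
no usable clinical assertion — they are variants of uncertain
significance (VUS) — and the genome-wide in-silico predictors disagree
with each other often enough that no single score is a reliable
arbiter. The premise of this package is that for a single gene the
*joint* distribution of several predictor scores is strongly bimodal:
variants that damage the protein tend to score "damaging" on most
predictors simultaneously, and tolerated variants score "benign" on
most. That structure can be learned from the unlabelled VUS themselves.

## Model and inference

Each variant contributes a vector $x_i \in \mathbb{R}^p$ of predictor
scores (up to eight: Grantham's distance, Sneath index, SIFT,
PolyPhen-2, CADD, REVEL, MetaLR, MutationAssessor; admissible ranges are
enforced at parse time, see `featureRanges()`). The model is a
two-component Gaussian mixture with conjugate priors:

$$x_i \mid z_i = k \sim \mathcal N(\mu_k, \Sigma_k), \qquad
  z_i \sim \mathrm{Cat}(\omega),$$
$$\omega \sim \mathrm{Dir}(1, 1), \qquad
  \mu_k \sim \mathcal N(\eta, \tau), \qquad
  \Sigma_k \sim \mathcal W^{-1}_p(\nu, \Psi).$$

`defaultPriors()` sets $\eta$ to the overall data mean, $\Psi$ to the
overall data covariance, $\nu = p$, and $\tau$ to the data covariance
scaled by a factor of 10. The scaling is applied multiplicatively —
i.e. the prior on cluster means is *wider* than the data covariance,
which is the weakly-informative reading; users who prefer the
concentrated alternative can pass `tauScale = 0.1`. Scores are modelled
on their raw scales (CADD on 0–32, the probability-like scores on
0–1): no standardization is applied, and near-singular data covariances
(e.g. constant columns) are regularized with a small ridge relative to
the mean diagonal, so the large CADD/Grantham scales cannot drown the
[0, 1] features numerically.

`runGibbs()` cycles the full conditionals in the order assignments →
weights → means → covariances. All conditionals are standard
conjugate updates; assignment responsibilities are computed in log
space, so simultaneous density underflow can never produce NaN. An
empty cluster makes the affected conditionals fall back to prior draws
(keeping the chain proper without restarts); if a cluster stays empty
for more than 50 consecutive sweeps a warning is issued.

**Label switching.** Mixture likelihoods are invariant to relabelling
the components, so draws are reordered post hoc under the constraint
$\omega_1 < \omega_2$, with cluster 1 read as benign and cluster 2 as
pathogenic — the model's a-priori assumption that the benign variants
are the minority among VUS of a severe recessive disease gene. An exact
tie $\omega_1 = \omega_2$ (a measure-zero event, but reachable through
serialization round-trips) is broken by the cluster means of an anchor
feature, REVEL by default, with the benign cluster taking the lower
value. Note the practical corollary: when the true weights are close to
one half, the constraint identifies the clusters only weakly and
posterior summaries can mix the components; the synthetic defaults
(0.43/0.57) keep the constraint informative.

**Chain length.** The published analysis does not state chain settings,
so the package chooses its own: `gibbsConfig()` defaults to 20 000
sweeps, 5 000 burn-in, thinning 5 (3 000 retained draws), which makes
the 2.5/50/97.5 posterior percentiles stable to about two decimals at
the package's target problem size (n ≈ 400, p ≤ 8). The test-suite and
pipeline defaults use shorter chains (400–4 000 sweeps); those sizes
were chosen as the smallest at which the parameter-recovery checks are
comfortably stable, and they are stated here as the package's own
choices.

## Classification

For each retained draw $m$, the responsibility of cluster $k$ for a
variant $x$ is
$$p_{k,m} = \frac{\omega_{k,m}\,|2\pi\Sigma_{k,m}|^{-1/2}
  \exp\!\big(-\tfrac12 (x-\mu_{k,m})^\top \Sigma_{k,m}^{-1} (x-\mu_{k,m})\big)}
  {\sum_{k'} \omega_{k',m}\,|2\pi\Sigma_{k',m}|^{-1/2}
  \exp\!\big(-\tfrac12 (x-\mu_{k',m})^\top \Sigma_{k',m}^{-1} (x-\mu_{k',m})\big)}.$$
The per-draw label is $\hat c_m = \arg\max_k p_{k,m}$ and the final
label is the mode of $\hat c_m$ over draws; the reported pathogenicity
probability is the mean of $p_{2,m}$. An exactly split vote (possible
with an even number of draws) is resolved to *pathogenic* and flagged —
in a screening context the asymmetric cost of a missed pathogenic
variant argues for the sensitive tie-break. `sanfilippoScore()` applies
the 0.50 probability threshold on the six-score panel (SIFT, PolyPhen-2,
CADD, REVEL, MetaLR, MutationAssessor); its `plug_in` mode evaluates a
single responsibility at the elementwise posterior medians, a
reconstruction of the centroid-based arithmetic a percentile-table
calculator can do. The exact arithmetic of such a calculator is not
fully specified anywhere, so `plug_in` is a best-faith approximation
and `draws` is the default and the reference mode; the two agree away
from the decision boundary (this is tested).

## Imputation

Missing score cells are imputed by chained equations with predictive
mean matching: each incomplete column is regressed (OLS) on all other
columns, and a missing cell receives the *observed* value of one of the
`donors = 5` rows whose predicted means are nearest (ties broken by row
index, then a uniform draw among the candidates). Consequences: imputed
values always lie in the column's empirical support, complete data pass
through unchanged, and the chain is deterministic under a seed. The
number of cycles (5), donors (5) and imputations (1) are conventional
defaults; nothing in the published analysis pins them down. Each data
split is imputed separately — train, validation and test — to avoid
information leakage across the evaluation boundary; the multiple
imputation variant (`nImputations > 1`) returns a list of completed
datasets and leaves pooling to the caller.

## DIC and feature elimination

Deviance is minus twice the observed-data mixture log-likelihood (the
canonical choice; the complete-data variant would depend on latent
assignments), and $p_D = \bar D - D(\bar\theta)$ with $\bar\theta$ the
elementwise posterior mean (weights renormalized, covariance means
projected back to SPD if needed). `backwardEliminate()` greedily drops
the feature whose removal yields the lowest DIC, stopping when no
removal lowers DIC or one feature remains. A caveat recorded in the
trace: comparing DIC across feature sets compares likelihoods of
different dimension, so the criterion is sensitive to the scales of the
dropped coordinates. The package reproduces the procedure as practised
rather than "correcting" it; the selection test constructs its synthetic
case so that the informative features (tight within-cluster spread,
separated means) are penalized by removal while the diffuse noise
features are rewarded by it, which is the regime in which the procedure
is informative.

## Evaluation panel

With pathogenic as the positive class: sensitivity $TP/(TP+FN)$,
specificity $TN/(TN+FP)$, accuracy, balanced accuracy, PPV, NPV, Cohen's
kappa from the marginal expected agreement, F1, the no-information rate
(larger reference-class proportion), the exact Clopper–Pearson interval
for accuracy and the one-sided exact binomial test of accuracy against
the NIR. Zero-denominator metrics are reported as `NA`, never 0. ROC
curves sweep the unique scores descending with tie grouping, so the
trapezoidal AUC equals the Mann–Whitney concordance probability with
half credit for ties (tested against brute-force pair counting and
against `pROC`). Metric cells are rounded half-up to two decimals only
when displayed; all computations keep full precision.

## The synthetic generator

Because clinical variant tables with curated assertions are not
redistributable, every stage is exercised on synthetic data from
`generatorSpec()`/`generateMixtureDataset()`: a two-component Gaussian
mixture over the eight scores with default weights (0.43, 0.57) and
default centroids that mimic the contrast between benign-like and
pathogenic-like NAGLU missense variants (benign: SIFT ≈ 0.38,
CADD ≈ 15, REVEL ≈ 0.39; pathogenic: SIFT ≈ 0.03, CADD ≈ 24.4,
REVEL ≈ 0.75, and so on — see `defaultCentroids()`). Within-cluster
covariances of the real data are unknowable without the original
table, so the generator uses documented diagonal spreads
(`defaultClusterSds()`) chosen once to give a clearly bimodal but
realistically overlapping mixture whose coordinates stay on their
natural scales. Values are clipped into the observed score ranges
(`clipRanges()`); clipping slightly biases component means near a
boundary (worst case ≈ 0.1 within-cluster SD for pathogenic SIFT), which
the tests account for, and a truncated-normal sampling switch exists for
users who prefer unbiased bounded draws at the cost of a different
distribution. `makeBenchmarkFixture()` reproduces the study layout: 415
unlabelled training variants, 101 + 96 labelled variants partitioned
into stratified validation (n = 99) and test (n = 98) sets, with 5%
MCAR missingness so the imputation stage is always exercised.

What passing tests on these fixtures do show: the conditional samplers
are correct (they match closed-form conjugate moments), the whole
sampler recovers known parameters with calibrated credible intervals,
and the classification/evaluation pipeline is internally consistent.
What they do not show: performance on real variant tables, whose
within-cluster covariances, non-Gaussian marginals (CADD is PHRED-like,
SIFT is zero-inflated) and annotation biases the generator deliberately
does not attempt to forge.

## Numerical choices and degenerate inputs

* Covariance operations go through Cholesky factorizations with an
  escalating *relative* ridge ($10^{-6}$ of the mean diagonal and up);
  this handles constant columns and tiny clusters without distorting
  well-conditioned problems.
* Initialization: random uniform assignments by default (re-drawn up to
  100 times if a cluster starts with fewer than $\min(p+2,
  \lfloor n/2 \rfloor)$ members), or a k-means split along the first
  principal direction (`init = "pca"`) for well-separated data.
* One seeded generator drives each stage; assignment draws consume
  exactly $n$ uniforms per sweep in row order, so runs are exactly
  reproducible and stage seeds fan out from the global seed by a hash.
* Validation/test partition: each class is split as evenly as possible;
  an odd class count sends the extra record to the validation set
  first, alternating afterwards (hence 101/96 labelled records give
  99 + 98).
* Strict parsing: only "", "NA", ".", "NaN" are missing; any other
  non-numeric token is a row-level error, and out-of-range scores are
  rejected rather than clipped.

## Known limitations

* Only the two-cluster model is supported; requesting $K \ne 2$ is a
  configuration error by design.
* The weight-ordering constraint cannot identify clusters whose weights
  are genuinely equal; in that regime the posterior summaries average
  over label permutations.
* DIC across feature sets of different dimension is scale-sensitive
  (see above); elimination results should be read together with the
  recorded per-step DIC values, not as an oracle.
* The package consumes predictor scores; it never computes them, and it
  performs no annotation, no VCF parsing and no database queries.
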