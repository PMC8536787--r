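---
title: "Cell-type deconvolution with negative-binomial reference profiles"
author: "NBDecon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-type deconvolution with negative-binomial reference profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NBDecon)
```

# The problem

A bulk RNA-Seq sample or a spatial transcriptomics spot measures a mixture
of transcripts from several cell types at once. Given an annotated
single-cell reference of the same tissue, reference-based deconvolution
asks: what fraction of each sample is contributed by each cell type?
NBDecon answers this with a weighted, regularized non-negative least
squares model built on per-gene, per-cell-type negative-binomial (NB)
expression profiles, together with an adaptive gene-wise correction for
the systematic measurement differences between the single-cell and the
compound platform.

A deliberate modeling choice runs through the whole package: **raw UMI
counts are never library-size normalized before model fitting**.
Normalizing forces every cell type to the same total transcript content,
but real cell types differ widely (neurons carry several-fold more
transcripts than glia, immune cells roughly ten-fold fewer). Those
differences carry exactly the information that converts transcript
fractions into cell fractions, so the NB profiles are fitted on raw UMIs.
Library-size normalization appears in one place only: the rank-sum test
used for marker *selection*, where it removes per-cell depth as a nuisance.

# The model

## Reference profiles

For each selected gene $i$ and cell type $k$, the UMI counts across the
type's cells are modeled as
$$X_{ik} \sim \mathrm{NB}(\lambda_{ik}, p_{ik}),$$
with dispersion $\lambda$ and success probability $p$, estimated by
maximum likelihood (L-BFGS-B on the exact NB log-likelihood,
method-of-moments start, bounds $\lambda \in [10^{-6}, 10^{6}]$,
$p \in [10^{-9}, 1-10^{-9}]$). Mean and variance follow as
$$\mu_{ik} = \frac{\lambda p}{1-p}, \qquad
  \sigma^2_{ik} = \frac{\lambda p}{(1-p)^2}.$$
Degenerate inputs bypass the optimizer: an all-zero vector is recorded as
`all_zero`; a vector whose sample variance does not exceed its mean has no
evidence of overdispersion and falls back to a Poisson profile
($\sigma^2 = \mu$, flag `poisson_fallback`). The fallback keeps the
specificity weight below finite and equal to 1 rather than letting a
boundary NB fit blow it up.

## Gene selection

Two modes, both excluding mitochondrial genes (configurable id prefixes
`mt-`, `MT-`, `Mt-`):

* **markers** (default): per cell type, a one-vs-rest Wilcoxon rank-sum
  test on log1p counts-per-10k values; genes with BH-adjusted $p$ below
  0.01 and positive enrichment are ranked by log2 fold change and the top
  200 kept. A gene appearing in more than 5 per-type lists is dropped as
  insufficiently specific. The rank-sum statistic is computed vectorized
  with tie correction and continuity correction and is unit-tested against
  `stats::wilcox.test`.
* **balanced HVGs**: cell types are first resampled to the median cluster
  size (without replacement when larger, with replacement when smaller —
  the balancing must upsample somehow, and resampling with replacement is
  the standard bootstrap choice), then genes are ranked by
  variance-stabilized standardized variance (loess fit of log variance on
  log mean, standardized values clipped at $\sqrt{N}$).

## Gene weights

Two multiplicative weights enter the loss:

* **cell-type specificity** $w^S_i = \mu_{ik'} / \sigma^2_{ik'}$, where
  $k'$ is the most-expressing type (argmax ties broken by the lowest type
  index, with a message). By the NB identities this equals $1 - \hat
  p_{ik'}$, so $w^S \in (0, 1]$, with Poisson-fallback genes at exactly 1.
* **cross-sample stability** $w^C_i = 1/\mathrm{VMR}_i$, the reciprocal
  variance-to-mean ratio of an NB fit across samples. Three availability
  modes mirror what data exist: replicated compound samples; per-subject
  pseudo-bulks from the reference; or $B = 20$ bootstrap pseudo-bulks
  (cells resampled with replacement per type at the original cluster
  sizes). The default $B = 20$ balances stability of the 2-parameter NB
  fit against runtime. Genes with all-zero cross-sample counts get
  $w^C = 0$ and drop out of the loss — a gene never observed cannot
  constrain proportions. Weights are clipped at 10; for `nb_ok` fits
  $\mathrm{VMR} \ge 1$ so the clip can only ever act on pathological
  fallback paths. When replicate groups coexist in one compound matrix the
  VMR is computed within each group and combined by a group-size-weighted
  mean. Real-valued inputs (simulated spots are weighted sums) are rounded
  to integers for this fit only.

## Platform correction and the loss

Deconvolution of a sample $y$ proceeds in three steps.

1. **Coarse composition.** Non-negative least squares of the sample's
   replicate-group mean on the panel columns, normalized to the simplex
   $\tau$; the absorbed scale constant $A$ is kept. The pipeline runs this
   fit weighted by $w^C w^S$ and then refines it by iteratively reweighted
   least squares under the variance model $s^2\,\mathrm{pred}^2 +
   \mathrm{pred}$ (a multiplicative platform/bias component plus a
   count-scale component, $s$ estimated from the log-ratio residuals of
   the better-measured half of the genes) with Huber downweighting
   ($k = 1.345$) of outlying log-ratios. This refinement matters: the
   coarse estimate's error propagates linearly into every correction
   factor, and platform bias perturbs genes multiplicatively — a raw-scale
   unweighted NNLS is very inefficient against that error structure. The
   exported `coarseEstimate()` defaults to the plain NNLS; the pipeline
   enables `robust = TRUE`.
2. **Gene-wise correction.** $r_i = \log_2\!\big(\mu_i / (A \sum_k
   \hat\tau_k \mu_{ik}) + 1\big)$, the log of the observed-to-fitted ratio
   plus one. The denominator is the coarse *fitted value* on the compound
   scale — with a simplex-normalized denominator the ratio would just
   measure the bulk-versus-per-cell scale gap. On the compound scale the
   correction has clean fixed points: a perfectly predicted gene has ratio
   1 and $r = 1$ (prediction unchanged); an observed zero gives $r = 0$
   (prediction zeroed); a gene observed 4-fold above its prediction gets
   $r = \log_2 5 \approx 2.3$ — deviant genes are moved toward the
   observation, but only partially (logarithmically), which is what makes
   the correction robust instead of self-fulfilling. Genes with a zero
   predicted denominator are excluded from that sample's loss.
3. **Weighted regularized fit.** Minimize
   $$L(\beta) = \sum_i w^C_i w^S_i \big(y_i - r_i \textstyle\sum_k
     \beta_k \hat\mu_{ik}\big)^2 + \lambda \sum_k \beta_k^2,
     \quad \beta_k \ge 0,$$
   by L-BFGS-B with the analytic gradient
   $G_k = -2\sum_i r_i \hat\mu_{ik} w^C_i w^S_i (y_i - r_i \sum_k \beta_k
   \hat\mu_{ik}) + 2\lambda\beta_k$, initialized at the coarse solution
   scaled to the sample's signal, followed by an exact active-set polish
   of the quadratic objective (Lawson–Hanson-style, KKT-checked) so the
   reported solution is the exact constrained minimizer rather than an
   optimizer approximation. Proportions are the rescaled coefficients
   $\theta_k = \hat\beta_k / \sum_k \hat\beta_k$. The constraint is the
   closed orthant $\beta_k \ge 0$: exact zeros are legitimate (absent cell
   types).

### The regularization default

No principled universal value of $\lambda$ exists, so the default makes
the penalty a fixed, small fraction of the data term:
$$\lambda_{\mathrm{auto}} = 10^{-3}\, L_0 \Big/ \sum_k \beta_{0k}^2,$$
with $L_0$ the unregularized loss at the scaled coarse solution
$\beta_0$. Both numerator and denominator scale with the squared counts,
so $\lambda_{\mathrm{auto}}$ is exactly invariant to rescaling the sample
— dividing the loss by $K$ instead (an alternative we evaluated) leaves
the penalty growing as the fourth power of the count scale and visibly
degrades high-depth samples. The L2 penalty tames collinearity among
similar subtypes; note that as $\lambda \to \infty$ the *normalized*
proportions do not tend to the uniform vector but to the normalized
positive part of the correlation between the design and the data, so the
package's property tests assert the true monotonicity (the coefficient
norm $\|\beta\|$ is non-increasing in $\lambda$) rather than a uniform
limit.

### Replicate groups

Samples in one replicate group share the coarse estimate and the
correction factors, both computed from the group mean; ungrouped samples
are their own group (a per-sample correction). Both behaviors are exposed
through the `groups` column of `CompoundSamples`. A tempting third option
— iterating the correction by re-estimating the group composition from
the corrected fits — was evaluated and diverges: each round's correction
anchors the fits to the previous composition estimate, so errors compound
instead of contracting. The package deliberately computes the correction
once.

# The synthetic-data harness

`generateSyntheticReference()` emulates the structure the model assumes:
NB counts per (gene, type) with uniform-random dispersions; lognormal
baseline gene means; disjoint marker blocks (default 20% of genes, split
over types) upweighted by a fold factor (default 8); per-type
total-transcript scales (default drawn from 0.5–5, reflecting the up to
~10-fold differences real tissues show); per-cell lognormal size factors
with exact unit mean; and optional subjects whose cell shares per type are
Dirichlet-distributed, with a mild unit-mean depth jitter. Everything is
reproducible from one seed and the generating parameters are returned as
recorded truth.

What it does **not** emulate: dropout beyond what the NB implies,
ambient-RNA contamination, doublets, cell types absent from the
reference, gene–gene correlation within a cell, and spatial structure.
Passing tests on this generator therefore demonstrate correctness of the
estimation machinery under the model's own assumptions, not robustness to
every artifact of real tissue.

`synthesizeBulk()` sums raw UMIs over a subject's cells (truth = exact
cell-count fractions; totals are conserved by construction).
`simulateSpot()` draws a fixed number of cells per type without
replacement and adds them up weighted by the mixing proportions, so spot
values are real-valued; printed schemes such as 0.33:0.33:0.33 are
normalized and recorded both ways. Cells are re-sampled for every
repetition. `injectPlatformBias()` multiplies each gene by
$e^{N(0,\sigma^2)}$.

# Study conditions used by the tests and the acceptance script

Problem sizes were chosen once as representative desk-scale conditions:

* noiseless recovery: 300 genes, 6 types, 80 cells/type;
* full-model recovery: 1000 genes, 8 types, 300 cells/type; 50 compound
  samples built as pools of 200 cells per type (bulk-like; spatial-spot
  sized pools are exercised separately), truths drawn Dirichlet(2), one
  platform-level lognormal bias draw ($\sigma = 0.3$) shared by all
  samples — platform bias is a property of the platform pair, not of a
  sample. Paired with/without-correction comparison on the same samples;
* rare-type detection: 600 genes, 4 types, 200 cells/type, spots of 10
  cells/type, rare type at 5%, 100 repetitions, detection threshold 0.5%
  (strict inequality);
* leave-one-out: 600 genes, 5 types, 250 cells/type over 5 subjects.

# Evaluation

`concordanceMetrics()` reports mAD, RMSD, Pearson and Spearman (average
ranks for ties; zero-variance inputs give NA with a warning). The
mean-squared variant of RMSD without the square root is reported alongside
as `rmsd_literal`, so either convention of the statistic can be
reproduced. `rocAuc()` pools (sample, type) pairs, sweeps all distinct
scores plus 0 and 1, treats equal scores as one threshold step, and
integrates by trapezoid — which makes the AUC equal the Mann–Whitney
probability of correct ordering, a property the tests verify
exhaustively. `detectionRate()` uses a strict `>` cutoff.
`leaveOneOutBenchmark()` rebuilds the panel without each subject,
synthesizes that subject's pseudo-bulk, deconvolutes and scores it.

# Known limitations

* Cell types absent from the reference are handled only implicitly: their
  signal is distributed over the modeled types.
* The gene-wise correction can only distinguish platform bias from
  composition error to the extent the coarse estimate is accurate; with a
  single sample and strong bias the two are partially confounded (this is
  why the robust coarse refinement exists, and why correction is computed
  once rather than iterated).
* Correlations between genes within a cell are not modeled; weights treat
  genes as independent evidence.
* The NB profile fit assumes within-type homogeneity; unannotated
  substructure inflates dispersions and deflates the affected genes'
  specificity weights (a graceful but information-losing degradation).
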