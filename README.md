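# NBDecon

Reference-based cell-type deconvolution for compound RNA-Seq — bulk
samples or spatial transcriptomics spots — from an annotated single-cell
UMI reference.

## What it does

A compound sample measures transcripts from many cell types at once.
Given single-cell data of the same tissue with cell-type annotations,
NBDecon estimates the fraction θ<sub>k</sub> of each cell type k in each
sample:

1. **Informative genes** are selected from the reference (one-vs-rest
   Wilcoxon markers ranked by fold change, or cluster-balanced highly
   variable genes); mitochondrial genes are excluded.
2. **NB profiles**: for each gene i and type k the raw UMI counts are fit
   by maximum likelihood as X<sub>ik</sub> ~ NB(λ<sub>ik</sub>,
   p<sub>ik</sub>), giving μ<sub>ik</sub> = λp/(1−p) and σ²<sub>ik</sub> =
   λp/(1−p)². Counts are never library-size normalized for fitting:
   cell-type differences in total transcript content are part of the
   signal.
3. **Gene weights**: cell-type specificity w<sup>S</sup><sub>i</sub> =
   μ<sub>ik′</sub>/σ²<sub>ik′</sub> in the most-expressing type k′, and
   cross-sample stability w<sup>C</sup><sub>i</sub> = 1/VMR<sub>i</sub>
   from an NB fit across (real, per-subject, or bootstrap) samples.
4. **Platform correction**: a coarse NNLS composition τ yields per-gene
   correction factors r<sub>i</sub> = log2(observed/fitted + 1), so genes
   deviating between platforms are partially moved toward the observation
   — the more deviant the gene, the larger the correction.
5. **Proportions** minimize the weighted regularized loss
   Σ<sub>i</sub> w<sup>C</sup>w<sup>S</sup>(y<sub>i</sub> −
   r<sub>i</sub>Σ<sub>k</sub>β<sub>k</sub>μ̂<sub>ik</sub>)² +
   λΣβ<sub>k</sub>² subject to β ≥ 0 (L-BFGS-B plus an exact active-set
   polish), rescaled to the simplex: θ<sub>k</sub> = β̂<sub>k</sub>/Σβ̂.

A full simulation harness (synthetic references with recorded truth,
pseudo-bulk, weighted spots, rare-cell series, platform-bias injection)
and evaluation utilities (mAD/RMSD/correlations, presence ROC/AUC,
detection rates, leave-one-out benchmarking) ship with the package.

## Worked example

```r
library(NBDecon)

## a synthetic reference with known truth: 400 genes, 4 types
sim <- generateSyntheticReference(nGenes = 400, nTypes = 4,
                                  cellsPerType = 100, seed = 3)
ref <- sim$ref

panel <- buildReference(ref, geneMode = "marker")
panel
#> ReferencePanel: 93 genes x 4 cell types
#>   gene mode: marker
#>   fits: nb_ok=350, poisson_fallback=22, all_zero=0
#>   cell types: type1, type2, type3, type4

wts <- computeCrossSampleWeights(ref, mode = "bootstrap", B = 20, seed = 5,
                                 genes = selectedGenes(panel))

## a compound sample: 30 cells/type pooled at 1:2:3:4, with gene-wise
## platform bias
truth <- c(type1 = 0.1, type2 = 0.2, type3 = 0.3, type4 = 0.4)
spot <- simulateSpot(ref, truth, nCellsPerType = 30, seed = 7)
biased <- injectPlatformBias(spot$counts, biasSigma = 0.3, seed = 9)

res <- deconvolute(CompoundSamples(cbind(sample1 = biased$counts)),
                   panel, weights = wts)
round(proportions(res), 4)
#>          type1  type2  type3  type4
#> sample1 0.0899 0.2052 0.3138 0.3911

round(concordanceMetrics(proportions(res)[1, ], truth), 4)
#>          mad         rmsd rmsd_literal      pearson     spearman
#>       0.0095       0.0100       0.0001       0.9962       1.0000
```

The estimated proportions recover the 10/20/30/40 mixture to within a
mean absolute difference of about 0.01 per cell type despite a 30%
(lognormal σ = 0.3) gene-wise platform bias, and rank the four types
perfectly (Spearman 1).

Panels can be persisted with `saveReference()` / `loadReference()` (a
plain-text bundle that round-trips bit-exactly), and a thin command-line
wrapper lives in `inst/scripts/nbdecon-cli.R`.

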