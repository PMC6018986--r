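# orgdriver

Integrative multi-omics analysis of cell-type-enriched intestinal organoid
cultures: absolute quantification anchored on spike-in standards,
protein-per-mRNA translation statistics, permutation-FDR differential
testing, TAD-level coordinated chromatin activity, preranked gene-set
enrichment, and — at its core — an iterative motif-selection procedure that
identifies the transcription factor driving epigenome remodelling during
differentiation.

## Who this is for

Groups profiling the same biological system under a handful of conditions
(e.g. stem-cell-enriched "CV", reference "ENR" and enterocyte-enriched "EN"
organoid media, three replicates each) across several layers: deep
label-free proteomes with a UPS2-style spike-in, spike-anchored RNA-seq
(ERCC mix), and peak-level chromatin data (ATAC, histone-mark
ChIPmentation). The package reimplements the downstream computations as
tested, reusable functions, and ships a seeded synthetic-study generator
that plants known ground truth — true copy numbers, a driver motif,
coordinated TADs, ratio-shifted genes — so that every stage can be
validated end to end without any external download.

## The methods in brief

**Absolute quantification.** Per sample, ordinary least squares of
log10(known amount) on log10(iBAQ intensity) over the spike-in panel
converts intensities to molecules per cell; a second regression transfers
the scale onto the deep fractionated run (stage 2), with stage-1 values
filling features the deep run missed (provenance recorded). mRNA copies
come from a single ERCC-anchored regression; zero counts are *missing*, not
zero.

**Translation statistics.** Protein-per-mRNA ratios are medians over all
replicate pairs `p_i / m_j`. Condition differences are tested per feature
with a Welch-form t-statistic on the pairwise log ratios whose variance is
rescaled to an unbiased estimate of `sigma_p^2 + sigma_m^2` and whose
reference distribution is restricted to the degrees of freedom the
biological replicates supply (8 for a 3 vs 3 design — never the 9 + 9 pair
count); Benjamini-Hochberg FDR across features, and a feature is called
only when both comparisons against the reference condition pass FDR < 0.05
and |fold change| > 3 in the same direction. A global test compares Fisher
z-transformed correlations of matched-replicate ratio profiles within
versus between conditions.

**Differential machinery.** Presence filtering (observed in all replicates
of at least one condition), downshifted-Gaussian detection-limit
imputation, the moderated statistic `d = (mean_A - mean_B) / (se + s0)`
with a label-permutation FDR, and for count matrices median-of-ratios
normalization with pseudocount-shrunken log2 fold changes.

**TAD coordination.** Peaks map to TADs by midpoint; TADs with >= 20 peaks
get a *percentage agreement* (share of member peaks whose fold-change sign
matches the TAD mean's sign); significance comes from an empirical FDR over
genome-wide fold-change shuffles, which automatically reproduces the
small-n bias of the statistic (null agreement > 50%).

**Driver motif selection.** Motifs are first restricted to TFs with
dynamic protein expression (FDR < 0.01). Best-match PWM log-odds scores
(both strands, min-max normalized per motif) over the significantly
changing peaks feed a 10-fold cross-validated LASSO, then an iterative
random forest: select the motif with the highest permutation importance
(%IncMSE), subtract the variance its single-predictor forest explains
out-of-bag, and repeat until the best candidate explains no residual
variance on its own. The whole selection runs five times with fresh seeds
and only motifs selected every time are kept.

**Enrichment.** Preranked GSEA (weighted Kolmogorov-Smirnov running sum)
with gene-*set* permutations for NES, nominal p and FDR.

## Worked example

```r
library(orgdriver)

study <- simulate_study(seed = 42)           # full synthetic study
la <- study$landscape

sel <- select_driver_motifs(la$peaks, la$peak_counts, la$genome, la$motifs,
                            la$motif_tf_map, la$tf_protein, study$design,
                            repeats = 5, n_trees = 500, seed = 99)
sel$selection
#>   motif stability selected pct_inc_mse sd_pct_inc_mse single_r2 first_rank
#> 1  M001         5     TRUE    51.40975      0.6650846 0.1617909          1
#>      tf    cor_fc
#> 1 TF001 0.4675648

la$truth$driver_motif_id
#> [1] "M001"
```

The selection table reads: across five independently seeded repeats, one
motif (M001) was always selected; permuting its scores raises the
forest's out-of-bag MSE by ~51%, its score explains ~16% of fold-change
variance on its own, its best score correlates r = 0.47 with the peak
log2 fold changes, and its most significantly changing linked TF is TF001
— exactly the planted driver.

The same pipeline is scriptable from a shell via the thin CLI:

```sh
orgdriver=$(Rscript -e 'cat(system.file("scripts","orgdriver",package="orgdriver"))')
Rscript $orgdriver simulate --outdir study --seed 7
Rscript $orgdriver quantify --dir study
Rscript $orgdriver diff --layer peaks --dir study
Rscript $orgdriver tads --dir study
Rscript $orgdriver motifs --dir study
```

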