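---
title: "Methods: models, statistics and design choices in orgdriver"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, statistics and design choices in orgdriver}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`orgdriver` analyses multi-layer profiles of cell-type-enriched organoid
cultures: three media conditions (stem-cell-enriched "CV", reference "ENR",
enterocyte-enriched "EN") times three biological replicates, measured as a
spike-in-anchored proteome, a spike-in-anchored transcriptome and
peak-level chromatin signal. This vignette documents the measurement
models, the statistics, the synthetic-data generator behind the test suite,
and the design decisions that were genuinely open.

## 1. The synthetic study and what it emulates

Every claim the test suite makes is checked against data from
`simulate_expression()` and `simulate_regulatory_landscape()`, whose
defaults define the study conditions.

**Expression layer.** True mRNA copy numbers per cell are log-normal
(median ~20, log10-sd 0.8 — the span typical of rRNA-depleted libraries);
each gene carries a log-normal protein-per-mRNA ratio (median ~1,000,
log10-sd 0.5), so true protein copies are `ratio x mRNA`. 30% of genes are
differential between conditions (log2 fold changes ~ N(0, 1.5) on the mRNA
layer, propagated to protein). 7.5% of genes are "ratio-shifted": their
protein copies are multiplied by 8 in the EN condition with mRNA untouched
— a planted translation-efficiency change at a magnitude a biologist would
call decisive, and at a prevalence that reflects how broadly translation is
reprogrammed between stem and differentiated states.

Measured protein intensity is `gain_s x copies x exp(eps)` with
`sd(log) = sqrt(log(1 + noise_cv^2))` and `noise_cv = 0.2` by default — the
middle of the replicate-CV range reported for careful label-free
experiments. The per-sample gain (jitter `noise_cv/4`) is shared by
spike-ins and endogenous proteins, so calibration removes it. The UPS2-like
panel (48 species, 8 levels, 4.5 orders of magnitude) is placed to overlap
the endogenous intensity range, so its lower levels are censored exactly as
a real UPS2 panel is. Missingness is logistic in log intensity
(probability 0.9 well below a detection threshold set at the
`missing_rate` quantile, 0.05 well above). mRNA counts are negative
binomial (`dispersion 0.02`, ~10 reads per molecule — a deep library)
around `depth_s x copies`, with a 92-species ERCC-like panel obeying the
same count model; sub-count panel members yield zero counts, as in real
data. `noise_cv = 0` switches every stochastic element off, giving exact
identities the noiseless recovery tests rely on.

**Chromatin layer.** Four 500-kb chromosomes of uniform random sequence;
2,000 non-overlapping 400-bp peaks on a jittered grid; 200 TADs tiling the
chromosomes; 50 motifs (one driver + 49 decoys) with one planted TF each
(20% get a second link). The driver PWM is near-deterministic (dominant
base probability 0.99-0.999, length 10): planted instances are sampled
from its probability columns, and only a near-deterministic matrix makes
sampled instances score near the consensus — which is what a "binding
site" means. Decoy PWMs have dominant probabilities 0.7-0.95 and are
planted in random peaks, uncorrelated with fold change. Driver instances
go into 30% of peaks (one instance, random offset and strand) and exactly
those peaks receive a +2 log2-unit negative-binomial mean shift in EN; 20%
of peaks get unrelated N(0, 1) condition shifts so the significant-peak set
is not driver-only. 5% of TADs are "coordinated" (all member peaks share an
extra signed shift); they are sampled first and driver instances are
planted outside them, because uniformly activating driver peaks would
dilute repressed TADs. The driver's TF is planted at >4-fold protein
change; 30% of decoy TFs are also differential, so expression filtering
alone cannot isolate the driver. TSS sites sit in inter-peak gaps, and
driver instances are planted in compact promoter windows (± 150 bp) of 60%
of a designated upregulated-gene subset; the compact window keeps promoter
content disjoint from peak sequence so the planted fraction is cleanly
recoverable.

What the generator does *not* emulate: peptide-level inference, fraction
handling, read-level artefacts (GC bias, duplicates), spatial crypt-villus
structure, single-cell heterogeneity, and correlated replicate batch
effects. Passing tests therefore demonstrate that the *computations* are
correct and calibrated under a realistic error model — not that any given
laboratory dataset satisfies that model.

## 2. Absolute quantification

All calibration regressions are ordinary least squares on the log10 scale:
an iBAQ-style intensity is proportional to molar amount only on average,
and log-log OLS linearizes the 4-5 orders of magnitude the panels span.
Stage 1 maps unfractionated intensities to amounts via the spike-ins
(refusing to fit on fewer than 5 detected spike-ins or a span under 2
orders; a non-positive slope is flagged as calibration failure). Stage 2
regresses stage-1 abundances on deep fractionated intensities over shared
features (>= 50) and applies that map to all fractionated features. One map
is fitted per sample on summed fraction intensities. Features only the
unfractionated run detected keep their stage-1 values; the `provenance`
attribute says per value which stage produced it. Copy-number units follow
the panel's units. Because both stages are affine on the log scale, any
per-sample multiplicative gain cancels — the test suite checks exact
invariance under tripling a run's intensities.

mRNA quantification is the single-stage analogue against the ERCC panel.
A zero count is reported as missing: the feature is below the counting
floor, and calling it zero copies would poison every downstream ratio.

## 3. Protein-per-mRNA statistics

The per-condition summary is the median over all `n_P x n_M` replicate
pairs of `protein_i / mrna_j` (computed on the log scale; the median is
order-invariant and robust to one bad replicate).

**The per-feature test.** The pairwise log ratios `x_ij = p_i - m_j` are
*not* independent observations, and treating them as such would be doubly
wrong. First, their sample variance is a biased estimate of
`sigma_p^2 + sigma_m^2`:

    E[s2_pairs] = [n_M (n_P - 1) sigma_p^2 + n_P (n_M - 1) sigma_m^2]
                  / (n_P n_M - 1)

which is 3/4 of the target for 3 x 3; `ratio_change_test()` rescales by
`2 (n_P n_M - 1) / (n_M (n_P - 1) + n_P (n_M - 1))` (exact when the layer
counts are equal). Second, the variance of the group mean is
`sigma_p^2 / n_P + sigma_m^2 / n_M` — the replicate counts, not the pair
count. Third, the reference distribution is restricted to

    df = (n_P^A - 1) + (n_M^A - 1) + (n_P^B - 1) + (n_M^B - 1)

the number of independent biological observations minus the estimated
means — 8 for a complete 3 vs 3 design, far below the 16 the pair count
would suggest. Null simulation (40,000 replicates) puts the type-I error
of this combination at 0.049 at the nominal 0.05. Per feature, observed
replicate counts (after missingness) drive both the scaling and the df.
Features missing in either layer are absent from the result, and features
with zero variance in both groups are skipped.

A feature is *called* only when both comparisons against the reference
condition (CV vs EN and ENR vs EN) pass FDR < 0.05 (Benjamini-Hochberg)
and |fold change| > 3 with consistent direction — fold changes taken on
the condition-level ratio estimates.

**The global test.** Correlations are computed between matched-replicate
ratio profiles `log(p_i / m_i)` — one vector per biological replicate.
Profiles of distinct replicates share no measurements, so within-condition
and between-condition correlation groups are exchangeable under the null;
Fisher z-transformed correlations are compared by a two-sample t-test
(|r| = 1 is clipped at `atanh(1 - 1e-12)` with a warning). All-pairs
pairwise-ratio columns were rejected for this test: columns sharing a
replicate are intrinsically correlated, which puts the within-group mean
above the between-group mean under the null and destroys calibration
(measured: 100% rejection). With matched profiles the measured null
rejection is 1.5% at nominal 5%.

## 4. Differential machinery

`permutation_fdr_ttest()` uses the moderated statistic
`d = (mean_A - mean_B) / (se_Welch + s0)` with `s0 = 0.1` on log2 data (the
conventional stabilizer magnitude for this family of tests; configurable).
The null comes from distinct group-label assignments — all of them when
fewer than `n_perm` exist — excluding the observed assignment and its
mirror, which only reproduce the observed statistics. The q-value of a
feature is the mean permuted count of `|d|` at or above its own, divided by
the observed count, made non-increasing in `|d|` and capped at 1; with few
replicates this estimate is conservative, which the calibration tests
accept (the bound is one-sided).

Detection-limit imputation draws missing log intensities per sample from
`Normal(mean_obs - 1.8 sd_obs, (0.3 sd_obs)^2)` — the standard downshifted
Gaussian for values censored at the instrument's floor. It is meant for
hard-censored data; with soft censoring that leaves survivors far below
the limit, the observed 1st percentile can sit below the downshifted mean.
Imputation is for intensity-level differential testing only: spike-in rows
must never be imputed (imputed calibration points wreck the regressions),
and the quantification path simply propagates missingness.

`count_fold_changes()` normalizes by median-of-ratios size factors
(geometric-mean reference over zero-free features; checked against the
DESeq2 implementation in the suite) and reports
`log2((mean_A + prior) / (mean_B + prior))` with `prior = 4` — a
pseudocount approximation to variance-shrunken fold changes, documented as
an approximation rather than a clone of any particular estimator; the
prior-to-infinity limit collapses all fold changes to 0.

## 5. TAD-level coordination

Peaks are assigned to the TAD containing their midpoint; TADs with >= 20
assigned peaks are scored. Agreement = share of member peaks whose log2
fold-change sign equals the sign of the TAD's mean fold change, x100.
Zero fold changes count as disagreement (conservative), and a TAD whose
mean is exactly 0 is skipped. Because the reference sign is estimated from
the same member peaks, the *expected null agreement exceeds 50%* at small
peak counts; rather than correcting the statistic, the null is built by
shuffling fold-change values across all peaks genome-wide (TAD membership
fixed, 100 shuffles by default; a within-chromosome mode is available),
which reproduces the bias exactly and keeps the empirical FDR calibrated:
`FDR(t)` = mean null count of TADs at agreement >= t over the observed
count, the significance cutoff is the smallest observed agreement with
FDR <= 0.05, and per-TAD FDRs are monotonized.

## 6. Motif-driver selection

Candidate motifs must link to a TF whose protein changes at q < 0.01
(strict) in the contrast of interest — TFs absent from a deep proteome are
unlikely drivers. Scanning uses log2 odds against a uniform background
with pseudocount 1e-3, maximum over all offsets of both strands (the
reverse strand via the reverse-complemented score matrix; a C++ kernel
makes scanning 2,000 peaks x 50 motifs sub-second). Per-motif best scores
are min-max normalized to [0, 1] across peaks so motifs of different
lengths and information contents are comparable in one regression; raw
log-odds are kept alongside.

The response is the vector of normalized, shrunken log2 fold changes of
the significantly changing peaks (q < 0.05). A 10-fold cross-validated
LASSO at the minimum-CV-error penalty pre-selects motifs (minimum error
rather than the one-sd rule: the less aggressive filter, deferring pruning
to the forest stage). The iterative forest then repeats: fit a random
forest (out-of-bag permutation importance, reported as percent increase in
OOB MSE with its per-tree standard error); take the top motif; fit a
single-predictor forest of the current residual on that motif alone — its
out-of-bag R^2 operationalizes "variance explained by that single motif",
and if it is not positive the loop stops without selecting; otherwise
subtract the single model's out-of-bag predictions from the residual,
drop the motif, continue. The single-predictor forest uses
`nodesize = max(5, n/20)`: with default 5-observation leaves a 1-D forest
memorizes noise and its OOB R^2 collapses toward zero even when a fifth of
the variance is explainable, defeating the stopping rule. A singleton
candidate set is still evaluated — a LASSO that narrows to exactly one
motif is a decisive pre-selection, not a failure.

Stability: the whole chain runs five times with independent seeds
(re-randomizing both CV folds and forests); only motifs selected every
time are reported as final, with stability counts for everything ever
selected. Each selected motif is labelled with its most significant linked
TF (minimum q, ties to larger |log2FC|, then lexicographic) and annotated
with the Pearson correlation of its score with the response. Forest size
defaults to 5,000 trees for production analyses; the repeated simulation
studies in the test suite use 500 trees, which leaves the selection
unchanged in every seeded run while keeping 20 end-to-end repetitions
inside a coffee break.

Promoter scanning reports the fraction of genes whose TSS-anchored window
reaches a score threshold; the synthetic checks use the consensus score
minus 2 bits, which under the near-deterministic driver PWM detects
sampled instances with ~95% probability.

## 7. Preranked enrichment

Rankings are sorted metric-descending with ties broken by gene id. Hits
increment the running sum by `|metric|^p` (p = 1 by default; the classic
KS form is p = 0) normalized over hits; misses decrement by `1/(N - N_h)`;
the enrichment score is the extremum of the running sum, with exact ties
between the positive and negative excursion resolved to the positive one
under a 1e-12 tolerance (the permutation path computes the same extremum
from hit positions alone in O(k)). "Gene set permutation" means null sets
drawn uniformly from the ranked universe at matched size (10,000 by
default): NES divides by the mean |null ES| of matching sign, the nominal
p is add-one corrected, and FDR uses the standard pooled-null NES ratio,
capped at 1 and monotonized within sign.

## 8. Numerical conventions and degenerate inputs

Intervals are 0-based half-open throughout; fixed-width extension recenters
on `floor((start + end)/2)` and clamping truncates at chromosome bounds
rather than shifting. Nearest-TSS ties resolve to the smaller coordinate,
then the lexicographically smaller gene id; promoter-proximal means
strictly under 500 bp. Book-ended intervals merge in peak unions.
Sequences shorter than a motif score as missing; constant score columns
correlate as missing with a message; empty gene lists, all-zero count
samples and sub-minimum spike-in panels are rejected with informative
errors. All randomness is seeded; seeded paths restore the caller's RNG
state.

## 9. Problem sizes used by the test suite

Oracle checks: 200 random scan instances, exhaustive enrichment-score
enumeration for all lists with N <= 12 and up to 4 hits, 1,000
random peaks against brute-force nearest-TSS. Calibration: 200 null runs
(300 features each) for the permutation t-test, 10,000 null features for
the ratio test, 1,000 runs for the global translation test, 50 self-null
TAD runs, 20 x 50 null gene sets. Recovery: 3 seeded noisy studies (2,000
genes) for ratio-shift sensitivity; 20 end-to-end driver-recovery runs and
40 permuted-response runs at 2,000 peaks / 50 motifs / 500 trees; 20
planted-TAD runs at 201 TADs x 20 peaks. These sizes make the full suite
reproducible on a single CPU in well under half an hour.

## 10. Known limitations

The ratio test assumes log-scale noise roughly symmetric within replicate
groups; heavy-tailed contamination would call for a robust variant. The
pseudocount fold-change shrinkage is a deliberate approximation to
model-based shrinkage estimators. The TAD shuffle null treats peaks as
exchangeable genome-wide; strong chromosome-scale fold-change gradients
would argue for the within-chromosome mode. GSEA supports gene-set
permutation only — phenotype permutation needs more replicates than this
design has. The selection procedure assumes motif activity is monotone in
the best-match score; partially redundant motif pairs can split stability
votes, which is the intended behaviour of the always-selected rule.
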