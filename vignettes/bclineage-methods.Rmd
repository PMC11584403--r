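---
title: "Methods: subtype and lineage calling from multi-omic breast cancer data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subtype and lineage calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bclineage)
```

This vignette is the package's account of its science: the models and
procedures, the parameters that matter, what the synthetic generators do
and do not emulate, and the numerical and design choices made where the
underlying methodology left the behaviour open.

## The problem

Breast tumors are classified into intrinsic expression subtypes
(luminal A, luminal B, HER2-enriched, basal-like, normal-like). The
breast duct contains three benign epithelial populations — luminal
progenitor (LP), luminal mature (LM) and basal/myoepithelial (BP)
cells — and the prevailing lineage model places the origin of basal-like
tumors in LP cells and of luminal A/B tumors in LM cells. Testing that
model from multi-omic data requires a chain of bespoke computations:
subtype assignment robust to cohort composition, a comparable chromatin
atlas across samples, high-confidence variant sets, staged differential
filters that separate lineage signal from generic cancer signal, and
defined imaging quantifications. Each is implemented here as a pure,
tested function over plain data structures.

## Consensus subtyping

`classify_nearest_centroid()` assigns the subtype whose 50-gene centroid
has the highest Spearman correlation with a median-centered profile.
Spearman is the default because the distributed nearest-centroid
implementation ranks profiles before correlating, which also makes calls
invariant under any strictly monotone transform of the profile; Pearson
is available by flag. A constant profile has no rank structure and is
reported as unclassifiable (`NA`) rather than as an arbitrary argmax.

Median adjustment exists because centroid correlation is biased by cohort
composition: an ER+-dominated cohort shifts per-gene medians toward
luminal values. `bootstrap_consensus_subtype()` therefore repeats, per
iteration: take **all** ER− entities plus an equal-size uniform random
ER+ subset (without replacement), recompute panel medians over that
subset, center the full cohort, classify everyone. The final call is the
modal subtype across iterations with the vote fraction reported.
Decisions fixed here:

- **Tie-break**: ties in the vote are broken by the subtype's mean
  correlation rank across iterations, then alphabetically — fully
  deterministic.
- **Fixed-median mode**: the `medians` argument centers every iteration
  with a supplied vector instead of subset medians, reproducing
  pipelines that bootstrap a provided median table. Note that with
  subset-derived medians a cohort of identical profiles centers to the
  constant zero profile and is therefore unclassifiable by design.
- **Balanced cohorts**: when the ER+ and ER− counts are equal every
  iteration uses the full cohort, so the consensus provably equals the
  single-pass call — a property the tests assert.
- Missing panel genes are an error by default; `allow_missing = TRUE`
  imputes the supplied median, centering those genes to zero.

Cluster-level assignment (`cluster_level_subtype()`) averages panel genes
within each tumor-cell cluster and classifies each mean once, without
bootstrapping — single-nucleus data are too sparse per cell but a cluster
mean is a stable profile. Bulk input is normalized by
`fpkm_uq_normalize()` (`count · 1e9 / (U · L)`, `U` the sample's upper
quartile of nonzero protein-coding counts, then `log2(x+1)`).

## Quality filters

All printed thresholds are applied with strict inequalities exactly as
written: a cell fails when counts < 300, genes < 200 or > 10,000,
UMIs < 1,000 or > 10,000, or mitochondrial percentage > 10; a nucleus is
kept only when fragments-in-peaks lies strictly between 1,000 and
20,000, percent reads in peaks > 15, blacklist fraction < 0.05,
nucleosome signal < 10 and TSS enrichment > 2. Boundary behaviour (300
kept, 15 removed) is pinned by tests at every threshold ±1. Total counts
and UMIs are retained as separate criteria even though correlated,
favouring fidelity over parsimony.

## Peak atlas

Peaks are standardized by dropping chrY peaks and peaks overlapping any
assembly N-gap (represented as an interval list — the filter needs only
intervals, never sequence), then resized to 501 bp centered on the
summit (`[summit−250, summit+251)`). Resized peaks that would extend
past a chromosome end are dropped, not clipped: clipping would break the
fixed-width invariant that makes downstream count matrices comparable.

`iterative_overlap_removal()` retains the highest-scoring remaining peak
and deletes everything sharing ≥ 1 base with it, until exhaustion.
Overlap ignores strand (ATAC peaks are unstranded). Score ties break by
(chrom, start) so the result is deterministic and input-order invariant.
The implementation precomputes the overlap graph and sweeps in rank
order — provably equivalent to the literal delete-and-rescan loop, which
the test suite keeps as an independent quadratic oracle. One subtlety:
the natural-sounding claim "every retained peak outranks everything it
overlapped" is false in general (a peak removed by a strong winner may
overlap a later, weaker retained peak); the true greedy invariant — every
removed peak overlaps a retained peak of greater-or-equal rank — is what
the tests assert.

Cross-sample comparability comes from score-per-million:
`spm = score / Σ score · 1e6` within each sample, conserving exactly
1e6 per sample. The cohort set is the same removal procedure on the
pooled, SPM-ranked peaks, and the winning sample is recorded per
retained peak. Promoter annotation uses the strand-oriented window from
1,000 bp upstream to 100 bp downstream of each TSS.

## Variant consensus

Merging is keyed on (chrom, pos, ref, alt) after parsimony trimming
(shared suffix, then shared prefix with position adjustment). Full
left-alignment is not attempted because the reference sequence is not an
input of these operations; trimming alone already reconciles the caller
representations exercised here. Consensus depths are taken from the
supporting record with the highest tumor depth (germline: normal depth),
ties broken by caller name — a deterministic rule where the methodology
is silent. All filters are pure predicates and the tests reproduce them
with exhaustive truth-table grids at every threshold ±1.

The rescue criterion for cohort drivers absent from a sample's calls is
not printed anywhere; the default here is ≥ 2 alt reads and VAF ≥ 0.02,
matching the somatic normal-contamination bound while excluding
single-read artifacts, and it is configurable. Variants missing from the
readcount table are reported "unassessable", never silently rescued.

`loh_fisher()` tests tumor alt-fraction > normal alt-fraction via the
one-sided hypergeometric tail (through `fisher.test`; the tests compare
against the explicit `dhyper` sum to 1e-10) and adjusts by
Benjamini–Hochberg across exactly the variants passed in one call — the
adjustment family is the caller's choice, made explicit.

`map_variants_to_cells()` gives each UMI one vote: reads below the
mapping/base-quality floors (20/20) are excluded, intra-molecule
conflicts resolve by majority and exact ties discard the molecule.

## Lineage calling

The logistic-regression test is a likelihood-ratio test of a binomial
regression of group label on normalized expression (plus optional
covariates, e.g. the per-cell fraction of fragments in peaks for
accessibility, where the covariate-only null absorbs depth-driven
signal). Prefilters mirror the field's convention: minimum expressing
fraction, minimum |log2 FC| (`log2(mean(expm1 x)+1)` difference), and
for accessibility a minimum difference in expressing fractions
(`min.diff.pct`, read as the absolute difference). Adjustment is
Bonferroni over tested features.

The staged gene filter works on significant sets from defined
comparisons — G1 ({basal tumor, LP} vs other epithelial), G2 ({luminal
tumors, LM} vs rest), G3 ({LP, LM} vs rest; computed and exposed but
consumed by nothing, as defined), C1/C2 (tumor vs origin within each
lineage), A1 (each group one-vs-rest). The basal branch starts from G1,
removes C1 ∪ C2 and G2, requires A1 membership in the lineage and
absence from all other groups' A1 sets, then screens at pct.exp > 20 and
log2 FC > 1. The luminal branch is implemented symmetrically (start G2,
remove G1): the literal printed text would start from G1 and then remove
G1, yielding the empty set, which contradicts the existence of distinct
luminal output; `literal_luminal = TRUE` reproduces the literal text for
comparison. Because each branch requires membership in its own G set and
absence from the other's, the basal and luminal survivor sets are
disjoint on any input. Survivors are labeled progenitor-high, tumor-high
or shared from their A1 provenance. Note a consequence of removing C1/C2
wholesale: genes up in the tumor relative to its origin are excluded, so
survivors are progenitor-high or shared programs — the generator's
planted truth is defined accordingly.

The TF motif filter tests lineage (tumor + origin) against all other
epithelial groups by two-sided Wilcoxon with BH adjustment ("enriched"
additionally requires a positive mean difference, since enrichment is
directional); removes TFs enriched in **both** tumor-vs-origin
comparisons (cancer-generic, not lineage); and removes candidates
significantly enriched in any non-lineage group with mean score
difference ≥ 0.5. Subtype-specific TF sets additionally require a
positive RNA fold change for that subtype versus pooled others. One
honest caveat: with BH control at 0.05 a null TF enters a candidate set
with probability roughly `3α` per comparison, so exact set equality with
a planted truth cannot hold on ~95% of seeds for any effect size; the
tests therefore assert recovery and the exclusion rules on every seed
and bound the exact-equality rate loosely, while FDR behaviour itself is
covered by a dedicated null-calibration test.

The surface-marker screen applies two cohort criteria (higher than every
other cell type with all pairwise tests significant in ≥ 1 sample;
higher than combined non-tumor in ≥ 90% of samples and significant in
≥ 75%) and intersects with the union of supplied surface-annotation
lists — the three source databases are inputs, never fetched.

## CNV mapping and imaging

Gene/arm calls use the overlap-weighted mean ratio in linear space (the
upstream caller's 0.9/1.1 thresholds are linear; a flag enables log2
averaging). Calls are strict: a weighted ratio of exactly 1.1 is
neutral. Sample-adaptive bounds (`1 ± z·sd` of segment ratios) default
off because only the clamp rule is printed, not the z computation; when
enabled they are clamped so the neutral zone never narrows below
(0.9, 1.1).

`masked_mean_intensity()` crops to the first 1,250 image lines,
thresholds the mask channel at half its cropped mean (pixel ≥ threshold
is positive — the boundary is tested) and averages the target channel
over the mask; the threshold scales with the mask mean, so the result is
invariant to global rescaling of the mask channel. The epithelial region
mask thresholds each channel, unions them, smooths with an in-package
separable Gaussian (σ = 2, kernel truncated at 3σ, replicate edge
padding — stated explicitly so a per-pixel convolution oracle can check
it exactly), re-binarizes at 0.5, fills holes (EBImage) and labels
8-connected components (chosen because duct rings close diagonally).
Smoothing-plus-thresholding acts as a discrete curvature flow: each
application shaves roughly one rim pixel off a convex boundary, so
re-running the construction on its own output preserves the region
partition but not every rim pixel — exact idempotence is mathematically
unattainable and the tests assert the partition-stability property
instead. Per-marker positivity thresholds are inputs, set per image
upstream; no automatic thresholding is attempted.

## The synthetic generators

The generators define the study conditions under which every claim is
tested; they are first-class, tested code.

- `generate_expression_cohort()` draws negative-binomial counts with
  log-linear means (matching the sparsity and overdispersion of the real
  assays without modelling ambient RNA or doublets). Subtype programs
  are unit-scale Gaussian patterns over the 50-gene panel; `effect_size`
  scales how strongly the data follow them but not the emitted
  reference centroids, so a zero-effect cohort classifies at chance
  (~1/5) rather than degenerating. Benign cells share one panel pattern
  and are distinguished by planted marker programs (shared basal-lineage,
  shared luminal-lineage, LP-only, LM-only, BP-only, pan-tumor,
  HER2-only), so the subtyping panel cannot masquerade as lineage
  markers. ER status is deterministic given subtype (luminals and
  normal-like ER+, basal-like and HER2-enriched ER−) to keep planted
  truth exact; the real-world association is directional, not
  deterministic, but nothing downstream depends on ER noise.
- `generate_caller_calls()` emits each true variant per caller with that
  caller's sensitivity, Poisson false calls, Poisson depths and
  beta-binomial alt counts around the planted VAF (depth-dependent noise
  at filter boundaries). Matched normals are clean by default;
  `normal_contamination` probes the normal-VAF boundary.
- `generate_peak_sets()`, `generate_motif_matrix()` and
  `generate_image()` plant overlap structure/chrY/N-gap peaks, group
  shifts on Gaussian deviations, and well-separated duct rings with
  per-channel inside/outside intensities and recorded truth masks. Duct
  rings are rejection-sampled to stay ≥ 8 px apart so σ = 2 smoothing
  cannot bridge two ducts.

What passing tests show — and do not show. Recovery at
`effect_size = 5` demonstrates that the procedures are correct and
well-calibrated, not that real cohorts separate that cleanly: real data
add batch effects, ambient RNA, doublets, impure clusters and much
smaller effects. Oracle-equality tests (peak atlas, truth tables, closed
forms, per-pixel loops) are exact statements about the algorithms and
transfer directly; planted-recovery rates are statements about the
generator's conditions only.

## Problem sizes and determinism

Every generator and the bootstrap accept a seed and are bit-reproducible
under it (RNG state is saved and restored, so calls do not disturb the
caller's stream). The shipped analyses and checks use: 60-entity bulk
cohorts over 20 seeds with 50 bootstrap iterations (1,000 remains the
production default); 8-sample × 40-cell cohorts for the lineage
workflow; 50 instances of 1,000 peaks against the quadratic oracle; 200
random 2×2 tables for the LOH closed form; 50 null seeds (2,000 tests)
for FDR calibration; 96–256 px images. These sizes were chosen so each
property is measured with comfortable margins while the whole suite
remains quick to run end to end.

## Known limitations

- Indel keys are parsimony-trimmed but not left-aligned (no reference
  sequence in scope); callers emitting differently-anchored
  representations of the same indel in a homopolymer run would need
  upstream normalization.
- The logistic LRT is a plain binomial GLM; it mirrors the referenced
  test's structure but is not a line-for-line reimplementation of any
  external package.
- The cluster-level subtyper inherits whatever clustering it is given;
  no clustering, embedding, label transfer or deviation computation is
  performed here — those remain the domain of the established upstream
  tools, and their outputs are this package's inputs.
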