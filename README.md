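# bclineage

Multi-omic procedures for linking breast cancer subtypes to their putative
cells of origin in the breast duct. Breast tumors fall into intrinsic
expression subtypes (luminal A/B, HER2-enriched, basal-like, normal-like),
and converging evidence ties basal-like tumors to luminal progenitor (LP)
cells and luminal A/B tumors to luminal mature (LM) cells rather than to
basal/myoepithelial (BP) cells. Studying that lineage relationship from
bulk RNA, snRNA-seq, snATAC-seq, WES and multiplex imaging requires a set
of bespoke computational steps that are usually buried in analysis
scripts. This package implements those steps as tested, reusable
functions, together with synthetic-data generators that plant known truth
so every step is verifiable without access to restricted patient data.

What is implemented:

- **PAM50 subtyping**: nearest-centroid classification by Spearman
  correlation of median-centered 50-gene profiles, with the ER-balanced
  bootstrap consensus (every iteration takes all ER− samples plus an
  equal-size random ER+ subset, recomputes panel medians, classifies the
  whole cohort; the final call is the modal subtype), cluster-level
  assignment for single-nucleus data, and GDC-style FPKM-UQ normalization
  `x_g = c_g · 10^9 / (U · L_g)` followed by `log2(x + 1)`.
- **QC filters** for scRNA/snRNA cells (counts ≥ 300, 200 ≤ genes ≤
  10,000, 1,000 ≤ UMIs ≤ 10,000, mito ≤ 10%) and snATAC nuclei
  (1,000 < fragments in peaks < 20,000, % reads in peaks > 15, blacklist
  fraction < 0.05, nucleosome signal < 10, TSS enrichment > 2), every
  inequality strict as printed.
- **Peak atlas**: drop chrY and N-gap peaks, resize to 501 bp around the
  summit, iterative overlap removal by MACS score, score-per-million
  normalization `spm_i = score_i / Σ score · 10^6`, cohort merging ranked
  by SPM, and strand-aware promoter annotation (−1,000/+100 bp of TSS).
- **Variant consensus**: tumor-normal somatic merging (≥ 2 admissible
  callers of strelka/varscan/mutect/pindel, normal VAF ≤ 0.02, tumor
  VAF ≥ 0.05, depths ≥ 14/8, indel < 100 bp, exonic, dbSNP-not-COSMIC
  excluded), tumor-only filtering (≥ 20× coverage, > 3 alt reads,
  VAF ≥ 0.1, panel-of-normals removal), driver rescue from readcounts,
  germline consensus (SNVs: gatk ∪ varscan; indels: pindel or ≥ 2 of 3),
  CharGer-score pathogenicity tiers behind a rare-AF gate (gnomAD
  ≤ 0.05%), the one-sided Fisher loss-of-heterozygosity test with BH
  adjustment, and barcode/UMI-resolved allele counting per cell.
- **Lineage calling**: Wilcoxon and logistic-regression LRT differential
  tests (Bonferroni-adjusted, Seurat-style prefilters), the staged
  G/C/A set-algebra filter that yields basal- and luminal-lineage gene
  lists, the TF motif filter (lineage-vs-rest at FDR 0.05, exclusion of
  TFs enriched in both tumor-vs-origin comparisons, exclusion of
  candidates enriched ≥ 0.5 in a non-lineage group), and the two-criterion
  tumor cell-surface marker screen (higher than every cell type in ≥ 1
  sample; higher than combined non-tumor in ≥ 90% of samples, significant
  in ≥ 75%).
- **CNV gene mapping**: overlap-weighted copy ratios
  `w = Σ r_i·o_i / Σ o_i` with amplified/neutral/deleted calls against the
  (0.9, 1.1) neutral zone.
- **Imaging**: masked mean intensity (first 1,250 image lines, mask at
  half the E-cadherin mean), epithelial region masks (threshold → union →
  Gaussian σ = 2 → fill holes → 8-connected labeling) and per-region
  positive-cell fractions averaged per sample.

The repository is organised as an analysis workflow: the package in `R/`
holds every computation; `analysis/01…06_*.R` are thin narrative drivers
that generate synthetic data, run each stage and write tables under
`results/`.

## Worked example

```r
library(bclineage)

co <- generate_expression_cohort(cohort_spec(
  60, c(LumA = 12, LumB = 12, Her2 = 12, Basal = 12, Normal = 12),
  n_genes = 60, effect_size = 5, noise_dispersion = 0.2, seed = 20260928))
er  <- setNames(co$entities$er_status, co$entities$entity)
res <- bootstrap_consensus_subtype(co$logexpr, er, co$ref,
                                   n_iter = 200, seed = 20260938)
mean(res$final == co$truth$entity_subtype[res$entity])
#> [1] 1
head(res, 3)
#>   entity  final vote_fraction
#> 1   S001   Her2             1
#> 2   S002 Normal             1
#> 3   S003   LumB             1
```

Each entity's `final` call is the modal subtype over 200 ER-balanced
bootstrap iterations and `vote_fraction` the share of iterations agreeing
with it; on this strongly separated synthetic cohort all 60 planted
subtypes are recovered unanimously. Running
`Rscript analysis/04_variant_consensus.R` prints, among others:

```
germline tiers: pathogenic, prioritized_VUS
LOH FDR: 9.61e-06 (shifted) vs 0.999 (balanced)
```

i.e. the variant with tumor alt fraction 61/70 against a balanced normal
(23/48) shows significant loss of heterozygosity, while the variant whose
tumor fraction matches its normal does not.

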