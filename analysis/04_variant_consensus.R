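#!/usr/bin/env Rscript
# Multi-caller somatic consensus, germline filtering with pathogenicity
# tiers, the loss-of-heterozygosity Fisher test and barcode-resolved
# variant-to-cell mapping on the bundled tagged-read fixture.

suppressMessages(library(bclineage))
dir.create("results", recursive = TRUE, showWarnings = FALSE)
seed <- 20260928L

tv <- data.frame(chrom = "chr17", pos = c(43045712, 43057062, 43091434),
                 ref = c("A", "C", "GTT"), alt = c("T", "G", "G"),
                 vaf = c(0.35, 0.42, 0.28))
cp <- data.frame(caller = c("strelka", "varscan", "mutect", "pindel"),
                 sensitivity = c(0.95, 0.9, 0.92, 0.85), false_rate = 2)
calls <- generate_caller_calls(tv, cp, seed = seed + 2)
cons <- merge_somatic_calls(calls)
write.table(cons, "results/somatic_consensus.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
recovered <- sum(paste(cons$chrom, cons$pos, cons$ref, cons$alt,
                       sep = ":") %in% attr(calls, "truth")$key)
cat(sprintf("somatic consensus: %d calls, %d/%d planted recovered\n",
            nrow(cons), recovered, nrow(tv)))

# germline candidates around a BRCA2-like locus with LOH in the tumor
germ <- data.frame(chrom = "chr13",
                   pos = c(32315508, 32340301),
                   ref = "G", alt = c("A", "T"),
                   caller = "gatk",
                   normal_depth = c(48, 52), normal_alt = c(23, 25),
                   normal_vaf = c(23 / 48, 25 / 52),
                   tumor_alt = c(61, 12))
kept <- merge_germline_calls(germ)
tiers <- classify_pathogenicity(cbind(
  kept[c("chrom", "pos", "ref", "alt")],
  gnomad_af = c(1e-5, NA), clinvar = c("pathogenic", NA),
  charger_score = c(10, 6),
  tumor_alt = c(61, 12), tumor_vaf = c(61 / 70, 12 / 55),
  normal_alt = c(23, 25), normal_vaf = c(23 / 48, 25 / 52)))
loh <- loh_fisher(data.frame(tumor_alt = c(61, 12), tumor_ref = c(9, 43),
                             normal_alt = c(23, 25),
                             normal_ref = c(25, 27)))
out <- cbind(tiers[c("chrom", "pos", "ref", "alt", "tier")],
             loh[c("p", "fdr", "significant")])
write.table(out, "results/germline_tiers_loh.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("germline tiers:", paste(out$tier, collapse = ", "), "\n")
cat(sprintf("LOH FDR: %.3g (shifted) vs %.3g (balanced)\n",
            out$fdr[1], out$fdr[2]))

al <- read_tagged_alignments(system.file(
  "extdata", "synthetic_tagged_reads.sam", package = "bclineage"))
cellcounts <- map_variants_to_cells(
  al, data.frame(chrom = "chr1", pos = 105, ref = "A", alt = "T"))
write.table(cellcounts, "results/cell_allele_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("cell-level allele counts:\n")
print(cellcounts)
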