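#!/usr/bin/env Rscript
# Generates the synthetic study inputs: a subtype-structured bulk-like
# cohort for subtyping, a cell-level cohort with planted lineage
# programs, multi-caller variant calls, per-sample peak sets, a motif
# deviation matrix and a duct image. Writes plain-text copies of the
# main tables under results/.

suppressMessages(library(bclineage))
dir.create("results", recursive = TRUE, showWarnings = FALSE)
seed <- 20260928L

bulk <- generate_expression_cohort(cohort_spec(
  60, c(LumA = 12, LumB = 12, Her2 = 12, Basal = 12, Normal = 12),
  n_genes = 60, effect_size = 5, noise_dispersion = 0.2, seed = seed))
write.table(data.frame(entity = bulk$entities$entity,
                       subtype = bulk$truth$entity_subtype,
                       er = bulk$entities$er_status),
            "results/cohort_truth.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("bulk cohort:", ncol(bulk$counts), "entities,",
    nrow(bulk$counts), "genes\n")

cells <- generate_expression_cohort(cohort_spec(
  8, c(LumA = 2, LumB = 2, Her2 = 2, Basal = 2), cells_per_sample = 40,
  n_genes = 120, effect_size = 4, noise_dispersion = 0.2, seed = seed + 1))
cat("cell cohort:", ncol(cells$counts), "cells;",
    length(cells$truth$lineage_genes$basal), "planted basal and",
    length(cells$truth$lineage_genes$luminal), "planted luminal genes\n")

tv <- data.frame(chrom = "chr17", pos = c(43045712, 43057062, 43091434),
                 ref = c("A", "C", "GTT"), alt = c("T", "G", "G"),
                 vaf = c(0.35, 0.42, 0.28))
cp <- data.frame(caller = c("strelka", "varscan", "mutect", "pindel"),
                 sensitivity = c(0.95, 0.9, 0.92, 0.85), false_rate = 2)
calls <- generate_caller_calls(tv, cp, seed = seed + 2)
write.table(calls, "results/caller_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("variant calls:", nrow(calls), "records from 4 callers\n")

gl <- c(chr1 = 2e6, chr2 = 1.5e6, chrY = 5e5)
gaps <- data.frame(chrom = "chr1", start = 9e5, end = 9.2e5)
peaks <- generate_peak_sets(3, 800, gl, seed = seed + 3,
                            overlap_fraction = 0.25, chry_fraction = 0.03,
                            n_gaps = gaps, gap_fraction = 0.02)
write_peaks_bed(do.call(rbind, peaks), "results/sample_peaks.bed")
cat("peaks:", sum(vapply(peaks, nrow, 1L)), "across 3 samples\n")

img <- generate_image(shape = c(256, 256), n_ducts = 3, noise_sd = 3,
                      seed = seed + 4)
write_image_tiff(img$channels, "results/synthetic_ducts.tiff")
cat("image: 256x256,", max(img$truth_labels), "ducts\n")
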