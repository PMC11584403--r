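#!/usr/bin/env Rscript
# Staged lineage calling: differential-expression set algebra for
# basal/luminal lineage genes, the TF motif filter with its shared- and
# non-lineage exclusions, and the tumor cell-surface marker screen.

suppressMessages(library(bclineage))
dir.create("results", recursive = TRUE, showWarnings = FALSE)
seed <- 20260928L

cells <- generate_expression_cohort(cohort_spec(
  8, c(LumA = 2, LumB = 2, Her2 = 2, Basal = 2), cells_per_sample = 40,
  n_genes = 120, effect_size = 4, noise_dispersion = 0.2, seed = seed + 1))
wf <- suppressWarnings(run_lineage_deg_workflow(
  log1p(cells$counts), setNames(cells$entities$group,
                                cells$entities$entity),
  exclude_genes = cells$ref$genes))
for (ln in c("basal", "luminal")) {
  planted <- cells$truth$lineage_genes[[ln]]
  cat(sprintf("%s lineage: %d genes (%d/%d planted recovered)\n", ln,
              nrow(wf[[ln]]), length(intersect(wf[[ln]]$gene, planted)),
              length(planted)))
}
write.table(rbind(cbind(lineage = "basal", wf$basal),
                  cbind(lineage = "luminal", wf$luminal)),
            "results/lineage_genes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

groups <- c(tumor_Basal = 60, tumor_Her2 = 60, tumor_Luminal = 60,
            LM = 60, LP = 60, BP = 60)
shifts <- rbind(
  data.frame(tf = "tfKLF5", group = c("tumor_Basal", "LP"), shift = 2),
  data.frame(tf = "tfBHLHE40", group = c("tumor_Luminal", "LM"),
             shift = 2),
  data.frame(tf = "tfSHARED", group = c("tumor_Basal", "tumor_Luminal"),
             shift = 2))
mm <- generate_motif_matrix(groups, shifts, n_tfs = 30, sd = 1,
                            seed = seed + 5)
tfres <- lineage_motif_filter(mm$scores, mm$cell_groups)
cat("basal-lineage TFs:", paste(tfres$basal, collapse = ", "), "\n")
cat("luminal-lineage TFs:", paste(tfres$luminal, collapse = ", "), "\n")
writeLines(c(paste("basal:", paste(tfres$basal, collapse = ",")),
             paste("luminal:", paste(tfres$luminal, collapse = ","))),
           "results/lineage_tfs.txt")

# cell-surface marker screen on per-sample summaries built from the
# cell cohort: tumor vs each cell type and vs combined non-tumor
expr <- log1p(cells$counts)
ann <- cells$entities
per_sample <- lapply(split(ann, ann$sample), function(s) {
  tum <- s$entity[s$cell_type == "tumor"]
  oth <- s$entity[s$cell_type != "tumor"]
  types <- unique(s$cell_type[s$cell_type != "tumor"])
  pw <- do.call(rbind, lapply(types, function(tp) {
    d <- suppressWarnings(differential_expression(
      expr, tum, s$entity[s$cell_type == tp], test = "wilcoxon",
      min_pct = 0, logfc_threshold = 0, only_pos = FALSE))
    cbind(d[c("gene", "avg_log2fc", "padj")], other_type = tp)
  }))
  cb <- suppressWarnings(differential_expression(
    expr, tum, oth, test = "wilcoxon", min_pct = 0, logfc_threshold = 0,
    only_pos = FALSE))
  list(pairwise = pw, combined = cb[c("gene", "avg_log2fc", "padj")])
})
surface <- union(cells$truth$marker_programs$tumor_shared,
                 cells$truth$marker_programs$her2_only)
markers <- surface_marker_call(per_sample, surface_genes = surface)
cat("tumor surface markers:", paste(markers$gene, collapse = ", "), "\n")
write.table(markers, "results/surface_markers.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
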