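# Small fixture builders shared by the unit tests.

make_peaks <- function(chrom, start, end, score, sample = "S1",
                       summit = NULL) {
  if (is.null(summit)) summit <- floor((start + end) / 2)
  data.frame(chrom = chrom, start = start, end = end, summit = summit,
             score = score, sample = sample, stringsAsFactors = FALSE)
}

random_peaks <- function(n, seed, chroms = c("chr1", "chr2"),
                         span = 50000L, width_range = c(100L, 800L)) {
  set.seed(seed)
  start <- sample.int(span, n, replace = TRUE)
  w <- sample(width_range[1]:width_range[2], n, replace = TRUE)
  make_peaks(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + w,
             score = stats::runif(n, 1, 100),
             sample = sample(c("S1", "S2"), n, replace = TRUE))
}

somatic_record <- function(chrom = "chr1", pos = 100, ref = "A", alt = "T",
                           caller = "strelka", tumor_depth = 50,
                           tumor_vaf = 0.3, normal_depth = 30,
                           normal_vaf = 0, exonic = TRUE, in_dbsnp = FALSE,
                           in_cosmic = FALSE) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             caller = caller, tumor_depth = tumor_depth,
             tumor_alt = round(tumor_vaf * tumor_depth),
             normal_depth = normal_depth,
             normal_alt = round(normal_vaf * normal_depth),
             tumor_vaf = tumor_vaf, normal_vaf = normal_vaf,
             exonic = exonic, in_dbsnp = in_dbsnp, in_cosmic = in_cosmic,
             stringsAsFactors = FALSE)
}

germline_record <- function(chrom = "chr1", pos = 100, ref = "A", alt = "T",
                            caller = "gatk", normal_depth = 40,
                            normal_vaf = 0.5, tumor_alt = 10) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             caller = caller, normal_depth = normal_depth,
             normal_alt = round(normal_vaf * normal_depth),
             normal_vaf = normal_vaf, tumor_alt = tumor_alt,
             stringsAsFactors = FALSE)
}

# A small lineage cohort with planted programs, used by several tests.
lineage_cohort <- function(seed, cells_per_sample = 40L, effect = 4) {
  spec <- cohort_spec(8, c(LumA = 2, LumB = 2, Her2 = 2, Basal = 2),
                      cells_per_sample = cells_per_sample, n_genes = 120,
                      effect_size = effect, noise_dispersion = 0.2,
                      seed = seed)
  generate_expression_cohort(spec)
}

# Motif fixtures. The full fixture adds boundary cases around the 0.5
# non-lineage exclusion rule (shifts chosen so the single-group mean
# differences land at 0.6 / 0.4: with six equal groups, BP vs rest has
# diff b - 2s/5 for lineage shift s); those are only meaningful at low
# dispersion, so the recovery sweep uses the clean fixture.
motif_groups <- function(n_cells) {
  c(tumor_Basal = n_cells, tumor_Her2 = n_cells, tumor_Luminal = n_cells,
    LM = n_cells, LP = n_cells, BP = n_cells)
}

motif_fixture <- function(seed, n_cells = 60L, sd = 0.05, n_tfs = 30L) {
  shifts <- rbind(
    data.frame(tf = "tfBAS", group = c("tumor_Basal", "LP"), shift = 2),
    data.frame(tf = "tfLUM", group = c("tumor_Luminal", "LM"), shift = 2),
    data.frame(tf = "tfBOTH", group = c("tumor_Basal", "tumor_Luminal"),
               shift = 2),
    data.frame(tf = "tfBP06", group = c("tumor_Basal", "LP"), shift = 0.5),
    data.frame(tf = "tfBP06", group = "BP", shift = 0.8),
    data.frame(tf = "tfBP04", group = c("tumor_Basal", "LP"), shift = 0.5),
    data.frame(tf = "tfBP04", group = "BP", shift = 0.6))
  generate_motif_matrix(motif_groups(n_cells), shifts, n_tfs = n_tfs,
                        sd = sd, seed = seed)
}

motif_recovery_fixture <- function(seed, n_cells = 60L, n_tfs = 30L) {
  shifts <- rbind(
    data.frame(tf = "tfBAS", group = c("tumor_Basal", "LP"), shift = 2),
    data.frame(tf = "tfLUM", group = c("tumor_Luminal", "LM"), shift = 2),
    data.frame(tf = "tfBOTH", group = c("tumor_Basal", "tumor_Luminal"),
               shift = 2))
  generate_motif_matrix(motif_groups(n_cells), shifts, n_tfs = n_tfs,
                        sd = 1, seed = seed)
}
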