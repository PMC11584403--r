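# Per-cell / per-nucleus quality filters.
#
# Every inequality is applied strictly as printed in the filter definitions:
# a cell fails when total_counts < 300, genes_detected < 200 or > 10000,
# umis < 1000 or > 10000, pct_mito > 10; a nucleus is kept only when
# fragments_in_peaks > 1000 and < 20000, pct_reads_in_peaks > 15,
# blacklist_fraction < 0.05, nucleosome_signal < 10, tss_enrichment > 2.
# Boundary values therefore behave deterministically (300 passes, 15 fails).

qc_check_metrics <- function(df, cols) {
  need_cols(df, c("barcode", cols), "QC table")
  for (cn in cols) {
    bad <- which(is.na(df[[cn]]))
    if (length(bad) > 0) {
      stop(sprintf("missing metric '%s' for barcode %s", cn,
                   df$barcode[bad[1]]), call. = FALSE)
    }
  }
  invisible(df)
}

qc_apply <- function(df, criteria) {
  per <- vapply(criteria, function(f) f(df), logical(nrow(df)))
  if (nrow(df) == 1L) per <- matrix(per, nrow = 1L,
                                    dimnames = list(NULL, names(criteria)))
  keep <- rowSums(!per) == 0L
  removed <- colSums(!per)
  structure(keep, removal_counts = removed, names = df$barcode)
}

#' Per-cell RNA quality filter
#'
#' @param cells data.frame with columns `barcode`, `total_counts`,
#'   `genes_detected`, `umis`, `pct_mito` (percent, 0-100).
#' @param thresholds Named list overriding the defaults
#'   `list(min_total = 300, min_genes = 200, max_genes = 10000,
#'   min_umis = 1000, max_umis = 10000, max_pct_mito = 10)`.
#'
#' @return Named logical keep mask (TRUE = keep) with attribute
#'   `removal_counts` giving per-criterion removal counts.
#' @export
rna_cell_qc <- function(cells, thresholds = list()) {
  th <- utils::modifyList(list(min_total = 300, min_genes = 200,
                               max_genes = 10000, min_umis = 1000,
                               max_umis = 10000, max_pct_mito = 10),
                          thresholds)
  qc_check_metrics(cells, c("total_counts", "genes_detected", "umis",
                            "pct_mito"))
  check(all(cells$pct_mito >= 0 & cells$pct_mito <= 100),
        "pct_mito must lie in [0, 100]")
  qc_apply(cells, list(
    total_counts   = function(d) !(d$total_counts < th$min_total),
    min_genes      = function(d) !(d$genes_detected < th$min_genes),
    max_genes      = function(d) !(d$genes_detected > th$max_genes),
    min_umis       = function(d) !(d$umis < th$min_umis),
    max_umis       = function(d) !(d$umis > th$max_umis),
    pct_mito       = function(d) !(d$pct_mito > th$max_pct_mito)
  ))
}

#' Per-nucleus ATAC quality filter
#'
#' @param nuclei data.frame with columns `barcode`, `fragments_in_peaks`,
#'   `pct_reads_in_peaks` (percent), `blacklist_fraction`,
#'   `nucleosome_signal`, `tss_enrichment`.
#' @param thresholds Named list overriding
#'   `list(min_fragments = 1000, max_fragments = 20000, min_pct_in_peaks =
#'   15, max_blacklist = 0.05, max_nucleosome = 10, min_tss = 2)`.
#'
#' @return Named logical keep mask with attribute `removal_counts`.
#' @export
atac_nucleus_qc <- function(nuclei, thresholds = list()) {
  th <- utils::modifyList(list(min_fragments = 1000, max_fragments = 20000,
                               min_pct_in_peaks = 15, max_blacklist = 0.05,
                               max_nucleosome = 10, min_tss = 2),
                          thresholds)
  qc_check_metrics(nuclei, c("fragments_in_peaks", "pct_reads_in_peaks",
                             "blacklist_fraction", "nucleosome_signal",
                             "tss_enrichment"))
  check(all(nuclei$blacklist_fraction >= 0 & nuclei$blacklist_fraction <= 1),
        "blacklist_fraction must lie in [0, 1]")
  qc_apply(nuclei, list(
    min_fragments = function(d) d$fragments_in_peaks > th$min_fragments,
    max_fragments = function(d) d$fragments_in_peaks < th$max_fragments,
    pct_in_peaks  = function(d) d$pct_reads_in_peaks > th$min_pct_in_peaks,
    blacklist     = function(d) d$blacklist_fraction < th$max_blacklist,
    nucleosome    = function(d) d$nucleosome_signal < th$max_nucleosome,
    tss           = function(d) d$tss_enrichment > th$min_tss
  ))
}
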