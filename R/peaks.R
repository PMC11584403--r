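# snATAC peak-atlas construction.
#
# Peak tables are data.frames with 0-based half-open `start`/`end`,
# an absolute `summit` position (start <= summit < end), a MACS-style
# significance `score` (-log10 q), a `sample` id and, after normalization,
# a score-per-million `spm`. Overlap means >= 1 shared base on the same
# chromosome; strand is ignored.

validate_peaks <- function(peaks, summit = TRUE) {
  need_cols(peaks, c("chrom", "start", "end", "score", "sample"), "peak table")
  check(all(peaks$start < peaks$end), "peak start must be < end")
  if (summit) {
    need_cols(peaks, "summit", "peak table")
    bad <- which(peaks$summit < peaks$start | peaks$summit >= peaks$end)
    check(length(bad) == 0L,
          "summit outside peak interval at row %s", toString(utils::head(bad, 3)))
  }
  check(all(peaks$score >= 0), "scores must be nonnegative")
  invisible(peaks)
}

#' Standardize per-sample peak calls
#'
#' Drops Y-chromosome peaks and peaks overlapping assembly N-gaps, then
#' resizes every remaining peak to 501 bp centered on its summit
#' (`[summit - 250, summit + 251)`). Resized peaks extending past a
#' chromosome end are dropped (clipping would break the fixed-width
#' invariant).
#'
#' @param peaks Peak data.frame (see above).
#' @param genome_lengths Named numeric vector chromosome -> length.
#' @param n_gaps Optional data.frame of N-gap intervals (`chrom`, `start`,
#'   `end`, 0-based half-open).
#'
#' @return Standardized peak data.frame (all widths 501).
#' @export
standardize_peaks <- function(peaks, genome_lengths, n_gaps = NULL) {
  validate_peaks(peaks)
  check(all(peaks$chrom %in% names(genome_lengths)),
        "genome_lengths must cover every chromosome present")
  keep <- !(peaks$chrom %in% c("chrY", "Y"))
  if (!is.null(n_gaps) && nrow(n_gaps) > 0) {
    hits <- GenomicRanges::findOverlaps(granges_from_bed(peaks),
                                        granges_from_bed(n_gaps))
    keep[unique(S4Vectors::queryHits(hits))] <- FALSE
  }
  out <- peaks[keep, , drop = FALSE]
  out$start <- out$summit - 250L
  out$end <- out$summit + 251L
  inb <- out$start >= 0L & out$end <= genome_lengths[out$chrom]
  out <- out[inb, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Iterative overlap removal
#'
#' Repeatedly retains the highest-ranking remaining peak and deletes every
#' remaining peak sharing >= 1 base with it, until no peaks remain. Rank
#' ties are broken by (chrom, start) lexicographic order, so the retained
#' set is deterministic and invariant to input order.
#'
#' @param peaks Peak data.frame.
#' @param rank_by Column used as the significance ranking ("score" for
#'   sample-level sets, "spm" for cohort merging).
#'
#' @return The pairwise non-overlapping retained peaks in genomic order.
#' @export
iterative_overlap_removal <- function(peaks, rank_by = "score") {
  validate_peaks(peaks, summit = FALSE)
  need_cols(peaks, rank_by, "peak table")
  n <- nrow(peaks)
  if (n == 0L) return(peaks)
  ord <- order(-peaks[[rank_by]], peaks$chrom, peaks$start)
  gr <- granges_from_bed(peaks)
  hits <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  nb <- split(s[q != s], q[q != s])
  alive <- rep(TRUE, n)
  kept <- logical(n)
  for (i in ord) {
    if (!alive[i]) next
    kept[i] <- TRUE
    alive[i] <- FALSE
    ov <- nb[[as.character(i)]]
    if (!is.null(ov)) alive[ov] <- FALSE
  }
  out <- peaks[kept, , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  stopifnot(!peaks_self_overlap(out))
  out
}

# TRUE if any two peaks in the table share a base (same chromosome).
peaks_self_overlap <- function(peaks) {
  if (nrow(peaks) < 2L) return(FALSE)
  gr <- granges_from_bed(peaks)
  hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                      drop.redundant = TRUE)
  length(hits) > 0L
}

#' Score-per-million normalization
#'
#' Within each sample, `spm_i = score_i / sum_j score_j * 1e6`, making peak
#' significance comparable across samples of different depth.
#'
#' @param peaks Peak data.frame (possibly several samples).
#' @return The table with an `spm` column added.
#' @export
score_per_million <- function(peaks) {
  validate_peaks(peaks, summit = FALSE)
  totals <- tapply(peaks$score, peaks$sample, sum)
  zero <- names(totals)[totals == 0]
  check(length(zero) == 0L, "all-zero peak scores in sample %s",
        paste(zero, collapse = ", "))
  peaks$spm <- peaks$score / as.numeric(totals[as.character(peaks$sample)]) * 1e6
  peaks
}

#' Build the cohort-level peak set
#'
#' Pools standardized, score-per-million-normalized peaks from all samples
#' and runs [iterative_overlap_removal()] ranking by `spm`; the retained
#' record's `sample` column records which sample won each locus.
#'
#' @param peaks Either one pooled data.frame or a list of per-sample
#'   data.frames, each already standardized and carrying `spm`.
#' @return Non-overlapping cohort peak data.frame.
#' @export
build_cohort_peakset <- function(peaks) {
  if (is.data.frame(peaks)) pooled <- peaks else pooled <- do.call(rbind, peaks)
  need_cols(pooled, "spm", "pooled peak table")
  iterative_overlap_removal(pooled, rank_by = "spm")
}

#' Annotate peaks as promoter or distal
#'
#' A peak is a promoter peak for gene g when it overlaps the
#' strand-oriented window from 1,000 bp upstream to 100 bp downstream of
#' g's TSS. All gene hits are reported.
#'
#' @param peaks Peak data.frame.
#' @param tss data.frame with columns `gene`, `chrom`, `tss` (1-based
#'   position), `strand` ("+"/"-").
#'
#' @return List with `peaks` (input plus `annotation` column) and `hits`
#'   (data.frame `peak`, `gene` for every promoter overlap; `peak` is the
#'   row index into `peaks`).
#' @export
annotate_peak_promoters <- function(peaks, tss) {
  validate_peaks(peaks, summit = FALSE)
  need_cols(tss, c("gene", "chrom", "tss", "strand"), "TSS table")
  check(all(tss$strand %in% c("+", "-")), "strand must be '+' or '-'")
  win_start <- ifelse(tss$strand == "+", tss$tss - 1000L, tss$tss - 100L)
  win_end <- ifelse(tss$strand == "+", tss$tss + 100L, tss$tss + 1000L)
  wins <- GenomicRanges::GRanges(tss$chrom,
                                 IRanges::IRanges(win_start, win_end))
  hits <- GenomicRanges::findOverlaps(granges_from_bed(peaks), wins)
  hit_df <- data.frame(peak = S4Vectors::queryHits(hits),
                       gene = tss$gene[S4Vectors::subjectHits(hits)],
                       stringsAsFactors = FALSE)
  peaks$annotation <- ifelse(seq_len(nrow(peaks)) %in% hit_df$peak,
                             "promoter", "distal")
  list(peaks = peaks, hits = hit_df)
}

#' Read / write peak tables as BED6+2
#'
#' Columns: chrom, start, end, name, score, strand, summit, sample. The
#' summit is stored as an absolute position; strand is written as ".".
#'
#' @param peaks Peak data.frame.
#' @param path File path.
#' @return `read_peaks_bed` returns a peak data.frame.
#' @export
write_peaks_bed <- function(peaks, path) {
  validate_peaks(peaks)
  bed <- data.frame(chrom = peaks$chrom, start = peaks$start,
                    end = peaks$end,
                    name = sprintf("peak_%d", seq_len(nrow(peaks))),
                    score = peaks$score, strand = ".",
                    summit = peaks$summit, sample = peaks$sample)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_peaks_bed
#' @export
read_peaks_bed <- function(path) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  check(ncol(bed) >= 8, "expected BED6+2 with summit and sample columns")
  data.frame(chrom = bed[[1]], start = bed[[2]], end = bed[[3]],
             score = bed[[5]], summit = bed[[7]], sample = bed[[8]],
             stringsAsFactors = FALSE)
}
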