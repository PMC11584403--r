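# Multi-caller variant consensus, pathogenicity tiers, LOH testing and
# barcode-resolved variant-to-cell mapping.
#
# Variant tables are data.frames keyed by (chrom, pos, ref, alt) with
# 1-based positions (VCF convention). Interval inputs (coding regions,
# BED) are 0-based half-open; conversions are centralized in
# granges_from_bed().

SOMATIC_CALLERS <- c("strelka", "varscan", "mutect", "pindel")
GERMLINE_CALLERS <- c("gatk", "varscan", "pindel")

# Parsimony-trim shared suffix then shared prefix of ref/alt, adjusting
# pos for removed prefix bases. Caller representations of the same indel
# then merge to one key. (Left alignment against the reference sequence is
# out of scope: the reference is not an input here.)
normalize_alleles <- function(chrom, pos, ref, alt) {
  pos <- as.integer(pos)
  for (i in seq_along(ref)) {
    r <- ref[i]; a <- alt[i]
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1L, nchar(r) - 1L)
      a <- substr(a, 1L, nchar(a) - 1L)
    }
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      r <- substr(r, 2L, nchar(r))
      a <- substr(a, 2L, nchar(a))
      pos[i] <- pos[i] + 1L
    }
    ref[i] <- r; alt[i] <- a
  }
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

variant_key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")

indel_length <- function(ref, alt) abs(nchar(ref) - nchar(alt))

variant_type <- function(ref, alt) {
  ifelse(nchar(ref) == nchar(alt) & nchar(ref) == 1L, "SNV", "indel")
}

# Pick the supporting record with the highest depth in `depth_col`
# (ties: caller name order) as the consensus representative.
representative <- function(records, depth_col) {
  records[order(-records[[depth_col]], records$caller), , drop = FALSE][1, ,
                                                                        drop = FALSE]
}

#' Merge and filter tumor-normal somatic calls from multiple callers
#'
#' SNVs are admissible from strelka, varscan and mutect; indels from
#' strelka, varscan and pindel. A variant (keyed chrom:pos:ref:alt after
#' parsimony trimming) is kept iff it is supported by at least two
#' admissible callers, has normal VAF <= 0.02 and tumor VAF >= 0.05,
#' tumor depth >= 14 and normal depth >= 8, indel length < 100 bp, is
#' exonic and is not in dbSNP without also being in COSMIC. Consensus
#' depths come from the supporting record with the highest tumor depth.
#'
#' @param calls data.frame of caller records: `chrom`, `pos`, `ref`,
#'   `alt`, `caller`, `tumor_depth`, `tumor_alt`, `normal_depth`,
#'   `normal_alt`, `tumor_vaf`, `normal_vaf`, `exonic`, `in_dbsnp`,
#'   `in_cosmic`.
#' @param audit Also return the per-clause pass table for every candidate
#'   key as attribute `audit`.
#'
#' @return Consensus data.frame of surviving variants with `callers`
#'   (comma-joined supporting set) and `n_callers`.
#' @export
merge_somatic_calls <- function(calls, audit = FALSE) {
  need_cols(calls, c("chrom", "pos", "ref", "alt", "caller", "tumor_depth",
                     "tumor_alt", "normal_depth", "normal_alt", "tumor_vaf",
                     "normal_vaf", "exonic", "in_dbsnp", "in_cosmic"),
            "somatic calls")
  bad <- setdiff(unique(calls$caller), SOMATIC_CALLERS)
  check(length(bad) == 0L, "unknown caller id(s): %s",
        paste(bad, collapse = ", "))
  if (nrow(calls) == 0L) return(calls)
  norm <- normalize_alleles(calls$chrom, calls$pos, calls$ref, calls$alt)
  calls[c("chrom", "pos", "ref", "alt")] <- norm
  calls$type <- variant_type(calls$ref, calls$alt)
  key <- variant_key(calls)

  # same locus + alt with conflicting ref across callers is unresolvable
  locus <- paste(calls$chrom, calls$pos, calls$alt, sep = ":")
  nref <- tapply(calls$ref, locus, function(r) length(unique(r)))
  check(all(nref == 1L), "inconsistent ref allele at %s",
        paste(names(nref)[nref > 1L], collapse = ", "))

  out <- list()
  aud <- list()
  for (k in unique(key)) {
    rec <- calls[key == k, , drop = FALSE]
    admissible <- if (rec$type[1] == "SNV") c("strelka", "varscan", "mutect")
    else c("strelka", "varscan", "pindel")
    sup <- rec[rec$caller %in% admissible, , drop = FALSE]
    callers <- sort(unique(sup$caller))
    if (nrow(sup) == 0L) {
      clause <- c(callers = FALSE, vaf = NA, depth = NA, indel_len = NA,
                  exonic = NA, dbsnp = NA)
      rep_rec <- rec[1, , drop = FALSE]
    } else {
      rep_rec <- representative(sup, "tumor_depth")
      clause <- c(
        callers = length(callers) >= 2L,
        vaf = rep_rec$normal_vaf <= 0.02 && rep_rec$tumor_vaf >= 0.05,
        depth = rep_rec$tumor_depth >= 14 && rep_rec$normal_depth >= 8,
        indel_len = rep_rec$type == "SNV" ||
          indel_length(rep_rec$ref, rep_rec$alt) < 100,
        exonic = isTRUE(rep_rec$exonic),
        dbsnp = !(isTRUE(rep_rec$in_dbsnp) && !isTRUE(rep_rec$in_cosmic))
      )
    }
    aud[[k]] <- data.frame(key = k, t(clause))
    if (all(clause %in% TRUE)) {
      rep_rec$caller <- NULL
      rep_rec$callers <- paste(callers, collapse = ",")
      rep_rec$n_callers <- length(callers)
      out[[k]] <- rep_rec
    }
  }
  res <- if (length(out)) do.call(rbind, out) else calls[0, ]
  res <- res[order(res$chrom, res$pos, res$ref, res$alt), , drop = FALSE]
  rownames(res) <- NULL
  if (audit) attr(res, "audit") <- do.call(rbind, aud)
  res
}

#' Filter tumor-only somatic calls
#'
#' Keeps calls with readcount-verified site coverage >= 20, alt reads > 3
#' and tumor VAF >= 0.1; calls present in the panel of normals are
#' removed.
#'
#' @param calls data.frame with `chrom`, `pos`, `ref`, `alt` and either
#'   readcount columns `depth`/`alt_count` or `tumor_depth`/`tumor_alt`;
#'   optional logical `in_pon`.
#' @param site_readcounts Optional data.frame (`chrom`, `pos`, `ref`,
#'   `alt`, `depth`, `alt_count`) overriding the caller's depths.
#'
#' @return The surviving calls.
#' @export
filter_tumor_only <- function(calls, site_readcounts = NULL) {
  need_cols(calls, c("chrom", "pos", "ref", "alt"), "tumor-only calls")
  depth <- calls$depth %||% calls$tumor_depth
  alt <- calls$alt_count %||% calls$tumor_alt
  if (!is.null(site_readcounts)) {
    need_cols(site_readcounts, c("chrom", "pos", "ref", "alt", "depth",
                                 "alt_count"), "site_readcounts")
    idx <- match(variant_key(calls), variant_key(site_readcounts))
    check(!anyNA(idx), "site_readcounts missing %d call site(s)",
          sum(is.na(idx)))
    depth <- site_readcounts$depth[idx]
    alt <- site_readcounts$alt_count[idx]
  }
  check(!is.null(depth) && !is.null(alt),
        "calls need depth/alt_count (or tumor_depth/tumor_alt) columns")
  in_pon <- calls$in_pon %||% rep(FALSE, nrow(calls))
  vaf <- ifelse(depth > 0, alt / depth, 0)
  keep <- depth >= 20 & alt > 3 & vaf >= 0.1 & !in_pon
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rescue cohort driver variants in samples lacking a call
#'
#' For each driver variant and each sample where it was not called, emits
#' a rescued record when the sample's readcounts (computed upstream with
#' mapping and base quality floors of 20) support it: at least `min_alt`
#' alt reads and VAF >= `min_vaf`. Variants absent from the readcount
#' table are reported "unassessable"; already-called variants pass
#' through unchanged.
#'
#' @param driver_variants data.frame `chrom`, `pos`, `ref`, `alt`.
#' @param per_sample_readcounts data.frame `sample`, `chrom`, `pos`,
#'   `ref`, `alt`, `depth`, `alt_count`.
#' @param called data.frame `sample`, `chrom`, `pos`, `ref`, `alt` of
#'   calls already made per sample.
#' @param samples Character vector of samples to assess (default: all in
#'   the readcount table).
#' @param min_alt,min_vaf Rescue criterion (defaults 2 reads, VAF 0.02).
#'
#' @return data.frame `sample`, `key`, `status`
#'   ("called"/"rescued"/"not_rescued"/"unassessable"), `depth`,
#'   `alt_count`, `rescued` (logical).
#' @export
rescue_variants <- function(driver_variants, per_sample_readcounts, called,
                            samples = NULL, min_alt = 2, min_vaf = 0.02) {
  need_cols(driver_variants, c("chrom", "pos", "ref", "alt"),
            "driver_variants")
  need_cols(per_sample_readcounts, c("sample", "chrom", "pos", "ref", "alt",
                                     "depth", "alt_count"),
            "per_sample_readcounts")
  need_cols(called, c("sample", "chrom", "pos", "ref", "alt"), "called")
  samples <- samples %||% unique(per_sample_readcounts$sample)
  dkey <- variant_key(driver_variants)
  ckey <- paste(called$sample, variant_key(called))
  rkey <- paste(per_sample_readcounts$sample,
                variant_key(per_sample_readcounts))
  grid <- expand.grid(sample = samples, key = dkey,
                      stringsAsFactors = FALSE)
  idx <- match(paste(grid$sample, grid$key), rkey)
  grid$depth <- per_sample_readcounts$depth[idx]
  grid$alt_count <- per_sample_readcounts$alt_count[idx]
  already <- paste(grid$sample, grid$key) %in% ckey
  grid$status <- ifelse(already, "called",
                 ifelse(is.na(idx), "unassessable",
                 ifelse(grid$alt_count >= min_alt &
                          grid$depth > 0 &
                          grid$alt_count / pmax(grid$depth, 1) >= min_vaf,
                        "rescued", "not_rescued")))
  grid$rescued <- grid$status == "rescued"
  grid
}

#' Merge and filter germline calls
#'
#' SNVs are the union of gatk and varscan calls; indels must be called by
#' pindel or by at least two of gatk/varscan/pindel. Surviving keys then
#' require normal coverage >= 10x and normal VAF >= 20%, alt allelic
#' depth >= 5 in both tumor and normal, indel length <= 100 bp and, when
#' a coding-interval table is supplied, overlap with an exon padded by
#' 2 bp of splice flank.
#'
#' @param calls data.frame of caller records: `chrom`, `pos`, `ref`,
#'   `alt`, `caller` in gatk/varscan/pindel, `normal_depth`,
#'   `normal_alt`, `normal_vaf`, `tumor_alt`.
#' @param coding_intervals Optional BED-style data.frame (`chrom`,
#'   `start`, `end`; 0-based half-open exons).
#' @param flank Splice flank padding in bp (default 2).
#'
#' @return Consensus data.frame with `callers`, `n_callers`.
#' @export
merge_germline_calls <- function(calls, coding_intervals = NULL, flank = 2L) {
  need_cols(calls, c("chrom", "pos", "ref", "alt", "caller", "normal_depth",
                     "normal_alt", "normal_vaf", "tumor_alt"),
            "germline calls")
  bad <- setdiff(unique(calls$caller), GERMLINE_CALLERS)
  check(length(bad) == 0L, "unknown caller id(s): %s",
        paste(bad, collapse = ", "))
  if (nrow(calls) == 0L) return(calls)
  norm <- normalize_alleles(calls$chrom, calls$pos, calls$ref, calls$alt)
  calls[c("chrom", "pos", "ref", "alt")] <- norm
  calls$type <- variant_type(calls$ref, calls$alt)
  key <- variant_key(calls)
  coding_gr <- if (is.null(coding_intervals)) NULL else {
    ci <- coding_intervals
    ci$start <- ci$start - flank
    ci$end <- ci$end + flank
    granges_from_bed(ci)
  }
  out <- list()
  for (k in unique(key)) {
    rec <- calls[key == k, , drop = FALSE]
    callers <- sort(unique(rec$caller))
    rep_rec <- representative(rec, "normal_depth")
    caller_ok <- if (rep_rec$type == "SNV") {
      any(c("gatk", "varscan") %in% callers)
    } else {
      "pindel" %in% callers || length(callers) >= 2L
    }
    if (!caller_ok) next
    if (!(rep_rec$normal_depth >= 10 && rep_rec$normal_vaf >= 0.20)) next
    if (!(rep_rec$tumor_alt >= 5 && rep_rec$normal_alt >= 5)) next
    if (rep_rec$type == "indel" &&
        indel_length(rep_rec$ref, rep_rec$alt) > 100) next
    if (!is.null(coding_gr)) {
      span <- granges_from_pos(rep_rec$chrom, rep_rec$pos,
                               width = nchar(rep_rec$ref))
      if (length(GenomicRanges::findOverlaps(span, coding_gr)) == 0L) next
    }
    rep_rec$caller <- NULL
    rep_rec$callers <- paste(callers, collapse = ",")
    rep_rec$n_callers <- length(callers)
    out[[k]] <- rep_rec
  }
  res <- if (length(out)) do.call(rbind, out) else calls[0, ]
  res <- res[order(res$chrom, res$pos, res$ref, res$alt), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Tier germline variant pathogenicity
#'
#' A rare-allele-frequency gate is applied first: gnomAD AF <= 0.05%
#' (missing AF counts as rare) and readcount support of at least 5 alt
#' reads with VAF >= 20% (in both tumor and normal for paired mode, in
#' tumor only for tumor-only mode). Gated-in variants are tiered:
#' ClinVar-pathogenic -> "pathogenic"; else CharGer score > 8 ->
#' "likely_pathogenic"; else score > 4 -> "prioritized_VUS"; else
#' "none". In tumor-only mode, variants also present in the somatic
#' consensus set and variants absent from gnomAD and not in COSMIC are
#' removed (tier "none").
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`,
#'   `gnomad_af` (NA = unreported), `clinvar` (character;
#'   "pathogenic" recognized), `charger_score`, `tumor_alt`, `tumor_vaf`
#'   and (paired mode) `normal_alt`, `normal_vaf`; optional `in_cosmic`.
#' @param mode "paired" or "tumor_only".
#' @param somatic_keys Character keys (chrom:pos:ref:alt) of the somatic
#'   consensus set (tumor-only mode).
#'
#' @return The input with a `tier` column.
#' @export
classify_pathogenicity <- function(variants,
                                   mode = c("paired", "tumor_only"),
                                   somatic_keys = character()) {
  mode <- match.arg(mode)
  need_cols(variants, c("chrom", "pos", "ref", "alt", "gnomad_af",
                        "clinvar", "charger_score", "tumor_alt",
                        "tumor_vaf"), "variants")
  if (mode == "paired") {
    need_cols(variants, c("normal_alt", "normal_vaf"), "variants")
  }
  af_ok <- is.na(variants$gnomad_af) | variants$gnomad_af <= 0.0005
  reads_ok <- variants$tumor_alt >= 5 & variants$tumor_vaf >= 0.20
  if (mode == "paired") {
    reads_ok <- reads_ok & variants$normal_alt >= 5 &
      variants$normal_vaf >= 0.20
  }
  gate <- af_ok & reads_ok
  if (mode == "tumor_only") {
    in_cosmic <- variants$in_cosmic %||% rep(FALSE, nrow(variants))
    gate <- gate & !(variant_key(variants) %in% somatic_keys)
    gate <- gate & (!is.na(variants$gnomad_af) | in_cosmic)
  }
  score <- variants$charger_score
  tier <- ifelse(!gate, "none",
          ifelse(!is.na(variants$clinvar) &
                   tolower(variants$clinvar) == "pathogenic", "pathogenic",
          ifelse(!is.na(score) & score > 8, "likely_pathogenic",
          ifelse(!is.na(score) & score > 4, "prioritized_VUS", "none"))))
  variants$tier <- tier
  variants
}

#' One-sided Fisher LOH test with BH adjustment
#'
#' For each variant, tests whether the tumor alt-allele fraction exceeds
#' the normal's via the one-sided Fisher exact (hypergeometric tail)
#' probability on the 2x2 table (tumor alt, tumor ref) vs (normal alt,
#' normal ref), then applies Benjamini-Hochberg adjustment across the
#' supplied variants. Zero-depth samples yield NA (p undefined).
#'
#' @param variants data.frame with `tumor_alt`, `tumor_ref`,
#'   `normal_alt`, `normal_ref` counts.
#' @param fdr_cutoff Significance flag threshold (default 0.05).
#'
#' @return The input with `p`, `fdr` and `significant` columns.
#' @export
loh_fisher <- function(variants, fdr_cutoff = 0.05) {
  need_cols(variants, c("tumor_alt", "tumor_ref", "normal_alt",
                        "normal_ref"), "variants")
  p <- vapply(seq_len(nrow(variants)), function(i) {
    ta <- variants$tumor_alt[i]; tr <- variants$tumor_ref[i]
    na <- variants$normal_alt[i]; nr <- variants$normal_ref[i]
    if (ta + tr == 0 || na + nr == 0) return(NA_real_)
    stats::fisher.test(matrix(c(ta, tr, na, nr), nrow = 2, byrow = TRUE),
                       alternative = "greater")$p.value
  }, numeric(1))
  fdr <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  fdr[ok] <- stats::p.adjust(p[ok], method = "BH")
  variants$p <- p
  variants$fdr <- fdr
  variants$significant <- !is.na(fdr) & fdr < fdr_cutoff
  variants
}

#' Count ref/alt-supporting molecules per cell at SNV sites
#'
#' For each cell barcode and variant, counts unique molecules (UMIs)
#' whose base at the variant site supports the reference vs the
#' alternative allele: one vote per molecule, intra-molecule read
#' conflicts resolved by majority, ties discarded. Reads failing the
#' mapping- or base-quality floors are excluded.
#'
#' @param alignments data.frame of reads with columns `barcode`, `umi`,
#'   `chrom`, `pos` (1-based leftmost aligned position), `seq` (aligned
#'   bases, no indels/clipping), `mapq`, `baseq` (per-read minimum base
#'   quality); see [read_tagged_alignments()].
#' @param variants data.frame of SNVs: `chrom`, `pos`, `ref`, `alt`.
#' @param min_mapq,min_baseq Quality floors (defaults 20/20).
#'
#' @return data.frame `barcode`, `key`, `ref_reads`, `alt_reads`
#'   (molecule counts).
#' @export
map_variants_to_cells <- function(alignments, variants, min_mapq = 20,
                                  min_baseq = 20) {
  need_cols(alignments, c("barcode", "umi", "chrom", "pos", "seq", "mapq",
                          "baseq"), "alignments")
  need_cols(variants, c("chrom", "pos", "ref", "alt"), "variants")
  check(all(nchar(variants$ref) == 1L & nchar(variants$alt) == 1L),
        "variants must be SNVs")
  al <- alignments[alignments$mapq >= min_mapq &
                     alignments$baseq >= min_baseq, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    covering <- al[al$chrom == v$chrom & al$pos <= v$pos &
                     al$pos + nchar(al$seq) - 1L >= v$pos, , drop = FALSE]
    if (nrow(covering) == 0L) next
    base <- substr(covering$seq, v$pos - covering$pos + 1L,
                   v$pos - covering$pos + 1L)
    votes <- data.frame(barcode = covering$barcode, umi = covering$umi,
                        is_ref = base == v$ref, is_alt = base == v$alt,
                        stringsAsFactors = FALSE)
    votes <- votes[votes$is_ref | votes$is_alt, , drop = FALSE]
    if (nrow(votes) == 0L) next
    mol <- unique(votes[c("barcode", "umi")])
    allele <- vapply(seq_len(nrow(mol)), function(m) {
      sel <- votes$barcode == mol$barcode[m] & votes$umi == mol$umi[m]
      n_ref <- sum(votes$is_ref[sel]); n_alt <- sum(votes$is_alt[sel])
      if (n_ref > n_alt) "ref" else if (n_alt > n_ref) "alt" else "tie"
    }, character(1))
    mol <- mol[allele != "tie", , drop = FALSE]
    allele <- allele[allele != "tie"]
    if (nrow(mol) == 0L) next
    tab <- table(mol$barcode, factor(allele, levels = c("ref", "alt")))
    out[[i]] <- data.frame(barcode = rownames(tab),
                           key = variant_key(v),
                           ref_reads = as.integer(tab[, "ref"]),
                           alt_reads = as.integer(tab[, "alt"]),
                           stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(barcode = character(), key = character(),
                      ref_reads = integer(), alt_reads = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read minimal caller output from a VCF
#'
#' Extracts CHROM, POS, REF, ALT plus per-sample AD (ref,alt) and DP from
#' a (single-ALT) VCF with TUMOR/NORMAL sample columns (or, failing those
#' names, the first two sample columns in that order).
#'
#' @param path VCF file path (uncompressed or bgzipped).
#' @param caller Caller id to stamp on the records.
#' @return Variant-record data.frame suitable for the merge operations.
#' @export
read_caller_vcf <- function(path, caller) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  cols <- colnames(ad)
  tcol <- if ("TUMOR" %in% cols) "TUMOR" else cols[min(2L, length(cols))]
  ncol_ <- if ("NORMAL" %in% cols) "NORMAL" else cols[1L]
  alt_of <- function(x) as.integer(vapply(strsplit(x, ","), function(p)
    p[min(2L, length(p))], character(1)))
  out <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT, caller = caller,
                    tumor_depth = as.integer(dp[, tcol]),
                    tumor_alt = alt_of(ad[, tcol]),
                    normal_depth = as.integer(dp[, ncol_]),
                    normal_alt = alt_of(ad[, ncol_]),
                    stringsAsFactors = FALSE)
  out$tumor_vaf <- ifelse(out$tumor_depth > 0,
                          out$tumor_alt / out$tumor_depth, 0)
  out$normal_vaf <- ifelse(out$normal_depth > 0,
                           out$normal_alt / out$normal_depth, 0)
  out
}

#' Read barcode/UMI-tagged alignments from a SAM file
#'
#' Converts the SAM to BAM in a temporary directory and extracts the
#' fields [map_variants_to_cells()] consumes, taking the cell barcode
#' from the CB tag and the molecule barcode from the UB tag. `baseq` is
#' the read's minimum base quality.
#'
#' @param sam_path Path to a SAM file with CB/UB tags.
#' @return Alignment data.frame.
#' @export
read_tagged_alignments <- function(sam_path) {
  bam <- Rsamtools::asBam(sam_path,
                          destination = tempfile(),
                          overwrite = TRUE, indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "seq", "mapq", "qual"),
    tag = c("CB", "UB"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  minq <- vapply(as.character(x$qual), function(q)
    if (nchar(q) == 0) 0 else min(utf8ToInt(q)) - 33, numeric(1),
    USE.NAMES = FALSE)
  data.frame(barcode = x$tag$CB, umi = x$tag$UB,
             chrom = as.character(x$rname), pos = x$pos,
             seq = as.character(x$seq), mapq = x$mapq, baseq = minq,
             stringsAsFactors = FALSE)
}
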