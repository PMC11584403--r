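# Synthetic generators for variant calls, peak sets and motif matrices,
# each deterministic under a fixed seed and returning planted ground truth.

#' Simulate multi-caller variant calls around a planted truth set
#'
#' Each true variant is emitted by each caller with that caller's
#' sensitivity; spurious calls are added per caller at its false-call rate
#' (expected count, Poisson). Depths are Poisson around the profile means
#' and alt counts are beta-binomial around the planted VAF, giving
#' realistic depth-dependent noise at filter boundaries. Normal-sample
#' VAFs for somatic truths are near zero.
#'
#' @param true_variants data.frame with columns `chrom`, `pos`, `ref`,
#'   `alt`, `vaf` (planted tumor VAF) and optionally `exonic`, `in_dbsnp`,
#'   `in_cosmic` (default TRUE/FALSE/FALSE).
#' @param caller_profiles data.frame with columns `caller`, `sensitivity`,
#'   `false_rate` and optionally `tumor_depth`, `normal_depth` (means,
#'   defaults 80/40).
#' @param seed RNG seed.
#' @param overdispersion Beta-binomial concentration (larger = tighter
#'   around the planted VAF).
#' @param normal_contamination Per-read probability of the alt allele in
#'   the matched normal (default 0: somatic truths are clean in the
#'   normal; raise it to probe the normal-VAF filter boundary).
#'
#' @return data.frame of caller records (one row per emitted call) with
#'   the full variant-record fields, plus attribute `truth` (the input
#'   truth with a `key` column).
#' @export
generate_caller_calls <- function(true_variants, caller_profiles, seed = 1L,
                                  overdispersion = 60,
                                  normal_contamination = 0) {
  need_cols(true_variants, c("chrom", "pos", "ref", "alt", "vaf"),
            "true_variants")
  need_cols(caller_profiles, c("caller", "sensitivity", "false_rate"),
            "caller_profiles")
  check(all(caller_profiles$sensitivity >= 0 &
              caller_profiles$sensitivity <= 1),
        "sensitivity must lie in [0, 1]")
  tv <- true_variants
  if (is.null(tv$exonic)) tv$exonic <- TRUE
  if (is.null(tv$in_dbsnp)) tv$in_dbsnp <- FALSE
  if (is.null(tv$in_cosmic)) tv$in_cosmic <- FALSE
  tv$type <- ifelse(nchar(tv$ref) == nchar(tv$alt), "SNV", "indel")
  cp <- caller_profiles
  if (is.null(cp$tumor_depth)) cp$tumor_depth <- 80
  if (is.null(cp$normal_depth)) cp$normal_depth <- 40

  with_seed(seed, {
    rows <- list()
    draw_record <- function(v, caller, td_mean, nd_mean, vaf) {
      td <- max(1L, stats::rpois(1, td_mean))
      nd <- max(1L, stats::rpois(1, nd_mean))
      p <- stats::rbeta(1, vaf * overdispersion,
                        (1 - vaf) * overdispersion)
      ta <- stats::rbinom(1, td, p)
      na <- stats::rbinom(1, nd, normal_contamination)
      data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
                 type = v$type, caller = caller,
                 tumor_depth = td, tumor_alt = ta,
                 normal_depth = nd, normal_alt = na,
                 tumor_vaf = ta / td, normal_vaf = na / nd,
                 exonic = v$exonic, in_dbsnp = v$in_dbsnp,
                 in_cosmic = v$in_cosmic, stringsAsFactors = FALSE)
    }
    for (j in seq_len(nrow(cp))) {
      for (i in seq_len(nrow(tv))) {
        if (stats::runif(1) <= cp$sensitivity[j]) {
          rows[[length(rows) + 1L]] <-
            draw_record(tv[i, ], cp$caller[j], cp$tumor_depth[j],
                        cp$normal_depth[j], min(max(tv$vaf[i], 1e-3), 1 - 1e-3))
        }
      }
      n_fp <- stats::rpois(1, cp$false_rate[j])
      for (k in seq_len(n_fp)) {
        v <- data.frame(chrom = sample(paste0("chr", 1:5), 1),
                        pos = sample.int(1e6, 1),
                        ref = sample(c("A", "C", "G", "T"), 1),
                        alt = sample(c("A", "C", "G", "T"), 1),
                        exonic = stats::runif(1) < 0.5,
                        in_dbsnp = stats::runif(1) < 0.5,
                        in_cosmic = FALSE, stringsAsFactors = FALSE)
        while (v$alt == v$ref) v$alt <- sample(c("A", "C", "G", "T"), 1)
        v$type <- "SNV"
        rows[[length(rows) + 1L]] <-
          draw_record(v, cp$caller[j], cp$tumor_depth[j], cp$normal_depth[j],
                      stats::runif(1, 0.01, 0.06))
      }
    }
    out <- if (length(rows)) do.call(rbind, rows) else
      data.frame(chrom = character(), pos = integer(), ref = character(),
                 alt = character(), type = character(), caller = character(),
                 tumor_depth = integer(), tumor_alt = integer(),
                 normal_depth = integer(), normal_alt = integer(),
                 tumor_vaf = numeric(), normal_vaf = numeric(),
                 exonic = logical(), in_dbsnp = logical(),
                 in_cosmic = logical(), stringsAsFactors = FALSE)
    tv$key <- paste(tv$chrom, tv$pos, tv$ref, tv$alt, sep = ":")
    attr(out, "truth") <- tv
    out
  })
}

#' Simulate per-sample MACS-style peak sets
#'
#' Peaks have random summits, widths 200-1500 bp and -log10 q scores drawn
#' log-uniformly. A configurable fraction of peaks is duplicated as
#' jittered overlapping copies; optional fractions are planted on chrY and
#' across N-gap intervals to exercise the standardization filters.
#'
#' @param n_samples Number of samples.
#' @param peaks_per_sample Baseline peaks per sample (before overlap
#'   copies).
#' @param genome_lengths Named chromosome -> length vector (include chrY
#'   to exercise that filter).
#' @param seed RNG seed.
#' @param overlap_fraction Fraction of peaks duplicated as overlapping
#'   jittered copies.
#' @param chry_fraction Fraction of peaks placed on chrY (if present).
#' @param n_gaps Optional N-gap data.frame (`chrom`, `start`, `end`);
#'   `gap_fraction` of peaks are planted across gaps.
#' @param gap_fraction See `n_gaps`.
#'
#' @return List of per-sample peak data.frames.
#' @export
generate_peak_sets <- function(n_samples, peaks_per_sample, genome_lengths,
                               seed = 1L, overlap_fraction = 0.2,
                               chry_fraction = 0, n_gaps = NULL,
                               gap_fraction = 0) {
  check(all(genome_lengths > 2000), "chromosome lengths must exceed 2 kb")
  with_seed(seed, {
    autos <- setdiff(names(genome_lengths), c("chrY", "Y"))
    one_peak <- function(chrom) {
      len <- genome_lengths[[chrom]]
      w <- sample(200:1500, 1)
      start <- sample.int(len - w - 600L, 1) + 300L
      summit <- start + sample.int(w, 1) - 1L
      data.frame(chrom = chrom, start = start, end = start + w,
                 summit = summit,
                 score = exp(stats::runif(1, log(2), log(100))),
                 stringsAsFactors = FALSE)
    }
    lapply(seq_len(n_samples), function(s) {
      n_y <- round(chry_fraction * peaks_per_sample)
      n_gap <- if (is.null(n_gaps)) 0L else round(gap_fraction * peaks_per_sample)
      n_base <- peaks_per_sample - n_y - n_gap
      chroms <- sample(autos, n_base, replace = TRUE,
                       prob = genome_lengths[autos])
      pk <- do.call(rbind, lapply(chroms, one_peak))
      if (n_y > 0) {
        pk <- rbind(pk, do.call(rbind, lapply(rep(
          intersect(names(genome_lengths), c("chrY", "Y"))[1], n_y), one_peak)))
      }
      if (n_gap > 0) {
        gi <- sample.int(nrow(n_gaps), n_gap, replace = TRUE)
        gp <- do.call(rbind, lapply(gi, function(g) {
          mid <- floor((n_gaps$start[g] + n_gaps$end[g]) / 2)
          w <- sample(200:1500, 1)
          start <- mid - sample.int(w, 1) + 1L
          data.frame(chrom = n_gaps$chrom[g], start = start,
                     end = start + w, summit = mid,
                     score = exp(stats::runif(1, log(2), log(100))),
                     stringsAsFactors = FALSE)
        }))
        pk <- rbind(pk, gp)
      }
      n_ov <- round(overlap_fraction * nrow(pk))
      if (n_ov > 0) {
        src <- pk[sample.int(nrow(pk), n_ov, replace = TRUE), , drop = FALSE]
        shift <- sample(-150:150, n_ov, replace = TRUE)
        src$start <- pmax(301L, src$start + shift)
        src$end <- src$start + sample(200:1500, n_ov, replace = TRUE)
        src$summit <- src$start +
          floor((src$end - src$start) / 2)
        src$score <- exp(stats::runif(n_ov, log(2), log(100)))
        pk <- rbind(pk, src)
      }
      pk$sample <- sprintf("S%02d", s)
      rownames(pk) <- NULL
      pk
    })
  })
}

#' Simulate a TF motif-score (deviation) matrix with planted shifts
#'
#' Scores are Gaussian per cell around zero; planted TFs are shifted by a
#' stated amount in stated groups, emulating bias-corrected accessibility
#' deviations with known lineage structure.
#'
#' @param groups Named integer vector group -> number of cells.
#' @param planted_shifts data.frame with columns `tf`, `group`, `shift`
#'   (may be empty / NULL for a null matrix).
#' @param n_tfs Total TFs (planted TFs must be among `tf1..tfN` or are
#'   added).
#' @param sd Gaussian noise standard deviation (default 1, the deviation
#'   scale).
#' @param seed RNG seed.
#'
#' @return List with `scores` (TF x cell matrix), `cell_groups` (named
#'   vector cell -> group) and `truth` (the planted shift table).
#' @export
generate_motif_matrix <- function(groups, planted_shifts = NULL, n_tfs = 40L,
                                  sd = 1, seed = 1L) {
  check(!is.null(names(groups)) && all(groups > 0),
        "groups must be a named positive vector")
  if (is.null(planted_shifts)) {
    planted_shifts <- data.frame(tf = character(), group = character(),
                                 shift = numeric(), stringsAsFactors = FALSE)
  }
  need_cols(planted_shifts, c("tf", "group", "shift"), "planted_shifts")
  check(all(planted_shifts$group %in% names(groups)),
        "planted shift names an unknown group")
  tfs <- union(sprintf("tf%03d", seq_len(n_tfs)), planted_shifts$tf)
  with_seed(seed, {
    cell_groups <- rep(names(groups), times = groups)
    cells <- sprintf("%s_c%04d", cell_groups, seq_along(cell_groups))
    names(cell_groups) <- cells
    scores <- matrix(stats::rnorm(length(tfs) * length(cells), sd = sd),
                     nrow = length(tfs), dimnames = list(tfs, cells))
    for (i in seq_len(nrow(planted_shifts))) {
      idx <- cell_groups == planted_shifts$group[i]
      scores[planted_shifts$tf[i], idx] <-
        scores[planted_shifts$tf[i], idx] + planted_shifts$shift[i]
    }
    list(scores = scores, cell_groups = cell_groups, truth = planted_shifts)
  })
}
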