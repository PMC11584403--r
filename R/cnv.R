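# Overlap-weighted mapping of copy-ratio segments to genes or chromosome
# arms.

#' Weighted segment-to-interval copy calls
#'
#' For each target interval, the weighted copy ratio is
#' `sum(ratio_i * overlap_i) / sum(overlap_i)` over overlapping segments;
#' the call is amplified when the weighted ratio exceeds the upper bound,
#' deleted when below the lower bound, neutral otherwise (strict
#' inequalities, so a ratio exactly at a bound is neutral). Targets with
#' no overlapping segment get "no_call". Optional sample-adaptive bounds
#' `1 +/- z * sd(segment ratios)` are clamped so the neutral zone is
#' never narrower than the default (0.9, 1.1) envelope.
#'
#' @param segments data.frame `chrom`, `start`, `end` (0-based
#'   half-open), `copy_ratio` (positive linear de-noised ratio).
#' @param targets data.frame `name`, `chrom`, `start`, `end` (gene or
#'   arm intervals).
#' @param bounds Numeric `c(lower, upper)` with lower < 1 < upper
#'   (default `c(0.9, 1.1)`).
#' @param adaptive Derive bounds from the dispersion of segment ratios
#'   (clamped to the default envelope); default FALSE.
#' @param z Z multiplier for adaptive bounds (default 2).
#' @param space Averaging space: "linear" (default; the caller's
#'   thresholds are linear) or "log2" (ratios averaged on log2 scale and
#'   exponentiated back before calling).
#'
#' @return data.frame `name`, `weighted_ratio`, `n_segments`, `call` in
#'   amplified/neutral/deleted/no_call.
#' @export
weighted_interval_call <- function(segments, targets, bounds = c(0.9, 1.1),
                                   adaptive = FALSE, z = 2,
                                   space = c("linear", "log2")) {
  space <- match.arg(space)
  need_cols(segments, c("chrom", "start", "end", "copy_ratio"), "segments")
  need_cols(targets, c("name", "chrom", "start", "end"), "targets")
  check(all(segments$start < segments$end), "segment start must be < end")
  check(all(segments$copy_ratio > 0), "copy ratios must be positive")
  check(bounds[1] < 1 && bounds[2] > 1, "bounds must straddle 1")
  if (adaptive) {
    sdv <- stats::sd(segments$copy_ratio)
    lower <- 1 - z * sdv
    upper <- 1 + z * sdv
    bounds <- c(min(lower, bounds[1]), max(upper, bounds[2]))
  }
  seg_gr <- granges_from_bed(segments)
  tgt_gr <- granges_from_bed(targets)
  # targets on chromosomes with no segment are legitimate no_calls
  hits <- suppressWarnings(GenomicRanges::findOverlaps(tgt_gr, seg_gr))
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ov <- suppressWarnings(GenomicRanges::width(
    GenomicRanges::pintersect(tgt_gr[q], seg_gr[s])))
  stopifnot(all(ov > 0))
  val <- if (space == "linear") segments$copy_ratio[s] else
    log2(segments$copy_ratio[s])
  wsum <- tapply(val * ov, q, sum)
  osum <- tapply(ov, q, sum)
  w <- rep(NA_real_, nrow(targets))
  w[as.integer(names(wsum))] <- as.numeric(wsum) / as.numeric(osum)
  if (space == "log2") w <- 2^w
  n_seg <- integer(nrow(targets))
  tab <- table(q)
  n_seg[as.integer(names(tab))] <- as.integer(tab)
  call <- ifelse(is.na(w), "no_call",
          ifelse(w > bounds[2], "amplified",
          ifelse(w < bounds[1], "deleted", "neutral")))
  data.frame(name = targets$name, weighted_ratio = w, n_segments = n_seg,
             call = call, stringsAsFactors = FALSE, row.names = NULL)
}
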