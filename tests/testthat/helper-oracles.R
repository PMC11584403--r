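# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (explicit loops, closed forms, enumerations) and
# never share code with the implementation paths they check.

# O(n^2) greedy iterative overlap removal: rescan the remaining table at
# every step.
oracle_iterative_removal <- function(pk, rank_by = "score") {
  keep <- pk[0, , drop = FALSE]
  rem <- pk
  while (nrow(rem) > 0) {
    o <- order(-rem[[rank_by]], rem$chrom, rem$start)
    top <- rem[o[1], , drop = FALSE]
    keep <- rbind(keep, top)
    ov <- rem$chrom == top$chrom & rem$start < top$end & rem$end > top$start
    rem <- rem[!ov, , drop = FALSE]
  }
  keep <- keep[order(keep$chrom, keep$start), , drop = FALSE]
  rownames(keep) <- NULL
  keep
}

# Closed-form one-sided hypergeometric tail for the LOH 2x2 table.
oracle_loh_p <- function(ta, tr, na_, nr) {
  m <- ta + na_          # total alt
  n <- tr + nr           # total ref
  k <- ta + tr           # tumor draws
  sum(stats::dhyper(ta:min(m, k), m, n, k))
}

# Definitional BH step-up adjustment.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration of group-A
# assignments (no ties assumed).
oracle_wilcoxon_exact <- function(x, y) {
  r <- rank(c(x, y))
  n <- length(x)
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(length(x) + length(y), n)
  w_all <- apply(combos, 2, function(i) sum(r[i])) - n * (n + 1) / 2
  mu <- length(x) * length(y) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Truth-table predicate for the tumor-normal somatic consensus filter,
# applied per variant key on a record table.
oracle_somatic_keep <- function(records) {
  key <- paste(records$chrom, records$pos, records$ref, records$alt, sep = ":")
  kept <- character()
  for (k in unique(key)) {
    rec <- records[key == k, , drop = FALSE]
    is_snv <- nchar(rec$ref[1]) == 1 && nchar(rec$alt[1]) == 1
    adm <- if (is_snv) c("strelka", "varscan", "mutect") else
      c("strelka", "varscan", "pindel")
    sup <- rec[rec$caller %in% adm, , drop = FALSE]
    if (nrow(sup) == 0) next
    r <- sup[order(-sup$tumor_depth, sup$caller), , drop = FALSE][1, ]
    ok <- length(unique(sup$caller)) >= 2 &&
      r$normal_vaf <= 0.02 && r$tumor_vaf >= 0.05 &&
      r$tumor_depth >= 14 && r$normal_depth >= 8 &&
      (is_snv || abs(nchar(r$ref) - nchar(r$alt)) < 100) &&
      r$exonic && !(r$in_dbsnp && !r$in_cosmic)
    if (ok) kept <- c(kept, k)
  }
  sort(kept)
}

# Truth-table predicate for the germline consensus filter.
oracle_germline_keep <- function(records) {
  key <- paste(records$chrom, records$pos, records$ref, records$alt, sep = ":")
  kept <- character()
  for (k in unique(key)) {
    rec <- records[key == k, , drop = FALSE]
    is_snv <- nchar(rec$ref[1]) == 1 && nchar(rec$alt[1]) == 1
    callers <- unique(rec$caller)
    r <- rec[order(-rec$normal_depth, rec$caller), , drop = FALSE][1, ]
    caller_ok <- if (is_snv) any(c("gatk", "varscan") %in% callers) else
      ("pindel" %in% callers || length(callers) >= 2)
    ok <- caller_ok && r$normal_depth >= 10 && r$normal_vaf >= 0.20 &&
      r$tumor_alt >= 5 && r$normal_alt >= 5 &&
      (is_snv || abs(nchar(r$ref) - nchar(r$alt)) <= 100)
    if (ok) kept <- c(kept, k)
  }
  sort(kept)
}

# Decision-table oracle for pathogenicity tiers (paired mode).
oracle_tier <- function(v) {
  gate <- (is.na(v$gnomad_af) | v$gnomad_af <= 0.0005) &
    v$tumor_alt >= 5 & v$tumor_vaf >= 0.20 &
    v$normal_alt >= 5 & v$normal_vaf >= 0.20
  ifelse(!gate, "none",
  ifelse(!is.na(v$clinvar) & tolower(v$clinvar) == "pathogenic", "pathogenic",
  ifelse(!is.na(v$charger_score) & v$charger_score > 8, "likely_pathogenic",
  ifelse(!is.na(v$charger_score) & v$charger_score > 4, "prioritized_VUS",
         "none"))))
}

# Independent set-algebra evaluation of the lineage DEG filter from
# already-computed comparison gene sets (character vectors).
oracle_lineage_sets <- function(g1, g2, c1, c2, a1, lineage, summary_df,
                                min_pct = 20, min_fc = 1) {
  if (lineage == "basal") {
    s <- g1
    s <- s[!(s %in% c1 | s %in% c2)]
    s <- s[!(s %in% g2)]
    s <- s[s %in% c(a1$tumor_Basal, a1$LP)]
    s <- s[!(s %in% c(a1$tumor_LumA, a1$tumor_LumB, a1$tumor_Her2,
                      a1$BP, a1$LM))]
  } else {
    s <- g2
    s <- s[!(s %in% c1 | s %in% c2)]
    s <- s[!(s %in% g1)]
    s <- s[s %in% c(a1$tumor_LumA, a1$tumor_LumB, a1$LM)]
    s <- s[!(s %in% c(a1$tumor_Her2, a1$BP, a1$tumor_Basal))]
  }
  i <- match(s, summary_df$gene)
  s[summary_df$pct_exp[i] > min_pct & summary_df$avg_log2fc[i] > min_fc]
}

# Per-pixel loop for masked mean intensity.
oracle_masked_mean <- function(mask_img, target_img, line_limit = 1250) {
  nr <- min(line_limit, nrow(mask_img))
  tot <- 0
  npx <- 0
  thr_sum <- 0
  for (i in seq_len(nr)) for (j in seq_len(ncol(mask_img))) {
    thr_sum <- thr_sum + mask_img[i, j]
  }
  thr <- 0.5 * thr_sum / (nr * ncol(mask_img))
  for (i in seq_len(nr)) for (j in seq_len(ncol(mask_img))) {
    if (mask_img[i, j] >= thr) {
      tot <- tot + target_img[i, j]
      npx <- npx + 1
    }
  }
  if (npx == 0) NA_real_ else tot / npx
}

# Per-pixel 2D Gaussian convolution with replicate padding, 3-sigma
# truncation (matches the stated smoothing contract, computed naively).
oracle_gaussian <- function(x, sigma) {
  r <- ceiling(3 * sigma)
  off <- -r:r
  k1 <- exp(-off^2 / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  out <- x * 0
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
    acc <- 0
    for (a in seq_along(off)) for (b in seq_along(off)) {
      ii <- min(max(i + off[a], 1), nrow(x))
      jj <- min(max(j + off[b], 1), ncol(x))
      acc <- acc + k2[a, b] * x[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}

# BFS 8-connected labeling.
oracle_label <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      queue <- list(c(i, j))
      lab[i, j] <- cur
      while (length(queue) > 0) {
        p <- queue[[1]]; queue <- queue[-1]
        for (di in -1:1) for (dj in -1:1) {
          ii <- p[1] + di; jj <- p[2] + dj
          if (ii >= 1 && ii <= nrow(mask) && jj >= 1 && jj <= ncol(mask) &&
              mask[ii, jj] && lab[ii, jj] == 0L) {
            lab[ii, jj] <- cur
            queue[[length(queue) + 1]] <- c(ii, jj)
          }
        }
      }
    }
  }
  lab
}

# Per-base brute-force weighted copy ratio for one target.
oracle_weighted_ratio <- function(segments, chrom, start, end) {
  vals <- numeric()
  for (b in start:(end - 1)) {
    hit <- which(segments$chrom == chrom & segments$start <= b &
                   segments$end > b)
    if (length(hit) == 1) vals <- c(vals, segments$copy_ratio[hit])
  }
  if (length(vals) == 0) NA_real_ else mean(vals)
}
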