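# Differential expression/accessibility tests and the staged filters that
# yield lineage-specific genes, lineage-specific TF motifs and tumor
# cell-surface markers.
#
# Epithelial group labels used throughout: tumor_Basal, tumor_Her2,
# tumor_LumA, tumor_LumB (or the pooled tumor_Luminal), LP, LM, BP.

# Percent of cells with nonzero expression.
pct_expressing <- function(x) 100 * rowMeans(x > 0)

# Seurat-style average log2 fold change on log1p-normalized expression.
avg_log2fc <- function(xa, xb) {
  log2(rowMeans(expm1(xa)) + 1) - log2(rowMeans(expm1(xb)) + 1)
}

# Likelihood-ratio test of a binomial regression of group label on gene
# expression (+ optional covariates) against the covariates-only null.
# The null fit does not involve the gene, so it is fitted once.
logistic_lrt_p <- function(expr_a, expr_b, latent_a = NULL, latent_b = NULL) {
  y <- c(rep(1L, ncol(expr_a)), rep(0L, ncol(expr_b)))
  covar <- if (is.null(latent_a)) NULL else c(latent_a, latent_b)
  null_dev <- if (is.null(covar)) {
    stats::glm(y ~ 1, family = stats::binomial())$deviance
  } else {
    stats::glm(y ~ covar, family = stats::binomial())$deviance
  }
  vapply(seq_len(nrow(expr_a)), function(i) {
    g <- c(expr_a[i, ], expr_b[i, ])
    fit <- if (is.null(covar)) {
      stats::glm(y ~ g, family = stats::binomial())
    } else {
      stats::glm(y ~ g + covar, family = stats::binomial())
    }
    stats::pchisq(max(null_dev - fit$deviance, 0), df = 1,
                  lower.tail = FALSE)
  }, numeric(1))
}

#' Differential expression between two cell groups
#'
#' Genes failing the expressing-fraction (`min_pct`) or log-fold-change
#' prefilters are excluded before testing; surviving genes are tested by
#' a two-sided Wilcoxon rank-sum test or a logistic-regression
#' likelihood-ratio test (group label ~ expression + covariates vs the
#' covariates-only null). P values are Bonferroni-adjusted over the
#' tested genes.
#'
#' @param expr Gene x cell matrix of log1p-normalized expression.
#' @param cells_a,cells_b Column names (or indices) of the two groups.
#' @param test "wilcoxon" or "logistic_lrt".
#' @param min_pct Minimum expressing fraction required in at least one
#'   group (0-1 scale; default 0.1).
#' @param logfc_threshold Minimum |avg_log2fc| to test (default 0.2).
#' @param only_pos Keep only genes up in group A (default TRUE).
#' @param min_diff_pct Minimum |pct1 - pct2| difference in expressing
#'   fractions (0-1 scale; default 0 = off).
#' @param latent Optional named per-cell covariate (e.g. fraction of
#'   fragments in peaks) used by the logistic test.
#'
#' @return data.frame `gene`, `avg_log2fc`, `pct1`, `pct2` (percent),
#'   `p`, `padj` for the tested genes.
#' @export
differential_expression <- function(expr, cells_a, cells_b,
                                    test = c("wilcoxon", "logistic_lrt"),
                                    min_pct = 0.1, logfc_threshold = 0.2,
                                    only_pos = TRUE, min_diff_pct = 0,
                                    latent = NULL) {
  test <- match.arg(test)
  xa <- expr[, cells_a, drop = FALSE]
  xb <- expr[, cells_b, drop = FALSE]
  check(ncol(xa) >= 3 && ncol(xb) >= 3,
        "each group needs at least 3 cells (got %d and %d)",
        ncol(xa), ncol(xb))
  pct1 <- pct_expressing(xa)
  pct2 <- pct_expressing(xb)
  fc <- avg_log2fc(xa, xb)
  keep <- pmax(pct1, pct2) >= 100 * min_pct
  keep <- keep & (abs(pct1 - pct2) >= 100 * min_diff_pct)
  keep <- keep & if (only_pos) fc >= logfc_threshold else
    abs(fc) >= logfc_threshold
  genes <- rownames(expr)[keep]
  if (length(genes) == 0L) {
    return(data.frame(gene = character(), avg_log2fc = numeric(),
                      pct1 = numeric(), pct2 = numeric(), p = numeric(),
                      padj = numeric(), stringsAsFactors = FALSE))
  }
  xa <- xa[genes, , drop = FALSE]
  xb <- xb[genes, , drop = FALSE]
  p <- if (test == "wilcoxon") {
    vapply(genes, function(g)
      suppressWarnings(stats::wilcox.test(xa[g, ], xb[g, ])$p.value),
      numeric(1))
  } else {
    la <- if (is.null(latent)) NULL else latent[colnames(xa)]
    lb <- if (is.null(latent)) NULL else latent[colnames(xb)]
    logistic_lrt_p(xa, xb, la, lb)
  }
  data.frame(gene = genes, avg_log2fc = fc[keep], pct1 = pct1[keep],
             pct2 = pct2[keep], p = unname(p),
             padj = pmin(1, unname(p) * length(genes)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Differential chromatin accessibility between two cell groups
#'
#' Logistic-regression likelihood-ratio test with the per-cell fraction
#' of fragments in peaks as a latent covariate (absorbing depth
#' differences), prefiltered at `min_pct = 0.1` and
#' `min_diff_pct = 0.1`, Bonferroni-adjusted; both directions are
#' reported.
#'
#' @param peak_counts Peak x cell accessibility matrix (counts or
#'   binarized).
#' @param cells_a,cells_b Cell groups.
#' @param latent Named per-cell fraction-of-fragments-in-peaks covariate.
#' @param min_pct,min_diff_pct Prefilters (0-1 scale).
#' @param padj_cutoff Significance threshold recorded in `significant`.
#'
#' @return data.frame as [differential_expression()] plus `significant`.
#' @export
differential_accessibility <- function(peak_counts, cells_a, cells_b, latent,
                                       min_pct = 0.1, min_diff_pct = 0.1,
                                       padj_cutoff = 0.05) {
  res <- differential_expression(peak_counts, cells_a, cells_b,
                                 test = "logistic_lrt", min_pct = min_pct,
                                 logfc_threshold = 0, only_pos = FALSE,
                                 min_diff_pct = min_diff_pct,
                                 latent = latent)
  res$significant <- res$padj < padj_cutoff
  res
}

# Turn a DEG result (or a plain character vector) into a significant gene
# set.
deg_set <- function(x, padj_cutoff) {
  if (is.character(x)) return(x)
  if (is.null(x)) stop("missing comparison set", call. = FALSE)
  need_cols(x, c("gene", "padj"), "DEG table")
  x$gene[x$padj < padj_cutoff]
}

#' Staged set-algebra filter for lineage-specific genes
#'
#' Starting from the lineage-group-vs-other-epithelial DEGs (G1 for the
#' basal branch, G2 for the luminal branch), removes intra-lineage DEGs
#' (C1: basal tumor vs LP; C2: luminal A/B tumors vs LM), removes the
#' opposite lineage group's DEGs, requires membership in the lineage's
#' one-vs-rest marker sets (A1) and absence from every other group's
#' one-vs-rest set, then applies a final expression screen
#' (`pct.exp > 20` and `avg_log2fc > 1`). Survivors are labeled
#' progenitor-high / tumor-high / shared from their A1 provenance.
#'
#' @param cmp List with elements `G1`, `G2`, `C1`, `C2` (DEG data.frames
#'   or gene character vectors; `G3` is accepted and ignored) and `A1`, a
#'   named list of one-vs-rest DEG results keyed by epithelial group
#'   (tumor_Basal, tumor_Her2, tumor_LumA, tumor_LumB, LP, LM, BP).
#' @param lineage "basal" or "luminal".
#' @param expr_summary data.frame `gene`, `pct_exp` (percent expressing in
#'   the lineage group), `avg_log2fc` (lineage group vs other epithelial).
#' @param padj_cutoff Significance threshold for the comparison sets.
#' @param min_pct_exp,min_fc Final screen thresholds (defaults 20, 1).
#' @param literal_luminal Reproduce the literal printed procedure for the
#'   luminal branch (start from G1 and remove G1, which empties the set);
#'   default FALSE uses the symmetric G2-based branch.
#'
#' @return data.frame `gene`, `category`
#'   ("progenitor-high"/"tumor-high"/"shared").
#' @export
lineage_deg_filter <- function(cmp, lineage = c("basal", "luminal"),
                               expr_summary, padj_cutoff = 0.05,
                               min_pct_exp = 20, min_fc = 1,
                               literal_luminal = FALSE) {
  lineage <- match.arg(lineage)
  for (nm in c("G1", "G2", "C1", "C2", "A1")) {
    if (is.null(cmp[[nm]])) {
      stop(sprintf("missing comparison set: %s", nm), call. = FALSE)
    }
  }
  a1 <- lapply(cmp$A1, deg_set, padj_cutoff = padj_cutoff)
  g1 <- deg_set(cmp$G1, padj_cutoff)
  g2 <- deg_set(cmp$G2, padj_cutoff)
  c12 <- union(deg_set(cmp$C1, padj_cutoff), deg_set(cmp$C2, padj_cutoff))
  need_a1 <- function(gr) {
    check(gr %in% names(a1), "A1 is missing group %s", gr)
    a1[[gr]]
  }
  if (lineage == "basal") {
    start <- g1
    other <- g2
    tumor_sets <- "tumor_Basal"
    origin <- "LP"
    excl_groups <- c("tumor_LumA", "tumor_LumB", "tumor_Her2", "BP", "LM")
  } else {
    start <- if (literal_luminal) g1 else g2
    other <- g1
    tumor_sets <- c("tumor_LumA", "tumor_LumB")
    origin <- "LM"
    excl_groups <- c("tumor_Her2", "BP", "tumor_Basal")
  }
  s <- setdiff(start, c12)
  s <- setdiff(s, other)
  in_tumor <- s %in% unique(unlist(lapply(tumor_sets, need_a1)))
  in_origin <- s %in% need_a1(origin)
  s_keep <- in_tumor | in_origin
  s <- s[s_keep]; in_tumor <- in_tumor[s_keep]; in_origin <- in_origin[s_keep]
  excl <- unique(unlist(lapply(excl_groups, need_a1)))
  keep2 <- !(s %in% excl)
  s <- s[keep2]; in_tumor <- in_tumor[keep2]; in_origin <- in_origin[keep2]
  need_cols(expr_summary, c("gene", "pct_exp", "avg_log2fc"), "expr_summary")
  idx <- match(s, expr_summary$gene)
  check(!anyNA(idx), "expr_summary missing gene(s): %s",
        paste(utils::head(s[is.na(idx)], 5), collapse = ", "))
  pass <- expr_summary$pct_exp[idx] > min_pct_exp &
    expr_summary$avg_log2fc[idx] > min_fc
  s <- s[pass]; in_tumor <- in_tumor[pass]; in_origin <- in_origin[pass]
  category <- ifelse(in_tumor & in_origin, "shared",
              ifelse(in_tumor, "tumor-high", "progenitor-high"))
  data.frame(gene = s, category = category, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Run the full lineage DEG comparison set and staged filters
#'
#' Composes the comparisons the staged filter consumes — G1
#' ({basal tumor, LP} vs other epithelial), G2 ({luminal A/B tumors, LM}
#' vs rest), G3 ({LP, LM} vs rest; computed and exposed but not consumed
#' by the filters), C1 (basal tumor vs LP), C2 (luminal tumors vs LM)
#' and A1 (each group one-vs-rest) — then applies
#' [lineage_deg_filter()] for both lineages.
#'
#' @param expr Gene x cell log1p expression matrix.
#' @param cell_groups Named vector cell -> epithelial group
#'   (tumor_Basal, tumor_Her2, tumor_LumA, tumor_LumB, LP, LM, BP).
#' @param test Test passed to [differential_expression()].
#' @param exclude_genes Genes dropped from the analysis space (e.g. the
#'   subtyping assay panel, which is designed to separate subtypes and
#'   would otherwise surface as incidental lineage markers).
#' @param padj_cutoff,min_pct_exp,min_fc Filter thresholds, see
#'   [lineage_deg_filter()].
#'
#' @return List with `comparisons` (G1..A1), `summaries` (per lineage)
#'   and `basal`, `luminal` (the survivor tables).
#' @export
run_lineage_deg_workflow <- function(expr, cell_groups,
                                     test = "logistic_lrt",
                                     exclude_genes = NULL,
                                     padj_cutoff = 0.05, min_pct_exp = 20,
                                     min_fc = 1) {
  if (!is.null(exclude_genes)) {
    expr <- expr[setdiff(rownames(expr), exclude_genes), , drop = FALSE]
  }
  cells <- colnames(expr)
  check(all(cells %in% names(cell_groups)),
        "cell_groups must cover every cell")
  grp <- cell_groups[cells]
  groups <- unique(grp)
  of <- function(g) cells[grp %in% g]
  de <- function(a, b) differential_expression(expr, of(a), of(b),
                                               test = test)
  lin_groups <- list(basal = c("tumor_Basal", "LP"),
                     luminal = c("tumor_LumA", "tumor_LumB", "LM"))
  cmp <- list(
    G1 = de(lin_groups$basal, setdiff(groups, lin_groups$basal)),
    G2 = de(lin_groups$luminal, setdiff(groups, lin_groups$luminal)),
    G3 = de(c("LP", "LM"), setdiff(groups, c("LP", "LM"))),
    C1 = de("tumor_Basal", "LP"),
    C2 = de(c("tumor_LumA", "tumor_LumB"), "LM"),
    A1 = lapply(stats::setNames(groups, groups),
                function(g) de(g, setdiff(groups, g)))
  )
  summarize <- function(g) {
    xa <- expr[, of(g), drop = FALSE]
    xb <- expr[, of(setdiff(groups, g)), drop = FALSE]
    data.frame(gene = rownames(expr), pct_exp = pct_expressing(xa),
               avg_log2fc = avg_log2fc(xa, xb),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  summaries <- lapply(lin_groups, summarize)
  list(comparisons = cmp, summaries = summaries,
       basal = lineage_deg_filter(cmp, "basal", summaries$basal,
                                  padj_cutoff, min_pct_exp, min_fc),
       luminal = lineage_deg_filter(cmp, "luminal", summaries$luminal,
                                    padj_cutoff, min_pct_exp, min_fc))
}

#' Differential TF motif activity between two cell groups
#'
#' Per-TF two-sided Wilcoxon rank-sum test on motif deviation scores with
#' Benjamini-Hochberg adjustment across all TFs in the assay.
#'
#' @param motif_matrix TF x cell deviation-score matrix.
#' @param cells_a,cells_b Cell groups.
#'
#' @return data.frame `tf`, `mean_a`, `mean_b`, `mean_diff`, `p`, `fdr`.
#' @export
differential_motif <- function(motif_matrix, cells_a, cells_b) {
  xa <- motif_matrix[, cells_a, drop = FALSE]
  xb <- motif_matrix[, cells_b, drop = FALSE]
  check(ncol(xa) >= 2 && ncol(xb) >= 2, "each group needs >= 2 cells")
  p <- vapply(seq_len(nrow(xa)), function(i)
    suppressWarnings(stats::wilcox.test(xa[i, ], xb[i, ])$p.value),
    numeric(1))
  data.frame(tf = rownames(motif_matrix),
             mean_a = rowMeans(xa), mean_b = rowMeans(xb),
             mean_diff = rowMeans(xa) - rowMeans(xb),
             p = p, fdr = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Significantly enriched TFs (positive mean difference) from a
# differential_motif result.
enriched_tfs <- function(res, fdr_cutoff, min_diff = 0) {
  res$tf[res$fdr < fdr_cutoff & res$mean_diff > 0 &
           res$mean_diff >= min_diff]
}

#' Staged filter for lineage-specific TF motifs
#'
#' Step 1: for each lineage, tests tumor + putative cell of origin
#' against all other epithelial groups and keeps TFs enriched at
#' `fdr < 0.05` with positive mean difference. Step 2: removes TFs
#' enriched in BOTH tumor-vs-origin comparisons (basal BC vs LP and
#' luminal BC vs LM) as cancer-associated rather than lineage-specific.
#' Step 3: runs each single group against all other epithelial cells and
#' removes candidates significantly enriched in a non-lineage group with
#' mean score difference >= `min_nonlineage_diff` (default 0.5).
#' Subtype-specific TF sets additionally require a positive RNA fold
#' change for that subtype versus pooled other subtypes.
#'
#' @param motif_matrix TF x cell deviation-score matrix.
#' @param cell_groups Named vector cell -> epithelial group; expected
#'   groups `tumor_Basal`, `tumor_Her2`, `tumor_Luminal`, `LM`, `LP`,
#'   `BP` (a missing tumor_Her2 is tolerated).
#' @param fdr_cutoff Step significance level (default 0.05).
#' @param min_nonlineage_diff Step-3 exclusion boundary (default 0.5).
#' @param rna_fc Optional TF x subtype matrix of RNA fold changes (each
#'   subtype vs pooled others); when given, per-subtype TF sets are
#'   returned for the tumor groups present.
#'
#' @return List with `basal`, `luminal` (character TF sets), optional
#'   `subtype` (named list) and `details` (the step results).
#' @export
lineage_motif_filter <- function(motif_matrix, cell_groups,
                                 fdr_cutoff = 0.05,
                                 min_nonlineage_diff = 0.5, rna_fc = NULL) {
  cells <- colnames(motif_matrix)
  check(all(cells %in% names(cell_groups)),
        "cell_groups must cover every cell")
  grp <- cell_groups[cells]
  groups <- unique(grp)
  lineages <- list(
    basal = list(members = c("tumor_Basal", "LP"), origin = "LP",
                 tumor = "tumor_Basal"),
    luminal = list(members = c("tumor_Luminal", "LM"), origin = "LM",
                   tumor = "tumor_Luminal")
  )
  of <- function(g) cells[grp %in% g]

  # step 1: lineage (tumor + origin) vs all other epithelial groups
  step1 <- lapply(lineages, function(ln) {
    differential_motif(motif_matrix, of(ln$members),
                       of(setdiff(groups, ln$members)))
  })
  cand <- lapply(step1, enriched_tfs, fdr_cutoff = fdr_cutoff)

  # step 2: drop TFs enriched in both tumor-vs-origin comparisons
  tumor_vs_origin <- lapply(lineages, function(ln) {
    differential_motif(motif_matrix, of(ln$tumor), of(ln$origin))
  })
  both <- Reduce(intersect, lapply(tumor_vs_origin, enriched_tfs,
                                   fdr_cutoff = fdr_cutoff))
  cand <- lapply(cand, setdiff, y = both)

  # step 3: each single group vs all other epithelial cells
  single <- lapply(stats::setNames(groups, groups), function(g) {
    differential_motif(motif_matrix, of(g), of(setdiff(groups, g)))
  })
  for (lname in names(cand)) {
    nonlineage <- setdiff(groups, lineages[[lname]]$members)
    excl <- unique(unlist(lapply(single[nonlineage], enriched_tfs,
                                 fdr_cutoff = fdr_cutoff,
                                 min_diff = min_nonlineage_diff)))
    cand[[lname]] <- setdiff(cand[[lname]], excl)
  }

  out <- list(basal = cand$basal, luminal = cand$luminal,
              details = list(step1 = step1,
                             tumor_vs_origin = tumor_vs_origin,
                             single = single))
  if (!is.null(rna_fc)) {
    tumor_groups <- grep("^tumor_", groups, value = TRUE)
    out$subtype <- lapply(stats::setNames(tumor_groups, tumor_groups),
                          function(g) {
      tfs <- enriched_tfs(single[[g]], fdr_cutoff)
      sub <- sub("^tumor_", "", g)
      if (!sub %in% colnames(rna_fc)) return(character())
      tfs <- intersect(tfs, rownames(rna_fc))
      tfs[rna_fc[tfs, sub] > 0]
    })
  }
  out
}

#' Screen for tumor cell-surface markers across samples
#'
#' A gene is called a tumor surface marker iff (1) in at least one sample
#' its expression is higher in tumor cells than in every other cell type
#' present, all pairwise differences significant (log fold change > 0,
#' adjusted p < `padj_cutoff`); (2) tumor exceeds the combined non-tumor
#' population in at least `frac_higher` of samples, significantly in at
#' least `frac_signif` of samples; and (3) the gene is annotated as cell
#' surface.
#'
#' @param per_sample_deg Named list (one element per sample), each a list
#'   with `pairwise` (data.frame `gene`, `other_type`, `avg_log2fc`,
#'   `padj`: tumor vs each other cell type) and `combined` (data.frame
#'   `gene`, `avg_log2fc`, `padj`: tumor vs combined non-tumor; NULL when
#'   the sample has no non-tumor cells).
#' @param surface_genes Character vector (union of the surface-annotation
#'   gene lists).
#' @param frac_higher,frac_signif Cohort fractions (defaults 0.90, 0.75).
#' @param padj_cutoff Significance threshold (default 0.05).
#'
#' @return data.frame `gene`, `n_samples_higher`, `n_samples_signif`,
#'   `n_samples` for the surviving markers.
#' @export
surface_marker_call <- function(per_sample_deg, surface_genes,
                                frac_higher = 0.90, frac_signif = 0.75,
                                padj_cutoff = 0.05) {
  usable <- Filter(function(s) !is.null(s$combined), per_sample_deg)
  if (length(usable) < length(per_sample_deg)) {
    warning(sprintf("%d sample(s) with no non-tumor cells excluded",
                    length(per_sample_deg) - length(usable)))
  }
  check(length(usable) > 0, "no usable samples")
  genes <- sort(unique(unlist(lapply(usable, function(s) s$combined$gene))))

  crit1 <- vapply(genes, function(g) {
    any(vapply(usable, function(s) {
      pw <- s$pairwise[s$pairwise$gene == g, , drop = FALSE]
      types <- unique(s$pairwise$other_type)
      nrow(pw) == length(types) && length(types) > 0 &&
        all(pw$avg_log2fc > 0 & pw$padj < padj_cutoff)
    }, logical(1)))
  }, logical(1))

  higher <- vapply(genes, function(g) {
    sum(vapply(usable, function(s) {
      cb <- s$combined[s$combined$gene == g, , drop = FALSE]
      nrow(cb) == 1 && cb$avg_log2fc > 0
    }, logical(1)))
  }, integer(1))
  signif_n <- vapply(genes, function(g) {
    sum(vapply(usable, function(s) {
      cb <- s$combined[s$combined$gene == g, , drop = FALSE]
      nrow(cb) == 1 && cb$avg_log2fc > 0 && cb$padj < padj_cutoff
    }, logical(1)))
  }, integer(1))
  n <- length(usable)
  crit2 <- higher >= frac_higher * n & signif_n >= frac_signif * n
  keep <- crit1 & crit2 & genes %in% surface_genes
  data.frame(gene = genes[keep], n_samples_higher = higher[keep],
             n_samples_signif = signif_n[keep],
             n_samples = rep(n, sum(keep)),
             stringsAsFactors = FALSE, row.names = NULL)
}
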