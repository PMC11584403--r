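#' Upper-quartile FPKM normalization with log2 transform
#'
#' Converts raw counts to FPKM-UQ: `count * 1e9 / (U * L)` where `U` is the
#' sample's 75th percentile of nonzero protein-coding counts and `L` the
#' gene length in bases, then (by default) applies `log2(x + 1)`.
#'
#' @param counts Gene x sample matrix of raw counts.
#' @param gene_lengths Named numeric vector of gene lengths (bases),
#'   covering all genes; must be positive.
#' @param protein_coding Optional character vector of protein-coding gene
#'   ids used for the upper-quartile; defaults to all genes.
#' @param log2p1 Apply log2(x + 1) after normalization (default TRUE).
#'
#' @return Matrix with the same dimensions as `counts`.
#' @export
fpkm_uq_normalize <- function(counts, gene_lengths, protein_coding = NULL,
                              log2p1 = TRUE) {
  check(is.matrix(counts), "counts must be a matrix")
  check(all(rownames(counts) %in% names(gene_lengths)),
        "gene_lengths must cover all genes")
  L <- gene_lengths[rownames(counts)]
  check(all(L > 0), "gene_lengths must be positive")
  pc <- if (is.null(protein_coding)) rownames(counts) else
    intersect(protein_coding, rownames(counts))
  check(length(pc) > 0, "no protein-coding genes present")
  out <- counts
  for (j in seq_len(ncol(counts))) {
    x <- counts[pc, j]
    x <- x[x > 0]
    check(length(x) > 0, "sample %s has no nonzero protein-coding counts",
          colnames(counts)[j] %||% j)
    U <- stats::quantile(x, 0.75, names = FALSE)
    check(U > 0, "degenerate sample %s: upper quartile is zero",
          colnames(counts)[j] %||% j)
    out[, j] <- counts[, j] * 1e9 / (U * L)
  }
  if (log2p1) out <- log2(out + 1)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Median-center a panel expression matrix
#'
#' Subtracts a per-gene reference median from each panel gene's row.
#' Non-panel genes in `expr` are dropped with a warning; panel genes absent
#' from `expr` raise an error unless `allow_missing = TRUE`, in which case
#' they are imputed at the supplied median (centering them to zero).
#'
#' @param expr Gene x entity expression matrix.
#' @param medians Named numeric vector of per-gene medians (the panel).
#' @param allow_missing Impute absent panel genes at their median.
#'
#' @return Centered matrix with rows exactly the panel genes.
#' @export
median_center <- function(expr, medians, allow_missing = FALSE) {
  check(is.matrix(expr), "expr must be a matrix")
  panel <- names(medians)
  extra <- setdiff(rownames(expr), panel)
  if (length(extra) > 0) {
    warning(sprintf("dropping %d non-panel gene(s)", length(extra)))
  }
  missing <- setdiff(panel, rownames(expr))
  if (length(missing) > 0 && !allow_missing) {
    stop(sprintf("panel gene(s) missing from expr: %s",
                 paste(utils::head(missing, 5), collapse = ", ")),
         call. = FALSE)
  }
  out <- matrix(0, nrow = length(panel), ncol = ncol(expr),
                dimnames = list(panel, colnames(expr)))
  present <- intersect(panel, rownames(expr))
  out[present, ] <- expr[present, , drop = FALSE] - medians[present]
  out
}

# Correlate centered profiles (panel x entities) with reference centroids.
# Returns a list(calls, correlations); constant (zero-variance) profiles get
# an NA call ("unclassifiable") rather than an arbitrary subtype.
centroid_correlations <- function(centered, ref, metric = "spearman") {
  x <- centered[ref$genes, , drop = FALSE]
  cors <- suppressWarnings(
    stats::cor(x, ref$centroids, method = metric))
  calls <- apply(cors, 1L, function(r) {
    if (all(is.na(r))) NA_character_ else ref$subtypes[which.max(r)]
  })
  list(calls = calls, correlations = cors)
}

#' Nearest-centroid subtype classification of one profile
#'
#' Assigns the subtype whose centroid has the highest rank (Spearman,
#' default) or Pearson correlation with the median-centered profile.
#'
#' @param profile Named numeric vector over the panel genes (centered).
#' @param ref A [pam50_reference()].
#' @param metric "spearman" (default) or "pearson".
#'
#' @return List with `subtype` (NA if the profile is constant, i.e.
#'   unclassifiable) and `correlations` (named per-subtype vector).
#' @export
classify_nearest_centroid <- function(profile, ref,
                                      metric = c("spearman", "pearson")) {
  metric <- match.arg(metric)
  check(all(ref$genes %in% names(profile)),
        "profile must cover all panel genes")
  m <- matrix(profile[ref$genes], ncol = 1,
              dimnames = list(ref$genes, "profile"))
  res <- centroid_correlations(m, ref, metric)
  list(subtype = unname(res$calls[1]), correlations = res$correlations[1, ])
}

#' Bootstrapped ER-balanced consensus subtyping
#'
#' Each iteration draws all ER-negative entities plus an equal-size uniform
#' subset (without replacement) of ER-positive entities, computes per-gene
#' panel medians over that subset, median-centers the full cohort with them
#' and classifies every entity. The final call is the modal subtype across
#' iterations; ties are broken by the subtype's mean correlation rank
#' across iterations (deterministic).
#'
#' @param expr Gene x entity expression matrix (uncentered, log scale).
#' @param er_status Named character vector entity -> "pos"/"neg".
#' @param ref A [pam50_reference()].
#' @param n_iter Number of bootstrap iterations (default 1000).
#' @param seed Optional RNG seed.
#' @param metric Correlation metric, see [classify_nearest_centroid()].
#' @param medians Optional fixed per-gene median vector. By default each
#'   iteration recomputes medians from its ER-balanced subset; supplying
#'   `medians` centers every iteration with this fixed vector instead
#'   (the ER subsets then only matter through it not at all), which
#'   reproduces pipelines that bootstrap a provided median table.
#'
#' @return data.frame with one row per entity: `entity`, `final`,
#'   `vote_fraction` (of the final call) plus attribute `calls`
#'   (iterations x entities matrix) and `votes` (entities x subtypes).
#' @export
bootstrap_consensus_subtype <- function(expr, er_status, ref, n_iter = 1000L,
                                        seed = NULL,
                                        metric = c("spearman", "pearson"),
                                        medians = NULL) {
  metric <- match.arg(metric)
  check(n_iter >= 1, "n_iter must be >= 1")
  ents <- colnames(expr)
  check(all(ents %in% names(er_status)),
        "er_status must cover every entity")
  er <- er_status[ents]
  neg <- ents[er == "neg"]
  pos <- ents[er == "pos"]
  if (length(neg) == 0L) {
    stop("no ER-negative entities: use plain medians via median_center()",
         call. = FALSE)
  }
  check(length(pos) >= length(neg),
        "fewer ER+ than ER- entities; cannot draw an equal-size ER+ subset")

  with_seed(seed, {
    calls <- matrix(NA_character_, nrow = n_iter, ncol = length(ents),
                    dimnames = list(NULL, ents))
    rank_sum <- matrix(0, nrow = length(ents), ncol = length(ref$subtypes),
                       dimnames = list(ents, ref$subtypes))
    for (it in seq_len(n_iter)) {
      subset <- c(neg, sample(pos, length(neg), replace = FALSE))
      med <- if (is.null(medians)) {
        row_medians(expr[ref$genes, subset, drop = FALSE])
      } else {
        medians[ref$genes]
      }
      centered <- expr[ref$genes, , drop = FALSE] - med
      res <- centroid_correlations(centered, ref, metric)
      calls[it, ] <- res$calls
      # rank 1 = highest correlation; used only for deterministic tie-breaks
      rk <- t(apply(-res$correlations, 1L, rank, ties.method = "average"))
      rk[is.na(res$correlations)] <- length(ref$subtypes)
      rank_sum <- rank_sum + rk
    }
    votes <- t(apply(calls, 2L, function(v)
      table(factor(v, levels = ref$subtypes))))
    final <- character(length(ents))
    vote_frac <- numeric(length(ents))
    for (i in seq_along(ents)) {
      v <- votes[i, ]
      if (sum(v) == 0L) { final[i] <- NA_character_; vote_frac[i] <- NA_real_; next }
      top <- names(v)[v == max(v)]
      if (length(top) > 1L) {
        top <- top[which.min(rank_sum[i, top])]
      }
      final[i] <- top
      vote_frac[i] <- v[top] / sum(v)
    }
    out <- data.frame(entity = ents, final = final,
                      vote_fraction = vote_frac, stringsAsFactors = FALSE)
    attr(out, "calls") <- calls
    attr(out, "votes") <- votes / pmax(rowSums(votes), 1L)
    out
  })
}

#' Cluster-level subtype assignment (no bootstrap)
#'
#' Averages panel-gene expression within each tumor-cell cluster, centers
#' the cluster means with a supplied median vector and classifies each
#' cluster mean once.
#'
#' @param tumor_expr Gene x cell expression matrix (tumor cells).
#' @param clusters Named vector cell -> cluster id.
#' @param ref A [pam50_reference()].
#' @param medians Per-gene medians for centering (defaults to
#'   `ref$medians`).
#' @param metric Correlation metric.
#'
#' @return data.frame cluster, subtype, plus attribute `correlations`.
#' @export
cluster_level_subtype <- function(tumor_expr, clusters, ref, medians = NULL,
                                  metric = c("spearman", "pearson")) {
  metric <- match.arg(metric)
  medians <- medians %||% ref$medians
  cells <- colnames(tumor_expr)
  check(all(cells %in% names(clusters)), "clusters must cover every cell")
  cl <- as.character(clusters[cells])
  ids <- unique(cl)
  sizes <- table(cl)
  check(all(sizes > 0), "empty cluster")
  means <- vapply(ids, function(k)
    rowMeans(tumor_expr[ref$genes, cl == k, drop = FALSE]),
    numeric(length(ref$genes)))
  rownames(means) <- ref$genes
  centered <- median_center(means, medians)
  res <- centroid_correlations(centered, ref, metric)
  out <- data.frame(cluster = ids, subtype = unname(res$calls),
                    stringsAsFactors = FALSE)
  attr(out, "correlations") <- res$correlations
  out
}

#' Read a centroid file
#'
#' Reads a tab-separated centroid table: first column (or rownames) gene
#' ids, one numeric column per subtype. This accepts both a plain TSV and
#' the published nearest-centroid training output layout.
#'
#' @param path File path.
#' @return A [pam50_reference()]; its median vector defaults to the
#'   per-gene row medians of the centroid table.
#' @export
read_centroids <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.numeric(df[[1]])) {
    rownames(df) <- df[[1]]
    df[[1]] <- NULL
  }
  num <- vapply(df, is.numeric, logical(1))
  m <- as.matrix(df[, num, drop = FALSE])
  pam50_reference(rownames(m), m, stats::setNames(row_medians(m), rownames(m)))
}
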