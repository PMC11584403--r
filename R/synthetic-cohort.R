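#' Breast cancer subtypes and benign duct cell types used throughout
#'
#' The five intrinsic expression subtypes and the three benign breast duct
#' epithelial populations (luminal progenitor, luminal mature,
#' basal/myoepithelial).
#'
#' @return Character vector of labels.
#' @export
bc_subtypes <- function() c("LumA", "LumB", "Her2", "Basal", "Normal")

#' @rdname bc_subtypes
#' @export
benign_cell_types <- function() c("LP", "LM", "BP")

#' Specification for a synthetic expression cohort
#'
#' Defines the study conditions a synthetic cohort is generated under:
#' cohort composition, panel size, the log2-scale separation between
#' subtype programs (`effect_size`) and the negative-binomial dispersion of
#' counts (`noise_dispersion`).
#'
#' @param n_samples Number of tumor samples.
#' @param subtype_mix Named integer vector, subtype -> number of samples;
#'   names must be a subset of [bc_subtypes()] and values must sum to
#'   `n_samples`.
#' @param cells_per_sample Entities generated per sample. With 1, each sample
#'   yields a single bulk-like tumor entity; with more, cells are split
#'   between tumor cells and the three benign duct cell types and
#'   lineage-marker programs are planted.
#' @param n_genes Total genes (panel genes first, then marker programs, then
#'   background genes).
#' @param panel_size Size of the subtyping panel (default 50).
#' @param effect_size Log2-scale separation of subtype/marker programs.
#' @param noise_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param markers_per_program Genes per planted marker program.
#' @param seed Integer RNG seed; generation is deterministic given the spec.
#'
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples, subtype_mix, cells_per_sample = 1L,
                        n_genes = 200L, panel_size = 50L, effect_size = 2,
                        noise_dispersion = 0.2, markers_per_program = 8L,
                        seed = 1L) {
  check(is.numeric(n_samples) && n_samples >= 1, "n_samples must be positive")
  check(!is.null(names(subtype_mix)), "subtype_mix must be named")
  unknown <- setdiff(names(subtype_mix), bc_subtypes())
  check(length(unknown) == 0L, "unknown subtype(s) in subtype_mix: %s",
        paste(unknown, collapse = ", "))
  check(all(subtype_mix >= 0) && sum(subtype_mix) == n_samples,
        "subtype_mix must be nonnegative and sum to n_samples")
  check(cells_per_sample >= 1, "cells_per_sample must be positive")
  check(panel_size <= n_genes, "panel_size must be <= n_genes")
  check(effect_size >= 0, "effect_size must be nonnegative")
  check(noise_dispersion > 0, "noise_dispersion must be positive")
  if (cells_per_sample > 1L) {
    check(n_genes >= panel_size + 7L * markers_per_program,
          "n_genes too small for panel plus 7 marker programs")
  }
  structure(list(n_samples = as.integer(n_samples),
                 subtype_mix = subtype_mix,
                 cells_per_sample = as.integer(cells_per_sample),
                 n_genes = as.integer(n_genes),
                 panel_size = as.integer(panel_size),
                 effect_size = effect_size,
                 noise_dispersion = noise_dispersion,
                 markers_per_program = as.integer(markers_per_program),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Subtyping reference: panel genes, per-subtype centroids, median vector
#'
#' @param genes Character vector of panel gene ids.
#' @param centroids Numeric matrix, panel genes x subtypes.
#' @param medians Named numeric vector of per-gene reference medians used
#'   for median adjustment.
#'
#' @return A list of class `pam50_ref`.
#' @export
pam50_reference <- function(genes, centroids, medians) {
  check(length(genes) == nrow(centroids),
        "centroids must have one row per panel gene")
  check(!anyDuplicated(colnames(centroids)), "subtype names must be unique")
  check(all(genes == rownames(centroids)),
        "centroid rownames must equal panel genes")
  check(all(genes %in% names(medians)), "medians must cover all panel genes")
  structure(list(genes = genes, centroids = centroids,
                 medians = medians[genes],
                 subtypes = colnames(centroids)),
            class = "pam50_ref")
}

# ER status is deterministic given subtype: luminal and normal-like ER+,
# basal-like and HER2-enriched ER-.
er_for_subtype <- function(subtype) {
  ifelse(subtype %in% c("LumA", "LumB", "Normal"), "pos", "neg")
}

#' Generate a subtype-structured synthetic expression cohort
#'
#' Counts are negative-binomial with log-linear means. Each tumor entity's
#' panel-gene program follows its subtype's centroid pattern scaled by
#' `effect_size`; benign duct cells (LP, LM, BP) carry their own panel
#' programs and, when cells are generated, distinct marker-gene programs
#' including shared tumor-origin lineage programs. The emitted reference
#' carries unit-scale centroids (independent of `effect_size`, so a
#' zero-effect cohort is classified at chance) and the cohort median vector.
#'
#' @param spec A [cohort_spec()].
#'
#' @return List of class `bc_cohort` with elements `counts` (genes x
#'   entities), `logexpr` (log2(count+1)), `entities` (annotation
#'   data.frame), `ref` ([pam50_reference()]) and `truth` (planted subtype
#'   per sample/entity, ER status, lineage gene sets and marker programs).
#' @export
generate_expression_cohort <- function(spec) {
  check(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  with_seed(spec$seed, {
    genes <- sprintf("gene%04d", seq_len(spec$n_genes))
    panel <- genes[seq_len(spec$panel_size)]
    subtypes <- bc_subtypes()

    base_log2 <- stats::runif(spec$n_genes, 2, 6)
    names(base_log2) <- genes

    # Unit-scale subtype patterns on the panel; effect_size scales how
    # strongly the data follows them, not the reference centroids.
    Z <- matrix(stats::rnorm(spec$panel_size * length(subtypes)),
                nrow = spec$panel_size,
                dimnames = list(panel, subtypes))
    # One shared benign-epithelial panel pattern: benign duct cell types are
    # distinguished by their marker programs, not by the subtyping panel, so
    # the panel does not create incidental lineage-specific genes.
    zb <- stats::rnorm(spec$panel_size)

    # Marker programs on the genes after the panel (cells mode only).
    programs <- list()
    if (spec$cells_per_sample > 1L) {
      m <- spec$markers_per_program
      prog_names <- c("shared_basal", "shared_luminal", "lp_only", "lm_only",
                      "bp_only", "tumor_shared", "her2_only")
      off <- spec$panel_size
      for (i in seq_along(prog_names)) {
        programs[[prog_names[i]]] <- genes[(off + (i - 1L) * m + 1L):(off + i * m)]
      }
    }
    # Which entity classes express each program at base + effect_size.
    program_groups <- list(
      shared_basal  = c("tumor_Basal", "LP"),
      shared_luminal = c("tumor_LumA", "tumor_LumB", "LM"),
      lp_only = "LP", lm_only = "LM", bp_only = "BP",
      tumor_shared = paste0("tumor_", subtypes),
      her2_only = "tumor_Her2"
    )

    sample_subtype <- rep(names(spec$subtype_mix), times = spec$subtype_mix)
    sample_subtype <- sample(sample_subtype)   # shuffle sample order
    sample_ids <- sprintf("S%03d", seq_len(spec$n_samples))

    ent <- list()
    for (s in seq_len(spec$n_samples)) {
      if (spec$cells_per_sample == 1L) {
        ent[[s]] <- data.frame(entity = sample_ids[s], sample = sample_ids[s],
                               cell_type = "tumor",
                               subtype = sample_subtype[s],
                               stringsAsFactors = FALSE)
      } else {
        n_tumor <- max(1L, ceiling(0.4 * spec$cells_per_sample))
        n_rest <- spec$cells_per_sample - n_tumor
        n_ben <- c(LP = n_rest %/% 3L, LM = n_rest %/% 3L,
                   BP = n_rest - 2L * (n_rest %/% 3L))
        ct <- c(rep("tumor", n_tumor),
                rep(names(n_ben), times = n_ben))
        ent[[s]] <- data.frame(
          entity = sprintf("%s_%s_%03d", sample_ids[s], ct,
                           seq_len(spec$cells_per_sample)),
          sample = sample_ids[s], cell_type = ct,
          subtype = ifelse(ct == "tumor", sample_subtype[s], NA_character_),
          stringsAsFactors = FALSE)
      }
    }
    entities <- do.call(rbind, ent)
    entities$er_status <- er_for_subtype(sample_subtype)[
      match(entities$sample, sample_ids)]
    # Epithelial group label used by lineage analyses.
    entities$group <- ifelse(entities$cell_type == "tumor",
                             paste0("tumor_", entities$subtype),
                             entities$cell_type)

    n_ent <- nrow(entities)
    mu_log2 <- matrix(rep(base_log2, n_ent), nrow = spec$n_genes,
                      dimnames = list(genes, entities$entity))
    tum <- entities$cell_type == "tumor"
    if (any(tum)) {
      mu_log2[panel, tum] <- mu_log2[panel, tum] +
        spec$effect_size * Z[, entities$subtype[tum], drop = FALSE]
    }
    ben <- entities$cell_type %in% benign_cell_types()
    if (any(ben)) {
      mu_log2[panel, ben] <- mu_log2[panel, ben] + spec$effect_size * zb
    }
    for (p in names(programs)) {
      idx <- entities$group %in% program_groups[[p]]
      if (any(idx)) {
        mu_log2[programs[[p]], idx] <- mu_log2[programs[[p]], idx] +
          spec$effect_size
      }
    }

    size <- 1 / spec$noise_dispersion
    counts <- matrix(stats::rnbinom(length(mu_log2), mu = 2^mu_log2,
                                    size = size),
                     nrow = spec$n_genes,
                     dimnames = dimnames(mu_log2))
    logexpr <- log2(counts + 1)

    centroids <- Z - row_medians(Z)
    tumor_log <- logexpr[panel, tum, drop = FALSE]
    medians <- if (any(tum)) row_medians(tumor_log) else
      stats::setNames(rep(0, spec$panel_size), panel)
    ref <- pam50_reference(panel, centroids, medians)

    truth <- list(
      sample_subtype = stats::setNames(sample_subtype, sample_ids),
      entity_subtype = stats::setNames(entities$subtype, entities$entity),
      entity_cell_type = stats::setNames(entities$cell_type, entities$entity),
      er_status = stats::setNames(er_for_subtype(sample_subtype), sample_ids),
      marker_programs = programs,
      lineage_genes = if (length(programs)) list(
        basal = c(programs$shared_basal, programs$lp_only),
        luminal = c(programs$shared_luminal, programs$lm_only)
      ) else list()
    )

    structure(list(counts = counts, logexpr = logexpr, entities = entities,
                   ref = ref, truth = truth, spec = spec),
              class = "bc_cohort")
  })
}

#' Pseudobulk tumor expression per sample
#'
#' Sums tumor-cell counts within each sample and returns log2(sum + 1),
#' the bulk-like input to cohort-level subtyping.
#'
#' @param cohort A `bc_cohort`.
#' @return Matrix genes x samples.
#' @export
pseudobulk_log2 <- function(cohort) {
  check(inherits(cohort, "bc_cohort"), "cohort must be a bc_cohort")
  tum <- cohort$entities$cell_type == "tumor"
  check(any(tum), "cohort has no tumor entities")
  samples <- unique(cohort$entities$sample[tum])
  out <- vapply(samples, function(s) {
    idx <- tum & cohort$entities$sample == s
    rowSums(cohort$counts[, idx, drop = FALSE])
  }, numeric(nrow(cohort$counts)))
  log2(out + 1)
}
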