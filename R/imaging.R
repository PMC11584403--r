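# Multiplex immunofluorescence quantifications: masked mean intensity,
# epithelial region-mask construction, per-region positive-cell fractions.
#
# A ChannelImage is a named list of equal-shape numeric matrices (one per
# channel), rows = image lines.

validate_image <- function(img) {
  check(is.list(img) && length(img) > 0 && !is.null(names(img)),
        "image must be a named list of channel matrices")
  dims <- vapply(img, dim, integer(2))
  check(all(dims[1, ] == dims[1, 1]) && all(dims[2, ] == dims[2, 1]),
        "all channels must share the same shape")
  invisible(img)
}

#' Masked mean intensity of a target channel
#'
#' Crops the image to its first `line_limit` rows, thresholds the mask
#' channel at half its cropped-image mean (pixel >= threshold is
#' positive), and returns the mean of the target channel over mask
#' pixels. The result is invariant to global rescaling of the mask
#' channel since the threshold scales with its mean.
#'
#' @param img Named list of channel matrices.
#' @param mask_channel,target_channel Channel names (e.g. "E_cadherin",
#'   "MELK").
#' @param line_limit Number of image lines retained (default 1250).
#'
#' @return Mean target intensity over the mask (NA with a warning when
#'   the mask is empty).
#' @export
masked_mean_intensity <- function(img, mask_channel, target_channel,
                                  line_limit = 1250L) {
  validate_image(img)
  check(mask_channel %in% names(img), "unknown mask channel %s", mask_channel)
  check(target_channel %in% names(img), "unknown target channel %s",
        target_channel)
  rows <- seq_len(min(line_limit, nrow(img[[1]])))
  m <- img[[mask_channel]][rows, , drop = FALSE]
  t <- img[[target_channel]][rows, , drop = FALSE]
  thr <- 0.5 * mean(m)
  mask <- m >= thr
  if (!any(mask)) {
    warning("empty mask; returning NA")
    return(NA_real_)
  }
  mean(t[mask])
}

# Separable Gaussian smoothing with replicate-edge padding and a kernel
# truncated at 3 sigma. The exact kernel is part of the mask contract so
# the operation is checkable against a direct per-pixel convolution.
gaussian_smooth <- function(x, sigma) {
  r <- ceiling(3 * sigma)
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  pad_idx <- function(n) pmin(pmax(seq(1 - r, n + r), 1L), n)
  # rows
  xp <- x[pad_idx(nrow(x)), , drop = FALSE]
  x1 <- vapply(seq_len(nrow(x)), function(i)
    as.numeric(k %*% xp[i:(i + 2L * r), , drop = FALSE]),
    numeric(ncol(x)))
  x1 <- t(x1)
  # columns
  xp <- x1[, pad_idx(ncol(x)), drop = FALSE]
  x2 <- vapply(seq_len(ncol(x)), function(j)
    as.numeric(xp[, j:(j + 2L * r), drop = FALSE] %*% k),
    numeric(nrow(x)))
  matrix(x2, nrow = nrow(x))
}

# 8-connected component labeling of a logical matrix; labels are assigned
# in raster order of each component's first pixel.
label_components <- function(mask) {
  n <- sum(mask)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (n == 0L) return(lab)
  idx <- which(mask)                      # column-major linear indices
  pos <- match(seq_len(length(mask)), idx)  # pixel -> vertex id
  nr <- nrow(mask)
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L
  edges <- list()
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- row + d[1]; c2 <- col + d[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(mask)
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    sel <- which(ok)[mask[nb]]
    if (length(sel)) {
      edges[[length(edges) + 1L]] <-
        cbind(seq_along(idx)[sel], pos[(col[sel] + d[2] - 1L) * nr +
                                         row[sel] + d[1]])
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges)) {
    e <- do.call(rbind, edges)
    g <- igraph::add_edges(g, t(e))
  }
  comp <- igraph::components(g)$membership
  # relabel by first appearance in raster (row-major) order
  ord <- order(row, col)
  relabel <- integer(max(comp))
  nxt <- 0L
  for (i in ord) {
    if (relabel[comp[i]] == 0L) {
      nxt <- nxt + 1L
      relabel[comp[i]] <- nxt
    }
  }
  lab[idx] <- relabel[comp]
  lab
}

#' Construct the labeled epithelial region mask
#'
#' Thresholds each epithelial channel (pixel >= threshold is positive),
#' merges them into a consensus mask by union, smooths the binary mask
#' with a Gaussian filter (sigma 2.0 by default), re-binarizes at 0.5,
#' fills holes and labels 8-connected components. Note the
#' smooth-and-rebinarize step acts as a curvature flow: a convex
#' boundary loses roughly a pixel of rim per application, so re-running
#' the construction on its own output preserves the region partition
#' but not every rim pixel.
#'
#' @param img Named list of channel matrices.
#' @param channels Channels entering the consensus mask (default panCK
#'   and E-cadherin).
#' @param thresholds Named numeric vector of per-channel positivity
#'   thresholds (set manually per image upstream).
#' @param sigma Gaussian smoothing sigma in pixels (default 2.0).
#'
#' @return Integer matrix of region labels (0 = background).
#' @export
epithelial_region_mask <- function(img, channels = c("panCK", "E_cadherin"),
                                   thresholds, sigma = 2.0) {
  validate_image(img)
  check(all(channels %in% names(img)), "missing channel(s): %s",
        paste(setdiff(channels, names(img)), collapse = ", "))
  check(all(channels %in% names(thresholds)),
        "thresholds must name every channel used")
  consensus <- Reduce(`|`, lapply(channels, function(ch)
    img[[ch]] >= thresholds[[ch]]))
  if (!any(consensus)) return(matrix(0L, nrow(consensus), ncol(consensus)))
  sm <- gaussian_smooth(consensus * 1, sigma) >= 0.5
  filled <- EBImage::fillHull(sm * 1) > 0
  label_components(filled)
}

#' Positive-cell fractions per region with sample-level averaging
#'
#' Computes the fraction of marker-positive cells within each region and
#' the unweighted mean of region fractions per sample. Regions with zero
#' cells are excluded with a warning.
#'
#' @param cells data.frame with columns `cell`, `sample`, `region` and a
#'   logical positivity column named by `marker` (e.g. `GATA3_pos`).
#' @param marker Name of the positivity column.
#'
#' @return List with `regions` (data.frame `sample`, `region`,
#'   `fraction`, `n_cells`) and `samples` (data.frame `sample`,
#'   `mean_fraction`, `n_regions`).
#' @export
positive_cell_fraction <- function(cells, marker) {
  need_cols(cells, c("cell", "sample", "region", marker), "cell table")
  check(is.logical(cells[[marker]]), "marker column must be logical")
  keyed <- paste(cells$sample, cells$region, sep = "\r")
  n <- tapply(cells[[marker]], keyed, length)
  pos <- tapply(cells[[marker]], keyed, sum)
  parts <- do.call(rbind, strsplit(names(n), "\r", fixed = TRUE))
  regions <- data.frame(sample = parts[, 1], region = parts[, 2],
                        fraction = as.numeric(pos) / as.numeric(n),
                        n_cells = as.integer(n), stringsAsFactors = FALSE,
                        row.names = NULL)
  empty <- regions$n_cells == 0
  if (any(empty)) {
    warning(sprintf("%d region(s) with zero cells excluded", sum(empty)))
    regions <- regions[!empty, , drop = FALSE]
  }
  mf <- tapply(regions$fraction, regions$sample, mean)
  nr <- tapply(regions$fraction, regions$sample, length)
  samples <- data.frame(sample = names(mf),
                        mean_fraction = as.numeric(mf),
                        n_regions = as.integer(nr),
                        stringsAsFactors = FALSE, row.names = NULL)
  list(regions = regions, samples = samples)
}
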