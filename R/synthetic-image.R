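# Synthetic multiplex images: duct-like annular structures with named
# marker channels and recorded truth masks.

#' Generate a duct-structured multichannel image
#'
#' Draws `n_ducts` ring (annulus) structures on a background and fills
#' each channel with its configured inside/outside intensity plus
#' optional Gaussian noise. The duct mask (and per-duct labels) is
#' recorded as ground truth.
#'
#' @param shape Integer c(rows, cols).
#' @param n_ducts Number of duct rings.
#' @param channel_means Named list; each element
#'   `c(inside = x, outside = y)` for channels such as `E_cadherin`,
#'   `MELK`, `panCK`, `SMA`.
#' @param noise_sd Gaussian noise SD added per pixel (0 = noiseless).
#' @param seed RNG seed.
#'
#' @return List with `channels` (named list of matrices), `truth_mask`
#'   (logical duct mask), `truth_labels` (integer per-duct labels) and
#'   `ducts` (geometry table).
#' @export
generate_image <- function(shape = c(256L, 256L), n_ducts = 3L,
                           channel_means = list(
                             E_cadherin = c(inside = 200, outside = 2),
                             MELK = c(inside = 120, outside = 1),
                             panCK = c(inside = 180, outside = 2),
                             SMA = c(inside = 40, outside = 15)),
                           noise_sd = 0, seed = 1L) {
  check(length(shape) == 2 && all(shape >= 32), "shape must be >= 32x32")
  with_seed(seed, {
    nr <- shape[1]; nc <- shape[2]
    rowm <- matrix(seq_len(nr), nr, nc)
    colm <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    labels <- matrix(0L, nr, nc)
    ducts <- data.frame()
    # rejection-sample duct centers so rings stay well separated (margin
    # wide enough that smoothing cannot bridge two ducts)
    margin <- 8
    for (d in seq_len(n_ducts)) {
      for (try in 1:200) {
        r_out <- stats::runif(1, 0.10, 0.16) * min(nr, nc)
        r_in <- r_out * stats::runif(1, 0.3, 0.5)
        cy <- stats::runif(1, r_out + 2, nr - r_out - 2)
        cx <- stats::runif(1, r_out + 2, nc - r_out - 2)
        ok <- nrow(ducts) == 0 ||
          all(sqrt((ducts$cy - cy)^2 + (ducts$cx - cx)^2) >
                ducts$r_out + r_out + margin)
        if (ok) break
      }
      check(ok, "could not place %d non-overlapping ducts", n_ducts)
      dist <- sqrt((rowm - cy)^2 + (colm - cx)^2)
      ring <- dist <= r_out & dist >= r_in
      labels[ring] <- d
      ducts <- rbind(ducts, data.frame(duct = d, cy = cy, cx = cx,
                                       r_in = r_in, r_out = r_out))
    }
    mask <- labels > 0L
    channels <- lapply(channel_means, function(mu) {
      img <- matrix(mu[["outside"]], nr, nc)
      img[mask] <- mu[["inside"]]
      if (noise_sd > 0) {
        img <- pmax(img + matrix(stats::rnorm(nr * nc, sd = noise_sd),
                                 nr, nc), 0)
      }
      img
    })
    list(channels = channels, truth_mask = mask, truth_labels = labels,
         ducts = ducts)
  })
}

#' Write / read a multichannel image as multi-page TIFF
#'
#' Pages are written in channel order; intensities are stored as 32-bit
#' floats scaled to [0, 1] by `scale` and restored on read.
#'
#' @param img Named list of channel matrices.
#' @param path TIFF file path.
#' @param scale Intensity divisor used to fit [0, 1] (default 65535).
#' @return `read_image_tiff` returns the named channel list.
#' @export
write_image_tiff <- function(img, path, scale = 65535) {
  validate_image(img)
  pages <- lapply(img, function(ch) ch / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  # channel names are not TIFF-native; store a sidecar
  writeLines(names(img), paste0(path, ".channels"))
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path, scale = 65535) {
  pages <- tiff::readTIFF(path, all = TRUE)
  nm <- if (file.exists(paste0(path, ".channels"))) {
    readLines(paste0(path, ".channels"))
  } else {
    sprintf("channel%02d", seq_along(pages))
  }
  stats::setNames(lapply(pages, function(p) p * scale), nm)
}
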