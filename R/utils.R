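# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# stopifnot with a formatted message
check <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}

# Require columns in a data.frame, naming the offender.
need_cols <- function(df, cols, what = "input") {
  miss <- setdiff(cols, names(df))
  check(length(miss) == 0L, "%s is missing column(s): %s", what,
        paste(miss, collapse = ", "))
  df
}

# Row medians of a numeric matrix.
row_medians <- function(x) apply(x, 1L, stats::median)

# Convert a 0-based half-open interval table to GRanges (1-based inclusive).
granges_from_bed <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# Convert 1-based point positions to width-1 GRanges.
granges_from_pos <- function(chrom, pos, width = 1L) {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = pos, width = width)
  )
}
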