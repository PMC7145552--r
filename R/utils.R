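# Internal helpers shared across modules.

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
withLocalSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Open a possibly gzipped text source. Returns a character vector of lines.
readTextLines <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con)
}

writeTextLines <- function(lines, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
}

# Build a width-1 GRanges from chrom/pos vectors (0-based positions).
summitGRanges <- function(chrom, pos, ...) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = pos + 1L, width = 1L), ...)
}

# 0-based half-open -> GRanges (1-based closed) conversion.
grFromHalfOpen <- function(chrom, start, end, ...) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start + 1L, end = end), ...)
}

# Centered moving average, truncated at the edges.
movingAverage <- function(x, width) {
  if (width <= 1L) return(x)
  n <- length(x)
  half <- (width - 1) %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + (width - 1L - half))
    v <- x[lo:hi]
    out[i] <- mean(v, na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  out
}

pkgWarn <- function(...) warning(sprintf(...), call. = FALSE)
pkgStop <- function(...) stop(sprintf(...), call. = FALSE)
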