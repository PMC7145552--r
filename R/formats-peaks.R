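#' Read ChIP-seq peak summits from a narrowPeak file
#'
#' Parses ENCODE narrowPeak (BED6+4). The summit of each peak is
#' \code{start + offset} (column 10, 0-based); an offset of \code{-1} falls
#' back to the interval midpoint with a warning. Returns width-1
#' \code{GRanges} with metadata \code{factor} and \code{score}.
#'
#' @param path path to a narrowPeak/BED file (may be gzipped).
#' @param factor label attached to every summit (e.g. \code{"ERa"}).
#' @return width-1 \code{GRanges} of summits (0-based positions are
#'   \code{start(gr) - 1}).
#' @export
readNarrowPeak <- function(path, factor) {
  lines <- readTextLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L)
    return(summitGRanges(character(), integer(), factor = character(), score = numeric()))
  f <- strsplit(lines, "\t")
  nf <- lengths(f)
  if (any(nf < 3L)) pkgStop("narrowPeak line %d has fewer than 3 fields", which(nf < 3L)[1])
  chrom <- vapply(f, `[`, "", 1L)
  start0 <- as.integer(vapply(f, `[`, "", 2L))
  end0 <- as.integer(vapply(f, `[`, "", 3L))
  score <- ifelse(nf >= 7L, suppressWarnings(as.numeric(vapply(f, function(x) x[7], ""))), NA_real_)
  off <- ifelse(nf >= 10L, suppressWarnings(as.integer(vapply(f, function(x) x[10], ""))), -1L)
  off[is.na(off)] <- -1L
  nofall <- off < 0L
  if (any(nofall))
    pkgWarn("readNarrowPeak: %d peaks without a summit offset; using interval midpoints",
            sum(nofall))
  pos <- ifelse(nofall, (start0 + end0) %/% 2L, start0 + off)
  summitGRanges(chrom, pos, factor = rep(factor, length(pos)),
                score = ifelse(is.na(score), 0, score))
}

#' Write summits as narrowPeak
#'
#' Each summit becomes a peak interval of \code{2 * halfWidth} bp centred on
#' the summit (clipped at position 0) with the summit offset in column 10.
#'
#' @param summits width-1 summit \code{GRanges} with \code{factor} and
#'   \code{score} metadata.
#' @param path output path.
#' @param halfWidth half-width of the emitted peak intervals.
#' @export
writeNarrowPeak <- function(summits, path, halfWidth = 50L) {
  pos <- GenomicRanges::start(summits) - 1L
  s0 <- pmax(0L, pos - halfWidth)
  e0 <- pos + halfWidth
  sc <- S4Vectors::mcols(summits)$score
  if (is.null(sc)) sc <- rep(0, length(summits))
  lines <- sprintf("%s\t%d\t%d\tpeak%d\t%d\t.\t%g\t-1\t-1\t%d",
                   as.character(GenomicRanges::seqnames(summits)),
                   s0, e0, seq_along(summits), 0L, sc, pos - s0)
  writeTextLines(lines, path)
}
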