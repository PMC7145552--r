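#' Read chromosome sizes into a GenomeIndex
#'
#' @param path two-column TSV of chromosome name and length.
#' @param exclude chromosome names to exclude from genome-wide fractions
#'   (e.g. \code{"chrY"}).
#' @return a [GenomeIndex-class].
#' @export
readGenomeIndex <- function(path, exclude = character()) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  GenomeIndex(stats::setNames(df$length, df$chrom),
              excluded = intersect(exclude, df$chrom))
}

#' Read JASPAR-format position frequency matrices
#'
#' Accepts the JASPAR text dialects: a \code{>name} header followed by four
#' rows, either bare counts or \code{A [ 1 2 3 ]} style. Counts are
#' normalized to per-position probabilities (plus \code{pseudocount}).
#'
#' @param path motif file path.
#' @param background background base probabilities (A, C, G, T).
#' @param pseudocount added to each count before normalization.
#' @return named list of [MotifPWM-class].
#' @export
readJasparPfm <- function(path, background = rep(0.25, 4), pseudocount = 0) {
  lines <- readTextLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  out <- list()
  for (i in seq_along(hdr)) {
    name <- sub("^>\\s*", "", lines[hdr[i]])
    name <- strsplit(name, "\\s+")[[1]][1]
    rows <- lines[(hdr[i] + 1L):(hdr[i] + 4L)]
    m <- do.call(rbind, lapply(rows, function(r) {
      r <- gsub("^\\s*[ACGTacgt]\\s*", "", r)
      r <- gsub("[][]", " ", r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    }))
    out[[name]] <- MotifPWM(name, m, background = background,
                            pseudocount = pseudocount)
  }
  out
}

#' Read MEME minimal motif format
#'
#' @param path MEME-format motif file.
#' @param pseudocount added per cell before renormalization.
#' @return named list of [MotifPWM-class].
#' @export
readMemeMotifs <- function(path, pseudocount = 0) {
  lines <- readTextLines(path)
  bg <- rep(0.25, 4)
  bgi <- grep("^Background letter frequencies", lines)
  if (length(bgi)) {
    f <- strsplit(trimws(lines[bgi[1] + 1L]), "\\s+")[[1]]
    bg <- as.numeric(f[c(2, 4, 6, 8)])
  }
  starts <- grep("^MOTIF\\b", lines)
  out <- list()
  for (s in starts) {
    name <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    li <- grep("^letter-probability matrix", lines[s:length(lines)])[1] + s - 1L
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[li]))
    rows <- lines[(li + 1L):(li + w)]
    m <- t(vapply(rows, function(r) as.numeric(strsplit(trimws(r), "\\s+")[[1]]),
                  numeric(4)))
    out[[name]] <- MotifPWM(name, t(m), background = bg, pseudocount = pseudocount)
  }
  out
}

#' Write PWMs in JASPAR text format
#'
#' @param pwms list of [MotifPWM-class]; probabilities are written scaled to
#'   counts of 100 per position.
#' @param path output path.
#' @export
writeJasparPfm <- function(pwms, path) {
  out <- character()
  for (p in pwms) {
    m <- round(p@matrix * 100, 4)
    out <- c(out, paste0(">", p@name),
             sprintf("%s [ %s ]", c("A", "C", "G", "T"),
                     apply(m, 1, function(r) paste(fmtNum(r), collapse = " "))))
  }
  writeTextLines(out, path)
}

#' Read a species tree in newick format
#'
#' Thin wrapper over [ape::read.tree()]; internal node labels name clades.
#'
#' @param path newick file path.
#' @return an \code{ape} \code{phylo} object.
#' @export
readSpeciesTree <- function(path) ape::read.tree(path)

#' Read a refFlat-like gene table
#'
#' Columns: geneName, name, chrom, strand, txStart, txEnd, cdsStart, cdsEnd,
#' exonCount, exonStarts, exonEnds (0-based half-open, comma-separated exon
#' lists). Returns a list with \code{tss} (width-1 GRanges of strand-aware
#' transcription start sites) and \code{cds} (reduced GRanges of
#' protein-coding bases: exons intersected with the CDS span).
#'
#' @param path gene table path.
#' @return list with elements \code{genes} (data.frame), \code{tss} and
#'   \code{cds} (GRanges).
#' @export
readGenes <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
    col.names = c("geneName", "name", "chrom", "strand", "txStart", "txEnd",
                  "cdsStart", "cdsEnd", "exonCount", "exonStarts", "exonEnds"),
    colClasses = c("character", "character", "character", "character",
                   "integer", "integer", "integer", "integer", "integer",
                   "character", "character"))
  tssPos <- ifelse(df$strand == "-", df$txEnd - 1L, df$txStart)
  tss <- summitGRanges(df$chrom, tssPos, gene = df$geneName)
  cdsList <- lapply(seq_len(nrow(df)), function(i) {
    es <- as.integer(strsplit(df$exonStarts[i], ",")[[1]])
    ee <- as.integer(strsplit(df$exonEnds[i], ",")[[1]])
    s <- pmax(es, df$cdsStart[i]); e <- pmin(ee, df$cdsEnd[i])
    k <- s < e
    if (!any(k)) return(NULL)
    data.frame(chrom = df$chrom[i], start = s[k], end = e[k])
  })
  cdsDf <- do.call(rbind, cdsList)
  cds <- if (is.null(cdsDf)) GenomicRanges::GRanges()
         else GenomicRanges::reduce(grFromHalfOpen(cdsDf$chrom, cdsDf$start, cdsDf$end))
  list(genes = df, tss = tss, cds = cds)
}

#' Write a refFlat-like gene table
#'
#' @param genes data.frame in the layout documented for [readGenes()].
#' @param path output path.
#' @export
writeGenes <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read conserved elements (phastCons-style BED with lod scores)
#'
#' @param path BED file whose name column carries \code{lod=NN}.
#' @return GRanges with an integer \code{lod} metadata column.
#' @export
readConservedElements <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          colClasses = c("character", "integer", "integer",
                                         "character", "numeric"))
  lod <- as.integer(sub(".*lod=(\\d+).*", "\\1", df[[4]]))
  grFromHalfOpen(df[[1]], df[[2]], df[[3]], lod = lod)
}

#' Read a chromatin-state segmentation BED
#'
#' @param path 4-column BED: chrom, start, end, state label.
#' @return GRanges with a \code{state} metadata column.
#' @export
readSegmentation <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          colClasses = c("character", "integer", "integer",
                                         "character"))
  grFromHalfOpen(df[[1]], df[[2]], df[[3]], state = df[[4]])
}

#' Write intervals as BED
#'
#' @param gr a GRanges; the \code{name} argument selects a metadata column
#'   for BED column 4.
#' @param path output path.
#' @param name optional metadata column for the name field.
#' @param score optional metadata column for the score field.
#' @export
writeBed <- function(gr, path, name = NULL, score = NULL) {
  nm <- if (!is.null(name)) as.character(S4Vectors::mcols(gr)[[name]]) else "."
  sc <- if (!is.null(score)) S4Vectors::mcols(gr)[[score]] else 0
  lines <- sprintf("%s\t%d\t%d\t%s\t%s",
                   as.character(GenomicRanges::seqnames(gr)),
                   GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr), nm,
                   fmtNum(sc))
  writeTextLines(lines, path)
}

#' Read a subfamily taxonomy table
#'
#' @param path TSV with columns subfamily, family, class.
#' @return data.frame.
#' @export
readTaxonomy <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", colClasses = "character")
}
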