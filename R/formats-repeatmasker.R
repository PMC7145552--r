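#' Read RepeatMasker .out annotation into a TE-copy GRanges
#'
#' Parses the whitespace-delimited RepeatMasker \code{.out} table (with or
#' without its three header lines) into a \code{GRanges} of TE copies with
#' metadata columns \code{subfamily}, \code{family}, \code{class} (one of
#' SINE, LINE, LTR, DNA, other), \code{divergence} (percent substitutions
#' from the consensus) and \code{copy_id}. RepeatMasker's 1-based inclusive
#' coordinates are converted to the package-wide 0-based half-open
#' convention on read; strand \code{C} becomes \code{-}.
#'
#' Satellite DNAs, simple repeats, low-complexity runs and small structural
#' RNAs are not transposable elements and are dropped; the number of dropped
#' records is reported via a message.
#'
#' @param path path to a \code{.out} file (may be gzipped).
#' @param taxonomy optional data.frame with columns \code{subfamily},
#'   \code{family}, \code{class} overriding the classification embedded in
#'   the \code{class/family} column. Subfamilies absent from the table fall
#'   back to the embedded classification; unknown classes become
#'   \code{"other"} with a warning.
#' @return a \code{GRanges} of TE copies.
#' @export
readRepeatMaskerOut <- function(path, taxonomy = NULL) {
  lines <- readTextLines(path)
  lines <- trimws(lines, which = "left")
  keep <- nzchar(lines) & grepl("^[0-9]", lines)
  lines <- lines[keep]
  if (length(lines) == 0L) return(emptyTeCopies())
  parts <- strsplit(lines, "\\s+")
  nf <- lengths(parts)
  bad <- which(nf < 14L)
  if (length(bad))
    pkgStop("malformed RepeatMasker .out record at data line %d: %d fields",
            bad[1], nf[bad[1]])
  m <- do.call(rbind, lapply(parts, function(p) p[1:15]))
  div <- as.numeric(m[, 2])
  chrom <- m[, 5]
  start1 <- as.integer(m[, 6])
  end1 <- as.integer(m[, 7])
  strand <- ifelse(m[, 9] %in% c("C", "-"), "-", "+")
  subfam <- m[, 10]
  clsfam <- m[, 11]
  id <- m[, 15]
  drop <- isNonTeClass(clsfam)
  nDropped <- sum(drop)
  if (nDropped > 0)
    message(sprintf("readRepeatMaskerOut: dropped %d satellite/simple-repeat/small-RNA records", nDropped))
  k <- !drop
  tax <- classifyRepeat(subfam[k], clsfam[k], taxonomy)
  gr <- grFromHalfOpen(chrom[k], start1[k] - 1L, end1[k],
                       strand = strand[k])
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    subfamily = subfam[k], family = tax$family, class = tax$class,
    divergence = div[k],
    copy_id = ifelse(is.na(id[k]) | id[k] == "", as.character(seq_len(sum(k))), id[k]))
  gr
}

emptyTeCopies <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    subfamily = character(), family = character(), class = character(),
    divergence = numeric(), copy_id = character())
  gr
}

# Classes excluded from TE analysis (not transposable elements).
isNonTeClass <- function(clsfam) {
  grepl("^(Satellite|Simple_repeat|Low_complexity|snRNA|tRNA|rRNA|scRNA|srpRNA|RNA)",
        clsfam)
}

TE_CLASSES <- c("SINE", "LINE", "LTR", "DNA")

classifyRepeat <- function(subfam, clsfam, taxonomy = NULL) {
  cls <- sub("/.*$", "", clsfam)
  fam <- ifelse(grepl("/", clsfam), sub("^[^/]*/", "", clsfam), clsfam)
  cls0 <- sub("\\?$", "", cls)
  known <- cls0 %in% TE_CLASSES
  cls0[!known] <- "other"
  if (!is.null(taxonomy)) {
    i <- match(subfam, taxonomy$subfamily)
    hit <- !is.na(i)
    fam[hit] <- taxonomy$family[i[hit]]
    cls0[hit] <- taxonomy$class[i[hit]]
    bad <- !(cls0 %in% c(TE_CLASSES, "other"))
    cls0[bad] <- "other"
  }
  if (any(cls0 == "other" & !is.null(taxonomy) & !(subfam %in% taxonomy$subfamily)))
    pkgWarn("classifyRepeat: %d subfamilies not in taxonomy, classified 'other'",
            sum(cls0 == "other" & !(subfam %in% taxonomy$subfamily)))
  list(family = fam, class = cls0)
}

#' Write TE copies as a RepeatMasker-style .out table
#'
#' Inverse of [readRepeatMaskerOut()]: emits one whitespace-delimited row per
#' copy with 1-based inclusive coordinates and strand \code{C} for minus.
#'
#' @param copies a TE-copy \code{GRanges} as returned by
#'   [readRepeatMaskerOut()].
#' @param path output path (gzipped if it ends in \code{.gz}).
#' @export
writeRepeatMaskerOut <- function(copies, path) {
  mc <- S4Vectors::mcols(copies)
  clsfam <- ifelse(mc$family == mc$class, mc$class,
                   paste0(mc$class, "/", mc$family))
  lines <- sprintf("%5d %5.1f %4.1f %4.1f %s %d %d (0) %s %s %s 1 %d (0) %s",
                   1000L, mc$divergence, 0, 0,
                   as.character(GenomicRanges::seqnames(copies)),
                   GenomicRanges::start(copies),  # GRanges is 1-based: matches .out
                   GenomicRanges::end(copies),
                   ifelse(as.character(GenomicRanges::strand(copies)) == "-", "C", "+"),
                   mc$subfamily, clsfam,
                   GenomicRanges::width(copies), mc$copy_id)
  writeTextLines(lines, path)
}

#' Read per-copy consensus alignments (.align dialect)
#'
#' Reads the pairwise genome-vs-consensus alignments that accompany a
#' RepeatMasker annotation and decomposes each into gapless blocks. The
#' accepted dialect is one record per copy:
#' \preformatted{
#' >align <copy_id> <chrom> <g_start1> <g_end1> <+|C> <consensus_name> <consensus_length>
#' <chrom> <s1> <gapped genome sequence> <e1>
#' <name>  <s1> <gapped consensus sequence> <e1>
#' ...            (further line pairs for long alignments)
#' }
#' Coordinates on sequence lines are 1-based inclusive. For minus-strand
#' (\code{C}) copies the genome runs forward and the consensus line carries
#' descending coordinates with reverse-complemented sequence; on read,
#' consensus block coordinates are normalized to consensus-forward
#' orientation so downstream binning is strand-agnostic.
#'
#' @param path path to an alignment file (may be gzipped).
#' @return a [CopyAlignments-class] object.
#' @export
readRepeatMaskerAlign <- function(path) {
  lines <- readTextLines(path)
  hdr <- grep("^>align\\b", lines)
  if (length(hdr) == 0L) return(CopyAlignments(emptyAlignBlocks()))
  ends <- c(hdr[-1] - 1L, length(lines))
  recs <- lapply(seq_along(hdr), function(i) {
    parseAlignRecord(lines[hdr[i]:ends[i]])
  })
  CopyAlignments(do.call(rbind, recs))
}

emptyAlignBlocks <- function() {
  data.frame(copy_id = character(), consensus_name = character(),
             strand = character(), consensus_length = integer(),
             chrom = character(), g_start = integer(), g_end = integer(),
             c_start = integer(), c_end = integer())
}

parseAlignRecord <- function(lines) {
  h <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  copy_id <- h[2]; chrom <- h[3]
  strand <- if (h[6] %in% c("C", "-")) "-" else "+"
  cname <- h[7]; clen <- as.integer(h[8])
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) %% 2L != 0L)
    pkgStop("alignment record for copy %s has an odd number of sequence lines", copy_id)
  gseq <- character(); cseq <- character()
  gpos0 <- NA_integer_; cpos0 <- NA_integer_
  for (i in seq(1L, length(body), by = 2L)) {
    gl <- strsplit(trimws(body[i]), "\\s+")[[1]]
    cl <- strsplit(trimws(body[i + 1]), "\\s+")[[1]]
    if (length(gl) < 4L || length(cl) < 4L)
      pkgStop("malformed alignment line in copy %s", copy_id)
    if (is.na(gpos0)) { gpos0 <- as.integer(gl[2]); cpos0 <- as.integer(cl[2]) }
    gseq <- c(gseq, gl[3]); cseq <- c(cseq, cl[3])
  }
  g <- strsplit(paste(gseq, collapse = ""), "")[[1]]
  cc <- strsplit(paste(cseq, collapse = ""), "")[[1]]
  if (length(g) != length(cc))
    pkgStop("alignment rows of copy %s differ in column count", copy_id)
  # fast path: ungapped alignment is a single block
  if (!any(g == "-") && !any(cc == "-")) {
    len <- length(g)
    cs <- if (strand == "+") cpos0 - 1L else cpos0 - len
    out <- data.frame(copy_id = copy_id, consensus_name = cname,
                      strand = strand, consensus_length = clen, chrom = chrom,
                      g_start = gpos0 - 1L, g_end = gpos0 - 1L + len,
                      c_start = cs, c_end = cs + len)
    if (out$c_end > clen)
      pkgStop("copy %s: reconstructed consensus span (%d) exceeds stated consensus length (%d)",
              copy_id, out$c_end, clen)
    return(out)
  }
  # Column walk: genome ascends; consensus ascends (+) or descends (-).
  gpos <- gpos0 - 1L                      # 0-based position of next genome base
  cstep <- if (strand == "+") 1L else -1L
  cpos <- cpos0 - 1L                      # 0-based position of next consensus base
  blocks <- list(); bg <- bc <- len <- NULL
  flush <- function() {
    if (!is.null(len) && len > 0L) {
      cs <- if (strand == "+") bc else bc - len + 1L
      blocks[[length(blocks) + 1L]] <<- data.frame(
        copy_id = copy_id, consensus_name = cname, strand = strand,
        consensus_length = clen, chrom = chrom,
        g_start = bg, g_end = bg + len, c_start = cs, c_end = cs + len)
    }
    bg <<- bc <<- len <<- NULL
  }
  for (k in seq_along(g)) {
    gGap <- g[k] == "-"; cGap <- cc[k] == "-"
    if (!gGap && !cGap) {
      if (is.null(len)) { bg <- gpos; bc <- cpos; len <- 0L }
      len <- len + 1L
      gpos <- gpos + 1L; cpos <- cpos + cstep
    } else if (gGap && !cGap) {
      flush(); cpos <- cpos + cstep
    } else if (!gGap && cGap) {
      flush(); gpos <- gpos + 1L
    } # both gaps: ignore column
  }
  flush()
  out <- do.call(rbind, blocks)
  if (is.null(out)) pkgStop("alignment of copy %s contains no aligned bases", copy_id)
  if (max(out$c_end) > clen)
    pkgStop("copy %s: reconstructed consensus span (%d) exceeds stated consensus length (%d)",
            copy_id, max(out$c_end), clen)
  out
}

#' Write per-copy consensus alignments
#'
#' Inverse of [readRepeatMaskerAlign()]. Reconstructs the gapped alignment
#' text from the gapless blocks; sequence letters are taken from the given
#' genome/consensus sequences when provided, otherwise \code{N} placeholders
#' are used (coordinates, not letters, carry the mapping).
#'
#' @param aln a [CopyAlignments-class] object.
#' @param path output path.
#' @param genomeSeqs optional named \code{DNAStringSet} of chromosomes.
#' @param consensusSeqs optional named \code{DNAStringSet} of consensus
#'   sequences.
#' @param width characters of sequence per alignment line.
#' @export
writeRepeatMaskerAlign <- function(aln, path, genomeSeqs = NULL,
                                   consensusSeqs = NULL, width = 60L) {
  b <- alignmentBlocks(aln)
  out <- character()
  for (id in unique(b$copy_id)) {
    cb <- b[b$copy_id == id, , drop = FALSE]
    cb <- cb[order(cb$g_start), , drop = FALSE]
    strand <- cb$strand[1]; chrom <- cb$chrom[1]
    cname <- cb$consensus_name[1]; clen <- cb$consensus_length[1]
    gseq <- cseq <- character(0)
    for (i in seq_len(nrow(cb))) {
      if (i > 1L) {
        dg <- cb$g_start[i] - cb$g_end[i - 1]        # genomic insertion
        dc <- if (strand == "+") cb$c_start[i] - cb$c_end[i - 1]
              else cb$c_start[i - 1] - cb$c_end[i]   # consensus deletion
        if (dg > 0L) {
          gseq <- c(gseq, fetchSeq(genomeSeqs, chrom, cb$g_end[i - 1], dg, FALSE))
          cseq <- c(cseq, strrep("-", dg))
        }
        if (dc > 0L) {
          cfrom <- if (strand == "+") cb$c_end[i - 1] else cb$c_end[i]
          gseq <- c(gseq, strrep("-", dc))
          cseq <- c(cseq, fetchSeq(consensusSeqs, cname, cfrom, dc, strand == "-"))
        }
      }
      len <- cb$g_end[i] - cb$g_start[i]
      gseq <- c(gseq, fetchSeq(genomeSeqs, chrom, cb$g_start[i], len, FALSE))
      cseq <- c(cseq, fetchSeq(consensusSeqs, cname, cb$c_start[i], len, strand == "-"))
    }
    gs <- strsplit(paste(gseq, collapse = ""), "")[[1]]
    cs <- strsplit(paste(cseq, collapse = ""), "")[[1]]
    g1 <- cb$g_start[1] + 1L
    c1 <- if (strand == "+") cb$c_start[1] + 1L else cb$c_end[1]
    out <- c(out, sprintf(">align %s %s %d %d %s %s %d", id, chrom,
                          cb$g_start[1] + 1L, cb$g_end[nrow(cb)],
                          if (strand == "-") "C" else "+", cname, clen))
    ncol <- length(gs)
    cstep <- if (strand == "+") 1L else -1L
    gp <- g1; cp <- c1
    for (off in seq(1L, ncol, by = width)) {
      idx <- off:min(ncol, off + width - 1L)
      gchunk <- paste(gs[idx], collapse = "")
      cchunk <- paste(cs[idx], collapse = "")
      gn <- sum(gs[idx] != "-"); cn <- sum(cs[idx] != "-")
      gEnd <- gp + max(gn - 1L, 0L)
      cEnd <- cp + cstep * max(cn - 1L, 0L)
      out <- c(out, sprintf("%s %d %s %d", chrom, gp, gchunk,
                            if (gn > 0) gEnd else gp - 1L),
               sprintf("%s %d %s %d", cname, cp, cchunk,
                       if (cn > 0) cEnd else cp - cstep))
      if (gn > 0) gp <- gEnd + 1L
      if (cn > 0) cp <- cEnd + cstep
    }
    out <- c(out, "")
  }
  writeTextLines(out, path)
}

fetchSeq <- function(seqs, name, start0, len, revcomp) {
  if (is.null(seqs) || !(name %in% names(seqs))) return(strrep("N", len))
  s <- Biostrings::subseq(seqs[[name]], start = start0 + 1L, width = len)
  if (revcomp) s <- Biostrings::reverseComplement(s)
  as.character(s)
}
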