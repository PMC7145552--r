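#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- queryHits subjectHits
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges findOverlaps reduce seqnames start end width strand
#' @importFrom GenomeInfoDb Seqinfo seqlengths seqlevels
NULL

#' Genome index with excluded chromosomes
#'
#' Holds the ordered chromosome names and lengths of an assembly together
#' with the set of chromosomes excluded from all genome-fraction arithmetic
#' (e.g. chrY for a female-derived cell line).
#'
#' @slot seqinfo a [GenomeInfoDb::Seqinfo] with chromosome names and lengths.
#' @slot excluded character vector of excluded chromosome names.
#' @export
setClass("GenomeIndex",
  representation(seqinfo = "Seqinfo", excluded = "character"))

setValidity("GenomeIndex", function(object) {
  msg <- character()
  len <- GenomeInfoDb::seqlengths(object@seqinfo)
  if (length(len) == 0L) msg <- c(msg, "genome has no chromosomes")
  if (any(is.na(len)) || any(len <= 0L))
    msg <- c(msg, "all chromosome lengths must be positive")
  if (!all(object@excluded %in% GenomeInfoDb::seqlevels(object@seqinfo)))
    msg <- c(msg, "excluded chromosomes must be a subset of chromosome names")
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeIndex
#'
#' @param chromLengths named integer vector of chromosome lengths (bp).
#' @param excluded character vector of chromosome names excluded from
#'   genome-wide fraction computations (default none).
#' @return a [GenomeIndex-class] object.
#' @examples
#' gi <- GenomeIndex(c(chr1 = 1e6, chr2 = 5e5), excluded = "chr2")
#' genomeLength(gi)
#' @export
GenomeIndex <- function(chromLengths, excluded = character()) {
  si <- GenomeInfoDb::Seqinfo(seqnames = names(chromLengths),
                              seqlengths = as.integer(chromLengths))
  new("GenomeIndex", seqinfo = si, excluded = as.character(excluded))
}

#' @describeIn GenomeIndex chromosome names (all, in order)
#' @param x,object a GenomeIndex
#' @export
chromNames <- function(x) GenomeInfoDb::seqlevels(x@seqinfo)

#' @describeIn GenomeIndex named chromosome lengths
#' @export
chromLengths <- function(x) GenomeInfoDb::seqlengths(x@seqinfo)

#' @describeIn GenomeIndex excluded chromosome names
#' @export
excludedChroms <- function(x) x@excluded

#' @describeIn GenomeIndex chromosome names not excluded
#' @export
activeChroms <- function(x) setdiff(chromNames(x), x@excluded)

#' @describeIn GenomeIndex total length (bp) of the non-excluded chromosomes
#' @export
genomeLength <- function(x) {
  sum(as.numeric(chromLengths(x)[activeChroms(x)]))
}

setMethod("show", "GenomeIndex", function(object) {
  cat("GenomeIndex with", length(chromNames(object)), "chromosomes (",
      length(object@excluded), "excluded );",
      format(genomeLength(object), big.mark = ","), "active bp\n")
})

#' Per-copy alignments to subfamily consensus sequences
#'
#' The coordinate bridge between genomic TE copies and their subfamily
#' consensus. Each alignment is decomposed into gapless blocks; consensus
#' coordinates are always stored in consensus-forward orientation, so for
#' minus-strand copies consensus coordinates decrease along the genome.
#'
#' @slot blocks a data.frame with one row per gapless block and columns
#'   `copy_id`, `consensus_name`, `strand`, `consensus_length`, `chrom`,
#'   `g_start`, `g_end` (0-based half-open genomic), `c_start`, `c_end`
#'   (0-based half-open consensus-forward). Within each copy, blocks are
#'   ordered by `g_start`.
#' @export
setClass("CopyAlignments", representation(blocks = "data.frame"))

setValidity("CopyAlignments", function(object) {
  b <- object@blocks
  need <- c("copy_id", "consensus_name", "strand", "consensus_length",
            "chrom", "g_start", "g_end", "c_start", "c_end")
  if (!all(need %in% names(b)))
    return(paste("blocks must have columns:", paste(need, collapse = ", ")))
  if (nrow(b) == 0L) return(TRUE)
  if (any(b$g_end <= b$g_start) || any(b$c_end <= b$c_start))
    return("blocks must be non-empty half-open intervals")
  if (any((b$g_end - b$g_start) != (b$c_end - b$c_start)))
    return("gapless blocks must have equal genomic and consensus lengths")
  if (any(b$c_start < 0) || any(b$c_end > b$consensus_length))
    return("consensus coordinates must lie within [0, consensus_length)")
  TRUE
})

#' @rdname CopyAlignments-class
#' @param blocks see the class slot description.
#' @export
CopyAlignments <- function(blocks) {
  blocks <- blocks[order(blocks$copy_id, blocks$g_start), , drop = FALSE]
  rownames(blocks) <- NULL
  new("CopyAlignments", blocks = blocks)
}

#' @rdname CopyAlignments-class
#' @param x a CopyAlignments
#' @export
alignmentBlocks <- function(x) x@blocks

#' @rdname CopyAlignments-class
#' @param copy_id a single copy identifier
#' @export
copyBlocks <- function(x, copy_id) {
  b <- x@blocks[x@blocks$copy_id == copy_id, , drop = FALSE]
  b[order(b$g_start), , drop = FALSE]
}

setMethod("show", "CopyAlignments", function(object) {
  cat("CopyAlignments:", length(unique(object@blocks$copy_id)), "copies,",
      nrow(object@blocks), "gapless blocks,",
      length(unique(object@blocks$consensus_name)), "consensus sequences\n")
})

#' One species' collection of alignment chains
#'
#' UCSC-chain-style chained gapless alignments from a reference ("target")
#' genome to one query species, normalized so that query coordinates are on
#' the forward strand. Supports short-interval liftover.
#'
#' @slot species query species name.
#' @slot chains list; each element is a list with fields `score`, `id`,
#'   `t_name`, `t_size`, `t_start`, `t_end`, `q_name`, `q_size`, `q_strand`,
#'   `q_start`, `q_end`, and `blocks`, a matrix with columns
#'   `t_start`, `q_start`, `size` giving gapless aligned blocks in target
#'   order (`q_start` in q_strand-relative coordinates, as in the format).
#' @export
setClass("ChainSet", representation(species = "character", chains = "list"))

setValidity("ChainSet", function(object) {
  for (ch in object@chains) {
    b <- ch$blocks
    if (!is.matrix(b) || !all(c("t_start", "q_start", "size") %in% colnames(b)))
      return("each chain needs a blocks matrix with t_start, q_start, size")
    if (any(b[, "t_start"] < ch$t_start) ||
        any(b[, "t_start"] + b[, "size"] > ch$t_end))
      return(sprintf("chain %s: blocks outside declared target interval", ch$id))
  }
  TRUE
})

#' @rdname ChainSet-class
#' @param species,chains see slots
#' @export
ChainSet <- function(species, chains) new("ChainSet", species = species, chains = chains)

setMethod("show", "ChainSet", function(object) {
  cat("ChainSet for", object@species, "with", length(object@chains), "chains\n")
})

#' Position weight matrix for motif scanning
#'
#' @slot name motif name.
#' @slot matrix 4 x L numeric matrix of per-position base probabilities,
#'   rows A, C, G, T; columns each sum to 1.
#' @slot background length-4 probability vector over A, C, G, T.
#' @slot pseudocount pseudocount added per cell when the matrix was
#'   normalized from counts.
#' @export
setClass("MotifPWM", representation(name = "character", matrix = "matrix",
                                    background = "numeric", pseudocount = "numeric"))

setValidity("MotifPWM", function(object) {
  m <- object@matrix
  if (nrow(m) != 4L) return("matrix must have 4 rows (A, C, G, T)")
  if (any(abs(colSums(m) - 1) > 1e-9))
    return("each matrix column must sum to 1")
  if (abs(sum(object@background) - 1) > 1e-9)
    return("background must sum to 1")
  TRUE
})

#' @rdname MotifPWM-class
#' @param name,matrix,background,pseudocount see slots. `matrix` may be a
#'   count matrix; it is normalized per column after adding `pseudocount`.
#' @export
MotifPWM <- function(name, matrix, background = rep(0.25, 4), pseudocount = 0) {
  matrix <- as.matrix(matrix)
  rownames(matrix) <- c("A", "C", "G", "T")
  matrix <- sweep(matrix + pseudocount, 2, colSums(matrix + pseudocount), "/")
  new("MotifPWM", name = name, matrix = matrix,
      background = background / sum(background), pseudocount = pseudocount)
}

#' @rdname MotifPWM-class
#' @param x a MotifPWM
#' @export
motifLength <- function(x) ncol(x@matrix)

setMethod("show", "MotifPWM", function(object) {
  cat("MotifPWM", object@name, "of length", ncol(object@matrix), "\n")
})

#' Consensus-coordinate binding profile of a TE subfamily
#'
#' Binding events projected to the subfamily consensus, binned into 100 bins,
#' with per-site copy coverage used to normalize for 5'-truncation of copies.
#' The normalized profile is events per copy per bin, scaled by 1e5.
#'
#' @slot consensusName subfamily consensus name.
#' @slot length consensus length L (bp).
#' @slot rawCounts integer vector of 100 per-bin event counts.
#' @slot coverage numeric vector of 100 mean per-site copy coverages.
#' @slot normalized numeric vector of 100 normalized values (NA where
#'   coverage is 0).
#' @slot nEvents total number of mapped events.
#' @slot nFlaggedGap number of events that fell in consensus-deletion gaps
#'   and were assigned the nearest downstream consensus base.
#' @export
setClass("ConsensusProfile",
  representation(consensusName = "character", length = "integer",
                 rawCounts = "integer", coverage = "numeric",
                 normalized = "numeric", nEvents = "integer",
                 nFlaggedGap = "integer"))

setValidity("ConsensusProfile", function(object) {
  if (length(object@rawCounts) != 100L || length(object@coverage) != 100L ||
      length(object@normalized) != 100L)
    return("profiles use exactly 100 bins")
  if (sum(object@rawCounts) != object@nEvents)
    return("raw counts must sum to nEvents")
  TRUE
})

setMethod("show", "ConsensusProfile", function(object) {
  cat("ConsensusProfile of", object@consensusName,
      sprintf("(L = %d bp): %d events in 100 bins; mode bin %d\n",
              object@length, object@nEvents,
              which.max(object@normalized)[1] - 1L))
})

#' @rdname ConsensusProfile-class
#' @param x a ConsensusProfile
#' @export
rawCounts <- function(x) x@rawCounts

#' @rdname ConsensusProfile-class
#' @export
binCoverage <- function(x) x@coverage

#' @rdname ConsensusProfile-class
#' @export
normalizedProfile <- function(x) x@normalized

#' @rdname ConsensusProfile-class
#' @export
nEvents <- function(x) x@nEvents
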