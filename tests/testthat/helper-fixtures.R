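# Shared fixtures: small random objects built in code, plus brute-force
# oracles kept deliberately independent of the package implementations.

randomTeCopyGRanges <- function(n, chromLens = c(chr1 = 10000L, chr2 = 8000L),
                                subfams = c("MIR", "L2", "AluY")) {
  chrom <- sample(names(chromLens), n, replace = TRUE)
  width <- sample(50:300, n, replace = TRUE)
  start0 <- vapply(seq_len(n), function(i)
    sample.int(chromLens[[chrom[i]]] - width[i], 1L) - 1L, 0L)
  sf <- sample(subfams, n, replace = TRUE)
  fam <- c(MIR = "MIR", L2 = "L2", AluY = "Alu")[sf]
  cls <- c(MIR = "SINE", L2 = "LINE", AluY = "SINE")[sf]
  gr <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(start = start0 + 1L, width = width),
    strand = sample(c("+", "-"), n, replace = TRUE))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    subfamily = sf, family = unname(fam), class = unname(cls),
    divergence = round(stats::runif(n, 0, 40), 1),
    copy_id = sprintf("c%04d", seq_len(n)))
  gr
}

# Occupancy bitmap oracle: per-base fraction of a chromosome set covered by
# intervals of one group.
bitmapFraction <- function(starts, ends, chromOf, chromLens) {
  bits <- lapply(chromLens, function(L) logical(L))
  for (i in seq_along(starts)) {
    idx <- (starts[i] + 1L):ends[i]
    bits[[chromOf[i]]][idx] <- TRUE
  }
  sum(vapply(bits, sum, 0L)) / sum(chromLens)
}

# Two-sided binomial by explicit enumeration (minimum-likelihood rule).
enumBinomTwoTailed <- function(k, n, p) {
  d <- vapply(0:n, function(i) choose(n, i) * p^i * (1 - p)^(n - i), 0)
  sum(d[d <= d[k + 1] * (1 + 1e-7)])
}

# Gapped-alignment column walk oracle: returns per-genome-base consensus
# positions from two gapped strings (0-based start coords; strand via
# descending consensus).
columnWalk <- function(gseq, cseq, gStart0, cStart0, strand) {
  g <- strsplit(gseq, "")[[1]]; cc <- strsplit(cseq, "")[[1]]
  gp <- gStart0; cp <- cStart0
  cstep <- if (strand == "+") 1L else -1L
  out <- list()
  for (i in seq_along(g)) {
    gGap <- g[i] == "-"; cGap <- cc[i] == "-"
    if (!gGap && !cGap) {
      out[[length(out) + 1L]] <- c(gp, cp)
      gp <- gp + 1L; cp <- cp + cstep
    } else if (gGap) cp <- cp + cstep
    else gp <- gp + 1L
  }
  m <- do.call(rbind, out)
  colnames(m) <- c("g", "c")
  m
}

# A tiny deterministic alignment-block table for one copy.
makeBlocks <- function(copy_id = "c1", strand = "+", chrom = "chr1",
                       gStarts, gEnds, cStarts, cEnds, L = 1000L,
                       consensus = "CONS") {
  data.frame(copy_id = copy_id, consensus_name = consensus, strand = strand,
             consensus_length = L, chrom = chrom, g_start = gStarts,
             g_end = gEnds, c_start = cStarts, c_end = cEnds,
             stringsAsFactors = FALSE)
}

# Identity chain over one chromosome.
identityChain <- function(chrom = "chr1", len = 10000, species = "sp") {
  ChainSet(species, list(list(score = len, t_name = chrom, t_size = len,
                              t_start = 0, t_end = len, q_name = chrom,
                              q_size = len, q_strand = "+", q_start = 0,
                              q_end = len, id = "1",
                              blocks = cbind(t_start = 0, q_start = 0,
                                             size = len))))
}

# Small-scale simulation config used across tests (fast; generator
# parameters besides scale stay at their defaults).
testSimConfig <- function(seed = 11L, ...) {
  base <- simConfig()
  lib <- base$teLibrary
  lib$nCopies <- as.integer(ceiling(lib$nCopies / 10))
  sm <- base$summitModel
  sm$count <- as.integer(ceiling(sm$count / 5))
  simConfig(seed = seed,
            chromLengths = c(chr1 = 250000L, chr2 = 250000L),
            teLibrary = lib, summitModel = sm,
            hotLocus = list(chrom = "chr2", start = 150000L, end = 170000L,
                            subfamily = "MIR", nCopies = 15L, factor = "ERa"),
            nReads = 2000L, ...)
}

# Events whose liftover window [pos - flank, pos + flank) does not straddle
# a TE copy boundary: their cross-species presence pattern is unambiguous.
interiorEventMask <- function(events, bundleDir, flank = 5L) {
  cp <- read.table(file.path(bundleDir, "manifest_copies.tsv"), header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE)
  vapply(seq_len(nrow(events)), function(i) {
    onCh <- cp[cp$chrom == events$chrom[i], ]
    lo <- events$pos[i] - flank; hi <- events$pos[i] + flank
    !any(onCh$start > lo & onCh$start < hi) &&
      !any(onCh$end > lo & onCh$end < hi)
  }, TRUE)
}

# Cache of one shared test bundle per session.
sharedBundle <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), "tecisreg-shared-bundle")
      if (!file.exists(file.path(dir, "repeats.out")))
        simulateBundle(testSimConfig(), dir)
    }
    dir
  }
})
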