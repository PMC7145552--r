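#' Genomic fraction occupied by TE groups
#'
#' Per-group fraction of the genome covered by TE copies, using union
#' (per-base) semantics within each group and excluding the genome index's
#' excluded chromosomes from both numerator and denominator.
#'
#' @param copies TE-copy \code{GRanges} (see [readRepeatMaskerOut()]).
#' @param genome a [GenomeIndex-class].
#' @param grouping one of \code{"subfamily"}, \code{"family"},
#'   \code{"class"}.
#' @return named numeric vector of fractions.
#' @export
genomeFraction <- function(copies, genome, grouping = c("subfamily", "family", "class")) {
  grouping <- match.arg(grouping)
  if (genomeLength(genome) <= 0) pkgStop("empty genome")
  keep <- as.character(GenomicRanges::seqnames(copies)) %in% activeChroms(genome)
  copies <- copies[keep]
  grp <- S4Vectors::mcols(copies)[[grouping]]
  tot <- genomeLength(genome)
  vapply(split(copies, grp), function(g) {
    sum(as.numeric(GenomicRanges::width(GenomicRanges::reduce(g, ignore.strand = TRUE)))) / tot
  }, 0)
}

#' Assign peak summits to host TE copies
#'
#' Each summit is matched against the TE annotation under the 0-based
#' half-open convention (a summit at a copy's \code{end} coordinate is
#' outside it). A summit inside several overlapping copies is assigned
#' deterministically to the copy with the smallest start, ties broken by
#' lexicographically smaller \code{copy_id}. Summits on excluded
#' chromosomes are dropped with a message.
#'
#' @param summits width-1 summit \code{GRanges} with \code{factor} metadata.
#' @param copies TE-copy \code{GRanges}.
#' @param genome optional [GenomeIndex-class]; its excluded chromosomes are
#'   removed from the summit set.
#' @return a data.frame of binding events: \code{chrom}, \code{pos}
#'   (0-based), \code{factor}, \code{in_te}, \code{copy_id},
#'   \code{subfamily}, \code{family}, \code{class}.
#' @export
intersectSummits <- function(summits, copies, genome = NULL) {
  if (!is.null(genome)) {
    drop <- as.character(GenomicRanges::seqnames(summits)) %in% excludedChroms(genome)
    if (any(drop))
      message(sprintf("intersectSummits: dropped %d summits on excluded chromosomes", sum(drop)))
    summits <- summits[!drop]
  }
  hits <- GenomicRanges::findOverlaps(summits, copies)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  mc <- S4Vectors::mcols(copies)
  pick <- rep(NA_integer_, length(summits))
  if (length(qh)) {
    ord <- order(qh, GenomicRanges::start(copies)[sh],
                 mc$copy_id[sh], method = "radix")
    qo <- qh[ord]; so <- sh[ord]
    first <- !duplicated(qo)
    pick[qo[first]] <- so[first]
  }
  inTe <- !is.na(pick)
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(summits)),
    pos = GenomicRanges::start(summits) - 1L,
    factor = S4Vectors::mcols(summits)$factor,
    in_te = inTe,
    copy_id = ifelse(inTe, mc$copy_id[pick], NA_character_),
    subfamily = ifelse(inTe, mc$subfamily[pick], NA_character_),
    family = ifelse(inTe, mc$family[pick], NA_character_),
    class = ifelse(inTe, mc$class[pick], NA_character_),
    stringsAsFactors = FALSE)
}

#' Two-tailed binomial test p-value
#'
#' Exact two-sided binomial p-value under the minimum-likelihood convention:
#' the sum of \eqn{P(X = i)} over all outcomes whose point probability does
#' not exceed \eqn{P(X = k)} times \eqn{1 + 10^{-7}}.
#'
#' @param k observed successes.
#' @param n trials.
#' @param p success probability, in (0, 1).
#' @return p-value in (0, 1].
#' @examples
#' binomTwoTailed(3, 10, 0.1)
#' @export
binomTwoTailed <- function(k, n, p) {
  if (p <= 0 || p >= 1) pkgStop("p must lie strictly between 0 and 1")
  if (k < 0 || k > n) pkgStop("k must lie in [0, n]")
  d <- stats::dbinom(0:n, n, p)
  min(1, sum(d[d <= d[k + 1] * (1 + 1e-7)]))
}

#' Family-level enrichment of TE-resident binding sites
#'
#' For each TE group and transcription factor, tests whether the count of
#' the factor's summits falling inside copies of the group deviates from
#' the group's genomic fraction, with a two-tailed binomial test and
#' Bonferroni correction across all (group x factor) tests. \code{n} is the
#' factor's total number of summits (TE and non-TE alike); the success
#' probability is the group's genome fraction.
#'
#' @param events binding events from [intersectSummits()].
#' @param fractions named genome fractions from [genomeFraction()].
#' @param grouping the grouping column of \code{events} matching
#'   \code{fractions} (default \code{"subfamily"}).
#' @param factors factor labels to test (default: all present).
#' @param nTests Bonferroni multiplier; defaults to
#'   \code{length(fractions) * length(factors)}.
#' @param alpha significance level applied to corrected p-values.
#' @return data.frame with one row per (group, factor): observed \code{k},
#'   total \code{n}, \code{fraction}, \code{fold} = (k/n)/fraction,
#'   \code{p_raw}, \code{p_bonf}, \code{n_tests}, \code{direction},
#'   \code{significant}.
#' @export
familyEnrichment <- function(events, fractions, grouping = "subfamily",
                             factors = NULL, nTests = NULL, alpha = 0.05) {
  if (is.null(factors)) factors <- sort(unique(events$factor))
  stopifnot(all(events$factor %in% factors))
  groups <- names(fractions)
  if (is.null(nTests)) nTests <- length(groups) * length(factors)
  res <- list()
  for (f in factors) {
    ev <- events[events$factor == f, , drop = FALSE]
    n <- nrow(ev)
    obs <- table(factor(ev[[grouping]][ev$in_te], levels = groups))
    for (g in groups) {
      k <- as.integer(obs[[g]])
      p <- unname(fractions[[g]])
      if (p <= 0) {
        if (k > 0)
          pkgStop("group %s has genome fraction 0 but %d observed summits", g, k)
        next
      }
      praw <- binomTwoTailed(k, n, p)
      res[[length(res) + 1L]] <- data.frame(
        group = g, factor = f, observed = k, total = n, fraction = p,
        fold = (k / n) / p, p_raw = praw,
        p_bonf = min(1, praw * nTests), n_tests = nTests,
        direction = if (k / n >= p) "enriched" else "depleted",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  out$significant <- out$p_bonf < alpha
  rownames(out) <- NULL
  out
}

#' TE class fractions of an annotation region set
#'
#' Fraction of region bases covered by each TE class, under union
#' semantics. For conserved non-coding elements (CNEs), first filter the
#' conserved elements with [filterConservedElements()] and subtract CDS.
#'
#' @param copies TE-copy \code{GRanges}.
#' @param regions \code{GRanges} of regions (e.g. CDS or CNE pieces).
#' @return named fractions per TE class (plus \code{"other"} when present).
#' @export
annotationFraction <- function(copies, regions) {
  if (is.unsorted(order(as.factor(GenomicRanges::seqnames(regions)),
                        GenomicRanges::start(regions)))) {
    pkgWarn("annotationFraction: unsorted regions; sorting internally")
  }
  regions <- GenomicRanges::reduce(regions, ignore.strand = TRUE)
  tot <- sum(as.numeric(GenomicRanges::width(regions)))
  cls <- S4Vectors::mcols(copies)$class
  vapply(split(copies, cls), function(g) {
    ov <- GenomicRanges::intersect(GenomicRanges::reduce(g, ignore.strand = TRUE), regions,
                                   ignore.strand = TRUE)
    sum(as.numeric(GenomicRanges::width(ov))) / tot
  }, 0)
}

#' Filter conserved elements and subtract coding sequence
#'
#' Keeps conserved elements of length > 20 bp with lod score > 60 (both
#' strict), then removes protein-coding bases, yielding conserved
#' non-coding element (CNE) pieces.
#'
#' @param elements \code{GRanges} with a \code{lod} metadata column.
#' @param cds \code{GRanges} of coding bases to subtract.
#' @param minLen,minLod strict lower bounds for element length and lod.
#' @return \code{GRanges} of CNE pieces.
#' @export
filterConservedElements <- function(elements, cds = GenomicRanges::GRanges(),
                                    minLen = 20L, minLod = 60L) {
  keep <- GenomicRanges::width(elements) > minLen &
    S4Vectors::mcols(elements)$lod > minLod
  GenomicRanges::setdiff(GenomicRanges::reduce(elements[keep], ignore.strand = TRUE),
                         GenomicRanges::reduce(cds, ignore.strand = TRUE),
                         ignore.strand = TRUE)
}
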