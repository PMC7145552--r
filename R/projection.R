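#' Project a genomic summit to its TE consensus coordinate
#'
#' Maps a 0-based genomic position through the gapless blocks of a copy's
#' alignment to a 0-based consensus-forward coordinate. A position falling
#' in a genomic insertion (no consensus base) is assigned the nearest
#' downstream consensus coordinate and flagged; a position outside the
#' aligned span is unmappable.
#'
#' @param pos 0-based genomic position.
#' @param blocks block table for one copy (see [copyBlocks()]).
#' @return list with \code{consensus_pos} (or NA), \code{flagged_gap},
#'   \code{mappable}.
#' @export
projectToConsensus <- function(pos, blocks) {
  if (nrow(blocks) == 0L)
    return(list(consensus_pos = NA_integer_, flagged_gap = FALSE, mappable = FALSE))
  strand <- blocks$strand[1]
  inBlock <- which(pos >= blocks$g_start & pos < blocks$g_end)
  if (length(inBlock)) {
    b <- blocks[inBlock[1], ]
    cp <- if (strand == "+") b$c_start + (pos - b$g_start)
          else b$c_end - 1L - (pos - b$g_start)
    return(list(consensus_pos = as.integer(cp), flagged_gap = FALSE, mappable = TRUE))
  }
  if (pos < min(blocks$g_start) || pos >= max(blocks$g_end))
    return(list(consensus_pos = NA_integer_, flagged_gap = FALSE, mappable = FALSE))
  # genomic insertion between two blocks: nearest downstream consensus base
  after <- which(blocks$g_start > pos)[1]
  before <- after - 1L
  candBefore <- if (strand == "+") blocks$c_end[before] - 1L else blocks$c_start[before]
  candAfter <- if (strand == "+") blocks$c_start[after] else blocks$c_end[after] - 1L
  list(consensus_pos = as.integer(max(candBefore, candAfter)),
       flagged_gap = TRUE, mappable = TRUE)
}

#' Per-site copy coverage of a consensus sequence
#'
#' Number of copies of a subfamily whose alignment covers each consensus
#' position, counting all copies (bound or not) — this is the
#' truncation-correction denominator.
#'
#' @param aln a [CopyAlignments-class].
#' @param consensusName subfamily consensus name.
#' @return integer vector of length \code{consensus_length}.
#' @export
consensusCoverage <- function(aln, consensusName) {
  b <- alignmentBlocks(aln)
  b <- b[b$consensus_name == consensusName, , drop = FALSE]
  if (nrow(b) == 0L) pkgStop("no alignments for consensus %s", consensusName)
  L <- b$consensus_length[1]
  delta <- numeric(L + 1L)
  for (i in seq_len(nrow(b))) {
    delta[b$c_start[i] + 1L] <- delta[b$c_start[i] + 1L] + 1
    delta[b$c_end[i] + 1L] <- delta[b$c_end[i] + 1L] - 1
  }
  as.integer(cumsum(delta[seq_len(L)]))
}

#' Build a 100-bin consensus binding profile
#'
#' Projects each in-TE binding event of one subfamily to the consensus,
#' bins positions into 100 bins (\code{bin = floor(pos * 100 / L)}, clipped
#' to 99), and normalizes per-bin event counts by the mean per-site copy
#' coverage within the bin, scaled by 1e5 (events per copy per bin). Events
#' flagged as falling in genomic insertions are kept in the bin counts.
#'
#' @param events binding-event data.frame (rows for one subfamily; needs
#'   \code{copy_id} and \code{pos}).
#' @param aln a [CopyAlignments-class] covering the subfamily's copies.
#' @param consensusName the subfamily consensus name.
#' @return a [ConsensusProfile-class].
#' @export
buildProfile <- function(events, aln, consensusName) {
  b <- alignmentBlocks(aln)
  b <- b[b$consensus_name == consensusName, , drop = FALSE]
  if (nrow(b) == 0L) pkgStop("no alignments for consensus %s", consensusName)
  L <- b$consensus_length[1]
  if (L <= 0L) pkgStop("consensus length must be positive")
  byCopy <- split(b, b$copy_id)
  raw <- integer(100); nGap <- 0L; nEv <- 0L
  for (i in seq_len(nrow(events))) {
    cb <- byCopy[[events$copy_id[i]]]
    if (is.null(cb)) next
    cb <- cb[order(cb$g_start), , drop = FALSE]
    pr <- projectToConsensus(events$pos[i], cb)
    if (!pr$mappable) next
    if (pr$flagged_gap) nGap <- nGap + 1L
    bin <- min((pr$consensus_pos * 100L) %/% L, 99L)
    raw[bin + 1L] <- raw[bin + 1L] + 1L
    nEv <- nEv + 1L
  }
  cov <- consensusCoverage(aln, consensusName)
  binIdx <- pmin((seq(0L, L - 1L) * 100L) %/% L, 99L) + 1L
  covBin <- vapply(split(cov, factor(binIdx, levels = 1:100)),
                   function(v) if (length(v)) mean(v) else NA_real_, 0)
  norm <- ifelse(!is.na(covBin) & covBin > 0, raw / covBin * 1e5, NA_real_)
  new("ConsensusProfile", consensusName = consensusName, length = as.integer(L),
      rawCounts = raw, coverage = unname(ifelse(is.na(covBin), 0, covBin)),
      normalized = unname(norm), nEvents = nEv, nFlaggedGap = nGap)
}

#' Positional uniformity test over ten consensus segments
#'
#' Collapses the 100 bins into ten equal segments and tests the event
#' counts against a uniform distribution. Profiles with more than 100
#' events use the chi-squared goodness-of-fit test (df = 9); profiles with
#' 30 to 100 events use an exact Monte-Carlo multinomial test (Pearson
#' statistic, \code{R} resamples, p = (1 + #\{T_sim >= T_obs\}) / (R + 1)).
#' Profiles with fewer than 30 events are not tested.
#'
#' @param profile a [ConsensusProfile-class] (or an integer vector of 100
#'   bin counts).
#' @param R Monte-Carlo resamples for the exact branch.
#' @param seed seed for the Monte-Carlo branch.
#' @return list with \code{p_value}, \code{statistic} (Pearson T),
#'   \code{method} (\code{"chisq"}, \code{"exact_mc"} or
#'   \code{"not_tested"}), \code{n}.
#' @export
uniformityTest <- function(profile, R = 100000L, seed = 20260101L) {
  raw <- if (is(profile, "ConsensusProfile")) rawCounts(profile) else profile
  stopifnot(length(raw) == 100L)
  seg <- vapply(split(raw, rep(1:10, each = 10)), sum, 0L)
  n <- sum(seg)
  E <- n / 10
  Tobs <- sum((seg - E)^2 / E)
  if (n < 30L)
    return(list(p_value = NA_real_, statistic = NA_real_,
                method = "not_tested", n = n))
  if (n > 100L) {
    p <- stats::pchisq(Tobs, df = 9, lower.tail = FALSE)
    return(list(p_value = p, statistic = Tobs, method = "chisq", n = n))
  }
  p <- withLocalSeed(seed, {
    sims <- stats::rmultinom(R, n, rep(0.1, 10))
    Tsim <- colSums((sims - E)^2 / E)
    (1 + sum(Tsim >= Tobs - 1e-9)) / (R + 1)
  })
  list(p_value = p, statistic = Tobs, method = "exact_mc", n = n)
}

#' Uniformity tests across subfamily x factor profiles with Bonferroni
#' correction
#'
#' Runs [uniformityTest()] on each profile and corrects the p-values with
#' the Bonferroni method, the multiplier being the number of profiles
#' actually tested (those with at least 30 events).
#'
#' @param profiles named list of [ConsensusProfile-class] objects.
#' @param ... passed to [uniformityTest()].
#' @return data.frame with per-profile p-values, corrected p-values, the
#'   multiplier used, and method tags.
#' @export
uniformityTests <- function(profiles, ...) {
  res <- lapply(profiles, uniformityTest, ...)
  tested <- vapply(res, function(r) r$method != "not_tested", TRUE)
  m <- sum(tested)
  data.frame(
    profile = names(profiles),
    n = vapply(res, `[[`, 0, "n"),
    statistic = vapply(res, `[[`, 0, "statistic"),
    method = vapply(res, `[[`, "", "method"),
    p_raw = vapply(res, `[[`, 0, "p_value"),
    p_bonf = pmin(1, vapply(res, `[[`, 0, "p_value") * m),
    n_tests = m, row.names = NULL, stringsAsFactors = FALSE)
}

#' Consensus peak regions of a binding profile
#'
#' Contiguous runs of bins whose normalized value exceeds a multiple of the
#' profile median, converted back to consensus base intervals. These are
#' the regions scanned for binding motifs.
#'
#' @param profile a [ConsensusProfile-class].
#' @param foldOverMedian threshold multiplier over the median normalized
#'   value (default 3).
#' @return data.frame of consensus intervals (\code{start}, \code{end},
#'   0-based half-open) with the peak bin range.
#' @export
profilePeakRegions <- function(profile, foldOverMedian = 3) {
  v <- normalizedProfile(profile)
  med <- stats::median(v, na.rm = TRUE)
  thr <- if (is.na(med) || med <= 0) {
    mx <- max(v, na.rm = TRUE)
    mx / 2
  } else med * foldOverMedian
  hot <- !is.na(v) & v > thr & rawCounts(profile) > 0
  if (!any(hot)) return(data.frame(start = integer(), end = integer(),
                                   bin_start = integer(), bin_end = integer()))
  r <- rle(hot)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  k <- which(r$values)
  L <- profile@length
  data.frame(start = as.integer(floor((starts[k] - 1L) * L / 100)),
             end = as.integer(ceiling(ends[k] * L / 100)),
             bin_start = starts[k] - 1L, bin_end = ends[k] - 1L)
}
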