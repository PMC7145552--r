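#' Meta-profile of a signal track around single-base sites
#'
#' Per-offset mean of the track over the given sites for offsets
#' \code{-flank..+flank}, followed by a centered moving average of width
#' \code{smooth} (bp), truncated at the profile edges. Sites nearer than
#' \code{flank} to a chromosome end contribute their available bases only;
#' windowed tracks contribute their window's value at every base.
#'
#' @param sites width-1 \code{GRanges} (or data.frame with \code{chrom},
#'   \code{pos}).
#' @param track a [SignalTrack-class].
#' @param flank flank size in bp (default 400).
#' @param smooth moving-average width in bp (default 10; 1 disables).
#' @return data.frame with \code{offset}, \code{mean} (smoothed),
#'   \code{raw_mean}, \code{n_sites} contributing per offset.
#' @export
metaProfile <- function(sites, track, flank = 400L, smooth = 10L) {
  sdf <- sitesToDf(sites)
  offs <- seq(-flank, flank)
  acc <- numeric(length(offs)); cnt <- integer(length(offs))
  for (i in seq_len(nrow(sdf))) {
    v <- trackValuesAt(track, sdf$chrom[i], sdf$pos[i] + offs)
    ok <- !is.na(v)
    acc[ok] <- acc[ok] + v[ok]
    cnt <- cnt + ok
  }
  rawMean <- ifelse(cnt > 0, acc / cnt, NA_real_)
  data.frame(offset = offs, mean = movingAverage(rawMean, smooth),
             raw_mean = rawMean, n_sites = cnt)
}

sitesToDf <- function(sites) {
  if (is.data.frame(sites)) {
    data.frame(chrom = sites$chrom, pos = sites$pos)
  } else {
    data.frame(chrom = as.character(GenomicRanges::seqnames(sites)),
               pos = GenomicRanges::start(sites) - 1L)
  }
}

#' Random genomic sites restricted to TEs
#'
#' Draws \code{nDraw} positions uniformly over the non-excluded
#' chromosomes and retains those falling inside a TE copy — the control
#' site set for conservation/accessibility and TSS-distance comparisons.
#'
#' @param genome a [GenomeIndex-class].
#' @param copies TE-copy \code{GRanges}.
#' @param nDraw number of uniform draws.
#' @param seed RNG seed (reproducible).
#' @return width-1 \code{GRanges} of retained sites with the host copy's
#'   \code{class} metadata.
#' @export
randomTeSites <- function(genome, copies, nDraw, seed) {
  lens <- chromLengths(genome)[activeChroms(genome)]
  if (sum(as.numeric(GenomicRanges::width(GenomicRanges::reduce(copies, ignore.strand = TRUE)))) == 0)
    pkgStop("annotation contains no TE bases")
  tot <- sum(as.numeric(lens))
  draws <- withLocalSeed(seed, {
    u <- floor(stats::runif(nDraw, 0, tot))
    u
  })
  cum <- cumsum(as.numeric(lens))
  ci <- findInterval(draws, cum) + 1L
  chrom <- names(lens)[ci]
  pos <- as.integer(draws - c(0, cum)[ci])
  gr <- summitGRanges(chrom, pos)
  hits <- GenomicRanges::findOverlaps(gr, copies, select = "first")
  keep <- !is.na(hits)
  out <- gr[keep]
  S4Vectors::mcols(out)$class <- S4Vectors::mcols(copies)$class[hits[keep]]
  out
}

#' Compare per-site mean signal between two site groups
#'
#' Welch two-sample two-tailed t-test on per-site means of the track over
#' \code{+/- flank} bp, e.g. conservation at TE-resident binding sites
#' versus random TE sites.
#'
#' @param aSites,bSites width-1 site \code{GRanges}.
#' @param track a [SignalTrack-class].
#' @param flank flank size in bp.
#' @return list with \code{t}, \code{p_value}, group means, \code{n_a},
#'   \code{n_b}, and \code{degenerate} flag (zero variance in both groups).
#' @export
compareProfiles <- function(aSites, bSites, track, flank = 400L) {
  a <- perSiteMeans(aSites, track, flank)
  b <- perSiteMeans(bSites, track, flank)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    pkgStop("both groups need at least 2 sites with data")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(t = if (eq) 0 else Inf, p_value = if (eq) 1 else 0,
                mean_a = mean(a), mean_b = mean(b),
                n_a = length(a), n_b = length(b), degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, alternative = "two.sided", var.equal = FALSE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       mean_a = mean(a), mean_b = mean(b),
       n_a = length(a), n_b = length(b), degenerate = FALSE)
}

perSiteMeans <- function(sites, track, flank) {
  sdf <- sitesToDf(sites)
  offs <- seq(-flank, flank)
  vapply(seq_len(nrow(sdf)), function(i) {
    v <- trackValuesAt(track, sdf$chrom[i], sdf$pos[i] + offs)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, 0)
}

#' Distances from binding sites to the nearest TSS
#'
#' Absolute distance (bp) from each summit to the nearest transcription
#' start site, averaged per TE class. A matched control from random TE
#' sites (see [randomTeSites()]) is returned when a genome and annotation
#' are supplied.
#'
#' @param events binding events (data.frame from [intersectSummits()]); only
#'   in-TE events contribute.
#' @param tss width-1 \code{GRanges} of TSSs.
#' @param genome,copies optional [GenomeIndex-class] and TE annotation for
#'   the random-site control.
#' @param nDraw,seed control sampling parameters.
#' @return data.frame per class: mean observed distance, n, and (when a
#'   control is drawn) mean control distance and control n.
#' @export
tssDistances <- function(events, tss, genome = NULL, copies = NULL,
                         nDraw = 100000L, seed = 1L) {
  if (length(tss) == 0L) pkgStop("TSS list is empty")
  ev <- events[events$in_te, , drop = FALSE]
  d <- nearestTssDistance(ev$chrom, ev$pos, tss)
  keep <- !is.na(d)
  if (any(!keep))
    message(sprintf("tssDistances: %d events on chromosomes without a TSS excluded", sum(!keep)))
  obs <- stats::aggregate(list(mean_distance = d[keep]),
                          by = list(class = ev$class[keep]), FUN = mean)
  obs$n <- as.integer(table(ev$class[keep])[obs$class])
  if (is.null(genome) || is.null(copies)) return(obs)
  ctrl <- randomTeSites(genome, copies, nDraw, seed)
  cd <- nearestTssDistance(as.character(GenomicRanges::seqnames(ctrl)),
                           GenomicRanges::start(ctrl) - 1L, tss)
  cc <- S4Vectors::mcols(ctrl)$class
  keepC <- !is.na(cd)
  ctrlAgg <- stats::aggregate(list(control_mean_distance = cd[keepC]),
                              by = list(class = cc[keepC]), FUN = mean)
  ctrlAgg$control_n <- as.integer(table(cc[keepC])[ctrlAgg$class])
  merge(obs, ctrlAgg, by = "class", all.x = TRUE)
}

nearestTssDistance <- function(chrom, pos, tss) {
  tdf <- data.frame(chrom = as.character(GenomicRanges::seqnames(tss)),
                    pos = GenomicRanges::start(tss) - 1L)
  out <- rep(NA_real_, length(pos))
  for (ch in unique(chrom)) {
    tp <- sort(tdf$pos[tdf$chrom == ch])
    idx <- which(chrom == ch)
    if (!length(tp)) next
    i <- findInterval(pos[idx], tp)
    lo <- pmax(i, 1L); hi <- pmin(i + 1L, length(tp))
    out[idx] <- pmin(abs(pos[idx] - tp[lo]), abs(pos[idx] - tp[hi]))
  }
  out
}

#' Read-coverage matrix around binding sites
#'
#' Subsamples the read intervals without replacement to a normalization
#' target and accumulates per-base coverage at offsets
#' \code{-flank..+flank} around each site — the per-site signal matrix
#' underlying chromatin-mark heat maps.
#'
#' @param sites width-1 site \code{GRanges}.
#' @param reads \code{GRanges} of read intervals.
#' @param flank flank size (default 4000).
#' @param targetReads subsampling target; when fewer reads are available,
#'   all are used with a warning.
#' @param seed subsampling seed.
#' @return numeric matrix, sites x offsets.
#' @export
signalMatrix <- function(sites, reads, flank = 4000L, targetReads = length(reads),
                         seed = 1L) {
  if (length(reads) < targetReads) {
    pkgWarn("signalMatrix: only %d reads available for a target of %d; using all",
            length(reads), targetReads)
    targetReads <- length(reads)
  }
  idx <- withLocalSeed(seed, sample.int(length(reads), targetReads))
  reads <- reads[sort(idx)]
  sdf <- sitesToDf(sites)
  n <- nrow(sdf); width <- 2L * flank + 1L
  mat <- matrix(0L, nrow = n, ncol = width)
  win <- grFromHalfOpen(sdf$chrom, sdf$pos - flank, sdf$pos + flank + 1L)
  hits <- GenomicRanges::findOverlaps(win, reads)
  for (h in seq_along(hits)) {
    i <- S4Vectors::queryHits(hits)[h]; r <- S4Vectors::subjectHits(hits)[h]
    rs <- GenomicRanges::start(reads)[r] - 1L; re <- GenomicRanges::end(reads)[r]
    lo <- max(rs - (sdf$pos[i] - flank), 0L) + 1L
    hi <- min(re - (sdf$pos[i] - flank), width)
    mat[i, lo:hi] <- mat[i, lo:hi] + 1L
  }
  colnames(mat) <- as.character(seq(-flank, flank))
  mat
}

#' Assign summits to chromatin-segmentation states
#'
#' Each summit receives the state of the segment containing it (the
#' segmentation must partition the genome: overlapping segments are an
#' error), then states are rolled up to promoter/enhancer/other via a map.
#'
#' @param events binding events data.frame (needs \code{chrom},
#'   \code{pos}).
#' @param segmentation \code{GRanges} with a \code{state} column.
#' @param rollup named character vector mapping state labels to rollup
#'   groups (e.g. \code{c(E2_active_promoter = "promoter")}); unmapped
#'   states become \code{"other"}.
#' @return the events data.frame with \code{state} and \code{rollup}
#'   columns appended (\code{"unannotated"} outside all segments).
#' @export
assignStates <- function(events, segmentation, rollup = NULL) {
  self <- GenomicRanges::findOverlaps(segmentation, segmentation)
  if (length(self) > length(segmentation))
    pkgStop("segmentation has overlapping segments; it must partition the genome")
  gr <- summitGRanges(events$chrom, events$pos)
  hit <- GenomicRanges::findOverlaps(gr, segmentation, select = "first")
  st <- ifelse(is.na(hit), "unannotated",
               S4Vectors::mcols(segmentation)$state[hit])
  ru <- rep("other", length(st))
  if (!is.null(rollup)) {
    m <- rollup[st]
    ru[!is.na(m)] <- m[!is.na(m)]
  }
  ru[st == "unannotated"] <- "unannotated"
  events$state <- st
  events$rollup <- ru
  events
}

#' Rollup proportions per subset of binding events
#'
#' @param events output of [assignStates()].
#' @param by subset column, e.g. \code{"in_te"} or \code{"factor"}.
#' @return data.frame of proportions summing to 1 within each subset.
#' @export
stateProportions <- function(events, by = "in_te") {
  tab <- table(events[[by]], events$rollup)
  prop <- prop.table(tab, margin = 1)
  as.data.frame(prop, responseName = "proportion", stringsAsFactors = FALSE) |>
    stats::setNames(c(by, "rollup", "proportion"))
}
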