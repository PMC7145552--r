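#' Per-copy factor binding table
#'
#' Which factors have at least one summit inside each TE copy, with the
#' copy's category (family by default).
#'
#' @param events binding events from [intersectSummits()].
#' @param copies TE-copy \code{GRanges}.
#' @param category metadata column of \code{copies} used as the copy
#'   category (default \code{"family"}).
#' @return data.frame with one row per (copy, factor) binding, plus
#'   attribute \code{"category_sizes"}: total copies per category.
#' @export
copyBindingTable <- function(events, copies, category = "family") {
  ev <- events[events$in_te, , drop = FALSE]
  mc <- S4Vectors::mcols(copies)
  cat <- mc[[category]][match(ev$copy_id, mc$copy_id)]
  tab <- unique(data.frame(copy_id = ev$copy_id, factor = ev$factor,
                           category = cat, stringsAsFactors = FALSE))
  sizes <- table(mc[[category]])
  attr(tab, "category_sizes") <- sizes
  tab
}

#' Conditional colocalization of two factors within TE copies
#'
#' Tests whether copies bound by factor \code{a} are enriched for binding
#' by factor \code{b}, per category and pooled. The observed quantity is
#' P(b | a-bound copies); the baseline is b's average binding probability
#' in the category (bound copies / total copies). The chi-squared test is a
#' one-sample goodness-of-fit (df = 1, no continuity correction) of the
#' a-bound copies' b/not-b split against the baseline. Categories with 10
#' or fewer a-binding events are skipped.
#'
#' @param table output of [copyBindingTable()].
#' @param factorA,factorB factor labels.
#' @param minEvents categories need more than this many a-bound copies
#'   (default 10).
#' @return data.frame per category (plus a \code{"pooled"} row): n a-bound
#'   copies, observed b fraction, baseline, fold, chi-squared statistic and
#'   p-value; \code{testable} is FALSE where the baseline is 0.
#' @export
colocTest <- function(table, factorA, factorB, minEvents = 10L) {
  sizes <- attr(table, "category_sizes")
  aCopies <- unique(table[table$factor == factorA, c("copy_id", "category")])
  bCopies <- unique(table$copy_id[table$factor == factorB])
  rows <- list()
  testCat <- function(catName, copyIds, nTotal, nBBound) {
    n <- length(copyIds)
    k <- sum(copyIds %in% bCopies)
    baseline <- nBBound / nTotal
    if (baseline <= 0 || baseline >= 1)
      return(data.frame(category = catName, n_a = n, observed = k / n,
                        baseline = baseline, fold = NA_real_,
                        chisq = NA_real_, p_value = NA_real_, testable = FALSE))
    exp1 <- n * baseline
    chisq <- (k - exp1)^2 / exp1 + ((n - k) - (n - exp1))^2 / (n - exp1)
    data.frame(category = catName, n_a = n, observed = k / n,
               baseline = baseline, fold = (k / n) / baseline, chisq = chisq,
               p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
               testable = TRUE)
  }
  for (cat in unique(aCopies$category)) {
    ids <- aCopies$copy_id[aCopies$category == cat]
    if (length(ids) <= minEvents) next
    nTotal <- as.integer(sizes[[cat]])
    nB <- length(unique(table$copy_id[table$factor == factorB &
                                        table$category == cat]))
    rows[[length(rows) + 1L]] <- testCat(cat, ids, nTotal, nB)
  }
  # pooled over tested categories
  if (length(rows)) {
    cats <- vapply(rows, `[[`, "", "category")
    ids <- aCopies$copy_id[aCopies$category %in% cats]
    nTotal <- sum(as.integer(sizes[cats]))
    nB <- length(unique(table$copy_id[table$factor == factorB &
                                        table$category %in% cats]))
    rows[[length(rows) + 1L]] <- testCat("pooled", ids, nTotal, nB)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  rownames(out) <- NULL
  out
}

#' Genome-wide density of factor-bound TE copies
#'
#' Sliding-window density (bound copies per kilobase) across the
#' non-excluded chromosomes: windows of \code{width} bp every \code{step}
#' bp; a copy belongs to the window containing its midpoint; windows
#' truncated at a chromosome end use the truncated width.
#'
#' @param boundCopies \code{GRanges} of distinct bound TE copies.
#' @param genome a [GenomeIndex-class].
#' @param width window width in bp (default 100000).
#' @param step window step in bp (default 50000).
#' @return data.frame with \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open), \code{count}, \code{density} (copies per kb).
#' @export
densityScan <- function(boundCopies, genome, width = 100000L, step = 50000L) {
  if (width %% step != 0L)
    pkgWarn("densityScan: window width is not a multiple of the step")
  mids <- (GenomicRanges::start(boundCopies) - 1L +
             GenomicRanges::end(boundCopies)) %/% 2L
  chs <- as.character(GenomicRanges::seqnames(boundCopies))
  rows <- list()
  for (chrom in activeChroms(genome)) {
    len <- chromLengths(genome)[[chrom]]
    starts <- seq(0L, max(0L, len - 1L), by = step)
    starts <- starts[starts < len]
    ends <- pmin(starts + width, len)
    m <- sort(mids[chs == chrom])
    cnt <- findInterval(ends - 1L, m) - findInterval(starts - 1L, m)
    rows[[chrom]] <- data.frame(chrom = chrom, start = starts, end = ends,
                                count = cnt,
                                density = cnt / ((ends - starts) / 1000))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Top-density locus from a density track
#'
#' Merges contiguous windows whose density falls in the top quantile and
#' reports the merged locus containing the maximum-density window.
#'
#' @param density output of [densityScan()].
#' @param topQuantile windows above this quantile are considered hot
#'   (default 0.99).
#' @return one-row data.frame: \code{chrom}, \code{start}, \code{end},
#'   \code{max_density}.
#' @export
topDensityLocus <- function(density, topQuantile = 0.99) {
  thr <- stats::quantile(density$density, topQuantile, names = FALSE)
  hot <- density$density >= thr
  imax <- which.max(density$density)
  ch <- density$chrom[imax]
  onCh <- which(density$chrom == ch)
  hotCh <- hot[onCh]
  pos <- match(imax, onCh)
  lo <- pos; while (lo > 1L && hotCh[lo - 1L]) lo <- lo - 1L
  hi <- pos; while (hi < length(onCh) && hotCh[hi + 1L]) hi <- hi + 1L
  data.frame(chrom = ch, start = density$start[onCh[lo]],
             end = density$end[onCh[hi]],
             max_density = density$density[imax])
}
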