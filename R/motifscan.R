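# PWM scanning with exact p-values on a discretized score lattice, the
# standard approach for exact motif-score distributions: each position's
# log-likelihood ratios are rounded to a fixed lattice step and the score
# distribution over background k-mers is built by dynamic-programming
# convolution.

BASES <- c("A", "C", "G", "T")

# Integer lattice representation of a PWM's log2 odds. step in bits.
pwmLattice <- function(pwm, step = 1e-3) {
  llr <- log2(pwm@matrix / pwm@background)
  # guard -Inf from zero probabilities: floor at a very negative score
  llr[!is.finite(llr)] <- -100
  round(llr / step)
}

# Exact tail distribution of the lattice score over iid background k-mers.
# Returns list(min, probs) where probs[i] = P(S = min + i - 1).
latticeDistribution <- function(intScores, background) {
  lo <- sum(apply(intScores, 2, min))
  hi <- sum(apply(intScores, 2, max))
  probs <- numeric(hi - lo + 1L)
  # DP over positions
  cur <- 1
  curLo <- 0L
  for (j in seq_len(ncol(intScores))) {
    s <- intScores[, j]
    newLo <- curLo + min(s)
    newHi <- curLo + length(cur) - 1L + max(s)
    nxt <- numeric(newHi - newLo + 1L)
    for (b in 1:4) {
      off <- s[b] - min(s)
      idx <- seq_along(cur) + off
      nxt[idx] <- nxt[idx] + cur * background[b]
    }
    cur <- nxt
    curLo <- newLo
  }
  list(min = curLo, probs = cur, tail = rev(cumsum(rev(cur))))
}

# P(S >= x) on the lattice; dist$tail is precomputed by latticeDistribution.
latticeTailP <- function(dist, x) {
  i <- x - dist$min + 1L
  if (i <= 1L) return(1)
  if (i > length(dist$probs)) return(0)
  min(1, dist$tail[i])
}

#' Scan a consensus region for PWM motif hits
#'
#' Slides the PWM over both strands of the region, scoring each window by
#' the summed log2 likelihood ratio against the background, and converts
#' scores to exact p-values (probability that a background k-mer scores at
#' least as high), computed by dynamic programming on a discretized score
#' lattice. Windows containing \code{N} are skipped.
#'
#' @param seq consensus sequence (character or \code{DNAString}).
#' @param pwm a [MotifPWM-class].
#' @param region optional 0-based half-open interval \code{c(start, end)}
#'   restricting the scan; default whole sequence.
#' @param alpha p-value threshold for reported hits.
#' @param latticeStep lattice discretization in bits.
#' @return data.frame of hits sorted by position: \code{pos} (0-based start
#'   on the forward sequence), \code{strand}, \code{score} (bits),
#'   \code{p_value}.
#' @export
scanMotif <- function(seq, pwm, region = NULL, alpha = 1e-4, latticeStep = 1e-3) {
  s <- toupper(as.character(seq))
  L <- nchar(s)
  if (is.null(region)) region <- c(0L, L)
  stopifnot(region[1] >= 0, region[2] <= L)
  w <- motifLength(pwm)
  empty <- data.frame(pos = integer(), strand = character(),
                      score = numeric(), p_value = numeric())
  if (region[2] - region[1] < w) return(empty)
  lat <- pwmLattice(pwm, latticeStep)
  revLat <- lat[4:1, w:1, drop = FALSE]    # reverse-complement strand scores
  dist <- latticeDistribution(lat, pwm@background)
  distRev <- latticeDistribution(revLat, pwm@background)
  sub <- substring(s, region[1] + 1L, region[2])
  chars <- strsplit(sub, "")[[1]]
  code <- match(chars, BASES)              # NA for N etc.
  starts <- seq_len(length(chars) - w + 1L)
  hits <- list()
  for (st in starts) {
    win <- code[st:(st + w - 1L)]
    if (anyNA(win)) next
    for (sd in c("+", "-")) {
      m <- if (sd == "+") lat else revLat
      sc <- sum(m[cbind(win, seq_len(w))])
      p <- latticeTailP(if (sd == "+") dist else distRev, sc)
      if (p < alpha)
        hits[[length(hits) + 1L]] <- data.frame(
          pos = region[1] + st - 1L, strand = sd,
          score = sc * latticeStep, p_value = p)
    }
  }
  if (!length(hits)) return(empty)
  out <- do.call(rbind, hits)
  out[order(out$pos, out$strand), , drop = FALSE]
}
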