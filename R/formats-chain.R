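#' Read a UCSC chain file
#'
#' Parses chained gapless alignments in the UCSC chain format. Each chain
#' header is \code{chain score tName tSize tStrand tStart tEnd qName qSize
#' qStrand qStart qEnd id} followed by \code{size dt dq} block lines and a
#' final bare \code{size}. Block coordinates are decomposed into absolute
#' per-block starts; query starts are normalized to forward-strand
#' coordinates on read (the strand is retained to orient per-base mapping).
#'
#' @param path path to a chain file (may be gzipped).
#' @param species query species label; defaults to the file name without
#'   extension.
#' @return a [ChainSet-class].
#' @export
readChain <- function(path, species = NULL) {
  if (is.null(species))
    species <- sub("\\.chain(\\.gz)?$", "", basename(path))
  lines <- readTextLines(path)
  hdr <- grep("^chain\\b", lines)
  chains <- vector("list", length(hdr))
  ends <- c(hdr[-1] - 1L, length(lines))
  for (i in seq_along(hdr)) {
    h <- strsplit(trimws(lines[hdr[i]]), "\\s+")[[1]]
    if (length(h) < 13L) pkgStop("chain header with %d fields at line %d", length(h), hdr[i])
    ch <- list(score = as.numeric(h[2]),
               t_name = h[3], t_size = as.numeric(h[4]),
               t_start = as.numeric(h[6]), t_end = as.numeric(h[7]),
               q_name = h[8], q_size = as.numeric(h[9]), q_strand = h[10],
               q_start = as.numeric(h[11]), q_end = as.numeric(h[12]),
               id = h[13])
    body <- lines[(hdr[i] + 1L):ends[i]]
    body <- body[nzchar(trimws(body))]
    rows <- lapply(strsplit(trimws(body), "\\s+"), as.numeric)
    sizes <- vapply(rows, `[`, 0, 1L)
    dt <- vapply(rows, function(r) if (length(r) >= 2) r[2] else 0, 0)
    dq <- vapply(rows, function(r) if (length(r) >= 3) r[3] else 0, 0)
    tHit <- ch$t_start + cumsum(c(0, (sizes + dt)[-length(sizes)]))
    qRel <- ch$q_start + cumsum(c(0, (sizes + dq)[-length(sizes)]))
    if (tHit[length(tHit)] + sizes[length(sizes)] != ch$t_end)
      pkgStop("chain %s: block sizes + gaps do not match target interval", ch$id)
    if (qRel[length(qRel)] + sizes[length(sizes)] != ch$q_end)
      pkgStop("chain %s: block sizes + gaps do not match query interval", ch$id)
    # forward-strand query coordinates per block
    qFwd <- if (ch$q_strand == "-") ch$q_size - (qRel + sizes) else qRel
    ch$blocks <- cbind(t_start = tHit, q_start = qFwd, size = sizes)
    chains[[i]] <- ch
  }
  ChainSet(species, chains)
}

#' Write a ChainSet as a UCSC chain file
#'
#' Inverse of [readChain()].
#'
#' @param chainSet a [ChainSet-class].
#' @param path output path.
#' @export
writeChain <- function(chainSet, path) {
  out <- character()
  for (ch in chainSet@chains) {
    b <- ch$blocks
    qRel <- if (ch$q_strand == "-") ch$q_size - (b[, "q_start"] + b[, "size"]) else b[, "q_start"]
    out <- c(out, sprintf("chain %s %s %s + %s %s %s %s %s %s %s %s",
                          fmtNum(ch$score), ch$t_name, fmtNum(ch$t_size),
                          fmtNum(ch$t_start), fmtNum(ch$t_end),
                          ch$q_name, fmtNum(ch$q_size), ch$q_strand,
                          fmtNum(ch$q_start), fmtNum(ch$q_end), ch$id))
    n <- nrow(b)
    if (n > 1L) {
      dt <- b[-1, "t_start"] - (b[-n, "t_start"] + b[-n, "size"])
      dq <- qRel[-1] - (qRel[-n] + b[-n, "size"])
      out <- c(out, sprintf("%s\t%s\t%s", fmtNum(b[-n, "size"]), fmtNum(dt), fmtNum(dq)))
    }
    out <- c(out, fmtNum(b[n, "size"]), "")
  }
  writeTextLines(out, path)
}

fmtNum <- function(x) format(x, scientific = FALSE, trim = TRUE)
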