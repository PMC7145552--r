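#' Windowed or per-base signal track
#'
#' A per-chromosome numeric signal at a fixed window size. A \code{step} of
#' 1 is a per-base track (e.g. phyloP conservation); a step of 20 matches
#' 20-bp windowed DHS signal. Values are stored from position 0 in windows
#' of \code{step} bp; windows never covered by the source data are
#' \code{NA}.
#'
#' @slot values named list, one numeric vector per chromosome (one value
#'   per window).
#' @slot step window size in bp.
#' @slot kind \code{"per_base"} or \code{"windowed"}.
#' @export
setClass("SignalTrack",
  representation(values = "list", step = "integer", kind = "character"))

setValidity("SignalTrack", function(object) {
  if (object@step < 1L) return("window size must be >= 1")
  if (any(vapply(object@values, function(v) any(is.infinite(v)), TRUE)))
    return("values must be finite or NA")
  TRUE
})

#' @rdname SignalTrack-class
#' @param values,step see slots.
#' @export
SignalTrack <- function(values, step = 1L) {
  new("SignalTrack", values = values, step = as.integer(step),
      kind = if (step == 1L) "per_base" else "windowed")
}

setMethod("show", "SignalTrack", function(object) {
  cat("SignalTrack (", object@kind, ", step ", object@step, " bp) on ",
      length(object@values), " chromosomes\n", sep = "")
})

#' @rdname SignalTrack-class
#' @param x a SignalTrack
#' @param chrom chromosome name
#' @param pos 0-based base positions
#' @return \code{trackValuesAt}: signal values at the given bases (a
#'   windowed value applies to every base of its window); NA outside data.
#' @export
trackValuesAt <- function(x, chrom, pos) {
  v <- x@values[[chrom]]
  if (is.null(v)) return(rep(NA_real_, length(pos)))
  idx <- pos %/% x@step + 1L
  out <- rep(NA_real_, length(pos))
  ok <- pos >= 0L & idx <= length(v)
  out[ok] <- v[idx[ok]]
  out
}

#' Read a wiggle or bedGraph signal track
#'
#' Supports fixedStep and variableStep wiggle declarations (with
#' \code{span}) and 4-column bedGraph lines. All values are resampled onto
#' a uniform grid of \code{step} bp from position 0 of each chromosome
#' (the step is taken from the first declaration unless given).
#'
#' @param path path to the track file (may be gzipped).
#' @param chromLengths named chromosome lengths used to size the vectors;
#'   if omitted, vectors extend to the last covered window.
#' @param step window size; defaults to the declaration's step/span.
#' @return a [SignalTrack-class].
#' @export
readWig <- function(path, chromLengths = NULL, step = NULL) {
  lines <- readTextLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  n <- length(lines)
  if (n == 0L) return(SignalTrack(list(), step = step %||0% 1L))
  decl <- grep("^(fixedStep|variableStep)", lines)
  wins <- list(); vals <- list(); chroms <- character()
  if (length(decl)) {
    ends <- c(decl[-1] - 1L, n)
    for (d in seq_along(decl)) {
      kv <- strsplit(lines[decl[d]], "\\s+")[[1]]
      param <- function(key, default = NA_character_) {
        hit <- grep(paste0("^", key, "="), kv, value = TRUE)
        if (length(hit)) sub(".*=", "", hit[1]) else default
      }
      chrom <- param("chrom")
      span <- as.integer(param("span", "1"))
      if (decl[d] + 1L > ends[d]) next
      body <- lines[(decl[d] + 1L):ends[d]]
      if (kv[1] == "fixedStep") {
        wstep <- as.integer(param("step", param("span", "1")))
        if (is.null(step)) step <- wstep
        start0 <- as.integer(param("start", "1")) - 1L
        pos <- start0 + (seq_along(body) - 1L) * wstep
        v <- as.numeric(body)
      } else {
        if (is.null(step)) step <- span
        m <- matrix(unlist(strsplit(trimws(body), "\\s+")), ncol = 2L,
                    byrow = TRUE)
        pos <- as.integer(m[, 1]) - 1L
        v <- as.numeric(m[, 2])
      }
      i <- length(wins) + 1L
      wins[[i]] <- pos %/% step + 1L
      vals[[i]] <- v
      chroms[i] <- chrom
    }
  } else {
    f <- strsplit(lines, "\t")
    if (any(lengths(f) < 4L)) f <- strsplit(lines, "\\s+")
    chromCol <- vapply(f, `[`, "", 1L)
    s0 <- as.integer(vapply(f, `[`, "", 2L))
    e0 <- as.integer(vapply(f, `[`, "", 3L))
    v <- as.numeric(vapply(f, `[`, "", 4L))
    if (is.null(step)) step <- e0[1] - s0[1]
    for (chrom in unique(chromCol)) {
      k <- chromCol == chrom
      pieces <- mapply(function(s, e) (s %/% step + 1L):((e - 1L) %/% step + 1L),
                       s0[k], e0[k], SIMPLIFY = FALSE)
      i <- length(wins) + 1L
      wins[[i]] <- unlist(pieces)
      vals[[i]] <- rep(v[k], times = lengths(pieces))
      chroms[i] <- chrom
    }
  }
  out <- list()
  for (chrom in unique(chroms)) {
    k <- which(chroms == chrom)
    w <- unlist(wins[k]); vv <- unlist(vals[k])
    len <- if (!is.null(chromLengths) && chrom %in% names(chromLengths))
      as.integer(ceiling(chromLengths[[chrom]] / step)) else max(w)
    x <- rep(NA_real_, len)
    x[w] <- vv
    out[[chrom]] <- x
  }
  SignalTrack(out, step = step)
}

`%||0%` <- function(a, b) if (is.null(a)) b else a

#' Write a SignalTrack as fixedStep wiggle
#'
#' Emits one fixedStep declaration per chromosome (step and span equal to
#' the track's window size); NA windows break the track into separate
#' declaration blocks.
#'
#' @param track a [SignalTrack-class].
#' @param path output path.
#' @param digits significant digits for values.
#' @export
writeWig <- function(track, path, digits = 4L) {
  out <- character()
  for (chrom in names(track@values)) {
    v <- track@values[[chrom]]
    ok <- !is.na(v)
    if (!any(ok)) next
    runs <- rle(ok)
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
    for (r in which(runs$values)) {
      idx <- starts[r]:ends[r]
      out <- c(out,
               sprintf("fixedStep chrom=%s start=%d step=%d span=%d",
                       chrom, (idx[1] - 1L) * track@step + 1L, track@step, track@step),
               formatC(v[idx], digits = digits, format = "g"))
    }
  }
  writeTextLines(out, path)
}
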