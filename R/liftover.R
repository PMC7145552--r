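#' Lift a reference interval through one species' chains
#'
#' Minimal chain-based liftover of a short interval: the highest-scoring
#' chain overlapping the interval is selected, every base is mapped through
#' its gapless blocks, and the lift succeeds if at least \code{minRatio} of
#' the bases map within that single chain and their image is one contiguous
#' query interval. Query-minus-strand images are reported in forward
#' coordinates.
#'
#' @param chrom,start,end 0-based half-open reference interval.
#' @param chains a [ChainSet-class].
#' @param minRatio minimum fraction of mapped bases (default 0.95,
#'   approximating the liftOver tool's minMatch default).
#' @return list with \code{mapped} (logical), \code{reason} (\code{"ok"},
#'   \code{"deleted/no chain"}, \code{"partial"}, \code{"split"}),
#'   \code{q_name}, \code{q_start}, \code{q_end} (forward coordinates).
#' @export
liftInterval <- function(chrom, start, end, chains, minRatio = 0.95) {
  stopifnot(end > start)
  cand <- Filter(function(ch) ch$t_name == chrom && ch$t_start < end &&
                   ch$t_end > start, chains@chains)
  if (!length(cand))
    return(list(mapped = FALSE, reason = "deleted/no chain",
                q_name = NA_character_, q_start = NA, q_end = NA))
  best <- cand[[which.max(vapply(cand, `[[`, 0, "score"))]]
  img <- mapBasesThroughChain(start:(end - 1L), best)
  nMapped <- sum(!is.na(img))
  if (nMapped / (end - start) < minRatio) {
    reason <- if (length(cand) > 1L && nMapped < (end - start)) "split" else "partial"
    return(list(mapped = FALSE, reason = reason,
                q_name = best$q_name, q_start = NA, q_end = NA))
  }
  m <- img[!is.na(img)]
  if (max(m) - min(m) + 1L != nMapped)
    return(list(mapped = FALSE, reason = "split", q_name = best$q_name,
                q_start = NA, q_end = NA))
  list(mapped = TRUE, reason = "ok", q_name = best$q_name,
       q_start = min(m), q_end = max(m) + 1)
}

# Map 0-based target bases through one chain; NA where unaligned.
# Returns forward-strand query coordinates.
mapBasesThroughChain <- function(pos, chain) {
  b <- chain$blocks
  out <- rep(NA_real_, length(pos))
  keep <- b[, "t_start"] + b[, "size"] > min(pos) & b[, "t_start"] <= max(pos)
  b <- b[keep, , drop = FALSE]
  for (i in seq_len(nrow(b))) {
    ts <- b[i, "t_start"]; qs <- b[i, "q_start"]; sz <- b[i, "size"]
    k <- pos >= ts & pos < ts + sz
    if (!any(k)) next
    off <- pos[k] - ts
    out[k] <- if (chain$q_strand == "-") qs + (sz - 1) - off else qs + off
  }
  out
}

#' Cross-species presence matrix of binding events
#'
#' Lifts a short region around each summit (default 10 bp) to every
#' species and records \code{"mapped"}, \code{"unmapped"} or
#' \code{"no_data"} (species without chain data).
#'
#' @param events binding events data.frame with \code{chrom}, \code{pos}.
#' @param chainSets named list of [ChainSet-class] per species; a NULL
#'   element marks a species with no chain data.
#' @param flank half-width of the lifted region (default 5, i.e. a 10-bp
#'   query).
#' @param minRatio passed to [liftInterval()].
#' @return character matrix, events x species.
#' @export
presenceMatrix <- function(events, chainSets, flank = 5L, minRatio = 0.95) {
  stopifnot(length(chainSets) >= 1L)
  sp <- names(chainSets)
  out <- matrix("no_data", nrow = nrow(events), ncol = length(sp),
                dimnames = list(NULL, sp))
  for (s in sp) {
    cs <- chainSets[[s]]
    if (is.null(cs) || length(cs@chains) == 0L) next
    for (i in seq_len(nrow(events))) {
      lo <- max(0L, events$pos[i] - flank)
      r <- liftInterval(events$chrom[i], lo, events$pos[i] + flank, cs, minRatio)
      out[i, s] <- if (r$mapped) "mapped" else "unmapped"
    }
  }
  out
}

# Clade label for an internal node (node.label), or a synthesized label.
cladeLabel <- function(tree, node) {
  nTips <- length(tree$tip.label)
  lbl <- if (!is.null(tree$node.label)) tree$node.label[node - nTips] else ""
  if (is.null(lbl) || is.na(lbl) || lbl == "")
    paste0("node", node) else lbl
}

#' Assign the clade of origin for one binding event
#'
#' Among the species whose ortholog was detected, find the most distantly
#' related species from the reference on the tree (the species whose MRCA
#' with the reference is oldest); the origin clade is that MRCA's label.
#' \code{no_data} species never determine the call. If the event lies in a
#' TE subfamily with a known limited species distribution, an apparent
#' mapping outside that range is flagged inconsistent and the call is
#' capped at the subfamily's maximal clade.
#'
#' @param presence named character vector for one event (values
#'   \code{"mapped"}/\code{"unmapped"}/\code{"no_data"}).
#' @param tree \code{phylo} species tree with labeled internal nodes.
#' @param reference reference species tip label.
#' @param subfamilyClade optional maximal clade label for the host
#'   subfamily (from the known subfamily range table).
#' @return list with \code{origin_clade}, \code{most_distant_species},
#'   \code{inconsistent} flag.
#' @export
assignOrigin <- function(presence, tree, reference, subfamilyClade = NULL) {
  mapped <- names(presence)[presence == "mapped"]
  mapped <- setdiff(mapped, reference)
  unknown <- setdiff(mapped, tree$tip.label)
  if (length(unknown))
    pkgStop("mapped species not in tree: %s", paste(unknown, collapse = ", "))
  if (!length(mapped))
    return(list(origin_clade = paste0(reference, "-specific"),
                most_distant_species = NA_character_, inconsistent = FALSE))
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(1, nrow(tree$edge))
  mr <- ape::mrca(tree)
  rootDepth <- ape::node.depth.edgelength(tree)
  nodes <- as.integer(vapply(mapped, function(s) mr[reference, s], 0))
  best <- which.min(rootDepth[nodes])   # oldest MRCA = closest to root
  originNode <- nodes[best]
  inconsistent <- FALSE
  if (!is.null(subfamilyClade)) {
    capNode <- cladeNode(tree, subfamilyClade)
    if (!is.na(capNode) && !(originNode %in% c(capNode, descendantNodes(tree, capNode)))) {
      # apparent origin older than the subfamily's known range: cap it
      inconsistent <- TRUE
      originNode <- capNode
    }
  }
  list(origin_clade = cladeLabel(tree, originNode),
       most_distant_species = mapped[best], inconsistent = inconsistent)
}

cladeNode <- function(tree, label) {
  if (is.null(tree$node.label)) return(NA_integer_)
  i <- match(label, tree$node.label)
  if (is.na(i)) return(NA_integer_)
  length(tree$tip.label) + i
}

descendantNodes <- function(tree, node) {
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  if (!length(kids)) return(integer())
  c(kids, unlist(lapply(kids, descendantNodes, tree = tree)))
}

#' Clade-of-origin calls for a set of binding events
#'
#' @param events binding events data.frame.
#' @param presence presence matrix from [presenceMatrix()].
#' @param tree species tree (\code{phylo}).
#' @param reference reference species.
#' @param subfamilyRanges optional data.frame with columns
#'   \code{subfamily}, \code{max_clade} giving the known maximal clade of
#'   each subfamily.
#' @return events with \code{origin_clade}, \code{most_distant_species},
#'   \code{origin_inconsistent} columns appended.
#' @export
assignOrigins <- function(events, presence, tree, reference,
                          subfamilyRanges = NULL) {
  res <- lapply(seq_len(nrow(events)), function(i) {
    cap <- NULL
    if (!is.null(subfamilyRanges) && isTRUE(events$in_te[i])) {
      j <- match(events$subfamily[i], subfamilyRanges$subfamily)
      if (!is.na(j)) cap <- subfamilyRanges$max_clade[j]
    }
    assignOrigin(presence[i, ], tree, reference, cap)
  })
  events$origin_clade <- vapply(res, `[[`, "", "origin_clade")
  events$most_distant_species <- vapply(res, function(r)
    as.character(r$most_distant_species), "")
  events$origin_inconsistent <- vapply(res, `[[`, TRUE, "inconsistent")
  events
}

#' Clade composition of binding events per group
#'
#' @param events output of [assignOrigins()].
#' @param by grouping column (e.g. \code{"factor"}, \code{"family"},
#'   \code{"rollup"}).
#' @return data.frame of per-group clade proportions (each group sums
#'   to 1).
#' @export
cladeComposition <- function(events, by = "factor") {
  stopifnot(nrow(events) > 0L)
  tab <- table(events[[by]], events$origin_clade)
  prop <- prop.table(tab, margin = 1)
  df <- as.data.frame(prop, stringsAsFactors = FALSE)
  names(df) <- c(by, "origin_clade", "proportion")
  df
}

#' Divergence-based age distribution of TE copies or bound events
#'
#' Histogram of percent divergence from the consensus in 1%-wide bins,
#' per group. For bound events, each event contributes its host copy's
#' divergence.
#'
#' @param divergence numeric vector of percent divergences.
#' @param group grouping vector (family or category), same length.
#' @return data.frame with \code{group}, \code{bin} (lower edge), and
#'   \code{count}; counts sum to \code{length(divergence)}.
#' @export
ageDistribution <- function(divergence, group) {
  stopifnot(length(divergence) == length(group), all(divergence >= 0))
  bin <- floor(divergence)
  agg <- stats::aggregate(list(count = rep(1L, length(bin))),
                          by = list(group = group, bin = bin), FUN = sum)
  agg[order(agg$group, agg$bin), , drop = FALSE]
}
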