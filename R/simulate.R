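#' Default synthetic-study configuration
#'
#' Configuration for the synthetic toy dataset: a small mammalian-like
#' genome carrying TE copies with lineage-dated insertions, 5'-truncation
#' and divergence from their consensus, transcription-factor summits
#' preferentially placed at motif instances planted in specific TE
#' subfamilies, conservation elevated at bound sites, and per-species
#' chains consistent with the insertion ages. Defaults emulate the
#' structure the analysis assumes: two chromosomes of 2 Mb, ~3000 TE
#' copies (~50% of the genome), ~2000 summits over five factors, and an
#' 8-species amniote-like tree with labeled clades.
#'
#' @param seed master RNG seed for the bundle.
#' @param ... named overrides of any default field (see the function body
#'   for the full field list: \code{chromLengths}, \code{treeNewick},
#'   \code{reference}, \code{teLibrary}, \code{motifPlantings},
#'   \code{summitModel}, \code{hotLocus}, \code{indelProb},
#'   \code{conservation}, \code{dhs}, \code{nGenesPerChrom},
#'   \code{emitReads}, \code{nReads}).
#' @return a list of class \code{SimConfig}.
#' @export
simConfig <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    chromLengths = c(chr1 = 2000000L, chr2 = 2000000L),
    treeNewick = paste0(
      "((((((human,chimp)Hominini,rhesus)Catarrhini,marmoset)Simiiformes,",
      "mouse)Euarchontoglires,(dog,cow)Laurasiatheria)Boreoeutheria,",
      "opossum)Theria;"),
    reference = "human",
    teLibrary = data.frame(
      subfamily = c("MIR", "L2", "L1MD", "MER41A", "MER49", "MLT1A",
                    "AluY", "Charlie1"),
      family = c("MIR", "L2", "L1", "ERV1", "ERV1", "MaLR", "Alu",
                 "hAT-Charlie"),
      class = c("SINE", "LINE", "LINE", "LTR", "LTR", "LTR", "SINE", "DNA"),
      consensusLength = c(260L, 3000L, 4000L, 600L, 550L, 400L, 300L, 500L),
      nCopies = c(600L, 350L, 150L, 300L, 250L, 500L, 600L, 250L),
      insertionClade = c("Theria", "Theria", "Boreoeutheria", "Simiiformes",
                         "Catarrhini", "Boreoeutheria", "Catarrhini",
                         "Theria"),
      divMean = c(25, 22, 12, 8, 6, 15, 3, 20),
      divSd = c(3, 3, 2, 1.5, 1, 2, 1, 3),
      truncProb = c(0.2, 0.8, 0.85, 0.1, 0.1, 0.2, 0.05, 0.2),
      truncMaxFrac = c(0.3, 0.9, 0.9, 0.2, 0.2, 0.3, 0.2, 0.3),
      stringsAsFactors = FALSE),
    motifPlantings = data.frame(
      subfamily = c("MIR", "L2", "MER41A", "L2", "MIR", "MLT1A"),
      motif = c("ERE", "ERE", "ERE", "FOXA1", "GATA3", "AP2G"),
      consStart = c(150L, 2600L, 300L, 1200L, 60L, 200L),
      stringsAsFactors = FALSE),
    motifSeqs = c(ERE = "AGGTCANNNTGACCT", FOXA1 = "TGTTTACTTTGG",
                  GATA3 = "AGATAAGA", AP2G = "GCCTGAGGC"),
    summitModel = data.frame(
      factor = c("ERa", "ERa", "ERa", "ERa",
                 "FoxA1", "FoxA1", "GATA3", "GATA3",
                 "AP2g", "AP2g", "p300", "p300"),
      mode = c("motif", "motif", "motif", "background",
               "motif", "background", "motif", "background",
               "motif", "background", "motif", "background"),
      subfamily = c("MIR", "L2", "MER41A", NA,
                    "L2", NA, "MIR", NA, "MLT1A", NA, "MIR", NA),
      count = c(250L, 150L, 100L, 300L,
                200L, 200L, 150L, 150L, 150L, 250L, 50L, 50L),
      cobindWith = c(NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, "ERa", NA),
      stringsAsFactors = FALSE),
    hotLocus = list(chrom = "chr2", start = 1200000L, end = 1300000L,
                    subfamily = "MIR", nCopies = 60L, factor = "ERa"),
    indelProb = 0,
    motifProtected = TRUE,
    conservation = list(baselineMean = 0.02, baselineSd = 0.1,
                        uplift = 0.4, upliftFlank = 20L),
    dhs = list(baselineMean = 0.5, baselineSd = 0.3, uplift = 3,
               upliftFlank = 100L),
    nGenesPerChrom = 15L,
    emitReads = TRUE,
    nReads = 10000L)
  over <- list(...)
  for (i in seq_along(over)) cfg[names(over)[i]] <- over[i]
  validateSimConfig(cfg)
  class(cfg) <- "SimConfig"
  cfg
}

validateSimConfig <- function(cfg) {
  tree <- ape::read.tree(text = cfg$treeNewick)
  clades <- c(tree$tip.label, tree$node.label)
  bad <- setdiff(cfg$teLibrary$insertionClade, clades)
  if (length(bad)) pkgStop("insertion clades not in tree: %s",
                           paste(bad, collapse = ", "))
  lib <- cfg$teLibrary
  for (i in seq_len(nrow(cfg$motifPlantings))) {
    pl <- cfg$motifPlantings[i, ]
    L <- lib$consensusLength[match(pl$subfamily, lib$subfamily)]
    w <- nchar(cfg$motifSeqs[[pl$motif]])
    if (is.na(L) || pl$consStart + w > L)
      pkgStop("planted motif %s outside consensus of %s", pl$motif, pl$subfamily)
  }
  invisible(TRUE)
}

# Species descending from a clade label (tip labels are their own clade).
cladeSpecies <- function(tree, label) {
  if (label %in% tree$tip.label) return(label)
  node <- cladeNode(tree, label)
  if (is.na(node)) pkgStop("unknown clade label: %s", label)
  tree$tip.label[descendantNodes(tree, node)[descendantNodes(tree, node) <=
                                               length(tree$tip.label)]]
}

# PWM with a dominant base per position from an IUPAC-ish string (N = uniform).
pwmFromString <- function(name, s, dominant = 0.91) {
  chars <- strsplit(toupper(s), "")[[1]]
  m <- vapply(chars, function(ch) {
    if (ch == "N") rep(0.25, 4)
    else {
      v <- rep((1 - dominant) / 3, 4)
      v[match(ch, BASES)] <- dominant
      v
    }
  }, numeric(4))
  MotifPWM(name, m)
}

# Most-probable sequence of a planted motif string (N -> A for determinism).
motifConsensusSeq <- function(s) gsub("N", "A", toupper(s))

revcompChr <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

randomDna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

#' Generate the synthetic study bundle
#'
#' Emits a fully self-consistent file bundle — genome FASTA, TE consensus
#' FASTA, RepeatMasker-style \code{.out}/\code{.align}, per-factor
#' narrowPeak summits, fixedStep conservation and 20-bp DHS tracks,
#' per-species chain files, species tree, gene table, conserved-element and
#' segmentation BEDs, taxonomy and subfamily-range tables, JASPAR motifs —
#' together with a ground-truth manifest (\code{manifest_*.tsv}) recording
#' every planted copy, summit and locus. Identical seeds give
#' byte-identical bundles.
#'
#' @param config a [simConfig()] list.
#' @param outdir output directory (created).
#' @return invisibly, the manifest as a list of data.frames.
#' @export
simulateBundle <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(outdir, "chains"), showWarnings = FALSE)
  withLocalSeed(config$seed, simulateBundleImpl(config, outdir))
}

simulateBundleImpl <- function(cfg, outdir) {
  tree <- ape::read.tree(text = cfg$treeNewick)
  lib <- cfg$teLibrary
  motifW <- vapply(cfg$motifSeqs, nchar, 0L)

  ## consensus sequences with planted motifs
  consensus <- list()
  for (i in seq_len(nrow(lib))) {
    s <- randomDna(lib$consensusLength[i])
    pls <- cfg$motifPlantings[cfg$motifPlantings$subfamily == lib$subfamily[i], ,
                              drop = FALSE]
    for (j in seq_len(nrow(pls))) {
      ms <- motifConsensusSeq(cfg$motifSeqs[[pls$motif[j]]])
      substr(s, pls$consStart[j] + 1L, pls$consStart[j] + nchar(ms)) <- ms
    }
    consensus[[lib$subfamily[i]]] <- s
  }

  ## protected consensus positions (0-based) per subfamily
  protected <- lapply(stats::setNames(lib$subfamily, lib$subfamily), function(sf) {
    pls <- cfg$motifPlantings[cfg$motifPlantings$subfamily == sf, , drop = FALSE]
    unlist(lapply(seq_len(nrow(pls)), function(j)
      seq(pls$consStart[j], pls$consStart[j] + motifW[[pls$motif[j]]] - 1L)))
  })

  ## realize copies (sequence + local alignment blocks)
  realize <- function(sf) {
    i <- match(sf, lib$subfamily)
    L <- lib$consensusLength[i]
    div <- max(0, stats::rnorm(1, lib$divMean[i], lib$divSd[i]))
    tfrac <- if (stats::runif(1) < lib$truncProb[i])
      stats::runif(1, 0, lib$truncMaxFrac[i]) else 0
    cs <- as.integer(floor(L * tfrac)); ce <- L
    len <- ce - cs
    chars <- strsplit(substring(consensus[[sf]], cs + 1L, ce), "")[[1]]
    subPos <- which(stats::runif(len) < div / 100)
    if (isTRUE(cfg$motifProtected) && length(protected[[sf]]))
      subPos <- setdiff(subPos, protected[[sf]] - cs + 1L)
    for (p in subPos)
      chars[p] <- sample(setdiff(BASES, chars[p]), 1L)
    realizedDiv <- length(subPos) / len * 100
    seqF <- paste(chars, collapse = "")
    # local forward blocks: g_start, g_end (copy-local), c_start, c_end
    blocks <- data.frame(g_start = 0L, g_end = len, c_start = cs, c_end = ce)
    if (stats::runif(1) < cfg$indelProb && len > 20L) {
      k <- sample(10:(len - 10L), 1L)
      d <- sample(3:7, 1L)
      seqF <- paste0(substring(seqF, 1, k), randomDna(d),
                     substring(seqF, k + 1L, len))
      blocks <- data.frame(g_start = c(0L, k + d),
                           g_end = c(k, len + d),
                           c_start = c(cs, cs + k), c_end = c(cs + k, ce))
    }
    strand <- sample(c("+", "-"), 1L)
    gl <- nchar(seqF)
    if (strand == "-") {
      seqF <- revcompChr(seqF)
      blocks <- data.frame(g_start = gl - blocks$g_end,
                           g_end = gl - blocks$g_start,
                           c_start = blocks$c_start, c_end = blocks$c_end)
      blocks <- blocks[order(blocks$g_start), , drop = FALSE]
    }
    list(subfamily = sf, strand = strand, seq = seqF, gl = gl,
         cs = cs, ce = ce, div = realizedDiv, tfrac = tfrac, blocks = blocks)
  }

  copyPool <- unlist(lapply(seq_len(nrow(lib)), function(i)
    rep(lib$subfamily[i], lib$nCopies[i])))
  copyPool <- sample(copyPool)
  copies <- lapply(copyPool, realize)

  hot <- cfg$hotLocus
  hotCopies <- if (!is.null(hot))
    lapply(seq_len(hot$nCopies), function(k) realize(hot$subfamily)) else list()

  ## placement: stick-breaking of gaps, hot locus reserved
  chromNamesV <- names(cfg$chromLengths)
  lens <- as.numeric(cfg$chromLengths)
  chromOf <- sample(chromNamesV, length(copies), replace = TRUE,
                    prob = lens / sum(lens))
  placed <- list()
  for (ch in chromNamesV) {
    idx <- which(chromOf == ch)
    cps <- copies[idx]
    Lc <- cfg$chromLengths[[ch]]
    resv <- if (!is.null(hot) && hot$chrom == ch) c(hot$start, hot$end) else NULL
    avail <- Lc - if (is.null(resv)) 0L else (resv[2] - resv[1])
    total <- sum(vapply(cps, `[[`, 0L, "gl"))
    if (total >= avail)
      pkgStop("copy placement overflow on %s: need > %d bp", ch, total)
    gls <- vapply(cps, `[[`, 0L, "gl")
    stickBreak <- function(glsSub, lo, hi) {
      # uniform non-overlapping placement of copies in [lo, hi)
      slack <- (hi - lo) - sum(glsSub)
      cuts <- sort(stats::runif(length(glsSub), 0, slack))
      as.integer(lo + floor(cuts) + cumsum(c(0L, glsSub))[seq_along(glsSub)])
    }
    if (is.null(resv)) {
      starts <- stickBreak(gls, 0L, Lc)
    } else {
      # split copies between the regions flanking the reserved interval
      cap <- c(resv[1], Lc - resv[2])
      for (try in 1:200) {
        side <- sample(1:2, length(cps), replace = TRUE, prob = cap)
        if (sum(gls[side == 1]) < cap[1] && sum(gls[side == 2]) < cap[2]) break
        if (try == 200) pkgStop("copy placement overflow around the reserved locus on %s", ch)
      }
      starts <- integer(length(cps))
      starts[side == 1] <- stickBreak(gls[side == 1], 0L, resv[1])
      starts[side == 2] <- stickBreak(gls[side == 2], resv[2], Lc)
    }
    for (k in seq_along(cps)) {
      cps[[k]]$chrom <- ch
      cps[[k]]$start <- starts[k]
    }
    placed <- c(placed, cps)
    if (!is.null(resv) && length(hotCopies)) {
      hs <- hot$start; he <- hot$end
      hTotal <- sum(vapply(hotCopies, `[[`, 0L, "gl"))
      if (hTotal >= he - hs) pkgStop("hot locus too small for its copies")
      hgls <- vapply(hotCopies, `[[`, 0L, "gl")
      hcuts <- sort(stats::runif(length(hotCopies), 0, (he - hs) - hTotal))
      hstarts <- as.integer(hs + floor(hcuts) +
                              cumsum(c(0L, hgls))[seq_along(hotCopies)])
      for (k in seq_along(hotCopies)) {
        hotCopies[[k]]$chrom <- ch
        hotCopies[[k]]$start <- hstarts[k]
        hotCopies[[k]]$hot <- TRUE
      }
      placed <- c(placed, hotCopies)
    }
  }
  ord <- order(vapply(placed, `[[`, "", "chrom"),
               vapply(placed, `[[`, 0L, "start"))
  placed <- placed[ord]
  for (k in seq_along(placed)) placed[[k]]$copy_id <-
    sprintf("cp%05d", k)

  copyDf <- do.call(rbind, lapply(placed, function(cp) data.frame(
    copy_id = cp$copy_id, chrom = cp$chrom, start = cp$start,
    end = cp$start + cp$gl, strand = cp$strand, subfamily = cp$subfamily,
    family = lib$family[match(cp$subfamily, lib$subfamily)],
    class = lib$class[match(cp$subfamily, lib$subfamily)],
    insertion_clade = lib$insertionClade[match(cp$subfamily, lib$subfamily)],
    divergence = round(cp$div, 1), trunc_frac = round(cp$tfrac, 4),
    cons_start = cp$cs, cons_end = cp$ce,
    hot = isTRUE(cp$hot), stringsAsFactors = FALSE)))

  ## genome sequence
  genomeChars <- lapply(cfg$chromLengths, function(Lc)
    sample(BASES, Lc, replace = TRUE))
  for (cp in placed) {
    genomeChars[[cp$chrom]][(cp$start + 1L):(cp$start + cp$gl)] <-
      strsplit(cp$seq, "")[[1]]
  }
  genome <- Biostrings::DNAStringSet(vapply(genomeChars, paste, "",
                                            collapse = ""))
  names(genome) <- chromNamesV

  ## alignment blocks in global coordinates
  alnBlocks <- do.call(rbind, lapply(placed, function(cp) {
    b <- cp$blocks
    data.frame(copy_id = cp$copy_id, consensus_name = cp$subfamily,
               strand = cp$strand,
               consensus_length = lib$consensusLength[match(cp$subfamily,
                                                            lib$subfamily)],
               chrom = cp$chrom, g_start = cp$start + b$g_start,
               g_end = cp$start + b$g_end, c_start = b$c_start,
               c_end = b$c_end, stringsAsFactors = FALSE)
  }))
  aln <- CopyAlignments(alnBlocks)

  ## summits
  mapConsToGenome <- function(cp, cpos) {
    b <- cp$blocks
    hit <- which(cpos >= b$c_start & cpos < b$c_end)[1]
    if (is.na(hit)) return(NA_integer_)
    as.integer(if (cp$strand == "+")
      cp$start + b$g_start[hit] + (cpos - b$c_start[hit])
    else cp$start + b$g_start[hit] + (b$c_end[hit] - 1L - cpos))
  }
  bySub <- split(seq_along(placed), vapply(placed, `[[`, "", "subfamily"))
  hotFlag <- vapply(placed, function(cp) isTRUE(cp$hot), TRUE)
  summitRows <- list()
  addSummit <- function(factor, chrom, pos, mode, copy_id, motif) {
    summitRows[[length(summitRows) + 1L]] <<- data.frame(
      factor = factor, chrom = chrom, pos = pos, mode = mode,
      copy_id = copy_id, motif = motif, stringsAsFactors = FALSE)
  }
  boundCopies <- list()   # factor -> copy indices holding a summit
  placeMotifSummits <- function(factor, sf, motif, count, hotOnly = FALSE,
                                cobindWith = NA_character_) {
    pl <- cfg$motifPlantings
    pl <- pl[pl$subfamily == sf & pl$motif == motif, , drop = FALSE][1, ]
    w <- motifW[[motif]]
    center <- pl$consStart + w %/% 2L
    cand <- bySub[[sf]]
    if (hotOnly) cand <- cand[hotFlag[cand]] else cand <- cand[!hotFlag[cand]]
    ok <- cand[vapply(cand, function(k) {
      b <- placed[[k]]$blocks
      any(pl$consStart >= b$c_start & pl$consStart + w <= b$c_end)
    }, TRUE)]
    if (!length(ok)) pkgStop("no copies of %s retain the %s motif", sf, motif)
    if (!is.na(cobindWith) && length(boundCopies[[cobindWith]])) {
      # co-binding: prefer copies already bound by the partner factor
      shared <- intersect(ok, boundCopies[[cobindWith]])
      if (length(shared)) ok <- shared
    }
    pick <- if (hotOnly && count <= length(ok))
      ok[sample.int(length(ok), count)]
    else ok[sample.int(length(ok), count, replace = TRUE)]
    boundCopies[[factor]] <<- union(boundCopies[[factor]], pick)
    for (k in pick) {
      cp <- placed[[k]]
      jit <- sample(-2:2, 1L)
      cpos <- min(max(center + jit, pl$consStart), pl$consStart + w - 1L)
      g <- mapConsToGenome(cp, cpos)
      addSummit(factor, cp$chrom, g, if (hotOnly) "hot" else "motif",
                cp$copy_id, motif)
    }
  }
  cum <- cumsum(lens)
  for (i in seq_len(nrow(cfg$summitModel))) {
    sm <- cfg$summitModel[i, ]
    if (sm$mode == "background") {
      draws <- floor(stats::runif(sm$count, 0, sum(lens)))
      ci <- findInterval(draws, cum) + 1L
      for (k in seq_len(sm$count))
        addSummit(sm$factor, chromNamesV[ci[k]],
                  as.integer(draws[k] - c(0, cum)[ci[k]]), "background",
                  NA_character_, NA_character_)
    } else if (sm$mode == "uniform_te") {
      cand <- bySub[[sm$subfamily]]
      # length-weighted copy choice = uniform over the subfamily's bases
      gls <- vapply(placed[cand], `[[`, 0L, "gl")
      pick <- cand[sample.int(length(cand), sm$count, replace = TRUE,
                              prob = gls)]
      for (k in pick) {
        cp <- placed[[k]]
        b <- cp$blocks[sample(nrow(cp$blocks), 1L,
                              prob = cp$blocks$g_end - cp$blocks$g_start), ]
        g <- cp$start + sample(b$g_start:(b$g_end - 1L), 1L)
        addSummit(sm$factor, cp$chrom, g, "uniform_te", cp$copy_id,
                  NA_character_)
      }
    } else {
      motif <- cfg$motifPlantings$motif[
        cfg$motifPlantings$subfamily == sm$subfamily][1]
      # factor-matched planting if available
      fm <- switch(sm$factor, ERa = "ERE", FoxA1 = "FOXA1", GATA3 = "GATA3",
                   AP2g = "AP2G", p300 = NA_character_, NA_character_)
      pls <- cfg$motifPlantings[cfg$motifPlantings$subfamily == sm$subfamily, ,
                                drop = FALSE]
      if (!is.na(fm) && fm %in% pls$motif) motif <- fm
      cb <- if ("cobindWith" %in% names(sm)) sm$cobindWith else NA_character_
      placeMotifSummits(sm$factor, sm$subfamily, motif, sm$count,
                        cobindWith = cb)
    }
  }
  if (!is.null(hot) && length(hotCopies)) {
    motif <- cfg$motifPlantings$motif[
      cfg$motifPlantings$subfamily == hot$subfamily][1]
    placeMotifSummits(hot$factor, hot$subfamily, motif, hot$nCopies,
                      hotOnly = TRUE)
  }
  summitDf <- do.call(rbind, summitRows)
  ## background draws can land inside a TE copy: record the host
  for (i in which(is.na(summitDf$copy_id))) {
    onCh <- copyDf[copyDf$chrom == summitDf$chrom[i], ]
    j <- findInterval(summitDf$pos[i], onCh$start)
    if (j >= 1L && summitDf$pos[i] < onCh$end[j])
      summitDf$copy_id[i] <- onCh$copy_id[j]
  }
  ## true origin clade: host copy's insertion clade, else root clade
  ## (background sequence is ancestral to every species in the tree)
  rootLabel <- cladeLabel(tree, length(tree$tip.label) + 1L)
  summitDf$true_origin_clade <- ifelse(
    is.na(summitDf$copy_id), rootLabel,
    copyDf$insertion_clade[match(summitDf$copy_id, copyDf$copy_id)])

  ## write sequence + annotation files
  Biostrings::writeXStringSet(genome, file.path(outdir, "genome.fa"))
  consSet <- Biostrings::DNAStringSet(unlist(consensus))
  Biostrings::writeXStringSet(consSet, file.path(outdir, "consensus.fa"))
  teGr <- grFromHalfOpen(copyDf$chrom, copyDf$start, copyDf$end,
                         strand = copyDf$strand)
  S4Vectors::mcols(teGr) <- S4Vectors::DataFrame(
    subfamily = copyDf$subfamily, family = copyDf$family,
    class = copyDf$class, divergence = copyDf$divergence,
    copy_id = copyDf$copy_id)
  writeRepeatMaskerOut(teGr, file.path(outdir, "repeats.out"))
  writeRepeatMaskerAlign(aln, file.path(outdir, "repeats.align"),
                         genomeSeqs = genome, consensusSeqs = consSet)
  for (f in unique(summitDf$factor)) {
    sd <- summitDf[summitDf$factor == f, ]
    gr <- summitGRanges(sd$chrom, sd$pos, factor = sd$factor,
                        score = rep(100, nrow(sd)))
    writeNarrowPeak(gr, file.path(outdir, sprintf("summits_%s.narrowPeak", f)))
  }

  ## signal tracks
  teSummits <- summitDf[!is.na(summitDf$copy_id), ]
  consTrack <- list()
  for (ch in chromNamesV) {
    v <- stats::rnorm(cfg$chromLengths[[ch]], cfg$conservation$baselineMean,
                      cfg$conservation$baselineSd)
    for (p in teSummits$pos[teSummits$chrom == ch]) {
      lo <- max(1L, p + 1L - cfg$conservation$upliftFlank)
      hi <- min(length(v), p + 1L + cfg$conservation$upliftFlank)
      v[lo:hi] <- v[lo:hi] + cfg$conservation$uplift
    }
    consTrack[[ch]] <- round(v, 3)
  }
  writeWig(SignalTrack(consTrack, 1L), file.path(outdir, "conservation.wig"))
  dhsTrack <- list()
  for (ch in chromNamesV) {
    nw <- as.integer(ceiling(cfg$chromLengths[[ch]] / 20))
    v <- abs(stats::rnorm(nw, cfg$dhs$baselineMean, cfg$dhs$baselineSd))
    for (p in summitDf$pos[summitDf$chrom == ch]) {
      lo <- max(1L, (p - cfg$dhs$upliftFlank) %/% 20L + 1L)
      hi <- min(nw, (p + cfg$dhs$upliftFlank) %/% 20L + 1L)
      v[lo:hi] <- v[lo:hi] + cfg$dhs$uplift
    }
    dhsTrack[[ch]] <- round(v, 3)
  }
  writeWig(SignalTrack(dhsTrack, 20L), file.path(outdir, "dhs.wig"))

  ## chains: one per chromosome per non-reference species
  speciesAll <- setdiff(tree$tip.label, cfg$reference)
  copyClades <- copyDf$insertion_clade
  for (sp in speciesAll) {
    chains <- list()
    for (ch in chromNamesV) {
      Lc <- cfg$chromLengths[[ch]]
      onCh <- copyDf$chrom == ch
      shared <- vapply(copyClades[onCh], function(cl)
        sp %in% cladeSpecies(tree, cl), TRUE)
      gaps <- copyDf[onCh, ][!shared, , drop = FALSE]
      gaps <- gaps[order(gaps$start), , drop = FALSE]
      bStarts <- c(0L, gaps$end)
      bEnds <- c(gaps$start, Lc)
      keep <- bEnds > bStarts
      bStarts <- bStarts[keep]; bEnds <- bEnds[keep]
      sizes <- bEnds - bStarts
      qStarts <- cumsum(c(0L, sizes[-length(sizes)]))
      qSize <- sum(sizes)
      chains[[length(chains) + 1L]] <- list(
        score = qSize, t_name = ch, t_size = Lc, t_start = bStarts[1],
        t_end = bEnds[length(bEnds)], q_name = ch, q_size = qSize,
        q_strand = "+", q_start = 0, q_end = qSize,
        id = paste0(sp, "_", ch),
        blocks = cbind(t_start = bStarts, q_start = qStarts, size = sizes))
    }
    writeChain(ChainSet(sp, chains),
               file.path(outdir, "chains", paste0(sp, ".chain")))
  }

  ## tree, taxonomy, subfamily ranges, motifs
  writeTextLines(cfg$treeNewick, file.path(outdir, "tree.nwk"))
  utils::write.table(lib[, c("subfamily", "family", "class")],
                     file.path(outdir, "taxonomy.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(subfamily = lib$subfamily,
                                max_clade = lib$insertionClade),
                     file.path(outdir, "subfamily_ranges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pwms <- lapply(names(cfg$motifSeqs), function(nm)
    pwmFromString(nm, cfg$motifSeqs[[nm]]))
  writeJasparPfm(pwms, file.path(outdir, "motifs.jaspar"))

  ## genes
  geneRows <- list()
  for (ch in chromNamesV) {
    Lc <- cfg$chromLengths[[ch]]
    n <- cfg$nGenesPerChrom
    gMax <- max(1000L, min(20000L, Lc %/% 5L))
    gMin <- max(500L, gMax %/% 4L)
    starts <- sort(sample.int(max(1L, Lc - gMax - 1000L), n))
    for (g in seq_len(n)) {
      txs <- starts[g]; txe <- txs + sample(gMin:gMax, 1L)
      nEx <- sample(2:5, 1L)
      exMax <- max(60L, min(400L, (txe - txs) %/% (2L * nEx)))
      exLen <- sample((exMax %/% 2L):exMax, nEx, replace = TRUE)
      exGap <- floor((txe - txs - sum(exLen)) / nEx)
      es <- txs + cumsum(c(0L, exLen[-nEx] + exGap))
      ee <- es + exLen
      cdsS <- es[1] + 30L; cdsE <- ee[nEx] - 30L
      geneRows[[length(geneRows) + 1L]] <- data.frame(
        geneName = sprintf("gene_%s_%d", ch, g),
        name = sprintf("tx_%s_%d", ch, g), chrom = ch,
        strand = sample(c("+", "-"), 1L), txStart = txs, txEnd = txe,
        cdsStart = cdsS, cdsEnd = cdsE, exonCount = nEx,
        exonStarts = paste(es, collapse = ","),
        exonEnds = paste(ee, collapse = ","), stringsAsFactors = FALSE)
    }
  }
  geneDf <- do.call(rbind, geneRows)
  writeGenes(geneDf, file.path(outdir, "genes.tsv"))

  ## conserved elements: around a subset of TE summits + random elements
  ceRows <- list()
  pickCe <- stats::runif(nrow(teSummits)) < 0.3
  for (i in which(pickCe)) {
    p <- teSummits$pos[i]
    ceRows[[length(ceRows) + 1L]] <- data.frame(
      chrom = teSummits$chrom[i], start = max(0L, p - 15L), end = p + 15L,
      lod = sample(70:120, 1L))
  }
  for (k in seq_len(200)) {
    ch <- sample(chromNamesV, 1L)
    s <- sample.int(cfg$chromLengths[[ch]] - 200L, 1L)
    len <- sample(c(sample(10:20, 1L), sample(25:80, 1L)), 1L)
    lod <- sample(c(sample(20:60, 1L), sample(61:150, 1L)), 1L)
    ceRows[[length(ceRows) + 1L]] <- data.frame(chrom = ch, start = s,
                                                end = s + len, lod = lod)
  }
  ceDf <- do.call(rbind, ceRows)
  ceDf <- ceDf[order(ceDf$chrom, ceDf$start), ]
  writeTextLines(sprintf("%s\t%d\t%d\tlod=%d\t%d", ceDf$chrom, ceDf$start,
                         ceDf$end, ceDf$lod, pmin(1000L, ceDf$lod * 5L)),
                 file.path(outdir, "conserved_elements.bed"))

  ## 8-state segmentation: promoters at TSSs, enhancers at summits
  states <- c("E1_promoter_active", "E2_promoter_weak", "E3_enhancer_strong",
              "E4_enhancer_weak", "E5_transcribed", "E6_insulator",
              "E7_repressed", "E8_quiescent")
  segRows <- list()
  for (ch in chromNamesV) {
    Lc <- cfg$chromLengths[[ch]]
    paint <- rep(8L, Lc %/% 200L + 1L)   # 200-bp painting resolution
    mark <- function(lo, hi, st) {
      lo <- max(1L, lo %/% 200L + 1L); hi <- min(length(paint), hi %/% 200L + 1L)
      paint[lo:hi] <<- st
    }
    nseg <- 40L
    segMax <- max(600L, min(15000L, Lc %/% 10L))
    for (k in seq_len(nseg)) {
      s <- sample.int(max(1L, Lc - segMax - 1000L), 1L)
      mark(s, s + sample((segMax %/% 5L):segMax, 1L), sample(c(5L, 6L, 7L), 1L))
    }
    gOn <- geneDf[geneDf$chrom == ch, ]
    for (g in seq_len(nrow(gOn))) {
      tss <- if (gOn$strand[g] == "-") gOn$txEnd[g] - 1L else gOn$txStart[g]
      mark(tss - 1000L, tss + 1000L, sample(c(1L, 2L), 1L, prob = c(0.7, 0.3)))
    }
    sOn <- summitDf[summitDf$chrom == ch, ]
    for (i in seq_len(nrow(sOn))) {
      st <- sample(c(3L, 4L, 8L), 1L, prob = c(0.45, 0.25, 0.3))
      if (st != 8L) mark(sOn$pos[i] - 400L, sOn$pos[i] + 400L, st)
    }
    r <- rle(paint)
    ends <- pmin(cumsum(r$lengths) * 200L, Lc)
    starts <- c(0L, ends[-length(ends)])
    keep <- ends > starts
    segRows[[ch]] <- data.frame(chrom = ch, start = starts[keep],
                                end = ends[keep],
                                state = states[r$values[keep]])
  }
  segDf <- do.call(rbind, segRows)
  writeTextLines(sprintf("%s\t%d\t%d\t%s", segDf$chrom, segDf$start,
                         segDf$end, segDf$state),
                 file.path(outdir, "segmentation.bed"))

  ## optional reads around summits (chromatin-mark-like coverage)
  if (isTRUE(cfg$emitReads)) {
    n <- cfg$nReads
    nearSummit <- floor(n * 0.6)
    idx <- sample.int(nrow(summitDf), nearSummit, replace = TRUE)
    off <- as.integer(round(stats::rnorm(nearSummit, 0, 300)))
    rch <- summitDf$chrom[idx]
    rst <- pmax(0L, summitDf$pos[idx] + off - 50L)
    bg <- n - nearSummit
    draws <- floor(stats::runif(bg, 0, sum(lens)))
    ci <- findInterval(draws, cum) + 1L
    rch <- c(rch, chromNamesV[ci])
    rst <- as.integer(c(rst, draws - c(0, cum)[ci]))
    ordR <- order(rch, rst)
    writeTextLines(sprintf("%s\t%d\t%d\tread%d\t0\t+", rch[ordR], rst[ordR],
                           rst[ordR] + 100L, seq_along(ordR)),
                   file.path(outdir, "reads_marks.bed"))
  }

  ## manifest
  manifest <- list(copies = copyDf, summits = summitDf,
                   plantings = cfg$motifPlantings,
                   hot_locus = if (is.null(hot)) NULL else
                     data.frame(chrom = hot$chrom, start = hot$start,
                                end = hot$end, n_copies = hot$nCopies))
  utils::write.table(copyDf, file.path(outdir, "manifest_copies.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(summitDf, file.path(outdir, "manifest_summits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cfg$motifPlantings,
                     file.path(outdir, "manifest_plantings.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(manifest$hot_locus))
    utils::write.table(manifest$hot_locus,
                       file.path(outdir, "manifest_hot_locus.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(chrom = chromNamesV,
                                length = as.integer(lens)),
                     file.path(outdir, "chrom_sizes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(manifest)
}

#' Audit a synthetic bundle against its manifest
#'
#' Re-parses every emitted file with the package's readers and verifies
#' consistency with the ground-truth manifest: copy intervals and
#' subfamilies in the \code{.out}, alignment block consistency with the
#' recorded truncation, summit positions inside their host copies, and the
#' chain mappability pattern implied by insertion clades (a region inside a
#' copy lifts to exactly the species of its insertion clade; background
#' lifts everywhere), on a sample of copies.
#'
#' @param bundleDir directory written by [simulateBundle()].
#' @param nSample copies sampled for the chain mappability check.
#' @return list with \code{pass} (logical) and \code{failures} (character).
#' @export
auditBundle <- function(bundleDir, nSample = 25L) {
  fail <- character()
  chk <- function(cond, msg, ...) {
    if (!isTRUE(cond)) fail <<- c(fail, sprintf(msg, ...))
  }
  man <- utils::read.table(file.path(bundleDir, "manifest_copies.tsv"),
                           header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  sm <- utils::read.table(file.path(bundleDir, "manifest_summits.tsv"),
                          header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  tax <- readTaxonomy(file.path(bundleDir, "taxonomy.tsv"))
  copies <- readRepeatMaskerOut(file.path(bundleDir, "repeats.out"), tax)
  chk(length(copies) == nrow(man), "copy count mismatch: .out %d vs manifest %d",
      length(copies), nrow(man))
  mc <- S4Vectors::mcols(copies)
  i <- match(man$copy_id, mc$copy_id)
  chk(!anyNA(i), "manifest copies missing from .out")
  if (!anyNA(i)) {
    chk(all(GenomicRanges::start(copies)[i] - 1L == man$start) &&
          all(GenomicRanges::end(copies)[i] == man$end),
        "copy intervals differ between .out and manifest")
    chk(all(mc$subfamily[i] == man$subfamily), "subfamily mismatch in .out")
  }
  aln <- readRepeatMaskerAlign(file.path(bundleDir, "repeats.align"))
  b <- alignmentBlocks(aln)
  perCopyCs <- tapply(b$c_start, b$copy_id, min)
  j <- match(man$copy_id, names(perCopyCs))
  chk(!anyNA(j) && all(perCopyCs[j] == man$cons_start),
      "alignment consensus starts differ from recorded truncation")
  inTe <- !is.na(sm$copy_id)
  k <- match(sm$copy_id[inTe], man$copy_id)
  chk(all(sm$pos[inTe] >= man$start[k]) && all(sm$pos[inTe] < man$end[k]),
      "summits outside their host copies")
  tree <- readSpeciesTree(file.path(bundleDir, "tree.nwk"))
  chainFiles <- list.files(file.path(bundleDir, "chains"),
                           pattern = "\\.chain$", full.names = TRUE)
  chainSets <- lapply(chainFiles, readChain)
  names(chainSets) <- vapply(chainSets, function(x) x@species, "")
  sampleIdx <- if (nrow(man) > nSample)
    seq(1L, nrow(man), length.out = nSample) else seq_len(nrow(man))
  for (ii in as.integer(sampleIdx)) {
    width <- man$end[ii] - man$start[ii]
    if (width < 30L) next
    mid <- (man$start[ii] + man$end[ii]) %/% 2L
    expectSp <- cladeSpecies(tree, man$insertion_clade[ii])
    for (sp in names(chainSets)) {
      r <- liftInterval(man$chrom[ii], mid - 5L, mid + 5L, chainSets[[sp]])
      should <- sp %in% expectSp
      chk(r$mapped == should,
          "chain mappability wrong for copy %s in %s (expected %s)",
          man$copy_id[ii], sp, if (should) "mapped" else "unmapped")
    }
  }
  list(pass = length(fail) == 0L, failures = fail)
}
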