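#' Build a run configuration for the end-to-end pipeline
#'
#' Collects input paths (defaulting to the layout written by
#' [simulateBundle()]) and analysis parameters into a validated list.
#'
#' @param bundleDir directory holding the input files.
#' @param outDir output directory for stage TSVs and the run record.
#' @param excludeChroms chromosomes excluded from genome fractions.
#' @param alpha significance level for corrected p-values.
#' @param flank conservation/DHS meta-profile flank (bp).
#' @param smooth meta-profile moving-average width (bp).
#' @param minProfileEvents minimum in-TE events for a subfamily x factor
#'   profile.
#' @param densityWidth,densityStep density-scan window and step (bp).
#' @param liftFlank half-width of lifted summit regions (bp).
#' @param minRatio liftover minimum mapped-base ratio.
#' @param seeds named list of stage seeds (\code{random_sites},
#'   \code{uniformity}).
#' @param rollup named state-to-rollup map for the segmentation.
#' @return list of class \code{RunConfig}.
#' @export
runConfig <- function(bundleDir, outDir = file.path(bundleDir, "results"),
                      excludeChroms = character(), alpha = 0.05,
                      flank = 400L, smooth = 10L, minProfileEvents = 30L,
                      densityWidth = 100000L, densityStep = 50000L,
                      liftFlank = 5L, minRatio = 0.95,
                      seeds = list(random_sites = 101L, uniformity = 202L),
                      rollup = c(E1_promoter_active = "promoter",
                                 E2_promoter_weak = "promoter",
                                 E3_enhancer_strong = "enhancer",
                                 E4_enhancer_weak = "enhancer")) {
  cfg <- list(bundleDir = bundleDir, outDir = outDir,
              excludeChroms = excludeChroms, alpha = alpha, flank = flank,
              smooth = smooth, minProfileEvents = minProfileEvents,
              densityWidth = densityWidth, densityStep = densityStep,
              liftFlank = liftFlank, minRatio = minRatio, seeds = seeds,
              rollup = rollup)
  class(cfg) <- "RunConfig"
  cfg
}

#' Validate a run configuration
#'
#' Checks that every input file the pipeline stages need exists before any
#' compute starts.
#'
#' @param config a [runConfig()] list.
#' @return invisibly TRUE; errors on the first missing input.
#' @export
validateRunConfig <- function(config) {
  need <- c("chrom_sizes.tsv", "repeats.out", "repeats.align", "taxonomy.tsv",
            "consensus.fa", "conservation.wig", "dhs.wig", "tree.nwk",
            "subfamily_ranges.tsv", "genes.tsv", "segmentation.bed",
            "conserved_elements.bed", "motifs.jaspar")
  for (f in need) {
    p <- file.path(config$bundleDir, f)
    if (!file.exists(p)) pkgStop("validation: missing input %s", p)
  }
  if (!dir.exists(file.path(config$bundleDir, "chains")))
    pkgStop("validation: missing chain directory %s",
            file.path(config$bundleDir, "chains"))
  if (!length(list.files(config$bundleDir, pattern = "^summits_.*\\.narrowPeak$")))
    pkgStop("validation: no summit narrowPeak files in %s", config$bundleDir)
  invisible(TRUE)
}

#' Run the full TE cis-regulatory analysis pipeline
#'
#' Executes the stages in dependency order — family enrichment, consensus
#' profiles with uniformity tests and motif scans, conservation/DHS
#' meta-profiles with a random-TE control, chromatin-state assignment, TSS
#' distances, cross-species dating, colocalization, and density scan —
#' writing one TSV per stage plus a machine-readable run record to
#' \code{config$outDir}.
#'
#' @param config a validated [runConfig()].
#' @return invisibly, a named list of the stage result data.frames.
#' @export
runPipeline <- function(config) {
  validateRunConfig(config)
  bd <- config$bundleDir
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      pkgStop("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  res <- list()

  inputs <- stage("load", {
    genome <- readGenomeIndex(file.path(bd, "chrom_sizes.tsv"),
                              exclude = config$excludeChroms)
    tax <- readTaxonomy(file.path(bd, "taxonomy.tsv"))
    copies <- readRepeatMaskerOut(file.path(bd, "repeats.out"), tax)
    aln <- readRepeatMaskerAlign(file.path(bd, "repeats.align"))
    peakFiles <- list.files(bd, pattern = "^summits_.*\\.narrowPeak$",
                            full.names = TRUE)
    summits <- do.call(c, lapply(peakFiles, function(p)
      readNarrowPeak(p, sub("^summits_(.*)\\.narrowPeak$", "\\1", basename(p)))))
    list(genome = genome, copies = copies, aln = aln, summits = summits,
         consensus = Biostrings::readDNAStringSet(file.path(bd, "consensus.fa")),
         motifs = readJasparPfm(file.path(bd, "motifs.jaspar")),
         tree = readSpeciesTree(file.path(bd, "tree.nwk")),
         ranges = utils::read.table(file.path(bd, "subfamily_ranges.tsv"),
                                    header = TRUE, sep = "\t",
                                    stringsAsFactors = FALSE))
  })

  events <- stage("enrich", {
    ev <- intersectSummits(inputs$summits, inputs$copies, inputs$genome)
    frac <- genomeFraction(inputs$copies, inputs$genome, "subfamily")
    enr <- familyEnrichment(ev, frac, grouping = "subfamily",
                            alpha = config$alpha)
    res$enrichment <- enr
    utils::write.table(enr, file.path(config$outDir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ev
  })

  stage("profile", {
    inTe <- events[events$in_te, ]
    combos <- unique(inTe[, c("subfamily", "factor")])
    profs <- list(); rows <- list()
    for (i in seq_len(nrow(combos))) {
      sub <- inTe[inTe$subfamily == combos$subfamily[i] &
                    inTe$factor == combos$factor[i], ]
      if (nrow(sub) < config$minProfileEvents) next
      pr <- buildProfile(sub, inputs$aln, combos$subfamily[i])
      key <- paste(combos$subfamily[i], combos$factor[i], sep = ":")
      profs[[key]] <- pr
    }
    ut <- if (length(profs))
      uniformityTests(profs, seed = config$seeds$uniformity) else NULL
    hits <- list()
    for (key in names(profs)) {
      sf <- strsplit(key, ":")[[1]][1]
      if (!is.null(ut) && ut$p_bonf[ut$profile == key] < config$alpha &&
          sf %in% names(inputs$consensus)) {
        regions <- profilePeakRegions(profs[[key]])
        for (r in seq_len(nrow(regions))) {
          for (m in inputs$motifs) {
            h <- scanMotif(inputs$consensus[[sf]], m,
                           region = c(regions$start[r], regions$end[r]))
            if (nrow(h)) hits[[length(hits) + 1L]] <-
                cbind(profile = key, motif = m@name, h)
          }
        }
      }
    }
    res$profiles <- profs
    res$uniformity <- ut
    res$motif_hits <- if (length(hits)) do.call(rbind, hits) else NULL
    profTab <- do.call(rbind, lapply(names(profs), function(key)
      data.frame(profile = key, bin = 0:99, raw = rawCounts(profs[[key]]),
                 normalized = normalizedProfile(profs[[key]]))))
    utils::write.table(profTab, file.path(config$outDir, "profiles.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(ut))
      utils::write.table(ut, file.path(config$outDir, "uniformity.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(res$motif_hits))
      utils::write.table(res$motif_hits,
                         file.path(config$outDir, "motif_hits.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  })

  stage("signal", {
    cons <- readWig(file.path(bd, "conservation.wig"),
                    chromLengths(inputs$genome))
    teEv <- events[events$in_te, ]
    teSites <- summitGRanges(teEv$chrom, teEv$pos)
    ctrl <- randomTeSites(inputs$genome, inputs$copies, 20000L,
                          seed = config$seeds$random_sites)
    prof <- metaProfile(teSites, cons, config$flank, config$smooth)
    cmp <- compareProfiles(teSites, ctrl, cons, config$flank)
    res$conservation_profile <- prof
    res$conservation_test <- cmp
    utils::write.table(prof, file.path(config$outDir, "conservation_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    seg <- readSegmentation(file.path(bd, "segmentation.bed"))
    st <- assignStates(events, seg, config$rollup)
    res$state_proportions <- stateProportions(st, "in_te")
    utils::write.table(res$state_proportions,
                       file.path(config$outDir, "state_proportions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    genes <- readGenes(file.path(bd, "genes.tsv"))
    td <- tssDistances(events, genes$tss, inputs$genome, inputs$copies,
                       nDraw = 20000L, seed = config$seeds$random_sites)
    res$tss_distances <- td
    utils::write.table(td, file.path(config$outDir, "tss_distances.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  stage("date", {
    chainFiles <- list.files(file.path(bd, "chains"), pattern = "\\.chain(\\.gz)?$",
                             full.names = TRUE)
    chainSets <- lapply(chainFiles, readChain)
    names(chainSets) <- vapply(chainSets, function(x) x@species, "")
    pm <- presenceMatrix(events, chainSets, flank = config$liftFlank,
                         minRatio = config$minRatio)
    ref <- setdiff(inputs$tree$tip.label, names(chainSets))[1]
    ev2 <- assignOrigins(events, pm, inputs$tree, ref, inputs$ranges)
    res$origins <- ev2
    res$clade_composition <- cladeComposition(ev2, "factor")
    utils::write.table(ev2, file.path(config$outDir, "origins.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$clade_composition,
                       file.path(config$outDir, "clade_composition.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    inTe <- ev2[ev2$in_te, ]
    mc <- S4Vectors::mcols(inputs$copies)
    div <- mc$divergence[match(inTe$copy_id, mc$copy_id)]
    res$age_distribution <- ageDistribution(div, inTe$family)
    utils::write.table(res$age_distribution,
                       file.path(config$outDir, "age_distribution.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  stage("coloc", {
    tab <- copyBindingTable(events, inputs$copies, "family")
    fs <- sort(unique(tab$factor))
    rows <- list()
    for (a in fs) for (b in setdiff(fs, a)) {
      ct <- colocTest(tab, a, b)
      if (nrow(ct)) rows[[length(rows) + 1L]] <-
          cbind(factor_a = a, factor_b = b, ct)
    }
    res$colocalization <- if (length(rows)) do.call(rbind, rows) else NULL
    if (!is.null(res$colocalization))
      utils::write.table(res$colocalization,
                         file.path(config$outDir, "colocalization.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  })

  stage("density", {
    bound <- unique(events$copy_id[events$in_te])
    mc <- S4Vectors::mcols(inputs$copies)
    boundGr <- inputs$copies[mc$copy_id %in% bound]
    dens <- densityScan(boundGr, inputs$genome, config$densityWidth,
                        config$densityStep)
    res$density <- dens
    res$top_locus <- topDensityLocus(dens)
    utils::write.table(dens, file.path(config$outDir, "density.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$top_locus, file.path(config$outDir, "top_locus.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  record <- list(package_version = as.character(utils::packageVersion("TEcisReg")),
                 bundle = bd,
                 parameters = config[setdiff(names(config),
                                             c("bundleDir", "outDir"))],
                 n_summits = nrow(events),
                 n_te_summits = sum(events$in_te))
  jsonlite::write_json(record, file.path(config$outDir, "run_record.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(res)
}
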