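test_that("genome fractions use union semantics and exclude chromosomes", {
  gi <- GenomeIndex(c(chr1 = 1000))
  one <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100),
                                subfamily = "X", family = "X", class = "SINE",
                                divergence = 1, copy_id = "a")
  expect_equal(unname(genomeFraction(one, gi, "family")), 0.1)
  # two same-family copies overlapping by 50 bp: union = 150 bp
  two <- c(one, GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 150),
                                       subfamily = "X", family = "X",
                                       class = "SINE", divergence = 1,
                                       copy_id = "b"))
  expect_equal(unname(genomeFraction(two, gi, "family")), 0.15)
  # excluded chromosome drops both numerator and denominator
  gi2 <- GenomeIndex(c(chr1 = 1000, chrY = 1000), excluded = "chrY")
  expect_equal(unname(genomeFraction(two, gi2, "family")), 0.15)
})

test_that("genome fractions equal the per-base bitmap oracle", {
  set.seed(5)
  chromLens <- c(chr1 = 10000L, chr2 = 8000L)
  gi <- GenomeIndex(chromLens)
  for (rep in 1:5) {
    copies <- randomTeCopyGRanges(60, chromLens)
    frac <- genomeFraction(copies, gi, "subfamily")
    for (sf in names(frac)) {
      sel <- copies[S4Vectors::mcols(copies)$subfamily == sf]
      oracle <- bitmapFraction(GenomicRanges::start(sel) - 1L,
                               GenomicRanges::end(sel),
                               as.character(GenomicRanges::seqnames(sel)),
                               chromLens)
      expect_equal(unname(frac[[sf]]), oracle)
    }
  }
})

test_that("summit-copy intersection follows half-open bounds and tie-breaks", {
  copies <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = c(101, 151), end = c(200, 190)),
    subfamily = c("A", "B"), family = c("A", "B"), class = c("SINE", "LINE"),
    divergence = c(1, 2), copy_id = c("c1", "c2"))
  s <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = c(151, 201, 180), width = 1),
    factor = "ERa", score = 0)
  ev <- intersectSummits(s, copies)
  expect_equal(ev$in_te, c(TRUE, FALSE, TRUE))   # pos 200 == end of c1: outside
  expect_equal(ev$copy_id[1], "c1")              # pos 150 inside c1 only
  expect_equal(ev$copy_id[3], "c1")              # overlap: smaller start wins
})

test_that("overlap assignment matches an exhaustive oracle on random data", {
  set.seed(9)
  chromLens <- c(chr1 = 5000L)
  copies <- randomTeCopyGRanges(80, chromLens, subfams = c("A", "B"))
  pos <- sample.int(5000L, 300L) - 1L
  s <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos + 1L, width = 1),
                              factor = "ERa", score = 0)
  ev <- intersectSummits(s, copies)
  st <- GenomicRanges::start(copies) - 1L
  en <- GenomicRanges::end(copies)
  ids <- S4Vectors::mcols(copies)$copy_id
  for (i in seq_along(pos)) {
    hit <- which(pos[i] >= st & pos[i] < en)
    if (!length(hit)) {
      expect_false(ev$in_te[i])
    } else {
      best <- hit[order(st[hit], ids[hit])][1]
      expect_equal(ev$copy_id[i], ids[best])
    }
  }
})

test_that("two-tailed binomial matches enumeration and binom.test", {
  cases <- list(c(3, 10, 0.1), c(0, 10, 0.5), c(7, 12, 0.3), c(12, 20, 0.9),
                c(5, 18, 0.25))
  for (cs in cases) {
    got <- binomTwoTailed(cs[1], cs[2], cs[3])
    expect_equal(got, enumBinomTwoTailed(cs[1], cs[2], cs[3]))
    expect_equal(got, stats::binom.test(cs[1], cs[2], cs[3])$p.value)
  }
  # symmetry at p = 0.5
  for (k in 0:10)
    expect_equal(binomTwoTailed(k, 10, 0.5), binomTwoTailed(10 - k, 10, 0.5))
  # degenerate: k = n with p near 1
  expect_equal(binomTwoTailed(50, 50, 1 - 1e-12), 1, tolerance = 1e-9)
  expect_error(binomTwoTailed(1, 10, 1.5), "strictly")
})

test_that("family enrichment flags a planted family and counts tests", {
  # planted: family X holds 30% of 500 summits at 1% genomic fraction
  set.seed(21)
  events <- data.frame(
    factor = "ERa",
    in_te = c(rep(TRUE, 150), rep(FALSE, 350)),
    subfamily = c(rep("X", 150), rep(NA, 350)))
  fr <- c(X = 0.01)
  enr <- familyEnrichment(events, fr, nTests = 2144)
  expect_true(enr$significant)
  expect_equal(enr$direction, "enriched")
  expect_equal(enr$n_tests, 2144)
  # depletion direction for k = 0
  ev0 <- data.frame(factor = "ERa", in_te = FALSE,
                    subfamily = NA_character_)[rep(1, 100), ]
  enr0 <- familyEnrichment(ev0, c(Y = 0.01))
  expect_equal(enr0$direction, "depleted")
  expect_equal(enr0$p_raw, binomTwoTailed(0, 100, 0.01))
  # multiplier defaults to groups x factors
  ev2 <- data.frame(factor = rep(c("ERa", "FoxA1"), each = 10),
                    in_te = FALSE, subfamily = NA_character_)
  enr2 <- familyEnrichment(ev2, c(A = 0.01, B = 0.02, C = 0.03))
  expect_equal(unique(enr2$n_tests), 6L)
})

test_that("type-I error of enrichment is controlled under the null", {
  # uniform summits, no planted signal: share of significant groups at
  # corrected 0.05 stays at or below the nominal rate over repeated seeds
  chromLens <- c(chr1 = 50000L)
  gi <- GenomeIndex(chromLens)
  nSig <- 0L; nTests <- 0L
  for (seed in 1:8) {
    set.seed(seed)
    copies <- randomTeCopyGRanges(100, chromLens,
                                  subfams = paste0("F", 1:10))
    pos <- sample.int(50000L, 400L) - 1L
    s <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos + 1L, width = 1),
                                factor = "ERa", score = 0)
    ev <- intersectSummits(s, copies)
    fr <- genomeFraction(copies, gi, "subfamily")
    enr <- familyEnrichment(ev, fr)
    nSig <- nSig + sum(enr$significant)
    nTests <- nTests + nrow(enr)
  }
  expect_lte(nSig / nTests, 0.05)
})

test_that("conserved-element filtering is strict and subtracts CDS", {
  el <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = c(1, 101, 301), width = c(100, 20, 50)),
    lod = c(70, 100, 60))
  cds <- GenomicRanges::GRanges("chr1", IRanges::IRanges(41, 60))
  cne <- filterConservedElements(el, cds)
  # length-20 and lod-60 elements excluded (strict >), CDS cut from [0,100)
  expect_equal(GenomicRanges::start(cne) - 1L, c(0L, 60L))
  expect_equal(GenomicRanges::end(cne), c(40L, 100L))
})

test_that("annotation fractions match the bitmap oracle", {
  set.seed(13)
  chromLens <- c(chr1 = 10000L)
  for (rep in 1:3) {
    copies <- randomTeCopyGRanges(40, chromLens)
    regS <- sort(sample.int(9000L, 20L)) - 1L
    regions <- GenomicRanges::GRanges("chr1",
      IRanges::IRanges(regS + 1L, width = 50L))
    fr <- annotationFraction(copies, regions)
    # oracle: per-base bitmaps
    regionBits <- logical(10000L)
    for (i in seq_along(regS)) regionBits[(regS[i] + 1L):(regS[i] + 50L)] <- TRUE
    for (cl in names(fr)) {
      sel <- copies[S4Vectors::mcols(copies)$class == cl]
      bits <- logical(10000L)
      for (j in seq_along(sel)) {
        bits[GenomicRanges::start(sel)[j]:GenomicRanges::end(sel)[j]] <- TRUE
      }
      expect_equal(unname(fr[[cl]]), sum(bits & regionBits) / sum(regionBits))
    }
    expect_lte(sum(fr), 1 + 1e-12)
  }
})
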