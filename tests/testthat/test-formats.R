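test_that("RepeatMasker .out coordinates and strand are normalized on read", {
  lines <- c(
    "1000 25.3 0.0 0.0 chr1 101 200 (0) C MIR SINE/MIR 1 100 (0) id1",
    "1000 5.0 0.0 0.0 chr1 301 400 (0) + AluY SINE/Alu 1 100 (0) id2",
    "1000 1.0 0.0 0.0 chr1 501 520 (0) + (TAACCC)n Simple_repeat 1 20 (0) id3")
  f <- withr::local_tempfile(lines = lines, fileext = ".out")
  copies <- suppressMessages(readRepeatMaskerOut(f))
  expect_length(copies, 2L)               # simple repeat dropped
  mir <- copies[S4Vectors::mcols(copies)$subfamily == "MIR"]
  expect_equal(GenomicRanges::start(mir) - 1L, 100L)  # 0-based start
  expect_equal(GenomicRanges::end(mir), 200L)
  expect_equal(as.character(GenomicRanges::strand(mir)), "-")
  expect_equal(S4Vectors::mcols(mir)$divergence, 25.3)
  expect_equal(S4Vectors::mcols(mir)$class, "SINE")
})

test_that("malformed .out rows raise a parse error naming the line", {
  f <- withr::local_tempfile(lines = "1000 25.3 0.0 chr1 101", fileext = ".out")
  expect_error(readRepeatMaskerOut(f), "line 1")
})

test_that(".out writer and reader are inverse on random records", {
  set.seed(42)
  copies <- randomTeCopyGRanges(50)
  f <- withr::local_tempfile(fileext = ".out")
  writeRepeatMaskerOut(copies, f)
  back <- readRepeatMaskerOut(f)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(copies))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(copies))
  expect_equal(as.character(GenomicRanges::strand(back)),
               as.character(GenomicRanges::strand(copies)))
  expect_equal(S4Vectors::mcols(back)$subfamily,
               S4Vectors::mcols(copies)$subfamily)
  expect_equal(S4Vectors::mcols(back)$divergence,
               S4Vectors::mcols(copies)$divergence)
  expect_equal(S4Vectors::mcols(back)$class, S4Vectors::mcols(copies)$class)
})

test_that(".align parsing handles ungapped and gapped records", {
  rec <- c(">align c1 chr1 1001 1100 + CONS 500",
           "chr1 1001 ACGTACGTAC 1010",
           "CONS 51 ACGTACGTAC 60",
           "")
  f <- withr::local_tempfile(lines = rec, fileext = ".align")
  aln <- readRepeatMaskerAlign(f)
  b <- alignmentBlocks(aln)
  expect_equal(nrow(b), 1L)
  expect_equal(b$g_start, 1000L)
  expect_equal(b$c_start, 50L)
  expect_equal(b$g_end - b$g_start, 10L)

  # 5-bp genomic insertion: consensus contiguous, genome jumps by 5
  rec2 <- c(">align c2 chr1 1001 1025 + CONS 500",
            "chr1 1001 ACGTACGTACTTTTTACGTACGTAC 1025",
            "CONS 51 ACGTACGTAC-----ACGTACGTAC 70",
            "")
  f2 <- withr::local_tempfile(lines = rec2, fileext = ".align")
  b2 <- alignmentBlocks(readRepeatMaskerAlign(f2))
  expect_equal(nrow(b2), 2L)
  expect_equal(b2$c_start[2], b2$c_end[1])            # consensus contiguous
  expect_equal(b2$g_start[2] - b2$g_end[1], 5L)       # genomic jump of 5
})

test_that(".align consensus span beyond stated length errors with the copy", {
  rec <- c(">align cbad chr1 1001 1010 + CONS 55",
           "chr1 1001 ACGTACGTAC 1010",
           "CONS 51 ACGTACGTAC 60", "")
  f <- withr::local_tempfile(lines = rec, fileext = ".align")
  expect_error(readRepeatMaskerAlign(f), "cbad")
})

test_that("gapped .align per-base mapping equals the column-walk oracle", {
  set.seed(101)
  for (rep in 1:20) {
    # build a random gapped alignment as text, parse it, compare per base
    n <- 40L
    ops <- sample(c("M", "I", "D"), n, replace = TRUE, prob = c(0.8, 0.1, 0.1))
    ops[1] <- "M"; ops[n] <- "M"
    g <- ifelse(ops == "D", "-", sample(c("A", "C", "G", "T"), n, replace = TRUE))
    cc <- ifelse(ops == "I", "-", sample(c("A", "C", "G", "T"), n, replace = TRUE))
    strand <- sample(c("+", "-"), 1)
    nG <- sum(g != "-"); nC <- sum(cc != "-")
    g1 <- 1001L
    c1 <- if (strand == "+") 21L else 20L + nC
    rec <- c(sprintf(">align cr chr1 %d %d %s CONS 500", g1, g1 + nG - 1L,
                     if (strand == "-") "C" else "+"),
             sprintf("chr1 %d %s %d", g1, paste(g, collapse = ""), g1 + nG - 1L),
             sprintf("CONS %d %s %d", c1, paste(cc, collapse = ""),
                     if (strand == "+") c1 + nC - 1L else c1 - nC + 1L),
             "")
    f <- withr::local_tempfile(lines = rec, fileext = ".align")
    aln <- readRepeatMaskerAlign(f)
    oracle <- columnWalk(paste(g, collapse = ""), paste(cc, collapse = ""),
                         g1 - 1L, c1 - 1L, strand)
    for (i in seq_len(nrow(oracle))) {
      blocks <- copyBlocks(aln, "cr")
      pr <- projectToConsensus(unname(oracle[i, "g"]), blocks)
      expect_false(pr$flagged_gap)
      expect_equal(pr$consensus_pos, unname(oracle[i, "c"]))
    }
  }
})

test_that("narrowPeak summits honor the offset and midpoint fallback", {
  lines <- c("chr1\t100\t200\tp1\t0\t.\t5.0\t-1\t-1\t25",
             "chr1\t100\t200\tp2\t0\t.\t3.0\t-1\t-1\t-1")
  f <- withr::local_tempfile(lines = lines, fileext = ".narrowPeak")
  expect_warning(s <- readNarrowPeak(f, "ERa"), "midpoint")
  pos <- GenomicRanges::start(s) - 1L
  expect_equal(pos, c(125L, 150L))
  expect_equal(unique(S4Vectors::mcols(s)$factor), "ERa")
})

test_that("narrowPeak round-trips many random summits", {
  set.seed(7)
  n <- 1000L
  pos <- sample.int(1000000L, n) - 1L
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos + 1L, width = 1L),
                               factor = "FoxA1", score = round(runif(n), 3))
  f <- withr::local_tempfile(fileext = ".narrowPeak")
  writeNarrowPeak(gr, f)
  back <- readNarrowPeak(f, "FoxA1")
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(gr))
  expect_equal(S4Vectors::mcols(back)$score, S4Vectors::mcols(gr)$score)
})

test_that("identity chain parses to an identity mapping and round-trips", {
  lines <- c("chain 10 chr1 10 + 0 10 chr1 10 + 0 10 1", "10", "")
  f <- withr::local_tempfile(lines = lines, fileext = ".chain")
  cs <- readChain(f, "sp1")
  expect_length(cs@chains, 1L)
  r <- liftInterval("chr1", 2, 9, cs)
  expect_true(r$mapped)
  expect_equal(c(r$q_start, r$q_end), c(2, 9))
  f2 <- withr::local_tempfile(fileext = ".chain")
  writeChain(cs, f2)
  cs2 <- readChain(f2, "sp1")
  expect_equal(cs2@chains, cs@chains)
})

test_that("chain block-sum mismatches error with the chain id", {
  lines <- c("chain 10 chr1 100 + 0 50 chr1 100 + 0 50 badchain", "10", "")
  f <- withr::local_tempfile(lines = lines, fileext = ".chain")
  expect_error(readChain(f), "badchain")
})

test_that("minus-strand chain queries are normalized to forward coordinates", {
  # target [0,10) maps to query minus strand; q_size 100, q rel [0,10)
  lines <- c("chain 10 chr1 10 + 0 10 chrQ 100 - 0 10 1", "10", "")
  f <- withr::local_tempfile(lines = lines, fileext = ".chain")
  cs <- readChain(f)
  r <- liftInterval("chr1", 0, 10, cs)
  expect_true(r$mapped)
  # forward coords: base t maps to 99 - t
  expect_equal(c(r$q_start, r$q_end), c(90, 100))
})

test_that("wiggle fixedStep/variableStep/bedGraph round-trip and resample", {
  tr <- SignalTrack(list(chr1 = c(1, 2, NA, 4, 5), chr2 = c(9, 8)), step = 1L)
  f <- withr::local_tempfile(fileext = ".wig")
  writeWig(tr, f)
  back <- readWig(f, chromLengths = c(chr1 = 5L, chr2 = 2L))
  expect_equal(back@values, tr@values)
  # windowed track values apply to all bases of the window
  tr20 <- SignalTrack(list(chr1 = c(3, 7)), step = 20L)
  expect_equal(trackValuesAt(tr20, "chr1", c(0, 19, 20, 39)), c(3, 3, 7, 7))
  # bedGraph
  f3 <- withr::local_tempfile(lines = c("chr1\t0\t20\t1.5", "chr1\t20\t40\t2.5"))
  bg <- readWig(f3)
  expect_equal(bg@values$chr1, c(1.5, 2.5))
  expect_equal(bg@step, 20L)
})

test_that("JASPAR counts normalize to probabilities and MEME parses", {
  lines <- c(">M1", "A [ 10 0 ]", "C [ 0 10 ]", "G [ 0 0 ]", "T [ 0 0 ]")
  f <- withr::local_tempfile(lines = lines)
  pwms <- readJasparPfm(f)
  expect_equal(colSums(pwms$M1@matrix), c(1, 1))
  expect_equal(unname(pwms$M1@matrix["A", 1]), 1)
  f2 <- withr::local_tempfile(lines = c(
    "MEME version 4", "", "ALPHABET= ACGT", "",
    "Background letter frequencies", "A 0.25 C 0.25 G 0.25 T 0.25", "",
    "MOTIF test", "letter-probability matrix: alength= 4 w= 2 nsites= 10",
    " 1.0 0.0 0.0 0.0", " 0.0 0.0 0.0 1.0"))
  mm <- readMemeMotifs(f2)
  expect_equal(motifLength(mm$test), 2L)
  expect_equal(mm$test@matrix["T", 2], 1)
})

test_that("newick trees read with clade labels; most distant leaf correct", {
  f <- withr::local_tempfile(lines = "((A,B)AB,C)root;")
  tree <- readSpeciesTree(f)
  pres <- c(B = "mapped", C = "mapped")
  call <- assignOrigin(pres, tree, "A")
  expect_equal(call$most_distant_species, "C")
  expect_equal(call$origin_clade, "root")
})

test_that("GenomeIndex validates lengths and exclusion subset", {
  gi <- GenomeIndex(c(chr1 = 1000, chrY = 500), excluded = "chrY")
  expect_equal(genomeLength(gi), 1000)
  expect_equal(activeChroms(gi), "chr1")
  expect_error(GenomeIndex(c(chr1 = 1000), excluded = "chrZ"), "subset")
  expect_error(GenomeIndex(c(chr1 = 0)), "positive")
})
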