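test_that("identity chains lift any interval to itself", {
  cs <- identityChain(len = 10000)
  for (iv in list(c(0, 10), c(500, 501), c(9990, 10000))) {
    r <- liftInterval("chr1", iv[1], iv[2], cs)
    expect_true(r$mapped)
    expect_equal(c(r$q_start, r$q_end), iv)
  }
})

test_that("the min-ratio threshold fails a 9/10 mapped query", {
  # one base of a 10-bp query falls in a chain gap: 9/10 < 0.95
  ch <- list(score = 100, t_name = "chr1", t_size = 1000, t_start = 0,
             t_end = 21, q_name = "chrQ", q_size = 1000, q_strand = "+",
             q_start = 0, q_end = 20, id = "1",
             blocks = cbind(t_start = c(0, 11), q_start = c(0, 10),
                            size = c(10, 10)))
  cs <- ChainSet("sp", list(ch))
  r <- liftInterval("chr1", 5, 15, cs)       # covers gap base t=10
  expect_false(r$mapped)
  r2 <- liftInterval("chr1", 5, 15, cs, minRatio = 0.9)
  expect_true(r2$mapped)
  # 9 mapped bases: q 5..9 then 10..13 (the gap base is absorbed)
  expect_equal(c(r2$q_start, r2$q_end), c(5, 14))
  # no overlapping chain
  r3 <- liftInterval("chr2", 0, 10, cs)
  expect_equal(r3$reason, "deleted/no chain")
})

test_that("per-base chain mapping equals a brute-force block walk", {
  set.seed(31)
  for (rep in 1:10) {
    nb <- sample(2:6, 1)
    sizes <- sample(5:30, nb, replace = TRUE)
    dt <- sample(0:15, nb - 1, replace = TRUE)
    dq <- sample(0:15, nb - 1, replace = TRUE)
    tStarts <- cumsum(c(10, sizes[-nb] + dt))
    qRel <- cumsum(c(3, sizes[-nb] + dq))
    qStrand <- sample(c("+", "-"), 1)
    qSize <- 2000
    qFwd <- if (qStrand == "-") qSize - (qRel + sizes) else qRel
    ch <- list(score = 10, t_name = "chr1", t_size = 2000,
               t_start = tStarts[1], t_end = tStarts[nb] + sizes[nb],
               q_name = "chrQ", q_size = qSize, q_strand = qStrand,
               q_start = qRel[1], q_end = qRel[nb] + sizes[nb], id = "r",
               blocks = cbind(t_start = tStarts, q_start = qFwd, size = sizes))
    # oracle: walk every block base by base
    oracle <- rep(NA_real_, 2000)
    for (b in seq_len(nb)) {
      for (o in seq_len(sizes[b]) - 1L) {
        qr <- qRel[b] + o
        oracle[tStarts[b] + o + 1L] <-
          if (qStrand == "-") qSize - 1 - qr else qr
      }
    }
    got <- TEcisReg:::mapBasesThroughChain(0:1999, ch)
    expect_equal(got, oracle)
  }
})

test_that("presence matrix distinguishes mapped, unmapped and no_data", {
  ev <- data.frame(chrom = "chr1", pos = c(100L, 200L))
  full <- identityChain(len = 1000, species = "a")
  none <- ChainSet("b", list())
  pm <- presenceMatrix(ev, list(a = full, b = none, c = NULL))
  expect_true(all(pm[, "a"] == "mapped"))
  expect_true(all(pm[, "b"] == "no_data"))
  expect_true(all(pm[, "c"] == "no_data"))
})

test_that("origin assignment picks the most distant mapped species", {
  tree <- ape::read.tree(text = "((human,chimp)Hominini,mouse)Root;")
  p1 <- c(chimp = "mapped", mouse = "unmapped")
  expect_equal(assignOrigin(p1, tree, "human")$origin_clade, "Hominini")
  p2 <- c(chimp = "mapped", mouse = "mapped")
  call2 <- assignOrigin(p2, tree, "human")
  expect_equal(call2$origin_clade, "Root")
  expect_equal(call2$most_distant_species, "mouse")
  # nothing mapped: reference-specific
  p3 <- c(chimp = "unmapped", mouse = "no_data")
  expect_match(assignOrigin(p3, tree, "human")$origin_clade, "human-specific")
  # species missing from the tree errors by name
  expect_error(assignOrigin(c(yeti = "mapped"), tree, "human"), "yeti")
})

test_that("subfamily range caps clamp inconsistent deep mappings", {
  tree <- ape::read.tree(
    text = "(((human,chimp)Hominini,mouse)Euarchontoglires,opossum)Theria;")
  # primate-specific subfamily with an apparent opossum mapping
  pres <- c(chimp = "mapped", opossum = "mapped")
  call <- assignOrigin(pres, tree, "human", subfamilyClade = "Hominini")
  expect_true(call$inconsistent)
  expect_equal(call$origin_clade, "Hominini")
  # consistent mapping is untouched
  ok <- assignOrigin(c(chimp = "mapped"), tree, "human",
                     subfamilyClade = "Euarchontoglires")
  expect_false(ok$inconsistent)
  expect_equal(ok$origin_clade, "Hominini")
})

test_that("clade composition proportions sum to one per group", {
  ev <- data.frame(factor = c("ERa", "ERa", "ERa", "FoxA1"),
                   origin_clade = c("A", "A", "B", "B"))
  cc <- cladeComposition(ev, "factor")
  sums <- tapply(cc$proportion, cc[[1]], sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_equal(cc$proportion[cc$factor == "ERa" & cc$origin_clade == "A"],
               2 / 3)
})

test_that("age distributions bin divergence at 1% width and conserve counts", {
  ad <- ageDistribution(c(12.3, 12.9, 0.4, 30.0), c("L2", "L2", "Alu", "L2"))
  expect_equal(sum(ad$count), 4L)
  expect_equal(ad$count[ad$group == "L2" & ad$bin == 12], 2L)
  expect_equal(ad$count[ad$group == "L2" & ad$bin == 30], 1L)
  # bimodal planted families separate
  set.seed(2)
  old <- rnorm(300, 25, 2); young <- rnorm(300, 4, 1)
  ad2 <- ageDistribution(c(old, pmax(0, young)),
                         rep(c("old_fam", "young_fam"), each = 300))
  mo <- ad2[ad2$group == "old_fam", ]
  my <- ad2[ad2$group == "young_fam", ]
  expect_gt(mo$bin[which.max(mo$count)], 20)
  expect_lt(my$bin[which.max(my$count)], 8)
})

test_that("round-trip liftover through consistent chains recovers intervals", {
  b <- sharedBundle()
  tree <- readSpeciesTree(file.path(b, "tree.nwk"))
  cs <- readChain(file.path(b, "chains", "dog.chain"))
  # build the reverse chain set by swapping t and q
  rev <- ChainSet("ref", lapply(cs@chains, function(ch) {
    list(score = ch$score, t_name = ch$q_name, t_size = ch$q_size,
         t_start = ch$q_start, t_end = ch$q_end, q_name = ch$t_name,
         q_size = ch$t_size, q_strand = "+", q_start = ch$t_start,
         q_end = ch$t_end, id = ch$id,
         blocks = cbind(t_start = ch$blocks[, "q_start"],
                        q_start = ch$blocks[, "t_start"],
                        size = ch$blocks[, "size"]))
  }))
  man <- read.table(file.path(b, "manifest_summits.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
  ok <- 0L; n <- 0L
  for (i in seq_len(min(40L, nrow(man)))) {
    fwdr <- liftInterval(man$chrom[i], man$pos[i] - 5L, man$pos[i] + 5L, cs)
    if (!fwdr$mapped) next
    n <- n + 1L
    back <- liftInterval(fwdr$q_name, fwdr$q_start, fwdr$q_end, rev)
    if (back$mapped && back$q_start == man$pos[i] - 5L &&
        back$q_end == man$pos[i] + 5L) ok <- ok + 1L
  }
  expect_gt(n, 0L)
  expect_equal(ok, n)
})

test_that("liftover agrees with the rtracklayer reference on bundle chains", {
  b <- sharedBundle()
  chainFile <- file.path(b, "chains", "mouse.chain")
  cs <- readChain(chainFile)
  ref <- rtracklayer::import.chain(chainFile)
  man <- read.table(file.path(b, "manifest_summits.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
  ev <- man[seq(1L, nrow(man), by = 11L), ]
  for (i in seq_len(nrow(ev))) {
    got <- liftInterval(ev$chrom[i], ev$pos[i] - 5L, ev$pos[i] + 5L, cs)
    gr <- GenomicRanges::GRanges(ev$chrom[i],
      IRanges::IRanges(ev$pos[i] - 4L, ev$pos[i] + 5L))
    img <- unlist(rtracklayer::liftOver(gr, ref))
    if (got$mapped) {
      # a fully-mapped query maps to the same single interval
      expect_equal(length(img), 1L)
      expect_equal(GenomicRanges::start(img) - 1L, got$q_start)
      expect_equal(GenomicRanges::end(img), got$q_end)
    } else {
      # our min-ratio rule fails only when rtracklayer maps < 10 bases
      expect_lt(sum(GenomicRanges::width(img)), 10L)
    }
  }
})
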