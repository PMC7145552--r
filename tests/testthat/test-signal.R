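test_that("meta-profile of a constant track is constant", {
  tr <- SignalTrack(list(chr1 = rep(3.5, 2000)), step = 1L)
  sites <- data.frame(chrom = "chr1", pos = c(600L, 1000L, 1399L))
  mp <- metaProfile(sites, tr, flank = 100L, smooth = 10L)
  expect_true(all(abs(mp$mean - 3.5) < 1e-12))
  expect_equal(nrow(mp), 201L)
})

test_that("meta-profile of delta signals is a spike at offset zero", {
  v <- numeric(2000)
  sites <- data.frame(chrom = "chr1", pos = c(500L, 1200L))
  v[sites$pos + 1L] <- 1
  tr <- SignalTrack(list(chr1 = v), step = 1L)
  mp <- metaProfile(sites, tr, flank = 50L, smooth = 1L)
  expect_equal(mp$raw_mean[mp$offset == 0], 1)
  expect_true(all(mp$raw_mean[mp$offset != 0] == 0))
})

test_that("meta-profile equals a naive per-site loop on random data", {
  set.seed(3)
  tr <- SignalTrack(list(chr1 = rnorm(3000), chr2 = rnorm(2500)), step = 1L)
  sites <- data.frame(chrom = sample(c("chr1", "chr2"), 40, replace = TRUE),
                      pos = sample(100:2300, 40))
  flank <- 60L
  mp <- metaProfile(sites, tr, flank = flank, smooth = 1L)
  for (off in c(-60L, -13L, 0L, 27L, 60L)) {
    vals <- vapply(seq_len(nrow(sites)), function(i)
      tr@values[[sites$chrom[i]]][sites$pos[i] + off + 1L], 0)
    expect_equal(mp$raw_mean[mp$offset == off], mean(vals, na.rm = TRUE))
  }
  # sites close to the chromosome end are included with missing tails
  edge <- data.frame(chrom = "chr1", pos = 2995L)
  mpe <- metaProfile(edge, tr, flank = 10L, smooth = 1L)
  expect_true(all(is.na(mpe$raw_mean[mpe$offset > 4])))
  expect_false(anyNA(mpe$raw_mean[mpe$offset <= 4]))
})

test_that("random TE sites are reproducible, in-TE, and proportional", {
  set.seed(1)
  chromLens <- c(chr1 = 20000L)
  gi <- GenomeIndex(chromLens)
  # TE covering 50% of the genome
  copies <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10000),
    subfamily = "X", family = "X", class = "LINE", divergence = 1,
    copy_id = "c1")
  s1 <- randomTeSites(gi, copies, 4000L, seed = 5L)
  s2 <- randomTeSites(gi, copies, 4000L, seed = 5L)
  expect_identical(GenomicRanges::start(s1), GenomicRanges::start(s2))
  frac <- length(s1) / 4000
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 4000))
  expect_true(all(GenomicRanges::start(s1) - 1L < 10000L))  # bitmap predicate
})

test_that("profile comparison matches t.test and handles degeneracy", {
  set.seed(8)
  tr <- SignalTrack(list(chr1 = rnorm(50000)), step = 1L)
  a <- data.frame(chrom = "chr1", pos = sample(500:20000, 30))
  b <- data.frame(chrom = "chr1", pos = sample(25000:49000, 40))
  got <- compareProfiles(a, b, tr, flank = 100L)
  am <- vapply(a$pos, function(p) mean(tr@values$chr1[(p - 100):(p + 100) + 1L]), 0)
  bm <- vapply(b$pos, function(p) mean(tr@values$chr1[(p - 100):(p + 100) + 1L]), 0)
  ref <- t.test(am, bm)
  expect_equal(got$t, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value)
  # identical groups with zero variance: degenerate, p = 1
  trc <- SignalTrack(list(chr1 = rep(1, 1000)), step = 1L)
  idf <- data.frame(chrom = "chr1", pos = c(300L, 600L))
  deg <- compareProfiles(idf, idf, trc, flank = 50L)
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
})

test_that("planted conservation uplift is detected against random TEs", {
  set.seed(12)
  v <- rnorm(50000, 0.02, 0.1)
  hot <- sample(1000:24000, 25)
  for (p in hot) v[(p - 20):(p + 20) + 1L] <- v[(p - 20):(p + 20) + 1L] + 0.4
  tr <- SignalTrack(list(chr1 = v), step = 1L)
  a <- data.frame(chrom = "chr1", pos = hot)
  b <- data.frame(chrom = "chr1", pos = sample(26000:49000, 200))
  got <- compareProfiles(a, b, tr, flank = 400L)
  expect_lt(got$p_value, 0.05)
  expect_gt(got$mean_a, got$mean_b)
})

test_that("TSS distances match an all-pairs oracle and report controls", {
  tss <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1001, 5001), width = 1), gene = c("g1", "g2"))
  ev <- data.frame(chrom = "chr1", pos = c(1500L, 3000L), factor = "ERa",
                   in_te = TRUE, copy_id = c("c1", "c2"),
                   subfamily = "X", family = "X", class = c("SINE", "LINE"))
  td <- tssDistances(ev, tss)
  expect_equal(td$mean_distance[td$class == "SINE"], 500)
  # equidistant to both TSSs: that distance
  expect_equal(td$mean_distance[td$class == "LINE"], 2000)
  # random oracle check
  set.seed(4)
  tssPos <- sort(sample.int(100000L, 20L)) - 1L
  tss2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(tssPos + 1L, width = 1),
                                 gene = paste0("g", seq_along(tssPos)))
  pos <- sample.int(100000L, 50L) - 1L
  ev2 <- data.frame(chrom = "chr1", pos = pos, factor = "ERa", in_te = TRUE,
                    copy_id = "c", subfamily = "X", family = "X", class = "SINE")
  td2 <- tssDistances(ev2, tss2)
  oracle <- mean(vapply(pos, function(p) min(abs(p - tssPos)), 0))
  expect_equal(td2$mean_distance, oracle)
})

test_that("signal matrix accumulates read coverage and subsamples deterministically", {
  sites <- data.frame(chrom = "chr1", pos = 1000L)
  reads <- GenomicRanges::GRanges("chr1", IRanges::IRanges(991, 1010))
  m <- signalMatrix(sites, reads, flank = 20L)
  expect_equal(unname(m[1, ]), c(rep(0, 10), rep(1, 20), rep(0, 11)))
  # column sums across random reads match a bitmap-coverage oracle
  set.seed(6)
  rs <- sample(500:1500, 200, replace = TRUE)
  reads2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(rs + 1, width = 50))
  m2 <- signalMatrix(sites, reads2, flank = 400L)
  cov <- integer(5000)
  for (r in rs) cov[(r + 1):(r + 50)] <- cov[(r + 1):(r + 50)] + 1L
  expect_equal(unname(m2[1, ]), cov[(1000 - 400):(1000 + 400) + 1L])
  # deterministic subsampling under a seed; warns when short of the target
  m3a <- signalMatrix(sites, reads2, flank = 50L, targetReads = 100L, seed = 2L)
  m3b <- signalMatrix(sites, reads2, flank = 50L, targetReads = 100L, seed = 2L)
  expect_identical(m3a, m3b)
  expect_warning(signalMatrix(sites, reads2, flank = 50L, targetReads = 1000L),
                 "using all")
})

test_that("state assignment requires a partition and recovers compositions", {
  seg <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = c(1, 1001, 2001), end = c(1000, 2000, 3000)),
    state = c("E3_enhancer_strong", "E1_promoter_active", "E8_quiescent"))
  rollup <- c(E3_enhancer_strong = "enhancer", E1_promoter_active = "promoter")
  ev <- data.frame(chrom = "chr1", pos = c(500L, 1500L, 2500L, 500L),
                   in_te = c(TRUE, TRUE, FALSE, FALSE))
  st <- assignStates(ev, seg, rollup)
  expect_equal(st$rollup, c("enhancer", "promoter", "other", "enhancer"))
  prop <- stateProportions(st, "in_te")
  sums <- tapply(prop$proportion, prop$in_te, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # overlapping segmentation is rejected
  bad <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = c(1, 500), end = c(1000, 1500)),
    state = c("a", "b"))
  expect_error(assignStates(ev, bad, rollup), "partition")
})

test_that("shuffled site labels show no central conservation elevation", {
  set.seed(19)
  v <- rnorm(60000, 0, 0.1)
  tr <- SignalTrack(list(chr1 = v), step = 1L)
  sites <- data.frame(chrom = "chr1", pos = sample(1000:59000, 100))
  mp <- metaProfile(sites, tr, flank = 200L, smooth = 10L)
  center <- mean(mp$raw_mean[abs(mp$offset) <= 20])
  flankM <- mean(mp$raw_mean[abs(mp$offset) > 150])
  se <- sd(mp$raw_mean) / sqrt(40)
  expect_lt(abs(center - flankM), 6 * max(se, 0.005))
})
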