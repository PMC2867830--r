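makeReads <- function(genome, ...) simulateReads(genome, ...)

test_that("error-free reads map back to their sampled positions", {
  g <- randomGenome(8000, 401)
  sim <- simulateReads(g, foldCoverage = 5, errorRate = 0, seed = 402)
  sam <- mapReads(sim$pairs, g)
  expect_true(all(bitwAnd(sam$flag, 4L) == 0L))
  m <- match(paste0(sim$origins$id, "/1"), sam$qname)
  uni <- sam$mapq[m] > 0
  expect_gt(mean(uni), 0.95)
  expect_true(all(sam$pos[m][uni] - 1L == sim$origins$start[uni]))
  m2 <- match(paste0(sim$origins$id, "/2"), sam$qname)
  expect_true(all(bitwAnd(sam$flag[m2], 16L) == 16L | sam$mapq[m2] == 0))
})

test_that("a read of pure N is unmapped", {
  g <- randomGenome(2000, 403)
  reads <- list(id = c("n1", "ok"), seq = c(strrep("N", 36),
                                            substr(g, 101, 136)),
                qual = rep(strrep("D", 36), 2))
  sam <- mapReads(reads, g)
  expect_equal(bitwAnd(sam$flag[1], 4L), 4L)
  expect_equal(sam$pos[2], 101L)
})

test_that("single-substitution reads place where the exhaustive scan says", {
  set.seed(404)
  g <- randomGenome(3000)
  n <- 30
  starts <- sample(0:(3000 - 36), n)
  reads <- vapply(starts, function(p) substr(g, p + 1, p + 36), "")
  for (i in seq_len(n)) {
    at <- sample(36, 1)
    old <- substr(reads[i], at, at)
    substr(reads[i], at, at) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
  }
  rc <- sample(c(TRUE, FALSE), n, TRUE)
  reads[rc] <- vapply(reads[rc], rcomp, "")
  sam <- mapReads(list(id = sprintf("r%02d", 1:n), seq = reads,
                       qual = rep(strrep("D", 36), n)), g)
  for (i in seq_len(n)) {
    want <- bestPlacementOracle(reads[i], g)
    expect_equal(sam$pos[i] - 1L, want$pos, info = paste("read", i))
    expect_equal(ifelse(bitwAnd(sam$flag[i], 16L) > 0, "-", "+"),
                 want$strand, info = paste("read", i))
  }
})

test_that("pileup equals the naive per-read expansion and conserves bases", {
  for (s in 1:10) {
    g <- randomGenome(500, 500 + s)
    sim <- simulateReads(g, foldCoverage = 4, errorRate = 0.02,
                         seed = 600 + s)
    sam <- mapReads(sim$pairs, g)
    sam <- sam[bitwAnd(sam$flag, 4L) == 0L, ]
    obs <- pileup(sam, g)
    want <- pileupOracle(sam)
    o <- function(d) {
      d <- d[order(d$pos, d$base, d$qual), ]; rownames(d) <- NULL; d
    }
    expect_equal(o(obs), o(want))
    expect_equal(nrow(obs), sum(nchar(sam$seq)))   # conservation
  }
})

test_that("pileup handles soft clips, insertions and deletions", {
  g <- paste0(strrep("A", 10), "CCGGTT", strrep("A", 10))
  sam <- data.frame(qname = c("clip", "ins", "del"), flag = 0L, rname = "r",
                    pos = c(3L, 5L, 5L), mapq = 60L,
                    cigar = c("2S4M", "3M2I3M", "3M2D3M"),
                    rnext = "*", pnext = 0L, tlen = 0L,
                    seq = c("GGAAAA", "AAGGAACC", "AAACCG"),
                    qual = c("IIIIII", "IIIIIIII", "IIIIII"))
  obs <- pileup(sam, g)
  expect_equal(sum(obs$base == "-"), 2L)            # deletion columns
  expect_equal(nrow(obs), 4L + 6L + 8L)             # aligned + del obs
  # insertion does not shift reference coordinates
  del <- obs[obs$base == "-", ]
  expect_equal(del$pos, c(7L, 8L))
  expect_error(pileup(data.frame(qname = "x", flag = 0L, rname = "r",
                                 pos = 25L, mapq = 60L, cigar = "6M",
                                 rnext = "*", pnext = 0L, tlen = 0L,
                                 seq = "AAAAAA", qual = "IIIIII"), g),
               "beyond the reference")
})

test_that("consensus base calls follow the additive Phred model", {
  expect_equal(callConsensusBase(character(0), integer(0)),
               list(base = "N", quality = 0L))
  expect_equal(callConsensusBase(rep("G", 5), rep(30L, 5)),
               list(base = "G", quality = 93L))     # 150 capped at 93
  expect_equal(callConsensusBase(c("A", "A", "C"), c(30L, 30L, 20L)),
               list(base = "A", quality = 40L))
  # tie -> N
  expect_equal(callConsensusBase(c("A", "C"), c(30L, 30L)),
               list(base = "N", quality = 0L))
  # N observations carry no vote
  expect_equal(callConsensusBase(c("N", "N", "T"), c(40L, 40L, 10L)),
               list(base = "T", quality = 10L))
})

test_that("draft equals the genome at covered positions when error-free", {
  g <- randomGenome(20000, 405)
  sim <- simulateReads(g, foldCoverage = 30, errorRate = 0, seed = 406)
  sam <- mapReads(sim$pairs, g)
  d <- buildDraft(sam, g)
  cov <- draftDepth(d) > 0
  gs <- strsplit(g, "")[[1]]
  ds <- strsplit(as.character(draftSequence(d)), "")[[1]]
  expect_true(all(ds[cov] == gs[cov]))
  expect_true(all(ds[!cov] == "N"))
  expect_gt(mean(confidentMask(d)), 0.99)
})

test_that("no reads give an all-N unconfident draft", {
  g <- randomGenome(500, 407)
  empty <- data.frame(qname = character(0), flag = integer(0),
                      rname = character(0), pos = integer(0),
                      mapq = integer(0), cigar = character(0),
                      rnext = character(0), pnext = integer(0),
                      tlen = integer(0), seq = character(0),
                      qual = character(0))
  d <- buildDraft(empty, g)
  expect_equal(as.character(draftSequence(d)), strrep("N", 500))
  expect_false(any(confidentMask(d)))
})

test_that("a homozygous SNP is carried into the draft at a confident position", {
  g <- randomGenome(10000, 408)
  mut <- g
  old <- substr(mut, 5000, 5000)
  substr(mut, 5000, 5000) <- setdiff(c("A", "C", "G", "T"), old)[1]
  sim <- simulateReads(mut, foldCoverage = 30, errorRate = 0, seed = 409)
  sam <- mapReads(sim$pairs, g)
  d <- buildDraft(sam, g)
  expect_equal(substr(as.character(draftSequence(d)), 5000, 5000),
               substr(mut, 5000, 5000))
  expect_true(confidentMask(d)[5000])
})

test_that("raising the quality cutoff never gains confident positions", {
  g <- randomGenome(5000, 410)
  sim <- simulateReads(g, foldCoverage = 8, errorRate = 0.02, seed = 411)
  sam <- mapReads(sim$pairs, g)
  counts <- vapply(c(10L, 30L, 50L, 70L), function(q)
    sum(confidentMask(buildDraft(sam, g, consensusParams(q)))), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("mapping report arithmetic matches independent summation", {
  g <- randomGenome(10000, 412)
  sim <- simulateReads(g, foldCoverage = 10, errorRate = 0, seed = 413)
  sam <- mapReads(sim$pairs, g)
  d <- buildDraft(sam, g)
  rep <- mappingReport(sam, g, d)
  expect_equal(rep@mappedFraction, 1.0)
  mappedRecs <- sam[bitwAnd(sam$flag, 4L) == 0L, ]
  expect_equal(rep@meanFoldCoverage, sum(nchar(mappedRecs$seq)) / 10000)
  expect_lte(rep@fracQ40, rep@fracQ30)

  empty <- sam[0, ]
  d0 <- buildDraft(empty, g)
  rep0 <- mappingReport(empty, g, d0)
  expect_equal(rep0@mappedFraction, 0)
  expect_equal(rep0@meanFoldCoverage, 0)
})

test_that("held-out remapping is ~1 on self and ~0 on unrelated sequence", {
  g <- randomGenome(10000, 414)
  sim <- simulateReads(g, foldCoverage = 3, errorRate = 0, seed = 415)
  expect_equal(remapValidation(sim$pairs, g), 1.0)
  other <- randomGenome(10000, 999)
  expect_lt(remapValidation(sim$pairs, other), 0.01)
})

test_that("SAM round-trips through the text writer and parser", {
  g <- randomGenome(3000, 416)
  sim <- simulateReads(g, foldCoverage = 2, errorRate = 0, seed = 417)
  sam <- mapReads(sim$pairs, g, refName = "chr")
  f <- tempfile(fileext = ".sam")
  writeSAM(sam, f, "chr", nchar(g))
  back <- readSAM(f)
  expect_equal(back$pos, sam$pos)
  expect_equal(back$seq, sam$seq)
  expect_equal(back$flag, sam$flag)
  expect_true(any(startsWith(attr(back, "header"), "@SQ")))
})
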