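test_that("an empty mutation spec derives an identical genome", {
  ref <- randomGenome(5000, 1001)
  dg <- deriveGenome(ref, mutationSpec())
  expect_equal(dg$genome, ref)
  expect_equal(nrow(truthEdits(dg$truth)), 0L)
})

test_that("a fixed deletion shortens the genome by its length", {
  ref <- randomGenome(10000, 1002)
  dg <- deriveGenome(ref, mutationSpec(deletions = list(c(4000L, 1000L))))
  expect_equal(nchar(dg$genome), 9000L)
  expect_equal(substr(dg$genome, 1, 4000), substr(ref, 1, 4000))
  expect_equal(substr(dg$genome, 4001, 9000), substr(ref, 5001, 10000))
})

test_that("IS copies appear the specified number of times in the derived genome", {
  ref <- randomGenome(50000, 1003)
  is1 <- randomGenome(1200, 1004)
  dg <- deriveGenome(ref, mutationSpec(
    isElements = list(list(sequence = is1, copies = 5L)), seed = 1005))
  # substring-count oracle
  hits <- gregexpr(is1, dg$genome, fixed = TRUE)[[1]]
  expect_equal(length(hits[hits > 0]), 5L)
  iv <- repeatIntervals(dg$truth)
  expect_equal(nrow(iv), 5L)
  expect_equal(sort(iv$start), sort(as.integer(hits) - 1L))
})

test_that("truth-table replay reproduces the derived genome byte-exactly", {
  for (s in 1:5) {
    ref <- randomGenome(20000, 1100 + s)
    spec <- mutationSpec(snpRate = 0.005, indelRate = 5e-4,
                         isElements = list(list(
                           sequence = randomGenome(800, 1200 + s),
                           copies = 3L)),
                         deletions = list(c(8000L, 1500L)),
                         seed = 1300 + s)
    dg <- deriveGenome(ref, spec)
    expect_identical(applyEdits(ref, truthEdits(dg$truth)), dg$genome,
                     label = paste("seed", 1100 + s))
  }
})

test_that("shredding conserves the genome when overlap and gap are zero", {
  g <- randomGenome(30000, 1008)
  sh <- shredToScaffolds(g, nBreaks = 10, seed = 1009)
  tr <- sh$origins[order(sh$origins$order), ]
  rebuilt <- paste(vapply(tr$scaffold_id, function(id) {
    s <- sh$scaffolds[[id]]
    if (tr$orientation[tr$scaffold_id == id] == "reverse") rcomp(s) else s
  }, ""), collapse = "")
  expect_equal(rebuilt, g)
})

test_that("repeat-aware shredding breaks inside each repeat copy", {
  ref <- randomGenome(60000, 1010)
  dg <- deriveGenome(ref, mutationSpec(
    isElements = list(list(sequence = randomGenome(1200, 1011),
                           copies = 5L)), seed = 1012))
  reps <- repeatIntervals(dg$truth)
  sh <- shredToScaffolds(dg$genome, nBreaks = 0, atRepeats = TRUE,
                         repeats = reps, seed = 1013)
  tr <- sh$origins[order(sh$origins$order), ]
  bounds <- c(tr$start[-1])                  # internal breakpoints
  inRepeat <- vapply(bounds, function(b)
    any(b >= reps$start & b < reps$end), logical(1))
  expect_gte(sum(inRepeat), 5L - 0L)         # one break per copy survives
})

test_that("revcompFraction 1 reverses every piece", {
  g <- randomGenome(20000, 1014)
  sh <- shredToScaffolds(g, nBreaks = 6, revcompFraction = 1, seed = 1015)
  expect_true(all(sh$origins$orientation == "reverse"))
})

test_that("read counts, insert sizes and error-free substrings are as specified", {
  g <- randomGenome(100000, 1016)
  sim <- simulateReads(g, foldCoverage = 30, errorRate = 0, seed = 1017)
  expect_equal(length(sim$pairs), ceiling(30 * 100000 / (2 * 36)))
  expect_equal(length(sim$pairs), 41667L)

  idx <- sample(length(sim$pairs), 50)
  for (i in idx) {
    expect_equal(sim$pairs$seq1[i],
                 substr(g, sim$origins$start[i] + 1,
                        sim$origins$start[i] + 36))
    expect_equal(rcomp(sim$pairs$seq2[i]),
                 substr(g, sim$origins$start[i] + sim$origins$insert[i] - 35,
                        sim$origins$start[i] + sim$origins$insert[i]))
  }
  # mean insert within 2 standard errors over >= 10^4 pairs
  se <- 15 / sqrt(length(sim$pairs))
  expect_lt(abs(mean(sim$origins$insert) - 163), 2 * se + 0.5)
  expect_true(all(sim$origins$insert >= 36))
})

test_that("generators are byte-deterministic under a fixed seed", {
  ref <- randomGenome(20000, 1018)
  spec <- mutationSpec(snpRate = 0.002, seed = 1019)
  expect_identical(deriveGenome(ref, spec)$genome,
                   deriveGenome(ref, spec)$genome)
  s1 <- shredToScaffolds(ref, nBreaks = 5, seed = 1020)
  s2 <- shredToScaffolds(ref, nBreaks = 5, seed = 1020)
  expect_identical(s1$scaffolds, s2$scaffolds)
  r1 <- simulateReads(ref, foldCoverage = 2, errorRate = 0.01, seed = 1021)
  r2 <- simulateReads(ref, foldCoverage = 2, errorRate = 0.01, seed = 1021)
  expect_identical(r1$pairs$seq1, r2$pairs$seq1)
  expect_identical(r1$pairs$seq2, r2$pairs$seq2)

  f1 <- tempfile(); f2 <- tempfile()
  writeFastqPairs(r1$pairs, f1, f2)
  back <- readFastqPairs(f1, f2)
  expect_identical(back$seq1, r1$pairs$seq1)
  expect_identical(back$qual2, r1$pairs$qual2)
})

test_that("mutation specs validate their rates and overlaps", {
  expect_error(mutationSpec(snpRate = 0.1), "0.05")
  expect_error(mutationSpec(deletions = list(c(100L, 500L), c(300L, 100L))),
               "overlap")
  expect_error(mutationSpec(isElements = list(list(sequence = "ACGT"))),
               "copies")
})
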