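test_that("constructed exact overlaps merge to the expected sequence", {
  set.seed(701)
  X <- rnd(300); S <- rnd(50); Y <- rnd(300)
  ro <- resolveOverlap(paste0(X, S), paste0(S, Y))
  expect_false(is.null(ro))
  expect_equal(ro$overlap, 50L)
  expect_equal(ro$sequence, paste0(X, S, Y))
  expect_equal(nchar(ro$sequence), 350L + 350L - 50L)

  expect_null(resolveOverlap(rnd(200), rnd(200)))
})

test_that("overlap detection agrees with the all-offsets oracle", {
  for (s in 1:30) {
    set.seed(720 + s)
    ov <- sample(30:120, 1)
    S <- rnd(ov)
    Smut <- S
    if (runif(1) < 0.6) {              # up to 1 mismatch, rate bound 0.05
      at <- sample(ov, 1)
      substr(Smut, at, at) <- sample(setdiff(c("A", "C", "G", "T"),
                                             substr(S, at, at)), 1)
    }
    left <- paste0(rnd(sample(50:200, 1)), S)
    right <- paste0(Smut, rnd(sample(50:200, 1)))
    got <- resolveOverlap(left, right, minOverlap = 30,
                          maxMismatchRate = 0.05)
    want <- overlapOracle(left, right, 30, 0.05)
    if (is.na(want)) {
      expect_null(got, info = paste("seed", 720 + s))
    } else {
      expect_equal(got$overlap, want, info = paste("seed", 720 + s))
    }
  }
})

test_that("draft filling splices exactly the intervening confident interval", {
  g <- randomGenome(30000, 702)
  sim <- simulateReads(g, foldCoverage = 30, errorRate = 0, seed = 703)
  d <- buildDraft(mapReads(sim$pairs, g), g)
  left <- substr(g, 2001, 12000)
  right <- substr(g, 12201, 22000)
  fd <- fillFromDraft(left, right, d)
  expect_false(is.null(fd))
  expect_equal(fd$insert, substr(g, 12001, 12200))
  expect_equal(paste0(left, fd$insert, right), substr(g, 2001, 22000))

  # a masked base inside the interval blocks the fill
  d2 <- d
  d2@confidentMask[12100] <- FALSE
  expect_null(fillFromDraft(left, right, d2))

  # out-of-order ends (rearrangement) yield none plus a warning
  expect_warning(res <- fillFromDraft(right, left, d), "out of order")
  expect_null(res)
})

test_that("shreds with universal overlaps reconstruct the genome exactly", {
  g <- randomGenome(50000, 704)
  sh <- shredToScaffolds(g, nBreaks = 8, overlapBp = 50,
                         revcompFraction = 0.3, seed = 705)
  lay <- placeScaffolds(sh$scaffolds, g)
  fin <- closeLayout(lay, sh$scaffolds)
  expect_equal(as.character(assemblySequence(fin)), g)
  expect_true(all(junctions(fin)$status == "overlap_merged"))
})

test_that("gapped shreds over a confident draft reconstruct via draft fills", {
  g <- randomGenome(50000, 706)
  sim <- simulateReads(g, foldCoverage = 30, errorRate = 0, seed = 707)
  d <- buildDraft(mapReads(sim$pairs, g), g)
  sh <- shredToScaffolds(g, nBreaks = 8, gapBp = c(100, 300),
                         revcompFraction = 0.3, seed = 708)
  lay <- placeScaffolds(sh$scaffolds, g)
  fin <- closeLayout(lay, sh$scaffolds, d)
  expect_equal(as.character(assemblySequence(fin)), g)
  expect_true(all(junctions(fin)$status == "draft_filled"))
})

test_that("with no draft and no overlaps all junctions open as N-runs", {
  g <- randomGenome(30000, 709)
  sh <- shredToScaffolds(g, nBreaks = 5, gapBp = 200, seed = 710)
  lay <- placeScaffolds(sh$scaffolds, g)
  fin <- closeLayout(lay, sh$scaffolds)
  jc <- junctions(fin)
  expect_true(all(jc$status == "open"))
  expect_equal(nrow(gapRecords(fin)), nrow(jc))
  # census conservation
  expect_equal(nrow(jc), nrow(placements(lay)) - 1L)
  # N-runs in the sequence equal the gap records
  seqc <- as.character(assemblySequence(fin))
  expect_equal(sum(strsplit(seqc, "")[[1]] == "N"),
               sum(gapRecords(fin)$estimated_size))
  expect_true(all(gapRecords(fin)$estimated_size >= 100))
})

test_that("AGP components concatenated in order reproduce the sequence", {
  g <- randomGenome(40000, 711)
  sh <- shredToScaffolds(g, nBreaks = 6, overlapBp = 60,
                         revcompFraction = 0.5, seed = 712)
  lay <- placeScaffolds(sh$scaffolds, g)
  fin <- closeLayout(lay, sh$scaffolds)
  agp <- agpTable(fin)
  rebuilt <- paste(vapply(seq_len(nrow(agp)), function(i) {
    if (agp$component_type[i] == "N")
      return(strrep("N", as.integer(agp$component_id[i])))
    s <- sh$scaffolds[[agp$component_id[i]]]
    seg <- substr(s, as.integer(agp$component_beg[i]),
                  as.integer(agp$component_end[i]))
    if (agp$orientation[i] == "-") rcomp(seg) else seg
  }, ""), collapse = "")
  expect_equal(rebuilt, as.character(assemblySequence(fin)))
})

test_that("closing a single-scaffold layout returns it unchanged", {
  g <- randomGenome(8000, 713)
  lay <- placeScaffolds(c(only = g), g)
  fin <- closeLayout(lay, c(only = g))
  expect_equal(as.character(assemblySequence(fin)), g)
  expect_equal(nrow(junctions(fin)), 0L)
})

test_that("enlarging the confident mask never loses draft-filled junctions", {
  g <- randomGenome(30000, 714)
  sim <- simulateReads(g, foldCoverage = 30, errorRate = 0, seed = 715)
  d <- buildDraft(mapReads(sim$pairs, g), g)
  sh <- shredToScaffolds(g, nBreaks = 5, gapBp = 150, seed = 716)
  lay <- placeScaffolds(sh$scaffolds, g)
  # shrink the mask: poke holes at regular intervals
  dSmall <- d
  dSmall@confidentMask[seq(1, 30000, by = 997)] <- FALSE
  nSmall <- sum(junctions(closeLayout(lay, sh$scaffolds,
                                      dSmall))$status == "draft_filled")
  nFull <- sum(junctions(closeLayout(lay, sh$scaffolds,
                                     d))$status == "draft_filled")
  expect_gte(nFull, nSmall)
})

test_that("containment screening finds excerpts and their reverse complements", {
  g <- randomGenome(40000, 717)
  sh <- shredToScaffolds(g, nBreaks = 5, overlapBp = 50, seed = 718)
  lay <- placeScaffolds(sh$scaffolds, g)
  fin <- closeLayout(lay, sh$scaffolds)
  ex <- substr(g, 10001, 10500)
  smalls <- c(fwd = ex, rev = rcomp(ex), junk = rnd(500, 719))
  got <- screenContained(smalls, fin)
  expect_setequal(got, c("fwd", "rev"))
  # tolerates mismatches within the rate bound
  mut <- ex
  for (at in c(100L, 300L)) {
    substr(mut, at, at) <- setdiff(c("A", "C", "G", "T"),
                                   substr(ex, at, at))[1]
  }
  expect_equal(screenContained(c(m = mut), fin, maxMismatchRate = 0.02), "m")
})

test_that("unplaced scaffolds are suggested for gaps whose flank they overlap", {
  g <- randomGenome(40000, 720)
  # pieces with a hole: [0, 15000), missing(15000..17000), [17000, 40000)
  sc <- c(a = substr(g, 1, 15050), b = substr(g, 17001, 40000))
  lay <- placeScaffolds(sc, g)
  fin <- closeLayout(lay, sc)
  expect_equal(junctions(fin)$status, "open")
  missingPiece <- substr(g, 15001, 17000)   # overlaps flank of 'a' by 50 bp
  sugg <- placeUnplacedIntoGaps(c(fill = missingPiece, junk = rnd(1500, 721)),
                                fin)
  expect_true("fill" %in% sugg$suggestions$scaffold_id)
  expect_true("junk" %in% sugg$unmatched)
  # suggestions never mutate the assembly
  expect_equal(length(assemblySequence(fin)),
               nchar(sc[["a"]]) + nchar(sc[["b"]]) +
                 gapRecords(fin)$estimated_size[1])
})
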