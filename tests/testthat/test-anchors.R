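test_that("identical and reverse-complement sequences give one full anchor", {
  ref <- rnd(1000, 101)
  a <- findAnchors(ref, ref, minLen = 40)
  expect_equal(nrow(a), 1L)
  expect_equal(a$q_start, 0L)
  expect_equal(a$q_end, 1000L)
  expect_equal(a$r_start, 0L)
  expect_equal(a$r_end, 1000L)
  expect_equal(a$strand, "forward")
  expect_equal(a$identity, 1)

  b <- findAnchors(rcomp(ref), ref, minLen = 40)
  expect_equal(nrow(b), 1L)
  expect_equal(b$strand, "reverse")
  expect_equal(b$q_start, 0L)
  expect_equal(b$q_end, 1000L)
  expect_equal(b$r_start, 0L)
  expect_equal(b$r_end, 1000L)
})

test_that("two conserved blocks are found at brute-force MEM coordinates", {
  set.seed(102)
  ref <- rnd(1500)
  q <- paste0(substr(ref, 201, 500), rnd(400), substr(ref, 901, 1200))
  got <- findAnchors(q, ref, minLen = 40, minIdentity = 1.0)
  want <- memOracle(q, ref, 40)
  expect_equal(canonAnchors(got), canonAnchors(want))
  # the two planted blocks are among the anchors
  expect_true(any(got$q_start == 0 & got$r_start == 200 & got$length >= 300))
  expect_true(any(got$r_start <= 900 & got$r_end >= 1200))
})

test_that("exact-identity anchor sets equal the MEM oracle on random pairs", {
  for (s in 1:25) {
    set.seed(200 + s)
    ref <- rnd(400)
    nb <- sample(1:3, 1)
    pieces <- character(0)
    for (i in seq_len(nb)) {
      st <- sample(1:(400 - 80), 1)
      blk <- substr(ref, st, st + sample(40:80, 1))
      if (runif(1) < 0.3) blk <- rcomp(blk)
      pieces <- c(pieces, blk, rnd(sample(10:60, 1)))
    }
    q <- paste0(pieces, collapse = "")
    got <- findAnchors(q, ref, minLen = 20, minIdentity = 1.0)
    want <- memOracle(q, ref, 20)
    expect_equal(canonAnchors(got), canonAnchors(want),
                 info = paste("seed", 200 + s))
  }
})

test_that("reported identity is verifiable by direct comparison", {
  set.seed(103)
  ref <- rnd(2000)
  q <- substr(ref, 501, 1500)
  qc <- strsplit(q, "")[[1]]
  qc[sample(1000, 20)] <- "A"          # some become mismatches
  q <- paste0(qc, collapse = "")
  a <- findAnchors(q, ref, minLen = 40, minIdentity = 0.9)
  expect_gt(nrow(a), 0)
  for (i in seq_len(nrow(a))) {
    qseg <- substr(q, a$q_start[i] + 1, a$q_end[i])
    if (a$strand[i] == "reverse") qseg <- rcomp(qseg)
    rseg <- substr(ref, a$r_start[i] + 1, a$r_end[i])
    direct <- mean(strsplit(qseg, "")[[1]] == strsplit(rseg, "")[[1]])
    expect_equal(a$identity[i], direct)
    expect_gte(direct, 0.9)
    expect_equal(a$q_end[i] - a$q_start[i], a$r_end[i] - a$r_start[i])
  }
})

test_that("anchor finding is symmetric on the forward strand", {
  set.seed(104)
  x <- rnd(800)
  y <- paste0(substr(x, 101, 400), rnd(300), substr(x, 501, 700))
  axy <- findAnchors(x, y, minLen = 30, minIdentity = 1.0)
  ayx <- findAnchors(y, x, minLen = 30, minIdentity = 1.0)
  fxy <- axy[axy$strand == "forward", c("q_start", "q_end", "r_start", "r_end")]
  fyx <- ayx[ayx$strand == "forward", c("r_start", "r_end", "q_start", "q_end")]
  names(fyx) <- c("q_start", "q_end", "r_start", "r_end")
  o <- function(d) { d <- d[order(d$q_start, d$r_start), ]; rownames(d) <- NULL; d }
  expect_equal(o(fxy), o(fyx))
})

test_that("N bases never seed and count as mismatches", {
  set.seed(105)
  ref <- rnd(500)
  q <- ref
  substr(q, 250, 250) <- "N"
  a <- findAnchors(q, ref, minLen = 40, minIdentity = 1.0)
  # the N splits the exact anchor in two
  expect_equal(nrow(a), 2L)
  expect_true(all(a$identity == 1))
  expect_false(any(a$q_start <= 249 & a$q_end > 249))
})

test_that("input validation rejects empty sequences and oversized seeds", {
  ref <- rnd(500, 106)
  expect_error(findAnchors("", ref), "non-empty")
  expect_error(findAnchors(ref, ref, minLen = 10), "seed weight")
  expect_error(seedPattern("0110"), "begin and end")
  expect_error(seedPattern("1111"), "at least 8")
})

test_that("bestAnchor picks the longest anchor with deterministic ties", {
  a <- data.frame(scaffold_id = "s", q_start = c(0, 10), q_end = c(200, 910),
                  r_start = c(50, 4000), r_end = c(250, 4900),
                  strand = "forward", length = c(200L, 900L), identity = 1)
  expect_equal(bestAnchor(a)$length, 900L)

  tie <- data.frame(scaffold_id = "s", q_start = c(5, 0), q_end = c(505, 500),
                    r_start = c(900, 100), r_end = c(1400, 600),
                    strand = "forward", length = c(500L, 500L), identity = 1)
  expect_equal(bestAnchor(tie)$r_start, 100)

  expect_error(bestAnchor(tie[0, ]), "non-empty")
  two <- tie; two$scaffold_id <- c("s1", "s2")
  expect_error(bestAnchor(two), "one scaffold")
})

test_that("bestAnchor equals exhaustive comparison under the total order", {
  for (s in 1:20) {
    set.seed(300 + s)
    n <- sample(2:12, 1)
    a <- data.frame(scaffold_id = "s", q_start = sample(0:50, n, TRUE),
                    r_start = sample(0:5000, n, TRUE),
                    length = sample(c(100L, 200L, 200L, 500L), n, TRUE),
                    strand = "forward", identity = 1)
    a$q_end <- a$q_start + a$length
    a$r_end <- a$r_start + a$length
    got <- bestAnchor(a)
    # exhaustive pairwise comparison under (length desc, r_start, q_start)
    better <- function(i, j) {
      if (a$length[i] != a$length[j]) return(a$length[i] > a$length[j])
      if (a$r_start[i] != a$r_start[j]) return(a$r_start[i] < a$r_start[j])
      a$q_start[i] <= a$q_start[j]
    }
    top <- 1L
    for (i in seq_len(nrow(a))) if (better(i, top)) top <- i
    expect_equal(got$length, a$length[top])
    expect_equal(got$r_start, a$r_start[top])
    expect_equal(got$q_start, a$q_start[top])
  }
})
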