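# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use different primitives (character vectors, rle,
# regex lookahead, exhaustive position scans) than the package code.

rnd <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rcomp <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# Maximal exact matches >= minLen between q and r, forward strand only,
# via per-diagonal run-length encoding of a character-vector comparison.
# Returns a data.frame of 0-based half-open coordinates.
memOracleForward <- function(q, r, minLen) {
  qc <- strsplit(q, "")[[1]]
  rc <- strsplit(r, "")[[1]]
  nq <- length(qc); nr <- length(rc)
  out <- list()
  for (d in seq(-(nq - minLen), nr - minLen)) {
    q0 <- max(0L, -d); q1 <- min(nq, nr - d)
    if (q1 - q0 < minLen) next
    qi <- (q0 + 1L):q1
    ri <- qi + d
    eq <- qc[qi] == rc[ri] & qc[qi] != "N"
    rl <- rle(eq)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths
    keep <- rl$values & rl$lengths >= minLen
    for (k in which(keep)) {
      out[[length(out) + 1L]] <- data.frame(
        q_start = q0 + starts[k], q_end = q0 + ends[k],
        r_start = q0 + starts[k] + d, r_end = q0 + ends[k] + d)
    }
  }
  if (!length(out)) {
    return(data.frame(q_start = integer(0), q_end = integer(0),
                      r_start = integer(0), r_end = integer(0)))
  }
  df <- unique(do.call(rbind, out))
  df[order(df$r_start, df$q_start), , drop = FALSE]
}

# Both-strand MEM oracle matching the anchor coordinate convention.
memOracle <- function(q, r, minLen) {
  fwd <- memOracleForward(q, r, minLen)
  if (nrow(fwd)) fwd$strand <- "forward"
  rev <- memOracleForward(rcomp(q), r, minLen)
  if (nrow(rev)) {
    nq <- nchar(q)
    tmp <- rev$q_start
    rev$q_start <- nq - rev$q_end
    rev$q_end <- nq - tmp
    rev$strand <- "reverse"
  }
  df <- rbind(fwd, rev)
  df <- df[order(df$r_start, df$q_start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# All-offsets suffix/prefix overlap oracle: every overlap length whose
# mismatch count is within the rate bound; returns the longest (or NA).
overlapOracle <- function(left, right, minOverlap, rate) {
  lc <- strsplit(left, "")[[1]]
  rc <- strsplit(right, "")[[1]]
  best <- NA_integer_
  for (ov in minOverlap:min(length(lc), length(rc))) {
    a <- lc[(length(lc) - ov + 1L):length(lc)]
    b <- rc[1:ov]
    if (sum(a != b) <= floor(rate * ov)) best <- ov
  }
  best
}

# Overlapping IUPAC motif scan via regex lookahead (0-based starts).
iupacRegexScan <- function(template, motif) {
  cls <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
           S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
           D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  pat <- paste0("(?=", paste0(cls[strsplit(motif, "")[[1]]], collapse = ""),
                ")")
  m <- gregexpr(pat, template, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

# Exhaustive PCR product oracle (exact primer matches, double scan).
pcrOracle <- function(template, fwd, rev, maxProduct) {
  fs <- iupacRegexScan(template, fwd)
  rs <- iupacRegexScan(template, rcomp(rev))
  out <- list()
  for (i in fs) for (j in rs) {
    len <- (j + nchar(rev)) - i
    if (j >= i + nchar(fwd) && len <= maxProduct)
      out[[length(out) + 1L]] <- data.frame(start = i, end = j + nchar(rev),
                                            length = len)
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0)))
  }
  df <- do.call(rbind, out)
  df[order(df$start, df$end), , drop = FALSE]
}

# Naive per-record pileup expansion for ungapped (nM CIGAR) SAM records.
pileupOracle <- function(sam) {
  sam <- sam[bitwAnd(sam$flag, 4L) == 0L, , drop = FALSE]
  rows <- lapply(seq_len(nrow(sam)), function(i) {
    b <- strsplit(sam$seq[i], "")[[1]]
    q <- utf8ToInt(sam$qual[i]) - 33L
    data.frame(pos = sam$pos[i] - 1L + seq_along(b) - 1L, base = b, qual = q)
  })
  do.call(rbind, rows)
}

# Exhaustive best ungapped placement of one read over a small reference.
bestPlacementOracle <- function(read, ref) {
  L <- nchar(ref); w <- nchar(read)
  best <- list(mism = Inf, pos = NA, strand = NA)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") read else rcomp(read)
    sc <- strsplit(s, "")[[1]]
    for (p in 0:(L - w)) {
      m <- sum(sc != strsplit(substr(ref, p + 1, p + w), "")[[1]])
      if (m < best$mism) best <- list(mism = m, pos = p, strand = strand)
    }
  }
  best
}

canonAnchors <- function(df) {
  df <- df[order(df$r_start, df$q_start, df$strand),
           c("q_start", "q_end", "r_start", "r_end", "strand")]
  rownames(df) <- NULL
  df
}
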