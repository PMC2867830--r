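# Low-level sequence utilities shared across modules.
#
# All coordinates in this package are 0-based half-open unless a function
# explicitly says otherwise (SAM and AGP writers convert at the boundary).

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

# IUPAC nucleotide codes as 4-bit masks (A=1, C=2, G=4, T=8).  A template
# 'N' (unknown base) is deliberately NOT given the four base bits: an
# unknown template base must never be claimed to satisfy a specific motif
# letter.  It carries a private 5th bit so that a motif 'N' (true
# wildcard) still accepts it.
.IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L
)
.TEMPLATE_N_BIT <- 16L

#' @keywords internal
.iupacMotifCodes <- function(motif) {
  chars <- strsplit(toupper(motif), "", fixed = TRUE)[[1]]
  bad <- !(chars %in% names(.IUPAC_BITS))
  if (any(bad)) {
    stop("invalid IUPAC code(s) in motif: ",
         paste(unique(chars[bad]), collapse = ", "))
  }
  codes <- .IUPAC_BITS[chars]
  # motif N is a genuine wildcard: accept unknown template bases too
  codes[chars == "N"] <- bitwOr(15L, .TEMPLATE_N_BIT)
  unname(codes)
}

#' @keywords internal
.templateCodes <- function(seq) {
  ints <- utf8ToInt(toupper(seq))
  codes <- integer(length(ints))
  codes[ints == utf8ToInt("A")] <- 1L
  codes[ints == utf8ToInt("C")] <- 2L
  codes[ints == utf8ToInt("G")] <- 4L
  codes[ints == utf8ToInt("T")] <- 8L
  codes[ints == utf8ToInt("N")] <- .TEMPLATE_N_BIT
  codes
}

# Scan a template (0-based result) for every position where an IUPAC motif
# matches with at most max.mismatch mismatching letters.  Vectorised over
# template positions; the loop runs over motif letters only.
#' @keywords internal
.iupacScan <- function(template, motif, max.mismatch = 0L) {
  m <- nchar(motif)
  L <- nchar(template)
  if (m > L) return(integer(0))
  tpl <- .templateCodes(template)
  mot <- .iupacMotifCodes(motif)
  starts <- seq_len(L - m + 1L)           # 1-based candidate starts
  mism <- integer(length(starts))
  for (i in seq_len(m)) {
    hit <- bitwAnd(tpl[starts + (i - 1L)], mot[i]) > 0L
    mism <- mism + !hit
  }
  starts[mism <= max.mismatch] - 1L        # 0-based
}

#' Coerce to a plain upper-case character DNA sequence
#' @keywords internal
.asSeq <- function(x) {
  if (is(x, "XString") || is(x, "XStringSet")) x <- as.character(x)
  toupper(as.character(x))
}

#' @keywords internal
.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(.asSeq(x))))
}

#' @keywords internal
.checkDNA <- function(seq, what = "sequence") {
  seq <- .asSeq(seq)
  if (length(seq) != 1L || is.na(seq) || nchar(seq) == 0L) {
    stop(what, " must be a single non-empty DNA sequence")
  }
  chars <- unique(strsplit(seq, "", fixed = TRUE)[[1]])
  if (!all(chars %in% DNA_ALPHABET)) {
    stop(what, " contains characters outside {A,C,G,T,N}: ",
         paste(setdiff(chars, DNA_ALPHABET), collapse = ", "))
  }
  seq
}

# Vectorised mismatch counts between pairs of equal-length strings.
# Collapses both vectors into single strings and compares raw bytes, so the
# per-pair work is all in C.
#' @keywords internal
.stringMismatchCounts <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) == 0L) return(integer(0))
  wa <- nchar(a)
  if (any(wa != nchar(b))) stop("strings must be pairwise equal length")
  ra <- charToRaw(paste0(a, collapse = ""))
  rb <- charToRaw(paste0(b, collapse = ""))
  diff <- ra != rb
  grp <- rep.int(seq_along(a), wa)
  as.integer(rowsum(as.integer(diff), grp, reorder = TRUE))
}

# Per-position match vector between two equal-length strings (TRUE = match).
# 'N' never matches anything, including another 'N'.
#' @keywords internal
.matchVector <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  isN <- ra == charToRaw("N") | rb == charToRaw("N")
  ra == rb & !isN
}

#' @keywords internal
.substrVec <- function(seq, start0, width) {
  # start0: 0-based starts; vectorised substring extraction
  substring(seq, start0 + 1L, start0 + width)
}

# Maximal runs of TRUE in a logical vector, as a two-column matrix of
# 0-based half-open [start, end) offsets.
#' @keywords internal
.trueRuns <- function(x) {
  if (length(x) == 0L) return(matrix(integer(0), ncol = 2))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  cbind(starts[keep], ends[keep])
}

# Maximal runs of a given character (default "N") in a sequence, 0-based
# half-open intervals.
#' @keywords internal
.charRuns <- function(seq, char = "N") {
  .trueRuns(charToRaw(seq) == charToRaw(char))
}

#' @keywords internal
.phredToChar <- function(q) {
  intToUtf8(pmin(pmax(q, 0L), 93L) + 33L, multiple = FALSE)
}

#' @keywords internal
.charToPhred <- function(s) {
  utf8ToInt(s) - 33L
}
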