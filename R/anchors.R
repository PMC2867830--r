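#' @importFrom data.table data.table as.data.table setkeyv
NULL

# ---------------------------------------------------------------------------
# Spaced-seed anchoring.
#
# Anchors are short, well-conserved UNGAPPED matches between a query
# (scaffold) and a reference genome, found by spaced-seed hashing of the
# reference, seed lookup from both strands of the query, and maximal
# ungapped extension of seed hits along each diagonal.  Indels therefore
# split anchors; 'N' bases never seed and always count as mismatches.
# ---------------------------------------------------------------------------

# Extract seed keys for every 0-based position of `seq`; positions whose
# key would contain an N are dropped.
.seedKeys <- function(seq, pattern) {
  span <- nchar(pattern@mask)
  L <- nchar(seq)
  if (L < span) return(list(key = character(0), pos = integer(0)))
  starts <- 0:(L - span)                         # 0-based window starts
  runs <- .trueRuns(strsplit(pattern@mask, "", fixed = TRUE)[[1]] == "1")
  pieces <- lapply(seq_len(nrow(runs)), function(i) {
    .substrVec(seq, starts + runs[i, 1L], runs[i, 2L] - runs[i, 1L])
  })
  keys <- do.call(paste0, pieces)
  ok <- !grepl("N", keys, fixed = TRUE)
  list(key = keys[ok], pos = starts[ok])
}

#' Precomputed seed index of a reference sequence
#'
#' Builds the spaced-seed hash of a reference once so that repeated
#' \code{\link{findAnchors}} calls (e.g. one per scaffold, or one per
#' junction during gap closing) reuse it.
#'
#' @param reference DNA sequence (character or \link[Biostrings]{DNAString}).
#' @param pattern a \linkS4class{SeedPattern}.
#' @return an object of class \code{SeedIndex}.
#' @export
seedIndex <- function(reference, pattern = seedPattern()) {
  seq <- .checkDNA(reference, "reference")
  sk <- .seedKeys(seq, pattern)
  dt <- data.table(seedkey = sk$key, rpos = sk$pos)
  setkeyv(dt, "seedkey")
  structure(list(table = dt, seq = seq, length = nchar(seq),
                 pattern = pattern),
            class = "SeedIndex")
}

#' @export
print.SeedIndex <- function(x, ...) {
  cat("SeedIndex: ", x$length, " bp reference, ", nrow(x$table),
      " seed positions, mask ", x$pattern@mask, "\n", sep = "")
  invisible(x)
}

# Maximal ungapped extension of seed hits along one diagonal.
#
# M: logical match vector along the diagonal (local 0-based coords: M[i+1]
# is position i), hits: sorted 0-based local seed start positions.
# Returns a matrix of 0-based half-open local intervals [a, e).  An anchor
# starts and ends on a match and is extended greedily to the farthest
# boundary keeping overall identity >= minIdentity, alternating sides
# until a fixpoint.
.extendOnDiagonal <- function(M, hits, minIdentity) {
  n <- length(M)
  C <- c(0L, cumsum(M))                     # C[i+1] = matches in [0, i)
  out <- list()
  lastE <- 0L
  for (s in hits) {
    if (s < lastE) next                     # inside the previous anchor
    if (s + 1L > n || !M[s + 1L]) next      # defensive; mask starts on '1'
    # maximal exact run containing s: [a, e)
    a <- s
    while (a > 0L && M[a]) a <- a - 1L
    e <- s + 1L
    while (e < n && M[e + 1L]) e <- e + 1L
    repeat {
      moved <- FALSE
      if (e < n) {                          # extend right: candidate ends
        cand <- (e + 1L):n
        ok <- M[cand] &
          (C[cand + 1L] - C[a + 1L]) / (cand - a) >= minIdentity
        if (any(ok)) { e <- max(cand[ok]); moved <- TRUE }
      }
      if (a > 0L) {                         # extend left: candidate starts
        cand <- 0:(a - 1L)
        ok <- M[cand + 1L] &
          (C[e + 1L] - C[cand + 1L]) / (e - cand) >= minIdentity
        if (any(ok)) { a <- min(cand[ok]); moved <- TRUE }
      }
      if (!moved) break
    }
    out[[length(out) + 1L]] <- c(a, e)
    lastE <- e
  }
  if (!length(out)) return(matrix(integer(0), ncol = 2))
  unique(do.call(rbind, out))
}

# Anchors of one strand of the query against an indexed reference.
.anchorsOneStrand <- function(qseq, index, minLen, minIdentity) {
  qk <- .seedKeys(qseq, index$pattern)
  if (!length(qk$pos)) return(NULL)
  qdt <- data.table(seedkey = qk$key, qpos = qk$pos)
  hits <- index$table[qdt, on = "seedkey", nomatch = NULL, allow.cartesian = TRUE]
  if (!nrow(hits)) return(NULL)
  Lq <- nchar(qseq)
  Lr <- index$length
  byDiag <- split(hits$qpos, hits$rpos - hits$qpos)
  res <- list()
  for (ds in names(byDiag)) {
    d <- as.integer(ds)
    q0 <- max(0L, -d)                       # diagonal overlap, query frame
    q1 <- min(Lq, Lr - d)
    n <- q1 - q0
    if (n < minLen) next
    qsub <- substr(qseq, q0 + 1L, q1)
    rsub <- substr(index$seq, q0 + d + 1L, q1 + d)
    M <- .matchVector(qsub, rsub)
    h <- sort(byDiag[[ds]]) - q0
    iv <- .extendOnDiagonal(M, h, minIdentity)
    if (!nrow(iv)) next
    len <- iv[, 2L] - iv[, 1L]              # intervals are half-open
    keep <- len >= minLen
    if (!any(keep)) next
    iv <- iv[keep, , drop = FALSE]
    C <- c(0L, cumsum(M))
    ident <- (C[iv[, 2L] + 1L] - C[iv[, 1L] + 1L]) / (iv[, 2L] - iv[, 1L])
    res[[length(res) + 1L]] <- data.frame(
      q_start = iv[, 1L] + q0,
      q_end = iv[, 2L] + q0,
      r_start = iv[, 1L] + q0 + d,
      r_end = iv[, 2L] + q0 + d,
      identity = ident)
  }
  if (!length(res)) return(NULL)
  unique(do.call(rbind, res))
}

#' Find anchors between a query and a reference
#'
#' Finds all maximal well-conserved ungapped matches (anchors) of length at
#' least \code{minLen} and identity at least \code{minIdentity} between the
#' query sequence(s) and the reference, on both strands.  Coordinates are
#' 0-based half-open; reverse-strand anchors report query coordinates in
#' the forward frame of the query.
#'
#' @param query a DNA sequence, a named character vector, or a
#'   \link[Biostrings]{DNAStringSet} of scaffolds.
#' @param reference the reference sequence, or a prebuilt
#'   \code{\link{seedIndex}}.
#' @param pattern a \linkS4class{SeedPattern} (ignored when
#'   \code{reference} is already an index).
#' @param minLen minimum anchor length in bases; must be at least the seed
#'   weight.
#' @param minIdentity minimum anchor identity in [0, 1].
#' @param id scaffold id used when \code{query} is a single unnamed
#'   sequence.
#' @return data.frame with columns \code{scaffold_id}, \code{q_start},
#'   \code{q_end}, \code{r_start}, \code{r_end}, \code{strand},
#'   \code{length}, \code{identity}, sorted by \code{r_start}.
#' @examples
#' ref <- paste(sample(c("A","C","G","T"), 500, TRUE), collapse = "")
#' findAnchors(ref, ref, minLen = 40)   # one full-length forward anchor
#' @export
findAnchors <- function(query, reference, pattern = seedPattern(),
                        minLen = 40L, minIdentity = 0.9, id = NULL) {
  if (!inherits(reference, "SeedIndex"))
    reference <- seedIndex(reference, pattern)
  if (minLen < reference$pattern@weight)
    stop("minLen (", minLen, ") must be at least the seed weight (",
         reference$pattern@weight, ")")
  if (minIdentity <= 0 || minIdentity > 1)
    stop("minIdentity must lie in (0, 1]")

  if (is(query, "XStringSet")) {
    qs <- as.character(query)
  } else if (is.character(query) && length(query) > 1L) {
    qs <- query
  } else {
    qs <- stats::setNames(.asSeq(query),
                          if (is.null(id)) names(query) %||% "query" else id)
  }
  if (is.null(names(qs)) || any(!nzchar(names(qs))))
    names(qs) <- if (length(qs) == 1L && !is.null(id)) id else
      paste0("query", seq_along(qs))

  out <- lapply(names(qs), function(nm) {
    qseq <- .checkDNA(qs[[nm]], paste0("query '", nm, "'"))
    Lq <- nchar(qseq)
    fwd <- .anchorsOneStrand(qseq, reference, minLen, minIdentity)
    rev <- .anchorsOneStrand(.revcomp(qseq), reference, minLen, minIdentity)
    if (!is.null(fwd)) fwd$strand <- "forward"
    if (!is.null(rev)) {
      # map reverse-complement coordinates back to the forward frame
      tmp <- rev$q_start
      rev$q_start <- Lq - rev$q_end
      rev$q_end <- Lq - tmp
      rev$strand <- "reverse"
    }
    a <- rbind(fwd, rev)
    if (is.null(a) || !nrow(a)) return(NULL)
    a$scaffold_id <- nm
    a$length <- a$q_end - a$q_start
    a
  })
  out <- do.call(rbind, out)
  if (is.null(out) || !nrow(out)) {
    return(data.frame(scaffold_id = character(0), q_start = integer(0),
                      q_end = integer(0), r_start = integer(0),
                      r_end = integer(0), strand = character(0),
                      length = integer(0), identity = numeric(0)))
  }
  out <- out[order(out$scaffold_id, out$r_start, out$q_start, out$strand), ]
  rownames(out) <- NULL
  out[, c("scaffold_id", "q_start", "q_end", "r_start", "r_end",
          "strand", "length", "identity")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Representative anchor of a scaffold
#'
#' Selects the anchor used to place a scaffold: the longest one, with ties
#' broken by smaller reference start, then smaller query start (a
#' deterministic total order).
#'
#' @param anchors data.frame of anchors for one scaffold, as returned by
#'   \code{\link{findAnchors}}.
#' @return the selected anchor (one-row data.frame).
#' @export
bestAnchor <- function(anchors) {
  if (is.null(anchors) || nrow(anchors) == 0L)
    stop("bestAnchor() requires a non-empty anchor collection")
  if (length(unique(anchors$scaffold_id)) > 1L)
    stop("all anchors must belong to one scaffold")
  o <- order(-anchors$length, anchors$r_start, anchors$q_start)
  anchors[o[1L], , drop = FALSE]
}

#' Write anchors as TSV
#'
#' @param anchors anchor data.frame from \code{\link{findAnchors}}.
#' @param path output file.
#' @export
writeAnchorsTSV <- function(anchors, path) {
  utils::write.table(anchors, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
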