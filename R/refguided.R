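#' @importFrom Biostrings DNAStringSet PDict matchPDict subseq
#' @importFrom Matrix sparseMatrix colSums
NULL

# ---------------------------------------------------------------------------
# Reference-guided draft: ungapped seed-and-extend read mapping, a
# qual-weighted pileup, and an additive-Phred consensus with a confidence
# cutoff.  The consensus model is deliberately simple and monotone: the
# called base maximises the summed Phred weight of agreeing observations
# and its quality is (agreeing - disagreeing) Phred, floored at 0 and
# capped at 93.  Positions are confident when quality >= cutoff and depth
# >= minDepth (the cutoff defaults to Phred 40).
# ---------------------------------------------------------------------------

#' Consensus parameters
#'
#' @param qualityCutoff Phred threshold for a confident position
#'   (default 40).
#' @param minDepth minimum read depth for a confident position.
#' @return list with validated fields.
#' @export
consensusParams <- function(qualityCutoff = 40L, minDepth = 1L) {
  qualityCutoff <- as.integer(qualityCutoff)
  minDepth <- as.integer(minDepth)
  if (qualityCutoff < 0L || qualityCutoff > 93L)
    stop("qualityCutoff must lie in [0, 93]")
  if (minDepth < 1L) stop("minDepth must be at least 1")
  list(qualityCutoff = qualityCutoff, minDepth = minDepth)
}

# Exact seed hits of constant-width patterns against one strand of the
# reference.  Returns 0-based candidate read-start positions.
.seedHits <- function(seqs, offset, ref, k) {
  usable <- which(!grepl("N", seqs, fixed = TRUE))
  if (!length(usable)) return(NULL)
  pd <- PDict(DNAStringSet(seqs[usable]))
  si <- Biostrings::startIndex(matchPDict(pd, ref))
  cnt <- lengths(si)
  if (sum(cnt) == 0L) return(NULL)
  data.table(ridx = rep(usable, cnt),
             start0 = unlist(si, use.names = FALSE) - 1L -
               offset[rep(usable, cnt)])
}

#' Map short reads to a reference by exact k-mer seeding and ungapped
#' extension
#'
#' Each read (and its reverse complement) is seeded with its first and
#' last \code{k} bases; every exact seed hit proposes an ungapped
#' placement, placements are scored by mismatch count, and the read is
#' reported at its best-scoring position.  Reads whose best score exceeds
#' \code{maxMismatch} (or that have no seed hit) are left unmapped; reads
#' with multiple equally best placements are flagged as multi-mapping
#' (MAPQ 0) and are excluded from consensus building downstream.  This is
#' a deliberately simple substitution-only mapper: any SAM produced by any
#' other mapper is equally accepted by \code{\link{buildDraft}}.
#'
#' @param reads a \code{ReadPairs} object (both mates are mapped
#'   independently), or a list with fields \code{id}, \code{seq},
#'   \code{qual} for single-end reads.
#' @param reference reference sequence (character or DNAString).
#' @param k seed length (default 18; must not exceed the read length).
#' @param maxMismatch maximum mismatches for a placement; default
#'   \code{floor(0.1 * read length)} per read.
#' @param refName reference name written in the SAM \code{rname} column.
#' @return data.frame of SAM records (11 mandatory columns, \code{pos}
#'   1-based).  MAPQ is 60 for unique placements, 0 for multi-mapping.
#' @export
mapReads <- function(reads, reference, k = 18L, maxMismatch = NULL,
                     refName = "ref") {
  if (inherits(reads, "ReadPairs")) {
    ids <- c(paste0(reads$id, "/1"), paste0(reads$id, "/2"))
    seqs <- c(reads$seq1, reads$seq2)
    quals <- c(reads$qual1, reads$qual2)
  } else {
    ids <- reads$id; seqs <- toupper(reads$seq); quals <- reads$qual
  }
  refSeq <- .checkDNA(reference, "reference")
  ref <- Biostrings::DNAString(refSeq)
  L <- nchar(refSeq)
  n <- length(seqs)
  w <- nchar(seqs)
  if (any(k > w)) stop("seed length k exceeds a read length")
  thr <- if (is.null(maxMismatch)) pmax(0L, floor(0.1 * w)) else
    rep_len(as.integer(maxMismatch), n)

  rcseqs <- as.character(Biostrings::reverseComplement(DNAStringSet(seqs)))
  cand <- list(
    fp = .seedHits(substr(seqs, 1L, k), integer(n), ref, k),
    fs = .seedHits(substr(seqs, w - k + 1L, w), w - k, ref, k),
    rp = .seedHits(substr(rcseqs, 1L, k), integer(n), ref, k),
    rs = .seedHits(substr(rcseqs, w - k + 1L, w), w - k, ref, k))
  strandOf <- c(fp = "+", fs = "+", rp = "-", rs = "-")
  cc <- list()
  for (nm in names(cand)) {
    if (is.null(cand[[nm]])) next
    x <- cand[[nm]]
    x$strand <- strandOf[[nm]]
    cc[[nm]] <- x
  }
  best <- NULL
  if (length(cc)) {
    cd <- unique(data.table::rbindlist(cc))
    cd <- cd[cd$start0 >= 0L & cd$start0 + w[cd$ridx] <= L, ]
    if (nrow(cd)) {
      readStr <- ifelse(cd$strand == "+", seqs[cd$ridx], rcseqs[cd$ridx])
      refStr <- .substrVec(refSeq, cd$start0, w[cd$ridx])
      cd$mism <- .stringMismatchCounts(refStr, readStr)
      cd <- cd[cd$mism <= thr[cd$ridx], ]
      if (nrow(cd)) {
        # deterministic best placement: fewest mismatches, then leftmost,
        # then forward strand
        data.table::setorderv(cd, c("ridx", "mism", "start0", "strand"))
        first <- cd[!duplicated(cd$ridx), ]
        nbest <- cd[, list(nb = sum(mism == min(mism))), by = "ridx"]
        best <- merge(first, nbest, by = "ridx")
      }
    }
  }

  flag <- rep(4L, n); pos <- rep(0L, n); mapq <- rep(0L, n)
  cigar <- rep("*", n); rname <- rep("*", n)
  outSeq <- seqs; outQual <- quals
  if (!is.null(best) && nrow(best)) {
    i <- best$ridx
    rev <- best$strand == "-"
    flag[i] <- ifelse(rev, 16L, 0L)
    pos[i] <- best$start0 + 1L
    mapq[i] <- ifelse(best$nb > 1L, 0L, 60L)
    cigar[i] <- paste0(w[i], "M")
    rname[i] <- refName
    outSeq[i] <- ifelse(rev, rcseqs[i], seqs[i])
    revQ <- function(s) vapply(s, function(x)
      intToUtf8(rev(utf8ToInt(x))), "", USE.NAMES = FALSE)
    outQual[i[rev]] <- revQ(quals[i[rev]])
  }
  data.frame(qname = ids, flag = flag, rname = rname, pos = pos,
             mapq = mapq, cigar = cigar, rnext = "*", pnext = 0L,
             tlen = 0L, seq = outSeq, qual = outQual)
}

# Parse a CIGAR string into op letters and lengths.
.parseCigar <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  if (length(lens) != length(ops) || !length(ops))
    stop("malformed CIGAR: ", cigar)
  list(ops = ops, lens = lens)
}

#' Pileup of aligned read bases over a reference
#'
#' Expands SAM records into per-position base/quality observations.  Every
#' aligned (M/=/X) base contributes exactly one observation at its
#' reference position; deletions (D) contribute gap observations
#' (base \code{"-"}, carrying the quality of the preceding read base);
#' insertions (I) and soft clips (S) consume read bases but no reference
#' positions.
#'
#' @param sam data.frame of SAM records (unmapped records are skipped).
#' @param reference reference sequence (used for bounds checking).
#' @return data.frame with columns \code{pos} (0-based reference
#'   position), \code{base}, \code{qual} (integer Phred).
#' @export
pileup <- function(sam, reference) {
  refLen <- nchar(.asSeq(reference))
  sam <- sam[bitwAnd(sam$flag, 4L) == 0L, , drop = FALSE]
  if (!nrow(sam)) {
    return(data.frame(pos = integer(0), base = character(0),
                      qual = integer(0)))
  }
  simple <- grepl("^[0-9]+M$", sam$cigar)
  parts <- list()

  if (any(simple)) {
    s <- sam[simple, , drop = FALSE]
    wid <- nchar(s$seq)
    over <- s$pos - 1L + wid > refLen | s$pos < 1L
    if (any(over))
      stop("SAM record '", s$qname[which(over)[1L]],
           "' extends beyond the reference")
    posv <- rep(s$pos - 1L, wid) + sequence(wid) - 1L
    basev <- rawToChar(charToRaw(paste0(s$seq, collapse = "")), multiple = TRUE)
    qualv <- as.integer(charToRaw(paste0(s$qual, collapse = ""))) - 33L
    parts[[1L]] <- data.frame(pos = posv, base = basev, qual = qualv)
  }

  if (any(!simple)) {
    s <- sam[!simple, , drop = FALSE]
    rows <- lapply(seq_len(nrow(s)), function(i) {
      cg <- .parseCigar(s$cigar[i])
      if (any(!cg$ops %in% c("M", "=", "X", "S", "I", "D")))
        stop("unsupported CIGAR op in record '", s$qname[i], "': ",
             s$cigar[i])
      rpos <- s$pos[i] - 1L          # 0-based
      qpos <- 0L                     # 0-based offset into SEQ
      seqc <- s$seq[i]; qualc <- s$qual[i]
      pos <- integer(0); base <- character(0); qual <- integer(0)
      lastQ <- 0L
      for (j in seq_along(cg$ops)) {
        op <- cg$ops[j]; ln <- cg$lens[j]
        if (op %in% c("M", "=", "X")) {
          if (rpos + ln > refLen)
            stop("SAM record '", s$qname[i], "' extends beyond the reference")
          pos <- c(pos, rpos + 0:(ln - 1L))
          base <- c(base, strsplit(substr(seqc, qpos + 1L, qpos + ln),
                                   "")[[1]])
          qv <- utf8ToInt(substr(qualc, qpos + 1L, qpos + ln)) - 33L
          qual <- c(qual, qv)
          lastQ <- qv[length(qv)]
          rpos <- rpos + ln; qpos <- qpos + ln
        } else if (op %in% c("S", "I")) {
          qpos <- qpos + ln
        } else if (op == "D") {
          pos <- c(pos, rpos + 0:(ln - 1L))
          base <- c(base, rep("-", ln))
          qual <- c(qual, rep(lastQ, ln))
          rpos <- rpos + ln
        }
      }
      data.frame(pos = pos, base = base, qual = qual)
    })
    parts[[length(parts) + 1L]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Call one consensus base from a pileup column
#'
#' The consensus base is the one among A/C/G/T with the largest summed
#' Phred weight of agreeing observations; its quality is the agreeing sum
#' minus the disagreeing sum (gap observations disagree with every base;
#' \code{N} observations carry no vote), floored at 0 and capped at 93.
#' An empty column or a tie yields \code{("N", 0)}.
#'
#' @param bases character vector of observed bases (\code{A,C,G,T,N,-}).
#' @param quals integer Phred values, parallel to \code{bases}.
#' @return list with \code{base} and \code{quality}.
#' @examples
#' callConsensusBase(c("A", "A", "C"), c(30, 30, 20))  # A, quality 40
#' @export
callConsensusBase <- function(bases, quals) {
  keep <- bases != "N"
  bases <- bases[keep]; quals <- quals[keep]
  if (!length(bases)) return(list(base = "N", quality = 0L))
  sums <- vapply(c("A", "C", "G", "T"),
                 function(b) sum(quals[bases == b]), numeric(1))
  total <- sum(quals)
  mx <- max(sums)
  if (mx == 0 || sum(sums == mx) > 1L) return(list(base = "N", quality = 0L))
  b <- names(sums)[which.max(sums)]
  q <- min(93L, max(0L, as.integer(mx - (total - mx))))
  list(base = b, quality = q)
}

# Vectorised consensus over all positions: sparse accumulation of Phred
# sums per (base, position).
.consensusTracks <- function(obs, refLen) {
  baseIdx <- match(obs$base, c("A", "C", "G", "T"))   # NA for '-' and 'N'
  isGap <- obs$base == "-"
  vote <- !is.na(baseIdx)
  Q <- matrix(0, nrow = 4L, ncol = refLen)
  if (any(vote)) {
    Qs <- sparseMatrix(i = baseIdx[vote], j = obs$pos[vote] + 1L,
                       x = as.numeric(obs$qual[vote]), dims = c(4L, refLen))
    Q <- as.matrix(Qs)
  }
  gapQ <- numeric(refLen)
  if (any(isGap)) {
    g <- sparseMatrix(i = rep(1L, sum(isGap)), j = obs$pos[isGap] + 1L,
                      x = as.numeric(obs$qual[isGap]), dims = c(1L, refLen))
    gapQ <- as.numeric(g[1L, ])
  }
  depth <- integer(refLen)
  if (any(vote)) {
    d <- sparseMatrix(i = rep(1L, sum(vote)), j = obs$pos[vote] + 1L,
                      x = 1, dims = c(1L, refLen))
    depth <- as.integer(d[1L, ])
  }
  total <- Matrix::colSums(Q) + gapQ
  mx <- pmax(Q[1L, ], Q[2L, ], Q[3L, ], Q[4L, ])
  nTop <- colSums(Q == rep(mx, each = 4L) & Q > 0)
  called <- mx > 0 & nTop == 1L
  baseNum <- max.col(t(Q), ties.method = "first")
  bases <- rep("N", refLen)
  bases[called] <- c("A", "C", "G", "T")[baseNum[called]]
  qual <- integer(refLen)
  qual[called] <- pmin(93L, pmax(0L, as.integer(
    mx[called] - (total[called] - mx[called]))))
  list(base = bases, quality = qual, depth = depth)
}

#' Build the reference-guided draft
#'
#' Computes the per-position consensus over the reference from read
#' alignments.  Multi-mapping records (MAPQ 0) are excluded so that
#' multi-copy repeats cannot corrupt the consensus.  Every covered
#' position keeps its consensus base in the sequence track; positions
#' failing the quality/depth rule are simply not flagged confident.
#' Uncovered positions are \code{N}.
#'
#' @param sam data.frame of SAM records (e.g. from \code{\link{mapReads}}
#'   or \code{\link{readSAM}}).
#' @param reference the reference sequence.
#' @param params see \code{\link{consensusParams}}.
#' @param referenceId name stored in the draft object.
#' @return a \linkS4class{ReferenceGuidedDraft}.
#' @export
buildDraft <- function(sam, reference, params = consensusParams(),
                       referenceId = "ref") {
  refSeq <- .checkDNA(reference, "reference")
  use <- sam[bitwAnd(sam$flag, 4L) == 0L & sam$mapq > 0L, , drop = FALSE]
  obs <- pileup(use, refSeq)
  tr <- .consensusTracks(obs, nchar(refSeq))
  mask <- tr$quality >= params$qualityCutoff & tr$depth >= params$minDepth
  new("ReferenceGuidedDraft",
      sequence = Biostrings::DNAString(paste0(tr$base, collapse = "")),
      quality = as.integer(tr$quality), depth = tr$depth,
      confidentMask = mask, referenceId = referenceId, params = params)
}

#' Mapping statistics
#'
#' Summarises a mapping run: fraction of reads mapped, mean fold coverage
#' (aligned bases divided by reference length), and the fractions of
#' covered draft positions with consensus quality at or above Phred 40
#' and 30.
#'
#' @param sam data.frame of SAM records.
#' @param reference the reference sequence.
#' @param draft the \linkS4class{ReferenceGuidedDraft} built from the
#'   same alignments.
#' @return a \linkS4class{MappingReport}.
#' @export
mappingReport <- function(sam, reference, draft) {
  refLen <- nchar(.asSeq(reference))
  nReads <- nrow(sam)
  mapped <- bitwAnd(sam$flag, 4L) == 0L
  simple <- grepl("^[0-9]+M$", sam$cigar)
  alignedBases <- sum(nchar(sam$seq[mapped & simple])) +
    sum(vapply(which(mapped & !simple), function(i) {
      cg <- .parseCigar(sam$cigar[i])
      sum(cg$lens[cg$ops %in% c("M", "=", "X")])
    }, numeric(1)))
  covered <- draft@depth >= 1L
  q <- draft@quality[covered]
  new("MappingReport",
      mappedFraction = if (nReads) sum(mapped) / nReads else 0,
      meanFoldCoverage = alignedBases / refLen,
      fracQ40 = if (length(q)) mean(q >= 40L) else 0,
      fracQ30 = if (length(q)) mean(q >= 30L) else 0,
      nReads = as.integer(nReads), nMapped = as.integer(sum(mapped)))
}

#' Held-out read remapping validation
#'
#' Maps a held-out read set against an assembled sequence and reports the
#' fraction of reads that could be placed — the split-half validation of
#' an assembly's completeness.
#'
#' @param pairs a \code{ReadPairs} object.
#' @param target the assembled sequence (character, DNAString or
#'   \linkS4class{ReferenceGuidedDraft}).
#' @param ... passed to \code{\link{mapReads}}.
#' @return fraction of reads mapped (multi-mapping counts as mapped).
#' @export
remapValidation <- function(pairs, target, ...) {
  if (is(target, "ReferenceGuidedDraft")) target <- target@sequence
  sam <- mapReads(pairs, target, ...)
  mean(bitwAnd(sam$flag, 4L) == 0L)
}

#' Write a MappingReport as TSV
#' @param report a \linkS4class{MappingReport}.
#' @param path output file.
#' @export
writeMappingReport <- function(report, path) {
  df <- data.frame(
    metric = c("total_reads", "mapped_reads", "mapped_fraction",
               "mean_fold_coverage", "frac_q40", "frac_q30"),
    value = c(report@nReads, report@nMapped, report@mappedFraction,
              report@meanFoldCoverage, report@fracQ40, report@fracQ30))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
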