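# ---------------------------------------------------------------------------
# Synthetic scenario generator.  Emulates the differences between a
# sequenced strain and its close reference: multi-copy insertion-sequence
# (IS) repeats, an operon-scale deletion, isolated SNPs and 1-bp indels.
# Scaffold shredding can place breakpoints inside repeat copies (the
# dominant real cause of assembly fragmentation), and the read simulator
# produces 36-bp paired ends with a ~163 bp insert.  Every operation is
# seeded and records a truth table so recovery can be measured exactly.
# ---------------------------------------------------------------------------

.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Random DNA sequence
#' @param length sequence length in bases.
#' @param seed RNG seed (NULL uses the current RNG state).
#' @param gc GC content (default 0.5).
#' @return character sequence.
#' @export
randomGenome <- function(length, seed = NULL, gc = 0.5) {
  .withSeed(seed, paste0(
    sample(c("A", "C", "G", "T"), length, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
    collapse = ""))
}

#' Mutation specification for deriving a genome
#'
#' @param snpRate per-base substitution probability (at most 0.05).
#' @param indelRate per-base 1-bp indel probability (at most 0.05).
#' @param isElements list of repeat elements, each
#'   \code{list(sequence =, copies =)}; sequences are typically 1-1.5 kbp
#'   (use \code{\link{randomGenome}} to make one).
#' @param deletions list of fixed deletions, each
#'   \code{c(position, length)} in 0-based reference coordinates;
#'   must not overlap.
#' @param seed RNG seed used by \code{\link{deriveGenome}}.
#' @return validated list of class \code{MutationSpec}.
#' @export
mutationSpec <- function(snpRate = 0, indelRate = 0, isElements = list(),
                         deletions = list(), seed = NULL) {
  if (snpRate < 0 || snpRate > 0.05 || indelRate < 0 || indelRate > 0.05)
    stop("snpRate and indelRate must lie in [0, 0.05]")
  for (e in isElements) {
    if (!all(c("sequence", "copies") %in% names(e)))
      stop("each IS element needs fields 'sequence' and 'copies'")
    if (e$copies < 0) stop("IS copy numbers must be >= 0")
  }
  if (length(deletions) > 1L) {
    iv <- do.call(rbind, deletions)
    iv <- iv[order(iv[, 1L]), , drop = FALSE]
    if (any(iv[-nrow(iv), 1L] + iv[-nrow(iv), 2L] > iv[-1L, 1L]))
      stop("deletions must not overlap")
  }
  structure(list(snpRate = snpRate, indelRate = indelRate,
                 isElements = isElements, deletions = deletions,
                 seed = seed),
            class = "MutationSpec")
}

#' Derive a mutated genome from a reference
#'
#' Applies the specified deletions, then IS insertions and 1-bp indels,
#' then SNPs, sampling positions uniformly outside previously edited
#' intervals.  Returns the derived genome together with a
#' \linkS4class{TruthTable} whose edit list replays to the derived genome
#' byte-exactly (see \code{\link{applyEdits}}).
#'
#' @param reference reference sequence.
#' @param spec a \code{\link{mutationSpec}}.
#' @return list with \code{genome} (character) and \code{truth}
#'   (\linkS4class{TruthTable}).
#' @export
deriveGenome <- function(reference, spec = mutationSpec()) {
  ref <- .checkDNA(reference, "reference")
  L <- nchar(ref)
  .withSeed(spec$seed, {
    edits <- list()
    blocked <- logical(L)        # reference positions already edited

    for (d in spec$deletions) {
      pos <- as.integer(d[1L]); len <- as.integer(d[2L])
      if (pos < 0L || pos + len > L) stop("deletion outside the reference")
      edits[[length(edits) + 1L]] <- data.frame(
        type = "deletion", ref_pos = pos, length = len,
        payload = substr(ref, pos + 1L, pos + len))
      blocked[(pos + 1L):(pos + len)] <- TRUE
    }

    freePos <- function(n, margin = 1L) {
      ok <- which(!blocked)
      ok <- ok[ok > margin & ok <= L - margin]
      if (length(ok) < n) stop("not enough unedited positions left")
      sort(sample(ok, n)) - 1L   # 0-based
    }

    isSeqs <- character(0)
    for (e in spec$isElements) {
      isSeqs <- c(isSeqs, rep(toupper(e$sequence), e$copies))
    }
    if (length(isSeqs)) {
      at <- freePos(length(isSeqs), margin = 100L)
      for (i in seq_along(at)) {
        edits[[length(edits) + 1L]] <- data.frame(
          type = "insertion", ref_pos = at[i],
          length = nchar(isSeqs[i]), payload = isSeqs[i])
        blocked[at[i] + 1L] <- TRUE
      }
    }

    nIndel <- stats::rbinom(1L, L, spec$indelRate)
    if (nIndel > 0L) {
      at <- freePos(nIndel)
      kind <- sample(c("ins1", "del1"), nIndel, replace = TRUE)
      for (i in seq_along(at)) {
        if (kind[i] == "ins1") {
          edits[[length(edits) + 1L]] <- data.frame(
            type = "ins1", ref_pos = at[i], length = 1L,
            payload = sample(c("A", "C", "G", "T"), 1L))
        } else {
          edits[[length(edits) + 1L]] <- data.frame(
            type = "del1", ref_pos = at[i], length = 1L,
            payload = substr(ref, at[i] + 1L, at[i] + 1L))
        }
        blocked[at[i] + 1L] <- TRUE
      }
    }

    nSnp <- stats::rbinom(1L, L, spec$snpRate)
    if (nSnp > 0L) {
      at <- freePos(nSnp)
      oldB <- substring(ref, at + 1L, at + 1L)
      newB <- vapply(oldB, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), "",
        USE.NAMES = FALSE)
      for (i in seq_along(at)) {
        edits[[length(edits) + 1L]] <- data.frame(
          type = "snp", ref_pos = at[i], length = 1L, payload = newB[i])
        blocked[at[i] + 1L] <- TRUE
      }
    }

    ed <- if (length(edits)) do.call(rbind, edits) else
      data.frame(type = character(0), ref_pos = integer(0),
                 length = integer(0), payload = character(0))
    ed <- ed[order(ed$ref_pos, ed$type), ]
    rownames(ed) <- NULL

    # build the derived genome left-to-right, recording derived positions
    pieces <- character(0)
    cursor <- 0L               # next unconsumed reference position
    shift <- 0L                # derived - reference offset so far
    dpos <- integer(nrow(ed))
    for (i in seq_len(nrow(ed))) {
      p <- ed$ref_pos[i]
      if (p > cursor) pieces <- c(pieces, substr(ref, cursor + 1L, p))
      dpos[i] <- p + shift
      switch(ed$type[i],
        deletion = , del1 = {
          cursor <- p + ed$length[i]
          shift <- shift - ed$length[i]
        },
        insertion = , ins1 = {
          pieces <- c(pieces, ed$payload[i])
          cursor <- p
          shift <- shift + ed$length[i]
        },
        snp = {
          pieces <- c(pieces, ed$payload[i])
          cursor <- p + 1L
        })
    }
    if (cursor < L) pieces <- c(pieces, substr(ref, cursor + 1L, L))
    ed$derived_pos <- dpos
    derived <- paste0(pieces, collapse = "")

    truth <- new("TruthTable", edits = ed,
                 scaffoldOrigins = data.frame(),
                 readOrigins = data.frame())
    list(genome = derived, truth = truth)
  })
}

#' Replay a truth-table edit list against the reference
#'
#' Independent reconstruction of the derived genome: edits are applied in
#' descending reference-coordinate order by direct string surgery, using
#' only the \code{ref_pos} column.  Used as the oracle for
#' \code{\link{deriveGenome}}.
#'
#' @param reference the original reference sequence.
#' @param edits edit data.frame from a \linkS4class{TruthTable}.
#' @return the reconstructed derived genome (character).
#' @export
applyEdits <- function(reference, edits) {
  g <- .asSeq(reference)
  if (!nrow(edits)) return(g)
  ed <- edits[order(-edits$ref_pos), ]
  for (i in seq_len(nrow(ed))) {
    p <- ed$ref_pos[i]
    switch(ed$type[i],
      deletion = , del1 = {
        g <- paste0(substr(g, 1L, p), substr(g, p + ed$length[i] + 1L,
                                             nchar(g)))
      },
      insertion = , ins1 = {
        g <- paste0(substr(g, 1L, p), ed$payload[i],
                    substr(g, p + 1L, nchar(g)))
      },
      snp = {
        g <- paste0(substr(g, 1L, p), ed$payload[i],
                    substr(g, p + 2L, nchar(g)))
      })
  }
  g
}

#' Repeat-copy intervals of a derived genome
#'
#' Derived-genome intervals occupied by the inserted IS copies, from the
#' edit list (0-based half-open).
#'
#' @param truth a \linkS4class{TruthTable} from \code{\link{deriveGenome}}.
#' @return data.frame with \code{start}, \code{end}.
#' @export
repeatIntervals <- function(truth) {
  ed <- truth@edits
  ins <- ed[ed$type == "insertion", , drop = FALSE]
  data.frame(start = ins$derived_pos, end = ins$derived_pos + ins$length)
}

#' Shred a genome into scaffold-like pieces
#'
#' Cuts the genome at breakpoints — optionally one inside every repeat
#' copy, emulating assemblers terminating contigs at repeats — into
#' pieces that may share true overlaps or be separated by true gaps.
#' A fraction of pieces is reverse-complemented, and piece order is
#' shuffled as an assembler's output would be.
#'
#' @param genome sequence to shred.
#' @param nBreaks number of random breakpoints (in addition to repeat
#'   breakpoints).
#' @param atRepeats when TRUE, place one breakpoint inside each interval
#'   of \code{repeats}.
#' @param repeats data.frame of repeat intervals (e.g. from
#'   \code{\link{repeatIntervals}}).
#' @param overlapBp true overlap between consecutive pieces (scalar).
#' @param gapBp true gap between consecutive pieces; scalar or
#'   \code{c(min, max)} range sampled per junction.  Mutually exclusive
#'   with \code{overlapBp}.
#' @param revcompFraction fraction of pieces reverse-complemented.
#' @param minSpacing minimum distance between breakpoints (default 1500).
#' @param seed RNG seed.
#' @return list with \code{scaffolds} (named character, shuffled) and
#'   \code{origins} (data.frame: scaffold_id, start, end on the genome,
#'   orientation, order).
#' @export
shredToScaffolds <- function(genome, nBreaks = 10L, atRepeats = FALSE,
                             repeats = NULL, overlapBp = 0L, gapBp = 0L,
                             revcompFraction = 0, minSpacing = 1500L,
                             seed = NULL) {
  g <- .checkDNA(genome, "genome")
  L <- nchar(g)
  if (any(overlapBp > 0L) && any(gapBp > 0L))
    stop("overlapBp and gapBp are mutually exclusive")
  .withSeed(seed, {
    breaks <- integer(0)
    if (atRepeats && !is.null(repeats) && nrow(repeats)) {
      mid <- (repeats$start + repeats$end) %/% 2L
      span <- pmax(1L, (repeats$end - repeats$start) %/% 4L)
      breaks <- c(breaks, mid + vapply(span, function(s)
        sample(seq(-s, s), 1L), integer(1)))
    }
    if (nBreaks > 0L)
      breaks <- c(breaks, sample(seq(minSpacing, L - minSpacing), nBreaks))
    breaks <- sort(unique(pmin(pmax(breaks, minSpacing), L - minSpacing)))
    if (length(breaks) > 1L) {          # greedy thinning to the min spacing
      keep <- breaks[1L]
      for (b in breaks[-1L])
        if (b - keep[length(keep)] >= minSpacing) keep <- c(keep, b)
      breaks <- keep
    }
    cuts <- c(0L, breaks, L)
    n <- length(cuts) - 1L

    gapAt <- if (length(gapBp) == 2L)
      sample(seq(gapBp[1L], gapBp[2L]), n - 1L, replace = TRUE)
    else rep_len(as.integer(gapBp), max(0L, n - 1L))

    starts <- cuts[-length(cuts)]
    ends <- cuts[-1L]
    if (n > 1L) {
      ends[-n] <- pmin(L, ends[-n] + as.integer(overlapBp))
      starts[-1L] <- starts[-1L] + gapAt
    }
    ori <- rep("forward", n)
    nRev <- round(revcompFraction * n)
    if (nRev > 0L) ori[sample(n, nRev)] <- "reverse"

    pieces <- substring(g, starts + 1L, ends)
    pieces[ori == "reverse"] <- vapply(pieces[ori == "reverse"],
                                       .revcomp, "", USE.NAMES = FALSE)
    ids <- sprintf("scaffold_%03d", seq_len(n))
    origins <- data.frame(scaffold_id = ids, start = starts, end = ends,
                          orientation = ori, order = seq_len(n) - 1L)
    shuffle <- sample(n)
    list(scaffolds = stats::setNames(pieces[shuffle], ids[shuffle]),
         origins = origins)
  })
}

#' Simulate paired-end short reads
#'
#' Samples \code{ceiling(foldCoverage * L / (2 * readLen))} fragments
#' with insert sizes from a truncated normal (minimum \code{readLen}),
#' reads the first \code{readLen} bases forward and the last
#' \code{readLen} bases reverse-complemented, and applies independent
#' per-base substitution errors.  Base qualities are a constant Phred 35.
#'
#' @param genome template sequence.
#' @param readLen read length (default 36).
#' @param insertMean,insertSd insert size distribution (defaults 163, 15).
#' @param foldCoverage target fold coverage.
#' @param errorRate per-base substitution error probability.
#' @param seed RNG seed.
#' @param baseQual constant Phred quality written for every base.
#' @return list with \code{pairs} (a \code{ReadPairs}) and \code{origins}
#'   (data.frame: id, fragment start, insert size; 0-based).
#' @export
simulateReads <- function(genome, readLen = 36L, insertMean = 163,
                          insertSd = 15, foldCoverage = 30,
                          errorRate = 0, seed = NULL, baseQual = 35L) {
  g <- .checkDNA(genome, "genome")
  L <- nchar(g)
  if (insertMean > L) stop("insert size exceeds the genome length")
  nPairs <- as.integer(ceiling(foldCoverage * L / (2 * readLen)))
  .withSeed(seed, {
    # truncated normal via resampling
    ins <- as.integer(round(stats::rnorm(nPairs, insertMean, insertSd)))
    bad <- which(ins < readLen | ins > L)
    while (length(bad)) {
      ins[bad] <- as.integer(round(stats::rnorm(length(bad), insertMean,
                                                insertSd)))
      bad <- bad[ins[bad] < readLen | ins[bad] > L]
    }
    start <- vapply(L - ins, function(m) sample.int(m + 1L, 1L) - 1L,
                    integer(1))
    r1 <- .substrVec(g, start, readLen)
    r2tpl <- .substrVec(g, start + ins - readLen, readLen)
    r2 <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(r2tpl)))

    addErrors <- function(reads) {
      cat1 <- paste0(reads, collapse = "")
      nb <- nchar(cat1)
      nerr <- stats::rbinom(1L, nb, errorRate)
      if (nerr == 0L) return(reads)
      at <- sample.int(nb, nerr)
      chars <- rawToChar(charToRaw(cat1), multiple = FALSE)
      v <- strsplit(chars, "")[[1]]
      v[at] <- vapply(v[at], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), "",
        USE.NAMES = FALSE)
      cat2 <- paste0(v, collapse = "")
      w <- nchar(reads)
      offs <- cumsum(c(0L, w[-length(w)]))
      .substrVec(cat2, offs, w)
    }
    if (errorRate > 0) {
      r1 <- addErrors(r1)
      r2 <- addErrors(r2)
    }
    ids <- sprintf("read_%07d", seq_len(nPairs))
    qual <- strrep(rawToChar(as.raw(33L + baseQual)), readLen)
    pairs <- newReadPairs(ids, r1, r2, rep(qual, nPairs),
                          rep(qual, nPairs))
    list(pairs = pairs,
         origins = data.frame(id = ids, start = start, insert = ins))
  })
}

#' Natto-like synthetic scenario preset
#'
#' One call that emulates the genome-difference structure between a
#' sequenced strain and its close reference at desk scale: a random
#' reference, a derived genome carrying two multi-copy IS elements
#' (5 + 6 copies, 1.2/1.3 kbp), one operon-scale deletion and scattered
#' SNPs/1-bp indels, scaffolds broken at the repeat copies, and 36-bp
#' paired-end reads.
#'
#' @param refLen reference length (default 200000).
#' @param deletionLen operon-scale deletion length (default 20000).
#' @param snpRate SNP rate (default 0.002).
#' @param indelRate 1-bp indel rate (default 1e-4).
#' @param foldCoverage read coverage of the derived genome (default 30).
#' @param errorRate sequencing error rate (default 0.01).
#' @param seed RNG seed (required for reproducibility).
#' @return list with \code{reference}, \code{derived}, \code{truth},
#'   \code{scaffolds}, \code{origins}, \code{pairs}, \code{readOrigins}.
#' @export
nattoLikePreset <- function(refLen = 200000L, deletionLen = 20000L,
                            snpRate = 0.002, indelRate = 1e-4,
                            foldCoverage = 30, errorRate = 0.01,
                            seed = 1L) {
  .withSeed(seed, {
    subSeeds <- sample.int(.Machine$integer.max, 5L)
    ref <- randomGenome(refLen, subSeeds[1L])
    isA <- randomGenome(1200L, subSeeds[2L])
    isB <- randomGenome(1300L, subSeeds[3L])
    delPos <- as.integer(refLen * 0.6)
    spec <- mutationSpec(
      snpRate = snpRate, indelRate = indelRate,
      isElements = list(list(sequence = isA, copies = 5L),
                        list(sequence = isB, copies = 6L)),
      deletions = list(c(delPos, deletionLen)),
      seed = subSeeds[4L])
    dg <- deriveGenome(ref, spec)
    shred <- shredToScaffolds(dg$genome, nBreaks = 15L, atRepeats = TRUE,
                              repeats = repeatIntervals(dg$truth),
                              revcompFraction = 0.3, seed = subSeeds[5L])
    sim <- simulateReads(dg$genome, foldCoverage = foldCoverage,
                         errorRate = errorRate, seed = subSeeds[5L] + 1L)
    list(reference = ref, derived = dg$genome, truth = dg$truth,
         scaffolds = shred$scaffolds, origins = shred$origins,
         pairs = sim$pairs, readOrigins = sim$origins)
  })
}
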