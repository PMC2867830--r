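# ---------------------------------------------------------------------------
# Junction closing.  Adjacent placed scaffolds are joined by (i) merging a
# suffix-prefix overlap, else (ii) splicing the fully-confident
# reference-guided draft interval that lies between their ends, else
# (iii) an open gap emitted as an N-run sized by the projected reference
# distance.  The census overlap_merged + draft_filled + open always equals
# placed - 1.
# ---------------------------------------------------------------------------

#' Merge two adjacent sequences by their suffix-prefix overlap
#'
#' Finds the longest overlap of at least \code{minOverlap} bases between
#' the end of \code{left} and the start of \code{right} whose mismatch
#' rate does not exceed \code{maxMismatchRate}.  Within the overlap, an
#' \code{N} yields to the other sequence's base; remaining mismatches are
#' resolved in favour of \code{left} (deterministic).
#'
#' @param left,right DNA sequences, already oriented per the layout.
#' @param minOverlap minimum overlap length (default 30).
#' @param maxMismatchRate maximum mismatch fraction within the overlap
#'   (default 0.02).
#' @return \code{NULL} when no acceptable overlap exists, else a list with
#'   \code{sequence} (the merged sequence), \code{overlap},
#'   \code{mismatches} and \code{overlapSeq} (the resolved overlap).
#' @examples
#' resolveOverlap(paste0(strrep("A", 40), strrep("G", 30)),
#'                paste0(strrep("G", 30), strrep("C", 40)))
#' @export
resolveOverlap <- function(left, right, minOverlap = 30L,
                           maxMismatchRate = 0.02) {
  left <- .asSeq(left); right <- .asSeq(right)
  nl <- nchar(left); nr <- nchar(right)
  top <- min(nl, nr)
  if (top < minOverlap) return(NULL)
  for (ov in top:minOverlap) {
    a <- substr(left, nl - ov + 1L, nl)
    b <- substr(right, 1L, ov)
    ra <- charToRaw(a); rb <- charToRaw(b)
    mism <- sum(ra != rb)
    if (mism <= floor(maxMismatchRate * ov)) {
      # resolve: N yields, otherwise left wins
      res <- ra
      aN <- ra == charToRaw("N")
      res[aN] <- rb[aN]
      overlapSeq <- rawToChar(res)
      merged <- paste0(substr(left, 1L, nl - ov), overlapSeq,
                       substr(right, ov + 1L, nr))
      return(list(sequence = merged, overlap = ov,
                  mismatches = as.integer(mism), overlapSeq = overlapSeq))
    }
  }
  NULL
}

# Locate one scaffold end on the draft.  Returns the projected draft
# coordinate of the scaffold terminus, or NA when the end does not locate
# uniquely on the forward strand.
.locateEndOnDraft <- function(endSeq, index, side, minLen, minIdentity) {
  anc <- findAnchors(endSeq, index, minLen = minLen,
                     minIdentity = minIdentity, id = "end")
  if (!nrow(anc)) return(NA_integer_)
  fwd <- anc[anc$strand == "forward", , drop = FALSE]
  if (!nrow(fwd)) return(NA_integer_)
  best <- bestAnchor(fwd)
  # uniqueness: every comparable anchor (>= 80% of the best length) must
  # agree with the best diagonal to within 2 kbp, and no reverse-strand
  # anchor may be comparable
  dBest <- best$r_start - best$q_start
  comp <- anc[anc$length >= 0.8 * best$length, , drop = FALSE]
  if (any(comp$strand == "reverse")) return(NA_integer_)
  if (any(abs((comp$r_start - comp$q_start) - dBest) > 2000L))
    return(NA_integer_)
  n <- nchar(endSeq)
  if (side == "left") best$r_end + (n - best$q_end)   # draft pos of terminus
  else best$r_start - best$q_start
}

#' Fill the gap between two scaffolds from the reference-guided draft
#'
#' Anchors the terminal \code{endLen} bases of the left and right
#' scaffolds onto the draft; when both ends locate uniquely, in order, and
#' every draft position between them is confident, the intervening draft
#' subsequence is returned as the insert.
#'
#' @param left,right oriented scaffold sequences flanking the junction.
#' @param draft a \linkS4class{ReferenceGuidedDraft}.
#' @param index optional prebuilt \code{\link{seedIndex}} of the draft
#'   sequence (built on the fly otherwise).
#' @param minLen,minIdentity anchor thresholds.
#' @param endLen how much of each scaffold end to anchor (default 1000).
#' @return \code{NULL}, or a list with \code{insert} (the draft
#'   subsequence, possibly empty), \code{start}, \code{end} (0-based
#'   half-open draft interval).
#' @export
fillFromDraft <- function(left, right, draft, index = NULL,
                          minLen = 40L, minIdentity = 0.9, endLen = 1000L) {
  stopifnot(is(draft, "ReferenceGuidedDraft"))
  left <- .asSeq(left); right <- .asSeq(right)
  if (is.null(index))
    index <- seedIndex(as.character(draft@sequence))
  nl <- nchar(left)
  lEnd <- substr(left, max(1L, nl - endLen + 1L), nl)
  rEnd <- substr(right, 1L, min(endLen, nchar(right)))
  a <- .locateEndOnDraft(lEnd, index, "left", minLen, minIdentity)
  b <- .locateEndOnDraft(rEnd, index, "right", minLen, minIdentity)
  if (is.na(a) || is.na(b)) return(NULL)
  if (a > b) {
    warning("scaffold ends anchor out of order on the draft ",
            "(possible rearrangement); junction left open")
    return(NULL)
  }
  if (a == b) return(list(insert = "", start = a, end = b))
  if (!all(draft@confidentMask[(a + 1L):b])) return(NULL)
  list(insert = as.character(Biostrings::subseq(draft@sequence, a + 1L, b)),
       start = a, end = b)
}

#' Close the junctions of a layout into a finished sequence
#'
#' Walks adjacent placed scaffolds in rank order.  Each junction is
#' resolved by \code{\link{resolveOverlap}} first, then by
#' \code{\link{fillFromDraft}} (when a draft is supplied), and otherwise
#' left open as an N-run whose length is the projected reference distance
#' between the flanking scaffolds, floored at \code{minGapN}.
#'
#' @param layout a \linkS4class{Layout}.
#' @param scaffolds the scaffold sequences (named character vector or
#'   DNAStringSet) the layout was built from.
#' @param draft optional \linkS4class{ReferenceGuidedDraft} built against
#'   the same reference as the layout.
#' @param minOverlap,maxMismatchRate overlap-merge parameters.
#' @param minGapN minimum emitted N-run length (default 100).
#' @param minLen,minIdentity anchor thresholds for draft filling.
#' @param objectName AGP object name.
#' @return a \linkS4class{FinalAssembly}.
#' @export
closeLayout <- function(layout, scaffolds, draft = NULL,
                        minOverlap = 30L, maxMismatchRate = 0.02,
                        minGapN = 100L, minLen = 40L, minIdentity = 0.9,
                        objectName = "assembly") {
  if (is(scaffolds, "XStringSet"))
    scaffolds <- stats::setNames(as.character(scaffolds), names(scaffolds))
  pl <- layout@placements
  if (!nrow(pl)) stop("layout has no placed scaffolds")
  if (!is.null(draft)) {
    stopifnot(is(draft, "ReferenceGuidedDraft"))
    if (!identical(draft@referenceId, layout@referenceId))
      stop("draft was built against reference '", draft@referenceId,
           "' but the layout is along '", layout@referenceId, "'")
  }
  missing <- setdiff(pl$scaffold_id, names(scaffolds))
  if (length(missing))
    stop("scaffold sequences missing for: ", paste(missing, collapse = ", "))

  oriented <- lapply(seq_len(nrow(pl)), function(i) {
    s <- toupper(scaffolds[[pl$scaffold_id[i]]])
    if (pl$orientation[i] == "reverse") .revcomp(s) else s
  })
  names(oriented) <- pl$scaffold_id

  dIndex <- if (!is.null(draft))
    seedIndex(as.character(draft@sequence)) else NULL

  n <- nrow(pl)
  outOfOrder <- character(0)
  pieces <- character(0)     # sequence pieces in order
  # AGP components in oriented-frame coords: list(type, id, beg0, end0, ori)
  comps <- list()
  junc <- list()
  gaps <- list()
  consumed <- 0L             # prefix of the current scaffold consumed by merge

  addComp <- function(type, id, beg0, end0, ori) {
    comps[[length(comps) + 1L]] <<- list(type = type, id = id, beg0 = beg0,
                                         end0 = end0, ori = ori)
  }
  addComp("W", pl$scaffold_id[1L], 0L, pl$length[1L], pl$orientation[1L])
  pieces <- oriented[[1L]]

  for (i in seq_len(n - 1L)) {
    leftSeq <- oriented[[i]]
    rightSeq <- oriented[[i + 1L]]
    est <- pl$ref_start_proj[i + 1L] - pl$ref_end_proj[i]
    ro <- resolveOverlap(leftSeq, rightSeq, minOverlap, maxMismatchRate)
    remaining <- nchar(leftSeq) - consumed
    if (!is.null(ro) && ro$overlap > remaining) ro <- NULL  # over-consumed
    if (!is.null(ro)) {
      ov <- ro$overlap
      cur <- pieces[length(pieces)]
      pieces[length(pieces)] <- paste0(
        substr(cur, 1L, nchar(cur) - ov), ro$overlapSeq)
      pieces <- c(pieces, substr(rightSeq, ov + 1L, nchar(rightSeq)))
      addComp("W", pl$scaffold_id[i + 1L], ov, pl$length[i + 1L],
              pl$orientation[i + 1L])
      junc[[i]] <- data.frame(left_id = pl$scaffold_id[i],
                              right_id = pl$scaffold_id[i + 1L],
                              status = "overlap_merged", overlap = ov,
                              insert_start = NA_integer_,
                              insert_end = NA_integer_,
                              gap_est = NA_integer_)
      consumed <- ov
      next
    }
    fd <- if (!is.null(draft)) {
      # out-of-order end projections are routine at junctions spanning a
      # novel insertion (e.g. an IS copy absent from the reference);
      # collect them instead of warning per junction
      withCallingHandlers(
        fillFromDraft(leftSeq, rightSeq, draft, index = dIndex,
                      minLen = minLen, minIdentity = minIdentity),
        warning = function(w) {
          if (grepl("out of order", conditionMessage(w))) {
            outOfOrder <<- c(outOfOrder, pl$scaffold_id[i])
            invokeRestart("muffleWarning")
          }
        })
    } else NULL
    if (!is.null(fd)) {
      if (nchar(fd$insert))
        addComp("W", sprintf("%s_draft_%d_%d", layout@referenceId,
                             fd$start, fd$end),
                0L, nchar(fd$insert), "forward")
      pieces <- c(pieces, fd$insert, rightSeq)
      addComp("W", pl$scaffold_id[i + 1L], 0L, pl$length[i + 1L],
              pl$orientation[i + 1L])
      junc[[i]] <- data.frame(left_id = pl$scaffold_id[i],
                              right_id = pl$scaffold_id[i + 1L],
                              status = "draft_filled", overlap = NA_integer_,
                              insert_start = fd$start, insert_end = fd$end,
                              gap_est = NA_integer_)
      consumed <- 0L
      next
    }
    gapLen <- max(minGapN, est)
    pieces <- c(pieces, strrep("N", gapLen), rightSeq)
    addComp("N", as.character(gapLen), 0L, gapLen, NA_character_)
    addComp("W", pl$scaffold_id[i + 1L], 0L, pl$length[i + 1L],
            pl$orientation[i + 1L])
    junc[[i]] <- data.frame(left_id = pl$scaffold_id[i],
                            right_id = pl$scaffold_id[i + 1L],
                            status = "open", overlap = NA_integer_,
                            insert_start = NA_integer_,
                            insert_end = NA_integer_, gap_est = gapLen)
    consumed <- 0L
  }

  if (length(outOfOrder))
    message(length(outOfOrder), " junction(s) left open because scaffold ",
            "ends project out of order on the draft (novel insertion or ",
            "rearrangement): after ",
            paste(unique(outOfOrder), collapse = ", "))
  sequence <- paste0(pieces, collapse = "")
  junctions <- if (length(junc)) do.call(rbind, junc) else
    data.frame(left_id = character(0), right_id = character(0),
               status = character(0), overlap = integer(0),
               insert_start = integer(0), insert_end = integer(0),
               gap_est = integer(0))

  # AGP rows (1-based; reverse components reported in original scaffold
  # coordinates) and gap records from component walk
  agp <- list(); gapRows <- list()
  pos <- 0L
  for (k in seq_along(comps)) {
    cm <- comps[[k]]
    w <- cm$end0 - cm$beg0
    if (cm$type == "N") {
      gapRows[[length(gapRows) + 1L]] <- data.frame(
        start = pos, end = pos + w, estimated_size = w,
        left_id = if (k > 1L) comps[[k - 1L]]$id else NA_character_,
        right_id = if (k < length(comps)) comps[[k + 1L]]$id
                   else NA_character_)
      agp[[k]] <- data.frame(object = objectName, object_beg = pos + 1L,
                             object_end = pos + w, part_number = k,
                             component_type = "N", component_id = w,
                             component_beg = "scaffold",
                             component_end = "yes",
                             orientation = "align_genus")
    } else {
      fullLen <- if (cm$id %in% names(scaffolds))
        nchar(scaffolds[[cm$id]]) else w
      if (identical(cm$ori, "reverse")) {
        cb <- fullLen - cm$end0 + 1L; ce <- fullLen - cm$beg0
        ori <- "-"
      } else {
        cb <- cm$beg0 + 1L; ce <- cm$end0
        ori <- "+"
      }
      agp[[k]] <- data.frame(object = objectName, object_beg = pos + 1L,
                             object_end = pos + w, part_number = k,
                             component_type = "W", component_id = cm$id,
                             component_beg = as.character(cb),
                             component_end = as.character(ce),
                             orientation = ori)
    }
    pos <- pos + w
  }
  gapsDf <- if (length(gapRows)) do.call(rbind, gapRows) else
    data.frame(start = integer(0), end = integer(0),
               estimated_size = integer(0), left_id = character(0),
               right_id = character(0))
  new("FinalAssembly",
      sequence = Biostrings::DNAString(sequence),
      gaps = gapsDf, junctions = junctions,
      agp = do.call(rbind, agp))
}

#' Screen small scaffolds for containment in the final sequence
#'
#' A scaffold is contained when it (or its reverse complement) aligns
#' end-to-end inside the final sequence with a mismatch rate not
#' exceeding \code{maxMismatchRate}.  Candidate placements are generated
#' from exact 16-mer seeds taken along the scaffold and verified by
#' direct comparison.
#'
#' @param smalls named character vector or DNAStringSet of (typically
#'   short) scaffolds.
#' @param final a \linkS4class{FinalAssembly} or a plain sequence.
#' @param maxMismatchRate maximum mismatch fraction (default 0.02).
#' @param nSeeds number of seeds per scaffold (default 8).
#' @return character vector of contained scaffold ids.
#' @export
screenContained <- function(smalls, final, maxMismatchRate = 0.02,
                            nSeeds = 8L) {
  if (is(final, "FinalAssembly")) final <- as.character(final@sequence)
  final <- .asSeq(final)
  if (is(smalls, "XStringSet"))
    smalls <- stats::setNames(as.character(smalls), names(smalls))
  subject <- Biostrings::DNAString(final)
  k <- 16L
  contained <- character(0)
  for (id in names(smalls)) {
    s <- toupper(smalls[[id]])
    len <- nchar(s)
    if (len < k) next
    hit <- FALSE
    for (cand in c(s, .revcomp(s))) {
      offs <- unique(pmin(len - k,
                          floor(seq(0L, len - k, length.out = nSeeds))))
      starts <- integer(0)
      for (o in offs) {
        seed <- substr(cand, o + 1L, o + k)
        if (grepl("N", seed, fixed = TRUE)) next
        m <- Biostrings::matchPattern(seed, subject)
        if (length(m))
          starts <- c(starts, BiocGenerics::start(m) - 1L - o)
      }
      starts <- unique(starts)
      starts <- starts[starts >= 0L & starts + len <= nchar(final)]
      if (length(starts)) {
        mism <- .stringMismatchCounts(.substrVec(final, starts, len),
                                      rep(cand, length(starts)))
        if (any(mism <= floor(maxMismatchRate * len))) { hit <- TRUE; break }
      }
    }
    if (hit) contained <- c(contained, id)
  }
  contained
}

#' Suggest unplaced scaffolds for open gaps
#'
#' For every open gap, tests whether an end of an unplaced scaffold
#' overlaps a gap flank (by \code{\link{resolveOverlap}}).  Suggestions
#' are report-only and never mutate the assembly.
#'
#' @param unplaced named character vector or DNAStringSet of unplaced
#'   scaffolds.
#' @param final a \linkS4class{FinalAssembly} with open gaps.
#' @param minOverlap,maxMismatchRate overlap parameters.
#' @param flankLen flank length examined on each side of a gap
#'   (default 500).
#' @return list with \code{suggestions} (data.frame: gap index, scaffold
#'   id, orientation, side, overlap length) and \code{unmatched}
#'   (scaffold ids with no suggestion, e.g. plasmid-like sequences).
#' @export
placeUnplacedIntoGaps <- function(unplaced, final, minOverlap = 30L,
                                  maxMismatchRate = 0.02, flankLen = 500L) {
  if (is(unplaced, "XStringSet"))
    unplaced <- stats::setNames(as.character(unplaced), names(unplaced))
  seqc <- as.character(final@sequence)
  gaps <- final@gaps
  sugg <- list()
  for (g in seq_len(nrow(gaps))) {
    lFlank <- substr(seqc, max(1L, gaps$start[g] - flankLen + 1L),
                     gaps$start[g])
    rFlank <- substr(seqc, gaps$end[g] + 1L,
                     min(nchar(seqc), gaps$end[g] + flankLen))
    for (id in names(unplaced)) {
      for (ori in c("forward", "reverse")) {
        s <- if (ori == "reverse") .revcomp(unplaced[[id]])
             else toupper(unplaced[[id]])
        roL <- resolveOverlap(lFlank, s, minOverlap, maxMismatchRate)
        roR <- resolveOverlap(s, rFlank, minOverlap, maxMismatchRate)
        if (!is.null(roL))
          sugg[[length(sugg) + 1L]] <- data.frame(
            gap = g, scaffold_id = id, orientation = ori,
            side = "left_flank", overlap = roL$overlap)
        if (!is.null(roR))
          sugg[[length(sugg) + 1L]] <- data.frame(
            gap = g, scaffold_id = id, orientation = ori,
            side = "right_flank", overlap = roR$overlap)
      }
    }
  }
  suggestions <- if (length(sugg)) do.call(rbind, sugg) else
    data.frame(gap = integer(0), scaffold_id = character(0),
               orientation = character(0), side = character(0),
               overlap = integer(0))
  list(suggestions = suggestions,
       unmatched = setdiff(names(unplaced), suggestions$scaffold_id))
}

#' Primer-flank sequences around open gaps
#'
#' Extracts the \code{flankLen} bases on each side of every open gap so
#' that primers spanning the gap can be designed externally.
#'
#' @param final a \linkS4class{FinalAssembly}.
#' @param flankLen flank length (default 500).
#' @return named character vector of flank sequences.
#' @export
gapFlanks <- function(final, flankLen = 500L) {
  seqc <- as.character(final@sequence)
  gaps <- final@gaps
  out <- character(0)
  for (g in seq_len(nrow(gaps))) {
    out[sprintf("gap%d_left", g)] <-
      substr(seqc, max(1L, gaps$start[g] - flankLen + 1L), gaps$start[g])
    out[sprintf("gap%d_right", g)] <-
      substr(seqc, gaps$end[g] + 1L,
             min(nchar(seqc), gaps$end[g] + flankLen))
  }
  out
}
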