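# ---------------------------------------------------------------------------
# Ordering and orienting de novo scaffolds along a reference genome.  A
# scaffold is placed at the location of its longest anchor (ties broken
# deterministically); scaffolds with no anchor stay unplaced, scaffolds at
# or below the length cutoff are set aside before anchoring.
# ---------------------------------------------------------------------------

#' Length-filter scaffolds
#'
#' Keeps scaffolds strictly longer than \code{minLen} (the conventional
#' "greater than 1 kbp" rule), returning both partitions.
#'
#' @param scaffolds named character vector or DNAStringSet.
#' @param minLen length cutoff in bases (default 1000).
#' @return list with \code{kept} and \code{belowMin} named character
#'   vectors.
#' @export
filterByLength <- function(scaffolds, minLen = 1000L) {
  if (is(scaffolds, "XStringSet"))
    scaffolds <- stats::setNames(as.character(scaffolds), names(scaffolds))
  keep <- nchar(scaffolds) > minLen
  list(kept = scaffolds[keep], belowMin = scaffolds[!keep])
}

#' Place scaffolds along a reference by their anchors
#'
#' Finds anchors for every scaffold, places each scaffold at its
#' representative (longest) anchor with the anchor's strand as the
#' scaffold orientation, and orders placements by anchor location on the
#' reference.  Scaffolds whose secondary anchors disagree with the
#' representative one (opposite strand, or a locus farther away than the
#' scaffold length) are flagged as misassembly candidates via a warning
#' and the \code{conflict} column.
#'
#' @param scaffolds named character vector or DNAStringSet; ids must be
#'   unique.  Pre-filter with \code{\link{filterByLength}}.
#' @param reference reference sequence or a \code{\link{seedIndex}}.
#' @param pattern a \linkS4class{SeedPattern}.
#' @param minLen,minIdentity anchor thresholds (see
#'   \code{\link{findAnchors}}).
#' @param belowMin ids already removed by the length filter (recorded in
#'   the layout so the id sets partition the input).
#' @param referenceId reference name recorded in the layout.
#' @return a \linkS4class{Layout}.  Placement coordinates: the best
#'   anchor in the oriented-scaffold frame (\code{q_start}, \code{q_end}),
#'   its reference interval, the projected reference interval of the whole
#'   scaffold, \code{ref_position} (anchor \code{r_start}) and 0-based
#'   \code{rank}.
#' @export
placeScaffolds <- function(scaffolds, reference, pattern = seedPattern(),
                           minLen = 40L, minIdentity = 0.9,
                           belowMin = character(0), referenceId = "ref") {
  if (is(scaffolds, "XStringSet"))
    scaffolds <- stats::setNames(as.character(scaffolds), names(scaffolds))
  if (is.null(names(scaffolds)) || any(!nzchar(names(scaffolds))))
    stop("scaffolds must be named")
  if (anyDuplicated(names(scaffolds)))
    stop("duplicate scaffold ids: ",
         paste(unique(names(scaffolds)[duplicated(names(scaffolds))]),
               collapse = ", "))
  if (!inherits(reference, "SeedIndex"))
    reference <- seedIndex(reference, pattern)

  rows <- list()
  unplaced <- character(0)
  conflicts <- character(0)
  for (id in names(scaffolds)) {
    seq <- toupper(scaffolds[[id]])
    anc <- findAnchors(seq, reference, minLen = minLen,
                       minIdentity = minIdentity, id = id)
    if (!nrow(anc)) { unplaced <- c(unplaced, id); next }
    best <- bestAnchor(anc)
    len <- nchar(seq)
    # secondary-anchor disagreement: opposite strand, or same strand at a
    # locus whose diagonal is off by more than the scaffold length
    bi <- which(anc$q_start == best$q_start & anc$r_start == best$r_start &
                  anc$strand == best$strand)[1L]
    othr <- anc[-bi, , drop = FALSE]
    conflict <- FALSE
    if (nrow(othr)) {
      dBest <- best$r_start - best$q_start
      dOth <- othr$r_start - othr$q_start
      conflict <- any(othr$strand != best$strand) ||
        any(abs(dOth[othr$strand == best$strand] - dBest) > len)
    }
    if (conflict) conflicts <- c(conflicts, id)
    # anchor coordinates in the oriented-scaffold frame
    if (best$strand == "reverse") {
      qs <- len - best$q_end; qe <- len - best$q_start
    } else {
      qs <- best$q_start; qe <- best$q_end
    }
    rows[[id]] <- data.frame(
      scaffold_id = id,
      orientation = if (best$strand == "reverse") "reverse" else "forward",
      length = len,
      q_start = qs, q_end = qe,
      r_start = best$r_start, r_end = best$r_end,
      anchor_len = best$length, identity = best$identity,
      ref_position = best$r_start,
      ref_start_proj = best$r_start - qs,
      ref_end_proj = best$r_end + (len - qe),
      conflict = conflict)
  }
  if (length(conflicts))
    warning("scaffolds with disagreeing secondary anchors ",
            "(misassembly candidates): ", paste(conflicts, collapse = ", "))

  pl <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scaffold_id = character(0), orientation = character(0),
               length = integer(0), q_start = integer(0), q_end = integer(0),
               r_start = integer(0), r_end = integer(0),
               anchor_len = integer(0), identity = numeric(0),
               ref_position = integer(0), ref_start_proj = integer(0),
               ref_end_proj = integer(0), conflict = logical(0))
  if (nrow(pl)) {
    pl <- pl[order(pl$ref_position, pl$scaffold_id), ]
    pl$rank <- seq_len(nrow(pl)) - 1L
    rownames(pl) <- NULL
  } else {
    pl$rank <- integer(0)
  }
  new("Layout", referenceId = referenceId, placements = pl,
      unplaced = unplaced, belowMin = as.character(belowMin),
      scaffoldLengths = stats::setNames(nchar(scaffolds), names(scaffolds)))
}

#' AGP 2.1 rows for an (unclosed) layout
#'
#' One W row per placed scaffold in rank order, separated by N gap rows
#' whose length is the projected reference distance between consecutive
#' scaffolds, floored at \code{minGapN}.
#'
#' @param layout a \linkS4class{Layout}.
#' @param objectName name of the assembled object (column 1).
#' @param minGapN minimum emitted gap length.
#' @return data.frame of AGP rows.
#' @export
layoutToAGP <- function(layout, objectName = "layout", minGapN = 100L) {
  pl <- layout@placements
  rows <- list()
  pos <- 0L; part <- 0L
  for (i in seq_len(nrow(pl))) {
    if (i > 1L) {
      est <- max(minGapN, pl$ref_start_proj[i] - pl$ref_end_proj[i - 1L])
      part <- part + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        object = objectName, object_beg = pos + 1L, object_end = pos + est,
        part_number = part, component_type = "N", component_id = est,
        component_beg = "scaffold", component_end = "yes",
        orientation = "align_genus")
      pos <- pos + est
    }
    part <- part + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      object = objectName, object_beg = pos + 1L,
      object_end = pos + pl$length[i], part_number = part,
      component_type = "W", component_id = pl$scaffold_id[i],
      component_beg = "1", component_end = as.character(pl$length[i]),
      orientation = if (pl$orientation[i] == "reverse") "-" else "+")
    pos <- pos + pl$length[i]
  }
  if (!length(rows)) {
    return(data.frame(object = character(0), object_beg = integer(0),
                      object_end = integer(0), part_number = integer(0),
                      component_type = character(0),
                      component_id = character(0),
                      component_beg = character(0),
                      component_end = character(0),
                      orientation = character(0)))
  }
  do.call(rbind, rows)
}

#' Write the unplaced-scaffold id list as TSV
#' @param layout a \linkS4class{Layout}.
#' @param path output file.
#' @export
writeUnplacedTSV <- function(layout, path) {
  df <- data.frame(
    scaffold_id = c(layout@unplaced, layout@belowMin),
    reason = c(rep("no_anchor", length(layout@unplaced)),
               rep("below_min_length", length(layout@belowMin))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
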