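#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
NULL

#' Spaced seed pattern
#'
#' A spaced seed is a string over \code{"1"} (position must match) and
#' \code{"0"} (free position) used to hash well-conserved subsequences.  The
#' \emph{weight} is the number of match positions.  The default seed used
#' throughout the package is the contiguous weight-16 seed, which anchors
#' scaffolds from a strain diverging by a fraction of a percent reliably.
#'
#' @slot mask character(1), string of \code{"1"}/\code{"0"}; must begin and
#'   end with \code{"1"}.
#' @slot weight integer(1), number of \code{"1"} positions; at least 8.
#' @export
setClass("SeedPattern",
  representation(mask = "character", weight = "integer"),
  validity = function(object) {
    msg <- character(0)
    chars <- strsplit(object@mask, "", fixed = TRUE)[[1]]
    if (!all(chars %in% c("0", "1")))
      msg <- c(msg, "mask may contain only '0' and '1'")
    if (length(chars) == 0L || chars[1] != "1" || chars[length(chars)] != "1")
      msg <- c(msg, "mask must begin and end with a match position ('1')")
    w <- sum(chars == "1")
    if (object@weight != w)
      msg <- c(msg, "weight must equal the number of '1' positions")
    if (w < 8L) msg <- c(msg, "seed weight must be at least 8")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a SeedPattern
#'
#' @param mask a string of \code{"1"} (must match) and \code{"0"} (free),
#'   e.g. \code{"1110111"}.  Defaults to the contiguous weight-16 seed.
#' @return a \linkS4class{SeedPattern}
#' @examples
#' seedPattern()                 # contiguous weight-16
#' seedPattern("111010010100110111")
#' @export
seedPattern <- function(mask = strrep("1", 16L)) {
  new("SeedPattern", mask = as.character(mask),
      weight = sum(strsplit(as.character(mask), "", fixed = TRUE)[[1]] == "1"))
}

setMethod("show", "SeedPattern", function(object) {
  cat("SeedPattern: ", object@mask, " (weight ", object@weight,
      ", span ", nchar(object@mask), ")\n", sep = "")
})

#' @describeIn seedPattern seed weight (number of match positions)
#' @param x a \linkS4class{SeedPattern}
#' @export
seedWeight <- function(x) x@weight

#' @describeIn seedPattern seed span (total mask length)
#' @export
seedSpan <- function(x) nchar(x@mask)

#' Reference-guided draft
#'
#' Per-base consensus over a reference genome computed from short-read
#' alignments.  The sequence track is coordinate-locked to the reference
#' (insertions relative to the reference are not placed); each position
#' carries a Phred-scale confidence, the read depth, and a flag saying
#' whether it passed the confidence cutoff (quality >= cutoff AND depth >=
#' minimum depth).
#'
#' @slot sequence \link[Biostrings]{DNAString}, same length as the reference.
#' @slot quality integer Phred value per position (0..93).
#' @slot depth integer read depth per position.
#' @slot confidentMask logical per position.
#' @slot referenceId character(1) name of the reference sequence.
#' @slot params list with \code{qualityCutoff} and \code{minDepth}.
#' @export
setClass("ReferenceGuidedDraft",
  representation(sequence = "DNAString", quality = "integer",
                 depth = "integer", confidentMask = "logical",
                 referenceId = "character", params = "list"),
  validity = function(object) {
    msg <- character(0)
    L <- length(object@sequence)
    if (length(object@quality) != L || length(object@depth) != L ||
        length(object@confidentMask) != L)
      msg <- c(msg, "sequence, quality, depth and confidentMask must have equal length")
    if (any(object@quality < 0L | object@quality > 93L))
      msg <- c(msg, "quality values must lie in [0, 93]")
    p <- object@params
    if (!all(c("qualityCutoff", "minDepth") %in% names(p))) {
      msg <- c(msg, "params must contain qualityCutoff and minDepth")
    } else {
      expect <- object@quality >= p$qualityCutoff & object@depth >= p$minDepth
      if (!identical(unname(expect), unname(object@confidentMask)))
        msg <- c(msg, "confidentMask inconsistent with quality/depth cutoff rule")
    }
    if (length(msg)) msg else TRUE
  }
)

setMethod("show", "ReferenceGuidedDraft", function(object) {
  L <- length(object@sequence)
  cat("ReferenceGuidedDraft over '", object@referenceId, "' (", L, " bp)\n",
      sep = "")
  cat("  confident positions: ", sum(object@confidentMask), " (",
      sprintf("%.1f%%", 100 * mean(object@confidentMask)), ") at Q>=",
      object@params$qualityCutoff, ", depth>=", object@params$minDepth, "\n",
      sep = "")
})

#' @describeIn buildDraft draft consensus sequence as a DNAString
#' @param x a \linkS4class{ReferenceGuidedDraft}
#' @export
draftSequence <- function(x) x@sequence

#' @describeIn buildDraft per-position Phred confidence
#' @export
draftQuality <- function(x) x@quality

#' @describeIn buildDraft per-position read depth
#' @export
draftDepth <- function(x) x@depth

#' @describeIn buildDraft logical confident-position mask
#' @export
confidentMask <- function(x) x@confidentMask

#' Scaffold layout along a reference
#'
#' The ordered, oriented arrangement of de novo scaffolds along a reference
#' genome, as produced by \code{\link{placeScaffolds}}.  The three id sets
#' (\code{placements$scaffold_id}, \code{unplaced}, \code{belowMin})
#' partition the input scaffolds.
#'
#' @slot referenceId character(1).
#' @slot placements data.frame ordered by \code{ref_position}: one row per
#'   placed scaffold with its orientation, best anchor coordinates (0-based
#'   half-open, in oriented-scaffold frame), projected reference interval
#'   and rank.
#' @slot unplaced character, ids of length-passing scaffolds with no anchor.
#' @slot belowMin character, ids filtered out by the length cutoff.
#' @slot scaffoldLengths named integer, lengths of all input scaffolds.
#' @export
setClass("Layout",
  representation(referenceId = "character", placements = "data.frame",
                 unplaced = "character", belowMin = "character",
                 scaffoldLengths = "integer"),
  validity = function(object) {
    msg <- character(0)
    ids <- c(object@placements$scaffold_id, object@unplaced, object@belowMin)
    if (anyDuplicated(ids))
      msg <- c(msg, "placed/unplaced/belowMin id sets must be disjoint")
    rp <- object@placements$ref_position
    if (length(rp) > 1L && is.unsorted(rp))
      msg <- c(msg, "placements must be sorted by ref_position")
    if (nrow(object@placements) &&
        !identical(object@placements$rank, seq_len(nrow(object@placements)) - 1L))
      msg <- c(msg, "rank must be 0..n-1 in placement order")
    if (length(msg)) msg else TRUE
  }
)

setMethod("show", "Layout", function(object) {
  cat("Layout along '", object@referenceId, "': ",
      nrow(object@placements), " placed, ", length(object@unplaced),
      " unplaced, ", length(object@belowMin), " below length cutoff\n",
      sep = "")
  if (nrow(object@placements)) {
    n <- min(5L, nrow(object@placements))
    print(utils::head(object@placements[, c("scaffold_id", "orientation",
                                            "ref_position", "rank")], n))
    if (nrow(object@placements) > n) cat("  ...\n")
  }
})

#' @describeIn placeScaffolds placements table of a Layout
#' @param x a \linkS4class{Layout}
#' @export
placements <- function(x) x@placements

#' @describeIn placeScaffolds ids of anchored-nowhere scaffolds
#' @export
unplacedIds <- function(x) x@unplaced

#' @describeIn placeScaffolds ids removed by the length filter
#' @export
belowMinIds <- function(x) x@belowMin

#' Finished assembly with gap records
#'
#' The single finished sequence produced by \code{\link{closeLayout}}:
#' oriented scaffolds and draft inserts concatenated, with open junctions
#' represented as N-runs.  Removing the N-runs and concatenating the AGP
#' components reproduces the component sequences exactly.
#'
#' @slot sequence \link[Biostrings]{DNAString} with N-run gaps.
#' @slot gaps data.frame: 0-based half-open N-run interval on the final
#'   sequence, estimated size, flanking scaffold ids.
#' @slot junctions data.frame: left_id, right_id, status
#'   (\code{overlap_merged}/\code{draft_filled}/\code{open}) and detail.
#' @slot agp data.frame of AGP 2.1 rows (1-based inclusive coordinates).
#' @export
setClass("FinalAssembly",
  representation(sequence = "DNAString", gaps = "data.frame",
                 junctions = "data.frame", agp = "data.frame"),
  validity = function(object) {
    msg <- character(0)
    st <- object@junctions$status
    if (length(st) && !all(st %in% c("overlap_merged", "draft_filled", "open")))
      msg <- c(msg, "junction status must be overlap_merged/draft_filled/open")
    if (nrow(object@gaps) != sum(st == "open"))
      msg <- c(msg, "one gap record per open junction required")
    if (length(msg)) msg else TRUE
  }
)

setMethod("show", "FinalAssembly", function(object) {
  st <- object@junctions$status
  cat("FinalAssembly: ", length(object@sequence), " bp, ",
      nrow(object@junctions), " junctions (",
      sum(st == "overlap_merged"), " overlap-merged, ",
      sum(st == "draft_filled"), " draft-filled, ",
      sum(st == "open"), " open)\n", sep = "")
})

#' @describeIn closeLayout finished sequence of a FinalAssembly
#' @param x a \linkS4class{FinalAssembly}
#' @export
assemblySequence <- function(x) x@sequence

#' @describeIn closeLayout junction table (status per adjacent pair)
#' @export
junctions <- function(x) x@junctions

#' @describeIn closeLayout gap records (N-run intervals, 0-based half-open)
#' @export
gapRecords <- function(x) x@gaps

#' @describeIn closeLayout AGP 2.1 rows (1-based)
#' @export
agpTable <- function(x) x@agp

#' Mapping statistics report
#'
#' Summary statistics of a short-read mapping: fraction of reads placed,
#' mean fold coverage (aligned bases / reference length), and the fraction
#' of covered consensus positions at or above Phred 40 / 30.
#'
#' @slot mappedFraction numeric(1) in [0,1].
#' @slot meanFoldCoverage numeric(1).
#' @slot fracQ40,fracQ30 numeric(1) fractions of covered positions.
#' @slot nReads,nMapped integer(1).
#' @export
setClass("MappingReport",
  representation(mappedFraction = "numeric", meanFoldCoverage = "numeric",
                 fracQ40 = "numeric", fracQ30 = "numeric",
                 nReads = "integer", nMapped = "integer"),
  validity = function(object) {
    if (object@fracQ40 > object@fracQ30 + 1e-12)
      return("fracQ40 cannot exceed fracQ30")
    if (object@meanFoldCoverage < 0) return("coverage cannot be negative")
    TRUE
  }
)

setMethod("show", "MappingReport", function(object) {
  cat(sprintf(paste0("MappingReport: %d/%d reads mapped (%.1f%%), ",
                     "%.1f-fold coverage, Q40 %.1f%%, Q30 %.1f%%\n"),
              object@nMapped, object@nReads, 100 * object@mappedFraction,
              object@meanFoldCoverage, 100 * object@fracQ40,
              100 * object@fracQ30))
})

#' Truth table of a synthetic scenario
#'
#' Record of every edit applied to derive a genome from its reference, of
#' the origin interval and orientation of every shredded scaffold, and of
#' the sampling position of every simulated read.  Used as the oracle in
#' recovery tests: replaying \code{edits} against the reference reproduces
#' the derived genome byte-exactly (see \code{\link{applyEdits}}).
#'
#' @slot edits data.frame: type (\code{deletion}/\code{insertion}/
#'   \code{snp}/\code{ins1}/\code{del1}), ref_pos, derived_pos (0-based),
#'   length, payload.
#' @slot scaffoldOrigins data.frame: scaffold_id, start, end (0-based
#'   half-open on the derived genome), orientation.
#' @slot readOrigins data.frame: read id, 0-based position, strand.
#' @export
setClass("TruthTable",
  representation(edits = "data.frame", scaffoldOrigins = "data.frame",
                 readOrigins = "data.frame"))

setMethod("show", "TruthTable", function(object) {
  cat("TruthTable: ", nrow(object@edits), " edits, ",
      nrow(object@scaffoldOrigins), " scaffold origins, ",
      nrow(object@readOrigins), " read origins\n", sep = "")
  if (nrow(object@edits))
    print(table(object@edits$type))
})

#' @describeIn deriveGenome edit list of a TruthTable
#' @param x a \linkS4class{TruthTable}
#' @export
truthEdits <- function(x) x@edits

#' @describeIn deriveGenome scaffold origin map of a TruthTable
#' @export
truthScaffoldOrigins <- function(x) x@scaffoldOrigins

#' @describeIn deriveGenome read origin map of a TruthTable
#' @export
truthReadOrigins <- function(x) x@readOrigins
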