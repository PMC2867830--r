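# ---------------------------------------------------------------------------
# In-silico restriction digestion and fragment-map comparison.  Cut
# positions are placed at the motif start: at the few-percent tolerance
# used for genome-scale physical maps the offset of the scission point
# inside the recognition site is irrelevant to fragment sizes.
# ---------------------------------------------------------------------------

.IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                       S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                       D = "H", H = "D", N = "N")

.iupacRevcomp <- function(motif) {
  chars <- rev(strsplit(toupper(motif), "", fixed = TRUE)[[1]])
  paste0(.IUPAC_COMPLEMENT[chars], collapse = "")
}

#' Restriction enzyme recognition sites
#'
#' A small built-in table of recognition motifs (IUPAC).  SfiI
#' (GGCCNNNNNGGCC, interrupted palindrome) is the enzyme used for
#' genome-scale physical maps of Bacillus chromosomes.
#'
#' @param name enzyme name (e.g. \code{"SfiI"}) or \code{NULL} to list.
#' @return a list with \code{name}, \code{motif}, \code{palindromic}.
#' @export
recognitionSite <- function(name = "SfiI") {
  motifs <- c(SfiI = "GGCCNNNNNGGCC", NotI = "GCGGCCGC", BamHI = "GGATCC",
              EcoRI = "GAATTC", AscI = "GGCGCGCC")
  if (is.null(name)) return(names(motifs))
  if (!name %in% names(motifs)) stop("unknown enzyme: ", name,
                                     " (use a custom motif instead)")
  customSite(name, motifs[[name]])
}

#' @describeIn recognitionSite build a site from a custom IUPAC motif
#' @param motif IUPAC DNA pattern, length at least 4.
#' @export
customSite <- function(name, motif) {
  motif <- toupper(motif)
  .iupacMotifCodes(motif)                       # validates the alphabet
  if (nchar(motif) < 4L) stop("motif must be at least 4 bp")
  list(name = name, motif = motif,
       palindromic = identical(motif, .iupacRevcomp(motif)))
}

#' In-silico restriction digest
#'
#' Finds every match of the recognition motif on both strands (the two
#' strands collapse for palindromic motifs), cuts at motif starts, and
#' returns fragment lengths in genome-position order.  For circular
#' topology the last and first fragments join, and motif matches spanning
#' the origin are found.
#'
#' @param sequence template (character or DNAString).
#' @param site a recognition site from \code{\link{recognitionSite}} or
#'   \code{\link{customSite}}.
#' @param topology \code{"linear"} or \code{"circular"}.
#' @return a list of class \code{FragmentSet}: \code{topology},
#'   \code{cuts} (0-based cut positions, sorted) and \code{fragments}
#'   (integer lengths in position order; sums to the template length).
#' @export
digestSequence <- function(sequence, site = recognitionSite("SfiI"),
                           topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  seq <- .checkDNA(sequence, "template")
  L <- nchar(seq)
  m <- nchar(site$motif)
  scanSeq <- if (topology == "circular" && L >= m)
    paste0(seq, substr(seq, 1L, m - 1L)) else seq
  cuts <- .iupacScan(scanSeq, site$motif)
  if (!site$palindromic) {
    rcCuts <- .iupacScan(scanSeq, .iupacRevcomp(site$motif))
    cuts <- c(cuts, rcCuts)
  }
  cuts <- sort(unique(cuts %% L))
  fragments <- if (!length(cuts)) {
    L
  } else if (topology == "linear") {
    lens <- diff(c(0L, cuts, L))
    lens[lens > 0L]
  } else if (length(cuts) == 1L) {
    L
  } else {
    c(diff(cuts), L - cuts[length(cuts)] + cuts[1L])
  }
  structure(list(topology = topology, cuts = as.integer(cuts),
                 fragments = as.integer(fragments)),
            class = "FragmentSet")
}

#' @export
print.FragmentSet <- function(x, ...) {
  cat("FragmentSet (", x$topology, "): ", length(x$fragments),
      " fragments, total ", sum(x$fragments), " bp\n", sep = "")
  invisible(x)
}

#' Build a FragmentSet from known fragment sizes
#'
#' Wraps an experimentally measured fragment list (in map order) so it
#' can be compared with a predicted digest.
#'
#' @param fragments integer fragment sizes in genome-position order.
#' @param topology \code{"linear"} or \code{"circular"}.
#' @return a \code{FragmentSet}.
#' @export
fragmentSet <- function(fragments, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  fragments <- as.integer(fragments)
  if (any(fragments <= 0L)) stop("fragment lengths must be positive")
  structure(list(topology = topology, cuts = NULL, fragments = fragments),
            class = "FragmentSet")
}

#' Read an experimental fragment map from a two-column TSV
#' @param path TSV with columns: fragment order, size in bp.
#' @param topology map topology.
#' @return a \code{FragmentSet}.
#' @export
readFragmentTSV <- function(path, topology = "circular") {
  df <- read.table(path, header = FALSE, sep = "\t")
  fragmentSet(df[[2]][order(df[[1]])], topology)
}

#' Compare predicted and experimental fragment maps
#'
#' Both maps are position-anchored, so the comparison is order-preserving
#' pairwise: fragments \code{a}, \code{b} match when
#' \code{|a - b| <= relTol * max(a, b)} (the conventional few-percent
#' sizing error of gel-based physical maps).
#'
#' @param predicted,experimental \code{FragmentSet}s.
#' @param relTol relative size tolerance (default 0.03).
#' @return list of class \code{FragmentComparison}: \code{countMatch},
#'   \code{table} (per-pair sizes, relative difference, matched flag) and
#'   \code{outliers} (indices of mismatched pairs).
#' @export
compareFragmentSets <- function(predicted, experimental, relTol = 0.03) {
  a <- predicted$fragments
  b <- experimental$fragments
  if (length(a) != length(b)) {
    return(structure(list(countMatch = FALSE, nPredicted = length(a),
                          nExperimental = length(b), table = NULL,
                          outliers = integer(0)),
                     class = "FragmentComparison"))
  }
  rel <- abs(a - b) / pmax(a, b)
  matched <- abs(a - b) <= relTol * pmax(a, b)
  structure(list(countMatch = TRUE,
                 table = data.frame(index = seq_along(a), predicted = a,
                                    experimental = b,
                                    rel_diff = rel, matched = matched),
                 outliers = which(!matched)),
            class = "FragmentComparison")
}

#' @export
print.FragmentComparison <- function(x, ...) {
  if (!x$countMatch) {
    cat("FragmentComparison: fragment COUNTS differ (",
        x$nPredicted, " predicted vs ", x$nExperimental,
        " experimental)\n", sep = "")
  } else {
    cat("FragmentComparison: ", sum(x$table$matched), "/",
        nrow(x$table), " fragments matched", sep = "")
    if (length(x$outliers))
      cat("; outliers at index ", paste(x$outliers, collapse = ", "),
          sep = "")
    cat("\n")
  }
  invisible(x)
}
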