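# ---------------------------------------------------------------------------
# In-silico PCR: product-size prediction from a primer pair on a
# template.  A product arises wherever the forward primer binds the
# forward strand at i and the reverse primer binds the reverse strand
# (i.e. its reverse complement matches the forward strand) at j >= i +
# |fwd|, with product length (j + |rev|) - i.  The 3'-terminal base of
# each primer must match exactly — extension cannot start from a
# mismatched 3' end.
# ---------------------------------------------------------------------------

#' Primer pair
#'
#' @param fwd,rev primer sequences, 5'->3', IUPAC codes allowed; at least
#'   15 bases each.
#' @param maxProduct maximum product length reported (default 10000).
#' @param maxMismatches mismatches tolerated per primer (default 0;
#'   the 3'-terminal base must always match exactly).
#' @return a validated list of class \code{PrimerPair}.
#' @export
primerPair <- function(fwd, rev, maxProduct = 10000L, maxMismatches = 0L) {
  fwd <- toupper(fwd); rev <- toupper(rev)
  .iupacMotifCodes(fwd); .iupacMotifCodes(rev)  # validates alphabets
  if (nchar(fwd) < 15L || nchar(rev) < 15L)
    stop("primers must be at least 15 bases")
  if (maxProduct <= nchar(fwd) + nchar(rev))
    stop("maxProduct must exceed the combined primer length")
  structure(list(fwd = fwd, rev = rev, maxProduct = as.integer(maxProduct),
                 maxMismatches = as.integer(maxMismatches)),
            class = "PrimerPair")
}

# Binding sites (0-based starts on the forward strand) of a motif with the
# 3'-relevant position required to match exactly.  `threePrime` is the
# 0-based offset within the motif that must match.
.bindingSites <- function(template, motif, maxMismatches, threePrime) {
  sites <- .iupacScan(template, motif, maxMismatches)
  if (!length(sites) || maxMismatches == 0L) return(sites)
  tpl <- .templateCodes(template)
  mot <- .iupacMotifCodes(motif)
  ok <- bitwAnd(tpl[sites + threePrime + 1L], mot[threePrime + 1L]) > 0L
  sites[ok]
}

#' Predict PCR products on a template
#'
#' @param template template sequence (character or DNAString).
#' @param pair a \code{\link{primerPair}}.
#' @param topology \code{"linear"} or \code{"circular"}.
#' @return data.frame with one row per product: \code{start} (0-based
#'   position of the forward primer's 5' end), \code{end} (0-based
#'   exclusive end of the reverse primer's 5' end, possibly > template
#'   length for origin-spanning circular products), \code{length} in bp
#'   and \code{kb} (rounded to 0.01 kb).
#' @examples
#' tpl <- paste0(strrep("T", 20), "GATTACAGATTACAAC", strrep("A", 100),
#'               "GTTGTAATCTGTAATC", strrep("T", 20))
#' p <- primerPair("GATTACAGATTACAAC", "GATTACAGATTACAAC")
#' predictProducts(tpl, p)
#' @export
predictProducts <- function(template, pair,
                            topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  seq <- .checkDNA(template, "template")
  L <- nchar(seq)
  lf <- nchar(pair$fwd); lr <- nchar(pair$rev)
  rcRev <- .iupacRevcomp(pair$rev)
  scanSeq <- if (topology == "circular")
    paste0(seq, substr(seq, 1L, min(L, pair$maxProduct))) else seq

  # forward primer 3' end = last motif position; reverse primer 3' end =
  # first position of its reverse complement on the forward strand
  fSites <- .bindingSites(scanSeq, pair$fwd, pair$maxMismatches, lf - 1L)
  rSites <- .bindingSites(scanSeq, rcRev, pair$maxMismatches, 0L)
  if (topology == "circular") fSites <- fSites[fSites < L]
  if (!length(fSites) || !length(rSites)) {
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), kb = numeric(0)))
  }
  out <- list()
  for (i in fSites) {
    js <- rSites[rSites >= i + lf & (rSites + lr) - i <= pair$maxProduct]
    if (length(js))
      out[[length(out) + 1L]] <- data.frame(start = i, end = js + lr,
                                            length = (js + lr) - i)
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), kb = numeric(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end), ]
  rownames(res) <- NULL
  res$kb <- round(res$length / 1000, 2)
  res
}

#' Polyketide-operon deletion verification primers
#'
#' The four primers bracketing the polyketide synthesis (pks) operon used
#' to verify its absence in B. subtilis natto: pairs A+B and C+D amplify
#' the operon's two ends from a pks+ genome, while A+D yields a short
#' product only when the whole operon is deleted.
#'
#' @return named character vector with primers \code{A}-\code{D}.
#' @export
pksDeletionPrimers <- function() {
  c(A = "AGAAAACAAATTGCAGAAGCAAC",
    B = "GCATGTTGTTAAAGCACATAGCA",
    C = "GATTGCATATGAAGTCACTCGC",
    D = "TACTCTACTCAGGTTGAGTGGGC")
}
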