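#' @importFrom Biostrings readDNAStringSet writeXStringSet
#' @importFrom utils read.table write.table
NULL

# ---------------------------------------------------------------------------
# File formats.  FASTA/FASTQ go through Biostrings; SAM text (the 11
# mandatory columns), AGP 2.1 and BED are simple tab formats written and
# parsed here.  SAM positions and AGP coordinates are 1-based on disk; the
# package converts to its internal 0-based half-open convention at these
# boundaries.
# ---------------------------------------------------------------------------

#' Read a FASTA file as a named character vector
#' @param path FASTA file (wrapped or unwrapped, multi-record).
#' @return named character vector of upper-case sequences.
#' @export
readFasta <- function(path) {
  x <- readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' Write sequences to FASTA
#' @param seqs named character vector or DNAStringSet.
#' @param path output file.
#' @export
writeFasta <- function(seqs, path) {
  if (!is(seqs, "XStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  writeXStringSet(seqs, path)
  invisible(path)
}

#' Read paired FASTQ files
#'
#' @param path1,path2 FASTQ files for mate 1 and mate 2 (gzip allowed).
#' @return a \code{ReadPairs} list: \code{id}, \code{seq1}, \code{seq2},
#'   \code{qual1}, \code{qual2} (parallel character vectors).
#' @export
readFastqPairs <- function(path1, path2) {
  r1 <- readDNAStringSet(path1, format = "fastq", with.qualities = TRUE)
  r2 <- readDNAStringSet(path2, format = "fastq", with.qualities = TRUE)
  if (length(r1) != length(r2))
    stop("mate files differ in read count: ", length(r1), " vs ", length(r2))
  newReadPairs(
    id = sub("/[12]$", "", sub("\\s.*$", "", names(r1))),
    seq1 = unname(as.character(r1)), seq2 = unname(as.character(r2)),
    qual1 = unname(as.character(S4Vectors::mcols(r1)$qualities)),
    qual2 = unname(as.character(S4Vectors::mcols(r2)$qualities)))
}

#' Construct a ReadPairs container
#'
#' @param id read-pair identifiers.
#' @param seq1,seq2 DNA sequences of mate 1/2.
#' @param qual1,qual2 Phred+33 quality strings, same lengths as the
#'   sequences.
#' @return a list of class \code{ReadPairs}.
#' @export
newReadPairs <- function(id, seq1, seq2, qual1, qual2) {
  n <- length(id)
  stopifnot(length(seq1) == n, length(seq2) == n,
            length(qual1) == n, length(qual2) == n)
  if (any(nchar(seq1) != nchar(qual1)) || any(nchar(seq2) != nchar(qual2)))
    stop("sequence and quality lengths differ")
  structure(list(id = as.character(id),
                 seq1 = toupper(seq1), seq2 = toupper(seq2),
                 qual1 = qual1, qual2 = qual2),
            class = "ReadPairs")
}

#' @export
print.ReadPairs <- function(x, ...) {
  cat("ReadPairs: ", length(x$id), " pairs, read length ",
      paste(range(nchar(c(x$seq1, x$seq2))), collapse = "-"), " bp\n",
      sep = "")
  invisible(x)
}

#' @export
length.ReadPairs <- function(x) length(x$id)

#' Write paired FASTQ files
#' @param pairs a \code{ReadPairs} object.
#' @param path1,path2 output FASTQ files.
#' @export
writeFastqPairs <- function(pairs, path1, path2) {
  .writeFastqOne(paste0(pairs$id, "/1"), pairs$seq1, pairs$qual1, path1)
  .writeFastqOne(paste0(pairs$id, "/2"), pairs$seq2, pairs$qual2, path2)
  invisible(c(path1, path2))
}

.writeFastqOne <- function(id, seq, qual, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", id, "\n", seq, "\n+\n", qual), con, sep = "\n")
}

# --- SAM -------------------------------------------------------------------

.SAM_COLS <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
               "rnext", "pnext", "tlen", "seq", "qual")

#' Read SAM alignment records (text)
#'
#' Parses the 11 mandatory columns of a SAM file; header lines are kept as
#' an attribute.  Only the CIGAR operations M/=/X/S/I/D are supported
#' downstream.
#'
#' @param path SAM file.
#' @return data.frame with the 11 mandatory SAM columns (\code{pos}
#'   1-based as in the format).
#' @export
readSAM <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (!length(body)) {
    sam <- data.frame(qname = character(0), flag = integer(0),
                      rname = character(0), pos = integer(0),
                      mapq = integer(0), cigar = character(0),
                      rnext = character(0), pnext = integer(0),
                      tlen = integer(0), seq = character(0),
                      qual = character(0))
    attr(sam, "header") <- hdr
    return(sam)
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(f) < 11L)) {
    bad <- which(lengths(f) < 11L)[1L]
    stop("malformed SAM record at line ", bad, ": fewer than 11 fields")
  }
  m <- matrix(unlist(lapply(f, `[`, 1:11)), ncol = 11L, byrow = TRUE)
  sam <- data.frame(qname = m[, 1], flag = as.integer(m[, 2]),
                    rname = m[, 3], pos = as.integer(m[, 4]),
                    mapq = as.integer(m[, 5]), cigar = m[, 6],
                    rnext = m[, 7], pnext = as.integer(m[, 8]),
                    tlen = as.integer(m[, 9]), seq = m[, 10],
                    qual = m[, 11])
  attr(sam, "header") <- hdr
  sam
}

#' Write SAM alignment records (text)
#' @param sam data.frame with the 11 mandatory SAM columns.
#' @param path output file.
#' @param refName,refLen reference name and length for the \code{@SQ}
#'   header line.
#' @export
writeSAM <- function(sam, path, refName = NULL, refLen = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  if (!is.null(refName))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", refName, as.integer(refLen)), con)
  if (nrow(sam)) {
    writeLines(do.call(paste, c(unname(sam[.SAM_COLS]), sep = "\t")), con)
  }
  invisible(path)
}

# --- AGP 2.1 ---------------------------------------------------------------

#' Write an assembly layout as AGP 2.1
#'
#' Component rows are type \code{W} with 1-based inclusive coordinates and
#' orientation \code{+}/\code{-}; gap rows are type \code{N} (known length
#' estimate), gap type \code{scaffold}, linkage \code{yes}.
#'
#' @param agp data.frame of AGP rows as stored in a
#'   \linkS4class{FinalAssembly} (or built by \code{\link{layoutToAGP}}).
#' @param path output file.
#' @export
writeAGP <- function(agp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  if (nrow(agp))
    writeLines(do.call(paste, c(unname(agp), sep = "\t")), con)
  invisible(path)
}

#' Read an AGP 2.1 file
#' @param path AGP file.
#' @return data.frame with the 9 AGP columns.
#' @export
readAGP <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(body, "\t", fixed = TRUE)
  m <- matrix(unlist(lapply(f, function(x) c(x, rep("", 9L))[1:9])),
              ncol = 9L, byrow = TRUE)
  data.frame(object = m[, 1], object_beg = as.integer(m[, 2]),
             object_end = as.integer(m[, 3]), part_number = as.integer(m[, 4]),
             component_type = m[, 5], component_id = m[, 6],
             component_beg = m[, 7], component_end = m[, 8],
             orientation = m[, 9])
}

#' Write 0-based half-open intervals as BED
#' @param df data.frame with columns \code{start}, \code{end} and
#'   optionally \code{name}.
#' @param chrom chromosome/sequence name.
#' @param path output file.
#' @export
writeBED <- function(df, chrom, path) {
  name <- if ("name" %in% names(df)) df$name else "."
  writeLines(paste(chrom, df$start, df$end, name, sep = "\t"), path)
  invisible(path)
}
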