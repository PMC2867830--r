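# ---------------------------------------------------------------------------
# Pipeline orchestration: draft -> place -> close -> digest, with a YAML
# config, stage-level logging of the counts a finishing run is judged by
# (mapped fraction, scaffolds placed/unplaced, junction census), and all
# intermediates written to disk.
# ---------------------------------------------------------------------------

.PIPELINE_DEFAULTS <- list(
  reference = NULL, scaffolds = NULL, reads1 = NULL, reads2 = NULL,
  sam = NULL, outputDir = ".", seed = 1L,
  minScaffoldLen = 1000L, anchorMinLen = 40L, anchorMinIdentity = 0.9,
  qualityCutoff = 40L, minDepth = 1L,
  minOverlap = 30L, maxMismatchRate = 0.02, minGapN = 100L,
  enzyme = "SfiI", topology = "linear", threads = 1L)

#' Assemble and validate a pipeline configuration
#'
#' @param ... configuration values overriding the defaults, or a single
#'   path to a YAML file with those keys.  Unknown keys are rejected.
#' @return validated configuration list.
#' @export
pipelineConfig <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.character(args[[1]]) && is.null(names(args)))
    args <- yaml::read_yaml(args[[1]])
  unknown <- setdiff(names(args), names(.PIPELINE_DEFAULTS))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(.PIPELINE_DEFAULTS, args)
  if (is.null(cfg$reference)) stop("configuration requires 'reference'")
  if (is.null(cfg$scaffolds)) stop("configuration requires 'scaffolds'")
  cfg
}

.loadSeqArg <- function(x, what) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) readFasta(x)
  else if (is.character(x)) x
  else stop("cannot interpret '", what, "' input")
}

#' Run the full finishing pipeline
#'
#' Executes the stages in order: map reads and build the reference-guided
#' draft (when reads or a SAM file are supplied), length-filter and place
#' the scaffolds along the reference, close the junctions (overlap merge,
#' then draft fill, else open N-gaps), and digest the final sequence.
#' Every intermediate is written under \code{outputDir}.
#'
#' @param config a \code{\link{pipelineConfig}} (or arguments for one).
#' @return list with \code{draft}, \code{layout}, \code{final},
#'   \code{mappingReport}, \code{digest}, \code{contained},
#'   \code{suggestions}.
#' @export
runPipeline <- function(config) {
  if (!is.list(config) || is.null(config$reference))
    config <- pipelineConfig(config)
  cfg <- config
  dir.create(cfg$outputDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$outputDir, f)

  refv <- .loadSeqArg(cfg$reference, "reference")
  refName <- names(refv)[1] %||% "ref"
  reference <- unname(refv[1])
  scaffolds <- .loadSeqArg(cfg$scaffolds, "scaffolds")
  if (is.null(names(scaffolds)))
    names(scaffolds) <- sprintf("scaffold_%03d", seq_along(scaffolds))

  # stage 1: reference-guided draft
  draft <- NULL; report <- NULL
  sam <- NULL
  if (!is.null(cfg$sam)) {
    sam <- if (is.character(cfg$sam)) readSAM(cfg$sam) else cfg$sam
  } else if (!is.null(cfg$reads1)) {
    pairs <- if (inherits(cfg$reads1, "ReadPairs")) cfg$reads1
             else readFastqPairs(cfg$reads1, cfg$reads2)
    message("mapping ", length(pairs), " read pairs")
    sam <- mapReads(pairs, reference, refName = refName)
    writeSAM(sam, out("alignments.sam"), refName, nchar(reference))
  }
  if (!is.null(sam)) {
    draft <- buildDraft(sam, reference,
                        consensusParams(cfg$qualityCutoff, cfg$minDepth),
                        referenceId = refName)
    report <- mappingReport(sam, reference, draft)
    message(sprintf("draft: %.1f%% reads mapped, %.1f-fold coverage, %.1f%% confident",
                    100 * report@mappedFraction, report@meanFoldCoverage,
                    100 * mean(draft@confidentMask)))
    writeFasta(stats::setNames(as.character(draft@sequence),
                               paste0(refName, "_draft")),
               out("draft.fa"))
    nonConf <- .trueRuns(!draft@confidentMask)
    writeBED(data.frame(start = nonConf[, 1], end = nonConf[, 2]),
             refName, out("draft_nonconfident.bed"))
    writeMappingReport(report, out("mapping_report.tsv"))
  }

  # stage 2: place scaffolds
  fl <- filterByLength(scaffolds, cfg$minScaffoldLen)
  index <- seedIndex(reference)
  layout <- placeScaffolds(fl$kept, index,
                           minLen = cfg$anchorMinLen,
                           minIdentity = cfg$anchorMinIdentity,
                           belowMin = names(fl$belowMin),
                           referenceId = refName)
  message("layout: ", nrow(layout@placements), " placed, ",
          length(layout@unplaced), " unplaced, ",
          length(layout@belowMin), " below ", cfg$minScaffoldLen, " bp")
  writeAGP(layoutToAGP(layout, minGapN = cfg$minGapN), out("layout.agp"))
  writeUnplacedTSV(layout, out("unplaced.tsv"))

  # stage 3: close junctions
  final <- closeLayout(layout, scaffolds, draft,
                       minOverlap = cfg$minOverlap,
                       maxMismatchRate = cfg$maxMismatchRate,
                       minGapN = cfg$minGapN,
                       minLen = cfg$anchorMinLen,
                       minIdentity = cfg$anchorMinIdentity,
                       objectName = paste0(refName, "_final"))
  cen <- table(factor(final@junctions$status,
                      c("overlap_merged", "draft_filled", "open")))
  message(sprintf("junctions: %d overlap-merged, %d draft-filled, %d open",
                  cen[[1]], cen[[2]], cen[[3]]))
  writeFasta(stats::setNames(as.character(final@sequence),
                             paste0(refName, "_final")), out("final.fa"))
  writeAGP(final@agp, out("final.agp"))
  write.table(final@junctions, out("junctions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (nrow(final@gaps)) {
    writeBED(final@gaps[, c("start", "end")], paste0(refName, "_final"),
             out("gaps.bed"))
    writeFasta(gapFlanks(final), out("gap_flanks.fa"))
  }

  # containment screen of short scaffolds + gap suggestions for unplaced
  contained <- screenContained(fl$belowMin, final,
                               maxMismatchRate = cfg$maxMismatchRate)
  sugg <- placeUnplacedIntoGaps(scaffolds[layout@unplaced], final,
                                minOverlap = cfg$minOverlap,
                                maxMismatchRate = cfg$maxMismatchRate)
  message(length(contained), "/", length(fl$belowMin),
          " short scaffolds contained in the final sequence")

  # stage 4: digest
  dig <- digestSequence(as.character(final@sequence),
                        recognitionSite(cfg$enzyme), cfg$topology)
  write.table(data.frame(order = seq_along(dig$fragments),
                         size = dig$fragments),
              out("fragments.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  list(draft = draft, layout = layout, final = final,
       mappingReport = report, digest = dig, contained = contained,
       suggestions = sugg)
}
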