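# PAS annotation handling: GENCODE polyA-dialect GFF3 input, hexamer
# classification against a genome, and the intersection with scan output that
# yields the editable-share summary.

#' Read polyA-signal annotations from GFF3
#'
#' Reads a GFF3 file in the GENCODE polyAs dialect and keeps only features of
#' the requested type (\code{polyA_signal} by default). Coordinates are
#' converted from the 1-based closed GFF3 convention to GRanges ranges.
#' Malformed lines (wrong column count, non-numeric coordinates) are skipped
#' and counted; the counts are stored in \code{S4Vectors::metadata()} under
#' \code{nMalformed} and \code{nOtherType}.
#'
#' @param path GFF3 file (plain text or gzip).
#' @param featureType feature type to keep.
#' @return \code{GRanges} with metadata column \code{type}.
#' @export
readPolyAGFF3 <- function(path, featureType = "polyA_signal") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) == 9L
  nMalformed <- sum(!ok)
  fields <- fields[ok]
  mat <- do.call(rbind, fields)
  if (is.null(mat)) mat <- matrix(character(), ncol = 9)
  start <- suppressWarnings(as.integer(mat[, 4]))
  end <- suppressWarnings(as.integer(mat[, 5]))
  badCoord <- is.na(start) | is.na(end) | start < 1L | end < start
  nMalformed <- nMalformed + sum(badCoord)
  keepType <- !badCoord & mat[, 3] == featureType
  nOtherType <- sum(!badCoord & !keepType)
  gr <- GenomicRanges::GRanges(
    seqnames = mat[keepType, 1],
    ranges = IRanges::IRanges(start = start[keepType], end = end[keepType]),
    strand = ifelse(mat[keepType, 7] %in% c("+", "-"), mat[keepType, 7], "*"))
  S4Vectors::mcols(gr)$type <- mat[keepType, 3]
  S4Vectors::metadata(gr) <- list(nMalformed = nMalformed,
                                  nOtherType = nOtherType)
  if (!length(gr))
    warning("no '", featureType, "' features found in ", path)
  gr
}

#' Classify annotated PAS hexamers against a genome
#'
#' Extracts the hexamer under each annotation on its annotated strand and
#' assigns a motif class: \code{AATAAA}, \code{ATTAAA}, \code{other}, or
#' \code{unextractable} (span not of length 6, contig absent from the genome,
#' or out of bounds).
#'
#' @param annotations \code{GRanges} (e.g. from \code{\link{readPolyAGFF3}}).
#' @param genome FASTA path, \code{DNAStringSet}, or named character vector.
#' @return the annotations with metadata columns \code{hexamer} and
#'   \code{motifClass} added.
#' @export
classifyPAS <- function(annotations, genome) {
  seqs <- .asGenome(genome)
  n <- length(annotations)
  hex <- rep(NA_character_, n)
  cls <- rep("unextractable", n)
  chroms <- as.character(GenomicRanges::seqnames(annotations))
  missing <- unique(chroms[!(chroms %in% names(seqs))])
  if (length(missing))
    warning("contig(s) absent from genome: ", paste(missing, collapse = ", "))
  st <- GenomicRanges::start(annotations)
  en <- GenomicRanges::end(annotations)
  strand <- as.character(GenomicRanges::strand(annotations))
  for (i in seq_len(n)) {
    if (!(chroms[i] %in% names(seqs))) next
    if (en[i] - st[i] + 1L != 6L) next
    L <- nchar(seqs[[chroms[i]]])
    if (st[i] < 1L || en[i] > L) next
    h <- substr(seqs[[chroms[i]]], st[i], en[i])
    if (strand[i] == "-") h <- .revcomp(h)
    hex[i] <- h
    cls[i] <- if (h %in% c("AATAAA", "ATTAAA")) h else "other"
  }
  S4Vectors::mcols(annotations)$hexamer <- hex
  S4Vectors::mcols(annotations)$motifClass <- cls
  annotations
}

#' Motif-class counts for classified annotations
#'
#' @param classified output of \code{\link{classifyPAS}}.
#' @return named integer vector over the classes
#'   \code{AATAAA, ATTAAA, other, unextractable}.
#' @export
motifClassCounts <- function(classified) {
  cls <- S4Vectors::mcols(classified)$motifClass
  if (is.null(cls)) stop("annotations are not classified; run classifyPAS()")
  lv <- c("AATAAA", "ATTAAA", "other", "unextractable")
  counts <- table(factor(cls, levels = lv))
  stats::setNames(as.integer(counts), lv)
}

#' Share of annotations carrying one of the two canonical motifs
#'
#' @inheritParams motifClassCounts
#' @return fraction in [0, 1], or \code{NA} when there are no annotations.
#' @export
twoMotifShare <- function(classified) {
  counts <- motifClassCounts(classified)
  total <- sum(counts)
  if (total == 0L) return(NA_real_)
  unname((counts["AATAAA"] + counts["ATTAAA"]) / total)
}

#' EditabilitySummary: annotated-PAS editability statistics
#'
#' @slot classCounts integer counts per motif class.
#' @slot nTwoMotif number of (deduplicated) AATAAA/ATTAAA annotations, the
#'   denominator of the editable share.
#' @slot nEditable how many of those have an editable scan record.
#' @slot editableFraction \code{nEditable / nTwoMotif} (NA when the
#'   denominator is 0).
#' @slot modeBreakdown editable counts by strand mode
#'   (\code{coding}, \code{template}, \code{both}).
#' @exportClass EditabilitySummary
setClass("EditabilitySummary", representation(
  classCounts = "integer",
  nTwoMotif = "integer",
  nEditable = "integer",
  editableFraction = "numeric",
  modeBreakdown = "integer"
))

setValidity("EditabilitySummary", function(object) {
  msg <- character()
  if (object@nEditable > object@nTwoMotif)
    msg <- c(msg, "editable count exceeds two-motif total")
  f <- object@editableFraction
  if (!is.na(f) && (f < 0 || f > 1))
    msg <- c(msg, "editableFraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EditabilitySummary", function(object) {
  cat("EditabilitySummary\n")
  cat("  motif classes:",
      paste(names(object@classCounts), object@classCounts, sep = "=",
            collapse = ", "), "\n")
  cat("  two-motif PAS:", object@nTwoMotif, "\n")
  cat("  editable:", object@nEditable,
      if (!is.na(object@editableFraction))
        sprintf("(%.1f%%)", 100 * object@editableFraction) else "(n/a)", "\n")
  cat("  by strand mode:",
      paste(names(object@modeBreakdown), object@modeBreakdown, sep = "=",
            collapse = ", "), "\n")
})

#' Intersect PAS annotations with scan results
#'
#' An annotation is editable iff a scan record with the identical
#' (chrom, interval, strand) exists and is editable - matching is by exact
#' hexamer span, not proximity, since GENCODE polyA_signal features are exact
#' hexamer spans. Identical (chrom, interval, strand) tuples shared by
#' transcript isoforms are deduplicated first. The denominator of the editable
#' share is the deduplicated AATAAA/ATTAAA annotations only.
#'
#' @param annotations classified \code{GRanges}
#'   (see \code{\link{classifyPAS}}); unclassified annotations are classified
#'   on the fly when \code{genome} is given.
#' @param scan an \code{\linkS4class{EditablePASScan}}.
#' @param genome optional genome for on-the-fly classification.
#' @return an \code{\linkS4class{EditabilitySummary}}.
#' @export
editabilitySummary <- function(annotations, scan, genome = NULL) {
  stopifnot(methods::is(scan, "EditablePASScan"))
  if (is.null(S4Vectors::mcols(annotations)$motifClass)) {
    if (is.null(genome))
      stop("annotations are unclassified and no genome was given")
    annotations <- classifyPAS(annotations, genome)
  }
  key <- function(gr) paste(as.character(GenomicRanges::seqnames(gr)),
                            GenomicRanges::start(gr),
                            GenomicRanges::end(gr),
                            as.character(GenomicRanges::strand(gr)),
                            sep = ":")
  annKey <- key(annotations)
  dedup <- !duplicated(annKey)
  annotations <- annotations[dedup]
  annKey <- annKey[dedup]
  classCounts <- motifClassCounts(annotations)
  cls <- S4Vectors::mcols(annotations)$motifClass
  twoMotif <- cls %in% c("AATAAA", "ATTAAA")

  sites <- scan@sites
  mc <- S4Vectors::mcols(sites)
  siteKey <- key(sites)
  idx <- match(annKey, siteKey)
  matched <- !is.na(idx)
  editable <- matched & mc$editable[ifelse(matched, idx, 1L)] & twoMotif
  coding <- matched & mc$editableCoding[ifelse(matched, idx, 1L)] & twoMotif
  template <- matched & mc$editableTemplate[ifelse(matched, idx, 1L)] &
    twoMotif

  if (!any(matched) && length(annotations) && length(sites) &&
      length(GenomicRanges::findOverlaps(annotations, sites,
                                         ignore.strand = TRUE)))
    warning("no exact (chrom, interval, strand) joins despite overlapping ",
            "ranges; check coordinate conventions of the inputs")

  nTwo <- sum(twoMotif)
  nEd <- sum(editable)
  methods::new("EditabilitySummary",
               classCounts = classCounts,
               nTwoMotif = as.integer(nTwo),
               nEditable = as.integer(nEd),
               editableFraction = if (nTwo) nEd / nTwo else NA_real_,
               modeBreakdown = c(
                 coding = sum(coding & !template),
                 template = sum(template & !coding),
                 both = sum(coding & template)))
}

#' Write an editability summary as TSV
#'
#' @param summary an \code{\linkS4class{EditabilitySummary}}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeSummaryTsv <- function(summary, path) {
  rows <- data.frame(
    key = c(paste0("n_", names(summary@classCounts)), "n_two_motif",
            "n_editable", "editable_fraction",
            paste0("n_editable_", names(summary@modeBreakdown))),
    value = c(summary@classCounts, summary@nTwoMotif, summary@nEditable,
              summary@editableFraction, summary@modeBreakdown),
    stringsAsFactors = FALSE)
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
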