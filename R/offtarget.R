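# Off-target candidate analysis: brute-force enumeration of near-match guide
# loci on both strands plus the three-criterion candidate filter
# (mismatch placement, window adenine content, locus uniqueness).

#' Construct an off-target query
#'
#' @param protospacer concrete guide protospacer (5' to 3' on the guide
#'   strand).
#' @param pam IUPAC PAM pattern (default \code{"NGG"}).
#' @param maxMismatch maximum total protospacer mismatches retained during
#'   enumeration (default 4).
#' @param seedLength PAM-proximal protospacer positions treated as the seed
#'   region by the candidate filter (default 12; the value is a convention,
#'   not a measured constant, and can be changed here or at filter time).
#' @return an \code{\linkS4class{OffTargetQuery}}.
#' @export
offTargetQuery <- function(protospacer, pam = "NGG", maxMismatch = 4L,
                           seedLength = 12L) {
  methods::new("OffTargetQuery", protospacer = toupper(protospacer),
               pam = toupper(pam), maxMismatch = as.integer(maxMismatch),
               seedLength = as.integer(seedLength))
}

setMethod("show", "OffTargetQuery", function(object) {
  cat("OffTargetQuery ", object@protospacer, " + ", object@pam,
      " (<= ", object@maxMismatch, " mismatches, seed ",
      object@seedLength, " nt)\n", sep = "")
})

# Near matches of `query` on one scanned strand of one sequence, vectorised
# over start positions via integer base codes. Genomic N counts as a
# protospacer mismatch and fails every PAM symbol. Returns 0-based protospacer
# starts on the scanned string plus mismatch annotation.
.nearMatchStrand <- function(seq, query) {
  P <- nchar(query@protospacer)
  pamSyms <- strsplit(query@pam, "", fixed = TRUE)[[1]]
  M <- length(pamSyms)
  L <- nchar(seq)
  nStarts <- L - P - M + 1L
  empty <- data.frame(start0 = integer(), nMismatch = integer(),
                      mismatchPositions = character(),
                      stringsAsFactors = FALSE)
  if (nStarts < 1L) return(empty)
  codes <- match(strsplit(seq, "", fixed = TRUE)[[1]], DNA_BASES)
  protoCodes <- match(strsplit(query@protospacer, "", fixed = TRUE)[[1]],
                      DNA_BASES)
  idx <- seq_len(nStarts)
  mm <- integer(nStarts)
  for (j in seq_len(P)) {
    b <- codes[idx + j - 1L]
    mm <- mm + (is.na(b) | b != protoCodes[j])
  }
  pamOK <- rep(TRUE, nStarts)
  for (k in seq_len(M)) {
    b <- codes[idx + P + k - 1L]
    pamOK <- pamOK & (DNA_BASES[b] %in% IUPAC_SETS[[pamSyms[k]]]) & !is.na(b)
  }
  keep <- which(pamOK & mm <= query@maxMismatch)
  if (!length(keep)) return(empty)
  mmPos <- vapply(keep, function(i) {
    b <- codes[i + seq_len(P) - 1L]
    paste(which(is.na(b) | b != protoCodes), collapse = ",")
  }, character(1))
  data.frame(start0 = keep - 1L, nMismatch = mm[keep],
             mismatchPositions = mmPos, stringsAsFactors = FALSE)
}

#' Enumerate near-match loci for a guide
#'
#' Brute-force contract: every placement on both strands of every sequence is
#' tested. A locus is reported when its PAM matches the query's IUPAC pattern
#' and its protospacer differs from the query protospacer at no more than
#' \code{maxMismatch} positions. The perfect-match on-target site is included
#' (0 mismatches) and flagged via \code{isOnTarget}. Genomic N counts as a
#' mismatch and never satisfies a PAM symbol.
#'
#' @param genome FASTA path, \code{DNAStringSet}, or named character vector.
#' @param query an \code{\linkS4class{OffTargetQuery}}.
#' @param editor an \code{\linkS4class{EditorSpec}}; its protospacer length
#'   must equal the query length (domain error otherwise), and its activity
#'   window and source base define the \code{windowSourceCount} column.
#' @return \code{GRanges} over the full protospacer+PAM locus with metadata
#'   columns: \code{protoSeq}, \code{pamSeq} (guide-strand reading),
#'   \code{mismatchPositions} (comma-separated, 1-based from the protospacer
#'   5' end), \code{nMismatch}, \code{windowSourceCount} (source-base count at
#'   activity-window positions), \code{copyCount} (genome-wide occurrences of
#'   the exact locus sequence on both strands) and \code{isOnTarget}.
#' @export
enumerateNearMatches <- function(genome, query, editor) {
  stopifnot(methods::is(query, "OffTargetQuery"),
            methods::is(editor, "EditorSpec"))
  P <- nchar(query@protospacer)
  if (P != editor@protospacerLen)
    stop("query protospacer length (", P, ") does not match the editor's (",
         editor@protospacerLen, ")")
  seqs <- .asGenome(genome)
  M <- nchar(query@pam)
  win <- seq(editor@window[1], editor@window[2])
  src <- editor@conversion[1]
  rows <- list()
  for (chrom in names(seqs)) {
    seq <- seqs[[chrom]]
    L <- nchar(seq)
    plus <- .nearMatchStrand(seq, query)
    if (nrow(plus)) {
      plus$chrom <- chrom
      plus$strand <- "+"
      plus$locusStart <- plus$start0          # protospacer start; PAM is 3'
      rows[[length(rows) + 1L]] <- plus
    }
    minus <- .nearMatchStrand(.revcomp(seq), query)
    if (nrow(minus)) {
      minus$chrom <- chrom
      minus$strand <- "-"
      # [start0, start0+P+M) on the revcomp maps to the mirrored plus interval
      minus$locusStart <- L - (minus$start0 + P + M)
      rows[[length(rows) + 1L]] <- minus
    }
  }
  if (!length(rows)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      protoSeq = character(), pamSeq = character(),
      mismatchPositions = character(), nMismatch = integer(),
      windowSourceCount = integer(), copyCount = integer(),
      isOnTarget = logical())
    return(gr)
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$chrom, df$locusStart, df$strand), , drop = FALSE]
  # guide-strand locus sequence: protospacer then PAM
  locusSeq <- vapply(seq_len(nrow(df)), function(i) {
    s <- substr(seqs[[df$chrom[i]]], df$locusStart[i] + 1L,
                df$locusStart[i] + P + M)
    if (df$strand[i] == "-") .revcomp(s) else s
  }, character(1))
  protoSeq <- substr(locusSeq, 1L, P)
  pamSeq <- substr(locusSeq, P + 1L, P + M)
  winCount <- vapply(protoSeq, function(s) {
    sum(strsplit(s, "", fixed = TRUE)[[1]][win] == src)
  }, integer(1), USE.NAMES = FALSE)
  copyCount <- .copyCounts(seqs, unique(locusSeq))[locusSeq]
  gr <- GenomicRanges::GRanges(
    seqnames = factor(df$chrom, levels = names(seqs)),
    ranges = IRanges::IRanges(start = df$locusStart + 1L, width = P + M),
    strand = df$strand,
    seqlengths = nchar(seqs))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    protoSeq = protoSeq, pamSeq = pamSeq,
    mismatchPositions = df$mismatchPositions, nMismatch = df$nMismatch,
    windowSourceCount = winCount, copyCount = unname(copyCount),
    isOnTarget = df$nMismatch == 0L)
  gr
}

# genome-wide exact occurrence counts (both strands) of each pattern
.copyCounts <- function(seqs, patterns) {
  subject <- Biostrings::DNAStringSet(unname(seqs))
  counts <- vapply(patterns, function(p) {
    fwd <- sum(Biostrings::vcountPattern(p, subject, fixed = TRUE))
    rev <- sum(Biostrings::vcountPattern(.revcomp(p), subject, fixed = TRUE))
    fwd + rev
  }, integer(1))
  stats::setNames(counts, patterns)
}

#' Apply the three off-target candidate filter criteria
#'
#' Criterion 1: mismatch placement - in the strict reading (default), every
#' mismatch lies outside the PAM and outside the PAM-proximal seed region AND
#' the mismatch total is at most \code{maxMismatchOutside}; in the loose
#' reading (\code{strict = FALSE}), only mismatches outside the seed are
#' counted against the cap and seed mismatches are tolerated. PAM mismatches
#' are never counted: loci whose PAM does not match are not sites at all.
#' Criterion 2: at least one source base (adenine for an ABE) in the activity
#' window. Criterion 3: the exact protospacer+PAM sequence occurs exactly once
#' genome-wide (both strands).
#'
#' @param sites output of \code{\link{enumerateNearMatches}}.
#' @param editor the \code{\linkS4class{EditorSpec}} used at enumeration.
#' @param seedLength PAM-proximal protospacer positions treated as seed
#'   (default 12).
#' @param maxMismatchOutside mismatch cap for criterion 1 (default 4).
#' @param strict use the strict reading of criterion 1 (default TRUE).
#' @return \code{sites} with logical metadata columns \code{crit1},
#'   \code{crit2}, \code{crit3} and \code{pass} (all three) added. The
#'   filtered candidate list is \code{sites[sites$pass]}.
#' @export
applyOffTargetFilters <- function(sites, editor, seedLength = 12L,
                                  maxMismatchOutside = 4L, strict = TRUE) {
  stopifnot(methods::is(editor, "EditorSpec"))
  mc <- S4Vectors::mcols(sites)
  P <- editor@protospacerLen
  seedFrom <- P - as.integer(seedLength) + 1L   # seed = positions seedFrom..P
  mmList <- lapply(strsplit(mc$mismatchPositions, ",", fixed = TRUE),
                   function(x) as.integer(x[nzchar(x)]))
  inSeed <- vapply(mmList, function(p) sum(p >= seedFrom), integer(1))
  total <- lengths(mmList)
  outside <- total - inSeed
  crit1 <- if (strict) inSeed == 0L & total <= maxMismatchOutside
           else outside <= maxMismatchOutside
  crit2 <- mc$windowSourceCount >= 1L
  crit3 <- mc$copyCount == 1L
  S4Vectors::mcols(sites)$crit1 <- crit1
  S4Vectors::mcols(sites)$crit2 <- crit2
  S4Vectors::mcols(sites)$crit3 <- crit3
  S4Vectors::mcols(sites)$pass <- crit1 & crit2 & crit3
  sites
}

#' Write off-target sites as TSV
#'
#' Columns mirror the site fields: locus (chrom, 0-based half-open interval,
#' strand), sequences, mismatch annotation, window source-base count, copy
#' count, and - when \code{\link{applyOffTargetFilters}} has been run - the
#' per-criterion verdicts.
#'
#' @param sites \code{GRanges} of off-target sites.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeOffTargetTsv <- function(sites, path) {
  mc <- as.data.frame(S4Vectors::mcols(sites))
  df <- cbind(data.frame(
    chrom = as.character(GenomicRanges::seqnames(sites)),
    start = GenomicRanges::start(sites) - 1L,
    end = GenomicRanges::end(sites),
    strand = as.character(GenomicRanges::strand(sites)),
    stringsAsFactors = FALSE), mc)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}
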