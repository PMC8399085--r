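# Genome-wide discovery of editable PAS sites. Two interchangeable engines:
# "direct" enumerates every guide via the placement geometry; "regex" compiles
# the motif+PAM geometry into explicit character-class patterns and decides
# editability from match existence alone.

#' Find all PAS motif occurrences on both strands
#'
#' Exact matching (overlaps included); reverse-strand occurrences are reported
#' with plus-strand intervals and strand \code{-}. Genomic N never matches.
#'
#' @param genome FASTA path, \code{DNAStringSet}, or named character vector.
#' @param motifs \code{PASMotifSpec} objects or hexamer strings
#'   (default: AATAAA and ATTAAA).
#' @param maskSoftmasked if \code{TRUE}, soft-masked (lowercase) bases are
#'   converted to N before matching; by default they are uppercased and
#'   scanned like any other base.
#' @return \code{GRanges} of hexamer spans with metadata column
#'   \code{hexamer} (the motif as read on its strand).
#' @export
findMotifSites <- function(genome, motifs = defaultPASMotifs(),
                           maskSoftmasked = FALSE) {
  seqs <- .asGenome(genome, maskSoftmasked)
  motifs <- .asMotifList(motifs)
  df <- .motifSiteTable(seqs, motifs)
  .sitesAsGRanges(df, seqs)
}

# data.frame(chrom, start0, strand, hexamer), deterministically sorted.
.motifSiteTable <- function(seqs, motifs) {
  rows <- list()
  for (chrom in names(seqs)) {
    subject <- Biostrings::DNAString(seqs[[chrom]])
    for (m in motifs) {
      hx <- m@hexamer
      plus <- Biostrings::start(Biostrings::matchPattern(hx, subject))
      if (length(plus))
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, start0 = plus - 1L, strand = "+", hexamer = hx,
          stringsAsFactors = FALSE)
      rcHits <- Biostrings::start(Biostrings::matchPattern(.revcomp(hx),
                                                           subject))
      if (length(rcHits))
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, start0 = rcHits - 1L, strand = "-", hexamer = hx,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(chrom = character(), start0 = integer(),
                      strand = character(), hexamer = character(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  df <- df[order(df$chrom, df$start0, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

.sitesAsGRanges <- function(df, seqs, extraMcols = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = factor(df$chrom, levels = names(seqs)),
    ranges = IRanges::IRanges(start = df$start0 + 1L, width = 6L),
    strand = df$strand,
    seqlengths = nchar(seqs))
  S4Vectors::mcols(gr)$hexamer <- df$hexamer
  if (!is.null(extraMcols))
    for (nm in names(extraMcols)) S4Vectors::mcols(gr)[[nm]] <- extraMcols[[nm]]
  gr
}

## Regex construction ---------------------------------------------------------

# Lay out one (disruptable position p, window position w) combination as a
# fixed-length vector of per-position character classes on the plus strand of
# the hexamer, intersecting protospacer [ACGT], hexamer literals and PAM IUPAC
# classes where they overlap. Returns NULL when the classes collide (combo is
# geometrically infeasible), else list(classes, hexOffset).
.layoutCombo <- function(editor, hexamer, p, w, strandMode) {
  P <- editor@protospacerLen
  pamSyms <- strsplit(editor@pam, "", fixed = TRUE)[[1]]
  M <- length(pamSyms)
  # coordinates relative to hexamer start h = 0
  if (strandMode == "coding") {
    g <- p - w                        # protospacer start
    pamSets <- lapply(pamSyms, function(s) IUPAC_SETS[[s]])
    pamFrom <- g + P
  } else {
    g <- p - 1L - P + w
    # reverse-strand PAM viewed on the plus strand: reverse order, complement
    pamSets <- rev(lapply(pamSyms, function(s)
      unname(.compBase[IUPAC_SETS[[s]]])))
    pamFrom <- g - M
  }
  lo <- min(0L, g, pamFrom)
  hi <- max(6L, g + P, pamFrom + M)
  sets <- rep(list(DNA_BASES), hi - lo)   # protospacer/gap default
  at <- function(x) x - lo + 1L
  # positions outside protospacer/PAM/hexamer cannot occur: the span is the
  # union of overlapping components, but guard by starting from ACGT anyway
  hexChars <- strsplit(hexamer, "", fixed = TRUE)[[1]]
  for (i in 0:5) {
    j <- at(i)
    sets[[j]] <- intersect(sets[[j]], hexChars[i + 1L])
    if (!length(sets[[j]])) return(NULL)
  }
  for (k in seq_len(M)) {
    j <- at(pamFrom + k - 1L)
    sets[[j]] <- intersect(sets[[j]], pamSets[[k]])
    if (!length(sets[[j]])) return(NULL)
  }
  classes <- vapply(sets, function(s)
    if (length(s) == 1L) s else paste0("[", paste(s, collapse = ""), "]"),
    character(1))
  list(classes = classes, hexOffset = -lo)
}

# All distinct per-combo patterns for (editor, motif, strandMode), with the
# hexamer offset from the match anchor. Used by the regex engine.
.regexAlternatives <- function(editor, motif, strandMode) {
  combos <- .comboTable(editor, motif, strandMode)
  pats <- character()
  offs <- integer()
  for (i in seq_len(nrow(combos))) {
    lay <- .layoutCombo(editor, motif@hexamer, combos$p[i], combos$w[i],
                        strandMode)
    if (is.null(lay)) next
    pat <- paste(lay$classes, collapse = "")
    if (!(pat %in% pats)) {
      pats <- c(pats, pat)
      offs <- c(offs, lay$hexOffset)
    }
  }
  if (!length(pats))
    stop("no geometrically feasible motif+PAM layout for motif ",
         motif@hexamer, " in ", strandMode,
         " mode (empty gap range under this editor)")
  data.frame(pattern = pats, hexOffset = offs, stringsAsFactors = FALSE)
}

#' Compile the editable-PAS geometry into a regular expression
#'
#' Returns a plus-strand pattern (for a plus-strand hexamer) whose match
#' existence at a hexamer is equivalent to "at least one valid guide exists in
#' \code{strandMode}". The pattern is an alternation of fixed-length runs of
#' explicit character classes - one per feasible (disruptable position,
#' window position) layout - with the hexamer span wrapped in a capture group;
#' no backreferences. For the default editor this is equivalent to the motif
#' followed by 10-16 arbitrary bases and an NGG (coding mode), or CCN followed
#' by 10-14 arbitrary bases and the motif (template mode), with the additional
#' guarantee that the full protospacer fits in the matched context.
#'
#' @inheritParams gapRange
#' @return a single pattern string (PCRE).
#' @examples
#' buildEditableRegex(editorSpec("abemax"), pasMotifSpec("ATTAAA"), "coding")
#' @export
buildEditableRegex <- function(editor, motif,
                               strandMode = c("coding", "template")) {
  strandMode <- match.arg(strandMode)
  alts <- .regexAlternatives(editor, motif, strandMode)
  withCapture <- vapply(seq_len(nrow(alts)), function(i) {
    # reinsert the capture group at class boundaries
    pat <- alts$pattern[i]
    off <- alts$hexOffset[i]
    classes <- .splitClasses(pat)
    paste0(paste(classes[seq_len(off)], collapse = ""),
           "(", paste(classes[off + 1:6], collapse = ""), ")",
           paste(classes[-seq_len(off + 6L)], collapse = ""))
  }, character(1))
  paste0("(?:", paste(withCapture, collapse = "|"), ")")
}

# split a concatenation of single bases and [..] classes back into elements
.splitClasses <- function(pat) {
  regmatches(pat, gregexpr("\\[[^]]*\\]|[ACGT]", pat))[[1]]
}

# 0-based hexamer starts (on the scanned strand) where some alternative
# matches; zero-width lookaheads make the search overlap-tolerant.
.regexHexStarts <- function(seq, alts) {
  hits <- integer()
  for (i in seq_len(nrow(alts))) {
    m <- gregexpr(paste0("(?=", alts$pattern[i], ")"), seq, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    hits <- c(hits, as.integer(m) - 1L + alts$hexOffset[i])
  }
  sort(unique(hits))
}

## Scan -----------------------------------------------------------------------

#' Scan a genome for editable polyadenylation signals
#'
#' Finds every occurrence of the given PAS motifs on both strands and decides,
#' per occurrence, whether an editor guide can disrupt it. The \code{direct}
#' engine enumerates all guide candidates via the placement geometry; the
#' \code{regex} engine decides editability from match existence of the
#' compiled patterns only (its guide table is empty and \code{guideCount} is
#' NA). Both engines flag exactly the same sites.
#'
#' @inheritParams findMotifSites
#' @param editor an \code{\linkS4class{EditorSpec}}.
#' @param engine \code{"direct"} (default) or \code{"regex"}.
#' @return an \code{\linkS4class{EditablePASScan}}.
#' @examples
#' g <- c(chr1 = paste0("ATTAAA", "TCATCTCATCTCAT", "TGGTT"))
#' scanEditablePAS(g, editorSpec("abemax"))
#' @export
scanEditablePAS <- function(genome, editor, motifs = defaultPASMotifs(),
                            engine = c("direct", "regex"),
                            maskSoftmasked = FALSE) {
  engine <- match.arg(engine)
  stopifnot(methods::is(editor, "EditorSpec"))
  seqs <- .asGenome(genome, maskSoftmasked)
  motifs <- .asMotifList(motifs)
  df <- .motifSiteTable(seqs, motifs)
  n <- nrow(df)
  edCoding <- edTemplate <- logical(n)
  guideCount <- integer(n)
  guideRows <- list()
  if (engine == "direct") {
    for (i in seq_len(n)) {
      g <- enumerateGuidesForSite(seqs[[df$chrom[i]]], df$start0[i],
                                  df$strand[i], editor,
                                  motifs[[df$hexamer[i]]])
      guideCount[i] <- nrow(g)
      if (nrow(g)) {
        edCoding[i] <- any(g$strandMode == "coding")
        edTemplate[i] <- any(g$strandMode == "template")
        g <- cbind(data.frame(siteIndex = i, chrom = df$chrom[i],
                              siteStart = df$start0[i],
                              siteStrand = df$strand[i],
                              hexamer = df$hexamer[i],
                              stringsAsFactors = FALSE), g)
        guideRows[[length(guideRows) + 1L]] <- g
      }
    }
  } else {
    # per motif x mode: editable hexamer starts per chrom and strand
    for (hx in names(motifs)) {
      idx <- which(df$hexamer == hx)
      if (!length(idx)) next
      for (mode in c("coding", "template")) {
        if (!length(disruptablePositions(motifs[[hx]], mode))) next
        alts <- .regexAlternatives(editor, motifs[[hx]], mode)
        for (chrom in unique(df$chrom[idx])) {
          seq <- seqs[[chrom]]
          L <- nchar(seq)
          plusHits <- .regexHexStarts(seq, alts)
          rcHits <- .regexHexStarts(.revcomp(seq), alts)
          minusHits <- L - rcHits - 6L
          sel <- idx[df$chrom[idx] == chrom]
          hit <- (df$strand[sel] == "+" & df$start0[sel] %in% plusHits) |
                 (df$strand[sel] == "-" & df$start0[sel] %in% minusHits)
          if (mode == "coding") edCoding[sel] <- edCoding[sel] | hit
          else edTemplate[sel] <- edTemplate[sel] | hit
        }
      }
    }
    guideCount <- rep(NA_integer_, n)
  }
  sites <- .sitesAsGRanges(df, seqs, extraMcols = list(
    editable = edCoding | edTemplate,
    editableCoding = edCoding,
    editableTemplate = edTemplate,
    guideCount = guideCount))
  guides <- if (length(guideRows))
    S4Vectors::DataFrame(do.call(rbind, guideRows))
  else
    S4Vectors::DataFrame(cbind(
      data.frame(siteIndex = integer(), chrom = character(),
                 siteStart = integer(), siteStrand = character(),
                 hexamer = character(), stringsAsFactors = FALSE),
      .emptyGuides()))
  methods::new("EditablePASScan", sites = sites, guides = guides,
               editor = editor, motifs = motifs, engine = engine)
}

#' @describeIn scanEditablePAS site ranges accessor.
#' @param x an \code{EditablePASScan}.
#' @export
pasSites <- function(x) x@sites

#' @describeIn scanEditablePAS guide table accessor.
#' @export
pasGuides <- function(x) x@guides

#' @describeIn scanEditablePAS engine accessor.
#' @export
scanEngine <- function(x) x@engine

setMethod("show", "EditablePASScan", function(object) {
  s <- object@sites
  cat("EditablePASScan (", object@engine, " engine, editor '",
      object@editor@name, "')\n", sep = "")
  cat("  ", length(s), " motif site(s), ",
      sum(S4Vectors::mcols(s)$editable), " editable\n", sep = "")
  if (object@engine == "direct")
    cat("  ", nrow(object@guides), " guide candidate(s)\n", sep = "")
})

## Output ---------------------------------------------------------------------

#' Write scan results as BED6
#'
#' One line per motif site: chrom, hexamer start, hexamer end (0-based
#' half-open), name = motif hexamer, score = guide count (0 when the engine
#' did not enumerate guides), strand. Deterministically sorted by
#' (chrom, start, strand).
#'
#' @param scan an \code{\linkS4class{EditablePASScan}}.
#' @param path output file.
#' @param editableOnly write only editable sites (default FALSE).
#' @return invisibly, the path.
#' @export
writeScanBed <- function(scan, path, editableOnly = FALSE) {
  s <- scan@sites
  mc <- S4Vectors::mcols(s)
  keep <- if (editableOnly) which(mc$editable) else seq_along(s)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(s))[keep],
    start = GenomicRanges::start(s)[keep] - 1L,
    end = GenomicRanges::end(s)[keep],
    name = mc$hexamer[keep],
    score = ifelse(is.na(mc$guideCount[keep]), 0L, mc$guideCount[keep]),
    strand = as.character(GenomicRanges::strand(s))[keep],
    stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$strand), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(df))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write the guide table as TSV
#'
#' One row per guide candidate with its site key, placement intervals
#' (0-based half-open), guide-strand protospacer and PAM sequences, window
#' position(s), captured disruptable positions and predicted mutant
#' hexamer(s). A header line is always written.
#'
#' @inheritParams writeScanBed
#' @return invisibly, the path.
#' @export
writeGuidesTsv <- function(scan, path) {
  g <- as.data.frame(scan@guides)
  cols <- c("chrom", "siteStart", "siteStrand", "hexamer", "guideStrand",
            "strandMode", "protoStart", "protoEnd", "pamStart", "pamEnd",
            "protospacer", "pam", "windowPositions", "capturedPositions",
            "predictedHexamers")
  if (!nrow(g)) {
    g <- as.data.frame(matrix(character(), ncol = length(cols),
                              dimnames = list(NULL, cols)))
  } else {
    g <- g[order(g$chrom, g$siteStart, g$siteStrand, g$protoStart,
                 g$guideStrand), cols, drop = FALSE]
  }
  utils::write.table(g, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a scan BED6 file back as GRanges
#'
#' @param path BED6 file written by \code{\link{writeScanBed}} (or any BED6
#'   with motif name and guide-count score).
#' @return \code{GRanges} with \code{name} and \code{score} metadata.
#' @export
readScanBed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(name = character(),
                                                 score = integer())
    return(gr)
  }
  rtracklayer::import(path, format = "BED")
}
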