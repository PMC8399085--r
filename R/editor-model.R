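#' Construct an EditorSpec
#'
#' @param name label for the editor.
#' @param pam IUPAC PAM pattern matched immediately 3' of the protospacer on
#'   the protospacer strand (default \code{"NGG"}, SpCas9).
#' @param protospacerLen protospacer length (default 20).
#' @param window inclusive activity-window bounds, 1-based from the
#'   protospacer 5' (PAM-distal) end. Default \code{c(4, 8)}, the positions at
#'   which ABEmax-class deaminases act efficiently.
#' @param conversion \code{c(source, product)} base pair; default A to G.
#' @return an \code{\linkS4class{EditorSpec}}.
#' @examples
#' abe <- editorSpec("spcas9-abemax")
#' activityWindow(abe)
#' @export
editorSpec <- function(name, pam = "NGG", protospacerLen = 20L,
                       window = c(4L, 8L), conversion = c("A", "G")) {
  methods::new("EditorSpec", name = as.character(name),
               pam = toupper(pam),
               protospacerLen = as.integer(protospacerLen),
               window = as.integer(window),
               conversion = toupper(conversion))
}

#' Load a named editor preset
#'
#' Presets are shipped as a small YAML config
#' (\code{inst/extdata/editor-presets.yaml}); users may point \code{file} at
#' their own config with the same layout to define further editors.
#'
#' @param name preset key, e.g. \code{"spcas9-abemax"} or
#'   \code{"spcas9-abe7.10"}.
#' @param file YAML config path.
#' @return an \code{\linkS4class{EditorSpec}}.
#' @export
editorPreset <- function(name,
                         file = system.file("extdata", "editor-presets.yaml",
                                            package = "pasedit")) {
  cfg <- yaml::read_yaml(file)
  if (!name %in% names(cfg))
    stop("unknown editor preset '", name, "'; available: ",
         paste(names(cfg), collapse = ", "))
  p <- cfg[[name]]
  editorSpec(name, pam = p$pam, protospacerLen = p$protospacer_len,
             window = c(p$window_lo, p$window_hi),
             conversion = c(p$source, p$product))
}

#' Construct a PASMotifSpec
#'
#' For the two canonical PAS hexamers AATAAA and ATTAAA the disruptable
#' position defaults encode the adenine-base-editor rules: the adenines at the
#' last three hexamer positions on the coding strand, and the adenine pairing
#' with the middle thymine on the template strand. For any other hexamer both
#' position sets must be given explicitly.
#'
#' @param hexamer length-6 DNA string.
#' @param codingDisruptable 1-based hexamer positions editable on the coding
#'   strand (must carry \code{sourceBase}).
#' @param templateDisruptable 1-based positions editable via the template
#'   strand (must carry the complement of \code{sourceBase}).
#' @param sourceBase the editor source base the sets refer to (default A).
#' @return a \code{\linkS4class{PASMotifSpec}}.
#' @examples
#' pasMotifSpec("ATTAAA")
#' @export
pasMotifSpec <- function(hexamer, codingDisruptable = NULL,
                         templateDisruptable = NULL, sourceBase = "A") {
  hexamer <- toupper(hexamer)
  canonical <- c("AATAAA", "ATTAAA")
  if (is.null(codingDisruptable) && is.null(templateDisruptable)) {
    if (!(hexamer %in% canonical) || sourceBase != "A")
      stop("disruptable-position defaults exist only for AATAAA/ATTAAA with ",
           "source base A; supply codingDisruptable/templateDisruptable")
    codingDisruptable <- 4:6
    templateDisruptable <- 3L
  }
  methods::new("PASMotifSpec", hexamer = hexamer,
               codingDisruptable = sort(unique(as.integer(codingDisruptable))),
               templateDisruptable =
                 sort(unique(as.integer(templateDisruptable))),
               sourceBase = toupper(sourceBase))
}

#' The default PAS motif set (AATAAA and ATTAAA)
#' @return named list of \code{\linkS4class{PASMotifSpec}}.
#' @export
defaultPASMotifs <- function() {
  list(AATAAA = pasMotifSpec("AATAAA"), ATTAAA = pasMotifSpec("ATTAAA"))
}

# Coerce a motif argument (PASMotifSpec, list thereof, or character hexamers)
# to a named list of PASMotifSpec.
.asMotifList <- function(motifs) {
  if (methods::is(motifs, "PASMotifSpec")) motifs <- list(motifs)
  if (is.character(motifs)) motifs <- lapply(motifs, pasMotifSpec)
  if (!is.list(motifs) ||
      !all(vapply(motifs, methods::is, logical(1), "PASMotifSpec")))
    stop("motifs must be PASMotifSpec objects or hexamer strings")
  names(motifs) <- vapply(motifs, function(m) m@hexamer, character(1))
  if (anyDuplicated(names(motifs))) stop("duplicate motif hexamers")
  motifs
}

## Accessors ------------------------------------------------------------------

#' @describeIn editorSpec PAM pattern accessor.
#' @param x an \code{EditorSpec}.
#' @export
pamPattern <- function(x) x@pam

#' @describeIn editorSpec protospacer length accessor.
#' @export
protospacerLength <- function(x) x@protospacerLen

#' @describeIn editorSpec activity window accessor (\code{c(lo, hi)}).
#' @export
activityWindow <- function(x) x@window

#' @describeIn editorSpec base conversion accessor (\code{c(source, product)}).
#' @export
baseConversion <- function(x) x@conversion

#' @describeIn pasMotifSpec hexamer accessor.
#' @param x a \code{PASMotifSpec}.
#' @export
pasHexamer <- function(x) x@hexamer

#' Disruptable hexamer positions for a strand mode
#' @param motif a \code{PASMotifSpec}.
#' @param strandMode \code{"coding"} or \code{"template"}.
#' @return integer vector of 1-based hexamer positions.
#' @export
disruptablePositions <- function(motif, strandMode = c("coding", "template")) {
  strandMode <- match.arg(strandMode)
  if (strandMode == "coding") motif@codingDisruptable
  else motif@templateDisruptable
}

setMethod("show", "EditorSpec", function(object) {
  cat("EditorSpec '", object@name, "': PAM ", object@pam,
      ", protospacer ", object@protospacerLen, " nt, window ",
      object@window[1], "-", object@window[2], ", ",
      object@conversion[1], "->", object@conversion[2], "\n", sep = "")
})

setMethod("show", "PASMotifSpec", function(object) {
  cat("PASMotifSpec ", object@hexamer,
      ": coding-disruptable {", paste(object@codingDisruptable, collapse = ","),
      "}, template-disruptable {",
      paste(object@templateDisruptable, collapse = ","), "}\n", sep = "")
})

## Placement geometry ---------------------------------------------------------

#' Enumerate guide placements that edit one genomic base
#'
#' Finds every protospacer placement, on either strand, for which the base at
#' \code{targetPos} (read on \code{targetStrand}, which is the strand carrying
#' the protospacer) falls at an activity-window position and the PAM
#' immediately 3' of the protospacer matches the editor's IUPAC pattern.
#' Placements extending beyond the sequence, or whose protospacer/PAM contain
#' non-ACGT characters, are never emitted.
#'
#' @param seq one chromosome as a plain uppercase character string.
#' @param targetPos 0-based plus-strand coordinate of the base to edit.
#' @param targetStrand \code{"+"} or \code{"-"}; the base at \code{targetPos}
#'   read on this strand must equal the editor's source base.
#' @param editor an \code{\linkS4class{EditorSpec}}.
#' @return data.frame with one row per placement: \code{targetPos},
#'   \code{guideStrand}, \code{windowPos} (1-based protospacer position of the
#'   edited base), 0-based half-open plus-strand intervals
#'   \code{protoStart}/\code{protoEnd}/\code{pamStart}/\code{pamEnd}, and the
#'   \code{protospacer} and \code{pam} sequences as read on the guide strand.
#' @examples
#' seq <- paste0("ATTAAA", "TCATCTCATCTCAT", "TGG")
#' placementsForTarget(seq, 3, "+", editorSpec("abemax"))
#' @export
placementsForTarget <- function(seq, targetPos, targetStrand, editor) {
  stopifnot(methods::is(editor, "EditorSpec"),
            targetStrand %in% c("+", "-"))
  L <- nchar(seq)
  targetPos <- as.integer(targetPos)
  if (is.na(targetPos) || targetPos < 0L || targetPos >= L)
    stop("targetPos out of range [0, ", L, ")")
  plusBase <- substr(seq, targetPos + 1L, targetPos + 1L)
  base <- if (targetStrand == "+") plusBase else .comp(plusBase)
  src <- editor@conversion[1]
  if (!(base %in% DNA_BASES)) {
    warning("unscannable base '", base, "' at position ", targetPos)
    return(.emptyPlacements())
  }
  if (base != src)
    stop("base at targetPos on targetStrand is ", base,
         ", not the editor source base ", src)
  P <- editor@protospacerLen
  M <- nchar(editor@pam)
  rows <- list()
  for (w in seq(editor@window[1], editor@window[2])) {
    if (targetStrand == "+") {
      ps <- targetPos - (w - 1L)
      pamS <- ps + P
    } else {
      ps <- targetPos - P + w
      pamS <- ps - M
    }
    pe <- ps + P
    pamE <- pamS + M
    if (min(ps, pamS) < 0L || max(pe, pamE) > L) next
    protoPlus <- substr(seq, ps + 1L, pe)
    pamPlus <- substr(seq, pamS + 1L, pamE)
    if (targetStrand == "+") {
      proto <- protoPlus; pam <- pamPlus
    } else {
      proto <- .revcomp(protoPlus); pam <- .revcomp(pamPlus)
    }
    if (!.isACGT(proto) || !.isACGT(pam)) next
    if (!.iupacMatch(editor@pam, pam)) next
    rows[[length(rows) + 1L]] <- data.frame(
      targetPos = targetPos, guideStrand = targetStrand, windowPos = w,
      protoStart = ps, protoEnd = pe, pamStart = pamS, pamEnd = pamE,
      protospacer = proto, pam = pam, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(.emptyPlacements())
  do.call(rbind, rows)
}

.emptyPlacements <- function() {
  data.frame(targetPos = integer(), guideStrand = character(),
             windowPos = integer(), protoStart = integer(),
             protoEnd = integer(), pamStart = integer(), pamEnd = integer(),
             protospacer = character(), pam = character(),
             stringsAsFactors = FALSE)
}

# One row per (disruptable position, window position) combination with the
# hexamer/PAM gap it implies. Coding gap: motif 3' end to PAM start. Template
# gap: PAM end to motif 5' start (plus-strand view of the reverse-strand
# guide). Both reduce to closed-form arithmetic in protospacer coordinates.
.comboTable <- function(editor, motif, strandMode) {
  pos <- disruptablePositions(motif, strandMode)
  if (!length(pos))
    stop("motif ", motif@hexamer, " has no disruptable positions in ",
         strandMode, " mode")
  P <- editor@protospacerLen
  win <- seq(editor@window[1], editor@window[2])
  grid <- expand.grid(p = pos, w = win)
  grid$gap <- if (strandMode == "coding") (P - 6L) - (grid$w - grid$p)
              else (P + 1L) - grid$p - grid$w
  grid
}

#' Range of hexamer-PAM gaps admitting a valid guide
#'
#' For the requested strand mode, returns the inclusive range of nucleotide
#' gaps between the hexamer and the PAM over all (disruptable position,
#' activity-window position) combinations: motif 3' end to PAM start in coding
#' mode, PAM end to motif 5' start (plus-strand view of the reverse-strand
#' guide) in template mode.
#'
#' @inheritParams disruptablePositions
#' @param editor an \code{\linkS4class{EditorSpec}}.
#' @return integer \code{c(lo, hi)}.
#' @examples
#' gapRange(editorSpec("abemax"), pasMotifSpec("AATAAA"), "coding")
#' @export
gapRange <- function(editor, motif, strandMode = c("coding", "template")) {
  strandMode <- match.arg(strandMode)
  gaps <- .comboTable(editor, motif, strandMode)$gap
  c(min(gaps), max(gaps))
}

#' Predict the hexamer after a base edit
#'
#' Coding mode substitutes the editor's source base with its product at the
#' given hexamer position; template mode edits the paired base on the opposite
#' strand, so the coding-strand base becomes the complement of the product
#' (for an adenine base editor: T to C, e.g. ATTAAA to ATCAAA).
#'
#' @inheritParams gapRange
#' @param position 1-based hexamer position; must be disruptable for
#'   \code{strandMode}.
#' @param editor optional \code{\linkS4class{EditorSpec}} supplying the base
#'   conversion; defaults to the adenine-base-editor A-to-G conversion.
#' @return the mutant hexamer (length-6 string).
#' @export
predictedEditedHexamer <- function(motif, position,
                                   strandMode = c("coding", "template"),
                                   editor = NULL) {
  strandMode <- match.arg(strandMode)
  position <- as.integer(position)
  if (!(position %in% disruptablePositions(motif, strandMode)))
    stop("position ", position, " is not ", strandMode,
         "-disruptable for motif ", motif@hexamer)
  conv <- if (is.null(editor)) c(motif@sourceBase, "G") else editor@conversion
  .editedHexamer(motif@hexamer, position, strandMode, conv)
}

# Core substitution used by both the exported helper and the scan machinery,
# parameterised by the editor's (source, product) pair.
.editedHexamer <- function(hexamer, position, strandMode, conversion) {
  chars <- strsplit(hexamer, "", fixed = TRUE)[[1]]
  chars[position] <- if (strandMode == "coding") conversion[2]
                     else unname(.compBase[conversion[2]])
  paste(chars, collapse = "")
}

#' Enumerate guide candidates disrupting one PAS site
#'
#' Unions placements over all disruptable positions in both strand modes.
#' Placements sharing a protospacer interval are merged into a single guide
#' candidate listing every disruptable position its window captures; a site is
#' "editable" iff the returned set is non-empty.
#'
#' @inheritParams placementsForTarget
#' @param hexStart 0-based plus-strand start of the hexamer span.
#' @param strand strand the hexamer is read on (\code{"+"}/\code{"-"}).
#' @param motif the \code{\linkS4class{PASMotifSpec}} the site was called for;
#'   the sequence at the site must spell its hexamer on \code{strand}.
#' @return data.frame with one row per guide candidate: placement coordinates
#'   (as in \code{\link{placementsForTarget}}), \code{strandMode},
#'   comma-separated \code{capturedPositions} / \code{windowPositions} /
#'   \code{predictedHexamers}, and \code{protospacer}/\code{pam}.
#' @export
enumerateGuidesForSite <- function(seq, hexStart, strand, editor, motif) {
  stopifnot(strand %in% c("+", "-"))
  hexStart <- as.integer(hexStart)
  plus6 <- substr(seq, hexStart + 1L, hexStart + 6L)
  observed <- if (strand == "+") plus6 else .revcomp(plus6)
  if (!identical(observed, motif@hexamer))
    stop("site hexamer mismatch: sequence reads '", observed,
         "' on strand ", strand, ", motif is ", motif@hexamer)
  hexPlusPos <- function(p) if (strand == "+") hexStart + p - 1L
                            else hexStart + 6L - p
  collect <- list()
  for (mode in c("coding", "template")) {
    pos <- disruptablePositions(motif, mode)
    if (!length(pos)) next
    guideStrand <- if (mode == "coding") strand else setdiff(c("+", "-"), strand)
    for (p in pos) {
      pl <- placementsForTarget(seq, hexPlusPos(p), guideStrand, editor)
      if (!nrow(pl)) next
      pl$hexPosition <- p
      pl$strandMode <- mode
      pl$predicted <- .editedHexamer(motif@hexamer, p, mode, editor@conversion)
      collect[[length(collect) + 1L]] <- pl
    }
  }
  if (!length(collect)) return(.emptyGuides())
  all <- do.call(rbind, collect)
  key <- paste(all$guideStrand, all$protoStart, sep = ":")
  out <- lapply(split(all, key), function(g) {
    o <- order(g$hexPosition)
    g <- g[o, , drop = FALSE]
    data.frame(
      guideStrand = g$guideStrand[1], strandMode = g$strandMode[1],
      protoStart = g$protoStart[1], protoEnd = g$protoEnd[1],
      pamStart = g$pamStart[1], pamEnd = g$pamEnd[1],
      protospacer = g$protospacer[1], pam = g$pam[1],
      capturedPositions = paste(g$hexPosition, collapse = ","),
      windowPositions = paste(g$windowPos, collapse = ","),
      predictedHexamers = paste(unique(g$predicted), collapse = ","),
      nCaptured = nrow(g), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$protoStart, out$guideStrand), , drop = FALSE]
}

.emptyGuides <- function() {
  data.frame(guideStrand = character(), strandMode = character(),
             protoStart = integer(), protoEnd = integer(),
             pamStart = integer(), pamEnd = integer(),
             protospacer = character(), pam = character(),
             capturedPositions = character(), windowPositions = character(),
             predictedHexamers = character(), nCaptured = integer(),
             stringsAsFactors = FALSE)
}
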