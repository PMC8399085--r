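#' EditorSpec: a base editor's targeting rules
#'
#' Bundles everything the placement geometry needs to know about a base
#' editor: the Cas PAM (an IUPAC pattern matched immediately 3' of the
#' protospacer on the protospacer strand), the protospacer length, the
#' activity window (inclusive 1-based positions counted from the protospacer
#' 5', PAM-distal end) and the base conversion the deaminase performs.
#'
#' @slot name human-readable label.
#' @slot pam IUPAC DNA pattern, e.g. \code{"NGG"}.
#' @slot protospacerLen protospacer length in nt (20 for SpCas9 guides).
#' @slot window integer length-2, inclusive window bounds \code{c(lo, hi)}.
#' @slot conversion character length-2 \code{c(source, product)}; an adenine
#'   base editor converts A to G.
#' @exportClass EditorSpec
setClass("EditorSpec", representation(
  name = "character",
  pam = "character",
  protospacerLen = "integer",
  window = "integer",
  conversion = "character"
))

setValidity("EditorSpec", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "name must be a non-empty string")
  if (length(object@pam) != 1L || !.isIupac(object@pam))
    msg <- c(msg, "pam must be a non-empty IUPAC DNA pattern")
  if (length(object@protospacerLen) != 1L || is.na(object@protospacerLen) ||
      object@protospacerLen < 1L)
    msg <- c(msg, "protospacerLen must be a positive integer")
  if (length(object@window) != 2L || anyNA(object@window) ||
      object@window[1] < 1L || object@window[1] > object@window[2] ||
      object@window[2] > object@protospacerLen)
    msg <- c(msg, "window must satisfy 1 <= lo <= hi <= protospacerLen")
  if (length(object@conversion) != 2L ||
      !all(object@conversion %in% DNA_BASES) ||
      object@conversion[1] == object@conversion[2])
    msg <- c(msg, "conversion must be two distinct bases (source, product)")
  if (length(msg)) msg else TRUE
})

#' PASMotifSpec: a polyadenylation-signal hexamer and its disruptable positions
#'
#' A PAS hexamer together with the 1-based hexamer positions an adenine base
#' editor can disrupt. Coding-strand positions carry the editor's source base
#' (adenine) on the strand the hexamer is read from; template-strand positions
#' carry its complement (thymine), so the edited adenine sits on the opposite
#' strand and the coding-strand base becomes the complement of the product
#' (T to C for an ABE, e.g. ATTAAA to ATCAAA).
#'
#' @slot hexamer length-6 DNA string over ACGT.
#' @slot codingDisruptable integer vector of 1-based hexamer positions.
#' @slot templateDisruptable integer vector of 1-based hexamer positions.
#' @slot sourceBase the editor source base the position sets were validated
#'   against (kept so validity is self-contained).
#' @exportClass PASMotifSpec
setClass("PASMotifSpec", representation(
  hexamer = "character",
  codingDisruptable = "integer",
  templateDisruptable = "integer",
  sourceBase = "character"
))

setValidity("PASMotifSpec", function(object) {
  msg <- character()
  hx <- object@hexamer
  if (length(hx) != 1L || nchar(hx) != 6L || !.isACGT(hx))
    msg <- c(msg, "hexamer must be a length-6 string over {A,C,G,T}")
  if (length(object@sourceBase) != 1L || !(object@sourceBase %in% DNA_BASES))
    msg <- c(msg, "sourceBase must be a single DNA base")
  pos <- c(object@codingDisruptable, object@templateDisruptable)
  if (length(pos) && (anyNA(pos) || any(pos < 1L | pos > 6L)))
    msg <- c(msg, "disruptable positions must lie in 1..6")
  if (!length(msg)) {
    chars <- strsplit(hx, "", fixed = TRUE)[[1]]
    src <- object@sourceBase
    bad <- object@codingDisruptable[chars[object@codingDisruptable] != src]
    if (length(bad))
      msg <- c(msg, paste0("coding-disruptable position(s) ",
                           paste(bad, collapse = ","),
                           " do not carry the source base ", src))
    cmp <- unname(.compBase[src])
    bad <- object@templateDisruptable[chars[object@templateDisruptable] != cmp]
    if (length(bad))
      msg <- c(msg, paste0("template-disruptable position(s) ",
                           paste(bad, collapse = ","),
                           " do not carry the source-base complement ", cmp))
  }
  if (length(msg)) msg else TRUE
})

#' OffTargetQuery: a protospacer+PAM query for near-match enumeration
#'
#' @slot protospacer concrete protospacer sequence (guide-strand, 5' to 3').
#' @slot pam IUPAC PAM pattern.
#' @slot maxMismatch maximum total protospacer mismatches retained.
#' @slot seedLength PAM-proximal protospacer positions counted as seed.
#' @exportClass OffTargetQuery
setClass("OffTargetQuery", representation(
  protospacer = "character",
  pam = "character",
  maxMismatch = "integer",
  seedLength = "integer"
))

setValidity("OffTargetQuery", function(object) {
  msg <- character()
  if (length(object@protospacer) != 1L || !.isACGT(object@protospacer))
    msg <- c(msg, "protospacer must be a non-empty string over {A,C,G,T}")
  if (length(object@pam) != 1L || !.isIupac(object@pam))
    msg <- c(msg, "pam must be a non-empty IUPAC pattern")
  n <- nchar(object@protospacer)
  if (length(object@maxMismatch) != 1L || is.na(object@maxMismatch) ||
      object@maxMismatch < 0L || object@maxMismatch > n)
    msg <- c(msg, "maxMismatch must lie in 0..protospacer length")
  if (length(object@seedLength) != 1L || is.na(object@seedLength) ||
      object@seedLength < 0L || object@seedLength > n)
    msg <- c(msg, "seedLength must lie in 0..protospacer length")
  if (length(msg)) msg else TRUE
})

#' EditablePASScan: the result of a genome-wide editable-PAS scan
#'
#' Container returned by \code{\link{scanEditablePAS}}. \code{sites} holds one
#' range per motif occurrence (hexamer span, 1-based closed as usual for
#' GRanges) with metadata columns \code{hexamer}, \code{editable},
#' \code{editableCoding}, \code{editableTemplate} and \code{guideCount};
#' \code{guides} holds one row per guide candidate (direct engine only; the
#' regex engine decides editability without enumerating guides and leaves it
#' empty with \code{guideCount} NA).
#'
#' @slot sites \code{GRanges} of motif occurrences.
#' @slot guides \code{DFrame} of guide candidates keyed by \code{siteIndex}.
#' @slot editor the \code{EditorSpec} used.
#' @slot motifs list of \code{PASMotifSpec} used.
#' @slot engine \code{"direct"} or \code{"regex"}.
#' @exportClass EditablePASScan
setClass("EditablePASScan", representation(
  sites = "GRanges",
  guides = "DFrame",
  editor = "EditorSpec",
  motifs = "list",
  engine = "character"
))

setValidity("EditablePASScan", function(object) {
  msg <- character()
  need <- c("hexamer", "editable", "editableCoding", "editableTemplate",
            "guideCount")
  have <- colnames(S4Vectors::mcols(object@sites))
  if (!all(need %in% have))
    msg <- c(msg, paste("sites must carry metadata columns:",
                        paste(setdiff(need, have), collapse = ", ")))
  if (!(object@engine %in% c("direct", "regex")))
    msg <- c(msg, "engine must be 'direct' or 'regex'")
  if (!length(msg) && object@engine == "direct") {
    gc <- S4Vectors::mcols(object@sites)$guideCount
    ed <- S4Vectors::mcols(object@sites)$editable
    if (anyNA(gc) || any(ed != (gc >= 1L)))
      msg <- c(msg, "direct engine: editable must equal guideCount >= 1")
    if (nrow(object@guides) != sum(gc))
      msg <- c(msg, "guide rows must sum to the site guide counts")
  }
  if (length(msg)) msg else TRUE
})
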