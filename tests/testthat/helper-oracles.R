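# Test-side helpers: random genomes and a brute-force placement oracle kept
# independent of the package's geometry code (own complement table, own IUPAC
# sets, exhaustive protospacer-start enumeration).

randomGenome <- function(L, prob = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)) {
  paste(sample(names(prob), L, replace = TRUE, prob = prob), collapse = "")
}

testEditor <- function() editorSpec("spcas9-abemax")

.tIUPAC <- list(A = "A", C = "C", G = "G", T = "T", N = c("A", "C", "G", "T"),
                R = c("A", "G"), Y = c("C", "T"))
.tCOMP <- c(A = "T", C = "G", G = "C", T = "A")

# every protospacer start on both strands, filtered by PAM match, window
# containment of the target, source base and pure-ACGT content
bruteforcePlacements <- function(seq, targetPos, targetStrand, editor) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(chars)
  P <- protospacerLength(editor)
  pamSyms <- strsplit(pamPattern(editor), "", fixed = TRUE)[[1]]
  M <- length(pamSyms)
  win <- activityWindow(editor)
  src <- baseConversion(editor)[1]
  found <- list()
  for (g in 0:(L - 1)) {
    if (targetStrand == "+") { pamS <- g + P } else { pamS <- g - M }
    if (min(g, pamS) < 0 || max(g + P, pamS + M) > L) next
    w <- if (targetStrand == "+") targetPos - g + 1L else g + P - targetPos
    if (w < win[1] || w > win[2]) next
    proto <- chars[(g + 1):(g + P)]
    pam <- chars[(pamS + 1):(pamS + M)]
    if (targetStrand == "-") {
      proto <- rev(unname(.tCOMP[proto]))
      pam <- rev(unname(.tCOMP[pam]))
    }
    if (anyNA(match(c(proto, pam), names(.tCOMP)))) next
    tb <- chars[targetPos + 1]
    tb <- if (targetStrand == "+") tb else unname(.tCOMP[tb])
    if (is.na(tb) || tb != src) next
    pamOK <- TRUE
    for (k in seq_len(M)) {
      if (!(pam[k] %in% .tIUPAC[[pamSyms[k]]])) { pamOK <- FALSE; break }
    }
    if (!pamOK) next
    found[[length(found) + 1L]] <- c(strand = targetStrand, g = g, w = w)
  }
  found
}

placementKeys <- function(df) {
  if (!nrow(df)) return(character())
  sort(paste(df$guideStrand, df$protoStart, df$windowPos))
}

bruteforceKeys <- function(lst) {
  if (!length(lst)) return(character())
  sort(vapply(lst, function(x) paste(x["strand"], x["g"], x["w"]),
              character(1), USE.NAMES = FALSE))
}

siteKeys <- function(gr) {
  paste(as.character(GenomicRanges::seqnames(gr)),
        GenomicRanges::start(gr) - 1L,
        as.character(GenomicRanges::strand(gr)),
        S4Vectors::mcols(gr)$hexamer)
}
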