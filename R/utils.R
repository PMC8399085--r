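# Low-level sequence utilities shared across modules. All genomic coordinates
# handled here are 0-based half-open on the plus strand unless noted; window
# positions are 1-based from the protospacer 5' (PAM-distal) end.

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC code -> set of concrete bases it matches. A genomic N never satisfies
# any symbol, including pattern N: ambiguous reference sequence is treated as
# unscannable, so protospacers/PAMs containing N are never emitted.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.isIupac <- function(x) {
  nzchar(x) && all(strsplit(x, "", fixed = TRUE)[[1]] %in% names(IUPAC_SETS))
}

.isACGT <- function(x) {
  nzchar(x) && !grepl("[^ACGT]", x)
}

.compBase <- c(
  A = "T", C = "G", G = "C", T = "A", N = "N",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D"
)

#' Reverse complement of character DNA strings
#'
#' Strand-aware helpers used throughout; `Biostrings::reverseComplement()` is
#' used for whole chromosomes, this for short character fragments.
#' @param x character vector of DNA strings (IUPAC letters allowed).
#' @return character vector of reverse complements.
#' @keywords internal
.revcomp <- function(x) {
  vapply(x, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    paste(rev(unname(.compBase[chars])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

.comp <- function(x) {
  chartr("ACGTNRYSWKMBVDH", "TGCANYRSWMKVBHD", x)
}

# Does `subject` (concrete bases) satisfy the IUPAC `pattern`? Both strings,
# equal length. Genomic non-ACGT characters fail every pattern symbol.
.iupacMatch <- function(pattern, subject) {
  if (nchar(pattern) != nchar(subject)) return(FALSE)
  p <- strsplit(pattern, "", fixed = TRUE)[[1]]
  s <- strsplit(subject, "", fixed = TRUE)[[1]]
  for (i in seq_along(p)) {
    set <- IUPAC_SETS[[p[i]]]
    if (is.null(set) || !(s[i] %in% set)) return(FALSE)
  }
  TRUE
}

# IUPAC symbol -> regex character class over concrete bases (pattern N is the
# explicit class [ACGT], never the regex wildcard, so genomic N cannot match).
.iupacClass <- function(sym) {
  set <- IUPAC_SETS[[sym]]
  if (is.null(set)) stop("not an IUPAC DNA symbol: ", sym)
  if (length(set) == 1L) set else paste0("[", paste(set, collapse = ""), "]")
}

# Normalise a genome argument (file path, DNAStringSet, or named character
# vector) to a named uppercase character vector. Sequence names are taken
# verbatim from FASTA headers up to the first whitespace. With
# `maskSoftmasked`, soft-masked (lowercase) bases become N before matching.
.asGenome <- function(genome, maskSoftmasked = FALSE) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- tryCatch(
      Biostrings::readDNAStringSet(genome),
      error = function(e) stop("failed to read FASTA '", genome, "': ",
                               conditionMessage(e), call. = FALSE)
    )
  }
  if (methods::is(genome, "DNAStringSet")) {
    seqs <- as.character(genome)
  } else if (is.character(genome)) {
    seqs <- genome
  } else {
    stop("genome must be a FASTA path, DNAStringSet, or named character vector")
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    if (length(seqs) == 1L && is.null(names(seqs))) {
      names(seqs) <- "seq1"
    } else {
      stop("all genome sequences must be named")
    }
  }
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) stop("duplicate sequence names in genome")
  if (maskSoftmasked) seqs <- gsub("[acgtn]", "N", seqs)
  toupper(seqs)
}

# Evaluate with a private RNG stream; the caller's .Random.seed is untouched.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
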