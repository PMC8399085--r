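# Deterministic synthetic-genome fixtures with planted editable PAS sites,
# decoys and off-target loci, plus the brute-force oracles used as ground
# truth. The oracles deliberately share no code with the scan engines or the
# off-target module: they re-implement complementation, IUPAC matching and the
# window geometry from scratch with naive loops.

## Oracles --------------------------------------------------------------------

.O_COMP <- c(A = "T", C = "G", G = "C", T = "A")
.O_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.oRevcomp <- function(chars) rev(unname(.O_COMP[chars]))

.oPamOK <- function(chars, pamSyms) {
  if (length(chars) != length(pamSyms)) return(FALSE)
  for (k in seq_along(pamSyms)) {
    set <- .O_IUPAC[[pamSyms[k]]]
    if (is.na(chars[k]) || !(chars[k] %in% set)) return(FALSE)
  }
  TRUE
}

# Distinct guide placements (keyed by strand and protospacer start) that edit
# a disruptable base of the hexamer at 0-based `hexStart` on `strand`.
# Exhaustive: every disruptable position x window position x strand mode.
.oracleSiteGuides <- function(chars, hexStart, strand, editor, motif) {
  P <- editor@protospacerLen
  pamSyms <- strsplit(editor@pam, "", fixed = TRUE)[[1]]
  M <- length(pamSyms)
  src <- editor@conversion[1]
  L <- length(chars)
  keys <- character()
  for (mode in c("coding", "template")) {
    pos <- if (mode == "coding") motif@codingDisruptable
           else motif@templateDisruptable
    guideStrand <- if (mode == "coding") strand
                   else if (strand == "+") "-" else "+"
    for (p in pos) {
      t <- if (strand == "+") hexStart + p - 1L else hexStart + 6L - p
      tBase <- chars[t + 1L]
      if (is.na(tBase) || !(tBase %in% names(.O_COMP))) next
      onGuide <- if (guideStrand == "+") tBase else unname(.O_COMP[tBase])
      if (onGuide != src) next
      for (w in seq(editor@window[1], editor@window[2])) {
        if (guideStrand == "+") {
          g <- t - (w - 1L); pamS <- g + P
        } else {
          g <- t - P + w; pamS <- g - M
        }
        if (min(g, pamS) < 0L || max(g + P, pamS + M) > L) next
        protoPlus <- chars[(g + 1L):(g + P)]
        pamPlus <- chars[(pamS + 1L):(pamS + M)]
        if (anyNA(match(protoPlus, names(.O_COMP)))) next
        pamChars <- if (guideStrand == "+") pamPlus else .oRevcomp(pamPlus)
        if (!.oPamOK(pamChars, pamSyms)) next
        keys <- c(keys, paste(guideStrand, g))
      }
    }
  }
  unique(keys)
}

#' Brute-force oracle scan for editable PAS sites
#'
#' Independent ground truth for the scan engines: every hexamer position on
#' both strands is tested by direct string comparison, and for each motif
#' occurrence every (disruptable position, window position, strand mode)
#' combination is enumerated with direct IUPAC comparison. Shares no code with
#' \code{\link{scanEditablePAS}}.
#'
#' @inheritParams scanEditablePAS
#' @return data.frame with one row per motif site: \code{chrom},
#'   \code{start0} (0-based hexamer start), \code{strand}, \code{hexamer},
#'   \code{editable}, \code{guideCount} (distinct protospacer placements).
#' @export
oracleScan <- function(genome, editor, motifs = defaultPASMotifs()) {
  seqs <- .asGenome(genome)
  motifs <- .asMotifList(motifs)
  rows <- list()
  for (chrom in names(seqs)) {
    chars <- strsplit(seqs[[chrom]], "", fixed = TRUE)[[1]]
    L <- length(chars)
    if (L < 6L) next
    for (m in motifs) {
      fwd <- strsplit(m@hexamer, "", fixed = TRUE)[[1]]
      rcv <- .oRevcomp(fwd)
      for (i in 0:(L - 6L)) {
        six <- chars[(i + 1L):(i + 6L)]
        for (strand in c("+", "-")) {
          ref <- if (strand == "+") fwd else rcv
          if (!all(six == ref)) next
          guides <- .oracleSiteGuides(chars, i, strand, editor, m)
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = chrom, start0 = i, strand = strand, hexamer = m@hexamer,
            editable = length(guides) > 0L, guideCount = length(guides),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(chrom = character(), start0 = integer(),
                      strand = character(), hexamer = character(),
                      editable = logical(), guideCount = integer(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  df <- df[order(df$chrom, df$start0, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Brute-force oracle for near-match enumeration
#'
#' Sliding-window Hamming comparison at every position on both strands with a
#' direct IUPAC PAM check; independent of
#' \code{\link{enumerateNearMatches}}. Genomic N counts as a mismatch and
#' fails every PAM symbol, matching the module's policy.
#'
#' @inheritParams enumerateNearMatches
#' @return data.frame with \code{chrom}, \code{start0} (0-based plus-strand
#'   start of the protospacer+PAM locus), \code{strand}, \code{nMismatch},
#'   \code{mismatchPositions}.
#' @export
oracleNearMatches <- function(genome, query) {
  seqs <- .asGenome(genome)
  proto <- strsplit(query@protospacer, "", fixed = TRUE)[[1]]
  pamSyms <- strsplit(query@pam, "", fixed = TRUE)[[1]]
  P <- length(proto)
  M <- length(pamSyms)
  rows <- list()
  for (chrom in names(seqs)) {
    chars <- strsplit(seqs[[chrom]], "", fixed = TRUE)[[1]]
    L <- length(chars)
    span <- P + M
    if (L < span) next
    for (i in 0:(L - span)) {
      window <- chars[(i + 1L):(i + span)]
      # plus strand: protospacer then PAM, read as-is
      mmP <- which(is.na(match(window[1:P], names(.O_COMP))) |
                     window[1:P] != proto)
      if (length(mmP) <= query@maxMismatch &&
          .oPamOK(window[(P + 1L):span], pamSyms)) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, start0 = i, strand = "+",
          nMismatch = length(mmP),
          mismatchPositions = paste(mmP, collapse = ","),
          stringsAsFactors = FALSE)
      }
      # minus strand: reverse complement of the window is PAM-last
      rc <- .oRevcomp(window)
      rc[is.na(rc)] <- "N"
      mmM <- which(!(rc[1:P] %in% names(.O_COMP)) | rc[1:P] != proto)
      if (length(mmM) <= query@maxMismatch &&
          .oPamOK(rc[(P + 1L):span], pamSyms)) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, start0 = i, strand = "-",
          nMismatch = length(mmM),
          mismatchPositions = paste(mmM, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(chrom = character(), start0 = integer(),
                      strand = character(), nMismatch = integer(),
                      mismatchPositions = character(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  df <- df[order(df$chrom, df$start0, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

## Fixture specification ------------------------------------------------------

#' FixtureSpec: parameters of a synthetic test genome
#'
#' @slot genomeLength total genome length (one chromosome).
#' @slot nCodingEditable,nTemplateEditable planted editable PAS counts per
#'   strand mode.
#' @slot nNoPamDecoy,nWrongGapDecoy,nWrongStrandPamDecoy,nPseudoMotif decoy
#'   counts: motif without any reachable PAM, motif with a PAM outside the
#'   valid gap range, motif with the PAM on the unusable strand, and an
#'   ATCAAA pseudo-motif with perfect PAM geometry.
#' @slot offTargetPlants list of \code{list(positions=, copies=)}: protospacer
#'   mismatch positions (1-based from the 5' end) and how many identical
#'   copies of the locus to plant.
#' @slot seed RNG seed; fully determines the output.
#' @slot baseComposition background base probabilities (A, C, G, T).
#' @exportClass FixtureSpec
setClass("FixtureSpec", representation(
  genomeLength = "integer",
  nCodingEditable = "integer",
  nTemplateEditable = "integer",
  nNoPamDecoy = "integer",
  nWrongGapDecoy = "integer",
  nWrongStrandPamDecoy = "integer",
  nPseudoMotif = "integer",
  offTargetPlants = "list",
  seed = "integer",
  baseComposition = "numeric"
))

setValidity("FixtureSpec", function(object) {
  msg <- character()
  counts <- c(object@genomeLength, object@nCodingEditable,
              object@nTemplateEditable, object@nNoPamDecoy,
              object@nWrongGapDecoy, object@nWrongStrandPamDecoy,
              object@nPseudoMotif)
  if (anyNA(counts) || any(counts < 0L) || object@genomeLength < 1L)
    msg <- c(msg, "lengths/counts must be non-negative (genomeLength >= 1)")
  if (length(object@baseComposition) != 4L ||
      any(object@baseComposition <= 0) ||
      abs(sum(object@baseComposition) - 1) > 1e-6)
    msg <- c(msg, "baseComposition must be 4 positive probabilities summing to 1")
  for (p in object@offTargetPlants) {
    if (!is.list(p) || is.null(p$positions) || is.null(p$copies) ||
        p$copies < 1L)
      msg <- c(msg, "offTargetPlants entries need $positions and $copies >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a FixtureSpec
#'
#' Defaults plant 20 editable PAS sites (12 coding-mode, 8 template-mode),
#' 20 decoys (7 motif-without-PAM, 6 wrong-gap, 4 wrong-strand-PAM, 3 ATCAAA
#' pseudo-motifs) and 4 off-target loci (a seed-free 2-mismatch site, a
#' seed-mismatch site, a 4-mismatch site and a duplicated 1-mismatch locus)
#' on a 50 kb uniform-composition chromosome.
#'
#' @param genomeLength genome length in nt.
#' @param nCodingEditable,nTemplateEditable,nNoPamDecoy,nWrongGapDecoy,nWrongStrandPamDecoy,nPseudoMotif
#'   per-category plant counts.
#' @param offTargetPlants list of \code{list(positions=, copies=)}.
#' @param seed RNG seed.
#' @param baseComposition background base probabilities, named A/C/G/T.
#' @return a \code{\linkS4class{FixtureSpec}}.
#' @export
fixtureSpec <- function(genomeLength = 50000L,
                        nCodingEditable = 12L, nTemplateEditable = 8L,
                        nNoPamDecoy = 7L, nWrongGapDecoy = 6L,
                        nWrongStrandPamDecoy = 4L, nPseudoMotif = 3L,
                        offTargetPlants = list(
                          list(positions = c(1L, 3L), copies = 1L),
                          list(positions = c(18L), copies = 1L),
                          list(positions = c(2L, 5L, 7L, 9L), copies = 1L),
                          list(positions = c(2L), copies = 2L)),
                        seed = 1L,
                        baseComposition = c(A = 0.25, C = 0.25,
                                            G = 0.25, T = 0.25)) {
  methods::new("FixtureSpec",
               genomeLength = as.integer(genomeLength),
               nCodingEditable = as.integer(nCodingEditable),
               nTemplateEditable = as.integer(nTemplateEditable),
               nNoPamDecoy = as.integer(nNoPamDecoy),
               nWrongGapDecoy = as.integer(nWrongGapDecoy),
               nWrongStrandPamDecoy = as.integer(nWrongStrandPamDecoy),
               nPseudoMotif = as.integer(nPseudoMotif),
               offTargetPlants = offTargetPlants,
               seed = as.integer(seed),
               baseComposition = baseComposition[c("A", "C", "G", "T")])
}

## Plant construction ---------------------------------------------------------

# realize an IUPAC pattern as concrete bases, preferring non-G/non-C members
# for ambiguous symbols so a realized PAM does not trivially seed further PAMs
.realizePam <- function(pamSyms) {
  vapply(pamSyms, function(s) {
    set <- IUPAC_SETS[[s]]
    if (length(set) == 1L) return(set)
    pref <- setdiff(set, c("G", "C"))
    if (length(pref)) sample(pref, 1L) else sample(set, 1L)
  }, character(1), USE.NAMES = FALSE)
}

.sampleBases <- function(n, comp) {
  sample(DNA_BASES, n, replace = TRUE, prob = comp)
}

# Resample the free positions of a plant layout until the conditions hold.
# fixed: named list of (0-based offset -> chars). Conditions are evaluated on
# the full character vector of length `len`.
.rejectionFill <- function(len, fixed, comp, condition, budget = 500L) {
  fixedIdx <- integer()
  fixedChars <- character()
  for (f in fixed) {
    fixedIdx <- c(fixedIdx, f$at + seq_along(f$chars))
    fixedChars <- c(fixedChars, f$chars)
  }
  free <- setdiff(seq_len(len), fixedIdx)
  for (i in seq_len(budget)) {
    chars <- character(len)
    chars[fixedIdx] <- fixedChars
    chars[free] <- .sampleBases(length(free), comp)
    if (condition(chars)) return(chars)
  }
  stop("plant construction rejection budget exceeded; ",
       "try another seed or a longer genome")
}

# count motif occurrences (either strand) in a character vector
.motifHits <- function(chars, motifs) {
  hits <- list()
  L <- length(chars)
  if (L >= 6L) {
    for (m in motifs) {
      fwd <- strsplit(m@hexamer, "", fixed = TRUE)[[1]]
      rcv <- .oRevcomp(fwd)
      for (i in 0:(L - 6L)) {
        six <- chars[(i + 1L):(i + 6L)]
        if (all(six == fwd))
          hits[[length(hits) + 1L]] <- c(i, 1L)
        if (all(six == rcv))
          hits[[length(hits) + 1L]] <- c(i, -1L)
      }
    }
  }
  hits
}

# Build one PAS-category plant in plus orientation. Returns list(chars,
# hexOffset, editable, guideCount). `pad` covers the editor's full geometric
# reach so no base outside the plant can influence the site's guides.
.buildPasPlant <- function(category, editor, motifs, comp) {
  P <- editor@protospacerLen
  pamSyms <- strsplit(editor@pam, "", fixed = TRUE)[[1]]
  M <- length(pamSyms)
  maxGap <- max(max(.comboTable(editor, motifs[[1]], "coding")$gap),
                max(.comboTable(editor, motifs[[1]], "template")$gap))
  pad <- P + M + maxGap
  motif <- motifs[[sample(length(motifs), 1L)]]
  hexChars <- strsplit(motif@hexamer, "", fixed = TRUE)[[1]]
  hexAt <- pad                      # 0-based offset of the hexamer
  len <- pad + 6L + pad
  fixed <- list(list(at = hexAt, chars = hexChars))
  wantEditable <- FALSE
  if (category %in% c("coding_editable", "template_editable")) {
    wantEditable <- TRUE
    mode <- sub("_editable", "", category)
    combos <- .comboTable(editor, motif, mode)
    cmb <- combos[sample(nrow(combos), 1L), ]
    pamAt <- if (mode == "coding") hexAt + 6L + cmb$gap
             else hexAt - cmb$gap - M
    pamChars <- .realizePam(pamSyms)
    if (mode == "template") pamChars <- .oRevcomp(pamChars)
    fixed <- c(fixed, list(list(at = pamAt, chars = pamChars)))
  } else if (category == "wrong_gap_decoy") {
    pamAt <- hexAt + 6L + maxGap + 3L
    len <- max(len, pamAt + M + 5L)
    fixed <- c(fixed, list(list(at = pamAt, chars = .realizePam(pamSyms))))
  } else if (category == "wrong_strand_pam_decoy") {
    # a PAM for the opposite strand placed downstream, where only a
    # same-strand PAM could serve the coding-mode geometry
    gap <- stats::median(.comboTable(editor, motif, "coding")$gap)
    fixed <- c(fixed, list(list(at = hexAt + 6L + gap,
                                chars = .oRevcomp(.realizePam(pamSyms)))))
  } else if (category == "pseudo_motif") {
    pseudo <- strsplit("ATCAAA", "", fixed = TRUE)[[1]]
    fixed <- list(list(at = hexAt, chars = pseudo))
    gap <- sample(.comboTable(editor, motifs[[1]], "coding")$gap, 1L)
    fixed <- c(fixed, list(list(at = hexAt + 6L + gap,
                                chars = .realizePam(pamSyms))))
  } else if (category != "no_pam_decoy") {
    stop("unknown plant category: ", category)
  }
  isPseudo <- category == "pseudo_motif"
  guideCount <- 0L
  condition <- function(chars) {
    hits <- .motifHits(chars, motifs)
    if (isPseudo) return(length(hits) == 0L)
    if (length(hits) != 1L || hits[[1]][1] != hexAt ||
        hits[[1]][2] != 1L) return(FALSE)
    guides <- .oracleSiteGuides(chars, hexAt, "+", editor, motif)
    if (wantEditable) {
      guideCount <<- length(guides)
      length(guides) >= 1L
    } else {
      length(guides) == 0L
    }
  }
  chars <- .rejectionFill(len, fixed, comp, condition)
  list(chars = chars, hexOffset = hexAt,
       motif = if (isPseudo) "ATCAAA" else motif@hexamer,
       editable = wantEditable, guideCount = if (wantEditable) guideCount
       else 0L)
}

## Generation -----------------------------------------------------------------

#' Generate a synthetic fixture genome with a truth manifest
#'
#' Plants editable PAS sites, decoys and off-target loci at well-separated
#' positions in a random background, then verifies the assembly with the
#' brute-force oracles before emission: any accidental motif+PAM configuration
#' (or accidental near-match of the query) arising in the background is
#' removed by mutating a single base outside all planted spans, iterating
#' until the oracle-derived truth equals the manifest. Identical seeds yield
#' byte-identical output.
#'
#' @param spec a \code{\linkS4class{FixtureSpec}}.
#' @param editor an \code{\linkS4class{EditorSpec}}.
#' @param motifs PAS motifs to plant (default AATAAA/ATTAAA).
#' @param query \code{\linkS4class{OffTargetQuery}} whose near-match loci are
#'   planted; the default uses a motif-free protospacer so off-target plants
#'   do not interact with the PAS truth set.
#' @return list with \code{genome} (named character vector), \code{manifest}
#'   (data.frame: category, chrom, start, end, strand, editable, guideCount,
#'   mismatchPositions, copies, crit1-crit3), \code{query}, \code{editor},
#'   \code{motifs} and \code{spec}.
#' @export
generateFixture <- function(spec, editor = editorSpec("spcas9-abemax"),
                            motifs = defaultPASMotifs(), query = NULL) {
  stopifnot(methods::is(spec, "FixtureSpec"))
  motifs <- .asMotifList(motifs)
  if (is.null(query))
    query <- offTargetQuery("GTCGAAGCGATCGTCGACGT",
                            pam = editor@pam,
                            maxMismatch = 4L, seedLength = 12L)
  .withSeed(spec@seed, .generateFixtureImpl(spec, editor, motifs, query))
}

.generateFixtureImpl <- function(spec, editor, motifs, query) {
  comp <- spec@baseComposition
  P <- nchar(query@protospacer)
  pamSyms <- strsplit(query@pam, "", fixed = TRUE)[[1]]
  M <- length(pamSyms)

  # ---- build plant strings (plus orientation) ----
  cats <- c(rep("coding_editable", spec@nCodingEditable),
            rep("template_editable", spec@nTemplateEditable),
            rep("no_pam_decoy", spec@nNoPamDecoy),
            rep("wrong_gap_decoy", spec@nWrongGapDecoy),
            rep("wrong_strand_pam_decoy", spec@nWrongStrandPamDecoy),
            rep("pseudo_motif", spec@nPseudoMotif))
  plants <- list()
  for (cat in cats) {
    built <- .buildPasPlant(cat, editor, motifs, comp)
    plants[[length(plants) + 1L]] <- list(
      category = cat, chars = built$chars, featOffset = built$hexOffset,
      featLen = 6L, motif = built$motif, editable = built$editable,
      guideCount = built$guideCount, mmPos = "", copies = 1L,
      crit = c(NA, NA, NA))
  }
  protoChars <- strsplit(query@protospacer, "", fixed = TRUE)[[1]]
  win <- seq(editor@window[1], editor@window[2])
  seedFrom <- P - query@seedLength + 1L
  for (pl in spec@offTargetPlants) {
    mut <- protoChars
    for (j in pl$positions)
      mut[j] <- sample(setdiff(DNA_BASES, mut[j]), 1L)
    locus <- c(mut, .realizePam(pamSyms))
    crit1 <- all(pl$positions < seedFrom) &&
      length(pl$positions) <= query@maxMismatch
    crit2 <- sum(mut[win] == editor@conversion[1]) >= 1L
    crit3 <- pl$copies == 1L
    for (k in seq_len(pl$copies)) {
      plants[[length(plants) + 1L]] <- list(
        category = "off_target", chars = locus, featOffset = 0L,
        featLen = P + M, motif = "", editable = NA,
        guideCount = NA_integer_,
        mmPos = paste(pl$positions, collapse = ","),
        copies = pl$copies, crit = c(crit1, crit2, crit3))
    }
  }

  # ---- place plants in non-overlapping slots ----
  n <- length(plants)
  L <- spec@genomeLength
  maxLen <- if (n) max(vapply(plants, function(p) length(p$chars),
                              integer(1))) else 0L
  buffer <- 10L
  if (n) {
    segLen <- L %/% n
    if (segLen < maxLen + 2L * buffer)
      stop("infeasible packing: ", n, " plants of up to ", maxLen,
           " nt do not fit a genome of length ", L)
  }
  genome <- .sampleBases(L, comp)
  ord <- if (n) sample(n) else integer()
  manifest <- list()
  protected <- matrix(integer(), ncol = 2)   # 0-based half-open plant spans
  for (k in seq_len(n)) {
    p <- plants[[ord[k]]]
    segStart <- (k - 1L) * (L %/% n)
    plantLen <- length(p$chars)
    offMax <- (L %/% n) - plantLen - buffer
    at <- segStart + buffer + sample.int(max(offMax - buffer, 1L), 1L) - 1L
    strand <- sample(c("+", "-"), 1L)
    chars <- if (strand == "+") p$chars else .oRevcomp(p$chars)
    genome[(at + 1L):(at + plantLen)] <- chars
    featStart <- if (strand == "+") at + p$featOffset
                 else at + plantLen - p$featOffset - p$featLen
    protected <- rbind(protected, c(at, at + plantLen))
    manifest[[k]] <- data.frame(
      category = p$category, chrom = "chr1", start = featStart,
      end = featStart + p$featLen, strand = strand,
      editable = p$editable, guideCount = p$guideCount,
      mismatchPositions = p$mmPos, copies = p$copies,
      crit1 = p$crit[1], crit2 = p$crit[2], crit3 = p$crit[3],
      stringsAsFactors = FALSE)
  }
  manifest <- if (n) do.call(rbind, manifest) else
    data.frame(category = character(), chrom = character(),
               start = integer(), end = integer(), strand = character(),
               editable = logical(), guideCount = integer(),
               mismatchPositions = character(), copies = integer(),
               crit1 = logical(), crit2 = logical(), crit3 = logical(),
               stringsAsFactors = FALSE)

  genome <- .scrubAccidentals(genome, manifest, protected, editor, motifs,
                              query)

  genomeStr <- c(chr1 = paste(genome, collapse = ""))
  manifest <- manifest[order(manifest$start), , drop = FALSE]
  rownames(manifest) <- NULL
  list(genome = genomeStr, manifest = manifest, query = query,
       editor = editor, motifs = motifs, spec = spec)
}

# Self-consistency gate: compare the oracle truth with the manifest and patch
# single background bases until they agree (bounded budget).
.scrubAccidentals <- function(genome, manifest, protected, editor, motifs,
                              query) {
  inProtected <- function(pos) {
    any(pos >= protected[, 1] & pos < protected[, 2])
  }
  pas <- manifest[manifest$category != "off_target", , drop = FALSE]
  expectedEditable <- pas[!is.na(pas$editable) & pas$editable, , drop = FALSE]
  edKey <- paste(expectedEditable$start, expectedEditable$strand)
  ot <- manifest[manifest$category == "off_target", , drop = FALSE]
  otKey <- paste(ot$start, ot$strand)
  otSpanHit <- function(s, e) {
    any(s < ot$end & e > ot$start)
  }
  for (iter in seq_len(100L)) {
    dirty <- FALSE
    genomeStr <- c(chr1 = paste(genome, collapse = ""))
    truth <- oracleScan(genomeStr, editor, motifs)
    truthEd <- truth[truth$editable, , drop = FALSE]
    if (nrow(expectedEditable) &&
        !all(edKey %in% paste(truthEd$start0, truthEd$strand)))
      stop("internal error: a planted editable site failed its own oracle")
    for (i in seq_len(nrow(truthEd))) {
      s <- truthEd$start0[i]
      if (paste(s, truthEd$strand[i]) %in% edKey) next
      if (otSpanHit(s, s + 6L)) next   # inside an off-target plant: allowed
      cand <- setdiff(s:(s + 5L), Filter(inProtected, s:(s + 5L)))
      if (!length(cand))
        stop("accidental editable site overlaps planted spans; ",
             "try another seed or a longer genome")
      j <- cand[1] + 1L
      genome[j] <- if (genome[j] != "C") "C" else "G"
      dirty <- TRUE
    }
    if (!dirty) {
      nm <- oracleNearMatches(genomeStr, query)
      for (i in seq_len(nrow(nm))) {
        key <- paste(nm$start0[i], nm$strand[i])
        if (key %in% otKey) next
        span <- nm$start0[i]:(nm$start0[i] + nchar(query@protospacer) +
                                nchar(query@pam) - 1L)
        cand <- setdiff(span, Filter(inProtected, span))
        if (!length(cand))
          stop("accidental near-match overlaps planted spans; ",
               "try another seed or a longer genome")
        patched <- FALSE
        for (pos in cand) {
          for (b in setdiff(DNA_BASES, genome[pos + 1L])) {
            old <- genome[pos + 1L]
            genome[pos + 1L] <- b
            sub <- paste(genome, collapse = "")
            still <- oracleNearMatches(
              c(chr1 = substr(sub, min(span) + 1L, max(span) + 1L)), query)
            if (!nrow(still)) { patched <- TRUE; break }
            genome[pos + 1L] <- old
          }
          if (patched) break
        }
        if (!patched)
          stop("could not remove accidental near-match; try another seed")
        dirty <- TRUE
      }
    }
    if (!dirty) return(genome)
  }
  stop("fixture rejection budget exceeded; use a longer genome")
}

#' Write a fixture to disk
#'
#' Emits \code{<prefix>.fa} (FASTA genome), \code{<prefix>.truth.tsv} (the
#' manifest) and \code{<prefix>.bed} (BED6 of planted features, name =
#' category).
#'
#' @param fixture output of \code{\link{generateFixture}}.
#' @param prefix output path prefix.
#' @return invisibly, the three paths.
#' @export
writeFixture <- function(fixture, prefix) {
  fa <- paste0(prefix, ".fa")
  dna <- Biostrings::DNAStringSet(fixture$genome)
  Biostrings::writeXStringSet(dna, fa)
  tsv <- paste0(prefix, ".truth.tsv")
  utils::write.table(fixture$manifest, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  bed <- paste0(prefix, ".bed")
  m <- fixture$manifest
  bedDf <- data.frame(chrom = m$chrom, start = m$start, end = m$end,
                      name = m$category,
                      score = ifelse(is.na(m$guideCount), 0L, m$guideCount),
                      strand = m$strand, stringsAsFactors = FALSE)
  utils::write.table(bedDf, bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(fa = fa, truth = tsv, bed = bed))
}
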