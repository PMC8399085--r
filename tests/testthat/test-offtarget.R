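# Near-match enumeration and the three-criterion candidate filter.

otQuery <- function(...) offTargetQuery("GTCGAAGCGATCGTCGACGT", ...)

# flanks without G/C so no spurious NGG/CCN arises next to a plant
flank <- function(n) paste(rep(c("T", "A"), length.out = n), collapse = "")

mutateAt <- function(seq, positions, to = "T") {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in positions) chars[p] <- if (chars[p] == to) "A" else to
  paste(chars, collapse = "")
}

test_that("an embedded perfect match is found once with zero mismatches", {
  ed <- testEditor()
  q <- otQuery()
  g <- c(chr1 = paste0(flank(15), "GTCGAAGCGATCGTCGACGT", "AGG", flank(15)))
  sites <- enumerateNearMatches(g, q, ed)
  expect_equal(length(sites), 1L)
  mc <- S4Vectors::mcols(sites)
  expect_equal(mc$nMismatch, 0L)
  expect_true(mc$isOnTarget)
  expect_equal(mc$copyCount, 1L)
  expect_equal(GenomicRanges::start(sites) - 1L, 15L)
  expect_equal(as.character(GenomicRanges::strand(sites)), "+")
  # the same locus planted on the minus strand is found strand-aware
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(paste0("GTCGAAGCGATCGTCGACGT", "AGG"))))
  g2 <- c(chr1 = paste0(flank(15), rc, flank(15)))
  sites2 <- enumerateNearMatches(g2, q, ed)
  expect_equal(as.character(GenomicRanges::strand(sites2)), "-")
  expect_equal(S4Vectors::mcols(sites2)$nMismatch, 0L)
  # query/editor length disagreement is a domain error
  expect_error(enumerateNearMatches(g, offTargetQuery("GTCGAAGCGA"), ed),
               "length")
})

test_that("planted variants are recovered with exact mismatch positions", {
  ed <- testEditor()
  q <- otQuery()
  proto <- "GTCGAAGCGATCGTCGACGT"
  var2 <- mutateAt(proto, c(2, 7))
  g <- c(chr1 = paste0(flank(12), var2, "TGG", flank(12)))
  sites <- enumerateNearMatches(g, q, ed)
  expect_equal(length(sites), 1L)
  expect_equal(S4Vectors::mcols(sites)$mismatchPositions, "2,7")
  expect_equal(S4Vectors::mcols(sites)$nMismatch, 2L)
  expect_equal(S4Vectors::mcols(sites)$protoSeq, var2)
  # five mismatches exceed the cap and the locus disappears
  var5 <- mutateAt(proto, c(2, 4, 7, 11, 14))
  g5 <- c(chr1 = paste0(flank(12), var5, "TGG", flank(12)))
  expect_equal(length(enumerateNearMatches(g5, q, ed)), 0L)
})

test_that("enumeration equals the Hamming oracle and Biostrings on random genomes", {
  ed <- testEditor()
  q <- otQuery()
  set.seed(41)
  for (i in 1:3) {
    g <- c(chr1 = randomGenome(4000))
    a <- enumerateNearMatches(g, q, ed)
    b <- oracleNearMatches(g, q)
    expect_identical(GenomicRanges::start(a) - 1L, b$start0)
    expect_identical(as.character(GenomicRanges::strand(a)), b$strand)
    expect_identical(S4Vectors::mcols(a)$mismatchPositions,
                     b$mismatchPositions)
    # third route: candidate protospacer matches via Biostrings, PAM checked
    # separately (plus strand only, enough for a cross-check)
    dna <- Biostrings::DNAString(unname(g))
    hits <- Biostrings::matchPattern(q@protospacer, dna, max.mismatch = 4)
    starts0 <- Biostrings::start(hits) - 1L
    pamOK <- vapply(starts0, function(s) {
      if (s + 23 > length(dna)) return(FALSE)
      grepl("^[ACGT]GG$", as.character(dna[(s + 21):(s + 23)]))
    }, logical(1))
    plus <- b[b$strand == "+", ]
    expect_setequal(starts0[pamOK], plus$start0)
  }
})

test_that("the three filter criteria behave as specified", {
  ed <- testEditor()
  q <- otQuery()
  proto <- "GTCGAAGCGATCGTCGACGT"
  # seed = PAM-proximal 12 of 20 -> positions 9..20
  g <- c(chr1 = paste0(
    flank(10), mutateAt(proto, c(1, 3)), "TGG",      # outside seed: passes
    flank(10), mutateAt(proto, 20), "TGG",           # inside seed: fails 1
    flank(10), mutateAt(proto, c(5, 6), to = "C"), "TGG",  # no window A: fails 2
    flank(10)))
  sites <- applyOffTargetFilters(enumerateNearMatches(g, q, ed), ed,
                                 seedLength = 12, maxMismatchOutside = 4)
  mc <- S4Vectors::mcols(sites)
  expect_equal(length(sites), 3L)
  byPos <- order(GenomicRanges::start(sites))
  expect_equal(mc$crit1[byPos], c(TRUE, FALSE, TRUE))
  expect_equal(mc$crit2[byPos], c(TRUE, TRUE, FALSE))
  expect_equal(mc$crit3[byPos], rep(TRUE, 3))
  expect_equal(mc$pass[byPos], c(TRUE, FALSE, FALSE))
  # loose reading tolerates the seed mismatch (0 mismatches outside seed)
  loose <- applyOffTargetFilters(enumerateNearMatches(g, q, ed), ed,
                                 seedLength = 12, maxMismatchOutside = 4,
                                 strict = FALSE)
  expect_true(S4Vectors::mcols(loose)$crit1[byPos][2])
})

test_that("duplicated loci fail the single-copy criterion", {
  ed <- testEditor()
  q <- otQuery()
  locus <- paste0(mutateAt("GTCGAAGCGATCGTCGACGT", 2), "TGG")
  g <- c(chr1 = paste0(flank(10), locus, flank(30), locus, flank(10)))
  sites <- applyOffTargetFilters(enumerateNearMatches(g, q, ed), ed)
  mc <- S4Vectors::mcols(sites)
  expect_equal(length(sites), 2L)
  expect_equal(mc$copyCount, c(2L, 2L))
  expect_equal(mc$crit3, c(FALSE, FALSE))
})

test_that("filters are idempotent, verdicts recomputable, mismatch cap monotone", {
  ed <- testEditor()
  q <- otQuery()
  set.seed(43)
  g <- c(chr1 = randomGenome(4000))
  # plant a couple of variants so the site list is non-trivial
  proto <- "GTCGAAGCGATCGTCGACGT"
  g <- c(chr1 = paste0(unname(g), flank(10), mutateAt(proto, c(2, 11)), "AGG",
                       flank(10), mutateAt(proto, c(1, 2, 3, 4)), "CGG",
                       flank(10)))
  s1 <- applyOffTargetFilters(enumerateNearMatches(g, q, ed), ed)
  s2 <- applyOffTargetFilters(s1, ed)
  expect_identical(S4Vectors::mcols(s1), S4Vectors::mcols(s2))
  mc <- as.data.frame(S4Vectors::mcols(s1))
  # recompute verdicts from the stored fields
  seedFrom <- 20 - 12 + 1
  for (i in seq_len(nrow(mc))) {
    pos <- as.integer(strsplit(mc$mismatchPositions[i], ",")[[1]])
    pos <- pos[!is.na(pos)]
    expect_equal(mc$crit1[i], all(pos < seedFrom) && length(pos) <= 4)
    expect_equal(mc$crit2[i], mc$windowSourceCount[i] >= 1)
    expect_equal(mc$crit3[i], mc$copyCount[i] == 1)
    expect_equal(mc$pass[i], mc$crit1[i] && mc$crit2[i] && mc$crit3[i])
  }
  # lowering the mismatch cap yields a subset
  qLow <- offTargetQuery("GTCGAAGCGATCGTCGACGT", maxMismatch = 2)
  low <- enumerateNearMatches(g, qLow, ed)
  all <- enumerateNearMatches(g, q, ed)
  keyOf <- function(x) paste(GenomicRanges::start(x),
                             GenomicRanges::strand(x))
  expect_true(all(keyOf(low) %in% keyOf(all)))
  expect_true(length(low) <= length(all))
})
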