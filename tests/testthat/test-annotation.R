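# GFF3 reading, hexamer classification and the editable-share summary.

writeToyGff <- function(lines) {
  path <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", lines), path)
  path
}

test_that("only polyA_signal features are kept and malformed lines are counted", {
  path <- writeToyGff(c(
    "chr1\thavana\tpolyA_signal\t101\t106\t.\t+\t.\tID=a",
    "chr1\thavana\tpolyA_site\t200\t201\t.\t+\t.\tID=b",
    "chr1\thavana\tpseudo_polyA\t300\t305\t.\t-\t.\tID=c",
    "chr1\thavana\tpolyA_signal\tnotanumber\t9\t.\t+\t.\tID=d",
    "just a broken line"))
  gr <- readPolyAGFF3(path)
  expect_equal(length(gr), 1L)
  # 1-based closed 101..106 corresponds to the 0-based half-open [100, 106)
  expect_equal(GenomicRanges::start(gr) - 1L, 100L)
  expect_equal(GenomicRanges::end(gr), 106L)
  expect_equal(S4Vectors::metadata(gr)$nMalformed, 2L)
  expect_equal(S4Vectors::metadata(gr)$nOtherType, 2L)
  expect_error(readPolyAGFF3(tempfile()), "no such file")
  empty <- writeToyGff("chr1\tx\tpolyA_site\t1\t6\t.\t+\t.\tID=e")
  expect_warning(readPolyAGFF3(empty), "no 'polyA_signal'")
})

test_that("hexamers are extracted strand-aware and classified", {
  # genome: AATAAA at 10(+), TTTATT at 30 (AATAAA on -), AGTAAA at 50
  g <- paste(rep("C", 100), collapse = "")
  substr(g, 11, 16) <- "AATAAA"
  substr(g, 31, 36) <- "TTTATT"
  substr(g, 51, 56) <- "AGTAAA"
  genome <- c(chr1 = g)
  ann <- GenomicRanges::GRanges(
    c("chr1", "chr1", "chr1", "chr1", "chr2"),
    IRanges::IRanges(start = c(11, 31, 51, 61, 1),
                     end = c(16, 36, 56, 70, 6)),
    strand = c("+", "-", "+", "+", "+"))
  cl <- suppressWarnings(classifyPAS(ann, genome))
  expect_equal(S4Vectors::mcols(cl)$hexamer[1:3],
               c("AATAAA", "AATAAA", "AGTAAA"))
  expect_equal(S4Vectors::mcols(cl)$motifClass,
               c("AATAAA", "AATAAA", "other", "unextractable",
                 "unextractable"))
  expect_warning(classifyPAS(ann, genome), "chr2")
  counts <- motifClassCounts(cl)
  expect_equal(sum(counts), length(ann))
})

test_that("the two-motif share is a forced 80% on the constructed toy", {
  g <- paste(rep("C", 200), collapse = "")
  hexes <- c("AATAAA", "AATAAA", "AATAAA", "ATTAAA", "AGTAAA")
  starts <- c(11, 41, 71, 101, 131)
  for (i in seq_along(hexes)) substr(g, starts[i], starts[i] + 5) <- hexes[i]
  ann <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = starts, width = 6), strand = "+")
  cl <- classifyPAS(ann, c(chr1 = g))
  expect_equal(unname(motifClassCounts(cl)[c("AATAAA", "ATTAAA", "other")]),
               c(3L, 1L, 1L))
  expect_equal(twoMotifShare(cl), 0.8)
  # empty annotation set: counts 0, share not available
  emptyAnn <- GenomicRanges::GRanges()
  clEmpty <- classifyPAS(emptyAnn, c(chr1 = g))
  expect_equal(sum(motifClassCounts(clEmpty)), 0L)
  expect_true(is.na(twoMotifShare(clEmpty)))
})

test_that("editability summary joins exactly and yields the forced 25%", {
  ed <- testEditor()
  # four two-motif PAS; only the first has a valid PAM geometry. The CT
  # background contains no CC/GG, so no accidental PAM can arise.
  g <- paste(rep("CT", 200), collapse = "")
  substr(g, 11, 16) <- "ATTAAA"
  substr(g, 17, 33) <- "TCATCTCATCTCATTGG"   # gap 14 + TGG
  substr(g, 101, 106) <- "AATAAA"
  substr(g, 201, 206) <- "ATTAAA"
  substr(g, 301, 306) <- "AATAAA"
  genome <- c(chr1 = g)
  ann <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = c(11, 101, 201, 301, 11), width = 6),
    strand = "+")   # the 5th duplicates the 1st and must be deduplicated
  scan <- scanEditablePAS(genome, ed)
  s <- editabilitySummary(ann, scan, genome = genome)
  expect_equal(s@nTwoMotif, 4L)
  expect_equal(s@nEditable, 1L)
  expect_equal(s@editableFraction, 0.25)
  expect_equal(unname(s@modeBreakdown["coding"]), 1L)
  # permuting the annotation order changes nothing
  perm <- sample(length(ann))
  s2 <- editabilitySummary(ann[perm], scan, genome = genome)
  expect_equal(s2@nEditable, s@nEditable)
  expect_equal(s2@editableFraction, s@editableFraction)
  expect_equal(s2@classCounts, s@classCounts)
  # an annotation with no scan record at all counts as non-editable
  annOff <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = 390, width = 6), strand = "+")
  s3 <- editabilitySummary(c(ann, annOff), scan, genome = genome)
  expect_equal(s3@nEditable, 1L)
  # shifted coordinates: overlaps but no exact join -> heuristic warning
  annShift <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = c(12, 102), width = 6), strand = "+")
  expect_warning(editabilitySummary(annShift, scan, genome = genome),
                 "coordinate")
})

test_that("summary TSV writer emits the expected keys", {
  ed <- testEditor()
  g <- c(chr1 = paste0("ATTAAA", "TCATCTCATCTCAT", "TGGTT"))
  ann <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 6), strand = "+")
  s <- editabilitySummary(ann, scanEditablePAS(g, ed), genome = g)
  path <- tempfile(fileext = ".tsv")
  writeSummaryTsv(s, path)
  tab <- utils::read.delim(path)
  expect_true(all(c("n_two_motif", "n_editable", "editable_fraction") %in%
                  tab$key))
  expect_equal(tab$value[tab$key == "editable_fraction"], 1)
})
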