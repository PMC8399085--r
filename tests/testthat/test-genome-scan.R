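# Motif discovery, regex construction and the two scan engines.

test_that("motif sites are found on both strands, overlaps included", {
  gr <- findMotifSites(c(chr1 = "AATAAA"))
  expect_equal(length(gr), 1L)
  expect_equal(as.character(GenomicRanges::strand(gr)), "+")
  # TTTAAT is the reverse complement of ATTAAA
  gr2 <- findMotifSites(c(chr1 = "TTTAAT"))
  expect_equal(as.character(GenomicRanges::strand(gr2)), "-")
  expect_equal(S4Vectors::mcols(gr2)$hexamer, "ATTAAA")
  # overlap stress: AATAAATAAA holds AATAAA at 0 and ATAAAT/ATTAAA? compare
  # against a sliding 6-mer oracle
  set.seed(11)
  for (i in 1:20) {
    seq <- randomGenome(400, prob = c(A = 0.4, C = 0.1, G = 0.1, T = 0.4))
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    exp <- character()
    for (j in 0:(length(chars) - 6L)) {
      six <- paste(chars[(j + 1):(j + 6)], collapse = "")
      for (hx in c("AATAAA", "ATTAAA")) {
        if (six == hx) exp <- c(exp, paste("chr1", j, "+", hx))
        rc <- paste(rev(unname(.tCOMP[strsplit(hx, "")[[1]]])), collapse = "")
        if (six == rc) exp <- c(exp, paste("chr1", j, "-", hx))
      }
    }
    got <- siteKeys(findMotifSites(c(chr1 = seq)))
    expect_setequal(got, exp)
  }
})

test_that("the compiled regex is equivalent to motif + gap-range + PAM with bounded context", {
  ed <- testEditor()
  att <- pasMotifSpec("ATTAAA")
  pat <- buildEditableRegex(ed, att, "coding")
  hit <- function(s) grepl(pat, s, perl = TRUE)
  filler <- function(n) paste(rep("T", n), collapse = "")
  pad <- "CTCTCTCTCTCTCTCTCT"   # no CC/GG, no motif: safe flanking context
  for (gap in 8:18) {
    s <- paste0(pad, "ATTAAA", filler(gap), "TGG", pad)
    expect_equal(hit(s), gap >= 10 && gap <= 16, label = paste("gap", gap))
  }
  # near the 5' end the protospacer must still fit: gap 10 needs 4 nt upstream
  expect_false(hit(paste0("ATTAAA", filler(10), "TGG")))
  expect_true(hit(paste0("CTCT", "ATTAAA", filler(10), "TGG")))
  expect_true(hit(paste0("ATTAAA", filler(14), "TGG")))
  patT <- buildEditableRegex(ed, att, "template")
  hitT <- function(s) grepl(patT, s, perl = TRUE)
  for (gap in 8:16) {
    # protospacer tail extends up to 14-gap nt past the hexamer
    s <- paste0(pad, "CCT", filler(gap), "ATTAAA", filler(6), pad)
    expect_equal(hitT(s), gap >= 10 && gap <= 14, label = paste("tgap", gap))
  }
  # geometrically impossible configuration: the PAM would overlap the hexamer
  tiny <- editorSpec("tiny", pam = "NGG", protospacerLen = 8L,
                     window = c(8L, 8L))
  m4 <- pasMotifSpec("AATAAA", codingDisruptable = 4L,
                     templateDisruptable = integer())
  expect_error(buildEditableRegex(tiny, m4, "coding"), "feasible")
})

test_that("both engines agree with each other and handle soft-masking", {
  ed <- testEditor()
  set.seed(21)
  for (i in 1:10) {
    g <- c(chr1 = randomGenome(5000))
    d <- scanEditablePAS(g, ed, engine = "direct")
    r <- scanEditablePAS(g, ed, engine = "regex")
    expect_identical(siteKeys(pasSites(d)), siteKeys(pasSites(r)))
    expect_identical(S4Vectors::mcols(pasSites(d))$editable,
                     S4Vectors::mcols(pasSites(r))$editable)
    expect_identical(S4Vectors::mcols(pasSites(d))$editableCoding,
                     S4Vectors::mcols(pasSites(r))$editableCoding)
  }
  # lowercase is scanned by default, excluded with maskSoftmasked
  soft <- c(chr1 = paste0("attaaa", "TCATCTCATCTCAT", "TGG"))
  expect_equal(length(pasSites(scanEditablePAS(soft, ed))), 1L)
  expect_equal(length(pasSites(scanEditablePAS(soft, ed,
                                               maskSoftmasked = TRUE))), 0L)
  # empty input
  expect_equal(length(pasSites(scanEditablePAS(c(chr1 = "CGCGCG"), ed))), 0L)
})

test_that("scan records respect sequence bounds and never contain N", {
  ed <- testEditor()
  set.seed(31)
  for (i in 1:10) {
    seq <- randomGenome(800, prob = c(A = 0.3, C = 0.15, G = 0.15, T = 0.3))
    # sprinkle N and push a motif against each end
    substr(seq, 1, 6) <- "ATTAAA"
    substr(seq, 795, 800) <- "AATAAA"
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    chars[sample(800, 20)] <- "N"
    g <- c(chr1 = paste(chars, collapse = ""))
    scan <- scanEditablePAS(g, ed, engine = "direct")
    gd <- as.data.frame(pasGuides(scan))
    if (nrow(gd)) {
      expect_true(all(gd$protoStart >= 0 & gd$protoEnd <= 800))
      expect_true(all(gd$pamStart >= 0 & gd$pamEnd <= 800))
      expect_false(any(grepl("N", gd$protospacer)))
      expect_false(any(grepl("N", gd$pam)))
    }
  }
})

test_that("BED and guide TSV writers emit sorted, round-trippable output", {
  ed <- testEditor()
  # one site served by two PAMs at gaps 10 and 14
  seq <- paste0("CTCT", "ATTAAA", "TCATCTCATC", "AGG", "T", "TGG", "TT")
  scan <- scanEditablePAS(c(chr1 = seq), ed, engine = "direct")
  s <- pasSites(scan)
  expect_equal(length(s), 1L)
  expect_equal(S4Vectors::mcols(s)$guideCount, 2L)
  bed <- tempfile(fileext = ".bed")
  tsv <- tempfile(fileext = ".tsv")
  writeScanBed(scan, bed)
  writeGuidesTsv(scan, tsv)
  lines <- readLines(bed)
  expect_equal(length(lines), 1L)
  expect_equal(strsplit(lines, "\t")[[1]],
               c("chr1", "4", "10", "ATTAAA", "2", "+"))
  gtab <- utils::read.delim(tsv)
  expect_equal(nrow(gtab), 2L)
  expect_equal(sort(gtab$pam), c("AGG", "TGG"))
  # round trip through the BED reader
  back <- readScanBed(bed)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(s))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(s))
  expect_equal(back$score, 2)
  # empty scan: valid empty BED, TSV with header only
  empty <- scanEditablePAS(c(chr1 = "CGCGCGCG"), ed)
  writeScanBed(empty, bed)
  writeGuidesTsv(empty, tsv)
  expect_equal(length(readLines(bed)), 0L)
  expect_equal(nrow(utils::read.delim(tsv)), 0L)
  expect_equal(length(readScanBed(bed)), 0L)
})
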