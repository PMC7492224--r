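test_that("single-codon exon skip removes exactly one residue", {
  tx <- toyTranscript()
  expect_equal(refProteinLength(tx), 5)
  cons <- skipExon(tx, 2)
  expect_equal(frameStatus(cons), "in_frame")
  expect_equal(proteinLength(cons), 4)
  expect_equal(aaLost(cons), 1)
  expect_true(is.na(stopExon(cons)))
  expect_equal(hgvsR(cons), "r.7_9del")
})

test_that("terminal, non-coding and start/stop-removing skips are rejected", {
  tx <- toyTranscript()
  expect_error(skipExon(tx, 1), "terminal")
  expect_error(skipExon(tx, 3), "terminal")
  expect_error(skipExon(tx, 9), "outside")
  # an internal exon lying wholly in the 5' UTR is rejected as non-coding
  nc <- TranscriptModel("nc", paste0("AAAA", "CCCC", "ATGGCTTAA", "TTT"),
                        cbind(c(1, 5, 9), c(4, 8, 20)),
                        cdsStart = 9, cdsEnd = 17)
  expect_error(skipExon(nc, 2), "non-coding")
})

test_that("frame law: frameshift iff net length change is not a multiple of 3", {
  lens <- c(3, 6, 9, 69, 70, 71, 138, 139)
  for (seed in 1:20) {
    len <- lens[(seed - 1) %% length(lens) + 1]
    sim <- simTranscript(plantExonLength = len, seed = seed)
    cons <- skipExon(sim$transcript, sim$truth$exon)
    expect_equal(frameStatus(cons),
                 if (len %% 3 == 0) "in_frame" else "frameshift",
                 info = paste("seed", seed, "len", len))
    expect_equal(proteinLength(cons), sim$truth$proteinLength,
                 info = paste("seed", seed))
    expect_equal(aaLost(cons), sim$truth$aaLost)
  }
})

test_that("in-frame skips preserve the downstream protein sequence", {
  for (seed in 21:30) {
    sim <- simTranscript(plantExonLength = 138, seed = seed)
    tx <- sim$transcript
    cons <- skipExon(tx, sim$truth$exon)
    expect_equal(frameStatus(cons), "in_frame")
    expect_equal(aaLost(cons), 46)
    ref <- as.character(refProtein(tx))
    # independent route: excise the exon from the cDNA by string surgery
    # and translate with Biostrings, then compare with the reference
    # sequence minus the 46-residue block
    ex <- exonRanges(tx)[sim$truth$exon]
    cdna <- as.character(cdnaSeq(tx))
    edited <- paste0(substr(cdna, 1, IRanges::start(ex) - 1),
                     substr(cdna, IRanges::end(ex) + 1, nchar(cdna)))
    cs <- IRanges::start(cdsRange(tx))
    ce <- IRanges::end(cdsRange(tx)) - IRanges::width(ex)
    mutAA <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(edited, cs, ce))))
    mutAA <- sub("\\*$", "", mutAA)
    del <- parseHgvsRDel(hgvsR(cons))
    firstCodon <- (del$start - 1) %/% 3 + 1
    expected <- paste0(substr(ref, 1, firstCodon - 1),
                       substr(ref, firstCodon + 46, nchar(ref)))
    expect_equal(mutAA, expected, info = paste("seed", seed))
    expect_equal(proteinLength(cons), nchar(expected))
  }
})

test_that("every frameshift consequence truncates below the reference length", {
  fsLens <- c(70, 100, 121)
  for (seed in 31:60) {
    len <- fsLens[(seed - 1) %% 3 + 1]
    sim <- simTranscript(plantExonLength = len, seed = seed)
    cons <- skipExon(sim$transcript, sim$truth$exon)
    expect_equal(frameStatus(cons), "frameshift")
    expect_lt(proteinLength(cons),
              refProteinLength(sim$transcript))
  }
})

test_that("fsTer nomenclature arithmetic matches re-translated lengths", {
  expect_equal(fsLength(1097, 16), 1111)
  expect_equal(fsLength(9, 2), 9)
  expect_equal(fsLength(1, 2), 1)
  expect_error(fsLength(0, 2))
  expect_error(fsLength(5, 1))
  # oracle equivalence on randomized transcripts: whenever applyIndel emits
  # fsTer nomenclature, the length implied by the nomenclature equals the
  # length found by re-translation
  nChecked <- 0
  for (seed in 1:200) {
    sim <- simTranscript(nExons = 5, seed = 1000 + seed)
    tx <- sim$transcript
    cdsLen <- IRanges::width(cdsRange(tx))
    pos <- sample(seq(4, cdsLen - 10), 1)
    delLen <- sample(c(1, 2, 4), 1)
    cons <- applyIndel(tx, pos, pos + delLen - 1)
    m <- regmatches(hgvsP(cons),
                    regexec("^p\\.\\([A-Za-z]{3}(\\d+)[A-Za-z]{3}fsTer(\\d+)\\)$",
                            hgvsP(cons)))[[1]]
    if (length(m)) {
      nChecked <- nChecked + 1
      expect_equal(fsLength(as.integer(m[2]), as.integer(m[3])),
                   proteinLength(cons),
                   info = paste("seed", seed, hgvsP(cons)))
    }
  }
  expect_gt(nChecked, 100)
})

test_that("delins and in-frame deletions report correct frame and loss", {
  tx <- toyTranscript()
  # net +5 nt: frameshift
  cons <- applyIndel(tx, 6, 6, "GTAAAG")
  expect_equal(frameStatus(cons), "frameshift")
  # 3-nt in-frame deletion of a whole codon loses exactly 1 aa
  cons2 <- applyIndel(tx, 7, 9)
  expect_equal(frameStatus(cons2), "in_frame")
  expect_equal(aaLost(cons2), 1)
  # HGVS right-aligns deletions in residue runs: the 3'-most Ala is named
  expect_equal(hgvsP(cons2), "p.(Ala4del)")
  expect_error(applyIndel(tx, 30, 31), "outside")
})

test_that("early frameshift with immediate stop matches fsTer2 accounting", {
  # mirror of a SMAD1-like c.27delinsGTAAAG event: replace the last base of
  # codon 9 so codon 10 of the mutant frame is TAA
  sim <- simTranscript(nExons = 4, exonLength = c(90, 120), seed = 77)
  tx <- sim$transcript
  cons <- applyIndel(tx, 27, 27, "GTAAAG")
  expect_equal(frameStatus(cons), "frameshift")
  if (grepl("fsTer2\\)$", hgvsP(cons))) expect_equal(proteinLength(cons), 9)
})

test_that("hgvs skip strings round-trip through both dialects", {
  tx <- toyTranscript()
  expect_equal(hgvsSkip(tx, 2), "r.7_9del")
  expect_equal(hgvsSkip(tx, 2, "legacy"), "r.del7_9")
  p <- parseHgvsRDel("r.del3330_3399")
  expect_equal(p, list(start = 3330L, end = 3399L))
  canonical <- sprintf("r.%d_%ddel", p$start, p$end)
  expect_equal(canonical, "r.3330_3399del")
  expect_equal(parseHgvsRDel(canonical), p)
  expect_error(parseHgvsRDel("r.whatever"), "parse")
})

test_that("reconstructed ABCC8-like transcript reproduces the documented skips", {
  tx <- syntheticAbcc8Transcript()
  expect_equal(refProteinLength(tx), 1581)
  expect_equal(hgvsSkip(tx, 27), "r.3330_3399del")
  expect_equal(hgvsSkip(tx, 27, "legacy"), "r.del3330_3399")

  s27 <- skipExon(tx, 27)
  expect_equal(frameStatus(s27), "frameshift")
  expect_equal(proteinLength(s27), 1118)
  expect_equal(stopExon(s27), 28)

  s22 <- skipExon(tx, 22)
  expect_equal(frameStatus(s22), "in_frame")
  expect_equal(aaLost(s22), 46)

  expect_equal(proteinLength(skipExon(tx, 20)), 836)
  expect_equal(proteinLength(skipExon(tx, 26)), 1056)
  expect_equal(proteinLength(skipExon(tx, 32)), 1292)

  del <- applyIndel(tx, 3288, 3289)
  expect_equal(hgvsP(del), "p.(His1097ProfsTer16)")
  expect_equal(proteinLength(del), 1111)
})

test_that("transcript validity catches malformed models", {
  expect_error(TranscriptModel("bad", "AAAATGGCTTAATTT",
                               cbind(c(1, 9), c(7, 15)), 4, 12),
               "contiguous|cover")
  expect_error(TranscriptModel("bad", "AAACTGGCTTAATTT",
                               cbind(c(1, 8), c(7, 15)), 4, 12),
               "ATG")
  expect_error(TranscriptModel("bad", "AAAATGGCTTACTTT",
                               cbind(c(1, 8), c(7, 15)), 4, 12),
               "stop")
})
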