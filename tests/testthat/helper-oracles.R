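# Independent oracles and shared fixture builders for the test suite.

# Hand-written ACMG combiner, independent of the declarative rule table in
# acmgRules(): straight transcription of the published combining criteria
# as nested conditionals over code counts.
oracleCombine <- function(codes) {
  codes <- unique(codes)
  pvs <- sum(grepl("^PVS", codes))
  ps <- sum(grepl("^PS[0-9]", codes))
  pm <- sum(grepl("^PM", codes))
  pp <- sum(grepl("^PP", codes))
  ba <- sum(grepl("^BA", codes))
  bs <- sum(grepl("^BS", codes))
  bp <- sum(grepl("^BP", codes))
  path <- FALSE; lp <- FALSE
  if (pvs >= 1) {
    if (ps >= 1 || pm >= 2 || (pm >= 1 && pp >= 1) || pp >= 2) path <- TRUE
    if (pm >= 1) lp <- TRUE
  }
  if (ps >= 2) path <- TRUE
  if (ps == 1) {
    if (pm >= 3 || (pm >= 2 && pp >= 2) || (pm >= 1 && pp >= 4)) path <- TRUE
    if (pm >= 1 || pp >= 2) lp <- TRUE
  }
  if (ps >= 2) lp <- TRUE  # stronger evidence subsumes
  if (pm >= 3 || (pm >= 2 && pp >= 2) || (pm >= 1 && pp >= 4)) lp <- TRUE
  ben <- ba >= 1 || bs >= 2
  lb <- (bs >= 1 && bp >= 1) || bp >= 2
  if ((path || lp) && (ben || lb)) return("VUS")
  if (path) return("pathogenic")
  if (lp) return("likely_pathogenic")
  if (ben) return("benign")
  if (lb) return("likely_benign")
  "VUS"
}

acmgVocabulary <- function() {
  c("PVS1", paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5),
    "BA1", paste0("BS", 1:4), paste0("BP", 1:7))
}

# a small hand-checkable transcript: 3 exons, CDS = ATG + 4 codons + TAA
# spread over the exon structure, with a 3-nt middle exon that is exactly
# one codon
toyTranscript <- function() {
  # cDNA:  exon1 = 5'UTR(3) + ATG GCT | exon2 = GCA | exon3 = GCC TGG TAA + UTR(3)
  TranscriptModel("toy",
    cdna = paste0("AAA", "ATGGCT", "GCA", "GCCTGGTAA", "TTT"),
    exons = cbind(c(1, 10, 13), c(9, 12, 24)),
    cdsStart = 4, cdsEnd = 21)
}

predictorFixture <- function()
  system.file("extdata", "abcc8_predictor_calls.tsv", package = "variantTriage")

clinicalFixture <- function()
  system.file("extdata", "abcc8_clinical_table.tsv", package = "variantTriage")
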