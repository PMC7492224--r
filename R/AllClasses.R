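#' TranscriptModel: exon structure, cDNA sequence and CDS range
#'
#' Container for a processed transcript in cDNA space: the spliced cDNA
#' sequence, the ordered exon segmentation of that sequence (1-based,
#' inclusive, contiguous), and the CDS span within it. HGVS c./r. coordinates
#' used elsewhere in the package are relative to the first base of the start
#' codon, i.e. `c.1 = cdsStart(tx)` in cDNA coordinates.
#'
#' @slot txId accession or label for the transcript.
#' @slot cdna [Biostrings::DNAString] spliced cDNA sequence.
#' @slot exons [IRanges::IRanges] exon segments partitioning the cDNA.
#' @slot cdsStart,cdsEnd integer bounds of the CDS (1-based, inclusive,
#'   in cDNA coordinates; the CDS includes the stop codon).
#'
#' @examples
#' tx <- simTranscript(nExons = 5, seed = 1)$transcript
#' tx
#' refProteinLength(tx)
#' @name TranscriptModel-class
#' @aliases TranscriptModel-class
#' @exportClass TranscriptModel
setClass("TranscriptModel",
  representation(
    txId = "character",
    cdna = "DNAString",
    exons = "IRanges",
    cdsStart = "integer",
    cdsEnd = "integer"
  )
)

setValidity("TranscriptModel", function(object) {
  msg <- character()
  n <- length(object@cdna)
  ex <- object@exons
  if (length(ex) < 1L) msg <- c(msg, "at least one exon required")
  if (length(ex) >= 1L) {
    if (IRanges::start(ex)[1] != 1L || IRanges::end(ex)[length(ex)] != n)
      msg <- c(msg, "exons must cover the cDNA from base 1 to its end")
    if (length(ex) > 1L &&
        !all(IRanges::start(ex)[-1] == IRanges::end(ex)[-length(ex)] + 1L))
      msg <- c(msg, "exons must be contiguous and non-overlapping")
  }
  cs <- object@cdsStart; ce <- object@cdsEnd
  if (length(cs) != 1L || length(ce) != 1L || is.na(cs) || is.na(ce)) {
    msg <- c(msg, "cdsStart/cdsEnd must be single integers")
  } else {
    if (cs < 1L || ce > n || ce <= cs) msg <- c(msg, "CDS outside cDNA")
    cdsLen <- ce - cs + 1L
    if (cdsLen %% 3L != 0L) msg <- c(msg, "CDS length not divisible by 3")
    if (cdsLen %% 3L == 0L && ce <= n) {
      cds <- Biostrings::subseq(object@cdna, cs, ce)
      aa <- as.character(Biostrings::translate(cds, no.init.codon = TRUE))
      if (as.character(Biostrings::subseq(cds, 1L, 3L)) != "ATG")
        msg <- c(msg, "CDS must begin with ATG")
      if (substr(aa, nchar(aa), nchar(aa)) != "*")
        msg <- c(msg, "CDS must end with a stop codon")
      if (grepl("\\*", substr(aa, 1L, nchar(aa) - 1L)))
        msg <- c(msg, "CDS contains an internal stop codon")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TranscriptModel
#'
#' @param txId transcript label (e.g. an accession).
#' @param cdna cDNA sequence as a character string or
#'   [Biostrings::DNAString].
#' @param exons [IRanges::IRanges] of exon bounds, or a two-column matrix /
#'   data.frame of (start, end) pairs in cDNA coordinates.
#' @param cdsStart,cdsEnd CDS bounds in cDNA coordinates (1-based inclusive,
#'   stop codon included).
#' @return a validated [TranscriptModel-class] object.
#' @examples
#' tx <- TranscriptModel("toy",
#'   cdna = paste0("AAA", "ATGGCTGCAGCT", "TGA", "TTT"),
#'   exons = cbind(c(1, 8, 14), c(7, 13, 22)),
#'   cdsStart = 4, cdsEnd = 18)
#' @export
TranscriptModel <- function(txId, cdna, exons, cdsStart, cdsEnd) {
  if (is.character(cdna)) cdna <- Biostrings::DNAString(cdna)
  if (!is(exons, "IRanges")) {
    exons <- as.matrix(exons)
    exons <- IRanges::IRanges(start = as.integer(exons[, 1]),
                              end = as.integer(exons[, 2]))
  }
  new("TranscriptModel", txId = as.character(txId), cdna = cdna,
      exons = exons, cdsStart = as.integer(cdsStart),
      cdsEnd = as.integer(cdsEnd))
}

#' ProteinConsequence: outcome of a simulated transcript edit
#'
#' @slot frameStatus `"in_frame"` or `"frameshift"`.
#' @slot hgvsR HGVS RNA-level description (canonical dialect).
#' @slot hgvsP HGVS protein-level description (may be `"p.?"` when the
#'   consequence is not expressible as a simple substitution/fs).
#' @slot proteinLength length of the resulting protein in amino acids,
#'   excluding the terminating codon.
#' @slot aaLost reference protein length minus consequence length.
#' @slot stopExon index of the former exon that harbours the novel stop
#'   codon, or `NA` when translation terminates at the reference stop.
#' @name ProteinConsequence-class
#' @exportClass ProteinConsequence
setClass("ProteinConsequence",
  representation(
    frameStatus = "character",
    hgvsR = "character",
    hgvsP = "character",
    proteinLength = "integer",
    aaLost = "integer",
    stopExon = "integer"
  )
)

#' DepthExperiment: per-target read depth across a cohort
#'
#' Thin [SummarizedExperiment::RangedSummarizedExperiment] subclass holding
#' one `"depth"` assay (target intervals x samples, non-negative) with a
#' `gene` column on its row ranges. Row ranges use the usual half-open BED
#' origin on input (converted to 1-based GRanges internally).
#'
#' @name DepthExperiment-class
#' @exportClass DepthExperiment
setClass("DepthExperiment", contains = "RangedSummarizedExperiment")

setValidity("DepthExperiment", function(object) {
  msg <- character()
  if (!"depth" %in% names(SummarizedExperiment::assays(object)))
    msg <- c(msg, "assay 'depth' is required")
  else if (any(SummarizedExperiment::assay(object, "depth") < 0, na.rm = TRUE))
    msg <- c(msg, "depths must be non-negative")
  if (!"gene" %in% names(S4Vectors::mcols(SummarizedExperiment::rowRanges(object))))
    msg <- c(msg, "rowRanges must carry a 'gene' metadata column")
  if (length(msg)) msg else TRUE
})

#' Construct a DepthExperiment
#'
#' @param depth numeric matrix of read depths, intervals x samples.
#' @param intervals [GenomicRanges::GRanges] with a `gene` metadata column,
#'   or a data.frame with columns `chrom`, `start`, `end`, `gene`
#'   (half-open 0-based, BED convention).
#' @param samples sample identifiers; defaults to `colnames(depth)`.
#' @return a [DepthExperiment-class].
#' @examples
#' de <- simDepthCohort(nSamples = 4, nIntervals = 6, seed = 1)$depths
#' de
#' @export
DepthExperiment <- function(depth, intervals, samples = colnames(depth)) {
  depth <- as.matrix(depth)
  if (is.data.frame(intervals)) {
    intervals <- GenomicRanges::GRanges(
      seqnames = intervals$chrom,
      ranges = IRanges::IRanges(start = intervals$start + 1L,
                                end = intervals$end),
      gene = intervals$gene)
  }
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(depth)))
  colnames(depth) <- samples
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(depth = depth),
    rowRanges = intervals,
    colData = S4Vectors::DataFrame(sample = samples, row.names = samples))
  new("DepthExperiment", se)
}

#' AlignmentWindow: fixed-width multi-species residue columns
#'
#' Pre-aligned sequence windows from several species, centred on the
#' position of a variant (centre column `(width + 1) / 2`; position 3 for
#' the default width 5).
#'
#' @slot variantId label of the variant the window is centred on.
#' @slot alphabet `"amino_acid"` or `"nucleotide"`.
#' @slot sequences [Biostrings::AAStringSet] or [Biostrings::DNAStringSet],
#'   one entry per species (names are the species), all of equal width.
#' @name AlignmentWindow-class
#' @exportClass AlignmentWindow
setClass("AlignmentWindow",
  representation(
    variantId = "character",
    alphabet = "character",
    sequences = "XStringSet"
  )
)

setValidity("AlignmentWindow", function(object) {
  msg <- character()
  if (!object@alphabet %in% c("amino_acid", "nucleotide"))
    msg <- c(msg, "alphabet must be 'amino_acid' or 'nucleotide'")
  w <- unique(Biostrings::width(object@sequences))
  if (length(w) > 1L) msg <- c(msg, "all sequences must have equal width")
  if (length(object@sequences) &&
      is.null(names(object@sequences)))
    msg <- c(msg, "sequences must be named by species")
  if (length(msg)) msg else TRUE
})

#' Construct an AlignmentWindow
#'
#' @param sequences named character vector (or XStringSet) of equal-length
#'   species windows; names are species labels.
#' @param alphabet `"amino_acid"` (default) or `"nucleotide"`.
#' @param variantId label for the centred variant.
#' @return an [AlignmentWindow-class].
#' @examples
#' w <- AlignmentWindow(c(human = "LIHRK", mouse = "LIHRK", frog = "LVHRK"))
#' logoMatrix(w)
#' @export
AlignmentWindow <- function(sequences, alphabet = c("amino_acid", "nucleotide"),
                            variantId = "variant") {
  alphabet <- match.arg(alphabet)
  if (is.character(sequences)) {
    sequences <- if (alphabet == "amino_acid")
      Biostrings::AAStringSet(sequences) else
      Biostrings::DNAStringSet(sequences)
  }
  new("AlignmentWindow", variantId = as.character(variantId),
      alphabet = alphabet, sequences = sequences)
}
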