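#' @name accessors
#' @title Accessors for variantTriage classes
#' @description Slot accessors for [TranscriptModel-class],
#'   [ProteinConsequence-class], [DepthExperiment-class] and
#'   [AlignmentWindow-class] objects.
#' @param x an object of the documented class.
#' @keywords internal
NULL

#' @rdname accessors
#' @export
setGeneric("txId", function(x) standardGeneric("txId"))
#' @rdname accessors
#' @export
setMethod("txId", "TranscriptModel", function(x) x@txId)

#' @rdname accessors
#' @export
setGeneric("cdnaSeq", function(x) standardGeneric("cdnaSeq"))
#' @rdname accessors
#' @export
setMethod("cdnaSeq", "TranscriptModel", function(x) x@cdna)

#' @rdname accessors
#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))
#' @rdname accessors
#' @export
setMethod("exonRanges", "TranscriptModel", function(x) x@exons)

#' @rdname accessors
#' @export
setGeneric("cdsRange", function(x) standardGeneric("cdsRange"))
#' @rdname accessors
#' @export
setMethod("cdsRange", "TranscriptModel", function(x)
  IRanges::IRanges(start = x@cdsStart, end = x@cdsEnd))

#' CDS and reference protein of a transcript
#'
#' `cdsSeq` extracts the CDS (stop codon included); `refProtein` translates
#' it (stop stripped); `refProteinLength` is its length in amino acids.
#'
#' @param tx a [TranscriptModel-class].
#' @return a [Biostrings::DNAString], [Biostrings::AAString] or integer.
#' @export
cdsSeq <- function(tx) Biostrings::subseq(tx@cdna, tx@cdsStart, tx@cdsEnd)

#' @rdname cdsSeq
#' @export
refProtein <- function(tx) {
  aa <- Biostrings::translate(cdsSeq(tx))
  Biostrings::subseq(aa, 1L, length(aa) - 1L)
}

#' @rdname cdsSeq
#' @export
refProteinLength <- function(tx) length(refProtein(tx))

#' @rdname accessors
#' @export
setGeneric("frameStatus", function(x) standardGeneric("frameStatus"))
#' @rdname accessors
#' @export
setMethod("frameStatus", "ProteinConsequence", function(x) x@frameStatus)

#' @rdname accessors
#' @export
setGeneric("hgvsR", function(x) standardGeneric("hgvsR"))
#' @rdname accessors
#' @export
setMethod("hgvsR", "ProteinConsequence", function(x) x@hgvsR)

#' @rdname accessors
#' @export
setGeneric("hgvsP", function(x) standardGeneric("hgvsP"))
#' @rdname accessors
#' @export
setMethod("hgvsP", "ProteinConsequence", function(x) x@hgvsP)

#' @rdname accessors
#' @export
setGeneric("proteinLength", function(x) standardGeneric("proteinLength"))
#' @rdname accessors
#' @export
setMethod("proteinLength", "ProteinConsequence", function(x) x@proteinLength)

#' @rdname accessors
#' @export
setGeneric("aaLost", function(x) standardGeneric("aaLost"))
#' @rdname accessors
#' @export
setMethod("aaLost", "ProteinConsequence", function(x) x@aaLost)

#' @rdname accessors
#' @export
setGeneric("stopExon", function(x) standardGeneric("stopExon"))
#' @rdname accessors
#' @export
setMethod("stopExon", "ProteinConsequence", function(x) x@stopExon)

#' @rdname accessors
#' @export
setGeneric("depth", function(x) standardGeneric("depth"))
#' @rdname accessors
#' @export
setMethod("depth", "DepthExperiment", function(x)
  SummarizedExperiment::assay(x, "depth"))

#' @rdname accessors
#' @export
setGeneric("species", function(x) standardGeneric("species"))
#' @rdname accessors
#' @export
setMethod("species", "AlignmentWindow", function(x) names(x@sequences))

#' @rdname accessors
#' @export
setGeneric("windowWidth", function(x) standardGeneric("windowWidth"))
#' @rdname accessors
#' @export
setMethod("windowWidth", "AlignmentWindow", function(x)
  if (length(x@sequences)) Biostrings::width(x@sequences)[1] else 0L)

#' Centre column of an alignment window
#'
#' The variant sits at column `(width + 1) / 2`: column 3 for the default
#' width of 5.
#' @param x an [AlignmentWindow-class].
#' @return integer column index.
#' @export
centerPosition <- function(x) (windowWidth(x) + 1L) %/% 2L

setMethod("show", "TranscriptModel", function(object) {
  cat("TranscriptModel ", object@txId, "\n",
      " cDNA: ", length(object@cdna), " nt in ", length(object@exons),
      " exons\n",
      " CDS:  ", object@cdsStart, "..", object@cdsEnd, " (",
      refProteinLength(object), " aa)\n", sep = "")
})

setMethod("show", "ProteinConsequence", function(object) {
  cat("ProteinConsequence\n",
      " frame:   ", object@frameStatus, "\n",
      " hgvs:    ", object@hgvsR, " / ", object@hgvsP, "\n",
      " protein: ", object@proteinLength, " aa (", object@aaLost,
      " aa lost)\n", sep = "")
  if (!is.na(object@stopExon))
    cat("  novel stop in former exon ", object@stopExon, "\n", sep = "")
})

setMethod("show", "AlignmentWindow", function(object) {
  cat("AlignmentWindow '", object@variantId, "' (", object@alphabet, "): ",
      length(object@sequences), " species x ", windowWidth(object),
      " columns, variant at column ", centerPosition(object), "\n", sep = "")
})
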