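# Exon-skipping / indel consequence simulation on a TranscriptModel:
# re-translation from the CDS start, frame status, HGVS r./p. strings,
# premature-stop discovery and truncated protein lengths.

.AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
          E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
          M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
          Y = "Tyr", V = "Val", `*` = "Ter")

.aa3 <- function(x) unname(.AA3[strsplit(x, "")[[1]]])

# cDNA position -> HGVS c. coordinate and back
.toC <- function(tx, pos) pos - tx@cdsStart + 1L
.toCdna <- function(tx, cpos) cpos + tx@cdsStart - 1L

# translate the edited cDNA from the (unchanged) CDS start to the first
# stop; returns the protein string (stop excluded) and the edited-cDNA
# position of the stop codon's first base (NA if translation runs off the
# 3' end without terminating)
.translateFrom <- function(cdna, cdsStart) {
  tailSeq <- Biostrings::subseq(cdna, cdsStart, length(cdna))
  n <- length(tailSeq) - length(tailSeq) %% 3L
  aa <- as.character(Biostrings::translate(Biostrings::subseq(tailSeq, 1L, n),
                                           no.init.codon = TRUE))
  k <- regexpr("*", aa, fixed = TRUE)
  if (k == -1L) list(protein = aa, stopPos = NA_integer_)
  else list(protein = substr(aa, 1L, k - 1L),
            stopPos = cdsStart + 3L * (as.integer(k) - 1L))
}

# HGVS p. string from reference and mutant protein strings
.hgvsPDiff <- function(ref, mut, frameshift) {
  if (identical(ref, mut)) return("p.(=)")
  nR <- nchar(ref); nM <- nchar(mut)
  refV <- strsplit(ref, "")[[1]]; mutV <- strsplit(mut, "")[[1]]
  upto <- min(nR, nM)
  mism <- which(refV[seq_len(upto)] != mutV[seq_len(upto)])
  f <- if (length(mism)) mism[1] else upto + 1L
  if (frameshift) {
    if (f > nR) return("p.?") # pure extension past the reference stop
    if (f > nM) # the first novel codon is itself a stop
      return(sprintf("p.(%s%dTer)", .AA3[refV[f]], f))
    return(sprintf("p.(%s%d%sfsTer%d)", .AA3[refV[f]], f, .AA3[mutV[f]],
                   nM - f + 2L))
  }
  if (nM < nR) {
    d <- nR - nM
    # clean deletion: downstream sequence must match the reference
    if (f <= nM + 1L &&
        identical(substr(mut, f, nM), substr(ref, f + d, nR))) {
      if (d == 1L) return(sprintf("p.(%s%ddel)", .AA3[refV[f]], f))
      return(sprintf("p.(%s%d_%s%ddel)", .AA3[refV[f]], f,
                     .AA3[refV[f + d - 1L]], f + d - 1L))
    }
  }
  "p.?"
}

.exonOfCdnaPos <- function(tx, pos) {
  which(IRanges::start(tx@exons) <= pos & IRanges::end(tx@exons) >= pos)[1]
}

.makeConsequence <- function(tx, newCdna, netChange, hgvsRStr, mapBack) {
  tr <- .translateFrom(newCdna, tx@cdsStart)
  refP <- as.character(refProtein(tx))
  frameshift <- (netChange %% 3L) != 0L
  stopEx <- NA_integer_
  if (!is.na(tr$stopPos)) {
    origStop <- mapBack(tr$stopPos)
    if (origStop != tx@cdsEnd - 2L)
      stopEx <- .exonOfCdnaPos(tx, origStop)
  }
  new("ProteinConsequence",
      frameStatus = if (frameshift) "frameshift" else "in_frame",
      hgvsR = hgvsRStr,
      hgvsP = .hgvsPDiff(refP, tr$protein, frameshift),
      proteinLength = nchar(tr$protein),
      aaLost = nchar(refP) - nchar(tr$protein),
      stopExon = stopEx)
}

#' Simulate complete skipping of an internal coding exon
#'
#' Removes the exon from the cDNA, re-translates from the unchanged CDS
#' start, locates the first stop codon and reports frame status, HGVS
#' strings and the truncated protein length (terminating codon excluded).
#' A skip is in frame iff the exon length is divisible by 3; an in-frame
#' skip that creates no novel stop loses exactly `exon length / 3`
#' residues.
#'
#' @param tx a [TranscriptModel-class].
#' @param exonIndex index of an internal exon lying fully inside the CDS
#'   (a skip that would remove the CDS start or stop codon is rejected).
#' @param dialect `"canonical"` emits `r.<start>_<end>del`; `"legacy"`
#'   emits the `r.del<start>_<end>` dialect.
#' @return a [ProteinConsequence-class].
#' @examples
#' tx <- syntheticAbcc8Transcript()
#' skipExon(tx, 27)   # frameshift, 1118 aa, stop in former exon 28
#' skipExon(tx, 22)   # in frame, 46 aa lost
#' @export
skipExon <- function(tx, exonIndex, dialect = c("canonical", "legacy")) {
  dialect <- match.arg(dialect)
  .checkSkippable(tx, exonIndex)
  s <- IRanges::start(tx@exons)[exonIndex]
  e <- IRanges::end(tx@exons)[exonIndex]
  newCdna <- Biostrings::xscat(Biostrings::subseq(tx@cdna, 1L, s - 1L),
                               Biostrings::subseq(tx@cdna, e + 1L,
                                                  length(tx@cdna)))
  exLen <- e - s + 1L
  mapBack <- function(pos) if (pos < s) pos else pos + exLen
  .makeConsequence(tx, newCdna, -exLen, hgvsSkip(tx, exonIndex, dialect),
                   mapBack)
}

.checkSkippable <- function(tx, exonIndex) {
  nEx <- length(tx@exons)
  if (exonIndex < 1L || exonIndex > nEx)
    stop("exon index ", exonIndex, " outside 1..", nEx)
  if (exonIndex == 1L || exonIndex == nEx)
    stop("refusing to skip a terminal exon (exon ", exonIndex, ")")
  s <- IRanges::start(tx@exons)[exonIndex]
  e <- IRanges::end(tx@exons)[exonIndex]
  if (e < tx@cdsStart || s > tx@cdsEnd)
    stop("exon ", exonIndex, " is non-coding; skipping it does not change ",
         "the protein")
  if (s <= tx@cdsStart + 2L)
    stop("skipping exon ", exonIndex, " would remove the CDS start codon")
  if (e >= tx@cdsEnd - 2L)
    stop("skipping exon ", exonIndex, " would remove the CDS stop codon")
}

#' HGVS r. description of an exon skip
#'
#' Formats the skip of an exon as an RNA-level deletion of its coding
#' (c./r.) span. Unlike [skipExon] this only names the event, so it also
#' accepts exons that straddle the CDS start (the emitted span is the
#' exon's intersection with the CDS).
#'
#' @inheritParams skipExon
#' @return character, e.g. `"r.3330_3399del"` (canonical) or
#'   `"r.del3330_3399"` (legacy).
#' @seealso [parseHgvsRDel] for the inverse.
#' @export
hgvsSkip <- function(tx, exonIndex, dialect = c("canonical", "legacy")) {
  dialect <- match.arg(dialect)
  nEx <- length(tx@exons)
  if (exonIndex < 1L || exonIndex > nEx)
    stop("exon index ", exonIndex, " outside 1..", nEx)
  s <- max(IRanges::start(tx@exons)[exonIndex], tx@cdsStart)
  e <- min(IRanges::end(tx@exons)[exonIndex], tx@cdsEnd)
  if (e < s) stop("exon ", exonIndex, " does not overlap the CDS")
  cs <- .toC(tx, s); ce <- .toC(tx, e)
  if (dialect == "canonical") sprintf("r.%d_%ddel", cs, ce)
  else sprintf("r.del%d_%d", cs, ce)
}

#' Parse an HGVS r. deletion string (canonical or legacy dialect)
#'
#' Accepts `r.<start>_<end>del` and the legacy `r.del<start>_<end>`;
#' re-emitting the parsed interval through the canonical formatter is
#' idempotent.
#'
#' @param x character string.
#' @return list with integer `start` and `end`.
#' @examples
#' parseHgvsRDel("r.del3330_3399")  # legacy dialect accepted
#' @export
parseHgvsRDel <- function(x) {
  m <- regmatches(x, regexec("^r\\.(\\d+)_(\\d+)del$", x))[[1]]
  if (!length(m))
    m <- regmatches(x, regexec("^r\\.del(\\d+)_(\\d+)$", x))[[1]]
  if (!length(m)) stop("cannot parse HGVS r. deletion: '", x, "'")
  list(start = as.integer(m[2]), end = as.integer(m[3]))
}

#' Apply a small deletion / delins to the CDS and derive its consequence
#'
#' Edits the cDNA (deleting the c. interval and inserting `insertedSeq`,
#' which may be empty), re-translates from the CDS start and reports the
#' consequence, with HGVS protein frameshift nomenclature
#' `p.(Xaa#YaafsTer#)` when the net length change is not a multiple of 3.
#'
#' @param tx a [TranscriptModel-class].
#' @param start,end 1-based inclusive bounds of the edited interval in
#'   HGVS c. coordinates (must lie within the CDS, upstream of the stop
#'   codon).
#' @param insertedSeq replacement sequence (default `""`, a pure deletion).
#' @return a [ProteinConsequence-class].
#' @examples
#' tx <- syntheticAbcc8Transcript()
#' applyIndel(tx, 3288, 3289)  # p.(His1097ProfsTer16), 1111 aa
#' @export
applyIndel <- function(tx, start, end, insertedSeq = "") {
  start <- as.integer(start); end <- as.integer(end)
  cdsLen <- tx@cdsEnd - tx@cdsStart + 1L
  if (start < 1L || end > cdsLen - 3L || end < start)
    stop("interval c.", start, "_", end, " outside the CDS (coding length ",
         cdsLen - 3L, " before the stop codon)")
  s <- .toCdna(tx, start); e <- .toCdna(tx, end)
  ins <- Biostrings::DNAString(insertedSeq)
  newCdna <- Biostrings::xscat(Biostrings::subseq(tx@cdna, 1L, s - 1L), ins,
                               Biostrings::subseq(tx@cdna, e + 1L,
                                                  length(tx@cdna)))
  delLen <- e - s + 1L
  insLen <- length(ins)
  net <- insLen - delLen
  mapBack <- function(pos) if (pos < s) pos else pos - insLen + delLen
  hgvsRStr <- if (insLen == 0L) {
    if (start == end) sprintf("r.%ddel", start)
    else sprintf("r.%d_%ddel", start, end)
  } else if (start == end) {
    sprintf("r.%ddelins%s", start, tolower(insertedSeq))
  } else sprintf("r.%d_%ddelins%s", start, end, tolower(insertedSeq))
  .makeConsequence(tx, newCdna, net, hgvsRStr, mapBack)
}

#' Truncated protein length implied by fsTer nomenclature
#'
#' HGVS `p.(Xaa<pos>Yaafs*Ter<offset>)` places the novel stop `offset`
#' codons after the first altered residue, so the truncated protein has
#' `pos + offset - 2` amino acids (stop excluded).
#'
#' @param proteinPos position of the first altered residue (>= 1).
#' @param terOffset distance to the novel stop in the mutant frame (>= 2).
#' @return integer protein length.
#' @examples
#' fsLength(1097, 16)  # 1111
#' fsLength(9, 2)      # 9
#' @export
fsLength <- function(proteinPos, terOffset) {
  stopifnot(proteinPos >= 1, terOffset >= 2)
  as.integer(proteinPos + terOffset - 2)
}
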