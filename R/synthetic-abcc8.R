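# Synthetic stand-in for the ABCC8 transcript (real accession
# ENST00000389817.7, not redistributable here). The stand-in reproduces the
# published coding architecture relevant to splice-consequence analysis:
# a 1581-aa product over 39 exons, exon 22 = c.2557_2694 (138 nt, in frame),
# exon 27 = c.3330_3399 (70 nt, frameshifting), and planted frame-shifted
# stop codons placed so that the documented consequences hold:
#   skip exon 27 -> frameshift, stop in former exon 28, 1118-aa protein
#   skip exon 22 -> in frame, 46 aa lost
#   skip exon 20 -> 836 aa;  skip exon 26 -> 1056 aa;  skip exon 32 -> 1292 aa
#   c.3288_3289del -> p.(His1097ProfsTer16), 1111 aa
# The filler sequence is random (fixed internal seed) and is NOT the real
# ABCC8 sequence. Construction is checked at build time against a naive
# codon-by-codon re-translation oracle independent of skipExon/applyIndel.

.STOPS <- c("TAA", "TAG", "TGA")

# naive oracle: residues before the first stop when reading `cds` (already
# edited, character string) codon by codon from base 1
.naiveOrf <- function(cds) {
  n <- nchar(cds) %/% 3L
  for (i in seq_len(n)) {
    codon <- substr(cds, 3L * i - 2L, 3L * i)
    if (codon %in% .STOPS) return(i - 1L)
  }
  n
}

#' Synthetic stand-in for the ABCC8 (SUR1) transcript
#'
#' Deterministically constructs a 39-exon [TranscriptModel-class] whose
#' coding geometry matches the ABCC8 exon architecture used in
#' splice-consequence analysis of PAH panel variants: a 1581-amino-acid
#' product, the in-frame 138-nt exon 22 (c.2557_2694) and the
#' frameshifting 70-nt exon 27 (c.3330_3399), with frame-shifted stop
#' codons planted so that exon skips and the c.3288_3289del frameshift
#' reproduce the documented truncated protein lengths (1118, 836, 1056,
#' 1292 and 1111 aa; 46 aa in-frame loss for exon 22).
#'
#' The filler sequence is synthetic; only the coding geometry is
#' reconstructed. All planted consequences are verified internally against
#' a naive re-translation oracle, so construction fails loudly if the
#' geometry is ever wrong.
#'
#' @return a [TranscriptModel-class] with `txId = "SYNTH_ABCC8"`.
#' @examples
#' tx <- syntheticAbcc8Transcript()
#' refProteinLength(tx)  # 1581
#' @export
syntheticAbcc8Transcript <- function() {
  nAA <- 1581L
  cdsLen <- 3L * (nAA + 1L)       # 4746, stop codon included
  utr5 <- 141L; utr3 <- 200L
  bases <- c("A", "C", "G", "T")
  nonStop <- setdiff(apply(expand.grid(bases, bases, bases), 1, paste,
                           collapse = ""), .STOPS)

  oldSeed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(1132L)

  codons <- c("ATG", sample(nonStop, nAA - 1L, replace = TRUE), "TAA")
  cds <- strsplit(paste(codons, collapse = ""), "")[[1]]
  pin <- rep(FALSE, cdsLen)
  plant <- function(at, what) {
    chars <- strsplit(what, "")[[1]]
    idx <- at + seq_along(chars) - 1L
    cds[idx] <<- chars
    pin[idx] <<- TRUE
  }
  plant(1L, "ATG"); plant(cdsLen - 2L, "TAA")
  # named residues of the documented events (cosmetic realism; Gln808,
  # Leu1096-His1097-Pro context for c.3288_3289del, Asp1132)
  plant(3L * 808L - 2L, "CAG")
  plant(3L * 1096L - 2L, "CTG")
  plant(3L * 1097L - 2L, "CAC")
  plant(3L * 1098L - 2L, "CCA")
  plant(3L * 1132L - 2L, "GAC")
  # frame-shifted stop codons that realise the documented truncations
  plant(2603L, "TAA")  # skip exon 20: stop at mutant codon 837  -> 836 aa
  plant(3336L, "TAA")  # c.3288_3289del: stop at codon 1112      -> 1111 aa
  plant(3341L, "TGA")  # skip exon 26: stop at mutant codon 1057 -> 1056 aa
  plant(3425L, "TAG")  # skip exon 27: stop at mutant codon 1119 -> 1118 aa
  plant(4005L, "TGA")  # skip exon 32: stop at mutant codon 1293 -> 1292 aa
  plant(3330L, "GCT")  # keeps the del-frame window stop-free here

  # windows that must be free of stop codons so each planted stop is the
  # FIRST one reached in its shifted frame (and the reference frame stays
  # free of internal stops); any violating triplet is repaired by setting a
  # non-pinned base to C, which no stop codon contains
  tripletAt <- function(idx) paste(cds[idx], collapse = "")
  windows <- c(
    lapply(seq(1L, cdsLen - 5L, by = 3L), function(s) s + 0:2),     # ref frame
    lapply(seq(2507L, 2600L, by = 3L), function(s) s + 0:2),        # skip 20
    lapply(seq(3294L, 3333L, by = 3L), function(s) s + 0:2),        # 3288del
    list(c(3286L, 3287L, 3290L), c(3291L, 3292L, 3293L)),
    list(c(3157L, 3330L, 3331L), c(3332L, 3333L, 3334L),
         c(3335L, 3336L, 3337L), c(3338L, 3339L, 3340L)),           # skip 26
    list(c(3328L, 3329L, 3400L)),
    lapply(seq(3401L, 3422L, by = 3L), function(s) s + 0:2),        # skip 27
    lapply(seq(3990L, 4002L, by = 3L), function(s) s + 0:2)         # skip 32
  )
  for (w in windows) {
    if (tripletAt(w) %in% .STOPS) {
      free <- w[!pin[w]]
      if (!length(free))
        stop("internal error: fully pinned stop triplet at ",
             paste(w, collapse = ","))
      cds[free[1]] <- "C"
    }
  }

  cdsStr <- paste(cds, collapse = "")
  cdna <- paste0(paste(sample(bases, utr5, replace = TRUE), collapse = ""),
                 cdsStr,
                 paste(sample(bases, utr3, replace = TRUE), collapse = ""))

  # exon lengths (cDNA space); coding boundaries pinned to the published
  # c. coordinates: exon 20 = c.2413_2506, 21 = c.2507_2556,
  # 22 = c.2557_2694, 26 = c.3158_3329, 27 = c.3330_3399, 28 = c.3400_3507,
  # 32 = c.3862_3989
  exonLens <- c(utr5 + 100L,                  # exon 1 (c.1_100)
                rep(129L, 8L), rep(128L, 10L),# exons 2-19 (to c.2412)
                94L, 50L, 138L,               # exons 20-22
                155L, 154L, 154L,             # exons 23-25 (to c.3157)
                172L, 70L, 108L,              # exons 26-28
                118L, 118L, 118L,             # exons 29-31 (to c.3861)
                128L, 128L,                   # exons 32-33
                rep(138L, 5L), 139L)          # exons 34-39
  stopifnot(sum(exonLens) == nchar(cdna), length(exonLens) == 39L)
  ends <- cumsum(exonLens)
  exons <- IRanges::IRanges(start = c(1L, head(ends, -1L) + 1L), end = ends)

  tx <- TranscriptModel("SYNTH_ABCC8", cdna, exons,
                        cdsStart = utr5 + 1L, cdsEnd = utr5 + cdsLen)

  # independent verification of every planted consequence
  skipLen <- function(cFrom, cTo)  # oracle: protein length after skip
    .naiveOrf(paste0(substr(cdsStr, 1L, cFrom - 1L),
                     substr(cdsStr, cTo + 1L, cdsLen)))
  stopifnot(
    skipLen(2413L, 2506L) == 836L,
    skipLen(2557L, 2694L) == nAA - 46L,
    skipLen(3158L, 3329L) == 1056L,
    skipLen(3330L, 3399L) == 1118L,
    skipLen(3862L, 3989L) == 1292L,
    .naiveOrf(paste0(substr(cdsStr, 1L, 3287L),
                     substr(cdsStr, 3290L, cdsLen))) == 1111L
  )
  tx
}
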