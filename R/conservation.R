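# Sequence-logo matrices (per-position letter frequencies and information
# content) from pre-aligned multi-species windows, and a conservation class
# for the centre (variant) column.

#' LogoMatrix: per-position letter frequencies and information content
#'
#' @slot freq letters x positions frequency matrix (columns sum to 1 over
#'   non-gap letters; all-gap columns are zero).
#' @slot ic per-position information content in bits,
#'   `log2(alphabet size) - Shannon entropy`.
#' @slot alphabetSize 20 for amino acids, 4 for nucleotides.
#' @name LogoMatrix-class
#' @exportClass LogoMatrix
setClass("LogoMatrix",
  representation(freq = "matrix", ic = "numeric", alphabetSize = "integer"))

setValidity("LogoMatrix", function(object) {
  msg <- character()
  cs <- colSums(object@freq)
  if (any(abs(cs[cs > 0] - 1) > 1e-9))
    msg <- c(msg, "column frequencies must sum to 1 (or 0 for all-gap)")
  if (any(object@ic < -1e-9 |
          object@ic > log2(object@alphabetSize) + 1e-9))
    msg <- c(msg, "information content outside [0, log2(alphabet size)]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "LogoMatrix", function(object) {
  cat("LogoMatrix: ", ncol(object@freq), " positions, alphabet size ",
      object@alphabetSize, "\n IC (bits): ",
      paste(round(object@ic, 2), collapse = " "), "\n", sep = "")
})

#' @rdname accessors
#' @export
setGeneric("letterFrequencies", function(x) standardGeneric("letterFrequencies"))
#' @rdname accessors
#' @export
setMethod("letterFrequencies", "LogoMatrix", function(x) x@freq)

#' @rdname accessors
#' @export
setGeneric("informationContent", function(x) standardGeneric("informationContent"))
#' @rdname accessors
#' @export
setMethod("informationContent", "LogoMatrix", function(x) x@ic)

.ALPHABETS <- list(
  amino_acid = c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
  nucleotide = c("A", "C", "G", "T")
)

#' Build the sequence-logo matrix of an alignment window
#'
#' Per position, letter frequencies over the species (gaps excluded from
#' the denominator) and information content
#' `IC = log2(|alphabet|) - H` with `H` the Shannon entropy of the column
#' (no small-sample correction). All-gap columns get frequency 0 and IC 0.
#'
#' @param w an [AlignmentWindow-class] with at least 2 sequences.
#' @return a [LogoMatrix-class].
#' @examples
#' w <- AlignmentWindow(setNames(rep("LIHRK", 14), paste0("sp", 1:14)))
#' informationContent(logoMatrix(w))  # log2(20) at every position
#' @export
logoMatrix <- function(w) {
  stopifnot(is(w, "AlignmentWindow"))
  if (length(w@sequences) < 2L)
    stop("at least 2 sequences are required for a logo")
  letters <- .ALPHABETS[[w@alphabet]]
  S <- length(letters)
  mat <- do.call(rbind, strsplit(as.character(w@sequences), ""))
  bad <- setdiff(unique(as.vector(mat)), c(letters, "-", "."))
  if (length(bad))
    stop("character(s) outside the ", w@alphabet, " alphabet: ",
         paste(bad, collapse = ", "))
  npos <- ncol(mat)
  freq <- matrix(0, nrow = S, ncol = npos,
                 dimnames = list(letters, seq_len(npos)))
  ic <- numeric(npos)
  for (p in seq_len(npos)) {
    col <- mat[, p]
    col <- col[col %in% letters]
    if (!length(col)) { ic[p] <- 0; next }
    f <- table(factor(col, levels = letters)) / length(col)
    freq[, p] <- as.numeric(f)
    nz <- f[f > 0]
    ic[p] <- log2(S) + sum(nz * log2(nz))
  }
  ic[ic < 0] <- 0  # guard tiny negative rounding
  new("LogoMatrix", freq = freq, ic = ic, alphabetSize = as.integer(S))
}

#' Conservation class of the variant (centre) column
#'
#' The centre column is `highly_conserved` when its modal residue reaches
#' frequency >= `cutoff` (default 0.9) across all species;
#' `conserved_vertebrates` when it reaches the cutoff within the
#' designated vertebrate subset (`vertebrateSpecies`) but not overall; and
#' `not_conserved` otherwise. The cutoff and subset are module policy, not
#' a property of the logo itself.
#'
#' @param w an [AlignmentWindow-class].
#' @param vertebrateSpecies character vector of species names forming the
#'   designated vertebrate subset; `NULL` disables the intermediate class.
#' @param center column to assess (default: the variant column,
#'   [centerPosition]).
#' @param cutoff modal-frequency threshold (default 0.9).
#' @return `"highly_conserved"`, `"conserved_vertebrates"` or `"not_conserved"`.
#' @examples
#' w <- simAlignmentWindow(nSpecies = 14, conservation = c(1, 1, 0.5, 1, 1),
#'                         seed = 3)
#' conservationClass(w$window)
#' @export
conservationClass <- function(w, vertebrateSpecies = NULL, center = centerPosition(w),
                              cutoff = 0.9) {
  stopifnot(is(w, "AlignmentWindow"))
  modal <- function(seqs) {
    ch <- substr(as.character(seqs), center, center)
    ch <- ch[!ch %in% c("-", ".")]
    if (!length(ch)) return(0)
    max(table(ch)) / length(ch)
  }
  if (modal(w@sequences) >= cutoff) return("highly_conserved")
  if (!is.null(vertebrateSpecies)) {
    sub <- w@sequences[names(w@sequences) %in% vertebrateSpecies]
    if (length(sub) && modal(sub) >= cutoff) return("conserved_vertebrates")
  }
  "not_conserved"
}

#' Write a logo matrix as TSV for external logo-plotting tools
#'
#' Long-format TSV with columns `position`, `letter`, `frequency`,
#' `information_bits` (the column IC repeated per letter), consumable by
#' ggseqlogo-style custom-matrix input after reshaping.
#'
#' @param m a [LogoMatrix-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeLogoMatrix <- function(m, path) {
  stopifnot(is(m, "LogoMatrix"))
  df <- data.frame(
    position = rep(seq_len(ncol(m@freq)), each = nrow(m@freq)),
    letter = rep(rownames(m@freq), times = ncol(m@freq)),
    frequency = as.vector(m@freq),
    information_bits = rep(m@ic, each = nrow(m@freq)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
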