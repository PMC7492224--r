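# Readers and writers: variant tables, depth matrices (BED + TSV),
# transcript fixtures (FASTA + JSON sidecar), alignment windows (FASTA),
# and the deterministic classification report.

.VARIANT_HEADERS <- c("variant_id", "gene", "variant_class")

#' Read a tab-separated variant table of predictor outputs
#'
#' Required headers: `variant_id`, `gene`, `variant_class` plus the seven
#' predictor columns (`annovar_impact`, `cadd`, `sift`, `polyphen2`,
#' `mutassessor`, `fathmm`, `vest`). Optional: `hgvs_c`, `hgvs_p`,
#' `gnomad_af`, `other_codes` (comma-separated ACMG codes). Empty cells,
#' `"-"` and `"NA"` are missing. Numeric predictor cells that parse
#' neither as a number nor as a known verbal label are reported with their
#' row and column.
#'
#' @param path TSV file.
#' @return data.frame, one row per variant, input order preserved.
#' @examples
#' tab <- readVariantTable(system.file("extdata", "abcc8_predictor_calls.tsv",
#'   package = "variantTriage"))
#' nrow(tab)  # 12
#' @export
readVariantTable <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c("NA", "", "-", "–"),
                          check.names = FALSE, colClasses = "character")
  need <- c(.VARIANT_HEADERS, PREDICTORS)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required header(s): ", paste(miss, collapse = ", "))
  # validate numeric predictor cells early, with cell coordinates
  for (p in setdiff(PREDICTORS, c("annovar_impact", "fathmm"))) {
    v <- df[[p]]
    bad <- which(!is.na(v) & is.na(suppressWarnings(as.numeric(v))) &
                   vapply(v, function(x)
                     inherits(try(.categoricalCategory(p, x), silent = TRUE),
                              "try-error"), logical(1)))
    if (length(bad))
      stop("cannot parse cell(s) in column '", p, "', row(s) ",
           paste(bad, collapse = ", "), ": '",
           paste(v[bad], collapse = "', '"), "'")
  }
  if ("gnomad_af" %in% names(df)) df$gnomad_af <- as.numeric(df$gnomad_af)
  df
}

#' Write the classification report (TSV + JSON)
#'
#' Deterministic output: a `classification.tsv` mirroring the
#' [classifyVariants] result and a `classification.json` carrying the same
#' rows plus run metadata (package version, seed, input configuration
#' hash). Identical inputs produce byte-identical files.
#'
#' @param results data.frame from [classifyVariants] (may have 0 rows).
#' @param outdir output directory (created if needed).
#' @param seed seed recorded in the metadata (NA if none applies).
#' @param configHash hash string identifying the run configuration;
#'   defaults to the MD5 of the serialized results.
#' @return named character vector of the written paths, invisibly.
#' @export
writeClassificationReport <- function(results, outdir, seed = NA,
                                      configHash = NULL) {
  stopifnot(!is.null(results))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(outdir, "classification.tsv")
  jsn <- file.path(outdir, "classification.json")
  utils::write.table(results, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (is.null(configHash)) {
    tmp <- tempfile()
    utils::write.table(results, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    configHash <- unname(tools::md5sum(tmp))
    unlink(tmp)
  }
  payload <- list(
    metadata = list(package = "variantTriage",
                    version = as.character(utils::packageVersion("variantTriage")),
                    seed = seed, config_hash = configHash),
    results = results)
  jsonlite::write_json(payload, jsn, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(c(tsv = tsv, json = jsn))
}

#' Read a depth matrix from a BED targets file and a depth TSV
#'
#' The BED file (half-open 0-based) provides `chrom`, `start`, `end` and
#' the target's gene in its name column; the TSV holds one row per target
#' in the same order (first column an interval id, remaining columns one
#' per sample).
#'
#' @param bedPath BED file of target intervals.
#' @param depthPath TSV of depths, intervals x samples, with a header row
#'   of sample names and the interval id in the first column.
#' @return a [DepthExperiment-class].
#' @export
readDepthTable <- function(bedPath, depthPath) {
  bed <- utils::read.delim(bedPath, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 4L)
    stop("BED file must have at least 4 columns (chrom, start, end, gene)")
  names(bed)[1:4] <- c("chrom", "start", "end", "gene")
  d <- utils::read.delim(depthPath, sep = "\t", row.names = 1,
                         check.names = FALSE)
  if (nrow(d) != nrow(bed))
    stop("depth table has ", nrow(d), " rows but BED has ", nrow(bed),
         " intervals")
  d <- as.matrix(d)
  rownames(d) <- NULL
  DepthExperiment(d, bed)
}

#' Write a depth matrix as BED + TSV
#'
#' Inverse of [readDepthTable] (BED half-open 0-based coordinates).
#'
#' @param x a [DepthExperiment-class].
#' @param bedPath,depthPath output paths.
#' @return the paths, invisibly.
#' @export
writeDepthTable <- function(x, bedPath, depthPath) {
  stopifnot(is(x, "DepthExperiment"))
  rr <- SummarizedExperiment::rowRanges(x)
  bed <- data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
                    start = IRanges::start(rr) - 1L,
                    end = IRanges::end(rr),
                    gene = as.character(S4Vectors::mcols(rr)$gene))
  utils::write.table(bed, bedPath, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  d <- depth(x)
  out <- data.frame(interval = sprintf("iv%04d", seq_len(nrow(d))), d,
                    check.names = FALSE)
  utils::write.table(out, depthPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(bed = bedPath, depth = depthPath))
}

#' Read per-species alignment windows from FASTA
#'
#' One record per species (record names are species labels), all of equal
#' width, pre-aligned and centred on the variant.
#'
#' @param path FASTA file.
#' @param alphabet `"amino_acid"` (default) or `"nucleotide"`.
#' @param variantId window label.
#' @return an [AlignmentWindow-class].
#' @export
readAlignmentFasta <- function(path, alphabet = c("amino_acid", "nucleotide"),
                               variantId = "variant") {
  alphabet <- match.arg(alphabet)
  seqs <- if (alphabet == "amino_acid")
    Biostrings::readAAStringSet(path) else Biostrings::readDNAStringSet(path)
  AlignmentWindow(seqs, alphabet, variantId)
}

#' Read / write a transcript fixture (cDNA FASTA + JSON sidecar)
#'
#' The sidecar holds `transcript_id`, `exons` (list of 1-based inclusive
#' `[start, end]` cDNA pairs) and `cds` (`[start, end]`).
#'
#' @param fastaPath cDNA FASTA (single record).
#' @param jsonPath JSON sidecar.
#' @return a [TranscriptModel-class].
#' @export
readTranscriptModel <- function(fastaPath, jsonPath) {
  dna <- Biostrings::readDNAStringSet(fastaPath)
  if (length(dna) != 1L)
    stop("expected exactly one cDNA record, found ", length(dna))
  meta <- jsonlite::read_json(jsonPath, simplifyVector = TRUE)
  exons <- if (is.matrix(meta$exons)) meta$exons else
    matrix(unlist(meta$exons), ncol = 2, byrow = TRUE)
  TranscriptModel(meta$transcript_id, as.character(dna[[1]]), exons,
                  meta$cds[1], meta$cds[2])
}

#' @rdname readTranscriptModel
#' @param tx a [TranscriptModel-class] to write.
#' @export
writeTranscriptModel <- function(tx, fastaPath, jsonPath) {
  stopifnot(is(tx, "TranscriptModel"))
  seqs <- Biostrings::DNAStringSet(setNames(list(tx@cdna), tx@txId))
  Biostrings::writeXStringSet(seqs, fastaPath)
  meta <- list(
    transcript_id = tx@txId,
    exons = lapply(seq_along(tx@exons), function(i)
      c(IRanges::start(tx@exons)[i], IRanges::end(tx@exons)[i])),
    cds = c(tx@cdsStart, tx@cdsEnd))
  jsonlite::write_json(meta, jsonPath, auto_unbox = TRUE)
  invisible(c(fasta = fastaPath, json = jsonPath))
}
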