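# LACONv-style panel CNV calling: minimum-depth filtering, two-stage
# median-of-ratios dose normalization, and dose / Z-score thresholding with
# merging of adjacent called intervals.

#' Drop low-depth samples and target intervals
#'
#' Samples whose mean depth falls below `minSampleDepth` (default 20x) and
#' intervals whose cohort-mean depth falls below `minIntervalDepth`
#' (default 15x) are removed; interval means are taken after sample
#' removal. The dropped identifiers are recorded in
#' `metadata(x)$dropped`.
#'
#' @param x a [DepthExperiment-class].
#' @param minSampleDepth minimum per-sample mean depth.
#' @param minIntervalDepth minimum per-interval cohort-mean depth.
#' @return the filtered [DepthExperiment-class]; an empty one (with a
#'   message) if everything is dropped.
#' @examples
#' de <- simDepthCohort(nSamples = 5, nIntervals = 10, seed = 1)$depths
#' dim(filterDepth(de))
#' @export
filterDepth <- function(x, minSampleDepth = 20, minIntervalDepth = 15) {
  stopifnot(is(x, "DepthExperiment"))
  d <- depth(x)
  keepS <- colMeans(d) >= minSampleDepth
  keepI <- rowMeans(d[, keepS, drop = FALSE]) >= minIntervalDepth
  if (!any(keepS)) keepI <- rep(FALSE, nrow(d))
  dropped <- list(samples = colnames(d)[!keepS],
                  intervals = which(!keepI))
  out <- x[keepI, keepS]
  S4Vectors::metadata(out)$dropped <- dropped
  if (nrow(out) == 0L || ncol(out) == 0L)
    message("filterDepth: no data left after depth filtering (dropped ",
            sum(!keepS), " samples, ", sum(!keepI), " intervals)")
  out
}

#' Per-cell dose ratios by two-stage median-of-ratios normalization
#'
#' Each depth is first scaled by its sample's median depth (removing
#' library-size differences), then by the cross-sample median of that
#' normalized interval depth (removing per-target capture efficiency).
#' By construction the cohort-median dose of every interval is 1; a
#' heterozygous deletion is expected near 0.5 and a heterozygous
#' duplication near 1.5.
#'
#' @param x a [DepthExperiment-class] (after [filterDepth]); at least 3
#'   samples are required for a stable reference.
#' @return numeric matrix of dose ratios, intervals x samples.
#' @examples
#' de <- simDepthCohort(nSamples = 8, nIntervals = 12, seed = 1)$depths
#' summary(as.vector(doseRates(de)))
#' @export
doseRates <- function(x) {
  stopifnot(is(x, "DepthExperiment"))
  d <- depth(x)
  if (ncol(d) < 3L)
    stop("dose normalization needs at least 3 samples, got ", ncol(d))
  sampleMed <- apply(d, 2, stats::median)
  if (any(sampleMed <= 0))
    stop("sample(s) with non-positive median depth: ",
         paste(colnames(d)[sampleMed <= 0], collapse = ", "))
  norm <- sweep(d, 2, sampleMed, "/")
  intervalMed <- apply(norm, 1, stats::median)
  if (any(intervalMed <= 0))
    stop("interval(s) with non-positive median normalized depth")
  dose <- sweep(norm, 1, intervalMed, "/")
  dimnames(dose) <- dimnames(d)
  dose
}

#' Call copy-number variants from dose ratios
#'
#' Per cell, `z = (dose - mean(interval dose)) / sd(interval dose)` across
#' samples. A deletion is called where `dose <= delThresh` and
#' `z <= zThresh`; a duplication where `dose >= dupThresh` (and, under the
#' symmetric policy `dupZ = TRUE`, `z >= -zThresh`). Adjacent called
#' intervals of the same sample and kind are merged into single calls
#' (reported dose and z are means over the merged span). Intervals with
#' zero dose variance are called on the dose criterion alone, with a
#' warning.
#'
#' @param x a [DepthExperiment-class] or a dose matrix from [doseRates];
#'   passing the experiment keeps interval coordinates in the output.
#' @param delThresh dose-rate threshold for deletions (default 0.60).
#' @param dupThresh dose-rate threshold for duplications (default 1.20).
#' @param zThresh Z-score threshold for deletions (default -2.0).
#' @param dupZ also require `z >= -zThresh` for duplications
#'   (default `FALSE`: duplications are called on dose alone).
#' @return data.frame of calls: `sample`, `gene`, `chrom`, `start`, `end`,
#'   `firstInterval`, `lastInterval`, `kind`, `doseRate`, `z` (zero rows
#'   when nothing is called). Coordinate columns are `NA` when `x` is a
#'   bare matrix.
#' @examples
#' sim <- simDepthCohort(nSamples = 10, nIntervals = 20, seed = 2,
#'   spikes = data.frame(sample = 3, firstInterval = 5, nIntervals = 3,
#'                       dose = 0.5))
#' callCnvs(sim$depths)
#' @export
callCnvs <- function(x, delThresh = 0.60, dupThresh = 1.20, zThresh = -2.0,
                     dupZ = FALSE) {
  if (is(x, "DepthExperiment")) {
    dose <- doseRates(x)
    rr <- SummarizedExperiment::rowRanges(x)
    gene <- as.character(S4Vectors::mcols(rr)$gene)
    chrom <- as.character(GenomicRanges::seqnames(rr))
    ivStart <- IRanges::start(rr); ivEnd <- IRanges::end(rr)
  } else {
    dose <- as.matrix(x)
    gene <- rep(NA_character_, nrow(dose))
    chrom <- rep(NA_character_, nrow(dose))
    ivStart <- rep(NA_integer_, nrow(dose)); ivEnd <- ivStart
  }
  mu <- rowMeans(dose)
  sigma <- apply(dose, 1, stats::sd)
  if (any(sigma == 0 &
          (apply(dose, 1, min) <= delThresh |
           apply(dose, 1, max) >= dupThresh)))
    warning("zero-variance interval(s) with out-of-range dose: Z undefined, ",
            "calling on the dose criterion alone")
  z <- (dose - mu) / ifelse(sigma > 0, sigma, NA)
  isDel <- dose <= delThresh & (is.na(z) | z <= zThresh)
  isDup <- dose >= dupThresh &
    (!dupZ | is.na(z) | z >= -zThresh)
  calls <- list()
  for (j in seq_len(ncol(dose))) {
    for (kind in c("deletion", "duplication")) {
      hit <- if (kind == "deletion") isDel[, j] else isDup[, j]
      if (!any(hit)) next
      # merge runs of adjacent called intervals (same chromosome)
      r <- rle(hit)
      endIdx <- cumsum(r$lengths)
      startIdx <- endIdx - r$lengths + 1L
      for (k in which(r$values)) {
        idx <- startIdx[k]:endIdx[k]
        # split runs that straddle a chromosome boundary
        grp <- cumsum(c(1L, diff(match(chrom[idx], unique(chrom[idx]))) != 0))
        for (g in unique(grp)) {
          ii <- idx[grp == g]
          calls[[length(calls) + 1L]] <- data.frame(
            sample = colnames(dose)[j],
            gene = paste(unique(gene[ii]), collapse = ","),
            chrom = chrom[ii[1]],
            start = ivStart[ii[1]], end = ivEnd[ii[length(ii)]],
            firstInterval = ii[1], lastInterval = ii[length(ii)],
            kind = kind,
            doseRate = mean(dose[ii, j]),
            z = mean(z[ii, j]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(calls))
    return(.emptyCalls())
  do.call(rbind, calls)
}

.emptyCalls <- function() {
  data.frame(sample = character(), gene = character(),
             chrom = character(), start = integer(),
             end = integer(), firstInterval = integer(),
             lastInterval = integer(), kind = character(),
             doseRate = numeric(), z = numeric(),
             stringsAsFactors = FALSE)
}

#' Merge adjacent CNV calls of the same sample and kind
#'
#' Calls whose interval runs are contiguous (`lastInterval + 1 ==
#' firstInterval` of the next call, same chromosome) are collapsed,
#' averaging dose and z over the merged span weighted by interval count.
#' [callCnvs] already returns merged calls, so applying this to its output
#' is the identity; it is exposed for combining call sets produced in
#' chunks.
#'
#' @param calls a calls data.frame as returned by [callCnvs].
#' @return a calls data.frame of the same shape.
#' @export
mergeCnvCalls <- function(calls) {
  if (!nrow(calls)) return(calls)
  o <- order(calls$sample, calls$kind, calls$firstInterval)
  calls <- calls[o, , drop = FALSE]
  out <- list()
  cur <- calls[1, , drop = FALSE]
  nIv <- function(x) x$lastInterval - x$firstInterval + 1L
  for (i in seq_len(nrow(calls))[-1]) {
    nxt <- calls[i, , drop = FALSE]
    if (nxt$sample == cur$sample && nxt$kind == cur$kind &&
        identical(nxt$chrom, cur$chrom) &&
        nxt$firstInterval == cur$lastInterval + 1L) {
      w <- c(nIv(cur), nIv(nxt))
      cur$doseRate <- sum(w * c(cur$doseRate, nxt$doseRate)) / sum(w)
      cur$z <- sum(w * c(cur$z, nxt$z)) / sum(w)
      cur$lastInterval <- nxt$lastInterval
      cur$end <- nxt$end
      cur$gene <- paste(unique(c(strsplit(cur$gene, ",")[[1]],
                                 strsplit(nxt$gene, ",")[[1]])),
                        collapse = ",")
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- nxt
    }
  }
  out[[length(out) + 1L]] <- cur
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
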