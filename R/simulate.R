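# Seeded generators of synthetic inputs with machine-readable ground truth
# for every pipeline stage. Same configuration + same seed => identical
# output (set.seed is called when `seed` is given).

# numeric sampling intervals lying strictly inside each category's score
# band, so discretizeCall recovers the planted category under either
# boundary policy
.SIM_BANDS <- list(
  cadd = list(damaging = c(14.5, 40), possibly_damaging = c(11.2, 13.8),
              benign = c(0.5, 10.5)),
  sift = list(damaging = c(0.005, 0.055), possibly_damaging = c(0.07, 0.22),
              benign = c(0.25, 0.95)),
  polyphen2 = list(damaging = c(0.35, 0.99),
                   possibly_damaging = c(0.04, 0.29),
                   benign = c(0.001, 0.025)),
  mutassessor = list(damaging = c(1.9, 4.5),
                     possibly_damaging = c(1.15, 1.75),
                     benign = c(-1, 1.05)),
  vest = list(damaging = c(0.66, 0.99), possibly_damaging = c(0.18, 0.64),
              benign = c(0.01, 0.16))
)

#' Simulate a predictor score table with known category structure
#'
#' Draws raw numeric scores uniformly inside the score band of the planted
#' category for the five numeric predictors (CADD, SIFT, PolyPhen-2,
#' MutationAssessor, VEST) and emits matching verbal labels for Annovar
#' impact and FATHMM, so that [discretizeCall] must recover the planted
#' category in every cell.
#'
#' @param nVariants number of variants to simulate.
#' @param categories optional nVariants x 7 data.frame/matrix of planted
#'   categories (`damaging`, `possibly_damaging`, `benign`, `missing`;
#'   columns named as the predictors); FATHMM does not admit
#'   `possibly_damaging` (it is a binary tool) and requesting it is an
#'   error. Defaults to uniform random planting (FATHMM drawn from its
#'   three admissible categories).
#' @param seed integer seed (`set.seed` is called when non-NULL).
#' @return list with `table` (a variant table consumable by
#'   [classifyVariants], `variant_class = "missense"`) and `truth`
#'   (the planted category data.frame).
#' @examples
#' sim <- simPredictorTable(5, seed = 1)
#' all(classifyVariants(sim$table)$cadd == sim$truth$cadd)
#' @export
simPredictorTable <- function(nVariants, categories = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(nVariants >= 1)
  cats3 <- c("damaging", "possibly_damaging", "benign", "missing")
  if (is.null(categories)) {
    categories <- data.frame(matrix(sample(cats3, nVariants * 7, TRUE),
                                    nrow = nVariants))
    names(categories) <- PREDICTORS
    categories$fathmm <- sample(c("damaging", "benign", "missing"),
                                nVariants, TRUE)
  }
  categories <- as.data.frame(categories, stringsAsFactors = FALSE)
  stopifnot(identical(sort(names(categories)), sort(PREDICTORS)),
            nrow(categories) == nVariants)
  bad <- !unlist(categories) %in% cats3
  if (any(bad)) stop("unknown planted category: ",
                     paste(unique(unlist(categories)[bad]), collapse = ", "))
  if (any(categories$fathmm == "possibly_damaging"))
    stop("FATHMM is binary: category 'possibly_damaging' cannot be planted")
  tab <- data.frame(variant_id = sprintf("sim%04d", seq_len(nVariants)),
                    gene = "SIMGENE", variant_class = "missense",
                    stringsAsFactors = FALSE)
  for (p in PREDICTORS) {
    cat <- categories[[p]]
    if (p == "annovar_impact") {
      val <- c(damaging = "HIGH", possibly_damaging = "MODERATE",
               benign = "LOW", missing = NA)[cat]
    } else if (p == "fathmm") {
      val <- c(damaging = "Damaging", benign = "Benign", missing = NA)[cat]
    } else {
      val <- vapply(cat, function(cc) {
        if (cc == "missing") return(NA_real_)
        b <- .SIM_BANDS[[p]][[cc]]
        stats::runif(1, b[1], b[2])
      }, numeric(1))
    }
    tab[[p]] <- unname(val)
  }
  list(table = tab, truth = categories)
}

#' Simulate a transcript with a planted skippable exon
#'
#' Builds a multi-exon [TranscriptModel-class] with random filler sequence
#' and, optionally, an internal exon of requested length whose skip has a
#' known consequence. The planted exon starts on a codon boundary, so a
#' length divisible by 3 gives a clean in-frame skip losing
#' `length / 3` residues; any other length frameshifts. The returned truth
#' is computed at generation time by a naive codon-by-codon re-translation
#' oracle, independent of [skipExon].
#'
#' @param nExons number of exons (>= 3).
#' @param exonLength integer range for random exon lengths.
#' @param plantExonLength length (>= 3 nt) of the planted skippable exon,
#'   or `NULL` for no planting.
#' @param plantExon index of the planted exon (internal; default middle).
#' @param seed integer seed.
#' @return list with `transcript` and `truth`
#'   (`exon`, `frameStatus`, `proteinLength`, `aaLost`, or `NULL` when
#'   nothing was planted).
#' @examples
#' sim <- simTranscript(plantExonLength = 138, seed = 7)
#' sim$truth$aaLost  # 46
#' @export
simTranscript <- function(nExons = 7, exonLength = c(60, 180),
                          plantExonLength = NULL,
                          plantExon = ceiling(nExons / 2), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(nExons >= 3)
  if (!is.null(plantExonLength)) {
    if (plantExonLength < 3)
      stop("planted exon length must be at least 3 nt")
    if (plantExon <= 1 || plantExon >= nExons)
      stop("planted exon must be internal")
  }
  lens <- sample(seq(exonLength[1], exonLength[2]), nExons, replace = TRUE)
  lens[1] <- max(lens[1], 30L)  # room for a UTR and codon-phase adjustment
  if (!is.null(plantExonLength)) lens[plantExon] <- as.integer(plantExonLength)
  starts <- cumsum(c(1L, lens[-nExons]))
  total <- sum(lens)
  # CDS start inside exon 1, phased so the planted (or middle) exon starts
  # on a codon boundary
  anchor <- starts[if (is.null(plantExonLength)) 2L else plantExon]
  cdsStart <- 10L + (anchor - 10L) %% 3L
  # CDS end: inside the last exon, leaving a 3' UTR
  lastOk <- total - 10L
  cdsEnd <- cdsStart - 1L + 3L * ((lastOk - cdsStart + 1L) %/% 3L)
  bases <- c("A", "C", "G", "T")
  seqv <- sample(bases, total, replace = TRUE)
  nonStop <- setdiff(apply(expand.grid(bases, bases, bases), 1, paste,
                           collapse = ""), .STOPS)
  nCodons <- (cdsEnd - cdsStart + 1L) %/% 3L
  codons <- c("ATG", sample(nonStop, nCodons - 2L, replace = TRUE), "TAA")
  seqv[cdsStart:cdsEnd] <- strsplit(paste(codons, collapse = ""), "")[[1]]
  tx <- TranscriptModel("SIM_TX", paste(seqv, collapse = ""),
                        cbind(starts, starts + lens - 1L),
                        cdsStart, cdsEnd)
  truth <- NULL
  if (!is.null(plantExonLength)) {
    s <- starts[plantExon]; e <- s + lens[plantExon] - 1L
    cdsStr <- paste(seqv[cdsStart:cdsEnd], collapse = "")
    edited <- paste0(substr(cdsStr, 1L, s - cdsStart),
                     substr(cdsStr, e - cdsStart + 2L, nchar(cdsStr)))
    pl <- .naiveOrf(edited)
    truth <- list(exon = plantExon,
                  frameStatus = if (lens[plantExon] %% 3L == 0L)
                    "in_frame" else "frameshift",
                  proteinLength = pl,
                  aaLost = (nCodons - 1L) - pl)
  }
  list(transcript = tx, truth = truth)
}

#' Simulate a cohort read-depth matrix with spiked CNVs
#'
#' Depth is `noise(meanDepth x interval profile x sample scale x dose)`,
#' with a log-normal per-interval capture-efficiency profile, a uniform
#' per-sample library-size scale, and Poisson (default) or
#' negative-binomial counting noise. Spiked cells are multiplied by the
#' requested dose ratio (0.5 = heterozygous deletion, 1.5 = heterozygous
#' duplication).
#'
#' @param nSamples number of samples (>= 3).
#' @param nIntervals number of target intervals.
#' @param meanDepth cohort mean depth (default 150x).
#' @param noise `"poisson"` or `"nbinom"`.
#' @param dispersion negative-binomial size parameter (ignored for
#'   Poisson).
#' @param spikes `NULL` or data.frame with columns `sample` (index or id),
#'   `firstInterval`, `nIntervals`, `dose` (in (0, 3]).
#' @param profileSd log-sd of the interval capture profile (default 0.05,
#'   i.e. ~5\% cohort CV between targets).
#' @param seed integer seed.
#' @return list with `depths` (a [DepthExperiment-class]) and `truth`
#'   (data.frame mirroring the [callCnvs] schema: `sample`,
#'   `firstInterval`, `lastInterval`, `kind`, `dose`; zero rows when
#'   nothing was spiked).
#' @examples
#' sim <- simDepthCohort(nSamples = 6, nIntervals = 10, seed = 42)
#' sim$truth  # empty: no spikes
#' @export
simDepthCohort <- function(nSamples, nIntervals, meanDepth = 150,
                           noise = c("poisson", "nbinom"), dispersion = 10,
                           spikes = NULL, profileSd = 0.05, seed = NULL) {
  noise <- match.arg(noise)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(nSamples >= 3, nIntervals >= 1, meanDepth > 0)
  profile <- stats::rlnorm(nIntervals, meanlog = 0, sdlog = profileSd)
  scale <- stats::runif(nSamples, 0.9, 1.1)
  lambda <- meanDepth * outer(profile, scale)
  samples <- sprintf("S%02d", seq_len(nSamples))
  truth <- data.frame(sample = character(), firstInterval = integer(),
                      lastInterval = integer(), kind = character(),
                      dose = numeric(), stringsAsFactors = FALSE)
  if (!is.null(spikes)) {
    for (i in seq_len(nrow(spikes))) {
      sp <- spikes[i, ]
      if (sp$dose <= 0 || sp$dose > 3)
        stop("spiked dose must lie in (0, 3], got ", sp$dose)
      j <- if (is.numeric(sp$sample)) as.integer(sp$sample) else
        match(sp$sample, samples)
      rows <- sp$firstInterval:(sp$firstInterval + sp$nIntervals - 1L)
      stopifnot(j >= 1, j <= nSamples, all(rows <= nIntervals))
      lambda[rows, j] <- lambda[rows, j] * sp$dose
      truth <- rbind(truth, data.frame(
        sample = samples[j], firstInterval = min(rows),
        lastInterval = max(rows),
        kind = if (sp$dose < 1) "deletion" else "duplication",
        dose = sp$dose, stringsAsFactors = FALSE))
    }
  }
  d <- if (noise == "poisson") {
    matrix(stats::rpois(length(lambda), lambda), nrow = nIntervals)
  } else {
    matrix(stats::rnbinom(length(lambda), mu = lambda, size = dispersion),
           nrow = nIntervals)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = "chr1",
    ranges = IRanges::IRanges(start = (seq_len(nIntervals) - 1L) * 1000L + 1L,
                              width = 500L),
    gene = paste0("GENE", ceiling(seq_len(nIntervals) / 5)))
  list(depths = DepthExperiment(d, gr, samples), truth = truth)
}

#' Simulate a multi-species alignment window with chosen conservation
#'
#' Per position, a modal letter is chosen and each species emits it with
#' the requested probability (otherwise a uniformly random different
#' letter), so the expected modal frequency equals the requested
#' conservation level; level 1 gives an invariant column.
#'
#' @param nSpecies number of species (default 14).
#' @param conservation numeric vector of per-position modal-letter
#'   probabilities in (0, 1]; its length sets the window width
#'   (default width 5, variant at position 3).
#' @param alphabet `"amino_acid"` or `"nucleotide"`.
#' @param variantId label for the window.
#' @param seed integer seed.
#' @return list with `window` (an [AlignmentWindow-class]) and `truth`
#'   (`modal` letters and the requested `conservation` levels).
#' @examples
#' sim <- simAlignmentWindow(conservation = c(1, 0.8, 1, 0.8, 1), seed = 1)
#' sim$window
#' @export
simAlignmentWindow <- function(nSpecies = 14,
                               conservation = rep(1, 5),
                               alphabet = c("amino_acid", "nucleotide"),
                               variantId = "simvar", seed = NULL) {
  alphabet <- match.arg(alphabet)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(nSpecies >= 2, all(conservation > 0 & conservation <= 1))
  letters <- .ALPHABETS[[alphabet]]
  width <- length(conservation)
  modal <- sample(letters, width, replace = TRUE)
  cols <- vapply(seq_len(width), function(p) {
    hit <- stats::runif(nSpecies) <= conservation[p]
    other <- sample(setdiff(letters, modal[p]), nSpecies, replace = TRUE)
    ifelse(hit, modal[p], other)
  }, character(nSpecies))
  seqs <- apply(cols, 1, paste, collapse = "")
  names(seqs) <- paste0("species", seq_len(nSpecies))
  list(window = AlignmentWindow(seqs, alphabet, variantId),
       truth = list(modal = modal, conservation = conservation))
}
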