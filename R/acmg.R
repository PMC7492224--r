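# Seven-predictor discretization, 7-point aggregation, ACMG evidence bands
# and the published evidence-combining rules.

PREDICTORS <- c("annovar_impact", "cadd", "sift", "polyphen2",
                "mutassessor", "fathmm", "vest")

CATEGORIES <- c("damaging", "possibly_damaging", "benign", "missing")

# numeric ranges accepted per predictor (values outside are rejected)
.PRED_RANGE <- list(
  cadd = c(0, 99), sift = c(0, 1), polyphen2 = c(0, 1),
  mutassessor = c(-6, 6), vest = c(0, 1)
)

.normCat <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[ /-]+", "_", x)
  x
}

.isMissing <- function(value) {
  length(value) == 0L || is.na(value) ||
    (is.character(value) && .normCat(value) %in% c("", "_", "na", "–"))
}

# Category of a numeric score under the published per-tool intervals.
# Interval boundaries the published ranges leave unassigned (CADD 14,
# SIFT 0.23, PolyPhen-2 0.03 and 0.3, MutationAssessor 1.8) go to the
# more-damaging-leaning closed side under the default policy and to the
# less-damaging side under "strict"; boundaries the ranges do assign
# (SIFT 0.06, MutationAssessor 1.12, VEST 0.17 and 0.65, CADD 11) are
# fixed in both policies.
.numericCategory <- function(predictor, value, boundaryPolicy) {
  d <- boundaryPolicy == "default"
  switch(predictor,
    cadd = if (if (d) value >= 14 else value > 14) "damaging"
           else if (value >= 11) "possibly_damaging" else "benign",
    sift = if (value <= 0.06) "damaging"
           else if (if (d) value <= 0.23 else value < 0.23)
             "possibly_damaging" else "benign",
    polyphen2 = if (value > 0.3) "damaging"
           else if (if (d) value >= 0.03 else value > 0.03)
             "possibly_damaging" else "benign",
    mutassessor = if (if (d) value >= 1.8 else value > 1.8) "damaging"
           else if (value >= 1.12) "possibly_damaging" else "benign",
    vest = if (value >= 0.65) "damaging"
           else if (value >= 0.17) "possibly_damaging" else "benign",
    stop("predictor '", predictor, "' does not take numeric scores")
  )
}

.categoricalCategory <- function(predictor, label) {
  lab <- .normCat(label)
  if (predictor == "annovar_impact") {
    return(switch(lab,
      high = "damaging", moderate = "possibly_damaging",
      low = "benign", modifier = "benign",
      stop("unknown Annovar impact '", label, "'")))
  }
  switch(lab,
    damaging = , high = "damaging",
    # PolyPhen-2's verbal "probably damaging" earns 0.5, not 1: only the
    # literal Damaging/High labels score a full point.
    possibly_damaging = , probably_damaging = , moderate =
      "possibly_damaging",
    benign = , neutral = , tolerated = , low = , modifier = "benign",
    stop("unknown category '", label, "' for predictor '", predictor, "'"))
}

#' Discretize one predictor output to a damaging/possibly/benign call
#'
#' Maps a raw numeric score or verbal label from one of the seven supported
#' in-silico predictors onto the three-level scale used by the 7-point
#' aggregation: `damaging` (1 point), `possibly_damaging` (0.5),
#' `benign` or `missing` (0).
#'
#' Numeric interval policy (default): CADD >= 14 damaging, 11-14 possibly,
#' < 11 benign; SIFT <= 0.06 damaging, (0.06, 0.23] possibly, > 0.23 benign;
#' PolyPhen-2 > 0.3 damaging, [0.03, 0.3] possibly, < 0.03 benign;
#' MutationAssessor >= 1.8 damaging, [1.12, 1.8) possibly, < 1.12 benign;
#' VEST >= 0.65 damaging, [0.17, 0.65) possibly, < 0.17 benign. Annovar
#' impact HIGH maps to damaging, MODERATE to possibly damaging, LOW and
#' MODIFIER to benign; FATHMM (and any verbal label) is passed through,
#' with "probably damaging" scoring 0.5 like "possibly damaging".
#'
#' @param predictor one of `"annovar_impact"`, `"cadd"`, `"sift"`,
#'   `"polyphen2"`, `"mutassessor"`, `"fathmm"`, `"vest"`.
#' @param value numeric score, verbal label, or `NA`/`"-"` for missing.
#' @param boundaryPolicy `"default"` assigns interval boundaries left
#'   unassigned by the published ranges to the more damaging side;
#'   `"strict"` to the less damaging side.
#' @return a one-row data.frame with columns `predictor`, `category`,
#'   `points`.
#' @examples
#' discretizeCall("vest", 0.66)   # damaging, 1 point
#' discretizeCall("sift", 0.5)    # benign, 0 points
#' discretizeCall("cadd", NA)     # missing, 0 points
#' @export
discretizeCall <- function(predictor, value,
                           boundaryPolicy = c("default", "strict")) {
  boundaryPolicy <- match.arg(boundaryPolicy)
  if (length(predictor) != 1L || !predictor %in% PREDICTORS)
    stop("unknown predictor '", paste(predictor, collapse = ","),
         "'; expected one of: ", paste(PREDICTORS, collapse = ", "))
  if (.isMissing(value)) {
    category <- "missing"
  } else if (is.numeric(value) ||
             (is.character(value) &&
              !is.na(suppressWarnings(as.numeric(value))))) {
    value <- as.numeric(value)
    if (predictor %in% c("annovar_impact", "fathmm"))
      stop("predictor '", predictor, "' takes categorical labels, not ",
           "numeric scores")
    rng <- .PRED_RANGE[[predictor]]
    if (value < rng[1] || value > rng[2])
      stop("score ", value, " outside the documented range [", rng[1], ", ",
           rng[2], "] for predictor '", predictor, "'")
    category <- .numericCategory(predictor, value, boundaryPolicy)
  } else {
    category <- .categoricalCategory(predictor, value)
  }
  points <- c(damaging = 1, possibly_damaging = 0.5, benign = 0,
              missing = 0)[[category]]
  data.frame(predictor = predictor, category = category, points = points,
             stringsAsFactors = FALSE)
}

#' Aggregate the seven predictor calls into the 0-7 point score
#'
#' Sums the discretized points (1 / 0.5 / 0) of the seven predictors.
#' Missing predictors contribute 0 but the 7-point denominator is unchanged.
#'
#' @param profile named list, vector or one-row data.frame holding the seven
#'   predictor outputs (names as in [discretizeCall]); absent names count
#'   as missing.
#' @param boundaryPolicy see [discretizeCall].
#' @return numeric score on the 0.5 grid in \[0, 7\].
#' @examples
#' aggregateScore(list(annovar_impact = "MODERATE", cadd = "Damaging",
#'   sift = "Damaging", polyphen2 = "Damaging",
#'   mutassessor = "Possibly damaging", fathmm = "Damaging",
#'   vest = "Damaging"))  # 6
#' @export
aggregateScore <- function(profile, boundaryPolicy = c("default", "strict")) {
  boundaryPolicy <- match.arg(boundaryPolicy)
  if (is.data.frame(profile)) profile <- as.list(profile)
  vals <- lapply(PREDICTORS, function(p)
    if (p %in% names(profile)) profile[[p]] else NA)
  pts <- vapply(seq_along(PREDICTORS), function(i)
    discretizeCall(PREDICTORS[i], vals[[i]], boundaryPolicy)$points,
    numeric(1))
  if (all(vapply(vals, .isMissing, logical(1))))
    stop("profile has no non-missing predictor entry")
  sum(pts)
}

#' Map the 7-point score to an ACMG computational evidence code
#'
#' Scores in \[0, 2) earn benign supporting evidence BP4, \[2, 4) no
#' computational code (VUS level), and \[4, 7\] pathogenic supporting
#' evidence PP3. Frameshift variants and variants with confirmed exon
#' skipping earn the very-strong null-variant code PVS1 irrespective of
#' the score.
#'
#' @param score value on the 0.5 grid in \[0, 7\] (ignored, and may be `NA`,
#'   for PVS1-class variants).
#' @param variantClass character; `"frameshift"` and
#'   `"exon_skipping_confirmed"` trigger PVS1, anything else (e.g.
#'   `"missense"`, `"intronic_splice"`) uses the score bands.
#' @return `"PVS1"`, `"BP4"`, `"none"` or `"PP3"`.
#' @examples
#' scoreToEvidence(4, "missense")     # "PP3"
#' scoreToEvidence(2.5, "missense")   # "none"
#' scoreToEvidence(1, "frameshift")   # "PVS1"
#' @export
scoreToEvidence <- function(score, variantClass = "missense") {
  if (variantClass %in% c("frameshift", "exon_skipping_confirmed"))
    return("PVS1")
  if (is.na(score) || score < 0 || score > 7 || (score * 2) %% 1 != 0)
    stop("score must lie on the 0.5 grid in [0, 7], got ", score)
  if (score < 2) "BP4" else if (score < 4) "none" else "PP3"
}

#' The ACMG evidence-combining rule table
#'
#' Declarative encoding of the published combining criteria: each row gives
#' the minimum number of codes per strength category (PVS very strong
#' pathogenic, PS strong, PM moderate, PP supporting; BA stand-alone benign,
#' BS strong, BP supporting) sufficient for the stated class.
#'
#' @return data.frame with columns `class`, `PVS`, `PS`, `PM`, `PP`,
#'   `BA`, `BS`, `BP`.
#' @export
acmgRules <- function() {
  rules <- rbind(
    c("pathogenic", 1, 1, 0, 0, 0, 0, 0),
    c("pathogenic", 1, 0, 2, 0, 0, 0, 0),
    c("pathogenic", 1, 0, 1, 1, 0, 0, 0),
    c("pathogenic", 1, 0, 0, 2, 0, 0, 0),
    c("pathogenic", 0, 2, 0, 0, 0, 0, 0),
    c("pathogenic", 0, 1, 3, 0, 0, 0, 0),
    c("pathogenic", 0, 1, 2, 2, 0, 0, 0),
    c("pathogenic", 0, 1, 1, 4, 0, 0, 0),
    c("likely_pathogenic", 1, 0, 1, 0, 0, 0, 0),
    c("likely_pathogenic", 0, 1, 1, 0, 0, 0, 0),
    c("likely_pathogenic", 0, 1, 0, 2, 0, 0, 0),
    c("likely_pathogenic", 0, 0, 3, 0, 0, 0, 0),
    c("likely_pathogenic", 0, 0, 2, 2, 0, 0, 0),
    c("likely_pathogenic", 0, 0, 1, 4, 0, 0, 0),
    c("benign", 0, 0, 0, 0, 1, 0, 0),
    c("benign", 0, 0, 0, 0, 0, 2, 0),
    c("likely_benign", 0, 0, 0, 0, 0, 1, 1),
    c("likely_benign", 0, 0, 0, 0, 0, 0, 2)
  )
  out <- data.frame(class = rules[, 1], stringsAsFactors = FALSE)
  cats <- c("PVS", "PS", "PM", "PP", "BA", "BS", "BP")
  for (i in seq_along(cats)) out[[cats[i]]] <- as.integer(rules[, i + 1])
  out
}

.ACMG_VOCAB <- c("PVS1", paste0("PS", 1:4), paste0("PM", 1:6),
                 paste0("PP", 1:5), "BA1", paste0("BS", 1:4),
                 paste0("BP", 1:7))

.codeCounts <- function(codes) {
  codes <- unique(codes)
  c(PVS = sum(grepl("^PVS", codes)),
    PS = sum(grepl("^PS[0-9]", codes)),
    PM = sum(grepl("^PM", codes)),
    PP = sum(grepl("^PP", codes)),
    BA = sum(grepl("^BA", codes)),
    BS = sum(grepl("^BS", codes)),
    BP = sum(grepl("^BP", codes)))
}

#' Combine ACMG evidence codes into a five-tier class
#'
#' Applies the published combining rules (see [acmgRules]). When both a
#' pathogenic-side and a benign-side rule fire the evidence is
#' contradictory and the variant is a VUS; when no rule fires it is a VUS.
#'
#' @param codes character vector of ACMG codes (e.g.
#'   `c("PVS1", "PM2")`); the empty set is allowed.
#' @return one of `"pathogenic"`, `"likely_pathogenic"`, `"VUS"`,
#'   `"likely_benign"`, `"benign"`.
#' @examples
#' combineEvidence(c("PVS1", "PM2"))  # likely_pathogenic
#' combineEvidence(character())       # VUS
#' combineEvidence("PP3")             # VUS
#' @export
combineEvidence <- function(codes) {
  codes <- as.character(codes)
  codes <- codes[nzchar(codes)]
  bad <- setdiff(codes, .ACMG_VOCAB)
  if (length(bad))
    stop("unknown ACMG code(s): ", paste(bad, collapse = ", "))
  n <- .codeCounts(codes)
  rules <- acmgRules()
  fired <- vapply(seq_len(nrow(rules)), function(i)
    all(n >= unlist(rules[i, c("PVS", "PS", "PM", "PP", "BA", "BS", "BP")])),
    logical(1))
  classes <- unique(rules$class[fired])
  pathSide <- any(classes %in% c("pathogenic", "likely_pathogenic"))
  benSide <- any(classes %in% c("benign", "likely_benign"))
  if (pathSide && benSide) return("VUS")
  if ("pathogenic" %in% classes) return("pathogenic")
  if ("likely_pathogenic" %in% classes) return("likely_pathogenic")
  if ("benign" %in% classes) return("benign")
  if ("likely_benign" %in% classes) return("likely_benign")
  "VUS"
}

#' Classify a table of variants end to end
#'
#' For each row: discretizes the seven predictor outputs, sums the 7-point
#' score, assigns the computational evidence code from the score bands (or
#' PVS1 for frameshift / confirmed exon skipping), merges caller-supplied
#' `other_codes`, and combines all evidence into the final five-tier class.
#' Input row order is preserved.
#'
#' Rows whose seven predictor cells are all missing are allowed only when
#' the variant class itself carries the evidence (frameshift or confirmed
#' exon skipping); they are reported with score `NA`.
#'
#' @param variants data.frame with columns `variant_id`, `variant_class`,
#'   the seven predictor columns of [discretizeCall], and optionally
#'   `other_codes` (comma-separated ACMG codes).
#' @param boundaryPolicy see [discretizeCall].
#' @return data.frame, one row per input row: `variant_id`, the seven
#'   per-predictor categories, `score`, `computational_code`, `final_class`.
#' @examples
#' tab <- readVariantTable(system.file("extdata", "abcc8_predictor_calls.tsv",
#'   package = "variantTriage"))
#' classifyVariants(tab)$score
#' @export
classifyVariants <- function(variants,
                             boundaryPolicy = c("default", "strict")) {
  boundaryPolicy <- match.arg(boundaryPolicy)
  stopifnot(is.data.frame(variants))
  need <- c("variant_id", "variant_class")
  miss <- setdiff(need, names(variants))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (nrow(variants) == 0L) {
    res <- data.frame(variant_id = character(), stringsAsFactors = FALSE)
    for (p in PREDICTORS) res[[p]] <- character()
    res$score <- numeric()
    res$computational_code <- character()
    res$final_class <- character()
    return(res)
  }
  out <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    row <- variants[i, , drop = FALSE]
    res <- tryCatch(.classifyRow(row, boundaryPolicy),
                    error = function(e)
                      stop("row ", i, " (", row$variant_id, "): ",
                           conditionMessage(e), call. = FALSE))
    out[[i]] <- res
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

.classifyRow <- function(row, boundaryPolicy) {
  calls <- lapply(PREDICTORS, function(p)
    discretizeCall(p, if (p %in% names(row)) row[[p]] else NA,
                   boundaryPolicy))
  cats <- vapply(calls, function(x) x$category, character(1))
  vclass <- as.character(row$variant_class)
  allMissing <- all(cats == "missing")
  score <- if (allMissing) NA_real_ else
    sum(vapply(calls, function(x) x$points, numeric(1)))
  if (allMissing && !vclass %in% c("frameshift", "exon_skipping_confirmed"))
    stop("all seven predictors missing and variant class '", vclass,
         "' carries no evidence of its own")
  code <- scoreToEvidence(score, vclass)
  other <- character()
  if ("other_codes" %in% names(row) && !.isMissing(row$other_codes))
    other <- trimws(strsplit(as.character(row$other_codes), ",")[[1]])
  evidence <- unique(c(if (code != "none") code, other))
  finalClass <- combineEvidence(evidence)
  res <- data.frame(variant_id = as.character(row$variant_id),
                    stringsAsFactors = FALSE)
  for (j in seq_along(PREDICTORS)) res[[PREDICTORS[j]]] <- cats[j]
  res$score <- score
  res$computational_code <- code
  res$final_class <- finalClass
  res
}
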