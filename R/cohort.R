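# Descriptive summaries of a clinical table of variant carriers.

#' Read a clinical table of variant carriers
#'
#' TSV, one row per patient. `"NA"`, `"-"` and empty cells parse as
#' missing. A `pap` column holding `"sys/dia/mean"` triplets (single
#' values treated as mean-only) is expanded into `pap_systolic`,
#' `pap_diastolic`, `pap_mean`.
#'
#' @param path TSV file path.
#' @return data.frame with numeric clinical columns parsed.
#' @examples
#' t1 <- readClinicalTable(system.file("extdata", "abcc8_clinical_table.tsv",
#'   package = "variantTriage"))
#' nrow(t1)
#' @export
readClinicalTable <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c("NA", "", "-", "–"),
                          check.names = FALSE)
  if ("pap" %in% names(df)) {
    parts <- strsplit(as.character(df$pap), "/", fixed = TRUE)
    getn <- function(x, i) if (is.na(x[1])) NA_real_ else
      if (length(x) >= 3L) as.numeric(x[i]) else
      if (i == 3L) as.numeric(x[1]) else NA_real_
    df$pap_systolic <- vapply(parts, getn, numeric(1), i = 1L)
    df$pap_diastolic <- vapply(parts, getn, numeric(1), i = 2L)
    df$pap_mean <- vapply(parts, getn, numeric(1), i = 3L)
    df$pap <- NULL
  }
  if (any(df$age_at_diagnosis < 0, na.rm = TRUE))
    stop("negative age_at_diagnosis")
  if ("functional_class" %in% names(df) &&
      !all(is.na(df$functional_class) |
           df$functional_class %in% c("I", "II", "III", "IV")))
    stop("functional_class must be one of I-IV")
  df
}

#' Descriptive summary of a clinical table
#'
#' Numeric columns: n non-missing, mean and sample (n-1) standard
#' deviation, missing values excluded column-wise. Categorical columns:
#' counts and percentages over non-missing rows. Single observations get
#' `sd = NA`; all-missing columns get `n = 0` and no mean.
#'
#' @param tab data.frame as from [readClinicalTable] (>= 1 row).
#' @return list with `numeric` (data.frame: column, n, mean, sd) and
#'   `categorical` (data.frame: column, level, count, percent).
#' @examples
#' t1 <- readClinicalTable(system.file("extdata", "abcc8_clinical_table.tsv",
#'   package = "variantTriage"))
#' s <- summarizeCohort(t1)
#' subset(s$numeric, column == "age_at_diagnosis")
#' @export
summarizeCohort <- function(tab) {
  stopifnot(is.data.frame(tab), nrow(tab) >= 1L)
  isNum <- vapply(tab, is.numeric, logical(1))
  num <- do.call(rbind, lapply(names(tab)[isNum], function(cn) {
    v <- tab[[cn]][!is.na(tab[[cn]])]
    data.frame(column = cn, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) >= 2L) stats::sd(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  catCols <- names(tab)[!isNum & names(tab) != "variant_id"]
  cat <- do.call(rbind, lapply(catCols, function(cn) {
    v <- tab[[cn]][!is.na(tab[[cn]])]
    if (!length(v)) return(NULL)
    tb <- table(v)
    data.frame(column = cn, level = names(tb), count = as.integer(tb),
               percent = 100 * as.integer(tb) / length(v),
               stringsAsFactors = FALSE)
  }))
  list(numeric = num, categorical = cat)
}

#' Fraction of panel patients carrying a variant, as a percentage
#'
#' @param nCarriers number of carriers (0 <= nCarriers <= nPatients).
#' @param nPatients number of patients screened (> 0).
#' @return percentage rounded to 2 decimals.
#' @examples
#' carrierFraction(11, 624)  # 1.76
#' @export
carrierFraction <- function(nCarriers, nPatients) {
  stopifnot(nPatients > 0, nCarriers >= 0, nCarriers <= nPatients)
  round(100 * nCarriers / nPatients, 2)
}
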