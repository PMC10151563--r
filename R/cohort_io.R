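#' Cohort tables
#'
#' A cohort table holds one row per tumor sample with the clinical
#' covariates the analysis uses: carrier status (verified pathogenic-variant
#' carrier vs first-degree relative), affected MMR gene, variant class,
#' tumor location, age at diagnosis, age of the FFPE block, and the
#' measured double-stranded DNA concentration. Synthetic cohorts carry an
#' extra `truth_mmr` column (ground-truth MMR status); real-data tables may
#' omit it.
#'
#' @name cohort_table
NULL

MMR_GENES <- c("MLH1", "MSH2", "MSH6", "PMS2")
CARRIER_LEVELS <- c("carrier", "FDR")
VARIANT_LEVELS <- c("truncating", "missense", "unknown")
LOCATION_LEVELS <- c("ureter", "renal_pelvis", "bladder")
MMR_LEVELS <- c("deficient", "proficient")

COHORT_REQUIRED <- c("sample_id", "carrier_status", "gene", "variant_class",
                     "location", "age_at_diagnosis", "block_age", "dna_conc")

validate_cohort <- function(df) {
  missing <- setdiff(COHORT_REQUIRED, names(df))
  if (length(missing)) {
    stop_msi("cohort table is missing required column(s): ",
             paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) stop_msi("duplicate sample_id in cohort")
  check_levels <- function(col, levels) {
    bad <- setdiff(unique(df[[col]]), levels)
    if (length(bad)) {
      stop_msi(sprintf("invalid %s value(s): %s (allowed: %s)", col,
                       paste(bad, collapse = ", "),
                       paste(levels, collapse = ", ")))
    }
  }
  check_levels("carrier_status", CARRIER_LEVELS)
  check_levels("gene", MMR_GENES)
  check_levels("variant_class", VARIANT_LEVELS)
  check_levels("location", LOCATION_LEVELS)
  if ("truth_mmr" %in% names(df)) check_levels("truth_mmr", MMR_LEVELS)
  if (any(df$dna_conc < 0)) stop_msi("dna_conc must be >= 0")
  if (any(df$age_at_diagnosis < 0) || any(df$block_age < 0)) {
    stop_msi("ages must be >= 0")
  }
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Read a cohort table from TSV
#'
#' @param path TSV with a single header row; see [cohort_table] for the
#'   required columns. `truth_mmr` is optional (absent in real-data mode).
#' @return a validated `cohort_table` data frame.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop_msi("cohort file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_cohort(df)
}

#' Write a cohort table to TSV
#'
#' @param cohort a `cohort_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  utils::write.table(as.data.frame(cohort), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Statistical configuration
#'
#' @param conf_level confidence level for all intervals (default 0.95).
#' @param wilson_continuity apply a continuity correction to Wilson
#'   intervals? Default `FALSE` (plain score interval).
#' @return a `stats_config` list.
#' @export
stats_config <- function(conf_level = 0.95, wilson_continuity = FALSE) {
  if (!is.numeric(conf_level) || conf_level <= 0 || conf_level >= 1) {
    stop_msi("conf_level must be strictly between 0 and 1")
  }
  structure(list(conf_level = conf_level,
                 wilson_continuity = isTRUE(wilson_continuity)),
            class = "stats_config")
}
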