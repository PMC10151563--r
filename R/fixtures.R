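#' Reference counts from the motivating urothelial-cancer study
#'
#' The package bundles the published confusion counts of a study that
#' compared immunohistochemical MMR protein status against three MSI
#' assays (Promega-style fragment analysis, and 24- and 54-marker
#' sequencing panels) in Lynch syndrome-associated urothelial tumors.
#' Pairs non-evaluable by either assay are already excluded, so each assay
#' has its own denominator (68, 72 and 72).
#'
#' @return `reference_confusion()`: a named list of [confusion_table()]
#'   objects for assays `promega`, `seq24` and `seq54`.
#' @export
#' @examples
#' cts <- reference_confusion()
#' concordance_wilson(cts$promega)$estimate  # 0.7059
reference_confusion <- function() {
  path <- system.file("extdata", "reference_confusion_counts.tsv",
                      package = "msiconcord", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    confusion_table(df$a[i], df$b[i], df$c[i], df$d[i])
  })
  names(out) <- df$assay
  out
}

#' @rdname reference_confusion
#' @return `reference_crosstabs()`: a named list of 2x2 matrices for the
#'   cohort-level Fisher tests — MMR loss by carrier status
#'   (carriers/FDRs x loss/retained), retained expression by tumor
#'   location (upper/lower tract x retained/loss), and the per-carrier-
#'   status location sub-analyses.
#' @export
reference_crosstabs <- function() {
  path <- system.file("extdata", "reference_crosstabs.tsv",
                      package = "msiconcord", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    matrix(c(df$r1c1[i], df$r1c2[i], df$r2c1[i], df$r2c2[i]),
           nrow = 2, byrow = TRUE)
  })
  names(out) <- df$name
  out
}

#' @rdname reference_confusion
#' @return `reference_panel_discordance()`: the discordant-pair counts of
#'   the 24- vs 54-marker panel comparison (six tumors MSS by the 24-marker
#'   panel but MSI-H by the 54-marker panel, none the reverse).
#' @export
reference_panel_discordance <- function() {
  list(b = 6L, c = 0L)
}
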