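#' Immunohistochemistry loss rules
#'
#' A protein is scored as lost when its tumor-cell positivity fraction is
#' at most 10% in the presence of internal positive staining (lymphocytes
#' or stromal cells); without the internal control the protein is
#' non-evaluable. Sample-level loss requires at least one lost protein.
#' Because the MMR proteins act as heterodimers (MutS-alpha = MSH2:MSH6,
#' MutL-alpha = MLH1:PMS2), loss of an obligate partner degrades the other:
#' MLH1 defects typically show MLH1+PMS2 loss, MSH2 defects MSH2+MSH6 loss,
#' while MSH6 and PMS2 defects show isolated loss.
#'
#' @name ihc_rules
NULL

# Expected lost-protein pattern per affected gene (heterodimer co-loss).
IHC_PATTERN <- list(
  MLH1 = c("MLH1", "PMS2"),
  MSH2 = c("MSH2", "MSH6"),
  MSH6 = "MSH6",
  PMS2 = "PMS2"
)

#' Call a single MMR protein from its positivity fraction
#'
#' @param pi tumor-cell positivity fraction in `[0, 1]`.
#' @param control internal positive control present?
#' @param cutoff loss threshold; expression in at most this fraction of
#'   tumor cells is scored as loss (default 0.10, boundary inclusive).
#' @return `"loss"`, `"retained"` or `"NE"`.
#' @export
#' @examples
#' call_protein(0.05, TRUE)  # "loss"
#' call_protein(0.30, TRUE)  # "retained"
call_protein <- function(pi, control = TRUE, cutoff = 0.10) {
  assert_prob(pi, "pi")
  if (!isTRUE(control)) return("NE")
  if (pi <= cutoff) "loss" else "retained"
}

#' Classify a sample's MMR status from four-protein IHC
#'
#' @param measurement named numeric vector or list with positivity
#'   fractions for `MLH1`, `MSH2`, `MSH6`, `PMS2`, plus a logical
#'   `internal_control_present` element (or the `control` argument).
#' @param family_gene the MMR gene affected in the family, one of
#'   `"MLH1"`, `"MSH2"`, `"MSH6"`, `"PMS2"`.
#' @param control internal control flag; overridden by the measurement's
#'   own `internal_control_present` if present.
#' @param cutoff per-protein loss cutoff (default 0.10).
#' @return an `ihc_result` list: `protein_calls` (named character),
#'   `sample_status` (`"loss"`/`"retained"`/`"NE"`), `lost_set`, and
#'   `pattern_consistent` — whether the lost set is contained in the
#'   heterodimer pattern expected for `family_gene` and includes that
#'   gene's protein.
#' @export
classify_sample_ihc <- function(measurement, family_gene, control = TRUE,
                                cutoff = 0.10) {
  if (!family_gene %in% MMR_GENES) {
    stop_msi("unknown MMR gene: ", family_gene)
  }
  m <- as.list(measurement)
  if (!is.null(m$internal_control_present)) {
    control <- isTRUE(m$internal_control_present)
  }
  missing <- setdiff(MMR_GENES, names(m))
  if (length(missing)) {
    stop_msi("measurement lacks protein(s): ", paste(missing, collapse = ", "))
  }
  calls <- vapply(MMR_GENES, function(p) {
    call_protein(as.numeric(m[[p]]), control, cutoff)
  }, "")
  lost <- names(calls)[calls == "loss"]
  status <- if (all(calls == "NE")) "NE" else if (length(lost)) "loss" else "retained"
  expected <- IHC_PATTERN[[family_gene]]
  consistent <- length(lost) > 0 && all(lost %in% expected) &&
    family_gene %in% lost
  if (status == "loss" && !consistent) {
    warning(sprintf(
      "sample lost {%s} which does not match the pattern expected for %s ({%s})",
      paste(lost, collapse = ","), family_gene,
      paste(expected, collapse = ",")))
  }
  structure(list(protein_calls = calls, sample_status = status,
                 lost_set = lost, pattern_consistent = consistent),
            class = "ihc_result")
}
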