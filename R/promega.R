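#' Fragment-length MSI rules without matched normal DNA
#'
#' The five mononucleotide markers of the Promega-style assay are each
#' called stable, unstable or "suggestive of instability" from the
#' fragment-length evidence; without germline DNA, sample classification
#' uses the conservative rule set: three or more unstable markers is
#' MSI-H, zero is MSS, one is unresolved MSS/MSI-L, two is unresolved
#' MSI-L/MSI-H, and any marker merely suggestive of instability renders
#' the sample non-evaluable. For 2x2 comparison with IHC, MSI-L/MSI-H is
#' pooled with MSI-H ("pooled MSI-H") and MSS/MSI-L with MSS
#' ("pooled MSS/MSI-L").
#'
#' @name promega_rules
NULL

PROMEGA_RAW <- c("MSS", "MSS/MSI-L", "MSI-L/MSI-H", "MSI-H", "NE")
PROMEGA_POOLED <- c("pooled MSI-H", "pooled MSS/MSI-L", "NE")
MARKER_STATUS <- c("stable", "unstable", "suggestive")

#' Promega rule configuration
#'
#' @param shift_threshold_bp modal shift (bp) at or beyond which a marker
#'   is unstable; default 3, the objective deviation rule recommended for
#'   mononucleotide markers in place of manual trace reading.
#' @param min_allele_fraction read-fraction floor for a non-reference
#'   modal allele to count as a real second allele rather than stutter
#'   (default 0.2).
#' @return a `promega_config` list.
#' @export
promega_config <- function(shift_threshold_bp = 3, min_allele_fraction = 0.2) {
  if (shift_threshold_bp < 1) stop_msi("shift_threshold_bp must be >= 1")
  assert_prob(min_allele_fraction, "min_allele_fraction")
  structure(list(shift_threshold_bp = shift_threshold_bp,
                 min_allele_fraction = min_allele_fraction),
            class = "promega_config")
}

#' Call one marker from its repeat-length histogram
#'
#' Finds the modal non-reference allele with read fraction at least
#' `min_allele_fraction`; the marker is `unstable` if its shift from the
#' reference length reaches `shift_threshold_bp`, `suggestive` for a 1 to
#' `shift_threshold_bp - 1` bp shift, and `stable` otherwise (including
#' when no such allele exists).
#'
#' @param hist data frame with columns `repeat_len`, `read_count`.
#' @param marker one row of a marker registry (needs `ref_len`).
#' @param config a [promega_config()].
#' @return status string in `{"stable", "unstable", "suggestive"}`.
#' @export
call_marker_shift <- function(hist, marker, config = promega_config()) {
  if (nrow(hist) == 0L || sum(hist$read_count) == 0) {
    stop_msi("empty histogram for marker ", marker$marker_id %||% "?")
  }
  ref <- marker$ref_len
  total <- sum(hist$read_count)
  alt <- hist[hist$repeat_len != ref & hist$read_count / total >=
                config$min_allele_fraction, , drop = FALSE]
  if (nrow(alt) == 0L) return("stable")
  modal <- alt$repeat_len[which.max(alt$read_count)]
  shift <- abs(modal - ref)
  if (shift >= config$shift_threshold_bp) "unstable"
  else if (shift >= 1) "suggestive"
  else "stable"
}

#' Classify a sample from its five marker calls
#'
#' @param calls character vector of five statuses (one per promega5
#'   marker), or a data frame with columns `marker_id`, `status`. When
#'   marker ids are available they must be exactly the promega5 panel.
#' @param panel_ids the expected marker ids (default the promega5 panel of
#'   the built-in registry).
#' @return a `promega_result` list: `n_unstable`, `raw_class`,
#'   `pooled_class`.
#' @export
#' @examples
#' classify_promega(c("unstable", "unstable", "unstable", "stable", "stable"))
classify_promega <- function(calls,
                             panel_ids = get_panel(default_marker_registry(),
                                                   "promega5")$marker_id) {
  if (is.data.frame(calls)) {
    if (!setequal(calls$marker_id, panel_ids)) {
      stop_msi("marker calls do not match the promega5 panel")
    }
    status <- calls$status
  } else {
    if (!is.null(names(calls)) && !setequal(names(calls), panel_ids)) {
      stop_msi("marker calls do not match the promega5 panel")
    }
    status <- unname(as.character(calls))
  }
  if (length(status) != 5L) {
    stop_msi("classify_promega expects exactly 5 marker calls, got ",
             length(status))
  }
  bad <- setdiff(status, MARKER_STATUS)
  if (length(bad)) stop_msi("unknown marker status: ", paste(bad, collapse = ", "))
  n_unstable <- sum(status == "unstable")
  raw <- if (any(status == "suggestive")) {
    "NE"
  } else if (n_unstable >= 3) {
    "MSI-H"
  } else if (n_unstable == 2) {
    "MSI-L/MSI-H"
  } else if (n_unstable == 1) {
    "MSS/MSI-L"
  } else {
    "MSS"
  }
  structure(list(n_unstable = n_unstable, raw_class = raw,
                 pooled_class = pool_class(raw)),
            class = "promega_result")
}

#' Pool raw fragment-assay classes for 2x2 comparison
#'
#' @param raw_class character vector of raw classes.
#' @return `"pooled MSI-H"` for MSI-H and MSI-L/MSI-H, `"pooled
#'   MSS/MSI-L"` for MSS and MSS/MSI-L, `"NE"` unchanged.
#' @export
pool_class <- function(raw_class) {
  map <- c("MSI-H" = "pooled MSI-H", "MSI-L/MSI-H" = "pooled MSI-H",
           "MSS" = "pooled MSS/MSI-L", "MSS/MSI-L" = "pooled MSS/MSI-L",
           "NE" = "NE")
  bad <- setdiff(raw_class, names(map))
  if (length(bad)) stop_msi("unknown raw class: ", paste(bad, collapse = ", "))
  unname(map[raw_class])
}
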