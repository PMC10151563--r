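#' Repeat profiling: from reads to per-marker features
#'
#' Each marker's reads are reduced to a repeat-length histogram and then to
#' two features used by the MSI classifier: the deletion frequency `d`
#' (fraction of reads strictly shorter than the registry reference length
#' — no matched normal is used, markers being quasi-monomorphic) and the
#' allelic bias `b` (fraction of deleted reads concentrated at the single
#' modal deleted length — high for a clonal somatic deletion, lower for
#' dispersed lengths). A marker is evaluable when its depth reaches
#' `min_depth`.
#'
#' @name repeat_profiling
NULL

#' Profiling configuration
#'
#' @param min_depth minimum reads for a marker to be evaluable (default
#'   200, i.e. 10% of the nominal 2000-read target depth per amplicon).
#' @return a `profiling_config` list.
#' @export
profiling_config <- function(min_depth = 200) {
  assert_count(min_depth, "min_depth")
  structure(list(min_depth = as.integer(min_depth), target_depth = 2000L),
            class = "profiling_config")
}

#' Extract a repeat-length histogram from FASTQ reads
#'
#' A read contributes when it contains the marker's exact left flank,
#' followed only by the repeat base, followed by the exact right flank;
#' the tallied length is the number of repeat bases between the flanks.
#' All other reads are discarded and counted.
#'
#' @param fastq path to a (plain-text) FASTQ file.
#' @param marker one row of a marker registry.
#' @return data frame with columns `repeat_len`, `read_count`; attribute
#'   `n_discarded` counts non-matching reads.
#' @export
extract_repeat_lengths <- function(fastq, marker) {
  if (is.null(marker) || is.na(marker$marker_id %||% NA)) {
    stop_msi("marker must be a registry row")
  }
  reads <- as.character(Biostrings::readDNAStringSet(fastq, format = "fastq"))
  pattern <- paste0(marker$left_flank, "(", marker$repeat_base, "*)",
                    marker$right_flank)
  m <- regexpr(pattern, reads)
  hit <- m != -1L
  lens <- integer(0)
  if (any(hit)) {
    # repeat length = match length minus both flanks
    lens <- attr(m, "match.length")[hit] -
      nchar(marker$left_flank) - nchar(marker$right_flank)
  }
  tab <- table(lens)
  out <- data.frame(repeat_len = as.integer(names(tab)),
                    read_count = as.integer(tab))
  attr(out, "n_discarded") <- sum(!hit)
  out
}

#' Profile one marker from its histogram
#'
#' @param hist data frame with columns `repeat_len`, `read_count`.
#' @param marker registry row providing `ref_len`.
#' @param config a [profiling_config()].
#' @return one-row data frame: `marker_id`, `depth`, `d`, `b`,
#'   `evaluable`. Ties for the modal deleted length break toward the
#'   larger deletion (smaller length) for determinism.
#' @export
#' @examples
#' h <- data.frame(repeat_len = c(27, 26, 25), read_count = c(900, 60, 40))
#' profile_marker(h, list(marker_id = "M", ref_len = 27L))
profile_marker <- function(hist, marker, config = profiling_config()) {
  if (is.null(marker$ref_len)) stop_msi("marker lacks ref_len")
  if (nrow(hist) == 0L) stop_msi("empty histogram")
  stopifnot(all(hist$read_count >= 0), all(hist$repeat_len >= 0))
  depth <- sum(hist$read_count)
  del <- hist[hist$repeat_len < marker$ref_len & hist$read_count > 0, ,
              drop = FALSE]
  n_del <- sum(del$read_count)
  d <- if (depth > 0) n_del / depth else 0
  b <- 0
  if (n_del > 0) {
    top <- max(del$read_count)
    modal_len <- min(del$repeat_len[del$read_count == top])
    b <- del$read_count[del$repeat_len == modal_len][1] / n_del
  }
  data.frame(marker_id = marker$marker_id %||% NA_character_,
             depth = depth, d = d, b = b,
             evaluable = depth >= config$min_depth,
             stringsAsFactors = FALSE)
}

#' Profile a sample over a panel
#'
#' @param histograms data frame with columns `marker_id`, `repeat_len`,
#'   `read_count` covering a subset of the panel.
#' @param panel marker registry rows (e.g. from [get_panel()]).
#' @param config a [profiling_config()].
#' @return data frame of one profile per panel marker, in panel order;
#'   markers without reads become non-evaluable rows with `depth = 0`.
#' @export
profile_sample <- function(histograms, panel, config = profiling_config()) {
  extra <- setdiff(unique(histograms$marker_id), panel$marker_id)
  if (length(extra)) {
    stop_msi("histograms contain markers outside the panel: ",
             paste(extra, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    mk <- panel[i, ]
    h <- histograms[histograms$marker_id == mk$marker_id, , drop = FALSE]
    if (nrow(h) == 0L || sum(h$read_count) == 0) {
      return(data.frame(marker_id = mk$marker_id, depth = 0L, d = 0, b = 0,
                        evaluable = FALSE, stringsAsFactors = FALSE))
    }
    profile_marker(h, mk, config)
  })
  do.call(rbind, rows)
}
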