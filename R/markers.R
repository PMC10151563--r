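#' Marker registries and panels
#'
#' A marker registry is a data frame describing mononucleotide-repeat loci:
#' one row per marker with its repeat base, reference repeat length (in
#' bases), flanking anchor sequences and panel membership. Three panels are
#' recognised: `promega5` (the five quasi-monomorphic markers BAT-25,
#' BAT-26, NR-21, NR-24 and MONO-27 used by fragment-length MSI assays),
#' and the sequencing panels `seq24` and `seq54`.
#'
#' The genomic identities of the 24- and 54-marker sequencing panels are
#' not part of this package; [default_marker_registry()] generates
#' synthetic A/T mononucleotide repeats with a fixed internal seed so the
#' registry is reproducible.
#'
#' @name marker_registry
NULL

PANEL_NAMES <- c("promega5", "seq24", "seq54")
PANEL_SIZES <- c(promega5 = 5L, seq24 = 24L, seq54 = 54L)
REGISTRY_COLS <- c("marker_id", "repeat_base", "ref_len",
                   "left_flank", "right_flank", "panel_tags")

validate_marker_registry <- function(reg) {
  missing <- setdiff(REGISTRY_COLS, names(reg))
  if (length(missing)) {
    stop_msi("marker registry is missing column(s): ",
             paste(missing, collapse = ", "))
  }
  if (anyDuplicated(reg$marker_id)) {
    stop_msi("duplicate marker_id in registry: ",
             paste(unique(reg$marker_id[duplicated(reg$marker_id)]),
                   collapse = ", "))
  }
  if (!all(reg$repeat_base %in% c("A", "C", "G", "T"))) {
    stop_msi("repeat_base must be one of A, C, G, T")
  }
  if (!all(reg$ref_len >= 5 & reg$ref_len == round(reg$ref_len))) {
    stop_msi("ref_len must be an integer >= 5")
  }
  if (!all(nchar(reg$left_flank) >= 8 & nchar(reg$right_flank) >= 8)) {
    stop_msi("flank sequences must be at least 8 bases")
  }
  runs_ok <- mapply(function(l, r, b) {
    max_char_run(l, b) <= 3 && max_char_run(r, b) <= 3
  }, reg$left_flank, reg$right_flank, reg$repeat_base)
  if (!all(runs_ok)) {
    stop_msi("flanks must not contain a run of the repeat base longer than 3: ",
             paste(reg$marker_id[!runs_ok], collapse = ", "))
  }
  tags <- strsplit(reg$panel_tags, ",", fixed = TRUE)
  bad <- !vapply(tags, function(t) all(t %in% PANEL_NAMES), logical(1))
  if (any(bad)) {
    stop_msi("unknown panel tag for marker(s): ",
             paste(reg$marker_id[bad], collapse = ", "))
  }
  reg$ref_len <- as.integer(reg$ref_len)
  class(reg) <- c("marker_registry", "data.frame")
  reg
}

# Random flank with no run of `base` longer than 3.
random_flank <- function(n, base) {
  repeat {
    fl <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                collapse = "")
    if (max_char_run(fl, base) <= 3) return(fl)
  }
}

#' Default synthetic marker registry
#'
#' Builds the package's built-in registry: the five Promega-style markers
#' (BAT-25, BAT-26, NR-21, NR-24, MONO-27 with their nominal repeat
#' lengths) plus 24 + 54 synthetic A/T mononucleotide repeats with
#' reference lengths drawn between 7 and 27 bases. Generation is seeded
#' internally so repeated calls return the identical registry.
#'
#' @param flank_len length in bases of each synthetic flank (default 12).
#' @return a `marker_registry` data frame.
#' @export
#' @examples
#' reg <- default_marker_registry()
#' table(unlist(strsplit(reg$panel_tags, ",")))
default_marker_registry <- function(flank_len = 12) {
  with_seed(101L, {
    promega <- data.frame(
      marker_id = c("BAT-25", "BAT-26", "NR-21", "NR-24", "MONO-27"),
      repeat_base = c("T", "A", "A", "T", "A"),
      ref_len = c(25L, 26L, 21L, 24L, 27L),
      stringsAsFactors = FALSE
    )
    promega$left_flank <- vapply(promega$repeat_base,
                                 function(b) random_flank(flank_len, b), "")
    promega$right_flank <- vapply(promega$repeat_base,
                                  function(b) random_flank(flank_len, b), "")
    promega$panel_tags <- "promega5"

    synth_panel <- function(prefix, n, tag) {
      base <- sample(c("A", "T"), n, replace = TRUE)
      out <- data.frame(
        marker_id = sprintf("%s-%02d", prefix, seq_len(n)),
        repeat_base = base,
        ref_len = as.integer(sample(7:27, n, replace = TRUE)),
        stringsAsFactors = FALSE
      )
      out$left_flank <- vapply(base, function(b) random_flank(flank_len, b), "")
      out$right_flank <- vapply(base, function(b) random_flank(flank_len, b), "")
      out$panel_tags <- tag
      out
    }
    reg <- rbind(promega,
                 synth_panel("CRC", 24L, "seq24"),
                 synth_panel("CMMRD", 54L, "seq54"))
    validate_marker_registry(reg)
  })
}

#' Read a marker registry from a TSV file
#'
#' @param path TSV file with columns `marker_id`, `repeat_base`, `ref_len`,
#'   `left_flank`, `right_flank`, `panel_tags` (comma-separated tags).
#' @return a validated `marker_registry`; an empty file yields an empty
#'   registry with a warning.
#' @export
load_marker_registry <- function(path) {
  if (!file.exists(path)) stop_msi("marker registry file not found: ", path)
  reg <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(reg) == 0L) {
    warning("marker registry '", path, "' contains no markers")
    reg <- reg[, intersect(REGISTRY_COLS, names(reg)), drop = FALSE]
    for (col in setdiff(REGISTRY_COLS, names(reg))) reg[[col]] <- character(0)
    reg$ref_len <- integer(0)
    class(reg) <- c("marker_registry", "data.frame")
    return(reg)
  }
  reg$ref_len <- as.integer(reg$ref_len)
  validate_marker_registry(reg)
}

#' Write a marker registry to TSV
#'
#' @param registry a `marker_registry`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_marker_registry <- function(registry, path) {
  utils::write.table(as.data.frame(registry)[, REGISTRY_COLS], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract a panel from a registry
#'
#' @param registry a `marker_registry`.
#' @param name one of `"promega5"`, `"seq24"`, `"seq54"`.
#' @param check_size enforce the canonical panel size (5/24/54)?
#' @return the registry rows belonging to the panel, in registry order.
#' @export
get_panel <- function(registry, name, check_size = FALSE) {
  name <- match.arg(name, PANEL_NAMES)
  tags <- strsplit(registry$panel_tags, ",", fixed = TRUE)
  sel <- vapply(tags, function(t) name %in% t, logical(1))
  panel <- registry[sel, , drop = FALSE]
  rownames(panel) <- NULL
  if (check_size && nrow(panel) != PANEL_SIZES[[name]]) {
    stop_msi(sprintf("panel '%s' has %d markers, expected %d",
                     name, nrow(panel), PANEL_SIZES[[name]]))
  }
  class(panel) <- c("marker_registry", "data.frame")
  panel
}
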