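#' Report bundles
#'
#' A report bundle collects the per-assay concordance reports of one
#' analysis run together with a cohort summary and provenance (seed,
#' configuration hash, panel sizes), and can be serialised to JSON plus a
#' human-readable table.
#'
#' @param reports named list of [concordance_report()] objects; names are
#'   the assay labels.
#' @param cohort_summary optional list or data frame summarising the cohort.
#' @param provenance list with at least `seed`; a hash of the run
#'   configuration and panel sizes are conventionally included.
#' @return a `report_bundle`.
#' @export
report_bundle <- function(reports, cohort_summary = NULL, provenance = list()) {
  if (length(reports) == 0L) stop_msi("report bundle must contain at least one report")
  if (is.null(names(reports)) || any(names(reports) == "")) {
    stop_msi("reports must be a named list (names = assay labels)")
  }
  ok <- vapply(reports, inherits, logical(1), "concordance_report")
  if (!all(ok)) stop_msi("all elements of 'reports' must be concordance_report objects")
  for (nm in names(reports)) {
    if (!identical(reports[[nm]]$assay, nm)) {
      stop_msi(sprintf("report named '%s' refers to assay '%s'",
                       nm, reports[[nm]]$assay))
    }
  }
  structure(list(reports = reports, cohort_summary = cohort_summary,
                 provenance = provenance),
            class = "report_bundle")
}

report_to_list <- function(bundle) {
  list(
    reports = lapply(bundle$reports, function(r) {
      list(assay = r$assay,
           table = r$table[c("a", "b", "c", "d", "n")],
           concordance = r$concordance,
           sensitivity = r$sens_spec$sensitivity,
           specificity = r$sens_spec$specificity,
           mcnemar = r$mcnemar,
           conf_level = r$conf_level)
    }),
    cohort_summary = bundle$cohort_summary,
    provenance = bundle$provenance
  )
}

#' Write a report bundle to disk
#'
#' Writes `<stem>.json` (lossless, full double precision) and `<stem>.txt`,
#' a fixed-width table of strata (assay x outcome counts and the derived
#' statistics).
#'
#' @param bundle a [report_bundle()].
#' @param stem output path without extension.
#' @return character vector of the two paths written, invisibly.
#' @export
write_report <- function(bundle, stem) {
  if (!inherits(bundle, "report_bundle")) stop_msi("not a report_bundle")
  json_path <- paste0(stem, ".json")
  txt_path <- paste0(stem, ".txt")
  jsonlite::write_json(report_to_list(bundle), json_path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(txt_path, "w")
  on.exit(close(con))
  writeLines(render_report_table(bundle), con)
  invisible(c(json = json_path, txt = txt_path))
}

render_report_table <- function(bundle) {
  rows <- lapply(bundle$reports, function(r) {
    data.frame(
      assay = r$assay, n = r$table$n,
      loss_msih = r$table$a, loss_mss = r$table$b,
      ret_msih = r$table$c, ret_mss = r$table$d,
      concordance_pct = round(100 * r$concordance$estimate, 1),
      sens_pct = round(100 * r$sens_spec$sensitivity$estimate, 1),
      spec_pct = round(100 * r$sens_spec$specificity$estimate, 1),
      mcnemar_p = signif(r$mcnemar$p_value, 3),
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  c(utils::capture.output(print(tab, row.names = FALSE)),
    "",
    paste0("provenance: ",
           paste(names(bundle$provenance),
                 vapply(bundle$provenance, function(x)
                   paste(format(x), collapse = ","), ""),
                 sep = "=", collapse = "; ")))
}

#' Read a report bundle back from its JSON form
#'
#' @param json_path path written by [write_report()].
#' @return a `report_bundle` structurally identical to the one written.
#' @export
read_report <- function(json_path) {
  x <- jsonlite::read_json(json_path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  reports <- lapply(x$reports, function(r) {
    ct <- confusion_table(r$table$a, r$table$b, r$table$c, r$table$d)
    structure(list(assay = r$assay, table = ct,
                   concordance = r$concordance,
                   sens_spec = list(sensitivity = r$sensitivity,
                                    specificity = r$specificity),
                   mcnemar = r$mcnemar,
                   conf_level = r$conf_level),
              class = "concordance_report")
  })
  report_bundle(reports, cohort_summary = x$cohort_summary,
                provenance = x$provenance)
}
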