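#' Diagnostic concordance statistics
#'
#' Agreement between immunohistochemical MMR protein status and a
#' dichotomized MSI call is summarised in a 2x2 confusion table
#'
#' |                | pooled MSI-H | pooled MSS/MSI-L |
#' |----------------|--------------|------------------|
#' | MMR loss       | a            | b                |
#' | MMR retained   | c            | d                |
#'
#' from which the package computes concordance `(a + d) / n` with a Wilson
#' score interval, sensitivity `a / (a + b)` and specificity `d / (c + d)`
#' (treating immunohistochemistry as the reference method) with exact
#' Clopper-Pearson intervals, and the exact McNemar test on the discordant
#' pair `(b, c)`.
#'
#' @name concordance_stats
NULL

#' Construct a 2x2 confusion table
#'
#' @param a loss & pooled MSI-H count.
#' @param b loss & pooled MSS/MSI-L count.
#' @param c retained & pooled MSI-H count.
#' @param d retained & pooled MSS/MSI-L count.
#' @return a `confusion_table` object with cells and total `n`.
#' @export
confusion_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop_msi("confusion-table cells must be non-negative integers")
  }
  structure(list(a = as.integer(a), b = as.integer(b), c = as.integer(c),
                 d = as.integer(d), n = as.integer(a + b + c + d)),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
              dimnames = list(c("MMR loss", "MMR retained"),
                              c("pooled MSI-H", "pooled MSS/MSI-L")))
  print(m)
  cat("n =", x$n, "\n")
  invisible(x)
}

#' Build a confusion table from paired assay results
#'
#' Pairs in which either assay is non-evaluable (`"NE"`) are dropped
#' (listwise per assay) and counted in the `n_dropped` attribute, so each
#' assay comparison has its own denominator.
#'
#' @param ihc_status character vector in `{"loss", "retained", "NE"}`.
#' @param msi_pooled character vector in
#'   `{"pooled MSI-H", "pooled MSS/MSI-L", "NE"}`.
#' @param sample_id optional ids; duplicates are an error.
#' @return a `confusion_table` with attribute `n_dropped`.
#' @export
build_confusion <- function(ihc_status, msi_pooled, sample_id = NULL) {
  if (length(ihc_status) != length(msi_pooled)) {
    stop_msi("ihc_status and msi_pooled must have equal length")
  }
  if (!is.null(sample_id) && anyDuplicated(sample_id)) {
    stop_msi("duplicate sample_id in paired results")
  }
  stopifnot(all(ihc_status %in% c("loss", "retained", "NE")),
            all(msi_pooled %in% c("pooled MSI-H", "pooled MSS/MSI-L", "NE")))
  keep <- ihc_status != "NE" & msi_pooled != "NE"
  if (!any(keep)) stop_msi("empty table: every pair is non-evaluable")
  ihc <- ihc_status[keep]
  msi <- msi_pooled[keep]
  ct <- confusion_table(
    a = sum(ihc == "loss" & msi == "pooled MSI-H"),
    b = sum(ihc == "loss" & msi == "pooled MSS/MSI-L"),
    c = sum(ihc == "retained" & msi == "pooled MSI-H"),
    d = sum(ihc == "retained" & msi == "pooled MSS/MSI-L")
  )
  attr(ct, "n_dropped") <- sum(!keep)
  ct
}

# Wilson score interval for x successes of n.
wilson_interval <- function(x, n, conf_level = 0.95, continuity = FALSE) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  if (!continuity) {
    centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    c(lower = max(0, centre - half), upper = min(1, centre + half))
  } else {
    denom <- 2 * (n + z^2)
    lo <- (2 * n * p + z^2 - 1 -
             z * sqrt(z^2 - 2 - 1 / n + 4 * p * (n * (1 - p) + 1))) / denom
    hi <- (2 * n * p + z^2 + 1 +
             z * sqrt(z^2 + 2 - 1 / n + 4 * p * (n * (1 - p) - 1))) / denom
    c(lower = if (x == 0) 0 else max(0, lo),
      upper = if (x == n) 1 else min(1, hi))
  }
}

# Clopper-Pearson exact interval via beta quantiles.
clopper_pearson_interval <- function(x, n, conf_level = 0.95) {
  alpha <- 1 - conf_level
  c(lower = if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1),
    upper = if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x))
}

#' Concordance with Wilson confidence interval
#'
#' Concordance is the matched fraction `(a + d) / n` over pairs evaluable
#' by both assays.
#'
#' @param ct a `confusion_table`.
#' @param config a [stats_config()].
#' @return list with `estimate`, `lower`, `upper`, `conf_level`.
#' @export
concordance_wilson <- function(ct, config = stats_config()) {
  if (ct$n == 0L) stop_msi("cannot compute concordance on an empty table")
  x <- ct$a + ct$d
  ci <- wilson_interval(x, ct$n, config$conf_level, config$wilson_continuity)
  list(estimate = x / ct$n, lower = unname(ci["lower"]),
       upper = unname(ci["upper"]), conf_level = config$conf_level)
}

#' Sensitivity and specificity with Clopper-Pearson intervals
#'
#' Immunohistochemistry is taken as the reference method: sensitivity is
#' the fraction of MMR-loss tumors called pooled MSI-H, specificity the
#' fraction of MMR-retained tumors called pooled MSS/MSI-L. Intervals are
#' exact (beta-quantile) Clopper-Pearson.
#'
#' @param ct a `confusion_table`.
#' @param config a [stats_config()].
#' @return list with `sensitivity` and `specificity`, each holding
#'   `estimate`, `lower`, `upper`.
#' @export
sens_spec_cp <- function(ct, config = stats_config()) {
  if (ct$a + ct$b == 0L) stop_msi("empty margin: no MMR-loss pairs (a + b = 0)")
  if (ct$c + ct$d == 0L) {
    stop_msi("empty margin: no MMR-retained pairs (c + d = 0)")
  }
  mk <- function(x, n) {
    ci <- clopper_pearson_interval(x, n, config$conf_level)
    list(estimate = x / n, lower = unname(ci["lower"]),
         upper = unname(ci["upper"]), x = x, n = n)
  }
  list(sensitivity = mk(ct$a, ct$a + ct$b),
       specificity = mk(ct$d, ct$c + ct$d))
}

#' Exact McNemar test
#'
#' Two-sided exact binomial test on the discordant pair of a paired 2x2
#' classification: with `n_d = b + c` discordant pairs and
#' `k = min(b, c)`, `p = min(1, 2 * P(X <= k))` for
#' `X ~ Binomial(n_d, 1/2)`; `p = 1` when there are no discordant pairs.
#'
#' @param ct a `confusion_table`, or `b` and `c` given directly.
#' @param b,c discordant counts (alternative to `ct`).
#' @return list with `b`, `c`, `p_value`.
#' @export
#' @examples
#' mcnemar_exact(b = 17, c = 3)$p_value  # 0.00258
mcnemar_exact <- function(ct = NULL, b = NULL, c = NULL) {
  if (!is.null(ct)) {
    b <- ct$b
    c <- ct$c
  }
  stopifnot(b >= 0, c >= 0, b == round(b), c == round(c))
  nd <- b + c
  p <- if (nd == 0) 1 else min(1, 2 * stats::pbinom(min(b, c), nd, 0.5))
  list(b = as.integer(b), c = as.integer(c), p_value = p)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by the probability-mass rule: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return list with `p_value` and the conditional odds-ratio estimate.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(69, 5, 17, 6), 2, byrow = TRUE))$p_value
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop_msi("table must be 2x2")
  if (any(table < 0) || any(table != round(table))) {
    stop_msi("table cells must be non-negative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop_msi("zero margin in 2x2 table")
  }
  ft <- stats::fisher.test(table)
  list(p_value = ft$p.value, odds_ratio = unname(ft$estimate))
}

#' Exact McNemar comparison of two MSI panels
#'
#' Compares paired dichotomous calls from two classifiers (e.g. the 24- and
#' 54-marker sequencing panels) on the same samples.
#'
#' @param calls_a,calls_b character vectors of `"MSS"` / `"MSI-H"` calls on
#'   the same samples, aligned by position (or by names when both are
#'   named).
#' @return list with discordant counts `b` (`a` MSS, `b` MSI-H), `c`
#'   (`a` MSI-H, `b` MSS) and `p_value`.
#' @export
compare_panels_mcnemar <- function(calls_a, calls_b) {
  if (!is.null(names(calls_a)) && !is.null(names(calls_b))) {
    if (!setequal(names(calls_a), names(calls_b))) {
      stop_msi("mismatched sample sets between the two panels")
    }
    calls_b <- calls_b[names(calls_a)]
  } else if (length(calls_a) != length(calls_b)) {
    stop_msi("mismatched sample sets between the two panels")
  }
  stopifnot(all(calls_a %in% c("MSS", "MSI-H")),
            all(calls_b %in% c("MSS", "MSI-H")))
  b <- sum(calls_a == "MSS" & calls_b == "MSI-H")
  c <- sum(calls_a == "MSI-H" & calls_b == "MSS")
  mcnemar_exact(b = b, c = c)
}

#' Full concordance report for one assay
#'
#' @param ct a `confusion_table`.
#' @param assay assay label (e.g. `"promega"`, `"seq24"`, `"seq54"`).
#' @param config a [stats_config()].
#' @return a `concordance_report` with concordance (Wilson CI),
#'   sensitivity/specificity (Clopper-Pearson CIs) and the exact McNemar
#'   test.
#' @export
concordance_report <- function(ct, assay, config = stats_config()) {
  structure(list(
    assay = assay,
    table = ct,
    concordance = concordance_wilson(ct, config),
    sens_spec = sens_spec_cp(ct, config),
    mcnemar = mcnemar_exact(ct),
    conf_level = config$conf_level
  ), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  pct <- function(v) sprintf("%.1f%%", 100 * v)
  cat("Concordance report:", x$assay, "(n =", x$table$n, "evaluable pairs)\n")
  cat(sprintf("  concordance %s (%s CI %s-%s)\n",
              pct(x$concordance$estimate),
              paste0(100 * x$conf_level, "%"),
              pct(x$concordance$lower), pct(x$concordance$upper)))
  ss <- x$sens_spec
  cat(sprintf("  sensitivity %s (CI %s-%s)   specificity %s (CI %s-%s)\n",
              pct(ss$sensitivity$estimate), pct(ss$sensitivity$lower),
              pct(ss$sensitivity$upper), pct(ss$specificity$estimate),
              pct(ss$specificity$lower), pct(ss$specificity$upper)))
  cat(sprintf("  exact McNemar on (b = %d, c = %d): p = %.4g\n",
              x$mcnemar$b, x$mcnemar$c, x$mcnemar$p_value))
  invisible(x)
}
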