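#' End-to-end simulated study
#'
#' Runs the whole comparison on synthetic data: generate a cohort with
#' ground truth, simulate the three assays (sequencing histograms for the
#' 24- and 54-marker panels, Promega-style marker calls, IHC positivity
#' fractions), train the naive-Bayes classifier on a simulated labelled
#' training cohort, score every evaluable tumor, and assemble per-assay
#' confusion tables and concordance reports against IHC.
#'
#' @param config a [sim_config()]; `config$seed` drives every random draw.
#' @param registry a marker registry (default the built-in synthetic one).
#' @param stats_cfg a [stats_config()].
#' @param prof_config a [profiling_config()].
#' @return a list with elements `cohort`, `truth`, `classifiers`
#'   (seq24/seq54), `calls` (per-sample data frame of IHC status, pooled
#'   Promega class and both sequencing calls with scores), `reports`
#'   (named list of `concordance_report`s), `panel_comparison` (exact
#'   McNemar of seq24 vs seq54), `cv` (5-fold cross-validation of the
#'   seq54 classifier on the training cohort) and `bundle` (a
#'   [report_bundle()]).
#' @export
run_simulated_study <- function(config = sim_config(),
                                registry = default_marker_registry(),
                                stats_cfg = stats_config(),
                                prof_config = profiling_config()) {
  panel24 <- get_panel(registry, "seq24", check_size = TRUE)
  panel54 <- get_panel(registry, "seq54", check_size = TRUE)
  panel_pm <- get_panel(registry, "promega5", check_size = TRUE)
  seq_markers <- validate_marker_registry(rbind(as.data.frame(panel24),
                                                as.data.frame(panel54)))

  cohort <- generate_cohort(config)
  samples <- cohort$samples
  truth <- cohort$truth
  n <- nrow(samples)

  # --- training + classifiers ---------------------------------------------
  training <- simulate_training_cohort(seq_markers, config,
                                       prof_config = prof_config)
  clf24 <- fit_msi_classifier(
    training$profiles[training$profiles$marker_id %in% panel24$marker_id, ],
    training$labels, panel24, "seq24")
  clf54 <- fit_msi_classifier(
    training$profiles[training$profiles$marker_id %in% panel54$marker_id, ],
    training$labels, panel54, "seq54")

  # --- per-sample assays ---------------------------------------------------
  seq_ok <- samples$dna_conc > 1.0 & truth$seq_evaluable
  calls <- data.frame(sample_id = samples$sample_id,
                      ihc = NA_character_,
                      promega_raw = NA_character_,
                      promega_pooled = NA_character_,
                      seq24_score = NA_real_, seq24_call = NA_character_,
                      seq54_score = NA_real_, seq54_call = NA_character_,
                      stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    smp <- samples[i, ]
    tr <- truth[i, ]
    sid <- smp$sample_id

    meas <- simulate_ihc(smp, tr, config, seed = child_seed(config$seed, i))
    ihc <- suppressWarnings(classify_sample_ihc(meas, smp$gene))
    calls$ihc[i] <- ihc$sample_status

    if (tr$promega_evaluable) {
      pm_calls <- simulate_promega_calls(smp, tr, config,
                                         panel_ids = panel_pm$marker_id,
                                         seed = child_seed(config$seed,
                                                           10000L + i))
      pm <- classify_promega(pm_calls, panel_ids = panel_pm$marker_id)
      calls$promega_raw[i] <- pm$raw_class
      calls$promega_pooled[i] <- pm$pooled_class
    } else {
      calls$promega_raw[i] <- "NE"
      calls$promega_pooled[i] <- "NE"
    }

    if (seq_ok[i]) {
      hists <- simulate_length_histograms(smp, tr, seq_markers, config,
                                          seed = child_seed(config$seed,
                                                            20000L + i))
      for (pn in c("seq24", "seq54")) {
        panel <- if (pn == "seq24") panel24 else panel54
        clf <- if (pn == "seq24") clf24 else clf54
        prof <- profile_sample(hists[hists$marker_id %in% panel$marker_id, ],
                               panel, prof_config)
        sc <- score_msi_sample(prof, clf, sid)
        calls[[paste0(pn, "_score")]][i] <- if (is.na(sc$score)) NA else sc$score
        calls[[paste0(pn, "_call")]][i] <- sc$call
      }
    } else {
      calls$seq24_call[i] <- "NE"
      calls$seq54_call[i] <- "NE"
    }
  }

  # --- concordance ----------------------------------------------------------
  seq_pooled <- function(call) {
    ifelse(call == "MSI-H", "pooled MSI-H",
           ifelse(call == "MSS", "pooled MSS/MSI-L", "NE"))
  }
  cts <- list(
    promega = build_confusion(calls$ihc, calls$promega_pooled,
                              calls$sample_id),
    seq24 = build_confusion(calls$ihc, seq_pooled(calls$seq24_call),
                            calls$sample_id),
    seq54 = build_confusion(calls$ihc, seq_pooled(calls$seq54_call),
                            calls$sample_id)
  )
  reports <- lapply(names(cts), function(a) {
    concordance_report(cts[[a]], a, stats_cfg)
  })
  names(reports) <- names(cts)

  both <- calls$seq24_call %in% c("MSS", "MSI-H") &
    calls$seq54_call %in% c("MSS", "MSI-H")
  panel_cmp <- compare_panels_mcnemar(calls$seq24_call[both],
                                      calls$seq54_call[both])

  cv <- cross_validate(
    training$profiles[training$profiles$marker_id %in% panel54$marker_id, ],
    training$labels, panel54, k = 5, seed = child_seed(config$seed, 99L))

  bundle <- report_bundle(
    reports,
    cohort_summary = list(
      n_samples = n,
      n_mmr_loss_ihc = sum(calls$ihc == "loss"),
      n_promega_evaluable = sum(calls$promega_pooled != "NE"),
      n_seq_evaluable = sum(calls$seq24_call != "NE")
    ),
    provenance = list(seed = config$seed,
                      panels = c(promega5 = nrow(panel_pm),
                                 seq24 = nrow(panel24),
                                 seq54 = nrow(panel54)),
                      package = as.character(utils::packageVersion("msiconcord")))
  )
  list(cohort = samples, truth = truth,
       classifiers = list(seq24 = clf24, seq54 = clf54),
       calls = calls, reports = reports, panel_comparison = panel_cmp,
       cv = cv, bundle = bundle)
}
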