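#' Synthetic cohort generation
#'
#' The generator emulates the FFPE tumor material of a Lynch-syndrome
#' urothelial-cancer cohort at the level the downstream assays see it:
#' clinical covariates with fixed marginal counts, a latent MMR ground
#' truth, per-marker read-length histograms with PCR/FFPE stutter and
#' somatic deletion alleles (gene-specific effect sizes, attenuated for
#' MSH6), Promega-style per-marker instability calls, IHC tumor-cell
#' positivity fractions, DNA-concentration QC and block-age-dependent
#' technical dropout, plus a labelled colorectal-style training cohort for
#' the sequencing classifier.
#'
#' @name synthetic_cohort
NULL

#' Simulation configuration
#'
#' Defaults encode the study conditions the analysis assumes: 97 tumors
#' with gene counts MLH1 9 / MSH2 64 / MSH6 23 / PMS2 1, 74 carriers and
#' 23 first-degree relatives, locations 27/34/36
#' (ureter/renal pelvis/bladder), a target depth of 2000 reads per
#' amplicon, and a training cohort of 50 MSI-H and 52 MSS samples.
#' Noise-level knobs (stutter rate, purity, instability probabilities)
#' are simulation parameters, not estimates from data.
#'
#' @param n_samples cohort size.
#' @param gene_counts,carrier_counts,location_counts named integer vectors
#'   of exact marginal counts; each must sum to `n_samples`.
#' @param fdr_noncarrier_prob probability that an FDR tumor is truly
#'   MMR-proficient (the FDR group may include non-carriers).
#' @param sporadic_bladder_prob probability that a carrier's bladder tumor
#'   is sporadic (MMR-proficient).
#' @param depth reads per amplicon.
#' @param stutter_rate geometric per-read slippage parameter (lambda); a
#'   read loses `k` repeat units with probability proportional to
#'   `lambda^k`, and gains one unit at rate `lambda / 10` (deletion-
#'   dominated stutter).
#' @param purity tumor-cell fraction.
#' @param somatic_del_mean mean somatic deletion size in bases (MSH6-
#'   deficient tumors use `somatic_del_mean_msh6`).
#' @param somatic_del_mean_msh6 attenuated deletion size for MSH6.
#' @param somatic_del_sd spread of the (rounded, positive) normal deletion
#'   size.
#' @param clonal_shape1,clonal_shape2 Beta parameters of the per-sample
#'   clonal fraction of the somatic deletion allele in deficient tumors.
#' @param instability_attenuation named per-gene multiplier on instability
#'   effect sizes; MSH6 < 1 encodes its systematically weaker signal.
#' @param seq54_marker_boost multiplier on the somatic allele fraction at
#'   markers tagged `seq54`, encoding the higher individual sensitivity of
#'   the CMMRD-blood-derived markers relative to the colorectal-derived
#'   24-marker panel (default 1.3).
#' @param missense_prob,unknown_variant_prob cohort fractions of missense
#'   and unreported variant classes (the rest truncating).
#' @param missense_retention_prob probability a deficient missense sample
#'   retains protein expression on IHC.
#' @param promega_instability_prob per-marker probability that a deficient
#'   sample's marker is called unstable (before gene attenuation).
#' @param promega_fp_prob per-marker false-positive instability rate in
#'   proficient samples.
#' @param suggestive_prob per-marker probability of a "trace suggestive of
#'   instability" call (renders the sample non-evaluable without germline
#'   DNA).
#' @param ihc_loss_shape,ihc_retained_shape Beta parameters of tumor-cell
#'   positivity for lost and retained proteins.
#' @param control_absent_prob probability the internal positive control is
#'   missing (IHC non-evaluable mechanism).
#' @param dropout_intercept,dropout_slope logistic model of technical
#'   non-evaluability versus FFPE block age (years):
#'   `P(dropout) = plogis(intercept + slope * block_age)`.
#' @param training_n_msih,training_n_mss training cohort sizes.
#' @param seed master seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_samples = 97,
                       gene_counts = c(MLH1 = 9, MSH2 = 64, MSH6 = 23, PMS2 = 1),
                       carrier_counts = c(carrier = 74, FDR = 23),
                       location_counts = c(ureter = 27, renal_pelvis = 34,
                                           bladder = 36),
                       fdr_noncarrier_prob = 0.25,
                       sporadic_bladder_prob = 0.1,
                       depth = 2000,
                       stutter_rate = 0.05,
                       purity = 0.6,
                       somatic_del_mean = 4,
                       somatic_del_mean_msh6 = 2,
                       somatic_del_sd = 1.5,
                       clonal_shape1 = 5, clonal_shape2 = 5,
                       instability_attenuation = c(MLH1 = 1, MSH2 = 1,
                                                   MSH6 = 0.5, PMS2 = 1),
                       seq54_marker_boost = 1.3,
                       missense_prob = 0.1,
                       unknown_variant_prob = 0.05,
                       missense_retention_prob = 0.5,
                       promega_instability_prob = 0.55,
                       promega_fp_prob = 0.02,
                       suggestive_prob = 0.05,
                       ihc_loss_shape = c(1, 30),
                       ihc_retained_shape = c(12, 3),
                       control_absent_prob = 0.02,
                       dropout_intercept = -3.5,
                       dropout_slope = 0.08,
                       training_n_msih = 50,
                       training_n_mss = 52,
                       seed = 1) {
  cfg <- as.list(environment())
  for (nm in c("gene_counts", "carrier_counts", "location_counts")) {
    if (sum(cfg[[nm]]) != n_samples) {
      stop_msi(sprintf("%s sums to %d, expected n_samples = %d",
                       nm, sum(cfg[[nm]]), n_samples))
    }
  }
  for (nm in c("fdr_noncarrier_prob", "sporadic_bladder_prob", "purity",
               "stutter_rate", "missense_prob", "unknown_variant_prob",
               "missense_retention_prob", "promega_instability_prob",
               "promega_fp_prob", "suggestive_prob", "control_absent_prob")) {
    assert_prob(cfg[[nm]], nm)
  }
  assert_count(depth, "depth")
  if (missense_prob + unknown_variant_prob > 1) {
    stop_msi("missense_prob + unknown_variant_prob must not exceed 1")
  }
  structure(cfg, class = "sim_config")
}

# Gene-specific knobs -------------------------------------------------------

attenuation_for <- function(gene, config) {
  if (is.na(gene) || !gene %in% names(config$instability_attenuation)) 1
  else unname(config$instability_attenuation[[gene]])
}

del_mean_for <- function(gene, config) {
  if (!is.na(gene) && identical(gene, "MSH6")) config$somatic_del_mean_msh6
  else config$somatic_del_mean
}

#' Generate a synthetic cohort with ground truth
#'
#' Marginal counts of gene, carrier status and location match the
#' configuration exactly (the cross-classification is random). Ground
#' truth MMR status is deficient for carriers except sporadic bladder
#' tumors, and for FDRs except a `fdr_noncarrier_prob` fraction of true
#' non-carriers. Deficient samples receive a per-sample clonal fraction of
#' the somatic deletion allele (Beta-distributed, gene-attenuated, shared
#' across markers); proficient samples have clonal fraction exactly 0 at
#' every marker. Latent per-assay technical evaluability flags are drawn
#' from the block-age logistic dropout model.
#'
#' @param config a [sim_config()].
#' @param seed overrides `config$seed` when given.
#' @return list with `samples` (a `cohort_table` including `truth_mmr`)
#'   and `truth` (per-sample latent variables).
#' @export
generate_cohort <- function(config = sim_config(), seed = NULL) {
  n <- config$n_samples
  with_seed(seed %||% config$seed, {
    samples <- data.frame(
      sample_id = sprintf("S%03d", seq_len(n)),
      carrier_status = sample(rep(names(config$carrier_counts),
                                  config$carrier_counts)),
      gene = sample(rep(names(config$gene_counts), config$gene_counts)),
      variant_class = sample(VARIANT_LEVELS, n, replace = TRUE,
                             prob = c(1 - config$missense_prob -
                                        config$unknown_variant_prob,
                                      config$missense_prob,
                                      config$unknown_variant_prob)),
      location = sample(rep(names(config$location_counts),
                            config$location_counts)),
      age_at_diagnosis = round(pmin(pmax(stats::rnorm(n, 63.9, 11), 31), 89)),
      block_age = round(pmin(5 + stats::rgamma(n, shape = 2, scale = 10), 42)),
      dna_conc = round(stats::rlnorm(n, log(10), 1.2), 2),
      stringsAsFactors = FALSE
    )
    sporadic <- samples$carrier_status == "carrier" &
      samples$location == "bladder" &
      stats::runif(n) < config$sporadic_bladder_prob
    noncarrier <- samples$carrier_status == "FDR" &
      stats::runif(n) < config$fdr_noncarrier_prob
    samples$truth_mmr <- ifelse(sporadic | noncarrier,
                                "proficient", "deficient")
    deficient <- samples$truth_mmr == "deficient"
    att <- vapply(samples$gene, attenuation_for, numeric(1), config = config)
    clonal <- numeric(n)
    clonal[deficient] <- stats::rbeta(sum(deficient), config$clonal_shape1,
                                      config$clonal_shape2) * att[deficient]
    p_drop <- stats::plogis(config$dropout_intercept +
                              config$dropout_slope * samples$block_age)
    truth <- data.frame(
      sample_id = samples$sample_id,
      truth_mmr = samples$truth_mmr,
      clonal_fraction = clonal,
      promega_evaluable = stats::runif(n) >= p_drop,
      seq_evaluable = stats::runif(n) >= p_drop,
      stringsAsFactors = FALSE
    )
    list(samples = validate_cohort(samples), truth = truth)
  })
}

# Stutter shift for `n` reads: -k slippage (geometric) or a rare +1
# insertion at one-tenth the rate.
stutter_shift <- function(n, lambda) {
  if (lambda == 0 || n == 0L) return(integer(n))
  ins <- stats::runif(n) < lambda / 10
  k <- stats::rgeom(n, 1 - lambda)
  ifelse(ins, 1L, -k)
}

#' Simulate per-marker read-length histograms for one sample
#'
#' Each of `depth` reads derives from the germline allele (reference
#' repeat length) or, with probability `purity * clonal_fraction`, from
#' the somatic deleted allele (reference minus a rounded positive normal
#' deletion of gene-specific mean size); stutter then shortens the read by
#' a geometric number of bases (rare one-base insertions at a tenth of the
#' rate), truncated at length zero.
#'
#' @param sample one row of a cohort table (or a list with `gene`).
#' @param truth_row the sample's row of the truth table (needs
#'   `clonal_fraction`).
#' @param markers marker registry rows to simulate.
#' @param config a [sim_config()].
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @return data frame with columns `marker_id`, `repeat_len`,
#'   `read_count`; the counts for every marker sum to `depth`.
#' @export
simulate_length_histograms <- function(sample, truth_row, markers,
                                       config = sim_config(), seed = NULL) {
  if (is.null(truth_row) || is.null(truth_row$clonal_fraction)) {
    stop_msi("sample has no truth entry")
  }
  if (nrow(markers) == 0L) stop_msi("empty marker panel")
  base_af <- config$purity * truth_row$clonal_fraction
  # CMMRD-derived seq54 markers are individually more sensitive
  boost <- rep(1, nrow(markers))
  if (!is.null(markers$panel_tags)) {
    is54 <- vapply(strsplit(markers$panel_tags, ",", fixed = TRUE),
                   function(t) "seq54" %in% t, logical(1))
    boost[is54] <- config$seq54_marker_boost %||% 1
  }
  p_som_m <- pmin(1, base_af * boost)
  dmean <- del_mean_for(sample$gene %||% NA_character_, config)
  depth <- config$depth
  with_seed(seed, {
    out <- lapply(seq_len(nrow(markers)), function(i) {
      ref <- markers$ref_len[i]
      p_som <- p_som_m[i]
      allele <- rep.int(ref, depth)
      if (p_som > 0) {
        is_som <- stats::runif(depth) < p_som
        n_som <- sum(is_som)
        if (n_som > 0) {
          delta <- pmax(1, round(stats::rnorm(n_som, dmean,
                                              config$somatic_del_sd)))
          allele[is_som] <- pmax(0L, ref - as.integer(delta))
        }
      }
      obs <- pmax(0L, allele + stutter_shift(depth, config$stutter_rate))
      tab <- tabulate(obs + 1L)
      lens <- which(tab > 0L) - 1L
      data.frame(marker_id = markers$marker_id[i], repeat_len = lens,
                 read_count = tab[tab > 0L], stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Simulate Promega-style per-marker instability calls
#'
#' Deficient samples draw `unstable` per marker with probability
#' `promega_instability_prob` times the gene's attenuation factor;
#' proficient samples with the false-positive rate. Markers not unstable
#' become `suggestive` with `suggestive_prob` (modelling traces suggestive
#' of instability that cannot be confirmed without germline DNA), else
#' `stable`.
#'
#' @inheritParams simulate_length_histograms
#' @param panel_ids promega5 marker ids.
#' @return data frame with columns `marker_id`, `status`.
#' @export
simulate_promega_calls <- function(sample, truth_row, config = sim_config(),
                                   panel_ids = NULL, seed = NULL) {
  if (is.null(panel_ids)) {
    panel_ids <- get_panel(default_marker_registry(), "promega5")$marker_id
  }
  p_unstable <- if (identical(truth_row$truth_mmr, "deficient")) {
    config$promega_instability_prob *
      attenuation_for(sample$gene %||% NA_character_, config)
  } else {
    config$promega_fp_prob
  }
  with_seed(seed, {
    n <- length(panel_ids)
    unstable <- stats::runif(n) < p_unstable
    suggestive <- !unstable & stats::runif(n) < config$suggestive_prob
    data.frame(marker_id = panel_ids,
               status = ifelse(unstable, "unstable",
                               ifelse(suggestive, "suggestive", "stable")),
               stringsAsFactors = FALSE)
  })
}

#' Simulate four-protein IHC positivity fractions
#'
#' Deficient samples lose the proteins of the affected gene's heterodimer
#' pattern (positivity drawn from a Beta concentrated below the 10%
#' cutoff) and retain the others (Beta concentrated well above it);
#' deficient missense samples retain all proteins with probability
#' `missense_retention_prob`. The internal positive control is absent with
#' a small probability, making the measurement non-evaluable.
#'
#' @inheritParams simulate_length_histograms
#' @return list with elements `MLH1`, `MSH2`, `MSH6`, `PMS2` (positivity
#'   fractions) and `internal_control_present`.
#' @export
simulate_ihc <- function(sample, truth_row, config = sim_config(),
                         seed = NULL) {
  gene <- sample$gene %||% NA_character_
  if (is.na(gene) || !gene %in% MMR_GENES) stop_msi("unknown gene: ", gene)
  with_seed(seed, {
    control <- stats::runif(1) >= config$control_absent_prob
    lost <- character(0)
    if (identical(truth_row$truth_mmr, "deficient")) {
      retained_anyway <- identical(sample$variant_class, "missense") &&
        stats::runif(1) < config$missense_retention_prob
      if (!retained_anyway) lost <- IHC_PATTERN[[gene]]
    }
    pis <- lapply(MMR_GENES, function(p) {
      if (p %in% lost) {
        stats::rbeta(1, config$ihc_loss_shape[1], config$ihc_loss_shape[2])
      } else {
        stats::rbeta(1, config$ihc_retained_shape[1],
                     config$ihc_retained_shape[2])
      }
    })
    names(pis) <- MMR_GENES
    c(pis, list(internal_control_present = control))
  })
}

#' Apply DNA-concentration QC and technical dropout
#'
#' A sample is kept only if its double-stranded DNA concentration is
#' strictly above 1 ng/uL; samples at exactly 1 are excluded. When
#' `evaluable` flags are supplied (the truth table's latent block-age
#' dropout draws), technically non-evaluable samples are excluded as well.
#'
#' @param samples a cohort table.
#' @param config a [sim_config()] (used for the logistic dropout model
#'   when `evaluable` is `NULL` and `draw_dropout = TRUE`).
#' @param evaluable optional logical vector aligned with `samples`.
#' @param draw_dropout draw dropout from the block-age logistic when no
#'   flags are given.
#' @param seed optional seed for the dropout draw.
#' @return list with `kept` and `excluded` cohort tables.
#' @export
apply_dna_qc <- function(samples, config = sim_config(), evaluable = NULL,
                         draw_dropout = FALSE, seed = NULL) {
  if (any(samples$dna_conc < 0)) stop_msi("dna_conc must be >= 0")
  keep <- samples$dna_conc > 1.0
  if (is.null(evaluable) && draw_dropout) {
    evaluable <- with_seed(seed, {
      p <- stats::plogis(config$dropout_intercept +
                           config$dropout_slope * samples$block_age)
      stats::runif(nrow(samples)) >= p
    })
  }
  if (!is.null(evaluable)) keep <- keep & evaluable
  list(kept = samples[keep, , drop = FALSE],
       excluded = samples[!keep, , drop = FALSE])
}

#' Simulate the labelled training cohort
#'
#' Emulates a colorectal reference cohort of `training_n_msih` MSI-H and
#' `training_n_mss` MSS samples profiled over the given markers: MSI-H
#' samples carry a Beta-distributed clonal somatic deletion fraction with
#' the default (unattenuated) effect size; MSS samples have none. Returns
#' long-format profiles ready for [fit_msi_classifier()].
#'
#' @param markers marker registry rows (typically the union of the seq24
#'   and seq54 panels).
#' @param config a [sim_config()].
#' @param seed optional seed (default derives from `config$seed`).
#' @param prof_config a [profiling_config()].
#' @return list with `profiles` (long data frame) and `labels` (named
#'   vector).
#' @export
simulate_training_cohort <- function(markers, config = sim_config(),
                                     seed = NULL,
                                     prof_config = profiling_config()) {
  seed <- seed %||% child_seed(config$seed, 777L)
  n_h <- config$training_n_msih
  n_s <- config$training_n_mss
  with_seed(seed, {
    ids <- c(sprintf("TR-MSIH-%02d", seq_len(n_h)),
             sprintf("TR-MSS-%02d", seq_len(n_s)))
    labels <- setNames(rep(c("MSI-H", "MSS"), c(n_h, n_s)), ids)
    clonal <- c(stats::rbeta(n_h, config$clonal_shape1, config$clonal_shape2),
                rep(0, n_s))
    profiles <- vector("list", length(ids))
    for (i in seq_along(ids)) {
      hists <- simulate_length_histograms(
        sample = list(gene = NA_character_),
        truth_row = list(clonal_fraction = clonal[i]),
        markers = markers, config = config, seed = NULL)
      prof <- profile_sample(hists, markers, prof_config)
      prof$sample_id <- ids[i]
      profiles[[i]] <- prof
    }
    list(profiles = do.call(rbind, profiles), labels = labels)
  })
}

#' Write simulated reads as FASTQ
#'
#' Reads are assembled as `left_flank + repeat + right_flank` with uniform
#' quality, reproducing each histogram count exactly.
#'
#' @param histograms data frame `marker_id`, `repeat_len`, `read_count`.
#' @param markers registry rows covering the histogram markers.
#' @param path output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_sim_fastq <- function(histograms, markers, path) {
  idx <- match(histograms$marker_id, markers$marker_id)
  if (anyNA(idx)) stop_msi("histogram markers missing from registry")
  seqs <- character(0)
  names_out <- character(0)
  for (i in seq_len(nrow(histograms))) {
    mk <- markers[idx[i], ]
    n <- histograms$read_count[i]
    if (n == 0) next
    s <- paste0(mk$left_flank,
                strrep(mk$repeat_base, histograms$repeat_len[i]),
                mk$right_flank)
    seqs <- c(seqs, rep.int(s, n))
    names_out <- c(names_out,
                   sprintf("%s_len%d_%d", mk$marker_id,
                           histograms$repeat_len[i], seq_len(n)))
  }
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- names_out
  qual <- Biostrings::PhredQuality(strrep("I", nchar(seqs)))
  qdna <- Biostrings::QualityScaledDNAStringSet(dna, qual)
  Biostrings::writeQualityScaledXStringSet(qdna, path)
  invisible(path)
}
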