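test_that("generated cohorts hit configured marginals exactly and are deterministic", {
  cfg <- sim_config(seed = 11)
  out <- generate_cohort(cfg)
  smp <- out$samples
  expect_equal(nrow(smp), 97L)
  expect_equal(as.vector(table(smp$gene)[names(cfg$gene_counts)]),
               unname(cfg$gene_counts))
  expect_equal(as.vector(table(smp$carrier_status)[names(cfg$carrier_counts)]),
               unname(cfg$carrier_counts))
  expect_equal(as.vector(table(smp$location)[names(cfg$location_counts)]),
               unname(cfg$location_counts))
  expect_identical(generate_cohort(cfg), out)

  # proficient samples carry no somatic deletion allele
  expect_true(all(out$truth$clonal_fraction[out$truth$truth_mmr ==
                                              "proficient"] == 0))
  expect_true(all(out$truth$clonal_fraction[out$truth$truth_mmr ==
                                              "deficient"] > 0))
})

test_that("fdr_noncarrier_prob = 0 makes every FDR tumor deficient", {
  out <- generate_cohort(sim_config(fdr_noncarrier_prob = 0, seed = 7))
  fdr <- out$samples$carrier_status == "FDR"
  expect_true(all(out$samples$truth_mmr[fdr] == "deficient"))
})

test_that("config validation catches inconsistent counts and probabilities", {
  expect_error(sim_config(n_samples = 96), "sums to 97")
  expect_error(sim_config(fdr_noncarrier_prob = 1.2), "probability")
  expect_error(sim_config(depth = 0), "positive integer")
})

test_that("histograms conserve depth and are noiseless when stutter is off", {
  reg <- tiny_registry()
  markers <- get_panel(reg, "promega5")
  cfg <- fast_config(stutter_rate = 0)
  smp <- list(gene = "MSH2")

  # proficient, no stutter: every read exactly at the reference length
  h0 <- simulate_length_histograms(smp, list(clonal_fraction = 0), markers,
                                   cfg, seed = 5)
  expect_equal(unique(h0$repeat_len - markers$ref_len[match(h0$marker_id,
                                                            markers$marker_id)]),
               0L)
  totals <- tapply(h0$read_count, h0$marker_id, sum)
  expect_true(all(totals == cfg$depth))

  # with stutter the totals are still conserved
  cfg2 <- fast_config()
  h1 <- simulate_length_histograms(smp, list(clonal_fraction = 0.5), markers,
                                   cfg2, seed = 5)
  expect_true(all(tapply(h1$read_count, h1$marker_id, sum) == cfg2$depth))

  expect_error(simulate_length_histograms(smp, list(clonal_fraction = 0),
                                          markers[0, ], cfg),
               "empty marker panel")
  expect_error(simulate_length_histograms(smp, NULL, markers, cfg),
               "no truth entry")
})

test_that("deletion frequency matches its closed-form expectation", {
  # purity 0.6 x clonal fraction 0.5, no stutter -> E[d] = 0.30 exactly
  reg <- tiny_registry()
  markers <- get_panel(reg, "promega5")[1, ]
  cfg <- sim_config(purity = 0.6, stutter_rate = 0, depth = 2000, seed = 1)
  n_rep <- 30
  d_hat <- vapply(seq_len(n_rep), function(i) {
    h <- simulate_length_histograms(list(gene = "MSH2"),
                                    list(clonal_fraction = 0.5),
                                    markers, cfg, seed = 100 + i)
    sum(h$read_count[h$repeat_len < markers$ref_len]) / sum(h$read_count)
  }, numeric(1))
  p <- 0.30
  se <- sqrt(p * (1 - p) / (cfg$depth * n_rep))
  expect_lt(abs(mean(d_hat) - p), 3 * se)
})

test_that("simulated marker instability counts follow the binomial expectation", {
  cfg <- sim_config(promega_instability_prob = 0.9, suggestive_prob = 0,
                    seed = 1)
  smp <- list(gene = "MSH2")
  tr <- list(truth_mmr = "deficient")
  n_draws <- 1000
  counts <- vapply(seq_len(n_draws), function(i) {
    calls <- simulate_promega_calls(smp, tr, cfg, seed = i)
    sum(calls$status == "unstable")
  }, numeric(1))
  # Binomial(5, 0.9): mean 4.5
  se <- sqrt(5 * 0.9 * 0.1 / n_draws)
  expect_lt(abs(mean(counts) - 4.5), 3 * se)
  expect_false(any(vapply(seq_len(50), function(i) {
    any(simulate_promega_calls(smp, tr, cfg, seed = i)$status == "suggestive")
  }, logical(1))))

  # proficient with zero false-positive rate: all stable
  cfg0 <- sim_config(promega_fp_prob = 0, suggestive_prob = 0, seed = 1)
  calls <- simulate_promega_calls(smp, list(truth_mmr = "proficient"), cfg0,
                                  seed = 3)
  expect_true(all(calls$status == "stable"))
})

test_that("IHC simulation respects heterodimer patterns and retention flags", {
  cfg <- sim_config(control_absent_prob = 0, seed = 1)
  smp <- list(gene = "MSH2", variant_class = "truncating")
  tr <- list(truth_mmr = "deficient")
  draws <- t(vapply(seq_len(1000), function(i) {
    m <- simulate_ihc(smp, tr, cfg, seed = i)
    c(m$MSH2, m$MSH6, m$MLH1, m$PMS2)
  }, numeric(4)))
  # lost proteins concentrate below the 10% cutoff, retained well above
  expect_gt(mean(draws[, 1] <= 0.10), 0.9)
  expect_gt(mean(draws[, 2] <= 0.10), 0.9)
  expect_gt(mean(draws[, 3] > 0.10), 0.95)
  expect_gt(mean(draws[, 4] > 0.10), 0.95)

  prof <- t(vapply(seq_len(500), function(i) {
    m <- simulate_ihc(smp, list(truth_mmr = "proficient"), cfg, seed = i)
    unlist(m[msiconcord:::MMR_GENES])
  }, numeric(4)))
  expect_gt(mean(apply(prof > 0.10, 1, all)), 0.9)

  # missense retention: deficiency hidden from IHC
  cfgm <- sim_config(missense_retention_prob = 1, control_absent_prob = 0,
                     seed = 1)
  m <- simulate_ihc(list(gene = "MSH6", variant_class = "missense"),
                    list(truth_mmr = "deficient"), cfgm, seed = 9)
  expect_true(all(unlist(m[msiconcord:::MMR_GENES]) > 0.10))
})

test_that("DNA QC keeps only concentrations strictly above 1 ng/uL", {
  smp <- generate_cohort(sim_config(seed = 2))$samples[1:4, ]
  smp$dna_conc <- c(0.5, 1.0, 1.01, 8)
  qc <- apply_dna_qc(smp)
  expect_equal(qc$kept$sample_id, smp$sample_id[3:4])
  expect_equal(qc$excluded$sample_id, smp$sample_id[1:2])
  smp$dna_conc[1] <- -1
  expect_error(apply_dna_qc(smp), "dna_conc")
})

test_that("technical dropout is monotone non-decreasing in block age", {
  cfg <- sim_config(seed = 1)
  ages <- seq(0, 45, by = 5)
  p <- plogis(cfg$dropout_intercept + cfg$dropout_slope * ages)
  expect_true(all(diff(p) >= 0))
  # empirical: older blocks drop out more often
  smp <- generate_cohort(cfg)$samples
  smp$block_age <- rep(c(5, 40), length.out = nrow(smp))
  drop_rate <- vapply(c(5, 40), function(a) {
    sub <- smp[smp$block_age == a, ]
    kept <- vapply(1:40, function(s) {
      nrow(apply_dna_qc(sub, cfg, draw_dropout = TRUE, seed = s)$kept)
    }, numeric(1))
    1 - mean(kept) / nrow(sub)
  }, numeric(1))
  expect_lt(drop_rate[1], drop_rate[2])
})

test_that("deficient samples show higher deletion frequencies than proficient at every marker", {
  reg <- tiny_registry()
  markers <- get_panel(reg, "seq24")[1:6, ]
  cfg <- fast_config()
  d_of <- function(clonal, seed) {
    h <- simulate_length_histograms(list(gene = "MSH6"),
                                    list(clonal_fraction = clonal),
                                    markers, cfg, seed = seed)
    prof <- profile_sample(h, markers, profiling_config(min_depth = 100))
    setNames(prof$d, prof$marker_id)
  }
  d_def <- rowMeans(vapply(1:10, function(s) d_of(0.5 * 0.5, s), numeric(6)))
  d_pro <- rowMeans(vapply(1:10, function(s) d_of(0, 100 + s), numeric(6)))
  expect_true(all(d_def > d_pro))
})
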