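# A hand-specified two-marker classifier used by the exact-score tests.
toy_classifier <- function(eps = 1, min_frac = 0) {
  structure(list(
    panel = "toy",
    markers = data.frame(
      marker_id = c("M1", "M2"),
      d_alpha_msih = c(2, 3), d_beta_msih = c(5, 6),
      d_alpha_mss = c(1.5, 2), d_beta_mss = c(30, 40),
      b_alpha_msih = c(2, 2), b_beta_msih = c(2, 3),
      b_alpha_mss = c(8, 9), b_beta_mss = c(2, 2),
      stringsAsFactors = FALSE
    ),
    epsilon = eps, min_marker_fraction = min_frac,
    training = list(n_msih = 2, n_mss = 2)
  ), class = "msi_classifier")
}

test_that("the score equals the hand-summed per-marker log-likelihood ratios", {
  clf <- toy_classifier()
  prof <- data.frame(marker_id = c("M1", "M2"),
                     depth = c(1000, 800),
                     d = c(0.2, 0.05), b = c(0.6, 0.9),
                     evaluable = TRUE)
  res <- score_msi_sample(prof, clf, "X")
  # independent recomposition with explicit Beta densities
  expected <- 0
  for (i in 1:2) {
    D <- prof$depth[i]
    d_shr <- (prof$d[i] * D + 1) / (D + 2)
    n_del <- round(prof$d[i] * D)
    b_shr <- (prof$b[i] * n_del + 1) / (n_del + 2)
    m <- clf$markers[i, ]
    expected <- expected +
      dbeta(d_shr, m$d_alpha_msih, m$d_beta_msih, log = TRUE) -
      dbeta(d_shr, m$d_alpha_mss, m$d_beta_mss, log = TRUE) +
      dbeta(b_shr, m$b_alpha_msih, m$b_beta_msih, log = TRUE) -
      dbeta(b_shr, m$b_alpha_mss, m$b_beta_mss, log = TRUE)
  }
  expect_equal(res$score, expected, tolerance = 1e-9)
  expect_equal(res$n_markers_used, 2L)
})

test_that("identical class-conditionals give score 0 and the tie goes to MSS", {
  clf <- toy_classifier()
  clf$markers$d_alpha_mss <- clf$markers$d_alpha_msih
  clf$markers$d_beta_mss <- clf$markers$d_beta_msih
  clf$markers$b_alpha_mss <- clf$markers$b_alpha_msih
  clf$markers$b_beta_mss <- clf$markers$b_beta_msih
  prof <- data.frame(marker_id = c("M1", "M2"), depth = 1000,
                     d = c(0.1, 0.3), b = c(0.5, 0.4), evaluable = TRUE)
  res <- score_msi_sample(prof, clf)
  expect_equal(res$score, 0)
  expect_equal(res$call, "MSS")
})

test_that("score is additive over markers", {
  clf <- toy_classifier(min_frac = 0)
  prof <- data.frame(marker_id = c("M1", "M2"), depth = 1000,
                     d = c(0.25, 0.02), b = c(0.7, 0.95), evaluable = TRUE)
  s_both <- score_msi_sample(prof, clf)$score
  s1 <- score_msi_sample(prof[1, ], clf)$score
  s2 <- score_msi_sample(prof[2, ], clf)$score
  expect_equal(s_both, s1 + s2, tolerance = 1e-12)
})

test_that("too few evaluable markers yields a non-evaluable call", {
  clf <- toy_classifier(min_frac = 0.5)
  prof <- data.frame(marker_id = c("M1", "M2"), depth = c(100, 100),
                     d = c(0.2, 0.2), b = c(0.5, 0.5), evaluable = FALSE)
  res <- score_msi_sample(prof, clf)
  expect_equal(res$call, "NE")
  expect_true(is.na(res$score))
  expect_error(score_msi_sample(transform(prof, marker_id = c("M1", "ZZ")),
                                clf), "unknown")
})

test_that("fitting on separated synthetic training orders the class means", {
  reg <- tiny_registry()
  panel <- get_panel(reg, "seq24")[1:8, ]
  tr <- small_training(panel, fast_config(), n_msih = 25, n_mss = 25)
  clf <- fit_msi_classifier(tr$profiles, tr$labels, panel, "sub8")
  mean_h <- clf$markers$d_alpha_msih /
    (clf$markers$d_alpha_msih + clf$markers$d_beta_msih)
  mean_s <- clf$markers$d_alpha_mss /
    (clf$markers$d_alpha_mss + clf$markers$d_beta_mss)
  expect_true(all(mean_h > mean_s))

  # monotone likelihood ratio in d holds on the fitted parameters
  expect_true(all(clf$markers$d_alpha_msih >= clf$markers$d_alpha_mss))
  expect_true(all(clf$markers$d_beta_msih <= clf$markers$d_beta_mss))

  # and therefore increasing d never decreases the score
  grid <- seq(0.01, 0.6, by = 0.01)
  scores <- vapply(grid, function(d) {
    prof <- data.frame(marker_id = panel$marker_id[1], depth = 1000,
                       d = d, b = 0.5, evaluable = TRUE)
    clf0 <- clf
    clf0$min_marker_fraction <- 0
    score_msi_sample(prof[, ], clf0)$score
  }, numeric(1))
  expect_true(all(diff(scores) > -1e-9))
})

test_that("degenerate training inputs are rejected or regularized", {
  reg <- tiny_registry()
  panel <- get_panel(reg, "seq24")[1:3, ]
  tr <- small_training(panel, fast_config(), n_msih = 6, n_mss = 6)
  one_class <- tr$labels[tr$labels == "MSS"]
  expect_error(fit_msi_classifier(tr$profiles, one_class, panel),
               "both MSI-H and MSS")

  # all-zero MSS deletion frequencies still give finite proper Betas
  prof0 <- tr$profiles
  prof0$d[prof0$sample_id %in% names(tr$labels)[tr$labels == "MSS"]] <- 0
  clf <- fit_msi_classifier(prof0, tr$labels, panel)
  expect_true(all(is.finite(unlist(clf$markers[, -1]))))
  expect_true(all(clf$markers$d_alpha_mss > 0 & clf$markers$d_beta_mss > 0))

  # a marker with no training coverage is named in the error
  prof1 <- tr$profiles[tr$profiles$marker_id != panel$marker_id[2], ]
  expect_error(fit_msi_classifier(prof1, tr$labels, panel),
               panel$marker_id[2], fixed = TRUE)
})

test_that("classifier serialization round-trips through JSON", {
  reg <- tiny_registry()
  panel <- get_panel(reg, "seq24")[1:4, ]
  tr <- small_training(panel, fast_config(), n_msih = 8, n_mss = 8)
  clf <- fit_msi_classifier(tr$profiles, tr$labels, panel, "sub4")
  path <- withr::local_tempfile(fileext = ".json")
  write_msi_classifier(clf, path)
  back <- read_msi_classifier(path)
  expect_equal(back$markers, clf$markers, tolerance = 1e-12)
  expect_equal(back$epsilon, clf$epsilon)
  expect_equal(back$panel, clf$panel)
})

test_that("cross-validation recovers separated classes and degrades to chance under label shuffling", {
  reg <- tiny_registry()
  panel <- get_panel(reg, "seq24")[1:10, ]
  tr <- small_training(panel, fast_config(), n_msih = 20, n_mss = 20)
  cv <- cross_validate(tr$profiles, tr$labels, panel, k = 5, seed = 3)
  expect_gte(cv$accuracy, 0.95)
  # determinism
  cv2 <- cross_validate(tr$profiles, tr$labels, panel, k = 5, seed = 3)
  expect_identical(cv, cv2)

  shuffled <- tr$labels
  names(shuffled) <- withr::with_seed(5, sample(names(shuffled)))
  cv0 <- cross_validate(tr$profiles, shuffled, panel, k = 5, seed = 3)
  n <- length(shuffled)
  expect_lt(abs(cv0$accuracy - 0.5), 3 * sqrt(0.25 / n) + 0.05)

  expect_error(cross_validate(tr$profiles, tr$labels, panel, k = 1), "at least 2")
  expect_error(cross_validate(tr$profiles, tr$labels, panel, k = 25),
               "exceeds")
})

test_that("MSH6 attenuation lowers scores relative to MSH2 deficiency", {
  reg <- tiny_registry()
  panel <- get_panel(reg, "seq24")
  cfg <- fast_config(seed = 8)
  tr <- small_training(panel, cfg, n_msih = 25, n_mss = 25)
  clf <- fit_msi_classifier(tr$profiles, tr$labels, panel, "seq24")
  score_gene <- function(gene, seed) {
    att <- msiconcord:::attenuation_for(gene, cfg)
    clonal <- 0.5 * att
    h <- simulate_length_histograms(list(gene = gene),
                                    list(clonal_fraction = clonal),
                                    panel, cfg, seed = seed)
    prof <- profile_sample(h, panel, profiling_config(min_depth = 100))
    score_msi_sample(prof, clf)$score
  }
  s_msh2 <- vapply(1:8, function(s) score_gene("MSH2", s), numeric(1))
  s_msh6 <- vapply(1:8, function(s) score_gene("MSH6", 100 + s), numeric(1))
  expect_gt(mean(s_msh2), mean(s_msh6))
})

test_that("more markers widen the score separation", {
  reg <- tiny_registry()
  p24 <- get_panel(reg, "seq24")
  p54 <- get_panel(reg, "seq54")
  cfg <- fast_config(seed = 10, seq54_marker_boost = 1)  # identical effects
  both <- msiconcord:::validate_marker_registry(
    rbind(as.data.frame(p24), as.data.frame(p54)))
  tr <- small_training(both, cfg, n_msih = 20, n_mss = 20)
  clf24 <- fit_msi_classifier(
    tr$profiles[tr$profiles$marker_id %in% p24$marker_id, ],
    tr$labels, p24, "seq24")
  clf54 <- fit_msi_classifier(
    tr$profiles[tr$profiles$marker_id %in% p54$marker_id, ],
    tr$labels, p54, "seq54")
  s24 <- s54 <- numeric(0)
  for (seed in 1:10) {
    clonal <- if (seed %% 2) 0.5 else 0
    h <- simulate_length_histograms(list(gene = "MSH2"),
                                    list(clonal_fraction = clonal),
                                    both, cfg, seed = 300 + seed)
    pr24 <- profile_sample(h[h$marker_id %in% p24$marker_id, ], p24,
                           profiling_config(min_depth = 100))
    pr54 <- profile_sample(h[h$marker_id %in% p54$marker_id, ], p54,
                           profiling_config(min_depth = 100))
    s24 <- c(s24, score_msi_sample(pr24, clf24)$score)
    s54 <- c(s54, score_msi_sample(pr54, clf54)$score)
  }
  expect_gt(sd(s54), sd(s24))
})
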