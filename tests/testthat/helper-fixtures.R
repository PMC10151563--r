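# Shared fixtures: small registries and fast simulation configs built in
# code at test time.

tiny_registry <- function() {
  default_marker_registry()
}

# Reduced-depth configuration for fast simulation tests; study-condition
# parameters (cohort counts, training sizes) unchanged.
fast_config <- function(seed = 1, ...) {
  sim_config(depth = 400, seed = seed, ...)
}

# A small labelled training set over a handful of markers.
small_training <- function(markers, config = fast_config(),
                           n_msih = 10, n_mss = 10, seed = 42) {
  cfg <- sim_config(depth = config$depth, training_n_msih = n_msih,
                    training_n_mss = n_mss, seed = seed)
  simulate_training_cohort(markers, cfg)
}

wilson_ct <- function(x, n, conf_level = 0.95, continuity = FALSE) {
  as.numeric(msiconcord:::wilson_interval(x, n, conf_level, continuity))
}

# Brute-force exact McNemar by enumeration of all 2^(b+c) equally likely
# discordant-pair outcomes.
mcnemar_enum <- function(b, c) {
  n <- b + c
  if (n == 0) return(1)
  k <- min(b, c)
  x <- 0:n
  mass <- choose(n, x) / 2^n
  min(1, sum(mass[x <= k]) + sum(mass[x >= n - k]))
}

# Brute-force two-sided Fisher p by hypergeometric enumeration over all
# tables with the observed margins (probability-mass rule).
fisher_enum <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  probs <- dhyper(lo:hi, r1, n - r1, c1)
  p_obs <- dhyper(tab[1, 1], r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
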