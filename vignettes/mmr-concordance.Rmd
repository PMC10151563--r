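---
title: "Comparing MMR-deficiency assays: models, rules and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing MMR-deficiency assays: models, rules and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msiconcord)
```

## The problem

Lynch syndrome tumors carry a germline pathogenic variant in one of the
mismatch-repair (MMR) genes *MLH1*, *MSH2*, *MSH6* or *PMS2*; a somatic
second hit abolishes MMR function, which manifests as loss of MMR protein
expression on immunohistochemistry (IHC) and as microsatellite instability
(MSI) — length changes at mononucleotide repeats. Both readouts are used to
screen for Lynch syndrome and to select patients for immune-checkpoint
therapy, but they do not always agree, and the disagreement is worse
outside colorectal cancer. In urothelial tumors the classical
fragment-length MSI assay is known to under-call deficiency relative to
IHC.

`msiconcord` implements three MMR-deficiency tests and the exact
statistical framework for comparing them on the same tumors:

1. a **sequencing-based naive-Bayes MSI classifier** over
   mononucleotide-repeat markers (24- and 54-marker panels),
2. a **fragment-length rule classifier** in the style of the Promega MSI
   Analysis System, run *without* matched normal DNA,
3. an **IHC loss rule** over the four MMR proteins,

joined by a diagnostic-concordance layer (exact McNemar test, Wilson and
Clopper–Pearson intervals, Fisher's exact test). A synthetic-data
generator stands in for the FFPE tumor material, so the whole pipeline is
testable end to end.

## The sequencing classifier

Each marker's reads are reduced to two features: the **deletion
frequency** $d$, the fraction of reads strictly shorter than the
registry's reference repeat length, and the **allelic bias** $b$, the
fraction of deleted reads concentrated at the single modal deleted
length. Deletions only are used: insertion rates at mononucleotide
repeats discriminate poorly between MMR-deficient and -proficient tumors,
whereas deletion rates differ strongly. Because the assay runs without a
matched normal and the markers are quasi-monomorphic, the germline allele
is assumed to sit at the reference length.

The classifier is naive Bayes with equal class priors. For marker $m$ and
class $c \in \{\mathrm{MSI\text{-}H}, \mathrm{MSS}\}$ we model $d$ and
$b$ with Beta densities $f_{m,c}$, $g_{m,c}$ and score a sample by the
summed log-likelihood ratio over its evaluable markers:

$$S = \sum_m \left[\log \frac{f_{m,\mathrm{MSI\text{-}H}}(d_m)}
{f_{m,\mathrm{MSS}}(d_m)} + \log \frac{g_{m,\mathrm{MSI\text{-}H}}(b_m)}
{g_{m,\mathrm{MSS}}(b_m)}\right].$$

$S > 0$ calls the sample MSI-H, otherwise MSS. The published description
of this approach names the features and the sign rule but not the density
family; the Beta/method-of-moments choice here is this package's own:
bounded support, a closed-form fit, and robustness at $d = 0$ via
pseudocount shrinkage $d' = (dD + \varepsilon)/(D + 2\varepsilon)$ with
$\varepsilon = 1$ read. Consequences of that choice:

* **Score scale.** The numeric score range is an artifact of the fitted
  densities and is *not* comparable with scores printed by other
  implementations of the same idea; only the sign and the ordering carry
  meaning.
* **Variance floor.** Moment-matched variances are floored at $10^{-3}$
  (and capped below $0.95\,m(1-m)$ to keep the fit proper). Without a
  floor, a class whose training values are nearly constant produces an
  extremely peaked Beta and single out-of-range samples receive absurd
  log-ratios.
* **Monotonicity guard.** A two-Beta log-likelihood ratio is monotone
  non-decreasing in $d$ exactly when
  $\alpha_H \ge \alpha_S$ and $\beta_H \le \beta_S$. Fits violating this
  (which happens when the classes are not actually separated, e.g. under
  label permutation) are *rejected*: the marker reverts to a pooled fit
  shared by both classes and contributes nothing to the score. Rejected
  markers are recorded in the classifier object.
* **Ties and the $b$ term.** $S = 0$ is resolved conservatively to MSS
  (the published rule defines only $<0$ and $>0$). When a marker shows no
  deleted reads, its $b$ term is skipped rather than evaluated at an
  arbitrary placeholder. The modal deleted length breaks ties toward the
  larger deletion.
* **Evaluability.** A marker is evaluable at depth $\ge$ 200 reads (10%
  of the 2000-read target depth; the threshold is ours — the source
  protocol states only the target). A sample is called only when at
  least half the panel is evaluable, else it is non-evaluable (NE).

Training mirrors the published design: a labelled reference cohort of 50
MSI-H and 52 MSS colorectal-style samples, simulated by the generator
with unattenuated effect sizes.

## The fragment-length rules

The capillary-electrophoresis assay types five mononucleotide markers
(BAT-25, BAT-26, NR-21, NR-24, MONO-27). In the original workflow the
traces are read by eye; this package substitutes the objective rule the
assay's current revision recommends: a marker is **unstable** when its
modal non-reference allele (read fraction $\ge 0.2$, a stutter floor of
our choosing) deviates from the reference by $\ge 3$ bp, **suggestive**
for a 1–2 bp deviation, and **stable** otherwise. Without germline DNA
the sample rule is: any suggestive marker $\to$ NE; otherwise 0 unstable
$\to$ MSS, 1 $\to$ unresolved MSS/MSI-L, 2 $\to$ unresolved MSI-L/MSI-H,
$\ge 3$ $\to$ MSI-H. For 2×2 comparison with IHC, MSI-L/MSI-H is pooled
with MSI-H and MSS/MSI-L with MSS.

## The IHC rule

A protein is lost when expressed in $\le 10\%$ of tumor cells in the
presence of internal positive staining; absent the control, the protein
is NE. Loss is expected to follow the heterodimer biology of the MMR
complexes (MutS$\alpha$ = MSH2:MSH6, MutL$\alpha$ = MLH1:PMS2): *MLH1*
defects co-lose PMS2, *MSH2* defects co-lose MSH6, while *MSH6* and
*PMS2* defects lose only their own protein. `classify_sample_ihc()`
flags lost sets inconsistent with the family's gene. Subclonal loss is
out of model: one positivity fraction per protein.

## Concordance statistics

Concordance is the matched fraction — IHC loss with pooled MSI-H, IHC
retained with pooled MSS/MSI-L — over pairs evaluable by both assays, so
each assay comparison has its own denominator. The package computes:

* concordance with a **Wilson score interval** (no continuity correction;
  a corrected variant is available via `stats_config()`),
* sensitivity and specificity against IHC as the reference method, with
  exact **Clopper–Pearson** intervals,
* the **exact McNemar test**: with $n_d = b + c$ discordant pairs,
  $p = \min(1,\, 2 \Pr[X \le \min(b, c)])$, $X \sim
  \mathrm{Bin}(n_d, 1/2)$, and $p = 1$ when $n_d = 0$ (the asymptotic
  chi-square version in `stats::mcnemar.test` is unsuitable at these
  sample sizes),
* two-sided **Fisher's exact test** by the probability-mass rule.

One numerical caveat, documented rather than patched: the interval
variant behind the published Wilson bounds is ambiguous. The standard
score interval reproduces the published concordance bounds to within
about 0.4 percentage points (e.g. 58.9 vs 58.8 for the fragment assay's
lower bound), and no standard variant (continuity-corrected Wilson,
Agresti–Coull, Jeffreys, t-quantile Wilson) matches all printed digits
exactly. This package fixes the standard formula and accepts the
sub-half-point divergence.

## What the generator emulates — and what it does not

The generator's defaults encode the study conditions: 97 tumors with gene
marginals MLH1 9 / MSH2 64 / MSH6 23 / PMS2 1, 74 carriers vs 23
first-degree relatives (FDRs), locations 27/34/36
(ureter/renal pelvis/bladder), DNA concentration QC at $> 1$ ng/µL
(boundary exclusive), 2000 reads per amplicon, and a 50 + 52 training
cohort. Where the underlying study reports no quantitative value, a
parameter was chosen once on domain grounds and is documented here:

* **Ground truth.** Carriers' tumors are MMR-deficient except a 10%
  sporadic fraction among bladder tumors (lower-tract tumors are common
  sporadically); FDR tumors are a carrier/non-carrier mixture with a 25%
  proficient fraction. Both are knobs, not estimates.
* **Stutter.** PCR/FFPE slippage is deletion-dominated: each read loses
  $k$ repeat units with geometric tail ($\lambda = 0.05$) and gains one
  unit at $\lambda/10$. Real stutter varies with repeat length and
  polymerase; this generator uses one rate for all markers.
* **Somatic deletions.** Deficient tumors carry a clonal deleted allele
  at every marker: per-sample clonal fraction $\sim$ Beta(5, 5), scaled
  by a per-gene attenuation (MSH6 = 0.5 — MSH6-deficient tumors show
  systematically weaker instability), observed at tumor purity 0.6.
  Deletion sizes are rounded positive normals with mean 4 bp (2 bp for
  MSH6).
* **Panel sensitivity.** Markers of the 54-marker panel receive a 1.3×
  boost of the somatic allele fraction, encoding the reported higher
  individual sensitivity of markers selected from constitutional-MMR-
  deficiency blood genomes; without it the qualitative 24-vs-54
  discordance direction (the 54-marker panel rescuing weak, mostly MSH6,
  samples) does not emerge.
* **Fragment-assay behavior.** Deficient samples draw unstable markers
  with probability 0.55 (gene-attenuated), proficient with 0.02, and
  any marker can be "suggestive" with probability 0.05. The 0.55 default
  was chosen so the simulated raw-class proportions qualitatively match
  the reported distribution (roughly 53% MSI-H, 18% MSI-L/MSI-H, 18%
  MSS/MSI-L, 12% MSS among evaluable tumors) — these are simulation
  knobs, not estimates of assay performance.
* **IHC.** Lost proteins draw positivity from Beta(1, 30), retained from
  Beta(12, 3); deficient missense tumors retain expression with
  probability 0.5; the internal control is absent with probability 0.02.
* **Dropout.** Technical non-evaluability is logistic in FFPE block age,
  $\mathrm{logit}^{-1}(-3.5 + 0.08 \cdot \text{age})$, drawn
  independently per assay; with the simulated block-age distribution
  this lands near the reported non-evaluable fractions (~30% fragment
  assay, ~26% sequencing).

Not modelled: pentanucleotide identity controls, UMI/consensus structure
of the capture chemistry, base-quality error, run-level normalisation of
$d$, subclonal MMR loss, inter-observer variation in either IHC or trace
reading, and any correlation structure between markers beyond the shared
clonal fraction. Passing tests on this generator therefore demonstrate
internal consistency of the pipeline and the statistical machinery —
not performance on real FFPE data, whose noise is richer.

Multi-tumor patients are not modelled either: every tumor is treated as
an independent sample, mirroring how per-sample statistics are computed
downstream.

## A worked run

```{r pipeline, eval = FALSE}
res <- run_simulated_study(sim_config(seed = 1))
res$reports$promega
res$panel_comparison
res$cv$accuracy
```

With the default conditions the simulated study reproduces the
qualitative findings: the fragment assay has the lowest concordance with
IHC (many deficient tumors with one or two unstable markers pool into
MSS/MSI-L), the 54-marker panel the highest, MSH6-deficient tumors score
lowest, and 5-fold cross-validated training accuracy is 1.0. The
published confusion counts are bundled (`reference_confusion()`), and
their derived statistics are recomputed exactly by
`scripts/acceptance.R`.

Problem sizes used throughout the examples and tests — 97 tumors, 102
training samples, 78 sequencing markers, 2000 reads per amplicon — are
the package's defaults; unit tests use reduced depths (300–500 reads)
where only relative behavior matters.

## Degenerate inputs and edge rules

* DNA concentration exactly 1 ng/µL: excluded (the QC wording is
  "above").
* Positivity exactly 10%: loss (the rule is "$\le$").
* Score exactly 0: MSS.
* Confusion tables with an empty margin (no retained pairs, say) raise
  an error naming the margin instead of returning NaN.
* All pairs NE: an error, not an empty report.
* `b` is defined as 0 when `d` is 0; both are scale-invariant in read
  counts.

## Known limitations

The classifier's density family, the allelic-bias definition, the 0.2
allele-fraction floor and the 200-read evaluability threshold are
reimplementation choices; results on real data will differ from any
specific published instrument. The synthetic cohort cannot reproduce
which individual tumor receives which call — only distribution-level
behavior — so sample-level comparisons with published per-tumor tables
are out of scope. The concordance layer assumes one 2×2 table per assay
after listwise NE exclusion; it does not model the missingness mechanism
(which is block-age-dependent, i.e. informative in principle).
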