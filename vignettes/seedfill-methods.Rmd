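---
title: "Methods: time-course multi-omics analysis of seed filling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-course multi-omics analysis of seed filling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedfill)
```

`seedfill` analyses paired metabolomic and transcriptomic profiles of
developing seeds sampled at a small number of developmental time points
(days after flowering, DAF). This vignette is the package's own account of
the statistics it implements: the models, the parameters that matter, the
numerical choices, and what the synthetic-data tests do and do not
demonstrate.

## Data model and normalisation

An `omics_matrix` is a features x samples abundance matrix bound to a
design (`time`, `replicate`). Raw values are strictly positive; missing
cells mark measurements below the platform's detection limit.

Two normalisation steps precede all statistics:

* **Detection filter.** A feature is retained only if there is at least one
  time point at which *all* of its replicates are present. This mirrors how
  analyte panels are curated: a feature reliably quantified somewhere in
  the series is kept even if it drops below detection elsewhere; one never
  quantified cleanly at any time point is discarded. No imputation is
  performed — remaining missing cells stay missing and are excluded from
  medians and model fits feature by feature.
* **ln / median centring.** Values are natural-log transformed and the
  per-sample (per-chip) median of the logged values is subtracted, so every
  sample has median 0. Centring per sample removes chip- or run-level
  intensity offsets; it deliberately leaves feature-level differences
  intact.

## Differential screening

For each feature the additive linear model

$$ y_{tr} = \mu + \beta_r + \tau_t + \varepsilon_{tr} $$

is fit with replicate ($\beta_r$) and time ($\tau_t$) both categorical, and
the overall F-test for dropping the time term asks whether mean abundance
changed at all across the series. Replicate enters as a block main effect
only — no interaction — because with the typical two replicates per time
point an interaction would consume all residual degrees of freedom.
Degenerate features (constant values, or zero residual df) are assigned
`p = 1` and flagged, rather than `NA`, so that downstream set operations
remain total.

With a balanced complete design all features share the same projection
matrices, so the F statistics are computed for the whole matrix with one QR
decomposition; features with missing cells fall back to a per-feature fit.

**q-values.** P-values are converted to Storey q-values:
with order statistics $p_{(1)} \le \dots \le p_{(m)}$,
$q_{(i)} = \min_{j \ge i} \pi_0\, m\, p_{(j)} / j$, clipped to 1. Three
$\pi_0$ estimators are available:

| `pi0_method` | estimate | notes |
|---|---|---|
| `lambda_0.5` (default) | $\#\{p > 0.5\} / (0.5\,m)$, clipped to $(0,1]$ | the classical single-$\lambda$ estimator; a good default when a substantial null fraction exists |
| `fixed_1` | $\pi_0 = 1$ | exactly Benjamini–Hochberg adjusted p-values |
| `smoother` | natural-spline fit of $\hat\pi_0(\lambda)$ extrapolated to $\lambda = 1$ | the smoother variant; useful when the p distribution is irregular |

The estimator is exposed because q-value software versions differ in this
choice and it can move counts near a threshold appreciably. Conventional
cutoffs in this field are q < 0.01 for transcript screens (large m, two
replicates) and q < 0.05 for metabolite panels, and those are the pipeline
defaults.

## Profile clustering and the number of clusters

Clustering operates on **standardized temporal profiles**: replicates are
averaged within time points, then each feature's profile is centred and
scaled to sd 1 across time points. Standardization makes clustering group
features by trajectory *shape*; the MRPP test below deliberately does not
standardize, because it targets change in accumulation, which
standardization would erase. Profiles use time-point means rather than full
replicate vectors so both platforms (6 vs 2 replicates) cluster in the same
d = 5 dimensional space; this is a design choice worth revisiting in a
sensitivity analysis when replicate-level structure matters.

**K-medoids (PAM).** Euclidean distance; deterministic BUILD
initialisation followed by steepest-descent SWAP to a local optimum; the
best of `n_restarts` starts (default 10, the rest random but seeded) by
total distance-to-medoid cost wins. Rows are processed in lexicographic
feature-id order and ties break toward the smaller id, so the result is
invariant to input row order. On instances small enough to enumerate, the
SWAP optimum coincides with the exhaustive medoid optimum (this is a test).

**Krzanowski–Lai criterion.** For each K the within-cluster dispersion
$W_K$ is the total *squared* Euclidean distance of members to their medoid
(staying inside the K-medoids frame rather than recomputing centroids;
with tight clusters the two differ negligibly, and the medoid form keeps
the criterion consistent with the clustering it evaluates). Then

$$ \mathrm{DIFF}(K) = (K-1)^{2/d} W_{K-1} - K^{2/d} W_K, \qquad
   \mathrm{KL}(K) = \left| \mathrm{DIFF}(K) \right| /
                    \left| \mathrm{DIFF}(K+1) \right|, $$

and the chosen K maximizes KL where both terms exist; ties break toward
smaller K (parsimony). $W_1$ is always computed so the lower end of the
K range is evaluable. On default synthetic data the criterion selects the
planted K = 5 for metabolites in 19–20 of 20 seeds.

## Category-level statistics

**MRPP.** For a category (pathway, GO term) with at least two measured
members, each sample is the vector of member values and groups are the time
points. The statistic is the group-size-weighted mean within-group pairwise
Euclidean distance, $\delta = \sum_g (n_g/N)\,\bar d_g$ — the classical
weighting; the permutation null shuffles sample-to-group labels preserving
group sizes, and $p = (1 + \#\{\delta^* \le \delta\})/(B+1)$, so p has
resolution $1/(B+1)$ and never equals zero. The chance-corrected agreement
$A = 1 - \delta/E[\delta]$ is reported informationally. Default
`B = 10000` for production runs; calibration tests use `B = 199` over many
categories instead, which is the efficient direction for verifying type-I
error.

**Over-representation.** One-sided hypergeometric upper-tail p for the
overlap between a selected feature list and a category, against an explicit
background universe; the odds ratio gets a 0.5 continuity substitution on
zero cells for reporting only. Categories need at least two measured
members to be testable.

**Class-by-cluster tests.** Given a metabolite cluster assignment and the
8-class chemical annotation (AA, AR, eFA, fFA, OA, SGD, ST, UK), three
families are computed from the class x cluster contingency table:

* *per class*: a Pearson chi-square goodness-of-fit of the class's counts
  across clusters against a **uniform** null (asymptotic, df = J − 1) —
  "is this class evenly spread over the clusters?" A proportional-to-
  cluster-size null and an exact 2 x J Fisher variant are available as
  options.
* *per cluster*: Pearson chi-square on the 2 x I cluster-versus-rest table
  with a Monte-Carlo p-value (default `B = 100000`, matching the
  resolution at which such tables are conventionally reported) — "does
  this cluster's class composition differ from the rest?"
* *overall*: a uniform goodness-of-fit on the cluster totals, plus a
  Monte-Carlo chi-square independence test on the full I x J table.

This combination was chosen because it exactly reproduces the reference
per-class, per-cluster and total p-values from the published metabolite
class-by-cluster table that the acceptance suite checks; a plain exact
Fisher test on the 2 x 5 tables demonstrably does not reproduce those
values.

## Co-analysis

**Volcano.** Per feature, a two-sample t-test between the replicate values
at two chosen time points, Welch by default (pooled optional): with so few
replicates, assuming equal variances buys little and risks much. The fold
change is the difference of group means on the ln scale.

**Correlation.** Pearson r between a query feature's time-point mean
profile and every target's, with the two-sided p from
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df. With n = 5 time points,
r = 0.86 gives p = 0.06 — the arithmetic the acceptance suite pins down.
Correlation over time-point means is the default (replicate-level is
available when the platforms share a sample layout). Correlated sets
(e.g. r in [0.9, 1], p < 0.05) feed into the over-representation test
against the full target background.

A sobering property of n = 5 correlations is their null spread: about 1.3%
of independent features exceed |r| = 0.95 by chance, so among hundreds of
transcripts several will track any query closely. Correlation ranking over
five points therefore only isolates *near-perfect* trackers; the recovery
tests plant an exactly tracking transcript and verify it ranks first, while
the ±0.05 realization contract of the correlation-planting generator is
tested separately. Interpret moderate correlation bands as screening, not
identification.

## Promoter motif enrichment

Promoters are the 1000 bp upstream of the translational start; longer
records are truncated keeping the ATG-proximal end, since the window is
defined from the ATG. Degenerate IUPAC motifs are scanned on the forward
strand and the reverse complement (plant cis-element collections annotate
elements on either strand); overlapping matches count, and an `N` in the
sequence matches nothing. Enrichment per (motif, cluster) pair is the
one-sided Fisher test on motif *presence* (≥ 1 hit) in the cluster's
promoters versus the background universe — presence rather than counts,
matching how "contains the motif" statements are made. No multiplicity
correction is applied by default (conventional reporting is p < 0.05 per
motif); a Storey q column is optional.

## The synthetic-data generator

`sim_spec()` defaults emulate the structure of a seed-fill study: five
harvests at 25, 30, 35, 45, 50 DAF; 273 metabolite analytes x 6 replicates
in the 8-class composition 31/7/12/12/15/41/30/125; 2,869 differential
transcripts x 2 replicates (null probes can fill the chip to 37,593 but
are off by default — see below); 5 planted metabolite and 8 planted
transcript clusters.

Abundances are log-normal. On the ln scale a feature is

$$ \ln y = \text{baseline} + \text{effect\_scale} \cdot s_c(t) +
   b_r + \varepsilon, $$

with $s_c$ a standardized deterministic template (shape families: steady
rise, steady fall, late rise, mid peak, early fall, early plateau, trough,
late fall — the qualitative profile classes seen in seed-fill data),
replicate offsets $b_r \sim N(0, \text{noise\_sd}/2)$ giving the model's
replication term something to absorb, and
$\varepsilon \sim N(0, \text{noise\_sd})$. Defaults
`effect_scale = 1`, `noise_sd = 0.25` put the noise at a quarter of the
effect amplitude, the regime in which a competent design should recover
its own structure; all recovery properties are stated under it.

What the generator does *not* emulate: probe cross-hybridization,
mass-spectral peak artefacts, heteroskedastic detection-limit censoring,
correlated features within pathways beyond the planted clusters, and
heavy-tailed biological variation. Passing recovery tests therefore shows
the pipeline is correct and well calibrated, not that real seed data are
this clean.

Two scale choices deserve explanation:

* **Chip-scale nulls.** With two replicates the F-test has 4 and 4 degrees
  of freedom, so individual true effects at the default noise ratio reach
  p ~ 10⁻³, not 10⁻¹⁰. Embedding the 2,869 differential features among
  34,724 nulls then leaves essentially nothing below q < 0.01 — a real
  property of two-replicate designs at stringent FDR, not an
  implementation artefact. The default universe is therefore the
  differential set itself (nulls opt-in via `n_trans_null`), which is also
  the universe that gets clustered.
* **Problem sizes in tests and the acceptance script.** Calibration uses
  1,500 null features (F-test KS), 500 null categories at B = 199 (MRPP),
  and 20 simulated studies of 800 features for FDR; recovery uses the full
  273-analyte metabolite default over 20 seeds, and 240–400-transcript
  universes for category/motif recovery. These sizes give the binomial
  margins needed by the stated rates while keeping the default test run
  fast; the Krzanowski–Lai scan inside the pipeline subsamples at most
  `kl_max_features = 800` profiles (seeded), with the final clustering at
  the chosen K using all features.

Determinism: every random stage draws from a named substream derived from
the single master seed, so adding a stage never perturbs another stage's
draws, and identical configurations produce byte-identical outputs.

## Known limitations

* No moderated (empirical-Bayes) variance shrinkage; with two replicates a
  limma-style approach would gain power, but the plain fixed-effects
  F-test is the model implemented here.
* Multi-factor designs (genotype x time, environment) are out of scope;
  the design is strictly replicate + time.
* The MRPP weighting and distance exponent follow the classical choice
  ($n_g/N$, unsquared distances); variants exist and are not exposed.
* Exact conditional tests on R x C tables are delegated to the standard
  network algorithm and fall back to Monte-Carlo when infeasible; extreme
  tail p-values below the Monte-Carlo resolution are reported at the
  resolution bound.
* Promoter scanning is exact-match IUPAC; no position-weight-matrix
  scoring, and no de-novo motif discovery.
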