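---
title: "Methods: woody vegetation structure along a land-abandonment chronosequence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: woody vegetation structure along a land-abandonment chronosequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronoveg)
```

## The analysis

`chronoveg` implements a chronosequence analysis of woody vegetation
structure: four Tamaulipan thornscrub sites differing only in time since
the land was abandoned (10, 20, 30 and more than 30 years; the oldest is
an undisturbed control) are compared through the structural statistics a
vegetation ecologist would compute from a stem-level inventory. The
space-for-time assumption — that differences across the sites estimate
the trajectory one site would follow through time — is taken as given by
the sampling design and is not testable inside the package.

The sampling design emulated throughout is four square 40 m × 40 m plots
(1600 m²) per site, censusing every woody individual with basal diameter
$d_{0.10} \geq 1$ cm measured 10 cm above ground, with total height $h$
(m) recorded per stem. The census rule is enforced at the data boundary:
`read_inventory()` drops sub-census rows with a warning and a count,
while the `chronosequence()` constructor treats them as an error, so no
analysis ever sees a stem below 1 cm.

## Statistics computed

**Alpha diversity.** Species richness $S$ is the count of species with
positive abundance. Shannon diversity uses natural logarithms,
$H' = -\sum_i p_i \ln p_i$ with $p_i$ the proportion of individuals of
species $i$, and the effective number of species is the first-order Hill
number $^1D = \exp(H')$. Because $p_i$ is scale-invariant, densities
(N ha⁻¹) and raw counts give identical values, which is why the analysis
can run equally from stem records or from a published density table.
Site-level $^1D$ is computed on abundances pooled over the four plots;
per-plot values are the replicated form used for group comparisons.

**Vertical structure.** Pretzsch's species height profile index
(A-index) partitions each plot into three zones relative to its tallest
stem (100%): zone I above 80%, zone II from 50% to 80%, zone III at or
below 50%. $A$ is the Shannon entropy over occupied species × zone
cells; its ceiling is $\ln(3S)$ with the zone capacity fixed at 3. Two
conventions are deliberate here. Boundary ties (a height exactly at 80%
or 50% of the reference) fall in the *lower* zone — the interval
notation of the index's definition does not resolve this, so the package
fixes strict inequality upward. And the 100% reference tree is chosen
*per plot* by default, which matches the replicated mean ± SD reporting
style of field studies; a site-wide reference is available via
`site_a_summary(reference = "site")`.

**Importance value.** For species $i$ in one site: absolute abundance
$A_i$ (N ha⁻¹), absolute dominance $D_i$ (summed basal area
$g = \pi (d/200)^2$ per hectare, m² ha⁻¹), and absolute frequency $F_i$,
the number of the site's plots where the species occurs. Each is
normalised over species to a relative form summing to 100, and
$IVI_i = (RA_i + Rd_i + Rf_i)/3$, so the IVI column also totals 100.
Frequency is counted over *plots within the site*: that is the only
reading under which frequency varies inside a one-site table, and it
reproduces the structure of per-site importance tables in the field
literature. Stand volume uses $V = g \, h \, MC$ per stem with the
morphic coefficient $MC = 0.5$, the accepted constant for thornscrub
growth forms, summed and rescaled to m³ ha⁻¹.

**Beta diversity.** Bray-Curtis similarity
$2\sum_i \min(x_i, y_i) / (\sum_i x_i + \sum_i y_i)$ is computed on
pooled per-site density vectors — pooled, not plot-averaged, because that
is the scale at which the reference results are reproducible. Sites are
clustered by UPGMA (unweighted average linkage) on $1 - \text{similarity}$,
and tree fit is summarised by the cophenetic correlation between input
and tree distances over the six site pairs. UPGMA is delegated to
`stats::hclust(method = "average")` behind the `upgma()` surface; the
test suite holds it against a brute-force implementation that recomputes
every cross-pair mean at each merge. Tied minimum distances follow
`hclust`'s deterministic internal order; ties have probability zero for
the continuous distances used here.

**Branch support.** Support for each dendrogram node is estimated by a
species-level bootstrap: columns of the site × species matrix are
resampled with replacement, the similarity matrix and UPGMA tree are
rebuilt, and a node's support is the percentage of replicate trees
containing the same label clade (counted with `ape::prop.clades`).
Replicates in which a site loses its entire abundance are redrawn and
counted. The resampling unit is a deliberate, documented choice
(`branch_support()` is explicit about the scheme) since cluster-support
conventions differ between packages; supports are reported as
percentages with the root trivially at 100.

```{r similarity}
abund <- thornscrub_abundance()
round(unclass(similarity_matrix(abund)), 3)
d <- similarity_to_dist(similarity_matrix(abund))
round(cophenetic_correlation(upgma(d), d), 3)
```

**Group comparisons.** Per-plot metrics (richness, $^1D$, A-index,
density, dominance, volume) are compared across sites by an
assumption-gated flow: Shapiro-Wilk on the ANOVA residuals and Levene's
test (Brown-Forsythe median-centred form, the common default of
assumption-checking tooling; mean-centring by flag) are always computed,
but routing is driven by Levene alone — with four plots per site a
normality test has almost no power, so the pipeline reports normality
without ever switching methods on it. Levene $p < \alpha$ (default
0.05, configurable) routes to Welch's ANOVA with Games-Howell post hoc;
otherwise classic ANOVA with Tukey HSD. Games-Howell is implemented
directly: pairwise $t_{ij} = (\bar x_i - \bar x_j) / \sqrt{s_i^2/n_i +
s_j^2/n_j}$, Welch-Satterthwaite degrees of freedom per pair, and the
adjusted p-value from the studentized range with $q = |t|\sqrt{2}$ and
$k$ groups. One degenerate route is handled explicitly: when Levene
flags unequal spread but some group is constant (common for discrete
richness with few plots), Welch weights are undefined and the comparison
falls back to the classic path, recording the forced route in its audit
field. Compact letter displays use the standard insert-and-absorb
aggregation over the adjusted p-values.

## The synthetic inventory generator

Because raw stem records for the study system are not shipped, the
package carries a generator whose defaults encode the design it
emulates. Each stage draws its species as the first $S$ entries of one
seeded shuffle of a 26-species thornscrub pool — a *single* shuffle
shared by all stages, so compositions are nested the way early-colonist
floras nest inside late-successional ones, and compositional similarity
decays with stage distance. Expected relative abundances follow a
truncated geometric series $p_r \propto \theta^{r-1}$; stem totals are
Poisson with mean `total_density` × site area; stems are multinomially
assigned to species and uniformly to plots; heights are log-normal and
diameters follow a log-log allometry on height with Gaussian noise,
redrawn (and finally clipped) to respect the 1 cm census rule. A single
integer seed drives everything through `withr::with_seed`, so no global
random state leaks.

The geometric series was chosen over a log-series precisely because its
Shannon entropy has a closed form, giving the generator an analytic
oracle: `paperlike_config()`'s decay ratios (0.0618, 0.2994, 0.5457,
0.7494) are the solutions of
$^1D(\theta, S) = \exp(-\sum_r p_r \ln p_r)$ equal to the reference
effective species numbers (1.28, 2.39, 4.53, 9.3) at the reference
richness values (4, 13, 12, 21). Total densities (1500, 1158, 762, 1828
N ha⁻¹) are the reference site totals; log-normal height medians rise
from 1.3 m to 2.8 m with widening spread; and the allometric intercepts
(1.0657, 1.4268, 1.4346, 0.8270) are solved in closed form from
log-normal moments so each stage's expected basal-area total matches the
reference dominance totals (2.20, 7.15, 8.03, 8.86 m² ha⁻¹). The
implied stand volumes (about 2, 10, 16, 25 m³ ha⁻¹) are of the right
magnitude and ordering for the system, though not calibrated to any
target.

What the generator does *not* emulate is worth stating: no spatial
pattern within plots, no species-level trait differences (heights and
diameters are exchangeable within a stage), no dispersal or interaction
dynamics, and rare tail species of a stage can fail to appear in a
realisation (expected counts below one stem). Passing tests therefore
demonstrate that the pipeline recovers the statistical structure it
assumes — rank-abundance shape, density, vertical gradient, nested
composition — not that it would behave identically on any field data
set.

```{r generator}
ch <- simulate_chronosequence(paperlike_config(), seed = 1)
site_diversity(ch, "pooled")[c("site", "richness", "effective_species")]
```

## Numerical choices and degenerate inputs

* All indices carry full double precision; rounding (2 dp for IVI and
  dominance, 3 dp for similarity) is left to presentation layers.
* Recomputing $^1D$ from the shipped density table — whose entries are
  themselves rounded to 2 dp — reproduces the four reference values to
  one unit in the last printed digit (the third value lands at 4.536,
  i.e. 0.006 above its printed 4.53); exact re-rounding would need the
  unrounded stem data.
* Empty plots are representable (the plot table is explicit), skipped
  with warnings where a statistic is undefined, and surface as
  `defined = FALSE` rows rather than errors. Empty sites yield volume 0
  with a warning; importance tables refuse empty sites outright.
* An all-zero abundance vector is a domain error for $H'$ and
  Bray-Curtis (proportions undefined), and richness of such a vector
  is 0.
* Cophenetic correlation needs at least three labels; with two it is
  flagged `NA` rather than fabricated.
* Species names are whitespace-normalised and matched case-insensitively
  with the first spelling kept; no synonym resolution is attempted, so
  internally inconsistent source taxonomies pass through as given.

## Problem sizes in the test suite

The suite exercises the pipeline at the scale of the design it emulates:
brute-force oracle comparisons for Shannon and UPGMA run on vectors of
up to 8 species and matrices of up to 6 labels at $10^{-12}$ tolerance;
the routed comparison's type-I error is estimated from 5,000 null
replicates of the 4-site × 4-plot layout; generator recovery of the
diversity and similarity orderings is checked over 500 seeded
simulations; and Games-Howell calibration under a 100-fold variance
ratio uses 2,000 replicates. These sizes give stable Monte-Carlo
estimates for the bands being checked while keeping a full run of the
suite in the low minutes on one core.

## Known limitations

* Per-species IVI values from the reference table cannot be recomputed
  cell-exactly because its relative-frequency column is not published;
  importance tables are validated structurally (normalisation, ranking,
  frequency bounds) instead.
* The A-index reference values of the study system (plot-level means
  2.68 ± 0.18 down to 1.01 ± 0.37) require the raw stem data; the
  package checks the qualitative site ordering on simulated data only,
  and its per-plot reference-tree convention is one of two defensible
  readings.
* Bootstrap branch support resamples species; other defensible units
  (plots, individuals) are not implemented.
* The comparison module makes no multiplicity correction across the six
  metrics, mirroring standard practice in this literature; p-values
  should be read per metric.
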