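---
title: "Methods: joint spatial and temporal analysis of gut microbiota"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint spatial and temporal analysis of gut microbiota}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutmosaic)
```

## The scientific problem

Fecal samples are the workhorse of gut microbiome studies, but they are a
pooled readout of a spatially structured ecosystem: the gastrointestinal
(GI) tract carries gradients of pH, oxygen, nutrients and antimicrobials
from the terminal ileum to the rectum, and mucosa-associated communities
differ between its segments. This package implements a joint analysis of
the two views a single subject can provide: a *spatial* snapshot (triplicate
biopsies at seven GI sites: TI, IV, AC, TC, DC, SC, R) and a *temporal*
record (daily fecal samples over months). The two views are then linked:
taxon pairs whose day-to-day dynamics indicate a biotic interaction are
asked whether they also co-occur along the tract.

All inputs are OTU count tables (taxa by samples) with sample metadata and,
optionally, a taxonomy. Every stage is also exercisable on synthetic data
with known ground truth, which is how the package tests itself.

## Normalization and filtering

Library sizes are normalized by **common scaling**: each sample's counts are
multiplied by (smallest library size) / (that sample's library size), so
every scaled library equals the smallest one. This is the expectation of
rarefying under infinitely repeated subsampling and avoids discarding
reads. Three filters are provided:

* **singleton removal** — OTUs with a single read in the whole table;
* **prevalence filter** (default 0.1% relative abundance in ≥ 3 samples) —
  applied before ordination and the site-versus-rest tests; the per-sample
  qualifying count is the ceiling of fraction × library size, so 0.1% of a
  10,662-read common library is 11 reads;
* **consistency filter** (default 0.05% of reads in ≥ 90% of samples,
  ceiling) — applied before time-series modeling, which only makes sense
  for taxa observed essentially every day.

Diversity indices are computed on common-scaled, singleton-removed tables
with no further filtering. The negative-binomial exact tests instead
receive **raw** counts: library-size differences are handled inside the
test by quantile equalization, and scaling first would distort its
sampling model.

## Spatial categories

Each OTU's profile over the 7 sites × 3 replicates is tested for six kinds
of structure. All 21 observations enter each regression; replicates are not
averaged, which preserves within-site variance for inference.

* **MGA / MGD** (monotonic gradient ascending/descending): ordinary least
  squares of relative abundance on position, two-sided slope test at
  α = 0.05. Two positional conventions are fitted — the tract as a
  continuum (position = distance from the anus in cm: TI 155, IV 150,
  AC 142, TC 109, DC 64, SC 20, R 10) and as a series of segments
  (ordinal 1..7). `site_positions()` negates the cm convention so that a
  positive slope always means "increasing toward the rectum" under both
  conventions; calls are reported per convention.
* **GAB / GDB** (gradient with breakpoint): a continuous two-segment
  ("broken stick") model, `abundance ~ pos + max(0, pos - bp)`, with the
  hinge at a candidate breakpoint site (AC, TC or DC — the interior colonic
  sites). The hinge coefficient is the slope change; its t-test at α = 0.05
  plus a sign change between segments makes the call. Because "ascending
  with breakpoint" is ambiguous, the package fixes a convention and always
  reports both segment slopes so calls can be audited: **GAB** = descending
  then ascending toward the rectum (a V shape, the shape of the dominant
  biopsy taxon with an AC breakpoint), **GDB** = the inverted V.
* **HS / HA** (habitat specialist/avoider): an exact test for a difference
  in means between the 3 samples of one site and the 18 others, for
  negative-binomially distributed counts — common dispersion estimated
  across OTUs by conditional maximum likelihood on quantile-equalized
  libraries, conditioning on the pooled total, and summing tail
  probabilities in both directions (implemented with edgeR, the standard
  implementation of this test family). HS requires enrichment with raw
  p < 0.01 and BH FDR < 0.05; HA the same for depletion.

An OTU may hold categories from different tests simultaneously (a steep
monotonic gradient is typically also a specialist at one end); the
classification table is deliberately long-format.

## The pairwise interaction model

For taxa $i \ne j$ with log relative abundances $x_{i,t}$ on day $t$, the
directed effect of $j$ on $i$ is estimated from the discrete-time model

$$x_{i,t+1} - x_{i,t} = \alpha_{i,j} + \beta_{i,j}\, x_{j,t}$$

fitted by OLS over all one-day transitions (transitions spanning a sampling
gap are dropped — the model is a one-day map). $\beta_{i,j} > 0$ is read as
a cooperative/commensal effect of $j$ on $i$, $\beta_{i,j} < 0$ as
competitive/amensal. All $n^2$ models are fitted; the diagonal is computed
but excluded from every summary (the predictor is part of the response).
The $n^2 - n$ off-diagonal p-values are BH-adjusted and a pair's two
directed calls at adjusted p < 0.01 give the ecological category:
+/+ cooperation, −/− competition, +/0 commensalism, −/0 amensalism,
+/− parasitism.

Counts are transformed as $x = \log((c + 0.5)/(N + 0.5 S))$ with $c$ the
(scaled) count, $N$ the library and $S$ the number of taxa: the 0.5
pseudocount is the standard continuity correction and keeps zeros finite.

**Robustness check.** The full model set is refitted after independently
permuting the time order of each predictor series (100 replicates by
default). The permutation destroys temporal association while preserving
marginals; on permuted data raw p-values should be distributed around 0.5
and BH-adjusted replicates should essentially never contain a significant
model. One wording subtlety: the permuted quantity is the predictor series
$x_{j,t}$ — the right-hand-side variable of each model — and both raw and
BH-adjusted averaged p-values are reported, since either averaging
convention is defensible.

## Co-occurrence

Two symmetric association matrices, each in two flavors (temporal =
across fecal days; spatial = across the 7 per-site mean profiles, means of
the three replicates):

* **Spearman** rank correlation of relative abundance profiles (average
  ranks for ties; constant taxa get 0 and a degenerate flag);
* **SparCC**, implemented in the package: per inner iteration, fractions
  are resampled from a per-sample Dirichlet posterior (counts + 1), the
  log-ratio variation matrix $t_{ij} = \mathrm{var}\log(x_i/x_j)$ is
  computed, basis variances are solved from the linear system implied by
  the sparsity assumption, and the most strongly correlated pair above a
  threshold is iteratively excluded from the system before re-solving
  (defaults: 20 inner resamplings, 10 exclusion rounds, threshold 0.1 —
  the algorithm's conventional settings); the estimate is the elementwise
  median over inner iterations, clipped to $[-1, 1]$.

With only 7 spatial observations per taxon, no p-values are attached to
spatial correlations — only coefficients are used downstream.

## Concordance between the temporal and spatial views

Two comparisons link the views:

1. **Coefficient versus correlation**: Spearman's rho / Pearson's r between
   the directed $\beta_{i,j}$ and the corresponding symmetric correlation.
   Each unordered pair enters once per direction by default (the
   correlation is symmetric, the coefficients are not); a symmetrized mode
   is available.
2. **Partitioned distributions**: the unordered-pair correlation
   coefficients are split by whether the pair has a significant time-series
   model — by default, *either* directed model at BH p < 0.01 (the "both"
   rule is a flag). Means of both partitions, a two-sample Wilcoxon
   rank-sum test, and a one-sample test of the significant partition
   against zero are reported. Under resource competition, pairs that
   interact over time should share habitat, so the significant partition of
   *spatial* correlations should be right-shifted — the analysis' headline
   concordance signal.

## The synthetic data generator

The generator is first-class, tested code: it defines the study conditions
under which every claim above is verified.

* **Time series**: the interaction model run forward as a generative
  process on log abundances, $x_{t+1} = x_t + \alpha + B x_t + \epsilon_t$
  with Gaussian process noise (sd 0.15), closed to a composition (softmax)
  each day, with multinomial read counts at lognormal library sizes
  matching daily fecal depths of ≈ 139,000 ± 71,000 reads; the default
  horizon is 139 daily samples. Intercepts place the deterministic system
  at equilibrium, so $B$ is the only source of cross-taxon dynamics.
  Stability requires the spectral radius of $I + B$ below 1.
* **Default dynamics**: self-regulation −0.9 (strong daily mean reversion,
  consistent with the rapid day-to-day fluctuation of dense fecal series)
  and interaction magnitude 0.7 for coupled pairs, 80% competitive by
  default. These two values were chosen together from the estimator's
  sampling theory: the pairwise model omits the partner's self-regulation
  term, which attenuates the recovered coefficient by $b\rho$ (diagonal
  $b$, pair correlation $\rho$), and reciprocal competition must satisfy
  $|c| < |b|$ for stability — so detectable interactions must be of the
  same order as the self-regulation. With (−0.9, 0.7) a true pair carries
  |t| ≈ 5–6 at 139 days, and recovered significant calls have the correct
  sign essentially always.
* **Spatial tables**: per-category archetype mean profiles over the 7
  ordinal sites (linear ramps for MGA/MGD, V and inverted-V hinge shapes
  for GAB/GDB, single-site spikes/dips for HS/HA), scaled by lognormal
  baseline abundances, closed per site, with negative-binomial counts
  (default dispersion 0.2, i.e. a biological CV of ≈ 45% on top of
  counting noise) at lognormal biopsy depths of ≈ 60,000 ± 40,000 reads.
  The default effect size is 4-fold (max/min of the mean profile).
* **Coupling**: `simulate_coupled_study()` gives every taxon a Gaussian
  spatial niche (sd 1.2 sites) and, with probability `niche_coupling`,
  places the two members of a competitive pair at the same niche center.
  At coupling 1 this builds the resource-competition signature (negative
  temporal interaction, positive spatial correlation) into the data; at
  coupling 0 the partitioned concordance test is null.

**What the generator does not emulate.** Real fecal series have shared
environmental drivers (diet, transit time) that induce *positive*
contemporaneous correlations between competitors; the generator has no
common drivers, so its competing pairs are temporally *anti*-correlated.
Passing the concordance tests on synthetic data therefore demonstrates that
the machinery detects the coupling that is present by construction — not
that real data will show the same sign pattern in the temporal flavor.
Taxon abundance spectra, phylogenetic correlation of interaction strength,
and overdispersion beyond the two-layer (process + multinomial /
negative-binomial) noise model are also not emulated.

## Numerical choices and degenerate inputs

* Shannon entropy uses the natural log (required for Pielou's
  $J = H/\ln S$); evenness of a single-taxon sample is defined as 1.
* ANOSIM uses average ranks, the +1-corrected permutation p-value
  (p can never be exactly 0), and an exact-enumeration path for two small
  groups; NMDS (Kruskal stress-1) starts from the classical metric-scaling
  configuration with optional random restarts, and zero distances are
  jittered by 1e-4 of the smallest positive distance since the stress
  majorizer requires positive dissimilarities.
* Zero-variance profiles or predictors are flagged degenerate (slope 0,
  p 1) rather than erroring mid-pipeline; numerically exact fits (zero
  residual) get p 0 or 1 by the sign of the coefficient instead of the
  meaningless t-test.
* The SparCC basis system drops a pair's contribution when excluding it;
  a taxon involved in so many exclusions that its equation would become
  unidentifiable stops further exclusions, and a singular system returns
  the last stable estimate with a warning.
* BH adjustment is always over the off-diagonal model set of the analysis
  at hand, never pooled across analyses.

## Problem sizes used by the test suite

The suite verifies the combinatorial identity (76 taxa ⇒ 5,700
off-diagonal models) at full scale, the permutation-null calibration at
20 taxa × 120 days × 20 replicates (7,600 pooled p-values), sign recovery
on three replicate coupled studies at 20 taxa × 139 days, spatial-category
recall on 100 replicate biopsy tables of 36 OTUs, and the concordance
construction on three pooled coupled studies of 40 taxa. These sizes give
stable pass/fail behavior at desk scale; all stochastic stages consume
explicit seeds.

## Known limitations

* The pairwise model is deliberately misspecified (no joint multivariate
  fit, no regularization): coefficients are attenuated relative to the
  generative matrix, and only their sign and significance are interpreted.
* One-vs-rest exact tests treat the 18 "other" samples as one group, so a
  strong gradient elsewhere in the table inflates the common dispersion
  and costs power; tagwise dispersion is exposed as an option but not the
  default.
* With 7 sites, breakpoint candidates are restricted to AC/TC/DC and
  nothing distinguishes a breakpoint exactly at a site from one between
  sites.
* Compositional closure couples all taxa; the log-ratio-based SparCC
  flavor mitigates but does not remove this for strongly dominant taxa.
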