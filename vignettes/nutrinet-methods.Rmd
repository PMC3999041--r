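---
title: "Methods: nutritional gradients, ReBoot correlations and co-occurrence network trends"
author: "nutrinet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nutritional gradients, ReBoot correlations and co-occurrence network trends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package models

`nutrinet` analyses gut-microbiome feature tables (genera, phyla, COGs,
CAZyme families, virulence factors) sampled from children whose
nutritional state spans a continuum from apparently healthy to severe
malnutrition.  The analysis axis is a *cumulative nutritional index*:
the sum of three LMS growth Z-scores (height-for-age, weight-for-age,
weight-for-height).  Around that axis the package provides abundance
profiling, correlation analysis with compositionality-aware
significance, three-group comparisons, abundance-pattern clustering,
and co-occurrence network construction with a sliding-window analysis
of how network topology drifts along the gradient.

# Nutritional scoring

The LMS Z-score of a measurement $X$ against reference skewness $L$,
median $M$ and coefficient of variation $S$ is

$$Z = \frac{(X/M)^L - 1}{L\,S}, \qquad Z \xrightarrow{L\to 0} \frac{\ln(X/M)}{S},$$

with $L$, $M$, $S$ linearly interpolated between the bracketing
reference keys (age in months, or height in cm for weight-for-height);
keys outside the tabulated range are an error rather than an
extrapolation.  The cumulative index is the exact sum $z_1+z_2+z_3$ and
classifies a child as `AH` (index $> -6$), `BL` ($-9 <$ index $\le -6$)
or `SM` (index $\le -9$).  The defining inequalities are open at both
cut-points in their usual statement; we close each boundary downward
(−6 into `BL`, −9 into `SM`) so the classes partition the line.

The bundled `toyGrowthReference()` is a synthetic, internally
consistent LMS table built in code (both sexes, 0–120 months): a child
sitting on the height-for-age and weight-for-age medians also sits on
the weight-for-height median at every age.  Its weight-for-age $S$
shrinks with age; this makes the three-axis inversion below well-posed
over a wide target range.  It is *not* WHO data and carries no claim of
anthropometric realism; the reference is a pluggable input
(`readGrowthReference()`).

# Profiling

Counts are normalised by each sample's *whole-metagenome* read total —
not by the assigned-read total — so per-sample column sums never exceed
one and unassigned reads dilute every feature equally.  Ranking is
ascending within each feature row with average ranks for ties; Spearman
statistics are invariant to this orientation choice, which only fixes
the sign convention of reported correlations.

A feature is *core* when its normalised abundance strictly exceeds
0.01 in at least `ceiling(0.5 × n)` samples.  All filter thresholds in
the package are strict (`>`), including the hit filters (identity
> 65, coverage > 70, alignment length > 75 bp for taxonomic
assignments; identity > 65, coverage > 90 for functional annotation):
a value exactly at a threshold fails.

Abundance-pattern clustering is agglomerative with average linkage on
the distance $1 - \rho_s$ (Spearman between feature rows).  The linkage
and metric are a package choice — rank-based distance matches the
ranked profiles being clustered and is invariant to row scaling — and
the number of groups is always an explicit parameter (4 for taxa, 7
for CAZyme families in the bundled defaults); there is no automatic
tree cut.  Rows are processed in feature-id order so results are
deterministic.

# ReBoot correlation significance

Relative abundances are compositional: because each sample's values
share a denominator, permuting one feature naively breaks not only its
association with a partner but also the closure constraint, biasing
null distributions.  `rebootSignificance()` scores a Spearman
correlation between a feature and a partner (a second feature, or an
external covariate such as the cumulative index) as follows:

1. **Bootstrap** — resample samples with replacement `nBootstraps`
   times, recomputing $\rho$ each time.
2. **Null** — permute the target feature's values across samples and
   renormalise every sample's composition back to its original total,
   `nPermutations` times, recomputing $\rho$ on the renormalised
   values (both features are renormalised for feature–feature tests;
   an external covariate is neither permuted nor renormalised).
3. $z = (\bar\rho_{boot} - \bar\rho_{null}) / sd(\rho_{null})$, and a
   two-sided p-value from the standard normal tail.  With the
   conventional threshold $|z| > 1.97$, the boundary p is ≈ 0.0488.

Defaults are 1000 permutations and 1000 bootstraps; tests and the
acceptance script use 150–300 of each, which we found sufficient for
stable z-values at these sample sizes.  A seed in `rebootParams()`
makes any scan deterministic; the caller's RNG stream is restored
afterwards.

ReBoot needs the relative-abundance composition to renormalise, so
`associateWithIndex()` and `buildNetwork()` take the *normalized*
table rather than the ranked one.  Nothing is lost: Spearman
correlations are identical on either representation.

Constant features have no defined rank correlation; they are excluded
from scans with a warning.  A degenerate permutation null (zero
spread) is an explicit error rather than a silent zero.

The statistical power attached to each correlation uses the Fisher
arctanh approximation: $\delta = \operatorname{atanh}(|\rho|)\sqrt{n-3}$,
power $= \Phi(\delta - z_{1-\alpha/2}) + \Phi(-\delta - z_{1-\alpha/2})$.
Published power values in this literature are not all reproducible
from any single standard variant of this formula, so the package
reports power as a descriptive quantity and never gates a decision on
it.

# Group comparisons

`groupCompare()` runs, per feature: one-way ANOVA ($F$, $p$),
tie-corrected Kruskal–Wallis ($H$, $p$),
$\eta^2 = SS_{between}/SS_{total}$, and Tukey–Kramer post-hoc
statistics for all class pairs with the unequal-$n$ standard error
$\sqrt{MS_{within}/2\,(1/n_i + 1/n_j)}$ judged against the
studentized-range quantile at family-wise $\alpha = 0.05$ with
$df = N - k$.  Benjamini–Hochberg q-values are computed across
features *separately within the ANOVA and Kruskal–Wallis families* —
the conservative reading when the correction family is not otherwise
specified.  All three classes must be present with at least two
samples each; an all-constant feature reports $F = 0$, $\eta^2 = 0$.

# Co-occurrence networks

`buildNetwork()` computes ReBoot ($\rho$, $z$, $p$) for every
unordered feature pair on the selected samples and links pairs with
$p < \alpha$ (0.05 for whole-cohort networks, 0.01 for per-class
networks in the bundled defaults).  Edges are canonical ($a < b$), the
node set is exactly the edge endpoints — a feature with no significant
partner does not appear, matching how such networks are conventionally
drawn — and no within-network multiple-testing correction is applied
(edge calling uses raw p thresholds).  All pairs are computed before
filtering, so lowering $\alpha$ can only remove edges at a fixed seed.

Graph properties follow the Cytoscape NetworkAnalyzer definitions:

* average number of neighbors: mean degree $2E/N$;
* characteristic path length: mean shortest-path length over
  *connected* ordered pairs (disconnected pairs are excluded, not
  infinite); the count of connected ordered pairs is also reported;
* clustering coefficient: mean local clustering over nodes with degree
  ≥ 2 (0 when no such node exists);
* density $2E/(N(N-1))$;
* centralization $\frac{N}{N-2}\left(\frac{d_{max}}{N-1} - density\right)$,
  undefined below 3 nodes;
* heterogeneity: population standard deviation of the degree
  distribution divided by its mean.

# Sliding windows

Samples are sorted by ascending cumulative index (ties by sample id)
and grouped into overlapping windows of 7 consecutive samples
advancing by 1 — 20 samples give 14 windows.  A network is built per
window and each graph property is Spearman-correlated with the
windows' mean index (`windowTrend()`), dropping windows where a
property is undefined and requiring at least 4 defined windows.

# The synthetic cohort generator

`generateCohort()` produces cohorts with the statistical structure the
analysis assumes, so the whole pipeline is testable without sequencing
data.  It emulates: 20 samples with cumulative indices drawn uniformly
over −11.58…−2.18; a dominant *Prevotella*-like genus holding ~35% of
each sample; five gradient-positive (G1-like) and five
gradient-negative (G4-like) genera plus twelve neutral genera — 23
genera in all, the scale of the reference core census; library sizes of
100k–200k synthetic reads; COG-, CAZyme- and virulence-factor-like
functional tables as partially-assigned read subsets; and planted
within-group co-occurrence hubs whose coupling strengthens as the
index falls.

**Latent model.**  Each taxon's latent log-abundance is Gaussian:
a baseline, plus `effectSize × (index − midpoint)` for
gradient-positive taxa (negated for gradient-negative), plus noise of
sd `latentSd`.  Hub members share a per-sample factor through a
*normalized* loading: with $\lambda_s = slope\,(index_{high} -
index_s)$, a member's noise is $w_s f_s + \sqrt{1-w_s^2}\,\epsilon$
with $w_s = \lambda_s/\sqrt{1+\lambda_s^2}$, giving within-hub
correlation $\lambda_s^2/(1+\lambda_s^2)$ at constant marginal
variance.  The normalization matters: a raw added loading would
inflate $E[e^{noise}]$ by $e^{\lambda_s^2/2}$ at the malnourished end
and push a systematic closure trend into every *neutral* taxon.

**Two-tier closure.**  Latent log-abundances map to proportions by
exponentiate-and-normalise, applied in two tiers: the planted
(gradient/hub) block holds a fixed expected share of the non-dominant
composition (logit-normal noise around 0.45), and softmax closure is
applied within the planted and neutral tiers separately.  A single
softmax over all taxa would give the planted block a
$\cosh$-shaped total mass along the gradient — at large effect sizes
every neutral taxon would inherit a V-shaped compositional trend and
cease to be a valid negative control.  Pinning the block share keeps
neutral proportions index-free while leaving the within-block gradient
and hub structure untouched.  Counts are Dirichlet-multinomial at the
drawn library size with concentration `library_size / overdispersion`.

**Anthropometrics.**  Measurements are generated by inverting the LMS
transform so `computeZScores()` recovers the planted Z-scores exactly.
A single (height, weight) pair cannot satisfy three Z-score targets at
a fixed age, so age is the free variable: the generator draws the
height-for-age target and an age, then solves (by root-finding) for
the weight-for-age target at which the implied weight-for-height
Z-score closes the triple to the drawn cumulative index.
`generateAnthropometrics()` applies the same root-finding to
user-supplied targets and errors when a triple is not reconcilable
within the reference's age range.

**Calibration.**  The gradient and hub magnitudes are calibration
choices, not reported values.  `effectSize = 0.35` makes planted-taxon
correlations with the index come out near $|\rho| \approx 0.7$ at
$n = 20$, the magnitude scale such cohort studies report;
`hubCouplingSlope = 0.35` was derived from the edge-calling geometry —
a 7-sample window needs $\rho \approx 0.8$ for an edge at
$\alpha = 0.05$, so the within-hub correlation should reach ≈ 0.9 at
the malnourished end, i.e. $\lambda \approx 3$ across the 9.4-unit
index span.  Planted taxa receive a core-scale baseline
(log-abundance N(0.3 sd) around the block mean) because the reference
gradient groups are all members of the core genus set.

**What the generator does not emulate** — and hence what passing tests
do not establish about real data: read-level sequence content and
sequencing error (no FASTQ simulation), real taxonomic correlation
structure beyond the planted blocks, non-uniform index distributions,
covariates such as age or diet, and the long-tailed genus census of
real gut metagenomes (the census here is exactly the configured taxa).

# Numerical and design notes

* All randomised routines take explicit seeds and restore the caller's
  RNG stream; rebuilding any result with the same seed is
  bit-identical.
* Boundary ties: thresholds are strict everywhere; rank ties get
  average ranks; clustering ties are resolved by feature-id order.
* Degenerate inputs: constant features are excluded from correlation
  scans (warning), give $F = 0$ and $\eta^2 = 0$ in group comparisons,
  and produce empty networks (warning) when nothing varies.
* Empty graphs report `NA` properties; centralization is `NA` below 3
  nodes; a graph with no degree-≥2 node reports clustering 0.
* Problem sizes in the test suite and acceptance script: oracle
  equivalence on 1000 random vectors, all connected 6-node graphs and
  500 random graphs up to 30 nodes; ReBoot calibration on 500 null
  feature pairs at 300 permutations/300 bootstraps; parameter recovery
  on 50 cohorts of 60 samples; window trends on 50 default cohorts at
  150/150 resamples.  These sizes give stable Monte-Carlo estimates
  while keeping a full run in the tens of minutes on one CPU.

# Limitations

The ReBoot null corrects the closure constraint for the permuted
feature but cannot remove genuine compositional coupling driven by
other features' structure; on real data, strong blooms will induce
relative-abundance trends in unrelated taxa that any
correlation-on-proportions method will report.  The power column is
descriptive (see above).  Per-class networks inherit the small sample
sizes of their classes; with fewer than 4 samples a class network is
skipped.  The pipeline's growth reference defaults to the synthetic
table and must be replaced with a real LMS reference for any use on
actual anthropometrics.
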