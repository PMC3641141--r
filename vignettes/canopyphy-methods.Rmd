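---
title: "Neighborhood diversity in mapped forest plots: models and choices"
author: "canopyphy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neighborhood diversity in mapped forest plots: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopyphy)
```

## The question the package answers

In a fully mapped forest census plot every freestanding woody stem above a
minimum diameter (dbh, cm) is located and identified. Around each individual
of a focal species one can ask: how many *other* species occur within 1 m,
2 m, ..., 50 m, and is that more or fewer than chance would produce? The
curve of expected neighborhood richness around an average individual is the
individual species–area relationship (ISAR). A species whose individuals
carry significantly richer neighborhoods than a spatial null model is a
diversity *accumulator* at that scale, significantly poorer neighborhoods
make it a *repeller*, and anything in between is *neutral*. The designation
is made independently at every radius, so one species can be an accumulator
at 5 m and neutral at 30 m.

`canopyphy` implements this classification, extends it to phylogenetic
diversity (the individual phylogenetic–area relationship, IPAR), and asks
whether accumulator/repeller status is itself phylogenetically structured —
via NRI/NTI dispersion metrics, a Sankoff parsimony permutation test, and
the Fritz–Purvis D statistic for binary traits.

## The spatial null model

Classifying a species requires a null distribution for its ISAR curve. A
homogeneous Poisson null (relocate the focal species' stems uniformly)
confounds fine-scale biotic association with broad-scale habitat
preference. The package therefore uses a **heterogeneous Poisson** null:

1. Fit a first-order intensity surface to the focal species' own mapped
   stems with a bivariate Epanechnikov kernel,
   $k(d) = \frac{2}{\pi h^2}\left(1 - d^2/h^2\right)$ for $d < h$,
   with bandwidth $h = 50$ m by default. Each stem's kernel is renormalized
   by its mass inside the window (switchable), so the surface integrates to
   the stem count.
2. In each of `n_sim` iterations (999 by default) relocate **only** the
   focal species' stems: exactly $n$ positions are drawn independently with
   probability proportional to the intensity (a binomial point process —
   conditioning on $n$ keeps count variance out of the comparison). All
   other species stay fixed, bit for bit.
3. Recompute the mean richness curve over the relocated, edge-buffered
   focals each time.

Relocation with a 50 m bandwidth erases the species' spatial structure at
scales below the bandwidth while preserving its broader habitat-driven
distribution, so departures from this null reflect fine-scale association
with other species rather than shared habitat.

The observed curve is then ranked within the ensemble, pointwise. With $m$
null values the upper tail probability is
$p_{hi} = (1 + \#\{\text{null} \ge \text{obs}\})/(m+1)$ and the lower tail
analogously; at the default two-sided $\alpha = 0.05$ and $m = 999$ a
species is an accumulator at a radius when its observed mean beats at least
975 null values (pooled rank $\ge 976$), a repeller in the mirror case.
Ties count in both tails, which breaks ties conservatively toward neutral.
No correction is applied across radii — the per-scale designation *is* the
scientific object — but `envelope = "simultaneous"` offers a Bonferroni
variant for plot-wide statements.

### Conventions that matter

* **Focal species excluded.** Neighborhood richness counts heterospecific
  species only, and a focal stem is never its own neighbor. Counting
  conspecifics would mix aggregation of the species itself into a statistic
  meant to describe its effect on *others*. `exclude_focal_species = FALSE`
  restores the inclusive convention.
* **Disc membership is closed**: a neighbor at exactly distance $r$ is in.
* **Edge buffer on focals only** (50 m by default): focal individuals must
  sit at least `buffer` meters from every window edge so no neighborhood
  disc is truncated; neighbors may lie anywhere in the window.
* **Simulated stems inherit the species' median observed dbh**, so
  downstream diameter filters treat real and relocated stems consistently.
* Census filters (dbh ≥ 1 cm or ≥ 10 cm; abundance ≥ 70) are applied before
  analysis and every exclusion is recorded in a sidecar table, keeping the
  all-species and common-species analyses reconcilable.

## Neighborhood phylogenetic diversity

For the IPAR, neighborhood composition is summarized by Faith's PD: the sum
of branch lengths of the minimal subtree connecting the neighborhood's
species on the plot phylogeny. Two conventions exist; by default the
subtree includes the path to the root (`rooted = TRUE`), so a singleton
neighborhood contributes its root-to-tip path rather than zero. The choice
is logged in every output and switchable, because it does not fully cancel
in the standardized effect size. Empty neighborhoods contribute PD 0;
counts of empty and singleton neighborhoods are reported per radius since
they dilute small-radius averages.

Whether a neighborhood's PD is high or low *given its richness* is judged
against a non-spatial null: species names are shuffled across the tips of
the plot's own phylogeny (999 times by default; species from other plots
never enter), the mean-PD curve is recomputed under each shuffle, and

$$\mathrm{S.E.S.\ PD} = \frac{PD_{obs} - \overline{PD_{null}}}{\mathrm{sd}(PD_{null})}.$$

Positive values mean the average individual accumulates more phylogenetic
diversity than its species richness predicts. (The subtraction is
observed-minus-null; the opposite order would flip the stated
interpretation of the sign, and the interpretation is what the statistic is
for.) Status (phylogenetic accumulator/repeller/neutral) uses the same
two-sided Monte-Carlo rank rule as the ISAR. PD values are averaged over
focals first and the average standardized (`standardize = "after"`); the
alternative — standardize each focal against its own null, then average —
is exposed as `standardize = "per_focal"` for sensitivity analysis. When
the null has zero spread (for example, neighborhoods that always contain
every species, or singleton neighborhoods on an ultrametric tree, where
every root-to-tip path is equal) the S.E.S. is undefined and the row is
flagged `degenerate_null` with a neutral status rather than silently
dropped.

## Phylogenetic structure of the designations

* **NRI / NTI.** For the accumulator, repeller and neutral assemblages at
  each radius, the package computes the negated standardized effect sizes
  of mean pairwise and mean nearest-taxon patristic distance against tip
  shuffles: positive values indicate the group is phylogenetically
  clustered, negative overdispersed. A group spanning the whole phylogeny
  has a spread-free null and is flagged, as are groups below two members.
* **Sankoff parsimony test.** The ternary status trait is scored by exact
  dynamic programming under a unit cost matrix (any cost matrix may be
  supplied; polytomies are handled natively by the recursion). Significance
  comes from randomly rearraying the states across tips:
  $p = (1 + \#\{\text{permuted score} \le \text{observed}\})/(n_{perm}+1)$,
  so small $p$ means fewer changes than random placement — phylogenetic
  signal.
* **Fritz–Purvis D.** Species are scored accumulator or repeller (neutral
  species are excluded — the binary statistic is defined on the two active
  designations), and the observed sum of sister-clade differences in nodal
  values $d_{obs}$ (nodal values estimated by averaging daughter values
  from the tips toward the root) is scaled between two simulated
  expectations:
  $$D = \frac{d_{obs} - \overline{d_{Brownian}}}{\overline{d_{random}} - \overline{d_{Brownian}}}.$$
  The random null permutes tip states preserving prevalence; the Brownian
  null simulates Brownian motion along the tree and thresholds it at the
  rank that reproduces the observed prevalence exactly (a rank threshold
  avoids prevalence drift between nulls). $D = 1$ for phylogenetically
  random traits, $0$ for Brownian-threshold traits, below 0 for traits more
  conserved than Brownian, above 1 for traits more labile than random. Two
  tail probabilities accompany it: the fraction of random-null $d$ values
  at or below $d_{obs}$, and the fraction of Brownian-null $d$ values at or
  above it. At polytomies, daughters contribute consecutive pairwise
  differences. Both nulls default to 1,000 simulations.
* **Cross-tabulation.** Richness status versus phylogenetic status at each
  shared radius is tested for independence with a two-tailed Fisher exact
  test; all-zero rows and columns are dropped first, and if the network
  algorithm's workspace is exceeded a Monte-Carlo exact approximation
  ($10^4$ tables) is reported as such.

## Synthetic data: what it emulates and what it does not

Every statistical claim in the test suite is checked against generated data
with known ground truth, because mapped census data of this kind are not
freely redistributable.

* `generate_forest()` produces multispecies mapped point patterns in a
  rectangular window: complete spatial randomness, Thomas cluster processes
  (parents Poisson, Gaussian dispersal), and engineered `attract`/`repel`
  species whose placement density is multiplied or divided inside discs of
  a chosen effect radius around a target species — these have ground-truth
  accumulator/repeller behavior at radii up to the effect radius.
  Abundances default to a log-series (parameter 0.99, mean ≈ 22
  individuals), mimicking tropical rank-abundance shape; the `uniform`
  option serves calibration tests where equal replication is wanted. All
  placements condition on the drawn counts, so replicate plots differ only
  in locations. Stem diameters follow $1 + \mathrm{Lognormal}(\log 2, 0.8)$
  cm — many small stems, a long right tail, everything above the 1 cm
  census threshold.
* `generate_tree()` produces pure-birth (Yule) trees with exact tip counts
  and time-calibrated, ultrametric branch lengths, plus binary tip traits
  with exact prevalence: `shuffle` (no signal) or `brownian_threshold`
  (signal inherited from the tree).

The generators deliberately omit habitat covariates (first-order
environmental gradients), explicit dispersal kernels and demography. Tests
passing on these data therefore demonstrate the statistical machinery —
calibration of the nulls, power against engineered association, exactness
of the combinatorial engines — not robustness to habitat structure in real
forests; the heterogeneous Poisson null's ability to absorb real habitat
association is a design assumption inherited from the method, not something
the synthetic plots can certify.

## Numerical choices and degenerate inputs

* Intensity lattice: 1 m cells by default; sampling jitters uniformly
  within the chosen cell, and the kernel mass is renormalized on the same
  lattice, so the surface integrates to the stem count up to floating
  point.
* Null iterations that leave no eligible focal (possible for sparse species
  in heavily buffered windows) yield an `NA` curve; classification uses the
  valid iterations and reports their number.
* Tip-shuffle nulls are evaluated through an incidence-matrix form of
  Faith's PD (tips × edges), so a shuffle is two small matrix products;
  trees of at most 7 tips can enumerate all permutations exactly
  (`method = "exhaustive"`), which the tests use as an oracle.
* Ties: disc membership includes the boundary; Monte-Carlo ties break
  toward neutral; the Brownian threshold uses first-occurrence ranking on
  exact ties (measure-zero for continuous traits).
* Degenerate traits (one state), degenerate nulls (zero spread), and
  coinciding null means for D all produce flagged `NA` results, never
  silent numbers.
* Seeds: every exported stochastic function takes an optional `seed`;
  pipeline runs are bit-reproducible from the config seed alone.

## Calibration behavior and known limitations

On fully random (CSR) plots the per-radius designation rate matches the
nominal two-sided level at informative radii (roughly 3–15 m for plots with
tens of species at densities near 0.25 stems/m²). Two regimes are
conservative by construction, which is worth knowing when interpreting
whole-curve summaries:

* **Saturation at large radii.** Once a disc is large enough that every
  species in the plot is present around essentially every focal, observed
  and null richness tie at the ceiling and the tie rule forces neutral. In
  a 20-species plot at these densities that affects radii beyond roughly
  30 m — nearly half of a 1–50 m grid. The designation rate over a full
  curve is correspondingly below the nominal level.
* **Scales approaching the bandwidth.** The null preserves spatial
  structure above 50 m by design, so at radii within a factor of ~2–3 of
  the bandwidth the observed and null curves share structure and rejection
  rates fall below nominal.

The test suite exercises the machinery at reduced problem sizes chosen for
tight Monte-Carlo behavior rather than realism: 199 null iterations for
calibration sweeps, 999 for power runs, 100 replicate 64-tip trees with
1,000 permutations per null for the D-statistic anchors, and 200 replicates
for the S.E.S. PD calibration. The anchors are recomputed from scratch by
`scripts/acceptance.R`; the suite asserts only quantities it computes
itself.

Known limitations: rectangular windows only (no torus correction — the
edge buffer is the design); no abundance-weighted ISAR or PD; phylogenies
are consumed, never estimated; the D statistic requires both binary states
with at least one species each, which at many radii of a real plot leaves
it undefined (flagged, not imputed).
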