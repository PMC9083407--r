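---
title: "Models and methods behind wildgut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind wildgut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wildgut)
```

wildgut analyses longitudinal 16S amplicon data from wild animal
populations sampled by capture-mark-recapture: irregular repeat captures
of tagged individuals, each yielding an ASV (amplicon sequence variant)
count profile. The questions it addresses are those this study design
makes answerable: which taxa are core to a population, how individual and
how seasonal is gut community composition, how fast does an individual's
community drift, and how much compositional variance is attributable to
host versus temporal factors. This vignette explains the models,
estimators and numerical choices; the README shows a worked run.

## The data container

`AsvExperiment` extends `SummarizedExperiment`: one `abundance` assay
(ASVs x samples), host metadata in `colData`, taxonomy in `rowData`, and
an `abundanceMode` flag (`"counts"` or `"relative"`) enforced by the
validity method. The flag exists because two mistakes are common and
silent in ad-hoc scripts: computing Bray-Curtis on unnormalised counts
(confounds sequencing depth with composition), and normalising twice.
Functions declare the mode they require and refuse the other.

## The generative model in the simulator

Every analysis stage is validated against data with known structure, so
the simulator is first-class, tested code rather than a fixture. For a
sample from individual $i$ of population $P$ on day-of-year $t$, the
expected relative abundance of ASV $j$ in the population's pool is a
softmax over

$$\eta_j + b_{ij} + A_j \cos\!\big(2\pi (t - \phi)/365\big),$$

where $\eta_j \sim N(0, \sigma_\eta^2)$ is a baseline log-abundance
(rank-abundance spread, default $\sigma_\eta = 1.5$), $b_{ij} \sim N(0,
\sigma_{\mathrm{ind}}^2)$ is the host's fixed signature (default
$\sigma_{\mathrm{ind}} = 1$), and $A_j$ equals `seasonal_amplitude`
(default 1) for a `seasonal_fraction` (default 25%) of each pool and 0
otherwise. Counts are Dirichlet-multinomial with concentration
$\theta p$ ($\theta$ = 50 by default; larger means less overdispersion)
at a log-normal depth (median 15,000 reads, log-sd 0.6, floored at one
read so no sample is empty). Optionally the signatures drift as a
Gaussian random walk with daily standard deviation `sigma_drift`
(default 0), giving true within-individual turnover.

Design choices worth making explicit:

* **One cosine harmonic.** The seasonal pattern being emulated is a
  smooth annual oscillation; a single harmonic is the minimal cyclic
  signal, and the analysis side fits harmonics too, so recovery tests
  compare like with like.
* **Softmax link.** Keeps the compositional constraint explicit and
  makes host and seasonal effects additive on the log scale, which is
  how the estimators model them.
* **Summer peak, winter convergence.** The default forcing peaks on
  day-of-year 200 (mid-July). Under the softmax link, inter-host
  *convergence* emerges near the seasonal **trough**: when the forced
  taxa are suppressed, all hosts' communities contract onto the shared
  non-seasonal pool and inter-individual Bray-Curtis dissimilarity
  falls. A mid-summer peak therefore produces a late-winter convergence
  window, matching both the phenology of woodland rodents (nut-rich
  autumn/winter diets) and the convergence season reported for such
  systems.
* **Population structure.** ASV identifier pools are disjoint across
  populations while family labels are drawn from a common pool — the
  regime where populations share no exact ASVs yet overlap almost fully
  at higher ranks, which the sharing module must reproduce.
* **Sampling design.** Sessions are placed sequentially with gaps drawn
  uniformly from 14-28 days (one trapping night every 2-4 weeks); each
  individual is captured per session with probability 0.3, so a typical
  animal across a year is caught about five times, with a long tail of
  singletons — the capture distribution such field studies report.
  Planted organelle-labelled ASVs (at a constant 0.1% expected fraction)
  and the natural low tail of the depth distribution exercise the
  filters.
* **Seeding.** All randomness flows from one integer seed through named
  substreams (taxonomy, schedule, counts, each analysis), so the
  schedule is reproducible independently of the counts and a pipeline
  rerun is byte-identical.

What the simulator does **not** emulate: phylogenetic relatedness among
ASVs (so UniFrac-style analyses are out of scope), spatial structure
within a grid, read-level error, chimeras, or batch effects beyond a
recorded run label. Passing recovery tests on these data shows the
estimators are correct under the stated model, not that real data meet
the model.

## Filtering

The cascade is organelle removal, then a sequencing-depth filter, then a
prevalence filter — in that order, so the depth filter operates on
bacterial reads only. Boundary semantics are deliberate and tested:
samples at exactly `min_reads` (default 8,000) are **kept** (the rule is
"below the threshold removed"); "more than one copy" means a count of at
least 2; "at least 1% of samples" is `ceiling(0.01 * n)` qualifying
samples, with a floor of one sample so an ASV must reach two copies
somewhere even when the fraction is set to zero. Organelle matching is a
case-insensitive substring search across all ranks because reference
taxonomies place "Chloroplast"/"Mitochondria" at different ranks across
versions. Dates are ISO-8601; day-of-year folds Feb 29 onto day 59 to
keep a fixed 365-day cycle for the seasonal model.

The prevalence filter is applied to whatever dataset is loaded; whether
that is one population or several is the caller's choice (the pipeline
applies it to the combined table before any per-population subsetting).

## Dissimilarity and ordination

Bray-Curtis $d(x,y) = \sum_j |x_j - y_j| / \sum_j (x_j + y_j)$ requires
relative mode; Jaccard dissimilarity $1 - |A \cap B|/|A \cup B|$ uses
presence (> 0) in the filtered table. Both are checked against naive
double-loop oracles and `vegan::vegdist` to 1e-12. Note that Bray-Curtis
on a binarised, renormalised table is *not* Jaccard — a common
confusion the tests guard against.

PCoA is classical scaling: Gower-centre $-\tfrac12 D^2$, symmetric
eigendecomposition, coordinates scaled by $\sqrt{\lambda}$. Bray-Curtis
is non-Euclidean, so negative eigenvalues are expected: they are
reported (as `negativeEigenvalueMass`) but excluded from coordinates and
from `proportionExplained`, and no correction is applied by default; a
Lingoes correction is available when a fully Euclidean embedding is
needed (the dispersion test exposes the same option). Axis signs are
fixed by making each axis's largest-magnitude score positive, so PC1
trajectories are reproducible across runs; the orientation is still
arbitrary with respect to any external quantity, which is why recovery
tests orient PC1 against the ground-truth seasonal share before reading
off a peak day.

## Core taxa

Three complementary statistics, computed on detection (any nonzero
count) unless stated:

* **Subsampled prevalence**: fraction of individuals whose single,
  randomly selected sample contains the ASV, averaged over 100
  iterations — removing the bias from unequal capture numbers.
* **Persistence**: mean within-individual detection fraction across
  individuals with at least 3 samples.
* **Core membership**: an ASV is core when at least 60% of samples
  contain it *at or above* 0.1% relative abundance. The abundance
  condition is read jointly per sample (a sample counts toward
  prevalence only if the ASV clears 0.1% in that sample) because
  "present at 0.1% or more" qualifies presence; the marginal reading
  (detection prevalence plus an any-sample abundance floor) is available
  via `joint = FALSE`. Both thresholds are inclusive.

Spearman's rho between prevalence and persistence is the Pearson
correlation of mid-ranks with the large-sample t approximation — chosen
over exact methods because the ASV vectors are long and heavily tied.

## Pair-based individuality statistics

All unordered sample pairs are typed: `same_mouse` (one individual,
different sessions), `same_date` (different individuals, one session),
`same_month_diff_mouse`, `other`. The individuality test compares
same-mouse against same-date dissimilarities with a permutational
rank-sum test, one-sided (same-mouse smaller): the observed statistic is
the Mann-Whitney U over pooled mid-ranks, the null is built by
reassigning pair labels, and $p = (1 + \#\{\text{as or more extreme}\}) /
(n_{\mathrm{perm}} + 1)$. When the label space is small
($\binom{n}{n_a} \le n_{\mathrm{perm}}$) the test enumerates it and the
p-value is exact.

Pairs sharing a sample are not independent, and permuting pair labels
ignores that. Under a fully exchangeable null this calibrates close to
nominal (the type-I test holds it to 0.03-0.07 at $\alpha = 0.05$), but
it is a known approximation; a stricter scheme — permuting individual
identities and re-deriving pairs — is the natural extension and the
`enumeratePairs`/`rankPermutationTest` split is designed so it can be
composed by the user.

**Time-decay** regresses $\log(1 - d)$ on the interval in days between
same-individual samples (individuals with $\ge 3$ captures), by ordinary
least squares; pairs with zero similarity are dropped with a count since
their log is undefined. **Rate of change** divides each pair's
dissimilarity by its interval and bins by lag; under a stationary
process the rate falls with lag because $d$ saturates while the interval
grows — a property, not an artefact. **Monthly convergence** compares,
per calendar month, same-session inter-individual dissimilarities
against the same-individual dissimilarities of the mice involved
(one-sided, inter < intra), with the study-wide same-mouse mean as
reference. Months are pooled across years; each month's test draws its
own seeded substream.

## Seasonal modelling

The cyclic smoother is harmonic regression: response on
$\cos(2\pi k\,t/365), \sin(2\pi k\,t/365)$ for $k = 1..K$ (default
$K = 2$) plus covariates. It replaces a cyclic-spline GAMM deliberately:
it is closed-form, dependency-free, and its first harmonic yields an
interpretable amplitude and peak day ($\mathrm{atan2}(b_1, a_1) \cdot
365/2\pi$); the cost is less flexibility (no effective-degrees-of-freedom
adaptivity). Repeated measures are absorbed by within-individual
centring of the response *and* all regressors — the fixed-effects
approximation to an individual random intercept; it estimates the
seasonal coefficients consistently but does not partition variance
between host and residual the way a mixed model would. With multiple
calendar years, harmonics are interacted with year so each year has its
own curve, and the reported first-harmonic coefficients are the
across-year average. The seasonal $R^2$ is the drop in residual sum of
squares attributable to the harmonic block over the total sum of squares
of the (possibly centred) response.

Paired seasonal contrasts average the response per individual within two
month windows (e.g. June-August vs September-November), keep individuals
present in both, and apply a paired two-sided t test. If every
individual shifts identically the t statistic is degenerate; the
implementation returns the limit (t = 0, p = 1 for no shift; p = 0
otherwise) rather than NaN.

## PERMANOVA and dispersion

The variance partition is distance-based linear modelling: with $G$ the
Gower-centred $-\tfrac12 D^2$, a model matrix $X$ with hat matrix $H$
explains $\mathrm{tr}(HGH)$. Marginal (default) sums of squares are
SS(full) − SS(full minus term); pseudo-F uses the full-model residual;
partial $R^2$ = SS(term)/SS(total). Significance permutes the rows of
$D$ (raw permutation), the simplest exchangeability scheme — adequate
for balanced factors, approximate for marginal tests with continuous
covariates (residual permutation would be the refinement). Pseudo-F is
verified against explicit projection-matrix computation to 1e-10 and
against `vegan::adonis2` (both `by = "margin"` and `by = "terms"`).
When the residual SS is numerically zero the statistic is reported as
+Inf and permuted statistics that also diverge count as ties; a
degenerate perfectly-separated design therefore yields the proportion of
block-preserving permutations as its p-value, not the floor
$1/(n_{\mathrm{perm}}+1)$.

To avoid pseudoreplication the pipeline subsets to one random sample per
individual (seeded) before PERMANOVA, at a real cost in power at desk
scale (25 individuals against an 11-df month term); the month term's
partial $R^2$ remains the ranking quantity. The dispersion test embeds
samples by PCoA (positive axes; Lingoes optional), measures each
sample's distance to its group's spatial median (Weiszfeld algorithm;
mean centroid optional), and permutes group labels around a one-way F.

## Problem sizes and tolerances

Validation simulations use 20-30 individuals, 40-60 ASVs per population
and one study year — sizes at which every recovery property tested is
comfortably identifiable while a full suite run stays in minutes.
Calibration checks use 300 replicates (binomial two-sigma on a 5%
rejection rate is about ±2.5 percentage points, hence the 3-7%
acceptance band); recovery checks use 10-20 replicates per condition and
test medians or rates rather than single draws. Metric and projection
oracles are held to 1e-12/1e-10; eigen-reconstruction to 1e-8. The
acceptance script (`scripts/acceptance.R`) regenerates the default
two-population study from the seed it is given and recomputes every
reported quantity from scratch; nothing in its output is stored.

## Known limitations

* No phylogeny: UniFrac-type metrics and phylogenetic core concepts are
  out of scope.
* The harmonic smoother cannot represent sharp or asymmetric seasonal
  transitions; raise `K` for more structure.
* Pair-label permutation and raw-label PERMANOVA permutation are
  approximations whose exactness degrades with strong covariate
  structure; both are documented above.
* The within-individual centring absorbs only intercepts — individual
  slopes in time are not modelled.
* Richness estimation, raw-read processing and figure rendering are
  intentionally outside the package.
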