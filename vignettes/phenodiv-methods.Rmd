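---
title: "Methods: diversity, heritability and selection response in multi-year trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, heritability and selection response in multi-year trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenodiv)
```

phenodiv evaluates two kinds of plant-breeding experiments from the same
plot-level table: a **germplasm collection** grown to describe phenotypic
diversity and pick parents, and a **breeding population** (for example,
recombinant inbred lines from a wide cross) grown to estimate genetic
parameters and screen superior lines. Both are multi-year randomized
complete block designs (RCBD): every genotype appears once in each of
`r` blocks, in each of `y` years, and years are treated as environments.

This vignette records the statistical model behind each stage, the
conventions adopted where the classical literature is ambiguous, the
design of the trial simulator that backs the test suite, and the known
limits of both.

## The observation model

All estimators assume the additive decomposition

$$y_{ijk} = \mu + g_i + t_j + b_{k(j)} + (gt)_{ij} + e_{ijk},$$

with genotype $i$, year $j$, block $k$ nested in year, genotype-by-year
interaction, and plot residual. Genotypes, years and interactions are
random with variances $\sigma^2_g$, $\sigma^2_y$, $\sigma^2_{gy}$,
$\sigma^2_e$. Balance is load-bearing: the closed-form expected mean
squares below hold only when every genotype occupies all $y \times r$
cells, so `anova_multiyear_rcbd()` refuses unbalanced data instead of
returning silently biased components. Descriptive statistics
(`summarize_traits()`, `genotype_means()`) tolerate missing cells by
averaging what is present, with across-year means taken as means of
per-year means so an under-replicated year is not over-weighted.

## Variance components, heritability, CVs

From the balanced ANOVA mean squares,

$$\hat\sigma^2_e = MS_E,\qquad
  \hat\sigma^2_{gy} = \frac{MS_{GY} - MS_E}{r},\qquad
  \hat\sigma^2_g = \frac{MS_G - MS_{GY}}{r\,y},$$

and the phenotypic variance **of a genotype mean** is

$$\hat\sigma^2_p = \hat\sigma^2_g + \frac{\hat\sigma^2_{gy}}{y}
  + \frac{\hat\sigma^2_e}{r\,y}.$$

The divisor $r \times y$ in the error term is read as $\sigma^2_e/(ry)$,
the standard result for the variance of a mean over $ry$ plots; the
alternative reading $(\sigma^2_e/r)\cdot y$ is dimensionally incoherent
with heritabilities near 100%. Negative component solutions — routine
sampling artifacts when a true component is near zero — are clamped to
zero and flagged in the `truncated` column rather than propagated, since
downstream ratios require non-negative variances but silent clamping
would hide estimator stress.

Broad-sense heritability is $h^2_b = 100\,\sigma^2_g/\sigma^2_p$, and the
coefficients of variation are $GCV = 100\sqrt{\sigma^2_g}/\mu$ and
$PCV = 100\sqrt{\sigma^2_p}/\mu$, classified low/moderate/high at 10%
and 20%, with heritability bands at 40/60/80%. Genotype F statistics use
$MS_G / MS_{GY}$ (years as environments); all other sources test
against $MS_E$.

## Selection response

Truncation selection keeping the best fraction $p$ of genotype means has
intensity $i = \phi(z_p)/p$, computed from the normal density and
quantile rather than hard-coded, so any selection fraction works
(`selection_intensity(0.05)` returns `r round(selection_intensity(0.05), 3)`).
The predicted one-cycle response and gain are

$$R = h^2_b\, i\, \sqrt{\sigma^2_p}, \qquad
  \Delta G = 100\,R/\mu,$$

with $h^2_b$ as a fraction in $R$. Selection operates on across-year
genotype means — the quantity whose variance is $\sigma^2_p$ above —
which is what makes the realized-gain check (select top 5% of simulated
phenotypes, measure their true genotypic superiority) line up with $R$.

## Correlations from covariance components

Sums of cross-products between two traits decompose by the same design
sources with the same degrees of freedom, and the same linear solve
yields $cov_g$, $cov_{gy}$, $cov_e$, $cov_p$. Then

$$r_p = \frac{cov_p}{\sqrt{\sigma^2_{p1}\sigma^2_{p2}}},\qquad
  r_g = \frac{cov_g}{\sqrt{\sigma^2_{g1}\sigma^2_{g2}}}.$$

$r_g$ is a ratio of estimated components and can stray outside
$[-1, 1]$; it is reported as computed with an `rg_out_of_range` flag,
because truncating would hide exactly the cases where the estimate is
untrustworthy. Significance for $r_p$ uses the two-sided t
approximation with $g - 2$ degrees of freedom; the same approximation is
attached to $r_g$ for convenience and should be read as approximate —
no exact small-sample test exists for component-based genotypic
correlations.

## Diversity indices and regional partitioning

Across-year genotype means are binned into five classes cut at
$\mu \pm \sigma$ and $\mu \pm 2\sigma$ of the whole-collection means.
The class list convention is ambiguous exactly at the cut points, so one
half-open scheme is pinned down (and unit-tested): class 1
$v \le \mu - 2\sigma$, class 2 $(\mu-2\sigma, \mu-\sigma]$, class 3
$(\mu-\sigma, \mu+\sigma)$, class 4 $[\mu+\sigma, \mu+2\sigma)$, class 5
$v \ge \mu+2\sigma$. Every value lands in exactly one class.

The normalized Shannon–Weaver index of a class distribution is
$H' = -\sum p_i \ln p_i / \ln n$ with $0\ln 0 \equiv 0$. Three
conventions matter and are fixed as follows:

* $n = 5$, the number of *defined* classes, not occupied ones — this
  keeps indices comparable across traits and regions (an occupied-class
  variant sits behind the `occupied_classes` flag);
* regional frequencies are tabulated under the **whole-collection** cut
  points — region-local binning would make the regional mean
  incomparable with the total and break the partition identity;
* each region's index is normalized first, then averaged unweighted
  over regions to give $H'_r$.

The partition is $H'_s = H'_r/H'_t$ within regions and
$G_{st} = (H'_t - H'_r)/H'_t$ between, so $H'_s + G_{st} = 1$ whenever
$H'_t > 0$. With few genotypes per region, sampling can push
$H'_r$ above $H'_t$; the resulting negative $G_{st}$ is reported and
flagged, never clamped. This small-region upward bias of estimated
per-region diversity also means realistic collection-sized simulations
(77 accessions, regions of 7–49) show $G_{st}$ around 0.10–0.20 even
from modest planted shifts; the zero-shift null is tested at 2000
genotypes, where the bias is negligible.

## PCA and Ward clustering

PCA is the eigen-decomposition of the trait correlation matrix of
standardized genotype means, so eigenvalues sum to the trait count and
the eigenvalue-$\ge$-1 retention rule means "keeps more variance than
one standardized trait". Eigenvector signs are fixed (largest loading
positive) for reproducibility across linear-algebra backends; constant
traits are dropped with a warning.

Clustering runs Ward's minimum-variance agglomeration on Euclidean
distances between retained component scores. The classical criterion on
squared distances (`hclust` method `ward.D`) is the default; the
un-squared `ward.D2` dialect is a flag. The tree is cut *relatively*: a
cut fraction of 0.20 undoes every merge above 20% of the maximum merge
height, mirroring the usual dotted-line dendrogram truncation;
fixed-$k$ cuts are also available. Genotypes are sorted by id before
clustering and cluster labels are assigned in order of first
appearance, making assignments invariant to input row order (merge-cost
ties, a measure-zero event for continuous traits, are resolved by
`hclust`'s deterministic ordering). Cluster profiles report per-cluster
means of genotype means and a fixed-effects nested F per trait
(between-cluster over genotype-within-cluster mean square). A REML
mixed-model version of that test would change nothing at the scale of
the designs handled here, so the fixed-effects F was chosen for
transparency.

## Superior-genotype screening

A genotype is superior for a trait when its mean strictly exceeds
$\mu + k\sigma$ of the screened population (or strictly falls below
$\mu - k\sigma$ for lower-better traits: heading time, plant height,
disease scores), $k = 1$ by default. "Exceeds" is implemented strictly
because that is what the word means; an inclusive flag exists. The
thresholds come from the breeding lines themselves — parents are
excluded from the screened population and contribute only the parent
mean $PM$, with the comparison $100(M - PM)/PM$ where $M$ averages the
multi-trait superior lines that are superior for that trait.
Multi-trait superior lines are those superior on at least `k_traits`
(default 6) traits. By default $PM$ averages **all** flagged parents;
a parent subset can be configured when only a specific cross's parents
are the relevant check.

## The trial simulator

`simulate_trial()` draws every effect in the observation model from
zero-mean normals with the configured variances, adds fixed regional
shifts to genotypic means, and returns the realized genotypic values
alongside the data — every estimator above therefore has a
parameter-recovery test with known truth and no external data.
Genotypic effects across traits are drawn jointly through the
positive-semidefinite square root of a genetic correlation matrix;
year, interaction and residual effects stay independent across traits,
so the environmental correlation is zero and genotypic correlations are
expected to exceed phenotypic ones, a tendency the test suite checks.
Draws are genotype-major within trait, so appending a trait never
perturbs an earlier trait's stream, and a config's seed fully
determines the dataset.

Two presets package realistic study conditions:

* `simulate_collection_like()`: 77 accessions from four regions
  (weights 49/12/9/7 over Asia, Europe, Africa, others), 3 years, 3
  blocks, seven agronomic traits. Published between-accession CVs
  describe across-year accession means, so $(CV/100 \cdot \mu)^2$ is
  taken as the phenotypic variance of a genotype mean and the published
  heritability splits it into $\sigma^2_g = h^2 \sigma^2_p$ plus a
  non-genetic remainder divided equally between the interaction and
  residual contributions, which are not published separately. Regional
  shifts are symmetric offsets scaled per trait by its relative
  between-region differentiation, one genotypic SD overall for the
  most-differentiated trait (1000-grain weight) — enough to make
  differentiation clearly detectable without inflating the
  between-accession CVs beyond their published range.
* `simulate_breeding_like()`: 790 lines plus 10 flagged parents, 3
  years, 3 blocks, eleven traits with published $\sigma^2_g$ and
  $\sigma^2_p$; the gap $\sigma^2_p - \sigma^2_g$ is again split
  equally between $\sigma^2_{gy}/y$ and $\sigma^2_e/(ry)$ (for the
  heading-time row this gives $\sigma^2_{gy} = 0.63$,
  $\sigma^2_e = 1.89$ and an analytic $h^2_b$ of 96.09%). Genotypic
  effects use the published genotypic correlation matrix, projected to
  the nearest positive-semidefinite correlation matrix because a
  triangle of independently rounded estimates need not be one. Disease
  scores are clipped to $[0, 9]$ after simulation — a deliberate
  simplification of ordinal scoring; clipping slightly shrinks their
  realized variances, which is why variance-recovery tests use
  unclipped traits.

What the simulator does **not** emulate: non-normal trait
distributions, spatial field trend, unbalanced or lattice designs,
genotype-specific environmental sensitivity (only an unstructured
G-by-year term), ordinal disease scoring, and parents drawn from a
different distribution than the lines (preset parents are ordinary
population draws, so parent contrasts exercise bookkeeping, not
published parent means). Passing recovery tests therefore demonstrate
estimator correctness under the stated model, not robustness to field
realities outside it.

## Numerical choices and problem sizes

Tolerances in the test suite are matched to the check: algebraic
identities at `1e-9`–`1e-12`, quadrature cross-checks at `1e-6`,
Monte-Carlo recoveries at 5–10% with fixed seeds. Heritability recovery
runs 200 replicates of an 800-genotype, 3-year, 3-block trial;
genotypic-correlation recovery 100 replicates at the same size;
planted-partition clustering 50 seeds of two 20-genotype groups
separated by six genotypic SDs; large-sample moment checks use 2000 to
5000 genotypes. These sizes put Monte-Carlo medians well inside the
asserted bands while keeping the whole suite around a minute or two of
compute.

Degenerate inputs are handled explicitly: zero SD at binning (all class
3, warning), zero mean for CVs (undefined, `NA`), zero phenotypic
variance for heritability (`NA`), zero genotypic variance for $r_g$
(`NA`), singleton clusters (mean reported, no within-cluster df), zero
trait SD at screening (empty set, warning).

## Reporting

`run_collection_workflow()` and `run_breeding_workflow()` chain the
stages and write one CSV per report table plus a full-precision JSON.
Report CSVs round for display (2 decimals for indices, heritabilities,
CVs and gains; 1 for means; 3 for the selection intensity); every cell
is a rounded copy of one upstream value — no report-side arithmetic.
With a fixed seed and config the whole bundle is byte-reproducible.
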