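---
title: "Evaluating transitivity in network meta-analysis from study dissimilarities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating transitivity in network meta-analysis from study dissimilarities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmadissim)
```

## The problem

Network meta-analysis (NMA) combines direct and indirect evidence on
multiple treatments, and its validity rests on *transitivity*: the
assumption that effect modifiers — study-level participant and
methodological characteristics that change relative treatment effects — are
similarly distributed across the treatment comparisons of a connected
network. Transitivity is epidemiological in nature and cannot be tested
directly from effect estimates. `nmadissim` operationalizes its empirical
exploration: it quantifies how dissimilar the studies informing each
comparison are (within and between comparisons) and applies hierarchical
clustering to detect "hot spots" of potential intransitivity.

## The dissimilarity model

For studies $x, y$ with $Z$ extracted characteristics, the weighted Gower
coefficient is

$$d(x,y) = \frac{\sum_{i=1}^{Z} w_i\,\delta_{xy,i}\,d(x,y)_i}
                {\sum_{i=1}^{Z} w_i\,\delta_{xy,i}},$$

where $\delta_{xy,i}$ is 1 when characteristic $i$ is observed in both
studies and 0 otherwise, and the per-characteristic dissimilarity
$d(x,y)_i \in [0,1]$ is

* $|x_i - y_i| / R_i$ for quantitative characteristics, with $R_i$ the
  observed range;
* the simple matching indicator $1[x_i \neq y_i]$ for binary and nominal
  characteristics;
* $|\mathrm{rank}(x_i) - \mathrm{rank}(y_i)| / RR_i$ for ordinal
  characteristics, with ranks taken from the declared level order and
  $RR_i$ the observed rank range.

With unit weights and complete data this reduces to the classical
(unweighted) Gower mean. Weights matter when a numeric characteristic is
reported through several summary statistics (for example the minimum and
the maximum of a mean lung-function measure): tying those columns into a
`summary_group` renormalizes their weights to sum to 1, so the underlying
characteristic contributes once.

Multi-arm studies are expanded to one observation per within-study
treatment pair ($\binom{T_i}{2}$ rows for a study with $T_i$ arms), so that
every comparison of a multi-arm study can be contrasted with every other
study; rows of one study are at dissimilarity 0 by construction. The
resulting matrix $\{d\}$ is $\sum_i \binom{T_i}{2}$-square.

For a comparison $p$ informed by $h$ studies, the within-comparison
dissimilarity is the zero-centered root mean square
$D_p^W = \sqrt{\sum_j d_{(j)}^2 / \binom{h}{2}}$ over the pairwise Gower
values among its studies — the spread from complete similarity, not from
the mean; a single-study comparison has $D_p^W = 0$. The between-comparison
dissimilarity $D_{pp'}^B$ is the same RMS over the $h \times h'$ cross
pairs. These populate the diagonal and off-diagonal of the
comparison-by-comparison matrix $\{D\}_{P \times P}$.

## Thresholds of low dissimilarity

Because $D$ values share the $[0,1]$ scale of the $I^2$ inconsistency
statistic, each cell is compared against the median of an empirically
derived predictive distribution of $I^2$ for a future meta-analysis,
indexed by outcome type (all-cause mortality, semi-objective, subjective),
comparator type (pharmacological vs placebo/control, pharmacological vs
pharmacological, non-pharmacological) and average study size (<50, 50–200,
>200 participants), plus a single general-healthcare-setting value of 0.13.
A cell strictly below the median is "low"; otherwise "likely concerning".
The strict rule follows the "falls below the median" definition; exact
equality never arises in practice at reported precision. The three design
factors are user-supplied (`lookup_threshold()`), never inferred from the
data, though `size_bucket()` derives the size class from the unweighted
mean of the study sample sizes.

## Clustering, linkage and partition selection

Hierarchical agglomerative clustering runs on the full expanded matrix
$\{d\}$ through `stats::hclust()`. Seven linkage methods are supported
(average, complete, single, weighted/McQuitty, Ward, centroid, median); the
cophenetic correlation coefficient (CCC) — the Pearson correlation between
the input dissimilarities and the tree-implied merge heights — selects the
linkage. Exact CCC ties are broken by a fixed preference order (average >
complete > single > weighted > ward > centroid > median) so that results
are reproducible; passing a seed restores randomized tie-breaking.

The number of clusters is chosen by silhouette profiling: the tree is cut
at every $k$ from 2 to $n-1$ and the partition with the highest overall
average silhouette width wins (ties go to the smaller $k$). Alongside the
global optimum the profile reports the leading local optima: when a very
fine partition is nominally optimal, the first few local optima often
correspond to more interpretable groupings and are worth inspecting.

A comparison whose expanded rows land in two or more clusters is
*fragmented*; its studies outside the modal cluster are *eloping*. The
report tags the overall pattern with one of four scenarios, ranging from
isolated fragmentation with eloping percentages at or below 5% (the
default minimum noteworthy percentage) to loose partitions with widespread
fragmentation. The scenario rules are this package's operationalization of
a qualitative taxonomy: "few" fragmented comparisons means at most
$\max(1, \lceil 0.05 P\rceil)$ of the $P$ comparisons, and the cluster
count separates the two-cluster (subnetwork split) cases from looser
partitions.

## Numerical choices and edge cases

* **Ranges.** $R_i$ is computed over *study* values, not expanded rows —
  duplicating multi-arm rows cannot change a min–max range, but the study
  set is the cleaner population. A `range` override in the characteristic
  configuration replaces the observed range, for example with a range from
  the review's inclusion criteria when the observed spread is narrow or
  outlier-driven (an observed range makes a 5-year age difference look
  maximal when all studies lie within 5 years of each other).
* **Constant quantitative characteristics** ($R_i = 0$) contribute
  dissimilarity 0 for every pair — all studies agree — with a warning,
  since 0/0 is otherwise undefined.
* **Missing data** are handled solely through $\delta$: a pair's
  coefficient averages over co-observed characteristics only. Pairs with
  *no* co-observed characteristic are flagged undefined, reported, and
  excluded from the RMS aggregation (with counts recorded); clustering
  refuses to run until such pairs are resolved upstream. No imputation is
  attempted.
* **Same-study cross pairs.** When two comparisons of one multi-arm study
  appear in $p$ and $p'$, their zero-valued pairs are included in
  $D_{pp'}^B$ — they are genuine elements of the designated block of
  $\{d\}$ — and their count is recorded for transparency.
* **Ward linkage** operates on squared dissimilarities (the `ward.D2`
  form); since Gower dissimilarities are not Euclidean the variance
  interpretation is heuristic, which is also why average linkage usually
  attains the highest CCC on these matrices.
* **Centroid/median inversions.** Non-monotone merge heights are permitted
  and counted (`inversions` attribute); cutting uses cluster counts, not
  heights, so inversions do not break partitions.
* **Silhouette conventions.** Singleton clusters get width 0; so do
  observations with $a(i) = b(i) = 0$ (exact duplicates split across
  clusters), avoiding 0/0.

## The synthetic generator

`generate_network()` emulates a connected network of $N$ studies over a
configurable comparison design (two- and multi-arm), with studies assigned
round-robin to $K$ planted clusters. Quantitative characteristics are drawn
from cluster-specific normal distributions with unit standard deviation and
means `shift` apart (adjacent clusters differ by `shift` within-cluster
standard deviations, with a random permutation of cluster centres per
characteristic). Qualitative characteristics assign each cluster a distinct
modal level and draw levels with probability proportional to
$\exp(\mathrm{shift} \cdot 1[\text{level is modal}])$, so `shift = 0`
yields identical distributions in every cluster (no signal) and large
shifts concentrate each cluster on its own level. Missingness is applied
completely at random at the configured rate; informative missingness is out
of scope. Everything is reproducible under the configured seed.

What passing recovery tests show — and what they do not: the generator
plants *compact, spherical-ish* structure aligned with the characteristics;
real extraction tables have correlated characteristics, uneven comparison
sizes, reporting artefacts and informative missingness, so recovery on
synthetic data demonstrates the machinery, not performance guarantees on
real reviews.

## Packaged fixtures

`fictional_fixture()` is a seven-study triangle network (three comparisons:
B vs A in three large studies with young participants and adequate
randomization; C vs A in two small studies with old participants and
inadequate randomization; C vs B in between). The cell values are this
package's own construction, chosen so that every within-comparison
dissimilarity is below 0.13, every between-comparison dissimilarity is
above it, and the three comparisons form three clean clusters with the C vs
B cluster closer to C vs A than to B vs A.

`load_synthetic_fixture("ra")` and `load_synthetic_fixture("copd")` load
two *synthetic stand-in* extraction tables mirroring published systematic
reviews: a rheumatoid-arthritis network (27 two-arm placebo-controlled
studies of six biologic agents, 10 characteristics, complete data, mean
study size above 200) and a COPD network (39 studies — 29 two-arm, 4
three-arm, 6 four-arm — over 8 treatments forming 16 comparisons, 11
characteristics of which minimum and maximum FEV$_1$ share a summary group
at weight 0.5 each, and 30 missing cells on the 77-row expansion, i.e.,
3.54%). The stand-ins reproduce the documented *structure* of those
extraction tables — treatments, comparison design, arm structure,
characteristic types, missingness pattern — but their cell values are
synthetic, so dissimilarity and clustering *values* computed from them are
illustrative, not reproductions of the published analyses. They carry
`synthetic` in their file names to keep this explicit.

## A worked run

```{r}
ds <- fictional_fixture()
ana <- run_transitivity(ds, threshold = 0.13)
ana
round(ana$D$values, 2)
```

```{r, fig.width = 6, fig.height = 4}
plot_comparison_heatmap(ana$D)
plot_silhouette_profile(ana$profile)
```

## Problem sizes and limitations

The test suite exercises matrices up to the 77-row COPD-like expansion,
brute-force cross-checks on networks of up to 10 studies, exhaustive
silhouette enumeration at $n = 7$, and generator recovery over 50 seeds of
24-study networks with planted $K \in \{2,3,4\}$ — sizes representative of
published networks, where $\{d\}$ rarely exceeds a few hundred rows.

Known limitations: characteristic weights are user-supplied, not estimated;
purely textual effect modifiers (inclusion criteria, dosing detail) are out
of scope; the $I^2$-based thresholds are a provisional convention rather
than field-specific empirical values; and silhouette-based partition
selection can favour very fine partitions when many near-duplicate studies
are present — inspect the reported local optima rather than the global
argmax alone.
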