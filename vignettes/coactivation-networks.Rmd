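---
title: "Co-activation networks from regional expression data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-activation networks from regional expression data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coactnet)
```

## The problem

Immunohistochemical markers of neuronal activity and plasticity (c-fos, Arc,
phosphorylated CREB) are measured post mortem, so each animal contributes a
single number per brain region. Task-evoked "functional connectivity" in such
experiments is therefore defined **across subjects**: two regions are
co-active when their expression densities covary over the animals of a group.
`coactnet` implements the full analysis chain built on that idea, as used in
lesion studies of contextual fear conditioning: a control group and a
lesioned group each yield an inter-regional correlation matrix; thresholding
those matrices yields weighted networks; and network topology, hub structure
and edge strength are compared between groups.

## Network construction

For a group with $n$ subjects and $R$ regions, the Pearson coefficient
$r_{ij}$ is computed for every unordered region pair ($R(R-1)/2$
coefficients; 435 for 30 regions, 351 for 27). Each coefficient gets an
exact two-tailed p-value from the $t$ transform

$$t = r\sqrt{\frac{n-2}{1-r^2}}, \qquad t \sim t_{n-2},$$

and a network retains the pairs with $p \le \alpha$ at each of three
uncorrected thresholds, by default $\alpha \in \{0.05, 0.025, 0.01\}$.
Thresholds are deliberately uncorrected: the aim is to strip coefficients
indistinguishable from chance, not to control a family-wise error rate on
edges. The threshold is non-strict ($\le$), matching the usual "$p \le
0.05$" phrasing.

Edges are weighted by $|r|$, with the signed coefficient kept as an
attribute, and shortest-path computations use the distance view $1 - |r|$.
Using $|r|$ rather than $r$ in both places keeps weights in $(0, 1]$ and
distances in $[0, 1)$ even when negative correlations survive a threshold;
when none do (as in the data this workflow was designed around), the two
conventions coincide. Missing cells are an input error, never imputed:
silent pairwise-complete correlation would change $n$ per pair and corrupt
the p-values.

When the groups cover different region sets (a lesioned group lacks the
damaged regions), the control matrix is recomputed on the lesioned group's
region set (`drop_regions()`); all between-group comparisons are made on
that common node set, since the centrality and edge statistics are not
comparable across networks of different size.

## Efficiency and small-worldness

Integration is measured by global efficiency, the mean inverse shortest-path
length over all unordered node pairs; segregation by mean local efficiency,
the global efficiency of each node's neighbor-induced subgraph, averaged over
nodes. Unreachable pairs contribute zero while staying in the denominator
(the standard harmonic-mean convention), so both are defined on the
fragmented networks that the strictest threshold produces; nodes with fewer
than two neighbors have local efficiency zero. This zero-contribution
convention, rather than restriction to the largest component, is a design
choice and is the main place where a disconnection convention matters.

Small-worldness is assessed against an ensemble of degree-preserving
rewired null networks. Each null applies $\lfloor E/2 \rfloor$ successful
double-edge swaps to a copy of the network (swaps creating self-loops or
duplicate edges are rejected and retried), with edge weights travelling
with the swapped edges, so every null has exactly the empirical degree
sequence and weight multiset. Per null, the empirical/random ratio of
global efficiency and of mean local efficiency is recorded; the 95%
percentile interval of each ratio summarizes the ensemble. A network is
called small-world when its mean-local-efficiency ratio interval lies
entirely above 1, with the global-efficiency ratio expected near 1; two
networks are called different on a ratio when their 95% intervals do not
overlap. In community-structured networks the global-efficiency ratio
typically sits somewhat below 1 (rewiring shortens paths), which is
consistent with the "around 1" expectation of the small-world account.
A null whose nodes happen to have edgeless neighbor subgraphs would have
mean local efficiency zero; its ratio is recorded as `NA` and excluded from
the interval (this does not occur at the edge densities this analysis
works at).

## Hubs

Four centralities are computed per region: weighted degree (sum of incident
$|r|$), eigenvector centrality (principal eigenvector of the weighted
adjacency, max-normalized to $[0,1]$), closeness and betweenness (both on
$1 - |r|$ distances). Two conventions for fragmented networks: eigenvector
scores follow the dominant component (largest leading eigenvalue) with all
other nodes at zero, and closeness scales each node's classical closeness by
its reachable fraction, $\mathrm{Clo}_i = \frac{k_i}{\sum_{j}d_{ij}} \cdot
\frac{k_i}{R-1}$ over reachable $j$, so nodes in small fragments are
penalized rather than spuriously central. Isolates score zero on all four.

A region is a hub of one network when it lies in the upper quartile
($\lceil 0.25R \rceil$ regions, ties at the cutoff all included) of at
least three of the four metrics — requiring three of four guarantees at
least one connection-based (degree, eigenvector) and one distance-based
(closeness, betweenness) metric. A stable hub is a hub at every threshold;
each region's hub score counts the thresholds at which it was a hub. The
rule is rank-based, hence invariant to monotone transformations of any one
metric.

## Group comparisons

**Centrality permutation test.** For two groups on an identical region set,
group labels are permuted without replacement and the entire
correlation → threshold → centrality pipeline is recomputed inside every
permutation — group membership enters the analysis only through the
correlation matrices, so permuting anything less would not propagate the
null. The empirical difference $\mathrm{Diff} = C_A - C_B$ per (region,
metric) is referred to the permutation distribution; the default p-value is
two-sided, $\Pr(|\mathrm{Diff}^\ast| \ge |\mathrm{Diff}|)$, because
differences in either direction are of interest; the one-sided
resampled-greater form and the add-one $(b+1)/(m+1)$ convention are
available as options. Cells are reported uncorrected, as per-cell evidence.

**Edge comparison.** The two networks' surviving coefficients are Fisher-Z
transformed, $Z = \operatorname{arctanh}(r)$; their distributions are
compared by a two-sample Kolmogorov–Smirnov test (asymptotic p), and every
cell retained in at least one network gets a difference z-score

$$dC = \frac{Z_A - Z_B}{\sqrt{\frac{1}{df_A-3} + \frac{1}{df_B-3}}},$$

the standard two-correlation comparison, with $df$ the group's subject
count so that the Fisher-Z variance is the textbook $1/(n-3)$ (an $n-2$
variant is switchable). $|dC| > 2$ is called significant; each significant
cell is assigned to the owner group (larger $Z$) and annotated with whether
it touches one of that group's hubs. For a cell surviving in only one
network, the absent side contributes its **unthresholded** coefficient by
default: treating a just-sub-threshold coefficient as exactly zero
manufactures large $dC$ values out of the thresholding rule rather than the
data. The thresholded-as-zero mode is available for comparison.

**Behavioral statistics.** Freezing times are compared by a classical
one-way F statistic whose p-value comes from a bootstrap null: subjects are
resampled with replacement from the pooled sample and reassigned
positionally to the original group slots — pooling is what breaks the
group–outcome link and makes the resampled statistics a null distribution —
and $p$ is the fraction of resampled statistics strictly exceeding the
empirical one. Pairwise comparisons use Welch $t$ (the safer default when
variances are unspecified; the bootstrap p does not rely on the statistic's
parametric null anyway) with the same bootstrap scheme on $|t|$ and
Bonferroni correction over the concomitant comparisons; per-region
expression comparisons use the same bootstrap $t$ with Benjamini–Hochberg
FDR across regions. Cohen's $d$ uses the $n-1$-weighted pooled SD and is
reported as a magnitude. Confidence intervals of means use the ordinary
percentile bootstrap (within-sample, no label breaking).

## The synthetic-data generator

Because each subject contributes one number per region, the analysis sees
only the second-order structure of the data; the generator is therefore a
truncated multivariate normal — the simplest family matching those
assumptions. A scenario fixes a region set, a community partition with
target within- and between-community correlations, designated hub regions
with elevated cross-community correlation, and per-group sample sizes,
density location/scale and edge modifications (correlation deltas on a pair
or a region's whole neighborhood). Modified target matrices are repaired to
the nearest positive-semidefinite correlation matrix by eigenvalue clipping
with re-normalized unit diagonal.

Defaults, chosen once as the package's study conditions:

- 30 regions (the default catalogue) with the six anatomical systems as
  communities; within-community $r = 0.7$, between $= 0.3$. These produce
  edge counts centered in the same range as real pCREB-cohort networks
  (median near 90 edges at $\alpha = 0.05$ for $n \approx 9$), with the
  large draw-to-draw spread that cross-subject correlation matrices
  genuinely have at cohort size — whole-matrix inflation by a single
  high-expressing animal is part of what the generator reproduces.
- Hub elevation $r = 0.65$ on a hub's cross-community pairs. This is what
  "a planted high-strength hub" means here: at cohort size ($n = 9$) such a
  region is recovered by the quartile-intersection rule in about 95% of
  datasets, whereas an elevation of 0.6 is recovered only ~85% of the time
  — i.e. 0.6 is not decisively high-strength at this sample size.
- Groups of 9 (control, all 30 regions) and 10 (lesioned, 27 regions),
  mirroring a typical immunolabelling cohort; the control group's RSC and
  Per_36 neighborhoods are weakened by 0.4 and the lesioned group's IL
  neighborhood by 0.4, so that the two groups develop different hubs from a
  shared backbone.
- Densities with mean 1000 nuclei/mm² and SD 150: means at least 3 SDs
  above zero keep the truncation mass well under 1%, so the normal
  correlation targets survive truncation essentially unchanged.
- Behavior: group means 170/135/68 s (SD 55/55/30) for
  control/lesioned/immediate-shock at $n$ = 12/12/8 over a 300 s session.
  These encode the canonical behavioral result — no control-vs-lesion
  difference beyond a small-to-medium effect ($d \approx 0.64$ analytic)
  and a large deficit in the immediate-shock group ($d \approx 2.2$) —
  at conventional freezing-time variability.

`null_twin()` strips all edge modifications from a scenario, giving two
groups one shared correlation structure; it is the basis of the
type-I-error suites.

**What the generator does not emulate:** measurement error structure of
nuclei counting, region-size-dependent density variance, non-Gaussian tails,
inter-animal batch effects, or any mechanistic neural dynamics. Passing
tests on this generator show that the pipeline recovers the second-order
structure it is pointed at; they are not evidence about biological claims.

## Numerical choices

- Shortest paths: igraph's Dijkstra for user-facing functions; a vectorized
  Floyd–Warshall on dense matrices inside the permutation and rewiring
  loops (unit-tested for exact agreement). Edge distances are floored at
  $10^{-12}$ so that $|r| = 1$ edges cannot produce zero-length cycles.
- Thresholding inside permutations uses the critical-$|r|$ form of the
  p-threshold ($p \le \alpha \iff |r| \ge r_{crit}(n, \alpha)$), which is
  algebraically identical to the p-value rule.
- Eigenvector centrality is computed per connected component by dense
  symmetric eigendecomposition; component ties are broken by the larger
  leading eigenvalue.
- Rewiring retries are bounded (200 attempts per requested swap); a graph
  admitting no legal swap errors out rather than spinning.
- The quartile cutoff is the $\lceil 0.25R \rceil$-th largest value per
  metric with inclusive ties, so hub calls never depend on the sort order
  of tied regions.

## Problem sizes used by the checks

The package's own verification suites run at sizes chosen to give stable
Monte Carlo estimates while staying lightweight: type-I-error suites use
500 null-twin datasets with 500 resamples/permutations each (on a
12-region, two-community scenario for the permutation test); hub recovery
and weakened-hub power use 200 datasets; the percentile-CI coverage check
uses 1000 datasets of 500 resamples; null ensembles in examples use
150–1000 rewirings, and the reproduction script uses 1000 rewirings, 2000
permutations and 10000 bootstrap resamples. The weakened-hub power suite
runs at $n = 50$ per group: per-region centrality inference at cohort size
($n \approx 10$) has power around 30% for a 0.4 weakening — a real
limitation of cross-subject co-activation designs worth knowing when
interpreting single-cohort hub contrasts — while at $n = 50$ the same
effect is detected essentially always.

## Known limitations

- Cross-subject correlation networks confound inter-individual variability
  with co-activation; nothing in the pipeline can separate the two.
- The uncorrected thresholds are a screening rule, not error control; edge
  counts are threshold-dependent by construction.
- The permutation test recomputes thresholds inside permutations; whether
  to fix the graphs instead is a genuine modeling fork (the recomputation
  propagates the null completely, and is the default here).
- Small cohorts make per-region centrality comparisons low-powered (see
  above); stable hubs across thresholds are the more robust readout.
- The KS p-value is asymptotic; with the edge-set sizes involved
  (tens to ~150) that approximation is adequate but not exact.
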