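---
title: "Temporal disease networks: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal disease networks: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdnet)
```

## The model

`tdnet` turns longitudinal outpatient diagnosis records into a directed,
statistically filtered **Temporal Disease Network (TDN)**. The object of
study is the order in which diseases first appear in patients' records.

Each patient's history is reduced to a *path*: the list of 3-digit ICD-9-CM
disease categories ordered by the visit date of their **first occurrence**.
Only first occurrences are used because repeat codes in administrative data
overwhelmingly reflect the management of an already-diagnosed condition, not
a new clinical event. Codes first seen on the same date share a *bucket*;
ICD-9 supplementary-classification codes (V and E chapters) are not diseases
and are excluded.

Transitions connect consecutive buckets bipartitely: every code of a bucket
is linked to every code of the next bucket, with no intra-bucket and no
skip edges, and no restriction on the time elapsed between the two dates.
Because each 3-digit code occurs at most once per patient, a patient
contributes at most one count to any ordered pair, so the edge weight
$w_{ij}$ is the number of patients whose record shows disease $i$
immediately preceding disease $j$ in first-occurrence order.

### Edge significance

Raw co-occurrence counts mix real precedence tendencies with the marginal
popularity of each diagnosis. Each directed pair is therefore tested with a
one-sided Fisher exact test on the transition-event contingency table

|              | target $= j$ | target $\neq j$ |
|--------------|--------------|-----------------|
| source $= i$ | $a = w_{ij}$ | $b$             |
| source $\neq i$ | $c$       | $d$             |

with alternative "greater" (enrichment of $i \to j$), i.e. the exact
hypergeometric tail $P(X \ge a)$ with all margins fixed. The edge
correlation is summarized by the $\phi$ coefficient
$(ad-bc)/\sqrt{(a{+}b)(c{+}d)(a{+}c)(b{+}d)}$, defined as 0 whenever a
marginal is zero. The table is built over *transition events* — the same
objects that define $w_{ij}$ — which directly measures the tendency of one
disease to precede another; a patient-level table is a conceivable
alternative, and the configuration reserves a `contingency_mode` key for it.

### Filters

Four filters are applied, in this order (counts removed at each stage are
recorded in the network's provenance):

1. **Node prevalence** — diagnoses carried by fewer patients than the 10th
   percentile (nearest-rank) of the prevalence distribution are dropped with
   all incident edges; an explicit minimum count can override the
   percentile. Low-prevalence codes in administrative data are dominated by
   miscoding.
2. **Pair count** — edges observed in fewer than `min_pair` patients
   (default 100) are dropped.
3. **Death diagnoses** — edges incident (in either direction) to a death
   code are dropped; a disease "followed by" a death diagnosis is an
   erroneous entry. The default death-code set is `"798"` (sudden death,
   cause unknown); real extracts should configure the local convention.
4. **Significance** — Benjamini–Hochberg correction at $\alpha = 0.05$ over
   the *tested family*, defined as the edges surviving steps 1–3. Running
   BH after the data-cleaning filters keeps the multiplicity correction
   aligned with the hypotheses actually under consideration; users probing
   sensitivity to this ordering can compare `bh_family_size` in the
   provenance across configurations.

### Centralities and fatality

Three node metrics characterize the TDN: the weighted degree $K_w$ (total
incoming plus outgoing patient flow of a disease), PageRank (stationary
density of damped random walkers — the expected flow of patients through a
diagnosis; damping 0.85, uniform teleport and dangling redistribution), and
betweenness centrality (how often a disease lies on shortest progression
routes between others). Betweenness uses $1/w$ edge distances by default so
that heavily travelled edges are short, consistent with the trajectory
metric below; an unweighted variant is available because hop-count
betweenness is also common.

*Fatality* is the fraction of patients dead within 8 years of their first
diagnosis of a disease. The denominator contains only patients whose
follow-up covers the full horizon or who died within it; recently diagnosed
survivors carry no information about the 8-year outcome and would bias the
estimate downward if counted. Rank relationships among metrics are assessed
with Spearman correlations (average ranks for ties, pairwise deletion of
missing fatality values).

### Communities

Flow communities are detected with the two-level map equation (Infomap),
which compresses the description length of a random walk that uses the
edge weights as relative transition rates. Communities with fewer than 5
diseases are discarded; the survivors are ranked by their total member flow
— computed as the stationary visit rate of the damped walk (teleportation
0.15) — and labeled `TDN1`, `TDN2`, ... so that a lower index means more
patient flow. Ties in flow are broken by larger size, then by smallest
member code, making labels reproducible. The Infomap optimization itself is
stochastic; `detect_communities()` takes a trial count and a seed and is
deterministic given both.

Community heterogeneity with respect to the canonical ICD-9 chapter
grouping is scored by the normalized chapter entropy

$$H = \sum_i \frac{-1}{\log_2(n)}\, p_i \log_2(p_i),$$

where $p_i$ is the proportion of the community's $n$ member diseases from
chapter $i$. $H = 0$ iff all members share a chapter and $H = 1$ iff every
member is from a distinct chapter. Note the normalization constant uses the
community size $n$, not the number of chapters; a singleton community is
defined to have $H = 0$ (the normalization is otherwise undefined, and a
single disease is trivially homogeneous). The 17 main ICD-9-CM chapters are
bundled (`icd9_chapters()`) and overridable.

### Trajectories

The most likely progression route between two diagnoses is the minimum-cost
directed path under inverted weights: each edge's distance is $w_{ij}^{-1}$,
so heavily travelled steps are cheap. All co-optimal paths are returned —
real networks tie, and picking one arbitrarily would make results depend on
traversal order; returning all, in lexicographic node order, keeps queries
deterministic. Chapter-wide queries (`trajectories_to_set()`) aggregate the
per-target trajectories into a trajectory network whose edge multiplicity
counts how many trajectories traverse each step; unreachable targets are
skipped and counted rather than fatal. Trajectory queries run on the fully
filtered TDN.

## The synthetic cohort generator

Real clinical extracts of this kind cannot be shared, so the generator is a
first-class module: it emulates the *structure* of such data with known
ground truth, making every pipeline stage testable.

What it emulates: multiple visits per patient (geometric-like visit count,
mean 8, minimum 2); several codes per visit date; raw codes with 4th/5th
digits and interspersed V/E rows; patient ages and sexes including decoy
patients that the cohort filters must remove (female, older than 99 years);
deaths triggered by planted per-disease 8-year death probabilities, with
the death date uniform in the window and no records after death; planted
directed precedence tendencies (a fraction `co_rate` of patients acquires
both diseases of a pair on consecutive visits, the source first with
probability $0.5 + \text{excess}/2$); and planted disease blocks whose
members co-occur on consecutive visits in random order, generating high
within-block flow.

Defaults were chosen once as a realistic desk-scale stand-in: 20 background
codes at a 0.6 per-visit diagnosis rate, co-affection rate 0.2 for planted
pairs, block participation 0.25, visit gaps of 7–120 days over a 2002–2018
window. What it does **not** emulate: realistic marginal prevalences of the
full ICD-9 vocabulary, age- or sex-dependent disease risks, coding drift
over calendar time, or recurrence dynamics. Passing tests on synthetic
cohorts therefore demonstrate that the machinery recovers known structure
at realistic signal strengths — not that any specific clinical finding
generalizes.

One instructive interaction surfaced by the generator: planted-pair
diseases occur in about `co_rate * n_patients` patients, which with the
default background sits near the 10th percentile of the prevalence
distribution, so the node-prevalence filter occasionally removes a genuine
planted disease. The validation suite therefore scores the planted pair
against the significance filter (the filter the signal is planted to
test), and the interaction is a useful reminder that the prevalence filter
trades sensitivity for robustness on real data too.

## Numerical choices and degenerate inputs

- Fisher p-values are exact hypergeometric tails; the test suite checks
  them against exhaustive choose()-product enumeration for **all** 2×2
  tables with $N \le 50$ to $10^{-12}$.
- $\phi$ with any zero marginal is 0; contingency cells are promoted to
  double before multiplication (the product of four margins overflows
  32-bit integers already at desk scale).
- The prevalence threshold uses the nearest-rank percentile (the
  $\lceil P/100 \cdot n \rceil$-th order statistic), so it is always an
  observed value.
- PageRank: damping 0.85, tolerance handled by igraph's PRPACK solver;
  validated against dense power iteration to $10^{-8}$.
- Shortest-path ties are co-optimal at exact floating-point equality; test
  fixtures use power-of-two weights so reciprocal path costs are exact.
- Empty inputs return typed empty tables; an empty network is an error for
  community detection and centralities (nothing to summarize).
- All-zero contingency tables give $p = 1$; a constant vector makes
  Spearman's $\rho$ undefined (`NA`), and such nodes are dropped pairwise
  from correlation summaries.

## Problem sizes used in validation

The packaged validation runs at desk scale, chosen so the full suite
completes in well under a minute of compute per stochastic block: planted
precedence pairs use 50 replicates of 2,000-patient cohorts; the null
false-positive check uses five 2,000-patient cohorts; community recovery
uses one 1,000-patient cohort with three planted blocks; graph-algorithm
oracles enumerate exhaustively on graphs of up to 8 nodes. Headline sizes
from multi-million-patient clinical systems (hundreds of nodes, tens of
thousands of edges) are not reproducible from synthetic desk-scale data and
are not targets of the test suite.

## Known limitations

- The transition-event contingency table is one defensible reading of a
  pairwise precedence test; a patient-level table (patients as trials)
  would weight multi-morbid patients differently.
- Fatality is a fixed-horizon fraction, not a survival model; no
  censoring-time weighting or competing risks.
- The two-level map equation is used; a hierarchical variant could split
  large communities further.
- Community flow is the damped-walk visit rate, computed alongside (not
  inside) the Infomap optimization.
- Trajectory multiplicities count query trajectories, not patients; the
  framework deliberately does not claim per-patient trajectory frequencies.
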