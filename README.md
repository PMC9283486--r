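# tdnet — Temporal Disease Networks from longitudinal diagnosis records

`tdnet` is an R package for epidemiologists and health-services researchers
who want to mine the *order* in which diseases first appear in longitudinal
outpatient records. It converts visit-level ICD-9-CM diagnosis data into a
directed, statistically filtered **Temporal Disease Network (TDN)**, and
provides the downstream analyses that make such a network useful:
centrality and fatality profiling, flow-based community detection, and
most-likely disease trajectory extraction.

## The method in brief

For each patient, the package keeps the **first occurrence** of every
3-digit ICD-9 category (V/E supplementary codes excluded) and orders them by
visit date; same-date diagnoses share a bucket. Every code of a bucket is
linked to every code of the next bucket, so the directed edge weight
*w<sub>ij</sub>* counts patients whose record shows disease *i* immediately
preceding disease *j* in first-occurrence order.

Each directed pair is tested with a one-sided Fisher exact test on the
transition-event 2×2 table (exact hypergeometric tail *P(X ≥ a)*), with
Benjamini–Hochberg correction; edges also carry the φ coefficient
(ad − bc)/√((a+b)(c+d)(a+c)(b+d)). The network is then filtered: nodes below
the 10th prevalence percentile, pairs with fewer than 100 patients, edges
touching death-diagnosis codes, and edges with adjusted p ≥ 0.05.

On the filtered TDN:

- **Centrality & fatality** — weighted degree K<sub>w</sub>, PageRank
  (random-walk patient flow), betweenness (1/w distances), the fraction of
  patients dead within 8 years of first diagnosis, and their Spearman rank
  correlations.
- **Communities** — two-level map-equation (Infomap) partition; communities
  with ≥ 5 diseases are labeled TDN1, TDN2, … by descending patient flow and
  scored with the normalized chapter entropy
  *H = Σ −p<sub>i</sub> log₂(p<sub>i</sub>) / log₂(n)* (0 = one chapter,
  1 = every member from a distinct chapter).
- **Trajectories** — minimum-cost directed paths under inverted weights
  w<sup>−1</sup>, aggregated over one-to-many queries (e.g. one disease to a
  whole ICD-9 chapter) into a trajectory network.

Because real clinical extracts of this kind are not shareable, the package
includes a **synthetic cohort generator** with planted ground truth
(precedence pairs, disease blocks, death probabilities) and a recovery
report, so the full pipeline is testable end to end.

## Worked example

Generate a cohort with one planted precedence tendency (colon cancer 153 →
secondary malignancy 197), one planted fracture block, and a lethal
disease; then run the pipeline and check recovery:

```r
library(tdnet)

spec <- cohort_spec(
  n_patients       = 1000,
  precedence_pairs = list(list(i = "153", j = "197", excess = 0.9, co_rate = 0.3)),
  disease_blocks   = list(list(members = c("810", "812", "813", "820", "823"),
                               within_prob = 0.9, participation = 0.3)),
  death_model      = c("153" = 0.6),
  seed             = 42)
cohort <- generate_cohort(spec)

paths <- extract_paths(filter_cohort(parse_records(cohort$visits),
                                     parse_patients(cohort$patients)))
net <- build_tdn(paths, min_pair = 20)
net
#> Temporal Disease Network: 7 nodes, 21 edges
#>   filters: prevalence (thr 187): -2 nodes/-102 edges; pair<20: -578; death codes: -0; BH alpha 0.05: -1

net$edges[order(p_adj)][1:2, .(source, target, w, p_adj = signif(p_adj, 3), phi = round(phi, 3))]
#>    source target     w     p_adj   phi
#> 1:    153    197   255 3.62e-178 0.491
#> 2:    820    810    62  1.05e-14 0.122
```

The planted 153 → 197 edge is the strongest in the network (255 patients,
adjusted p ≈ 10⁻¹⁷⁸). The fracture block forms a single flow community with
H = 0 (all members from the Injury And Poisoning chapter):

```r
part <- detect_communities(net, trials = 10, seed = 1)
filter_and_label(part, min_size = 5)[, .(label, n, flow = round(flow, 3), h = round(h, 3))]
#>    label     n  flow     h
#> 1:  TDN1     5 0.921     0

shortest_trajectory(net, "153", "197")[[1]]
#> $nodes: "153" "197"     $cost: 0.00392

ground_truth_report(cohort$truth, net, part)[c("edge_recall", "edge_precision", "partition_exact")]
#> $edge_recall 1   $edge_precision 1   $partition_exact TRUE
```

Every planted edge is recovered with nothing spurious, and the planted
block partition is matched exactly.

A full run — including fatality, correlations, community summaries,
chapter incidence and trajectory exports plus a provenance report — is one
call (`run_pipeline()`), also available from a shell via the thin CLI in
`inst/cli/tdn.R` (`simulate`, `run-all`, `trajectory` subcommands).

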