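# famdyn

Gene-family (orthogroup) copy-number dynamics on time-calibrated
phylogenies, and the parallel-versus-convergent bookkeeping needed to
compare independent habitat transitions — built for studies of repeated
subterranean colonization, where several unrelated lineages move
underground and the question is whether the *same* gene families shift
(parallel evolution) or *different* families with *similar functions*
shift (functional convergence).

## What it does

famdyn models each orthogroup's copy number $n$ as a
birth–death–innovation (BDI) Markov chain along every branch of a time
tree, with up-rate $n\beta + \iota$ and down-rate $n\delta$ (per Myr).
Per orthogroup it fits, by maximum likelihood over discrete count
states (Felsenstein pruning, uniformization of the tridiagonal
generator):

* a **global-rates (GR)** model — one $(\beta, \delta, \iota)$ for all
  branches — and
* a **branch-specific (SR)** model — separate rates for a designated
  foreground branch class (e.g. branches where lineages became
  subterranean),

compares them by AIC ($2k - 2\ln L$; significant when
$\mathrm{AIC}_{SR} + 2 \le \mathrm{AIC}_{GR}$), and reports the
direction and magnitude of the foreground shift via the net rate
$\beta - \delta$. Downstream it reconstructs ancestral copy numbers
(max-marginal, up–down pass), parses every branch into gene
gains/losses and orthogroup expansions/contractions/originations/
losses, intersects per-lineage lists into Venn cells (parallel = shared
by ≥ 2 lineages), clusters lineage-exclusive orthogroups by Wang GO
semantic similarity with affinity propagation (exemplar = the
cluster's "centroid" function), embeds them in 2-D by classical MDS
for constellation-style displays, and runs Fisher/Benjamini–Hochberg
GO enrichment against branch-specific backgrounds. A fully seeded
synthetic-data generator (Gillespie simulation of the BDI process,
themed ontologies, planted annotations) makes the whole chain testable
without any external data.

## Worked example

The built-in demo emulates a three-tribe beetle study with six
independent subterranean transitions (aquatic B1, B2, H1; terrestrial
L1, L2, L3) on a fixed 20-Myr tree; 20% of 200 families carry a 5×
birth shift on all six transition branches, per-lineage blocks carry
it on one branch only, and annotations come from four planted
functional themes:

```r
library(famdyn)

cfg <- demo_config(seed = 7)
res <- run_pipeline(cfg, out_dir = "demo_out")
res$report
```

```
  n_og n_converged n_significant pct_significant n_expanded n_contracted
1  200         200            48              24         45            3
  pct_expanded pct_contracted n_parallel_expanded n_exclusive_expanded
1        93.75           6.25                 177                   17
  n_parallel_contracted n_exclusive_contracted n_clusters_expanded
1                    58                     71                   4
  ogs_per_cluster_expanded n_clusters_contracted ogs_per_cluster_contracted
1                     4.25                     4                      17.75
  power direction_accuracy parallel_recall  fpr theme_ari
1 0.925           0.972973               1 0.01         1
```

Reading the key columns: 24% of families are called significant under
the branch-specific model, 93.75% of them as expansions; 92.5% of the
truly shifted families are recovered (`power`) at a 1% false-positive
rate, 97% of the recovered shifts are correctly called expansions
(`direction_accuracy`), every planted parallel family lands in a
multi-lineage Venn cell (`parallel_recall`), and the
affinity-propagation clusters recover the planted functional themes
exactly (`theme_ari` = 1). `demo_out/` holds the per-stage tables
(calls, ancestral states, branch changes and summaries, per-branch
orthogroup lists, overlap reports, cluster memberships and
coordinates, enrichment results). The demo takes a few minutes on one
core; the per-family maximum-likelihood fits dominate.

Individual stages are ordinary data-frame-in/tibble-out functions —
`fit_all()`, `ancestral_states()`, `branch_changes()`,
`overlap_report()`, `og_similarity_matrix()`, `build_clusters()`,
`go_enrichment()` — so any slice of the pipeline can be run or
inspected on its own; fitted objects have `tidy()`/`glance()` methods
and result objects have `autoplot()` methods.

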