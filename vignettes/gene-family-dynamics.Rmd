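---
title: "Modelling gene-repertoire dynamics and functional convergence with famdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling gene-repertoire dynamics and functional convergence with famdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famdyn)
```

## The scientific problem

When distantly related lineages move into the same extreme habitat --
here, subterranean life, colonized independently by several beetle
lineages -- their gene repertoires can respond in two distinguishable
ways. *Parallel* evolution means the **same** gene families (orthogroups)
shift their copy-number dynamics in two or more independent lineages.
*Convergent* evolution means **different**, lineage-exclusive families
shift, but the shifted families carry similar functional annotations, so
the lineages converge functionally rather than genically. famdyn
implements the full analytical chain needed to make those calls from a
time-calibrated species tree, an orthogroup-by-species count table and
per-orthogroup GO annotations -- and, because the real inputs require
heavyweight upstream inference (assembly, orthology, dating,
annotation), it ships a fully seeded synthetic-data generator that
emulates their statistical structure, so every stage is testable end to
end on a laptop.

## The birth-death-innovation model

Copy number $n$ of one orthogroup evolves along each branch as a
continuous-time Markov chain with

* up-rate $\;u(n) = n\beta + \iota$,
* down-rate $\;d(n) = n\delta$,

where $\beta$ is the per-gene birth (duplication) rate, $\delta$ the
per-gene death (loss) rate and $\iota$ the per-family innovation rate
(gain from zero), all per Myr. The **net rate** $\beta - \delta$
measures net family expansion. Two model classes are fitted per
orthogroup by maximum likelihood:

* **GR** (global rates): one $(\beta,\delta,\iota)$ triple for every
  branch (3 free parameters);
* **SR** (branch-specific rates): separate triples for the background
  and for a designated foreground branch class, e.g. the branches on
  which lineages became subterranean (6 free parameters).

The likelihood of one orthogroup's tip counts is computed by
Felsenstein pruning over the discrete count states $0..n_{\max}$: tip
partials are indicator vectors, each branch applies its class's
transition operator, and the root combines with a prior. Models are
compared with AIC ($2k - 2\ln L$); an orthogroup is called significant
when $\mathrm{AIC}_{SR} + \Delta \le \mathrm{AIC}_{GR}$ with
$\Delta = 2$ by default (a conventional support level; set
`threshold = 0` to reproduce plain arg-min selection -- the choice is
exposed because published analyses of this kind rarely state their
cut). The direction of a significant shift is "expanded" when the
foreground-minus-background net rate is positive, and its magnitude is
that difference.

## Numerical choices

**Transition operator.** The truncated generator is tridiagonal with a
leaking boundary (from $n_{\max}$ the up-rate leaves the state space),
so rows of $P(t)$ sum to $1-$leak. All exponentials use
*uniformization* -- Poisson-weighted powers of $M = I + Q/q$ -- which
is unconditionally stable and guarantees nonnegative probabilities.
The likelihood never forms $P(t)$: it propagates vectors through the
tridiagonal operator at $O(3n)$ per Poisson term, with long intervals
split into segments of $qt \le 500$ and per-segment rescaling. A
spectral (symmetrized eigendecomposition) alternative was evaluated
and rejected: the back-transform multiplies by
$\exp((\mathrm{lpi}_k-\mathrm{lpi}_j)/2)$ factors that amplify
rounding error as $e^{\mathrm{range}} \times 10^{-16}$, which becomes
catastrophic precisely in the foreground regime $\beta \gg \delta$ the
SR model is designed to detect. The full-matrix form (exported as
`transition_matrix()`) adds scaling-and-squaring for long intervals
and is cross-checked in the test suite against an independent
Taylor-series matrix exponential to $10^{-9}$.

**Truncation.** Default $n_{\max} = 3\max(\text{observed},5)$ per
orthogroup for small families, bounded by
$m + \lceil 3\sqrt m\rceil + 10$ for large ones: copy-number
fluctuations scale as $\sqrt n$, so mass far above the observed
maximum is negligible while tripling a large state space only slows
the likelihood (uniformization cost grows with $q t n$ and
$q \propto n_{\max}$). Rows near the boundary always leak, so the
truncation-tolerance check applies to start states
$0..\lfloor n_{\max}/3\rfloor$ (the range observed data occupy under
the default rule); `check_states` overrides this, and an explicit
larger `n_max` can always be passed when a truncation error asks for
one.

**Root prior.** The low-level likelihood defaults to uniform over
$0..n_{\max}$ (making the zero-rate degenerate case exactly
$\log 1/(n_{\max}{+}1)$), but *fitting* defaults to the stationary
distribution of the proposed chain, recomputed at every likelihood
evaluation from the background-class rates. A flat prior is not
neutral here: it loads most of its mass onto large ancestral counts,
and the maximizer then prefers birth-free, death-heavy rate sets that
collapse any large root onto the small observed counts --
a several-fold upward bias in the death rate in simulation. The
stationary prior removes the bias and matches what reference
implementations of this model family do; exact numerical agreement
with any particular tool's undocumented prior is still not claimed.
Ancestral reconstruction under fitted models uses the same stationary
prior.

**Optimization.** Log-rate space with bounds $[10^{-8}, 10]$ per Myr,
five seed-controlled starts: two fixed heuristics (slow turnover,
all rates 0.01; moderate turnover, $(0.1, 0.05, 0.02)$) plus
stratified log-uniform draws on $[10^{-4}, 0.3]$. Each start gets a
short Nelder-Mead screen, the winner a longer Nelder-Mead refinement
and a capped L-BFGS-B polish; simplex phases use a soft quadratic
penalty outside the bounds, and branches whose proposed rates imply
more than $\sim$1000 uniformization terms (tens of expected events per
gene on one branch) are treated as $-\infty$, a feasibility wall far
from any realistic optimum. Families observed at more than 30 copies
skip the random restarts: their likelihoods are sharply peaked -- the
restarts exist for flat small-count surfaces -- and they dominate
runtime otherwise. The SR fit always includes the GR solution among
its starts, which enforces $\ln L_{SR} \ge \ln L_{GR}$ (nesting) up to
optimizer noise. Identical count patterns are fitted once and the
result reused. Non-converged orthogroups are flagged, excluded from
downstream sets, and counted.

**Ancestral reconstruction** is max-marginal, not joint: an up-down
(inside-outside) pass yields the marginal posterior per node, and the
reported state is the argmax with ties broken toward the *smaller*
count -- biased against inventing genes. Branch deltas are differences
of reconstructed integer states, so every downstream tally is an
integer. "Duplication events" are operationalized as gene gains on
branches where the family already existed (parent count > 0), keeping
them distinct from originations; published figures plot duplications
separately without defining them, so this is recorded as an
interpretation.

## Set bookkeeping and functional convergence

Per branch, orthogroups are classified as expanded/contracted
($\Delta \neq 0$) with the special cases origination (parent 0) and
orthogroup loss (child 0); gained $\subset$ expanded and lost
$\subset$ contracted by construction. `overlap_report()` performs the
exact Venn algebra across lineages; *parallel* = shared by two or more
lineages (the all-lineage cell is also reported), *exclusive* sets
feed the convergence machinery.

Functional similarity uses Wang's graph-based measure (edge weights
0.8 for `is_a`, 0.6 for `part_of`) combined across term sets by
best-match average. The similarity package cited in analyses of this
kind defaults to this measure but the measure actually used is rarely
stated, so it is pluggable and no claim of matching an unstated choice
is made. Information-content measures are deliberately absent: they
need a reference corpus, and depth (longest path to the root)
substitutes for specificity wherever "most specific term" is needed.
The representative (`reduced_term()`) of an annotation set keeps the
three deepest terms (sets smaller than three are kept whole -- the
behaviour for such sets is otherwise unspecified), greedily merges
terms at 0.95 similarity, and returns the deepest member of the
largest group; all ties break lexicographically on term id,
determinism over fidelity to an unstated rule.

Clustering runs affinity propagation **on the similarity matrix**, as
the method is defined, with damping 0.9, up to 1000 iterations and a
100-iteration convergence window. `affinity_propagation()` keeps the
conventional preference default (median similarity); `build_clusters()`
instead defaults to `min - max(0.4, n/30) * range` of the off-diagonal
similarities, because functional-convergence units are broad themes --
the median convention fragments them into sub-theme clusters (the
simulated themes, like much of the real GO graph, have internal
sub-structure that is genuine similarity signal). The linear-in-`n`
drop reflects that the cost of one extra exemplar must scale with
typical cluster size; the rule was calibrated on planted-theme
fixtures of 16-100 orthogroups, and the test suite asserts the
recovery it delivers on the 100-family fixture and in the end-to-end
demo. The
original algorithm's random symmetry-breaking noise is replaced by an
infinitesimal deterministic preference offset favouring earlier
indices (without it, perfectly symmetric inputs cancel all messages
and no exemplar ever emerges), so results are fully deterministic.
The classical-MDS embedding of $1-s$ (negative eigenvalues clamped,
with a warning, as standard for non-Euclidean dissimilarities) is
computed for display coordinates only. Whether the original analysis
clustered the matrix or the embedded coordinates is ambiguous; the
matrix is the method-faithful reading and is the default. Each
cluster is labelled by its exemplar's reduced term.

Enrichment uses two-tailed Fisher exact tests per GO term of a branch
query list against a branch-specific background (families present at
the branch that carry annotations), after true-path propagation of
annotations to ancestors, with Benjamini-Hochberg correction and
significance at $q \le 0.01$. The significance direction is read as
$q \le 0.01$ (a printed "$q$-value > 0.01" in the source literature is
taken as a typo for the discard rule). Terms with fewer than 2 query
hits are not tested (untested rare terms inflate the correction);
`min_count = 1` restores them.

## What the synthetic generator emulates -- and what it does not

`simulate_counts()` runs exact Gillespie simulation of the BDI jump
process along every branch (recording all internal node states), with
root counts from a geometric distribution (mean 2, truncated at 10) --
dispersed, with most mass at small counts, like real orthogroup size
distributions. Foreground shifts are multiplicative factors on
$(\beta,\delta,\iota)$ per branch class and per orthogroup subset, so
"expanded foreground" scenarios are one parameter. Exactness is the
point: the simulator doubles as an oracle for the likelihood core
(single-branch frequencies must match `transition_matrix()` rows by
chi-square).

`simulate_ontology()` builds one root plus disjoint theme subtrees
(level $d$ has $b^d$ terms), and `simulate_annotations()` draws each
orthogroup's terms from its theme with per-term noise. Planted themes
give ground truth for cluster recovery (scored by adjusted Rand
index).

The demo study (`demo_config()`) runs on a fixed, hand-designed 12-tip
ultrametric tree of height 20 Myr (`demo_tree()`) shaped like a
three-tribe beetle phylogeny: two aquatic tribes contributing
transitions B1, B2 and H1 and one terrestrial tribe contributing L1,
L2 and L3. The transition tips carry 10-Myr terminal branches (6 Myr
for L3): long enough that a 5x birth shift leaves a decisive
copy-number signature. A fixed tree was chosen over a sampled one
after piloting showed that random pure-birth geometries often hand the
foreground class near-zero-length terminal branches, on which no rate
shift is detectable even in principle. Root counts in the demo are
restricted to 2..4 copies: a family absent from the clade ancestor
cannot express a birth-rate shift at all, and pilot runs showed that
every missed detection involved a single-copy ancestor whose lineage
lost its only copy before the shift could act -- a biological floor on
per-family detectability, not a property of the inference. Power is
therefore defined over families seeded with at least two ancestral
copies. Background rates are
$(\beta,\delta,\iota) = (0.05, 0.05, 0.02)$/Myr; 20% of families carry
the 5x birth shift on all six foreground branches (the parallel,
detectable set), small per-lineage blocks carry it on one branch only
(the exclusive, convergence-feeding sets), and every family gets one
of four annotation themes (5 terms, 5% noise), with each lineage's
exclusive block concentrated in one theme. The default 200 families
(and the test suite's problem sizes generally) are a desk-scale choice
that keeps the statistical targets measurable -- power and
false-positive rates estimated on tens to hundreds of families -- while
the whole pipeline stays runnable in minutes on one core.

What the generator does **not** emulate: assembly or annotation error,
orthology mis-inference, among-family rate heterogeneity beyond the
planted shifts, correlated evolution between families, gene-tree /
species-tree discordance, and dating uncertainty. Passing recovery
tests therefore demonstrates that the *analysis chain* is correct and
well calibrated under its own model assumptions -- not that those
assumptions hold for any real dataset.

## Degenerate inputs and edge cases

Zero rates give an exact identity transition; constant counts then
reconstruct exactly with posterior mass 1, and conflicting counts give
$-\infty$ likelihood. Empty count tables return empty call tables.
Unannotated orthogroups are excluded *and listed* by the similarity
matrix, never silently scored zero. The root is not a branch and is
rejected by branch-list queries. Requesting more MDS dimensions than
points minus one, unknown branch ids, term ids or categories, negative
Fisher cells, and query sets outside their background all fail fast
with classed validation errors before any computation.

## Known limitations

* Per-branch free rates are out of scope; only class-structured models
  are fitted, as in the motivating analyses.
* No ascertainment correction for unobservable all-zero families is
  applied by default (orthology pipelines only emit families observed
  somewhere); `root_prior()` and the likelihood accept custom priors if
  conditioning is needed.
* AIC calls are not calibrated p-values; the type-I behaviour of the
  $\Delta \ge 2$ rule is checked by simulation in the test suite, not
  derived.
* Per-family ML rate estimates are biased when few events are realized
  per family: on shallow trees the death and innovation rates come out
  high (up-rate $n\beta+\iota$ is barely separable at small $n$, and
  rates are bounded below by zero), on very deep trees unobserved
  event pairs push estimates down. Pooled medians are reliable only in
  an intermediate regime (the recovery experiments use a 200-Myr,
  10-tip tree); per-family point estimates should never be
  over-interpreted, which is why downstream calls rest on AIC model
  comparison rather than on the rate values themselves.
* Wang similarity with best-match average saturates for orthogroups
  annotated with many shallow terms; depth-based term reduction
  mitigates but does not remove this.
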