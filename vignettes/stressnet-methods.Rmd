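---
title: "Consensus Bayesian networks for condition-associated gene discovery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus Bayesian networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressnet)
```

## The problem

Differential-expression screens of stressed versus unstressed animals
routinely return hundreds of genes, too many to interpret or validate.
`stressnet` implements a multi-step reduction: combine two independent
RNA-seq studies of the same condition, keep only the genes both studies call
differentially expressed, and then learn a discrete Bayesian network over
those genes plus the binary condition variable. The network's local
structure around the condition node — its Markov blanket, and its community
under divisive clustering — nominates a handful of genes in close
statistical association with the condition.

The package is organised as an analysis workflow: numbered drivers under
`analysis/` narrate a full synthetic run, while every computation lives in
package functions that the tests exercise directly.

## Stage models and assumptions

### Differential-expression selection

Counts are filtered (CPM $> 1$ in at least 2 samples), transformed to
$\log_2$ counts-per-million with a pseudo-count of 0.5, and fitted per gene
with the two-group linear model. The per-gene residual variances $s^2_g$ (on
$d = n - 2$ df) are shrunk toward a common prior by empirical Bayes: a
scaled-$F$ prior $(d_0, s_0^2)$ is estimated by Smyth-type moment matching
(through `limma::fitFDist`), and the moderated statistic uses
$\tilde s^2_g = (d_0 s_0^2 + d\, s^2_g)/(d_0 + d)$ with $d + d_0$ degrees of
freedom. Setting `prior_df = 0` recovers the ordinary pooled-variance t
exactly, which is how the reduction is tested. Genes with Benjamini–Hochberg
adjusted $p \le 0.05$ are kept per study and the per-study lists are
intersected.

Normalization is plain library-size CPM. TMM-style composition-bias factors
are deliberately not applied: the synthetic data have no composition bias,
and keeping the stage self-contained makes every number reproducible from
the stated formulas. Library sizes are column sums of the *filtered* matrix;
this is a documented convention, not a claim of superiority, and users can
recompute with pre-filter sizes by transforming before filtering.

### Discretization

Each selected gene's expression, pooled across all samples of all studies,
is cut into three categories (low/medium/high) at the empirical tertiles
(type-7 interpolated quantiles). Values equal to a cutpoint go to the lower
bin, so the mapping is deterministic; a warning flags degenerate vectors
with fewer distinct values than bins. Discretizing the pooled vector rather
than per study is the implemented interpretation of building one combined
dataset first; the coarse categories are also what absorbs residual
between-study location shifts. The binary condition variable (0 =
non-stress, 1 = stress) is appended last and is treated like any other
variable during learning — no edge constraints are imposed on it.

### BDeu scoring

A structure's fit is its log marginal likelihood under the
Bayesian–Dirichlet equivalent uniform prior with equivalent sample size
`ess = 1`: for node $i$ with $r_i$ states and $q_i$ parent configurations,

$$\sum_j \left[\ln\Gamma(\alpha_{ij}) - \ln\Gamma(\alpha_{ij} + N_{ij})\right]
 + \sum_{jk} \left[\ln\Gamma(\alpha_{ijk} + N_{ijk}) - \ln\Gamma(\alpha_{ijk})\right],$$

with $\alpha_{ijk} = \mathrm{ess}/(r_i q_i)$ and
$\alpha_{ij} = \mathrm{ess}/q_i$. The score decomposes over node families,
is cached by (node, parent set) during search, and assigns equal values to
Markov-equivalent DAGs — both properties are asserted in the tests, the
latter against an exhaustive enumeration of all 25 three-node DAGs grouped
by skeleton and v-structures.

### Simulated-annealing search

The search starts from the empty graph and proposes single-edge additions,
deletions and reversals drawn uniformly among the currently valid moves
(moves that would create a cycle or exceed `max_parents` are never
proposed; uniformity is achieved by rejection sampling from the structural
superset, which has constant size $n(n-1)$). Improving moves are always
accepted; a worsening move with score change $\Delta$ is accepted with
probability $\exp(\Delta/T)$. The schedule is geometric: initial $T = 10^4$
score units, multiplied by 0.9 every `n_proposals / 100` proposals by
default, with a reanneal (reset to the initial temperature) after 5000
consecutive rejections. Making the cooling interval budget-relative keeps
the temperature *profile* — hot start, effectively zero at the end —
identical at any proposal budget; with a fixed interval, short runs end
while still hot and behave as random walks whose "top" networks carry
scores of spurious edges. A fixed interval can still be supplied. All
schedule knobs sit in `search_config()` because none of them is canonical.
`t0 = 0` gives the pure hill-climbing variant used to test the
monotone-acceptance contract. The `top_n` (default 100) best-scoring *distinct* structures ever
visited are tracked by canonical edge-set identity in bounded memory.

The hot loop is compiled (Rcpp); the R-level `bde_score()` is the reference
scorer, and the tests require compiled and reference scores to agree to
1e-9 on searched structures.

### Ensemble consensus

One annealed run is stochastic, so the final network is built from many:
each run is first reduced to the arcs present in more than a configurable
fraction of its top 100 structures (`consensus_of_top` defaults to a
strict majority; the pipeline passes 0.3, because likelihood equivalence
puts each direction of a reversible arc near half of the top networks, and
a strict cut would drop the adjacency in both directions — the grouped
cross-run weighting below is the step that should arbitrate); the runs are
then divided, in run order, into groups
(full scale: 1000 runs, 10 groups of 100); within a group each arc is
weighted by the number of member networks containing it (1–100 at full
scale); and an arc is selected iff its mean weight across groups reaches
the threshold (50 of 100 at full scale), inclusively. The cross-group
combination is genuinely underdetermined: requiring the threshold in at
least $k$ of the groups is the natural alternative and is available via
`rule = "groups"`; the mean rule is the default because a single 1–100
weight scale reads most naturally as an average, and the choice is recorded
in the run manifest. If both directions of an edge pass, the heavier mean
wins (lexicographic tie-break, logged). Aggregated majority graphs need not
be acyclic; no re-acyclification is applied, and downstream semantics are
graph-theoretic. Variables with no selected arc are dropped from the node
list but reported as isolated.

### Interpretation

The Markov blanket of the condition node is its parents, children and
spouses (other parents of its children); on a cyclic aggregate this is the
purely structural definition, and the conditional-independence reading is
only claimed for acyclic inputs. Communities are found on the undirected,
unit-weight skeleton by the divisive edge-betweenness algorithm: repeatedly
remove a highest-betweenness edge (ties broken by lexicographically
smallest edge), score every intermediate partition by Newman–Girvan
modularity $Q = \sum_c (e_{cc} - a_c^2)$ on the original graph, and return
the maximizer (earliest step on ties, i.e. the coarsest best partition).
The full removal sequence is returned so the dendrogram can instead be cut
at a fixed community count with `cut_communities()`. Mean arc weights are
ignored during clustering; a weighted variant would be a one-line change
but is not what the reference toolchain computes.

## The synthetic-data module

Two generators provide ground truth.

**Count studies.** `simulate_two_study_counts()` draws two independent
negative-binomial studies (variance $\mu + \phi\mu^2$) sharing a planted
set of condition-responsive genes whose stress-group mean is
$2^{\pm\mathrm{lfc}}$ times the baseline, with directions alternating
(up, down, up, ...) across the planted set so the groups keep comparable
library sizes — a composition-balanced design is the regime in which plain
library-size normalization is unbiased, which is exactly the normalization
this pipeline uses. Sizes used throughout the workflow: 300 genes, studies
of 15 and 10 samples per group (a pooled 50-individual final dataset), 19
planted genes, $|\mathrm{lfc}| = 4$, $\phi = 0.05$, baseline means uniform
on $\log(5)\ldots\log(500)$ — mirroring a two-study spleen comparison with
a ~19-gene shared list, with an effect size large enough that selection
behaviour is governed by the method rather than borderline power. The
generator does not model batch effects, GC or composition bias, or
multi-factor designs, so passing tests demonstrate correctness of the
pipeline's logic, not robustness to those artifacts.

**Discrete networks.** `random_cpts()` fills a DAG with symmetric-Dirichlet
CPT rows (tiny concentrations give near-deterministic rows; a log-space
Marsaglia–Tsang draw keeps them from underflowing). For structure-recovery
tests, `strong_dependence_bn()` is preferred: uniform root marginals and
child rows that put $1 - \mathrm{noise}$ on a target state that changes
with every parent. A Dirichlet draw with a tiny concentration can make a
root nearly constant — strong *rows* but no usable signal — whereas the
deterministic construction guarantees identifiable dependence on every
edge, including into colliders.

All generators are pure functions of their arguments; sub-streams for
studies and ensemble runs derive from one master seed by integer mixing
(`derive_seed`), so ensembles are reproducible without correlated runs.

## Numerical choices and degenerate inputs

- Empty datasets score 0 (log of an empty product); all-constant genes keep
  a positive posterior variance whenever $d_0 s_0^2 > 0$.
- If the moment system for $(d_0, s_0^2)$ has no finite solution, the prior
  collapses to complete shrinkage ($d_0 = \infty$, $\tilde s^2 = s_0^2$).
- Family scores whose contingency table would exceed ~5e6 cells are given
  $-\infty$, which simply keeps the chain out of absurdly large parent
  sets; with the default unrestricted `max_parents` this is the only guard.
- `enumerate_all_dags()` refuses $n > 4$ (543 graphs at $n=4$ is the
  largest oracle the tests need).
- Zero-valid-move states (saturated tiny graphs) terminate the search
  cleanly; with $\ge 2$ variables a valid move always exists.

## Problem sizes used by tests and the acceptance script

Search-optimality checks use 3 variables, $n = 1000$, $10^5$ proposals and
100 seeds against the exhaustive 25-DAG oracle. Consensus recovery uses a
6-node, 6-edge truth, $n = 500$, 50 runs of $10^5$ proposals in 10 groups
of 5 with threshold 2.5, median over 5 master seeds. The end-to-end
workflow runs two 300-gene studies through a 20-variable learning problem
with 20–40 runs of $2\times 10^4$ proposals. These sizes give stable
pass/fail behaviour in minutes on one CPU; the full-scale knobs (250
million proposals, 1000 runs) remain available in the same configuration
objects.

## Known limitations

- The within-run consensus keeps only arcs in a strict majority of the top
  structures; for equivalence classes whose members disagree on an edge's
  direction, an arc can fail in both directions even when the undirected
  edge is certain. The grouped ensemble largely repairs this, which is one
  reason skeleton-level metrics are the right recovery currency.
- No structural priors or condition-node constraints are supported.
- Parameter (CPT) estimation on learned structures is out of scope; the
  learned object is a structure with confidence weights, not a fitted
  generative model.
- GEO retrieval is not implemented; the workflow's entry point is any pair
  of count matrices with condition labels in the documented TSV format.
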