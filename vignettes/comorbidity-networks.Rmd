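---
title: "Mining disease comorbidity networks from case-report co-occurrence data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining disease comorbidity networks from case-report co-occurrence data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorbnet)
```

## The problem

Post-market drug-safety surveillance databases collect millions of case
reports, each listing the indications (diseases) for which a patient's drugs
were prescribed. Diseases that are repeatedly co-reported within the same
patients are comorbidity candidates, and the global structure of these
co-occurrences — which diseases cluster together, and whether those clusters
line up with shared genetics, shared treatments, and ontological proximity —
is informative about disease biology.

`comorbnet` implements that analysis end to end:

1. **Ingest** case-report indication files (FAERS-style `$`-delimited ASCII
   or an internal two-column TSV), mapping raw indication strings to
   canonical disease terms through a user-supplied normalization table.
2. **Mine** association rules $\{X \to Y\}$ between disease sets with a
   from-scratch FP-growth implementation.
3. **Build** an undirected, unweighted disease comorbidity network (DCN)
   from the rules.
4. **Cluster** the DCN with the Girvan–Newman divisive algorithm, keeping
   the modularity-maximizing cut.
5. **Validate** clusters against external disease knowledge — shared genes,
   shared drugs, and Resnik ontology similarity — with a
   node-label-shuffling permutation null.
6. **Prioritize** diseases related to a seed disease by random walk with
   restart (RWR).

A synthetic-data module generates all required inputs with planted,
recoverable structure, so the full pipeline is testable without downloading
a surveillance corpus, a GWAS catalog, or a drug-indication database.

## The generative model behind the synthetic data

A `synthetic_spec()` defines disjoint planted disease clusters. Each
simulated case report:

* picks one cluster uniformly at random;
* includes one uniformly chosen *anchor* disease from it (mirroring a
  report's primary indication, and guaranteeing non-empty reports);
* includes each other member of that cluster independently with probability
  `p_within`;
* includes every other vocabulary disease independently with probability
  `p_background`.

The expected report size is therefore fully determined by the cluster sizes
and the two probabilities; `synthetic_spec()` computes it and stores it as
`mean_diseases_per_report` rather than accepting it as an independent dial.
Cluster members additionally share `genes_per_cluster` genes and
`drugs_per_cluster` drugs (none across clusters), and the synthetic ontology
places each cluster's diseases as leaves under a dedicated parent beneath a
single root. All generators are deterministic given `rng_seed`.

What this emulates is the *co-occurrence signal* of real surveillance data.
What it deliberately does not emulate: reporting biases, demographics, drug
exposures, duplicated case versions, temporal trends, overlapping disease
clusters, or graded (non-uniform) annotation sharing. Passing the planted
recovery tests therefore demonstrates that the algorithms are correct, not
that any particular real-world corpus will yield clean clusters.

### The benchmark conditions

Tests and the acceptance script use one benchmark throughout: 3 clusters ×
6 diseases, `p_within = 0.8`, `p_background = 0.01`, 5000 reports. Under
this model a within-cluster disease pair co-occurs in roughly 23% of
reports and a cross-cluster pair in roughly 0.6%, a 40-fold separation.

## Rule mining

`mine_frequent_itemsets()` is a textbook FP-growth: items are filtered and
ordered by global frequency (ties broken lexicographically so output is
deterministic), transactions are inserted into a prefix tree with header
side-links, and itemsets are mined through recursive conditional pattern
bases. `generate_rules()` turns frequent itemsets of size ≥ 2 into rules;
the default `single_item` consequent mode emits one-disease consequents
(the form comorbidity rules are usually reported in), while `all_splits`
enumerates every non-trivial bipartition.

Two conventions matter:

* **Support is an absolute transaction count**, and both thresholds are
  **strict** lower bounds: an itemset at exactly `min_support_count`, or a
  rule at exactly `min_confidence`, is excluded. The package defaults are
  support > 12 and confidence > 0.5 — sensible for a multi-million-report
  corpus.
* **Support scales with corpus size.** A count of 12 means a frequency of
  2 × 10⁻⁶ in a 5.8-million-report corpus but 0.24% in a 5000-report
  benchmark — *below* the benchmark's background co-occurrence band, where
  it admits mixed-antecedent rules (e.g. `{a, c1} → {c2}` with `a` riding
  along as background noise) that wire spurious cross-cluster edges. The
  benchmark therefore sets the threshold through the fractional alias,
  `min_support_fraction = 0.01`, placed between the background (~0.6%) and
  within-cluster (~23%) pair frequencies. The confidence threshold stays at
  0.5.

The test suite checks FP-growth against an exhaustive power-set enumeration
oracle (bitmask counting, shared code with nothing in the implementation)
on dozens of random databases, in both consequent modes, exactly.

## Network construction

`build_network()` collapses rules into an undirected simple graph. The
default `edge_policy = "cross_only"` adds an edge from each antecedent
disease to each consequent disease: a rule directly evidences
antecedent-with-consequent co-occurrence, whereas pairs *within* the
antecedent are not themselves asserted by the rule. The `clique` policy
(every pair within $X \cup Y$) is provided for users who prefer the more
generous reading; `cross_only` edges are always a subset of `clique` edges.

## Community detection

`girvan_newman()` iteratively removes the edge of highest betweenness,
recomputing betweenness (Brandes-style BFS accumulation, written here so
that the tie-break — lexicographically smallest edge — and the removal
trace are fully specified and deterministic) after every removal. Whenever
a removal splits a component, the Newman–Girvan modularity

$$Q = \sum_c \left( \frac{e_c}{m} - \left(\frac{d_c}{2m}\right)^2 \right)$$

of the current component partition is evaluated **on the original
network**, and the partition with maximum recorded $Q$ wins (ties go to
fewer removals). The intact network's component partition is recorded
first, so "no cut" can win on networks that are already well separated.
On an edgeless network every node is its own cluster and $Q = 0$ by
convention. Components with more than `min_report_size` nodes (default 10;
the benchmark uses 5 because its planted clusters have 6 members) are
flagged as reported; smaller ones are retained in the assignment.

`category_enrichment()` scores each (cluster, category) pair by fold
enrichment and a one-sided hypergeometric upper-tail p-value (no
multiplicity correction by default — consumers can `p.adjust` as needed).

Betweenness and modularity are verified in the tests against an explicit
all-shortest-paths enumeration oracle and against `igraph`, and the
returned $Q$ is always re-derivable from the returned assignment. One
conservation law worth knowing: summed over edges, betweenness equals the
total pairwise shortest-path distance (each connected pair spreads one unit
of credit per hop, split across tied shortest paths).

## Cluster validation

For a cluster $D$ with $m = |D|(|D|-1)/2$ unordered pairs:

* $C(G) = \frac{1}{m} \sum_{d_1 \neq d_2} g(d_1, d_2)$ — mean pairwise
  shared-gene count;
* $C(D) = \frac{1}{m} \sum_{d_1 \neq d_2} d(d_1, d_2)$ — mean pairwise
  shared-drug count;
* $C(SIM) = \frac{1}{m} \sum_{d_1 \neq d_2} sim(d_1, d_2)$ — mean pairwise
  Resnik similarity, $sim(d_1,d_2) = \max_{a \in A(d_1,d_2)} -\log p(a)$
  over common ancestors $a$.

Because the pairwise functions are symmetric, the unordered-pair mean
equals the ordered-pair mean; we use unordered pairs. Diseases missing
from the gene/drug maps contribute empty sets (their absence is
informative sparsity); diseases missing from the ontology are dropped from
$C(SIM)$ with a message (their absence is a vocabulary mismatch). A cluster
with fewer than two usable members yields `NA`, never a silent 0.

Two choices are under-determined by common usage and made explicit here:
$p(a)$ is the **structural descendant fraction**
$|desc(a) \cup \{a\}| / |terms|$ (no annotation corpus is required, the
root gets $p = 1$ hence similarity 0, and $p$ is monotone along is_a
edges), and the logarithm is **natural**. Both are isolated in
`information_content()` so corpus-based variants can be added.

`permutation_null()` holds the network structure — and hence the cluster
sizes — fixed and shuffles node labels uniformly, 100 times by default,
recomputing each cluster's statistic per shuffle. Two p-values are
reported:

* `p_value`: a two-sided one-sample t-test of the null sample against the
  observed value. This matches the usual reporting style for such
  validation tables, but note its standard error shrinks with the number
  of permutations, so it is a statement about distance from the *null
  mean*, and it degenerates when the null sample is constant (we then
  report 1 if null equals observed, else 0).
* `p_empirical`: the one-sided permutation p-value
  $(1 + \#\{null \ge obs\}) / (n_{perm} + 1)$, uniform when there is no
  signal. Use this one to decide *whether* a cluster is enriched at all;
  the t-test p to describe *how far* the observed value sits from the
  null mean.

## Random walk with restart

$$p_{k+1} = (1 - \gamma)\, M p_k + \gamma\, p_0, \qquad \gamma = 0.15$$

with $p_0$ uniform over the seed diseases, iterated until the L1 change
drops below `tol` (default $10^{-6}$). $M$ is the **column-normalized**
adjacency matrix: with a raw 0/1 adjacency the iteration is not a
probability flow at all (mass is not conserved and the iteration can
diverge), so the transition-matrix reading is the only one under which the
steady state is a probability vector. Columns of isolated nodes are
replaced by $p_0$ (the walker restarts), keeping $M$ column-stochastic, and
$\sum_i p_k(i) = 1$ holds at every iteration. $\gamma = 1$ degenerates to
$p = p_0$ after one step.

Non-seed diseases are ranked by percentile, $100 \times \#\{\text{strictly
higher}\} / \#\{\text{non-seeds}\}$, so the top disease prints 0.00 and
ties share the better percentile. Tie detection first rounds probabilities
to 9 significant digits: structurally symmetric nodes (leaves of a star,
members of a complete planted cluster) must tie exactly even though
floating-point summation order introduces ~10⁻¹⁶ noise; anything separated
by less than that rounding is far below the $10^{-6}$ convergence
tolerance anyway. The iterative fixed point is verified in tests against
the direct linear solve $p = \gamma (I - (1-\gamma) M)^{-1} p_0$ on graphs
up to 200 nodes.

`evaluate_comorbidities()` treats a disease's network neighbors as its
predicted comorbidities and scores them against a reference table
(precision undefined — `NA` — for an isolated disease; composite reference
entries such as "mental illness (depression, anxiety)" should be stored
pre-expanded, as the shipped reference fixture is).

## Problem sizes and determinism

The test suite and the acceptance script run entirely on synthetic data:
the benchmark above (5000 reports, 18 diseases), oracle comparisons on
random databases of up to 12 items and 100 transactions, random graphs of
10–200 nodes, and 100-permutation nulls. The complete suite runs in well
under a minute on one core. Every stochastic stage takes an explicit seed
and restores the caller's RNG state; same-seed runs are byte-identical.

## Known limitations

* Girvan–Newman recomputes betweenness after every removal
  ($O(|E|^2 |V|)$ overall); it is meant for networks of up to a few
  thousand edges, which matches rule-derived comorbidity networks after
  thresholding. For larger graphs a faster algorithm (Louvain/Leiden)
  would be the pragmatic substitute, at the cost of the removal trace.
* The miner loads all transactions into memory; quarterly surveillance
  files should be pre-filtered through the ingest step first.
* Case-version deduplication across quarterly files is not performed;
  `normalize_and_filter()` is the natural hook point.
* The OBO reader handles `[Term]` stanzas with `id`/`is_a` tags only —
  enough for is_a backbones; richer OBO semantics (relationship types,
  obsolete terms) are out of scope.
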