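# comorbnet

Disease comorbidity networks from case-report co-occurrence data.

Drug-safety case reports list the indications (diseases) a patient's drugs
were prescribed for. Diseases co-reported across many patients are
comorbidity candidates, and the network they form carries signal about
shared genetics, shared treatment, and disease-ontology structure.
`comorbnet` is for researchers who want to mine that signal from
FAERS-style indication files (or any transaction-shaped co-occurrence
data) and interrogate the resulting network. It covers:

* **Association rule mining** — a from-scratch FP-growth implementation
  producing rules {X → Y} between disease sets with support counts and
  confidences; thresholds are strict (`support > s`, `confidence > c`).
* **Network construction** — an undirected, unweighted disease comorbidity
  network (DCN) whose edges come from mined rules.
* **Community detection** — Girvan–Newman divisive clustering by iterated
  highest-betweenness edge removal, keeping the cut that maximizes
  Newman–Girvan modularity Q = Σ_c (e_c/m − (d_c/2m)²), plus per-cluster
  System-Organ-Class-style category enrichment (hypergeometric).
* **Cluster validation** — mean pairwise shared genes C(G), shared drugs
  C(D), and Resnik ontology similarity C(SIM) = mean of
  max_{a ∈ A(d1,d2)} −log p(a) per cluster, each tested against a
  node-label-shuffling permutation null (100 shuffles, t-test and
  empirical permutation p-values).
* **Prioritization** — random walk with restart,
  p_{k+1} = (1 − γ) M p_k + γ p_0 with γ = 0.15 and column-stochastic M,
  ranking diseases by proximity to a seed; plus neighbor-based
  precision/recall evaluation against reference comorbidity tables (a
  reference table for obesity, psoriasis, and multiple sclerosis ships in
  `inst/extdata/`).
* **Synthetic data** — a planted-cluster case-report generator (plus
  matched ontology, gene/drug annotations, and reference comorbidities) so
  the full pipeline is testable end to end without external downloads.

## Worked example

Simulate 5000 case reports over three planted 6-disease clusters, mine
rules, build and cluster the network, validate against planted gene
annotations, and rank diseases from a seed:

```r
library(comorbnet)

spec <- synthetic_spec(
  n_reports = 5000,
  clusters  = list(paste0("cardio_", 1:6), paste0("metab_", 1:6),
                   paste0("psych_", 1:6)),
  p_within = 0.8, p_background = 0.01, rng_seed = 42
)
db <- generate_transactions(spec)
#> Transaction DB: 5000 reports kept of 5000 raw; 18 diseases

params <- mining_params(min_confidence = 0.5, min_support_fraction = 0.01)
res <- comorbidity_pipeline(db, params, node_category = spec$category_of,
                            min_report_size = 5)
head(res$rules, 3)
#>   antecedent consequent support_count confidence
#> 1    psych_3    psych_4          1209  0.8303571
#> 2    psych_4    psych_3          1209  0.8207739
#> 3    psych_2    psych_4          1204  0.8263555
res$network
#> Disease network: 18 nodes, 45 edges (558 rules, cross_only)
res$partition
#> Partition: 3 clusters, Q = 0.6667
#>   sizes: 6, 6, 6
#>   reported (size > 5 ): 3 cluster(s)
```

The three planted clusters are recovered exactly (Q = 2/3 is the maximum
for three equal cliques). Each rule reads as "reports containing the
antecedent disease(s) also contain the consequent disease with the given
confidence"; `support_count` is the number of co-occurring reports.

```r
maps <- generate_annotations(spec)
permutation_null(res$network, res$partition, maps, "genes",
                 n_perm = 100, seed = 7)
#>   cluster size observed null_mean null_sd  p_value p_empirical n_perm
#> 1       1    6        3     0.888   0.258 9.26e-93      0.0099    100
#> 2       2    6        3     0.908   0.300 5.83e-86      0.0099    100
#> 3       3    6        3     0.896   0.275 6.58e-90      0.0099    100
```

Observed mean pairwise shared genes (3, by construction of the planted
annotations) far exceeds the label-shuffle null (~0.9): the clusters are
genetically coherent.

```r
rwr(res$network, "cardio_1")
#> RWR from {cardio_1}: 10 iterations, converged
#>   top non-seed diseases: cardio_2 (0.00%), cardio_3 (0.00%), ...

rank_report(rwr(res$network, "cardio_1"), c("cardio_2", "metab_1"),
            generate_reference_comorbidities(spec))
#>    disease rank_percent comorbidity in_network
#> 1 cardio_2         0.00         yes       TRUE
#> 2  metab_1        29.41          no       TRUE
```

The seed's co-cluster diseases all tie at percentile 0.00 (best); diseases
in other clusters rank far behind.

For real data, start from `read_faers_indications()` +
`normalize_and_filter()` with your term-normalization table, and see the
methods vignette (`vignettes/comorbidity-networks.Rmd`) for every model
and parameter choice.

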