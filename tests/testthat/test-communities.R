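# Two triangles joined by one bridge; the classic divisive-clustering example.
barbell <- function() {
  disease_network(
    c("a", "b", "c", "x", "y", "z"),
    data.frame(from = c("a", "a", "b", "c", "x", "x", "y"),
               to   = c("b", "c", "c", "x", "y", "z", "z"))
  )
}

test_that("edge betweenness matches hand values on a path and a triangle", {
  path <- disease_network(c("a", "b", "c"),
                          data.frame(from = c("a", "b"), to = c("b", "c")))
  eb <- edge_betweenness(path)
  expect_equal(unname(eb["a;b"]), 2)
  expect_equal(unname(eb["b;c"]), 2)
  tri <- disease_network(c("a", "b", "c"),
                         data.frame(from = c("a", "a", "b"),
                                    to = c("b", "c", "c")))
  expect_equal(unname(edge_betweenness(tri)), rep(1, 3))
})

test_that("Brandes accumulation equals path-enumeration oracle and igraph", {
  set.seed(52)
  for (trial in 1:6) {
    net <- random_network(12, stats::runif(1, 0.15, 0.4))
    eb <- edge_betweenness(net)
    expect_equal(eb, bf_edge_betweenness(net), tolerance = 1e-10)
    ig <- to_igraph(net)
    eb_ig <- igraph::edge_betweenness(ig, directed = FALSE)
    keys_ig <- apply(igraph::as_edgelist(ig), 1L,
                     function(e) paste(sort(e), collapse = ";"))
    expect_equal(unname(eb[keys_ig]), eb_ig, tolerance = 1e-10)
  }
})

test_that("total betweenness equals the total pairwise shortest-path distance", {
  # each connected pair (s, t) spreads d(s, t) units of credit over its
  # shortest-path edges (1 unit per hop, split across the tied paths)
  set.seed(61)
  for (trial in 1:5) {
    net <- random_network(10, 0.25)
    ig <- to_igraph(net)
    d <- igraph::distances(ig)
    total_dist <- sum(d[upper.tri(d)][is.finite(d[upper.tri(d)])])
    expect_equal(sum(edge_betweenness(net)), total_dist, tolerance = 1e-9)
  }
})

test_that("modularity matches hand values and igraph on random partitions", {
  net <- barbell()
  one <- stats::setNames(rep(1L, 6L), net$nodes)
  expect_equal(modularity(net, one), 0)
  singletons <- stats::setNames(seq_len(6L), net$nodes)
  deg <- network_properties(net)$degree
  expect_equal(modularity(net, singletons), -sum((deg / 14)^2))
  expect_lt(modularity(net, singletons), 0)
  set.seed(71)
  for (trial in 1:5) {
    rnet <- random_network(9, 0.35)
    assign <- stats::setNames(sample(1:3, 9, TRUE), rnet$nodes)
    ig <- to_igraph(rnet)
    expect_equal(
      modularity(rnet, assign),
      igraph::modularity(ig, assign[igraph::V(ig)$name]),
      tolerance = 1e-12
    )
  }
  expect_error(modularity(net, one[-1L]), "missing")
})

test_that("the barbell bridge is removed first and its two-triangle cut wins", {
  net <- barbell()
  part <- girvan_newman(net, min_report_size = 2L)
  expect_equal(part$removal_trace$edge[1L], "c;x")
  members <- cluster_members(part)
  expect_length(members, 2L)
  expect_true(any(vapply(members, setequal, logical(1L), c("a", "b", "c"))))
  # hand-derived modularity: 2 * (3/7 - (7/14)^2) = 5/14
  expect_equal(part$modularity_Q, 5 / 14, tolerance = 1e-12)
})

test_that("the returned Q always equals its recomputation from the assignment", {
  set.seed(81)
  for (trial in 1:4) {
    net <- random_network(10, 0.3)
    part <- girvan_newman(net, min_report_size = 1L)
    expect_equal(part$modularity_Q, modularity(net, part$assignment),
                 tolerance = 1e-12)
    expect_gte(part$modularity_Q, -0.5)
    expect_lte(part$modularity_Q, 1)
    expect_setequal(names(part$assignment), net$nodes)
  }
})

test_that("component counts never decrease along the removal trace", {
  set.seed(91)
  net <- random_network(10, 0.3)
  edges <- net$edges
  n_comp <- max(comorbnet:::graph_components(net$nodes, edges))
  part <- girvan_newman(net, min_report_size = 1L)
  for (edge in part$removal_trace$edge) {
    e <- strsplit(edge, ";", fixed = TRUE)[[1L]]
    edges <- edges[!(edges$from == e[1L] & edges$to == e[2L]), , drop = FALSE]
    n_now <- max(comorbnet:::graph_components(net$nodes, edges))
    expect_gte(n_now, n_comp)
    n_comp <- n_now
  }
})

test_that("an edgeless network yields singleton clusters with Q = 0", {
  net <- disease_network(c("a", "b"), data.frame(from = character(0L),
                                                 to = character(0L)))
  part <- girvan_newman(net)
  expect_equal(part$modularity_Q, 0)
  expect_equal(length(unique(part$assignment)), 2L)
})

test_that("the planted benchmark partition is recovered exactly", {
  run <- benchmark_run()
  planted <- planted_labels(run$spec)
  common <- intersect(names(planted), names(run$partition$assignment))
  expect_gte(length(common), 15L)
  ari <- mclust::adjustedRandIndex(planted[common],
                                   run$partition$assignment[common])
  expect_gte(ari, 0.9)
  expect_equal(sum(run$partition$reported), 3L)
})

test_that("category enrichment folds and p-values follow the hypergeometric", {
  nodes <- sprintf("d%03d", 1:100)
  category <- stats::setNames(rep("other", 100L), nodes)
  category[1:10] <- "target"
  # a ring so the network is valid; partition imposed manually
  net <- disease_network(nodes,
                         data.frame(from = nodes, to = nodes[c(2:100, 1)]),
                         node_category = category)
  part <- girvan_newman(net, min_report_size = 1L)
  part$assignment[] <- 2L
  part$assignment[nodes[1:10]] <- 1L
  part$reported <- c(`1` = TRUE, `2` = TRUE)
  enr <- category_enrichment(net, part)
  row <- enr[enr$cluster == "1" & enr$category == "target", ]
  expect_equal(row$fold, (10 / 10) / (10 / 100))  # fold 10 by hand
  expect_equal(row$p_value, bf_hyper_upper(10, 10, 100, 10), tolerance = 1e-12)
  # uniformly spread category has fold ~ 1
  spread <- enr[enr$cluster == "2" & enr$category == "other", ]
  expect_equal(spread$fold, (90 / 90) / (90 / 100), tolerance = 1e-12)
  set.seed(99)
  for (i in seq_len(nrow(enr))) {
    expect_equal(enr$p_value[i],
                 bf_hyper_upper(enr$cluster_hits[i], enr$network_hits[i],
                                enr$network_size[i], enr$cluster_size[i]),
                 tolerance = 1e-12)
  }
})

test_that("enrichment without categories instructs the user to supply them", {
  net <- barbell()
  part <- girvan_newman(net, min_report_size = 1L)
  expect_error(category_enrichment(net, part), "categor")
})

test_that("benchmark cluster enrichment recovers the planted categories", {
  run <- benchmark_run()
  enr <- category_enrichment(run$network, run$partition)
  top <- enr[!duplicated(enr$cluster), ]  # best category per cluster
  expect_setequal(top$category, c("cluster_1", "cluster_2", "cluster_3"))
  expect_true(all(top$fold > 2))
  expect_true(all(top$p_value < 0.01))
})
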