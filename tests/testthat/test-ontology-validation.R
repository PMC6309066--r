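# A 7-term DAG used throughout: root with two branches, one shared leaf.
#
#        root
#       /    \
#      p1     p2
#     /  \   /  \
#    l1   l2    l3     (l2 has both p1 and p2 as parents)
toy_dag <- function() {
  ontology(
    terms = c("root", "p1", "p2", "l1", "l2", "l3", "l4"),
    parents = list(p1 = "root", p2 = "root",
                   l1 = "p1", l2 = c("p1", "p2"), l3 = "p2", l4 = "p2")
  )
}

test_that("information content is the descendant fraction, monotone up the DAG", {
  ont <- information_content(toy_dag())
  expect_equal(unname(ont$p["root"]), 1)
  expect_equal(unname(ont$p["p1"]), 3 / 7)   # p1, l1, l2
  expect_equal(unname(ont$p["p2"]), 4 / 7)   # p2, l2, l3, l4
  expect_equal(unname(ont$p["l1"]), 1 / 7)
  for (ch in names(ont$parents)) {
    for (pa in ont$parents[[ch]]) {
      expect_lte(ont$p[[ch]], ont$p[[pa]])
    }
  }
  # a leaf in a 10-term tree has p = 0.1
  chain <- ontology(terms = paste0("t", 1:10),
                    parents = stats::setNames(
                      as.list(paste0("t", 1:9)), paste0("t", 2:10)))
  expect_equal(unname(information_content(chain)$p["t10"]), 0.1)  # the leaf
  expect_equal(unname(information_content(chain)$p["t1"]), 1)     # the root
})

test_that("cyclic parent relations are rejected", {
  expect_error(ontology(terms = c("a", "b"),
                        parents = list(a = "b", b = "a")), "cyclic")
})

test_that("Resnik similarity matches its defining cases and the scan oracle", {
  ont <- information_content(toy_dag())
  expect_equal(resnik_similarity("l1", "l1", ont),
               -log(unname(ont$p["l1"])))       # sim(d, d) = -log p(d)
  expect_equal(resnik_similarity("l1", "l3", ont), 0)  # root-only ancestors
  expect_equal(resnik_similarity("l1", "l2", ont), -log(3 / 7))
  expect_equal(resnik_similarity("l2", "l3", ont), -log(4 / 7))
  for (pair in list(c("l1", "l4"), c("l2", "l4"), c("p1", "l2"),
                    c("root", "l1"))) {
    expect_equal(resnik_similarity(pair[1L], pair[2L], ont),
                 bf_resnik(pair[1L], pair[2L], ont), tolerance = 1e-12)
  }
  expect_error(resnik_similarity("l1", "nope", ont), "nope")
})

test_that("shared gene/drug counts follow the empty-set convention", {
  maps <- annotation_maps(
    genes_of = list(a = c("g1", "g2", "g3"), b = c("g1", "g2", "g3"),
                    c = "g9"),
    drugs_of = list(a = "d1", b = "d1")
  )
  expect_equal(shared_genes("a", "b", maps), 3L)
  expect_equal(shared_genes("a", "c", maps), 0L)
  expect_equal(shared_genes("a", "absent", maps), 0L)
  expect_equal(shared_drugs("a", "b", maps), 1L)
  expect_equal(shared_drugs("c", "a", maps), 0L)
})

test_that("cluster statistics equal the double-loop oracle", {
  set.seed(13)
  diseases <- paste0("d", 1:6)
  genes_of <- lapply(diseases, function(d) sample(paste0("g", 1:10),
                                                  sample(2:6, 1L)))
  names(genes_of) <- diseases
  drugs_of <- lapply(diseases, function(d) sample(paste0("r", 1:8),
                                                  sample(1:5, 1L)))
  names(drugs_of) <- diseases
  ont <- information_content(generate_ontology(
    synthetic_spec(5, list(diseases[1:3], diseases[4:6]), rng_seed = 1)))
  maps <- annotation_maps(genes_of, drugs_of, ont)
  expect_equal(cluster_stat_genes(diseases, maps),
               bf_pair_mean(diseases, function(a, b) shared_genes(a, b, maps)),
               tolerance = 1e-12)
  expect_equal(cluster_stat_drugs(diseases, maps),
               bf_pair_mean(diseases, function(a, b) shared_drugs(a, b, maps)),
               tolerance = 1e-12)
  expect_equal(cluster_stat_semantic(diseases, maps),
               bf_pair_mean(diseases,
                            function(a, b) resnik_similarity(a, b, ont)),
               tolerance = 1e-12)
})

test_that("hand-computed cluster statistics and degenerate sizes behave", {
  maps <- annotation_maps(
    genes_of = list(a = c("g1", "g2", "g3"), b = c("g1", "g2", "g3")),
    drugs_of = list(a = "d1", b = "d1")
  )
  expect_equal(cluster_stat_genes(c("a", "b"), maps), 3)
  expect_equal(cluster_stat_drugs(c("a", "b"), maps), 1)
  expect_true(is.na(cluster_stat_genes("a", maps)))         # < 2 members
  expect_equal(cluster_stat_drugs(c("x", "y"), maps), 0)    # unannotated
  # every pair sharing exactly 2 genes averages to 2
  g4 <- stats::setNames(rep(list(c("s1", "s2")), 4L), paste0("q", 1:4))
  expect_equal(cluster_stat_genes(paste0("q", 1:4), annotation_maps(g4)), 2)
})

test_that("cluster of two siblings under a shared parent scores -log p(parent)", {
  ont <- information_content(toy_dag())
  maps <- annotation_maps(ontology = ont)
  expect_equal(cluster_stat_semantic(c("l1", "l3"), maps), 0)
  # siblings under p1 (p = 3/7)
  expect_equal(cluster_stat_semantic(c("l1", "l2"), maps), -log(3 / 7))
  expect_message(
    val <- cluster_stat_semantic(c("l1", "l2", "not_in_ontology"), maps),
    "absent")
  expect_equal(val, -log(3 / 7))
  expect_true(is.na(suppressMessages(
    cluster_stat_semantic(c("l1", "nope"), maps))))
})

test_that("statistics are invariant under consistent annotation relabeling", {
  set.seed(17)
  diseases <- paste0("d", 1:5)
  genes_of <- lapply(diseases, function(d) sample(paste0("g", 1:12),
                                                  sample(2:6, 1L)))
  names(genes_of) <- diseases
  relabel <- stats::setNames(sample(paste0("h", 1:12)), paste0("g", 1:12))
  genes_relab <- lapply(genes_of, function(g) unname(relabel[g]))
  m1 <- annotation_maps(genes_of)
  m2 <- annotation_maps(genes_relab)
  expect_equal(cluster_stat_genes(diseases, m1),
               cluster_stat_genes(diseases, m2))
})

test_that("permutation null: identical annotations give p ~ 1, and seeds fix the null", {
  net <- disease_network(paste0("d", 1:6),
                         data.frame(from = paste0("d", 1:5),
                                    to = paste0("d", 2:6)))
  part <- girvan_newman(net, min_report_size = 1L)
  same <- stats::setNames(rep(list(c("g1", "g2")), 6L), paste0("d", 1:6))
  maps <- annotation_maps(genes_of = same)
  rep1 <- permutation_null(net, part, maps, "genes", n_perm = 20, seed = 4,
                           reported_only = FALSE)
  expect_true(all(rep1$p_value == 1))
  expect_true(all(rep1$null_mean == rep1$observed))
  rep2 <- permutation_null(net, part, maps, "genes", n_perm = 20, seed = 4,
                           reported_only = FALSE)
  expect_identical(attr(rep1, "null_values"), attr(rep2, "null_values"))
  expect_error(permutation_null(net, part, maps, "genes", n_perm = 1),
               "n_perm")
})

test_that("planted clusters beat the shuffled null on all three statistics", {
  run <- benchmark_run()
  for (stat in c("genes", "drugs", "semantic")) {
    rep <- permutation_null(run$network, run$partition, run$maps, stat,
                            n_perm = 100, seed = 31)
    expect_equal(nrow(rep), 3L)
    expect_true(all(rep$observed > rep$null_mean))
    expect_true(all(rep$p_value < 0.01))
    expect_true(all(lengths(attr(rep, "null_values")) == 100L))
  }
})

test_that("ontologies round-trip through OBO and parent-child TSV", {
  ont <- toy_dag()
  obo <- withr::local_tempfile(fileext = ".obo")
  write_obo(ont, obo)
  back <- read_obo(obo)
  expect_setequal(back$terms, ont$terms)
  expect_equal(back$parents[order(names(back$parents))],
               ont$parents[order(names(ont$parents))])
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_ontology_tsv(ont, tsv)
  back2 <- read_ontology_tsv(tsv)
  expect_setequal(back2$terms, ont$terms)
  expect_equal(information_content(back2)$p[ont$terms],
               information_content(ont)$p[ont$terms])
})

test_that("annotation maps round-trip through two-column TSVs", {
  maps <- list(a = c("g1", "g2"), b = "g3")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_tsv(maps, path, "gene")
  expect_equal(read_annotation_tsv(path, "gene"), maps)
})
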