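# Cluster-level concordance of the comorbidity network with external disease
# knowledge: shared genes (GWAS-style disease-gene map), shared drugs
# (drug-indication map), and ontology semantic similarity, each summarized
# per cluster as the mean over unordered disease pairs, and each tested
# against a null of 100 node-label-shuffled networks with a t-test.

#' Bundle the annotation maps
#'
#' @param genes_of named list disease -> character vector of genes.
#' @param drugs_of named list disease -> character vector of drugs.
#' @param ontology an [ontology()]; information content is populated on
#'   construction if absent.
#' @return an `annotation_maps` object. Lookups for diseases absent from a
#'   map return the empty set.
#' @export
annotation_maps <- function(genes_of = list(), drugs_of = list(),
                            ontology = NULL) {
  if (!is.null(ontology)) {
    stopifnot(inherits(ontology, "ontology"))
    if (is.null(ontology$p)) ontology <- information_content(ontology)
  }
  structure(list(genes_of = genes_of, drugs_of = drugs_of,
                 ontology = ontology),
            class = "annotation_maps")
}

#' @export
print.annotation_maps <- function(x, ...) {
  cat("Annotation maps:", length(x$genes_of), "diseases with genes,",
      length(x$drugs_of), "with drugs,",
      if (is.null(x$ontology)) "no ontology"
      else paste(length(x$ontology$terms), "ontology terms"), "\n")
  invisible(x)
}

#' Read a two-column disease-annotation TSV
#'
#' Columns `disease` and either `gene` or `drug` (header required); one row
#' per association, as in a GWAS-catalog-style extract.
#'
#' @param path TSV path.
#' @param value_col name of the annotation column (`"gene"` or `"drug"`).
#' @return named list disease -> sorted unique annotation vector.
#' @export
read_annotation_tsv <- function(path, value_col = c("gene", "drug")) {
  value_col <- match.arg(value_col)
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", colClasses = "character",
                          stringsAsFactors = FALSE)
  if (!all(c("disease", value_col) %in% names(df))) {
    stop("annotation TSV must have columns disease and ", value_col,
         call. = FALSE)
  }
  lapply(split(df[[value_col]], df$disease), function(x) sort(unique(x)))
}

#' Write a disease-annotation TSV
#'
#' @param map named list disease -> annotation vector.
#' @param path output path.
#' @param value_col column name for the annotation.
#' @export
write_annotation_tsv <- function(map, path, value_col = c("gene", "drug")) {
  value_col <- match.arg(value_col)
  df <- data.frame(disease = rep(names(map), lengths(map)),
                   value = unlist(map, use.names = FALSE),
                   stringsAsFactors = FALSE)
  names(df)[2L] <- value_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Shared genes / drugs between two diseases
#'
#' Size of the intersection of the two annotation sets; a disease absent
#' from the map contributes the empty set (count 0).
#'
#' @param d1,d2 disease terms.
#' @param maps an `annotation_maps`.
#' @return integer count.
#' @export
shared_genes <- function(d1, d2, maps) {
  stopifnot(inherits(maps, "annotation_maps"))
  length(intersect(maps$genes_of[[d1]] %||% character(0L),
                   maps$genes_of[[d2]] %||% character(0L)))
}

#' @rdname shared_genes
#' @export
shared_drugs <- function(d1, d2, maps) {
  stopifnot(inherits(maps, "annotation_maps"))
  length(intersect(maps$drugs_of[[d1]] %||% character(0L),
                   maps$drugs_of[[d2]] %||% character(0L)))
}

# Mean of f(d1, d2) over the n(n-1)/2 unordered pairs of `cluster`. The
# pairwise functions are symmetric, so this equals the ordered-pair mean.
pairwise_mean <- function(cluster, f) {
  n <- length(cluster)
  if (n < 2L) return(NA_real_)
  pairs <- utils::combn(cluster, 2L)
  mean(vapply(seq_len(ncol(pairs)),
              function(j) f(pairs[1L, j], pairs[2L, j]), numeric(1L)))
}

#' Cluster concordance statistics
#'
#' `cluster_stat_genes()` is the mean number of shared genes over all
#' unordered disease pairs of the cluster (C(G)); `cluster_stat_drugs()` the
#' same for drugs (C(D)); `cluster_stat_semantic()` the mean Resnik
#' similarity (C(SIM)), computed over the cluster members present in the
#' ontology (absent members are dropped with a message — their absence is a
#' vocabulary mismatch, not informative sparsity).
#'
#' A cluster with fewer than two (mappable) members has no pairs; the
#' statistic is `NA`, not 0.
#'
#' @param cluster character vector of disease terms, size >= 2.
#' @param maps an `annotation_maps` (with an ontology, for the semantic
#'   statistic).
#' @return mean pairwise statistic, or `NA` if undefined.
#' @export
cluster_stat_genes <- function(cluster, maps) {
  stopifnot(inherits(maps, "annotation_maps"))
  pairwise_mean(cluster, function(a, b) shared_genes(a, b, maps))
}

#' @rdname cluster_stat_genes
#' @export
cluster_stat_drugs <- function(cluster, maps) {
  stopifnot(inherits(maps, "annotation_maps"))
  pairwise_mean(cluster, function(a, b) shared_drugs(a, b, maps))
}

#' @rdname cluster_stat_genes
#' @export
cluster_stat_semantic <- function(cluster, maps) {
  stopifnot(inherits(maps, "annotation_maps"))
  ont <- maps$ontology
  if (is.null(ont)) stop("no ontology in `maps`", call. = FALSE)
  mappable <- intersect(cluster, ont$terms)
  dropped <- setdiff(cluster, mappable)
  if (length(dropped) > 0L) {
    message(length(dropped), " cluster member(s) absent from the ontology ",
            "dropped from C(SIM): ", paste(dropped, collapse = ", "))
  }
  pairwise_mean(mappable, function(a, b) resnik_similarity(a, b, ont))
}

cluster_stat_fun <- function(statistic, maps) {
  switch(statistic,
         genes = function(cl) cluster_stat_genes(cl, maps),
         drugs = function(cl) cluster_stat_drugs(cl, maps),
         semantic = function(cl) suppressMessages(cluster_stat_semantic(cl, maps)))
}

#' Permutation null for cluster statistics
#'
#' Builds the random-network null: the network structure (and hence the
#' cluster sizes) is held fixed while node labels are shuffled uniformly at
#' random; the chosen cluster statistic is recomputed for every cluster in
#' each of `n_perm` shuffles. Significance per cluster is a two-sided
#' one-sample t-test of the null sample against the observed value. If the
#' null sample is constant (zero variance) the t-test is undefined and the
#' p-value is 1 when the null equals the observed value, 0 otherwise.
#'
#' @param net the `disease_network` the partition was computed on.
#' @param partition a `cluster_partition`.
#' @param maps an `annotation_maps`.
#' @param statistic `"genes"`, `"drugs"` or `"semantic"`.
#' @param n_perm number of label shuffles (>= 2; 100 by default).
#' @param seed RNG seed; results are deterministic given it.
#' @param reported_only restrict to reported clusters (default TRUE).
#' @return a `cluster_stat_report`: data.frame `cluster`, `size`, `observed`,
#'   `null_mean`, `null_sd`, `p_value` (t-test), `p_empirical`, `n_perm`,
#'   with the per-cluster null samples in attribute `null_values` (list of
#'   length-`n_perm` vectors).
#'
#' @details The t-test asks whether the observed value sits away from the
#' null *mean*; with many permutations its standard error is tiny, so it is
#' extremely sensitive — appropriate for demonstrating a real excess, but
#' not calibrated as a type-I check (an observed value that is itself one
#' draw from the null still lands several null-mean standard errors out).
#' `p_empirical` is the standard one-sided permutation p-value,
#' `(1 + #\{null >= observed\}) / (n_perm + 1)`, which is uniform under no
#' signal; use it to judge whether any enrichment exists at all.
#' @export
permutation_null <- function(net, partition, maps,
                             statistic = c("genes", "drugs", "semantic"),
                             n_perm = 100L, seed = 1L,
                             reported_only = TRUE) {
  stopifnot(inherits(net, "disease_network"),
            inherits(partition, "cluster_partition"),
            inherits(maps, "annotation_maps"))
  statistic <- match.arg(statistic)
  if (n_perm < 2L) stop("`n_perm` must be >= 2 (t-test undefined)", call. = FALSE)
  stat_fun <- cluster_stat_fun(statistic, maps)
  members <- cluster_members(partition, reported_only = reported_only)
  members <- members[lengths(members) >= 2L]
  if (length(members) == 0L) {
    stop("no cluster with >= 2 members to test", call. = FALSE)
  }
  observed <- vapply(members, stat_fun, numeric(1L))
  nodes <- net$nodes
  null_values <- lapply(members, function(cl) numeric(n_perm))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      relabel <- stats::setNames(sample(nodes), nodes)
      for (cl in names(members)) {
        null_values[[cl]][b] <- stat_fun(unname(relabel[members[[cl]]]))
      }
    }
  })
  p_value <- vapply(names(members), function(cl) {
    nv <- null_values[[cl]]
    if (stats::sd(nv) == 0) {
      return(if (isTRUE(all.equal(mean(nv), observed[[cl]]))) 1 else 0)
    }
    stats::t.test(nv, mu = observed[[cl]])$p.value
  }, numeric(1L))
  p_empirical <- vapply(names(members), function(cl) {
    (1 + sum(null_values[[cl]] >= observed[[cl]])) / (n_perm + 1)
  }, numeric(1L))
  report <- data.frame(
    cluster = names(members),
    size = lengths(members),
    observed = unname(observed),
    null_mean = vapply(null_values, mean, numeric(1L))[names(members)],
    null_sd = vapply(null_values, stats::sd, numeric(1L))[names(members)],
    p_value = unname(p_value),
    p_empirical = unname(p_empirical),
    n_perm = as.integer(n_perm),
    stringsAsFactors = FALSE
  )
  rownames(report) <- NULL
  attr(report, "null_values") <- null_values
  attr(report, "statistic") <- statistic
  class(report) <- c("cluster_stat_report", "data.frame")
  report
}

#' Write a cluster statistic report as TSV
#'
#' Columns mirror the per-cluster validation tables: cluster, size,
#' observed, null mean, null sd, p-value.
#'
#' @param report a `cluster_stat_report`.
#' @param path TSV path.
#' @export
write_stat_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
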