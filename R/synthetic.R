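# Synthetic case-report generator with planted comorbidity structure.
#
# Emulates, at toy scale, the inputs of a FAERS-style comorbidity study:
# case-report transactions (sets of co-reported disease indications), a
# disease ontology, disease-gene and disease-drug annotation maps, and a
# reference comorbidity table, all with planted cluster structure that the
# downstream pipeline (mine -> network -> cluster -> validate -> rank) should
# recover.

#' Specify a synthetic comorbidity study
#'
#' Defines the generative model for synthetic case reports: a set of disjoint
#' planted disease clusters, an inclusion probability for co-cluster diseases
#' (`p_within`), a background co-reporting probability for all other diseases
#' (`p_background`), and planted shared gene/drug annotations per cluster.
#'
#' Each simulated report picks one cluster uniformly at random, includes one
#' uniformly chosen anchor disease from it, includes every other member of
#' that cluster independently with probability `p_within`, and every
#' non-member disease in the vocabulary independently with probability
#' `p_background`. The expected number of diseases per report is therefore
#' determined by the cluster sizes and the two probabilities; it is computed
#' and stored as `mean_diseases_per_report` for reference.
#'
#' @param n_reports number of case reports to simulate.
#' @param clusters list of character vectors, the planted disease clusters;
#'   must be pairwise disjoint.
#' @param p_within probability in \[0, 1\] that a report includes each
#'   additional disease of its chosen cluster.
#' @param p_background probability in \[0, 1\] that a report includes any
#'   given out-of-cluster disease.
#' @param rng_seed integer seed; all generator functions are deterministic
#'   given the spec (including this seed).
#' @param category_of named character vector mapping every disease to a
#'   category label (the System Organ Class analog). Defaults to
#'   `"cluster_<i>"` per planted cluster. Diseases listed here but absent
#'   from all clusters form the background pool.
#' @param genes_per_cluster,drugs_per_cluster number of genes/drugs shared by
#'   all members of each planted cluster.
#' @return an object of class `synthetic_spec`.
#' @examples
#' spec <- synthetic_spec(
#'   n_reports = 100,
#'   clusters = list(c("asthma", "hay fever"), c("obesity", "diabetes")),
#'   p_within = 0.9, p_background = 0.01, rng_seed = 1
#' )
#' db <- generate_transactions(spec)
#' @export
synthetic_spec <- function(n_reports,
                           clusters,
                           p_within = 0.8,
                           p_background = 0.01,
                           rng_seed = 1L,
                           category_of = NULL,
                           genes_per_cluster = 3L,
                           drugs_per_cluster = 3L) {
  if (!is.numeric(n_reports) || length(n_reports) != 1L || n_reports < 1 ||
      n_reports != round(n_reports)) {
    stop("invalid `n_reports`: must be a positive integer count", call. = FALSE)
  }
  if (!is.list(clusters) || length(clusters) == 0L ||
      !all(vapply(clusters, is.character, logical(1L)))) {
    stop("invalid `clusters`: must be a non-empty list of character vectors",
         call. = FALSE)
  }
  members <- unlist(clusters, use.names = FALSE)
  if (anyDuplicated(members)) {
    stop("invalid `clusters`: planted clusters must be pairwise disjoint",
         call. = FALSE)
  }
  check_prob <- function(p, what) {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
      stop("invalid `", what, "`: probabilities must lie in [0, 1]",
           call. = FALSE)
    }
  }
  check_prob(p_within, "p_within")
  check_prob(p_background, "p_background")
  if (is.null(category_of)) {
    category_of <- stats::setNames(
      rep(paste0("cluster_", seq_along(clusters)), lengths(clusters)),
      members
    )
  }
  if (is.null(names(category_of)) || !all(members %in% names(category_of))) {
    stop("invalid `category_of`: every disease in `clusters` must have a category",
         call. = FALSE)
  }
  check_count <- function(k, what) {
    if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k)) {
      stop("invalid `", what, "`: must be a positive integer", call. = FALSE)
    }
  }
  check_count(genes_per_cluster, "genes_per_cluster")
  check_count(drugs_per_cluster, "drugs_per_cluster")
  vocabulary <- names(category_of)
  # E[size] = 1 anchor + (cluster size - 1) * p_within + background * p_background,
  # averaged over the uniform cluster choice.
  mean_size <- mean(vapply(clusters, function(cl) {
    1 + (length(cl) - 1L) * p_within +
      (length(vocabulary) - length(cl)) * p_background
  }, numeric(1L)))
  structure(
    list(
      n_reports = as.integer(n_reports),
      clusters = lapply(clusters, sort),
      p_within = p_within,
      p_background = p_background,
      mean_diseases_per_report = mean_size,
      rng_seed = as.integer(rng_seed),
      category_of = category_of,
      genes_per_cluster = as.integer(genes_per_cluster),
      drugs_per_cluster = as.integer(drugs_per_cluster)
    ),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("Synthetic comorbidity spec:", x$n_reports, "reports,",
      length(x$clusters), "planted clusters,",
      length(x$category_of), "diseases\n")
  cat(sprintf("  p_within = %g, p_background = %g, E[diseases/report] = %.2f\n",
              x$p_within, x$p_background, x$mean_diseases_per_report))
  invisible(x)
}

#' Generate synthetic case-report transactions
#'
#' Simulates `spec$n_reports` case reports under the planted-cluster model
#' described in [synthetic_spec()]. Every report carries at least its anchor
#' disease, so transactions are never empty. Deterministic given
#' `spec$rng_seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return a `transaction_db` (see [transaction_db()]); report ids are
#'   `"R000001"` and so on.
#' @export
generate_transactions <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  vocab <- names(spec$category_of)
  n_clusters <- length(spec$clusters)
  with_seed(spec$rng_seed, {
    txs <- vector("list", spec$n_reports)
    i <- 0L
    while (i < spec$n_reports) {
      k <- sample.int(n_clusters, 1L)
      cl <- spec$clusters[[k]]
      anchor <- cl[sample.int(length(cl), 1L)]
      others <- setdiff(cl, anchor)
      within <- others[stats::runif(length(others)) < spec$p_within]
      pool <- setdiff(vocab, cl)
      background <- pool[stats::runif(length(pool)) < spec$p_background]
      diseases <- unique(c(anchor, within, background))
      if (length(diseases) == 0L) next  # unreachable: anchor always present
      i <- i + 1L
      txs[[i]] <- sort(diseases)
    }
    names(txs) <- sprintf("R%06d", seq_len(spec$n_reports))
    transaction_db(txs, n_raw_reports = spec$n_reports)
  })
}

#' Generate a synthetic disease ontology
#'
#' Builds a rooted DAG in which each planted cluster's diseases are leaves
#' under a dedicated parent term (`"cluster_parent_<i>"`), all parents hang
#' under a single root (`"disease_root"`), and background diseases attach
#' directly to the root. Deterministic (no randomness is needed).
#'
#' @param spec a [synthetic_spec()].
#' @return an `ontology` object (see [ontology()]).
#' @export
generate_ontology <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  root <- "disease_root"
  parents <- list()
  for (i in seq_along(spec$clusters)) {
    pa <- paste0("cluster_parent_", i)
    parents[[pa]] <- root
    for (d in spec$clusters[[i]]) parents[[d]] <- pa
  }
  background <- setdiff(names(spec$category_of),
                        unlist(spec$clusters, use.names = FALSE))
  for (d in background) parents[[d]] <- root
  ontology(terms = c(root, names(parents)), parents = parents)
}

#' Generate planted disease-gene and disease-drug annotations
#'
#' Members of planted cluster i all carry genes `"G<i>_1" ...` and drugs
#' `"D<i>_1" ...`; diseases in different clusters (and background diseases)
#' share no annotations. Deterministic given the spec.
#'
#' @param spec a [synthetic_spec()].
#' @param ontology optionally, the ontology to bundle into the returned maps;
#'   defaults to [generate_ontology()] of the same spec.
#' @return an `annotation_maps` object (see [annotation_maps()]).
#' @export
generate_annotations <- function(spec, ontology = generate_ontology(spec)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  genes_of <- list()
  drugs_of <- list()
  for (i in seq_along(spec$clusters)) {
    genes <- sprintf("G%d_%d", i, seq_len(spec$genes_per_cluster))
    drugs <- sprintf("D%d_%d", i, seq_len(spec$drugs_per_cluster))
    for (d in spec$clusters[[i]]) {
      genes_of[[d]] <- genes
      drugs_of[[d]] <- drugs
    }
  }
  annotation_maps(genes_of = genes_of, drugs_of = drugs_of,
                  ontology = ontology)
}

#' Generate the reference comorbidity table for the planted clusters
#'
#' For each planted cluster and each of its diseases taken as an anchor, the
#' reference comorbidity set is the cluster's other members — the ground
#' truth for precision/recall evaluation of the mined network.
#'
#' @param spec a [synthetic_spec()].
#' @return a named list mapping each planted disease to the character vector
#'   of its reference comorbidities, with attribute `source` noting the
#'   synthetic provenance; class `reference_comorbidities`.
#' @export
generate_reference_comorbidities <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  ref <- list()
  for (cl in spec$clusters) {
    for (d in cl) ref[[d]] <- setdiff(cl, d)
  }
  structure(ref,
            source = rep("synthetic planted cluster", length(ref)),
            class = "reference_comorbidities")
}
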