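# Random walk with restart on the comorbidity network, and neighbor-based
# precision/recall evaluation against reference comorbidity tables.
#
# The walker iterates p_{k+1} = (1 - gamma) * M %*% p_k + gamma * p_0 with
# restart probability gamma, where p_0 is uniform over the seed diseases and
# M is the column-normalized adjacency matrix (transition matrix), until the
# L1 change drops below `tol`. The steady state scores each disease's
# proximity to the seeds.

#' Random-walk-with-restart parameters
#'
#' @param gamma restart probability in (0, 1\]; 0.15 by default.
#' @param tol L1 convergence threshold (default 1e-6).
#' @param max_iter safety cap on iterations.
#' @return an `rwr_params` object.
#' @export
rwr_params <- function(gamma = 0.15, tol = 1e-6, max_iter = 10000L) {
  if (!is.numeric(gamma) || gamma <= 0 || gamma > 1) {
    stop("`gamma` must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(tol) || tol <= 0) stop("`tol` must be > 0", call. = FALSE)
  structure(list(gamma = gamma, tol = tol, max_iter = as.integer(max_iter)),
            class = "rwr_params")
}

# Column-normalized adjacency; degree-0 columns are replaced by p0 so every
# column stays stochastic (a walker on an isolated node restarts).
transition_matrix <- function(net, p0) {
  n <- length(net$nodes)
  M <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges) > 0L) {
    i <- match(net$edges$from, net$nodes)
    j <- match(net$edges$to, net$nodes)
    M[cbind(i, j)] <- 1
    M[cbind(j, i)] <- 1
  }
  colsum <- colSums(M)
  for (c_idx in seq_len(n)) {
    if (colsum[c_idx] == 0) M[, c_idx] <- p0 else M[, c_idx] <- M[, c_idx] / colsum[c_idx]
  }
  M
}

#' Random walk with restart from seed diseases
#'
#' @param net a `disease_network`.
#' @param seeds character vector of seed diseases (must be network nodes).
#' @param params an [rwr_params()].
#' @return an `rwr_result`: `probabilities` (named, sums to 1),
#'   `rank_percent` (named percentile per NON-seed disease; 0 = top; ties —
#'   probabilities equal after rounding to 9 significant digits — share the
#'   better percentile), `iterations`, `converged`, plus the params used.
#' @examples
#' net <- disease_network(c("a", "b"), data.frame(from = "a", to = "b"))
#' rwr(net, "a")
#' @export
rwr <- function(net, seeds, params = rwr_params()) {
  stopifnot(inherits(net, "disease_network"), inherits(params, "rwr_params"))
  missing_seed <- setdiff(seeds, net$nodes)
  if (length(missing_seed) > 0L) {
    stop("seed disease(s) not in network: ",
         paste(missing_seed, collapse = ", "), call. = FALSE)
  }
  n <- length(net$nodes)
  p0 <- stats::setNames(rep(0, n), net$nodes)
  p0[seeds] <- 1 / length(seeds)
  M <- transition_matrix(net, p0)
  p <- p0
  converged <- FALSE
  iters <- 0L
  for (k in seq_len(params$max_iter)) {
    p_next <- (1 - params$gamma) * as.vector(M %*% p) + params$gamma * p0
    names(p_next) <- net$nodes
    iters <- k
    delta <- sum(abs(p_next - p))
    p <- p_next
    if (delta < params$tol) { converged <- TRUE; break }
  }
  non_seed <- setdiff(net$nodes, seeds)
  # round so that exactly symmetric nodes tie despite float summation noise
  pr <- signif(p[non_seed], 9)
  rank_percent <- vapply(pr, function(v) 100 * sum(pr > v) / length(pr),
                         numeric(1L))
  structure(
    list(probabilities = p, rank_percent = rank_percent,
         seeds = seeds, iterations = iters, converged = converged,
         params = params),
    class = "rwr_result"
  )
}

#' @export
print.rwr_result <- function(x, ...) {
  cat("RWR from {", paste(x$seeds, collapse = ", "), "}: ",
      x$iterations, " iterations, ",
      if (x$converged) "converged" else "NOT converged", "\n", sep = "")
  top <- utils::head(sort(x$rank_percent), 5L)
  cat("  top non-seed diseases:",
      paste(sprintf("%s (%.2f%%)", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate predicted comorbidities against a reference table
#'
#' The predicted comorbidities of a disease are its network neighbors;
#' precision is the fraction of predictions found in the reference set and
#' recall the fraction of the reference set predicted. Reference terms are
#' matched after normalization to the network vocabulary (composite
#' reference entries should be stored pre-expanded into constituents).
#'
#' @param net a `disease_network`.
#' @param disease the disease to evaluate (must be a network node and a
#'   reference key).
#' @param reference a `reference_comorbidities` list (see
#'   [read_reference_comorbidities()] or
#'   [generate_reference_comorbidities()]).
#' @return list `precision` (NA if the disease has no neighbors), `recall`,
#'   `predicted`, `reference`, `matched`.
#' @export
evaluate_comorbidities <- function(net, disease, reference) {
  stopifnot(inherits(net, "disease_network"))
  if (!disease %in% names(reference)) {
    stop("disease '", disease, "' has no reference comorbidity set", call. = FALSE)
  }
  predicted <- neighbors(net, disease)
  ref <- reference[[disease]]
  matched <- intersect(predicted, ref)
  list(
    precision = if (length(predicted) == 0L) NA_real_
                else length(matched) / length(predicted),
    recall = length(matched) / length(ref),
    predicted = predicted, reference = ref, matched = matched
  )
}

#' Read a reference comorbidity table
#'
#' TSV with columns `disease`, `comorbidity` and optionally `source`; one
#' row per (disease, reference comorbidity) pair, composites pre-expanded.
#' Terms are normalized through `term_map` when given (DROP/unmapped terms
#' are removed), so the table can be matched against the network vocabulary.
#'
#' @param path TSV path.
#' @param term_map optional [term_map()] used to canonicalize both the
#'   disease keys and the comorbidity terms.
#' @return a `reference_comorbidities` named list.
#' @export
read_reference_comorbidities <- function(path, term_map = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", colClasses = "character",
                          stringsAsFactors = FALSE)
  if (!all(c("disease", "comorbidity") %in% names(df))) {
    stop("reference table must have columns disease and comorbidity",
         call. = FALSE)
  }
  if (!is.null(term_map)) {
    stopifnot(inherits(term_map, "term_map"))
    dmap <- unname(term_map[normalize_term(df$disease)])
    cmap <- unname(term_map[normalize_term(df$comorbidity)])
    keep <- !is.na(dmap) & !is.na(cmap) & dmap != "DROP" & cmap != "DROP"
    df <- data.frame(disease = dmap[keep], comorbidity = cmap[keep],
                     source = (df$source %||% rep("", nrow(df)))[keep],
                     stringsAsFactors = FALSE)
  }
  ref <- lapply(split(df$comorbidity, df$disease), function(x) sort(unique(x)))
  if (any(lengths(ref) == 0L)) {
    stop("reference sets must be non-empty", call. = FALSE)
  }
  structure(ref,
            source = vapply(split(df$source %||% rep("", nrow(df)), df$disease),
                            function(s) paste(unique(s[s != ""]), collapse = "; "),
                            character(1L)),
            class = "reference_comorbidities")
}

#' Rank report for diseases of interest
#'
#' One row per disease: its RWR percentile (2 decimals; 0.00 = top) and
#' whether it is a known reference comorbidity of the seed. Diseases absent
#' from the network are flagged with an `NA` rank. Rows are sorted by rank.
#'
#' @param result an `rwr_result`.
#' @param diseases_of_interest character vector.
#' @param reference optional `reference_comorbidities`; membership is looked
#'   up under the (single) seed disease.
#' @return data.frame `disease`, `rank_percent`, `comorbidity`
#'   (`"yes"`/`"no"`/`""` when no reference), `in_network`.
#' @export
rank_report <- function(result, diseases_of_interest, reference = NULL) {
  stopifnot(inherits(result, "rwr_result"))
  ref_set <- if (!is.null(reference) && length(result$seeds) == 1L &&
                 result$seeds %in% names(reference)) {
    reference[[result$seeds]]
  } else {
    NULL
  }
  rank <- result$rank_percent[diseases_of_interest]
  df <- data.frame(
    disease = diseases_of_interest,
    rank_percent = round(unname(rank), 2L),
    comorbidity = if (is.null(ref_set)) ""
                  else ifelse(diseases_of_interest %in% ref_set, "yes", "no"),
    in_network = diseases_of_interest %in% names(result$rank_percent),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$rank_percent, na.last = TRUE), , drop = FALSE]
  rownames(df) <- NULL
  df
}
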