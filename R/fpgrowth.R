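# Frequent-itemset mining by FP-growth, and association-rule generation.
#
# FP-growth compresses the transaction database into a prefix tree (FP-tree)
# whose paths are transactions with items sorted by descending global
# frequency, then mines frequent itemsets by recursively building
# conditional pattern bases per item, avoiding Apriori-style candidate
# generation. Support here is an absolute transaction count and both the
# support and the confidence thresholds are STRICT lower bounds, matching
# the mining convention "support > s, confidence > c" used for comorbidity
# rules.

#' Mining parameters
#'
#' @param min_support_count strict lower bound on support counts: an itemset
#'   is frequent iff its count is strictly greater than this. May be given
#'   as a fraction via `min_support_fraction` instead, converted by
#'   multiplying with the database size at mining time.
#' @param min_confidence strict lower bound in \[0, 1) on rule confidence.
#' @param max_itemset_size optional cap on mined itemset size (`Inf` =
#'   unlimited).
#' @param consequent_mode `"single_item"` (one-disease consequents, the
#'   default) or `"all_splits"` (every non-trivial bipartition of each
#'   frequent itemset).
#' @param min_support_fraction optional fractional alias for
#'   `min_support_count`.
#' @return a `mining_params` object.
#' @export
mining_params <- function(min_support_count = 12L,
                          min_confidence = 0.5,
                          max_itemset_size = Inf,
                          consequent_mode = c("single_item", "all_splits"),
                          min_support_fraction = NULL) {
  consequent_mode <- match.arg(consequent_mode)
  if (is.null(min_support_fraction)) {
    if (!is.numeric(min_support_count) || min_support_count < 1 ||
        min_support_count != round(min_support_count)) {
      stop("`min_support_count` must be an integer >= 1", call. = FALSE)
    }
  } else if (min_support_fraction < 0 || min_support_fraction >= 1) {
    stop("`min_support_fraction` must lie in [0, 1)", call. = FALSE)
  }
  if (!is.numeric(min_confidence) || min_confidence < 0 || min_confidence >= 1) {
    stop("`min_confidence` must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(min_support_count = if (is.null(min_support_fraction))
           as.integer(min_support_count) else NA_integer_,
         min_support_fraction = min_support_fraction,
         min_confidence = min_confidence,
         max_itemset_size = max_itemset_size,
         consequent_mode = consequent_mode),
    class = "mining_params"
  )
}

resolve_min_support <- function(params, n_transactions) {
  if (!is.null(params$min_support_fraction)) {
    params$min_support_fraction * n_transactions
  } else {
    params$min_support_count
  }
}

#' Support of an itemset
#'
#' Number of transactions containing every member of `itemset`.
#'
#' @param db a `transaction_db`.
#' @param itemset non-empty character vector of disease terms.
#' @return integer count.
#' @export
support <- function(db, itemset) {
  stopifnot(inherits(db, "transaction_db"))
  if (length(itemset) == 0L) stop("`itemset` must be non-empty", call. = FALSE)
  itemset <- unique(itemset)
  sum(vapply(db$transactions, function(tx) all(itemset %in% tx), logical(1L)))
}

# ---- FP-tree internals -----------------------------------------------------
# Nodes are environments (mutable): fields item, count, parent, children
# (named list of child environments). The header table maps each item to the
# list of its tree nodes for the side links used when collecting conditional
# pattern bases.

fp_new_node <- function(item, parent) {
  node <- new.env(parent = emptyenv())
  node$item <- item
  node$count <- 0L
  node$parent <- parent
  node$children <- list()
  node
}

# itemsets: list of character vectors already filtered to frequent items and
# ordered by the global rank; weights: transaction multiplicities.
fp_build_tree <- function(itemsets, weights) {
  root <- fp_new_node(NA_character_, NULL)
  header <- new.env(parent = emptyenv())
  for (i in seq_along(itemsets)) {
    node <- root
    for (item in itemsets[[i]]) {
      child <- node$children[[item]]
      if (is.null(child)) {
        child <- fp_new_node(item, node)
        node$children[[item]] <- child
        header[[item]] <- c(header[[item]], list(child))
      }
      child$count <- child$count + weights[i]
      node <- child
    }
  }
  list(root = root, header = header)
}

# Recursive mining over conditional pattern bases. `suffix` is the itemset
# conditioned on so far; results are appended into `out` (an environment used
# as a growable hash: canonical itemset key -> support).
fp_mine <- function(itemsets, weights, min_support, suffix, max_size, out) {
  if (length(itemsets) == 0L) return(invisible())
  counts <- tapply(rep(weights, lengths(itemsets)),
                   unlist(itemsets, use.names = FALSE), sum)
  keep_items <- names(counts)[counts > min_support]
  if (length(keep_items) == 0L) return(invisible())
  # global order: frequency descending, ties lexicographic (deterministic)
  rank <- order(-counts[keep_items], keep_items)
  ordered_items <- keep_items[rank]
  item_rank <- stats::setNames(seq_along(ordered_items), ordered_items)
  filtered <- lapply(itemsets, function(tx) {
    tx <- tx[tx %in% keep_items]
    tx[order(item_rank[tx])]
  })
  nonempty <- lengths(filtered) > 0L
  tree <- fp_build_tree(filtered[nonempty], weights[nonempty])
  # mine items from least to most frequent (bottom of the tree upward)
  for (item in rev(ordered_items)) {
    supp <- sum(vapply(tree$header[[item]], function(nd) nd$count, numeric(1L)))
    new_set <- c(item, suffix)
    out[[itemset_key(new_set)]] <- as.integer(supp)
    if (length(new_set) >= max_size) next
    # conditional pattern base: prefix path of every node carrying `item`
    base <- list()
    base_w <- numeric(0L)
    for (nd in tree$header[[item]]) {
      path <- character(0L)
      up <- nd$parent
      while (!is.null(up$parent)) {
        path <- c(up$item, path)
        up <- up$parent
      }
      if (length(path) > 0L) {
        base[[length(base) + 1L]] <- path
        base_w <- c(base_w, nd$count)
      }
    }
    fp_mine(base, base_w, min_support, new_set, max_size, out)
  }
  invisible()
}

#' Mine frequent itemsets with FP-growth
#'
#' Returns every itemset (size >= 1) whose support count is strictly greater
#' than the support threshold. Output is canonically ordered (support
#' descending, then itemset key lexicographically) and independent of
#' transaction order.
#'
#' @param db a `transaction_db`.
#' @param params a [mining_params()].
#' @return data.frame with columns `itemset` (sorted, `;`-joined), `size`,
#'   and `support`.
#' @examples
#' db <- transaction_db(list(r1 = c("A", "B"), r2 = c("A", "B"), r3 = "A"))
#' mine_frequent_itemsets(db, mining_params(min_support_count = 1))
#' @export
mine_frequent_itemsets <- function(db, params = mining_params()) {
  stopifnot(inherits(db, "transaction_db"), inherits(params, "mining_params"))
  if (length(db$transactions) == 0L) {
    warning("empty transaction database: no frequent itemsets", call. = FALSE)
    return(data.frame(itemset = character(0L), size = integer(0L),
                      support = integer(0L)))
  }
  min_support <- resolve_min_support(params, length(db$transactions))
  out <- new.env(parent = emptyenv())
  fp_mine(unname(db$transactions), rep(1L, length(db$transactions)),
          min_support, character(0L), params$max_itemset_size, out)
  keys <- ls(out)
  res <- data.frame(
    itemset = keys,
    size = vapply(keys, function(k) length(split_key(k)), integer(1L)),
    support = vapply(keys, function(k) out[[k]], integer(1L)),
    stringsAsFactors = FALSE
  )
  res <- res[order(-res$support, res$itemset), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Generate association rules from frequent itemsets
#'
#' For each frequent itemset of size >= 2, emits rules `X -> Y` whose
#' confidence `support(X u Y) / support(X)` is strictly greater than the
#' confidence threshold. In `single_item` mode each single item is tried as
#' the consequent; in `all_splits` mode every non-trivial bipartition is.
#' Output is ordered by support descending, then antecedent and consequent
#' lexicographically.
#'
#' @param itemsets data.frame from [mine_frequent_itemsets()]. Must be closed
#'   under subsets (FP-growth output is).
#' @param params a [mining_params()].
#' @return data.frame with columns `antecedent`, `consequent` (sorted,
#'   `;`-joined), `support_count`, `confidence`; class `association_rules`.
#' @export
generate_rules <- function(itemsets, params = mining_params()) {
  stopifnot(is.data.frame(itemsets), inherits(params, "mining_params"))
  supp_of <- stats::setNames(itemsets$support, itemsets$itemset)
  lookup <- function(key) {
    s <- unname(supp_of[match(key, names(supp_of))])
    if (is.na(s)) {
      stop("internal consistency error: support of antecedent {", key,
           "} missing from itemset table", call. = FALSE)
    }
    s
  }
  ante <- character(0L); cons <- character(0L)
  supp <- integer(0L); conf <- numeric(0L)
  big <- itemsets[itemsets$size >= 2L, , drop = FALSE]
  for (i in seq_len(nrow(big))) {
    items <- split_key(big$itemset[i])
    s_all <- big$support[i]
    splits <- if (params$consequent_mode == "single_item") {
      lapply(seq_along(items), function(j) list(x = items[-j], y = items[j]))
    } else {
      # every non-empty proper subset of `items` as consequent
      n <- length(items)
      unlist(lapply(seq_len(2^n - 2L), function(mask) {
        sel <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1L)))
        list(list(x = items[!sel], y = items[sel]))
      }), recursive = FALSE)
    }
    for (sp in splits) {
      s_x <- lookup(itemset_key(sp$x))
      if (s_all / s_x > params$min_confidence) {
        ante <- c(ante, itemset_key(sp$x))
        cons <- c(cons, itemset_key(sp$y))
        supp <- c(supp, s_all)
        conf <- c(conf, s_all / s_x)
      }
    }
  }
  rules <- data.frame(antecedent = ante, consequent = cons,
                      support_count = supp, confidence = conf,
                      stringsAsFactors = FALSE)
  rules <- rules[order(-rules$support_count, rules$antecedent, rules$consequent),
                 , drop = FALSE]
  rownames(rules) <- NULL
  class(rules) <- c("association_rules", "data.frame")
  rules
}

#' Mine association rules in one step
#'
#' Convenience wrapper: [mine_frequent_itemsets()] then [generate_rules()].
#'
#' @inheritParams mine_frequent_itemsets
#' @return an `association_rules` data.frame.
#' @export
mine_rules <- function(db, params = mining_params()) {
  generate_rules(mine_frequent_itemsets(db, params), params)
}

#' Write / read association rules as TSV
#'
#' Columns `antecedent`, `consequent` (semicolon-joined, sorted),
#' `support_count`, `confidence` (6 decimals on disk).
#'
#' @param rules an `association_rules` data.frame.
#' @param path TSV path.
#' @return `path` invisibly / the rules data.frame.
#' @export
write_rules <- function(rules, path) {
  out <- rules
  out$confidence <- sprintf("%.6f", out$confidence)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          colClasses = c("character", "character",
                                         "integer", "numeric"))
  class(df) <- c("association_rules", "data.frame")
  df
}
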