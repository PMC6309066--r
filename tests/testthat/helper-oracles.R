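# Independent brute-force oracles used to verify the algorithmic modules.
# They deliberately share no code with the implementations they check.

# ---- frequent-itemset / rule oracles (bitmask power-set enumeration) -------

# Exhaustive itemset counting: every non-empty subset of the vocabulary is a
# candidate; support by bitmask containment. Returns the same column layout
# and ordering contract as mine_frequent_itemsets().
bf_itemsets <- function(db, min_support) {
  items <- db$vocabulary
  n <- length(items)
  stopifnot(n <= 16L)
  tx_mask <- vapply(db$transactions, function(tx) {
    sum(2L^(match(tx, items) - 1L))
  }, numeric(1L))
  keys <- character(0L); sizes <- integer(0L); supports <- integer(0L)
  for (mask in seq_len(2L^n - 1L)) {
    supp <- sum(bitwAnd(tx_mask, mask) == mask)
    if (supp > min_support) {
      members <- items[bitwAnd(mask, 2L^(seq_len(n) - 1L)) > 0L]
      keys <- c(keys, paste(sort(members), collapse = ";"))
      sizes <- c(sizes, length(members))
      supports <- c(supports, supp)
    }
  }
  out <- data.frame(itemset = keys, size = sizes, support = supports,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$support, out$itemset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exhaustive rule generation over every frequent itemset's splits.
bf_rules <- function(itemsets, min_confidence, mode) {
  supp_of <- stats::setNames(itemsets$support, itemsets$itemset)
  rows <- list()
  for (i in seq_len(nrow(itemsets))) {
    if (itemsets$size[i] < 2L) next
    members <- strsplit(itemsets$itemset[i], ";", fixed = TRUE)[[1L]]
    n <- length(members)
    masks <- if (mode == "single_item") 2L^(seq_len(n) - 1L) else seq_len(2L^n - 2L)
    for (mask in masks) {
      y <- members[bitwAnd(mask, 2L^(seq_len(n) - 1L)) > 0L]
      x <- setdiff(members, y)
      if (length(x) == 0L || length(y) == 0L) next
      s_x <- supp_of[[paste(sort(x), collapse = ";")]]
      conf <- itemsets$support[i] / s_x
      if (conf > min_confidence) {
        rows[[length(rows) + 1L]] <- data.frame(
          antecedent = paste(sort(x), collapse = ";"),
          consequent = paste(sort(y), collapse = ";"),
          support_count = itemsets$support[i], confidence = conf,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(antecedent = character(0L), consequent = character(0L),
                      support_count = integer(0L), confidence = numeric(0L)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$support_count, out$antecedent, out$consequent), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

random_db <- function(n_items, n_transactions, max_tx_size = 5L) {
  items <- LETTERS[seq_len(n_items)]
  max_tx_size <- min(max_tx_size, n_items)
  txs <- lapply(seq_len(n_transactions), function(i) {
    sample(items, sample.int(max_tx_size, 1L))
  })
  names(txs) <- sprintf("t%03d", seq_len(n_transactions))
  transaction_db(txs)
}

# ---- edge betweenness oracle (explicit shortest-path enumeration) ----------

# For every unordered node pair, enumerate ALL shortest paths (via the BFS
# predecessor DAG) and give each edge on each path 1/#paths credit.
bf_edge_betweenness <- function(net) {
  nodes <- net$nodes
  n <- length(nodes)
  adj <- lapply(nodes, function(v) {
    c(net$edges$to[net$edges$from == v], net$edges$from[net$edges$to == v])
  })
  names(adj) <- nodes
  eb <- stats::setNames(numeric(nrow(net$edges)),
                        paste(net$edges$from, net$edges$to, sep = ";"))
  all_paths <- function(preds, target, source) {
    if (target == source) return(list(source))
    out <- list()
    for (p in preds[[target]]) {
      for (sub in all_paths(preds, p, source)) {
        out[[length(out) + 1L]] <- c(sub, target)
      }
    }
    out
  }
  for (si in seq_len(n - 1L)) {
    s <- nodes[si]
    # BFS predecessor DAG from s
    dist <- stats::setNames(rep(Inf, n), nodes)
    dist[s] <- 0
    preds <- stats::setNames(vector("list", n), nodes)
    queue <- s
    while (length(queue) > 0L) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1) preds[[w]] <- union(preds[[w]], v)
      }
    }
    for (ti in seq.int(si + 1L, n)) {
      t <- nodes[ti]
      if (is.infinite(dist[t])) next
      paths <- all_paths(preds, t, s)
      for (pth in paths) {
        for (k in seq_len(length(pth) - 1L)) {
          a <- min(pth[k], pth[k + 1L]); b <- max(pth[k], pth[k + 1L])
          key <- paste(a, b, sep = ";")
          eb[key] <- eb[key] + 1 / length(paths)
        }
      }
    }
  }
  eb
}

random_network <- function(n_nodes, p_edge = 0.3) {
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- utils::combn(nodes, 2L)
  keep <- stats::runif(ncol(pairs)) < p_edge
  if (!any(keep)) keep[sample.int(ncol(pairs), 1L)] <- TRUE
  disease_network(nodes, data.frame(from = pairs[1L, keep],
                                    to = pairs[2L, keep]))
}

to_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

# ---- cluster statistic / similarity oracles --------------------------------

# Explicit double loop over ordered pairs, halved — independent of combn().
bf_pair_mean <- function(cluster, f) {
  n <- length(cluster)
  if (n < 2L) return(NA_real_)
  total <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) total <- total + f(cluster[i], cluster[j])
    }
  }
  total / (n * (n - 1))
}

# Resnik oracle: transitive-closure ancestorhood by repeated parent lookup,
# descendant counts by scanning every term for reachability.
bf_ancestor_set <- function(ont, term) {
  out <- term
  repeat {
    nxt <- unique(c(out, unlist(ont$parents[out], use.names = FALSE)))
    if (length(nxt) == length(out)) return(out)
    out <- nxt
  }
}

bf_resnik <- function(d1, d2, ont) {
  n <- length(ont$terms)
  p_of <- vapply(ont$terms, function(a) {
    sum(vapply(ont$terms, function(t) a %in% bf_ancestor_set(ont, t),
               logical(1L))) / n
  }, numeric(1L))
  common <- intersect(bf_ancestor_set(ont, d1), bf_ancestor_set(ont, d2))
  if (length(common) == 0L) return(0)
  max(-log(p_of[common]))
}

# ---- RWR closed-form oracle ------------------------------------------------

bf_rwr_solve <- function(net, seeds, gamma) {
  n <- length(net$nodes)
  A <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges) > 0L) {
    i <- match(net$edges$from, net$nodes)
    j <- match(net$edges$to, net$nodes)
    A[cbind(i, j)] <- 1
    A[cbind(j, i)] <- 1
  }
  p0 <- stats::setNames(rep(0, n), net$nodes)
  p0[seeds] <- 1 / length(seeds)
  cs <- colSums(A)
  M <- A
  for (c_idx in seq_len(n)) {
    M[, c_idx] <- if (cs[c_idx] == 0) p0 else A[, c_idx] / cs[c_idx]
  }
  p <- solve(diag(n) - (1 - gamma) * M, gamma * p0)
  stats::setNames(as.vector(p), net$nodes)
}

# ---- hypergeometric tail oracle --------------------------------------------

bf_hyper_upper <- function(k, K, N, n_draw) {
  ks <- k:min(K, n_draw)
  sum(choose(K, ks) * choose(N - K, n_draw - ks)) / choose(N, n_draw)
}
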