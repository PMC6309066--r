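# End-to-end convenience wrapper: transactions -> rules -> network ->
# clusters. Each stage is also exposed on its own; this wrapper exists for
# the common mine-and-cluster path used in benchmarks and examples.

#' Run the mine-build-cluster pipeline
#'
#' Mines association rules from the transactions, builds the comorbidity
#' network and detects its communities.
#'
#' @param db a `transaction_db`.
#' @param params a [mining_params()].
#' @param edge_policy passed to [build_network()].
#' @param node_category optional named category labels for the network.
#' @param min_report_size passed to [girvan_newman()].
#' @return list with `itemsets`, `rules`, `network`, `partition`.
#' @export
comorbidity_pipeline <- function(db, params = mining_params(),
                                 edge_policy = "cross_only",
                                 node_category = NULL,
                                 min_report_size = 10L) {
  itemsets <- mine_frequent_itemsets(db, params)
  rules <- generate_rules(itemsets, params)
  network <- build_network(rules, edge_policy, node_category = node_category)
  partition <- girvan_newman(network, min_report_size = min_report_size)
  list(itemsets = itemsets, rules = rules, network = network,
       partition = partition)
}
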