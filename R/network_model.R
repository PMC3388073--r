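# Count, for every node, how many of its neighbors are DEG nodes, and its
# total degree. Vectorized over the edge table.
node_deg_counts <- function(net) {
  nodes <- net$nodes$node
  is_deg <- stats::setNames(net$nodes$role == "deg", nodes)
  deg_n <- stats::setNames(integer(length(nodes)), nodes)
  tot_n <- deg_n
  if (nrow(net$edges)) {
    ends <- c(net$edges$from, net$edges$to)
    other <- c(net$edges$to, net$edges$from)
    t_tab <- table(factor(ends, levels = nodes))
    tot_n[] <- as.integer(t_tab)
    d_tab <- table(factor(ends[is_deg[other]], levels = nodes))
    deg_n[] <- as.integer(d_tab)
  }
  data.frame(node = nodes, deg_neighbors = unname(deg_n),
             total_degree = unname(tot_n), stringsAsFactors = FALSE)
}

#' Build the initial DEG-seeded first-neighbor network
#'
#' The initial network contains the seed DEGs and all of their first
#' neighbors in the interaction data, with every interaction edge whose two
#' endpoints both fall in that node set. Seed DEGs absent from the
#' interaction data are retained as isolated nodes (degree 0); it is an
#' error if *no* seed appears in the interaction data. Node roles are set
#' to `"deg"` for seeds and `"neighbor"` otherwise.
#'
#' @param degs Character vector of seed DEG identifiers (non-empty).
#' @param interactions An [interaction_network()] of the full interactome.
#' @return An [interaction_network()] restricted to the closed first
#'   neighborhood of the seeds.
#' @export
build_initial_network <- function(degs, interactions) {
  stopifnot(inherits(interactions, "interaction_network"))
  degs <- unique(as.character(degs))
  if (!length(degs)) stop("empty DEG seed set")
  known <- interactions$nodes$node
  if (!any(degs %in% known))
    stop("no seed DEG appears in the interaction data")
  ed <- interactions$edges
  touch <- ed$from %in% degs | ed$to %in% degs
  neighbors <- setdiff(unique(c(ed$from[touch], ed$to[touch])), degs)
  keep_nodes <- c(degs, neighbors)
  keep_edges <- ed[ed$from %in% keep_nodes & ed$to %in% keep_nodes, ,
                   drop = FALSE]
  roles <- stats::setNames(ifelse(keep_nodes %in% degs, "deg", "neighbor"),
                           keep_nodes)
  interaction_network(keep_edges, nodes = keep_nodes, roles = roles,
                      regulators = net_regulators(interactions))
}

# regulator identifiers flagged on a network's node table
net_regulators <- function(net) net$nodes$node[net$nodes$regulator]

#' Prune non-bridging neighbors from a DEG-seeded network
#'
#' Removes every first neighbor that does not contribute to connecting DEG
#' nodes, operationalized as adjacency to at least two DEG nodes (a
#' neighbor touching a single DEG connects nothing). DEG nodes are never
#' removed; edges are restricted to the surviving nodes. The rule is a
#' single pass and idempotent, since removing neighbors never changes any
#' other node's DEG adjacency.
#'
#' @param net An [interaction_network()] with roles assigned (from
#'   [build_initial_network()]).
#' @return The pruned network.
#' @export
prune_network <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  counts <- node_deg_counts(net)
  is_deg <- net$nodes$role == "deg"
  keep <- is_deg | counts$deg_neighbors >= 2L
  keep_nodes <- net$nodes$node[keep]
  ed <- net$edges[net$edges$from %in% keep_nodes &
                    net$edges$to %in% keep_nodes, , drop = FALSE]
  roles <- stats::setNames(net$nodes$role[keep], keep_nodes)
  interaction_network(ed, nodes = keep_nodes, roles = roles,
                      regulators = net_regulators(net))
}

#' Degree centrality of a node over the DEG set
#'
#' The number of DEG nodes adjacent to `node` — the quantity that measures
#' a regulator's reach over the differentially expressed genes. (Total
#' degree is available from [node_degrees()].)
#'
#' @param net An [interaction_network()].
#' @param node A node identifier present in the network.
#' @return Integer count of adjacent DEG nodes.
#' @export
degree_centrality <- function(net, node) {
  stopifnot(inherits(net, "interaction_network"))
  if (!node %in% net$nodes$node)
    stop("unknown node: ", node)
  counts <- node_deg_counts(net)
  counts$deg_neighbors[match(node, counts$node)]
}

#' Per-node degree summaries
#'
#' @param net An [interaction_network()].
#' @return Data frame with columns `node`, `deg_neighbors` (DEG-adjacent
#'   count, the primary centrality), `total_degree`.
#' @export
node_degrees <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  node_deg_counts(net)
}

#' Rank candidate regulators by degree centrality
#'
#' Sorts the supplied regulators (transcription factors / signaling genes
#' among the DEG nodes) by their DEG-adjacent degree in the network,
#' descending, with alphabetical tie-breaking, and assigns dense ranks
#' 1..R. A regulator with high degree centrality is a candidate key
#' controller of the processes in the network.
#'
#' @param net An [interaction_network()] (typically pruned).
#' @param regulators Non-empty character vector; must be DEG nodes of
#'   `net`.
#' @return Data frame `gene`, `degree` (DEG-adjacent), `total_degree`,
#'   `rank`.
#' @export
rank_regulators <- function(net, regulators) {
  stopifnot(inherits(net, "interaction_network"))
  regulators <- unique(as.character(regulators))
  if (!length(regulators)) stop("empty regulator set")
  deg_nodes <- net$nodes$node[net$nodes$role == "deg"]
  bad <- setdiff(regulators, deg_nodes)
  if (length(bad))
    stop("regulator(s) not among the network's DEG nodes: ",
         paste(bad, collapse = ", "))
  counts <- node_deg_counts(net)
  idx <- match(regulators, counts$node)
  out <- data.frame(gene = regulators,
                    degree = counts$deg_neighbors[idx],
                    total_degree = counts$total_degree[idx],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$gene), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Group network nodes into functional modules
#'
#' Labels every node with the most significantly enriched annotation term
#' that contains it (smallest raw p, alphabetical term tiebreak), using an
#' enrichment result computed on the network's DEG nodes; nodes covered by
#' no enriched term are labeled `"unassigned"`.
#'
#' @param net An [interaction_network()].
#' @param enrichment An [enrich()] result.
#' @param sets The term -> members list the enrichment was computed from.
#' @param alpha Raw-p significance cutoff defining "enriched" terms
#'   (default 0.05).
#' @return `net` with the `module` column of its node table filled.
#' @export
assign_modules <- function(net, enrichment, sets, alpha = 0.05) {
  stopifnot(inherits(net, "interaction_network"))
  sig <- enrichment[enrichment$p < alpha, , drop = FALSE]
  sig <- sig[order(sig$p, sig$term), , drop = FALSE]
  labels <- rep("unassigned", nrow(net$nodes))
  if (nrow(sig)) {
    for (i in seq_len(nrow(net$nodes))) {
      node <- net$nodes$node[i]
      hit <- which(vapply(sig$term, function(tm) node %in% sets[[tm]],
                          logical(1L)))
      if (length(hit)) labels[i] <- sig$term[hit[1L]]
    }
  }
  net$nodes$module <- labels
  net
}
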