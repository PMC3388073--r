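#' Interaction network container
#'
#' An undirected graph of gene/protein nodes. Edges carry their provenance
#' kind (`"pp"` protein-protein, `"pd"` protein-DNA); nodes carry a role
#' (`"deg"` or `"neighbor"`), a regulator flag, and an optional module label.
#' Self-loops are rejected and duplicate (unordered) edges are collapsed.
#'
#' @param edges Data frame with columns `from`, `kind`, `to` (or `from`,
#'   `to`, `kind`); kinds must be `"pp"` or `"pd"`.
#' @param nodes Optional character vector of node identifiers; defaults to
#'   the nodes appearing in `edges`. Extra isolated nodes are allowed.
#' @param roles Optional named character vector node -> `"deg"`/`"neighbor"`;
#'   defaults to `"neighbor"` for all.
#' @param regulators Optional character vector of regulator node identifiers.
#' @return An object of class `interaction_network`: list with `nodes`
#'   (data frame: `node`, `role`, `regulator`, `module`) and `edges`
#'   (data frame: `from`, `to`, `kind`; `from < to` lexicographically).
#' @export
interaction_network <- function(edges, nodes = NULL, roles = NULL,
                                regulators = character()) {
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        kind = character(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("from", "to", "kind") %in% colnames(edges)))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$kind <- as.character(edges$kind)
  bad_kind <- setdiff(unique(edges$kind), c("pp", "pd"))
  if (length(bad_kind))
    stop("unknown interaction kind(s): ", paste(bad_kind, collapse = ", "),
         "; accepted tokens are 'pp' and 'pd'")
  loops <- edges$from == edges$to
  if (any(loops))
    stop("self-loop edge(s) not allowed: ",
         paste(unique(edges$from[loops]), collapse = ", "))
  # canonical unordered representation, then dedupe (kind kept from first)
  lo <- pmin(edges$from, edges$to)
  hi <- pmax(edges$from, edges$to)
  edges <- data.frame(from = lo, to = hi, kind = edges$kind,
                      stringsAsFactors = FALSE)
  edges <- edges[!duplicated(paste(edges$from, edges$to, sep = "\r")), ,
                 drop = FALSE]
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL

  endpoint_nodes <- union(edges$from, edges$to)
  if (is.null(nodes)) {
    all_nodes <- endpoint_nodes
  } else {
    undeclared <- setdiff(endpoint_nodes, nodes)
    if (length(undeclared))
      stop("edge endpoint(s) not among declared nodes: ",
           paste(undeclared, collapse = ", "))
    all_nodes <- nodes
  }
  all_nodes <- sort(unique(all_nodes))
  role <- rep("neighbor", length(all_nodes))
  names(role) <- all_nodes
  if (!is.null(roles)) {
    bad <- setdiff(unique(roles), c("deg", "neighbor"))
    if (length(bad)) stop("unknown role(s): ", paste(bad, collapse = ", "))
    role[names(roles)[names(roles) %in% all_nodes]] <-
      roles[names(roles) %in% all_nodes]
  }
  nd <- data.frame(node = all_nodes, role = unname(role),
                   regulator = all_nodes %in% regulators,
                   module = NA_character_, stringsAsFactors = FALSE)
  rownames(nd) <- NULL
  structure(list(nodes = nd, edges = edges), class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("interaction_network: %d nodes (%d deg, %d regulator), %d edges\n",
              nrow(x$nodes), sum(x$nodes$role == "deg"),
              sum(x$nodes$regulator), nrow(x$edges)))
  invisible(x)
}

#' Read an interaction edge list (SIF / 3-column TSV)
#'
#' Each non-empty line encodes `node <kind> node`, whitespace- or
#' tab-separated, with kind `"pp"` (protein-protein) or `"pd"`
#' (protein-DNA). The graph is undirected; duplicate edges are collapsed
#' and self-loops are an error.
#'
#' @param path Path to the SIF/TSV file.
#' @return An [interaction_network()].
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(interaction_network(NULL))
  parts <- strsplit(lines, "[\t ]+")
  nf <- lengths(parts)
  if (any(nf != 3L))
    stop("line ", which(nf != 3L)[1L],
         ": expected 3 fields (node kind node), found ", nf[nf != 3L][1L])
  m <- do.call(rbind, parts)
  interaction_network(data.frame(from = m[, 1L], kind = m[, 2L], to = m[, 3L],
                                 stringsAsFactors = FALSE))
}

#' Write an interaction network as a SIF edge list
#'
#' @param net An [interaction_network()].
#' @param path Output path.
#' @return `net`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "interaction_network"))
  writeLines(paste(net$edges$from, net$edges$kind, net$edges$to, sep = "\t"),
             path)
  invisible(net)
}

# igraph view of the network (attributes carried over).
as_igraph <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  igraph::graph_from_data_frame(
    d = net$edges[, c("from", "to", "kind")],
    directed = FALSE,
    vertices = net$nodes
  )
}

#' Export a network to GraphML
#'
#' Node attributes exported: `role` (deg/neighbor), `regulator`,
#' `module_label`, and optional per-node differential-expression directions
#' from the two datasets (matching the network figure's color semantics).
#'
#' @param net An [interaction_network()].
#' @param path Output `.graphml` path.
#' @param direction_mouse,direction_human Optional named character vectors
#'   (node -> "up"/"down") recorded as node attributes.
#' @return `net`, invisibly.
#' @export
write_graphml <- function(net, path, direction_mouse = NULL,
                          direction_human = NULL) {
  stopifnot(inherits(net, "interaction_network"))
  nd <- net$nodes
  nd$module_label <- ifelse(is.na(nd$module), "unassigned", nd$module)
  nd$module <- NULL
  fill_dir <- function(v) {
    out <- rep("none", nrow(nd))
    if (!is.null(v)) {
      hit <- match(nd$node, names(v))
      out[!is.na(hit)] <- unname(v[hit[!is.na(hit)]])
    }
    out
  }
  nd$direction_mouse <- fill_dir(direction_mouse)
  nd$direction_human <- fill_dir(direction_human)
  g <- igraph::graph_from_data_frame(net$edges[, c("from", "to", "kind")],
                                     directed = FALSE, vertices = nd)
  igraph::write_graph(g, path, format = "graphml")
  invisible(net)
}

# adjacency list: node -> character vector of neighbors
adjacency_list <- function(net) {
  adj <- vector("list", nrow(net$nodes))
  names(adj) <- net$nodes$node
  if (nrow(net$edges)) {
    for (i in seq_len(nrow(net$edges))) {
      f <- net$edges$from[i]; t <- net$edges$to[i]
      adj[[f]] <- c(adj[[f]], t)
      adj[[t]] <- c(adj[[t]], f)
    }
  }
  adj
}
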