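net_from <- function(edge_lines, degs, regulators = character()) {
  parts <- strsplit(edge_lines, " ")
  edges <- data.frame(from = vapply(parts, `[[`, "", 1L),
                      kind = vapply(parts, `[[`, "", 2L),
                      to = vapply(parts, `[[`, "", 3L),
                      stringsAsFactors = FALSE)
  nodes <- union(union(edges$from, edges$to), degs)
  roles <- stats::setNames(ifelse(nodes %in% degs, "deg", "neighbor"), nodes)
  interaction_network(edges, nodes = nodes, roles = roles,
                      regulators = regulators)
}

test_that("initial network is the closed first neighborhood of the seeds", {
  inter <- net_from(c("d1 pp a", "a pp b"), degs = character())
  net <- build_initial_network("d1", inter)
  expect_setequal(net$nodes$node, c("d1", "a"))  # b is a second neighbor
  expect_equal(nrow(net$edges), 1L)
  expect_identical(net$nodes$role[net$nodes$node == "d1"], "deg")
  # a seed absent from the interaction data stays as an isolated node
  net2 <- build_initial_network(c("d1", "lonely"), inter)
  expect_true("lonely" %in% net2$nodes$node)
  expect_equal(degree_centrality(net2, "lonely"), 0L)
  expect_error(build_initial_network("zz", inter), "no seed DEG")
})

test_that("initial node set equals the brute-force neighborhood union", {
  withr::with_seed(51, {
    nodes <- sprintf("n%02d", 1:25)
    pairs <- utils::combn(nodes, 2L)
    pick <- stats::runif(ncol(pairs)) < 0.12
    edges <- data.frame(from = pairs[1L, pick], to = pairs[2L, pick],
                        kind = "pp", stringsAsFactors = FALSE)
    degs <- sample(nodes, 6L)
  })
  inter <- interaction_network(edges, nodes = nodes)
  net <- build_initial_network(degs, inter)
  expect_setequal(net$nodes$node, oracle_neighborhood(edges, degs))
})

test_that("pruning keeps exactly the neighbors bridging >= 2 DEGs", {
  net <- net_from(c("d1 pp n1",              # n1 touches one DEG -> removed
                    "d1 pp n2", "d2 pp n2",  # n2 bridges two DEGs -> kept
                    "d1 pp d2"),
                  degs = c("d1", "d2", "d3"))
  pruned <- prune_network(net)
  expect_setequal(pruned$nodes$node, c("d1", "d2", "d3", "n2"))
  # DEG-DEG edge survives; the dangling neighbor edge is gone
  expect_true(any(pruned$edges$from == "d1" & pruned$edges$to == "d2"))
  expect_false("n1" %in% c(pruned$edges$from, pruned$edges$to))
})

test_that("pruning is idempotent and enforces its postcondition", {
  for (s in 1:20) {
    net <- random_network(n_deg = 7L, n_other = 13L, p_edge = 0.12, seed = s)
    p1 <- prune_network(net)
    p2 <- prune_network(p1)
    expect_identical(p2, p1)
    counts <- node_degrees(p1)
    non_deg <- p1$nodes$role != "deg"
    if (any(non_deg))
      expect_gte(min(counts$deg_neighbors[non_deg]), 2L)
    # no DEG node is ever removed
    expect_setequal(p1$nodes$node[p1$nodes$role == "deg"],
                    net$nodes$node[net$nodes$role == "deg"])
  }
  # a network with no neighbors is a fixed point
  only_degs <- net_from(c("d1 pp d2"), degs = c("d1", "d2"))
  expect_identical(prune_network(only_degs), only_degs)
})

test_that("every DEG-neighbor-DEG bridge survives pruning", {
  for (s in 21:30) {
    net <- random_network(n_deg = 6L, n_other = 10L, p_edge = 0.15, seed = s)
    counts <- node_degrees(net)
    bridges <- net$nodes$node[net$nodes$role != "deg" &
                                counts$deg_neighbors >= 2L]
    pruned <- prune_network(net)
    expect_true(all(bridges %in% pruned$nodes$node))
  }
})

test_that("degree centrality counts DEG neighbors, matching brute force", {
  net <- random_network(n_deg = 8L, n_other = 12L, p_edge = 0.2, seed = 99)
  for (node in net$nodes$node)
    expect_equal(degree_centrality(net, node), oracle_deg_degree(net, node))
  expect_error(degree_centrality(net, "missing"), "unknown node")
})

test_that("regulator ranking sorts by degree with alphabetical ties", {
  net <- net_from(c("ATF3 pd t1", "ATF3 pd t2", "ATF3 pd t3",
                    "X pd t1", "X pd t2", "Y pd t1", "Y pd t3"),
                  degs = c("ATF3", "X", "Y", "t1", "t2", "t3"))
  rk <- rank_regulators(net, c("Y", "ATF3", "X"))
  expect_identical(rk$gene, c("ATF3", "X", "Y"))
  expect_identical(rk$rank, 1:3)
  expect_identical(rk$degree, c(3L, 2L, 2L))
  # all-zero degrees fall back to alphabetical order
  iso <- net_from("a pp b", degs = c("r2", "r1"))
  rk0 <- rank_regulators(iso, c("r2", "r1"))
  expect_identical(rk0$gene, c("r1", "r2"))
  expect_error(rank_regulators(net, character()), "empty")
  expect_error(rank_regulators(net, "t9"), "DEG nodes")
})

test_that("a planted hub ranks first in a simulated interactome", {
  degs <- sprintf("d%02d", 1:40)
  sim <- simulate_interactome(80, degs, hubs = c(d01 = 6L),
                              background_edge_prob = 0.01, seed = 61)
  net <- prune_network(build_initial_network(degs, sim$network))
  rk <- rank_regulators(net, degs[1:10])
  expect_identical(rk$gene[1L], "d01")
  expect_gte(rk$degree[1L], 6L)
})

test_that("module labels pick each node's most significant enriched term", {
  net <- net_from(c("a pp b", "b pp c"), degs = c("a", "b", "c"))
  enr <- data.frame(term = c("T_STRONG", "T_WEAK", "T_NS"),
                    p = c(0.001, 0.01, 0.5), stringsAsFactors = FALSE)
  sets <- list(T_STRONG = c("a", "b"), T_WEAK = c("b", "c"), T_NS = "c")
  out <- assign_modules(net, enr, sets)
  lab <- stats::setNames(out$nodes$module, out$nodes$node)
  expect_identical(lab[["a"]], "T_STRONG")
  expect_identical(lab[["b"]], "T_STRONG")   # 0.001 beats 0.01
  expect_identical(lab[["c"]], "T_WEAK")     # T_NS is not significant
  # with no enriched terms everything is unassigned
  out0 <- assign_modules(net, enr[enr$p > 0.2, ], sets)
  expect_true(all(out0$nodes$module == "unassigned"))
})

test_that("GraphML export writes roles, regulator flags and directions", {
  net <- net_from(c("ATF3 pd ID1", "ATF3 pd ICA1"),
                  degs = c("ATF3", "ID1", "ICA1"), regulators = "ATF3")
  f <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, f, direction_mouse = c(ATF3 = "down"),
                direction_human = c(ATF3 = "up"))
  doc <- paste(readLines(f), collapse = "\n")
  expect_match(doc, "direction_mouse")
  expect_match(doc, "ATF3")
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::gorder(g), 3)
  expect_equal(igraph::gsize(g), 2)
})
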