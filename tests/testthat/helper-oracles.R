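# Independent brute-force oracles used to freeze expected values.
# These deliberately avoid the package's vectorized code paths.

# Pooled-variance t via the textbook formula, scalar arithmetic only.
oracle_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  d <- mean(a) - mean(b)
  sp <- sqrt(((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
               (n1 + n2 - 2))
  se <- sp * sqrt(1 / n1 + 1 / n2)
  if (se == 0) return(if (d == 0) 0 else sign(d) * Inf)
  d / se
}

oracle_m <- function(a, b) stats::median(a) - stats::median(b)

# Exhaustive per-gene permutation p-values by direct enumeration of all
# group-A subsets, one gene at a time.
oracle_perm_pergene <- function(mat, n_a, statistic = "t") {
  n <- ncol(mat)
  sets <- utils::combn(n, n_a)
  fn <- if (statistic == "t") oracle_t else oracle_m
  apply(mat, 1L, function(x) {
    obs <- fn(x[seq_len(n_a)], x[-seq_len(n_a)])
    cnt <- 0L
    for (j in seq_len(ncol(sets))) {
      ia <- sets[, j]
      s <- fn(x[ia], x[-ia])
      if (abs(s) >= abs(obs) - 1e-9) cnt <- cnt + 1L
    }
    cnt / ncol(sets)
  })
}

# Step-by-step Storey q-value recomputation (explicit double loop).
oracle_qvalues <- function(p, lambda = seq(0, 0.90, by = 0.05)) {
  n <- length(p)
  pi0_hat <- numeric(length(lambda))
  for (i in seq_along(lambda))
    pi0_hat[i] <- sum(p > lambda[i]) / ((1 - lambda[i]) * n)
  pi0 <- min(max(stats::median(pi0_hat), 1e-8), 1)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in i:n) best <- min(best, pi0 * n * ps[j] / j)
    q[i] <- min(best, 1)
  }
  out <- numeric(n)
  out[o] <- q
  out
}

# Hypergeometric upper tail P(X >= k) by enumerating every draw of size n
# from a universe of N with K marked elements.
oracle_hyper_tail <- function(N, K, n, k) {
  if (n == 0L) return(if (k <= 0L) 1 else 0)
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)   # elements 1..K are the marked ones
  mean(hits >= k)
}

# Closed first neighborhood of the seed set, via the adjacency matrix.
oracle_neighborhood <- function(edges, seeds) {
  nodes <- sort(unique(c(edges$from, edges$to, seeds)))
  A <- matrix(FALSE, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    A[edges$from[i], edges$to[i]] <- TRUE
    A[edges$to[i], edges$from[i]] <- TRUE
  }
  nb <- seeds
  for (s in intersect(seeds, nodes))
    nb <- union(nb, nodes[A[s, ]])
  sort(nb)
}

# DEG-adjacent neighbor count of one node, by scanning the edge table.
oracle_deg_degree <- function(net, node) {
  degs <- net$nodes$node[net$nodes$role == "deg"]
  cnt <- 0L
  for (i in seq_len(nrow(net$edges))) {
    f <- net$edges$from[i]; t <- net$edges$to[i]
    if (f == node && t %in% degs) cnt <- cnt + 1L
    if (t == node && f %in% degs) cnt <- cnt + 1L
  }
  cnt
}

# Random interaction_network for property tests.
random_network <- function(n_deg = 8L, n_other = 12L, p_edge = 0.15,
                           seed = 1L) {
  withr::with_seed(seed, {
    degs <- sprintf("D%02d", seq_len(n_deg))
    others <- sprintf("N%02d", seq_len(n_other))
    nodes <- c(degs, others)
    pairs <- utils::combn(nodes, 2L)
    pick <- stats::runif(ncol(pairs)) < p_edge
    edges <- data.frame(from = pairs[1L, pick], to = pairs[2L, pick],
                        kind = "pp", stringsAsFactors = FALSE)
    roles <- stats::setNames(rep(c("deg", "neighbor"), c(n_deg, n_other)),
                             nodes)
    interaction_network(edges, nodes = nodes, roles = roles)
  })
}
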