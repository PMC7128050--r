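# Independent brute-force oracles shared across test files. These are kept
# deliberately naive (loops, enumeration) so they do not share code paths
# with the implementation they check.

# upper-tail hypergeometric by explicit enumeration of the support
oracle_hyper_upper <- function(k, n_success, n_draw, n_pop) {
  if (k <= 0) return(1)
  js <- k:min(n_success, n_draw)
  sum(choose(n_success, js) * choose(n_pop - n_success, n_draw - js)) /
    choose(n_pop, n_draw)
}

# k-core of a graph given as an edge matrix, by iterative pruning
oracle_kcore_nodes <- function(edges, nodes, k) {
  repeat {
    deg <- table(factor(c(edges[, 1L], edges[, 2L]), levels = nodes))
    drop <- names(deg)[deg < k]
    if (!length(drop) || !length(nodes)) break
    nodes <- setdiff(nodes, drop)
    keep <- edges[, 1L] %in% nodes & edges[, 2L] %in% nodes
    edges <- edges[keep, , drop = FALSE]
  }
  list(nodes = nodes, edges = edges)
}

# MCODE vertex weight by brute force: highest k-core of the closed
# neighborhood, weight = k * density of that core subgraph
oracle_mcode_weight <- function(graph, v) {
  nb <- igraph::V(graph)$name[c(v, as.integer(igraph::neighbors(graph, v)))]
  el <- igraph::as_edgelist(graph)
  el <- el[el[, 1L] %in% nb & el[, 2L] %in% nb, , drop = FALSE]
  best_k <- 0L
  best <- NULL
  for (k in seq_len(length(nb))) {
    core <- oracle_kcore_nodes(el, nb, k)
    if (length(core$nodes) == 0L) break
    best_k <- k
    best <- core
  }
  n <- length(best$nodes)
  if (n < 2L) return(0)
  best_k * 2 * nrow(best$edges) / (n * (n - 1))
}

# inter-set edge count by a double loop over the edge list
oracle_inter_edges <- function(edges, a, b) {
  a_only <- setdiff(a, b)
  b_only <- setdiff(b, a)
  cnt <- 0L
  for (i in seq_len(nrow(edges))) {
    u <- edges[i, 1L]; v <- edges[i, 2L]
    if ((u %in% a_only && v %in% b_only) || (u %in% b_only && v %in% a_only)) {
      cnt <- cnt + 1L
    }
  }
  cnt
}

# SAM d statistic per feature by an explicit loop over the textbook formula
oracle_sam_d <- function(expr, labels, s0) {
  g <- as.factor(labels)
  a <- which(g == levels(g)[1L]); b <- which(g == levels(g)[2L])
  na <- length(a); nb <- length(b)
  vapply(seq_len(nrow(expr)), function(i) {
    xa <- expr[i, a]; xb <- expr[i, b]
    pooled <- (sum((xa - mean(xa))^2) + sum((xb - mean(xb))^2)) / (na + nb - 2)
    s <- sqrt((1 / na + 1 / nb) * pooled)
    (mean(xb) - mean(xa)) / (s + s0)
  }, 0)
}

# small random simple graph with named nodes
random_named_graph <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  g
}

# two named 6-cliques joined by a single bridge edge
two_cliques_bridge <- function(clique_size = 6) {
  g1 <- igraph::make_full_graph(clique_size)
  igraph::V(g1)$name <- paste0("a", seq_len(clique_size))
  g2 <- igraph::make_full_graph(clique_size)
  igraph::V(g2)$name <- paste0("b", seq_len(clique_size))
  g <- igraph::disjoint_union(g1, g2)
  igraph::add_edges(g, c(which(igraph::V(g)$name == "a1"),
                         which(igraph::V(g)$name == "b1")))
}

# compact default study for recovery tests
small_study <- function(seed, ...) {
  simulate_study(seed = seed, ...)
}
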