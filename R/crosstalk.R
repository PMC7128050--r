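#' Count inter-module edges
#'
#' Number of edges with one endpoint in `A` only and the other in `B` only.
#' Edges inside the overlap of the two modules are internal to both and are
#' not counted as crosstalk; each qualifying edge is counted once.
#'
#' @param ppi igraph network.
#' @param a,b character vectors of node ids (subsets of the network).
#' @return integer edge count.
#' @export
inter_module_edges <- function(ppi, a, b) {
  el <- igraph::as_edgelist(ppi)
  count_inter_edges(el, a, b)
}

# edge-list version shared with the permutation loop
count_inter_edges <- function(el, a, b) {
  a_only <- setdiff(a, b)
  b_only <- setdiff(b, a)
  u_in_a <- el[, 1L] %in% a_only
  v_in_a <- el[, 2L] %in% a_only
  u_in_b <- el[, 1L] %in% b_only
  v_in_b <- el[, 2L] %in% b_only
  sum((u_in_a & v_in_b) | (u_in_b & v_in_a))
}

#' Degree-preserving network randomization
#'
#' Runs a double-edge-swap Markov chain (`igraph::rewire` with
#' `keeping_degseq`) for `n_swaps` swap trials; trials that would create a
#' self-loop or multi-edge are rejected, so the output is a simple graph on
#' the same node set with every node's degree unchanged.
#'
#' @param ppi simple igraph network.
#' @param n_swaps number of swap trials (default 10 x edge count).
#' @param seed optional integer seed (`set.seed` is applied when given).
#' @return rewired igraph network.
#' @export
degree_preserving_randomize <- function(ppi, n_swaps = 10 * igraph::ecount(ppi),
                                        seed = NULL) {
  if (igraph::ecount(ppi) < 2L) {
    warnf("graph has fewer than 2 edges; returned unchanged")
    return(ppi)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  igraph::rewire(ppi, igraph::keeping_degseq(loops = FALSE, niter = n_swaps))
}

#' Permutation test for crosstalk between stage III and stage IV modules
#'
#' For every stage III x stage IV module pair, the real inter-module edge
#' count is compared with the counts in `n_random` degree-preserving
#' randomizations of the PPI. One shared ensemble of random networks is
#' used for all pairs. The empirical p-value is the fraction of random
#' networks whose count strictly exceeds the real one
#' (`P = sum(S_i) / N`, `S_i = 1` when the random count is more than the
#' real one), so a real count that nothing can exceed gives `P = 0`.
#' An optional pseudocount reports `(sum(S_i) + 1) / (N + 1)` instead.
#'
#' @param ppi igraph PPI network.
#' @param modules_iii,modules_iv module lists from [discover_modules()]
#'   (or any lists whose elements have `id` and `node_ids`).
#' @param n_random number of random networks (a warning below 100).
#' @param alpha significance level (significant when `p < alpha`).
#' @param n_swaps swap trials per randomization.
#' @param pseudocount use the `(r + 1) / (N + 1)` estimator.
#' @param seed integer seed.
#' @return `data.frame` with one row per pair: `module_III_id`,
#'   `module_IV_id`, `real_edges`, `p_value`, `significant`, plus the
#'   matrix of null counts as attribute `null_counts`.
#' @export
crosstalk_test <- function(ppi, modules_iii, modules_iv, n_random = 1000,
                           alpha = 0.05, n_swaps = 10 * igraph::ecount(ppi),
                           pseudocount = FALSE, seed = 1L) {
  if (n_random < 100) warnf("n_random < 100: p-value resolution is only 1/%d", n_random)
  nodes <- igraph::V(ppi)$name
  get_nodes <- function(m) intersect(m$node_ids, nodes)
  sets_iii <- lapply(modules_iii, get_nodes)
  sets_iv <- lapply(modules_iv, get_nodes)
  if (!all(vapply(modules_iii, function(m) all(m$node_ids %in% nodes), TRUE)) ||
      !all(vapply(modules_iv, function(m) all(m$node_ids %in% nodes), TRUE))) {
    stopf("module node sets must be subsets of the PPI node set")
  }
  pairs <- expand.grid(i = seq_along(sets_iii), j = seq_along(sets_iv))
  real <- mapply(function(i, j) {
    count_inter_edges(igraph::as_edgelist(ppi), sets_iii[[i]], sets_iv[[j]])
  }, pairs$i, pairs$j)

  set.seed(as.integer(seed))
  null_counts <- matrix(0L, nrow = nrow(pairs), ncol = n_random)
  for (b in seq_len(n_random)) {
    rg <- igraph::rewire(ppi, igraph::keeping_degseq(loops = FALSE, niter = n_swaps))
    el <- igraph::as_edgelist(rg)
    null_counts[, b] <- mapply(function(i, j) {
      count_inter_edges(el, sets_iii[[i]], sets_iv[[j]])
    }, pairs$i, pairs$j)
  }

  exceed <- rowSums(null_counts > real)
  p <- if (pseudocount) (exceed + 1) / (n_random + 1) else exceed / n_random
  out <- data.frame(
    module_III_id = vapply(modules_iii, `[[`, "", "id")[pairs$i],
    module_IV_id = vapply(modules_iv, `[[`, "", "id")[pairs$j],
    real_edges = as.integer(real),
    p_value = p,
    significant = p < alpha,
    stringsAsFactors = FALSE
  )
  attr(out, "null_counts") <- null_counts
  attr(out, "n_random") <- n_random
  out
}
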